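#' @keywords internal
#' @importFrom Rcpp sourceCpp
#' @useDynLib syndyn, .registration = TRUE
"_PACKAGE"

# Column schemas for the delimited-table dialects used across the pipeline.
.SCHEMAS <- list(
  curves = c("lag_s", "g", "variance"),
  bursts = c("event_id", "i_donor", "i_acceptor"),
  tau = c("protein", "construct", "ph", "tau_r_us", "sd_us"),
  et = c("protein", "construct", "ph", "eteff", "sd"),
  dynamics = c("protein", "construct", "ph", "tau_r_us", "sd_us", "eteff",
               "sd", "rms_raw", "rms", "rg", "rg_sd", "d_abs", "delta_d",
               "d_rel", "delta_d_rel", "tau_rec_s")
)

#' Validate a pipeline table against its schema
#'
#' @param table Data frame to validate.
#' @param schema One of `"curves"`, `"bursts"`, `"tau"`, `"et"`,
#'   `"dynamics"`.
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending columns.
#' @export
validate_table <- function(table, schema) {
  cols <- .SCHEMAS[[schema]]
  if (is.null(cols)) stop("unknown schema: ", schema, call. = FALSE)
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0) {
    stop("table does not match schema '", schema, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(cols, c("protein", "construct", "event_id"))
  for (cl in num_cols) {
    v <- table[[cl]]
    if (is.character(v) && any(grepl(",", v, fixed = TRUE))) {
      stop("column '", cl, "' contains decimal commas; write the file with ",
           "'.' as the decimal separator", call. = FALSE)
    }
    if (!is.numeric(v)) {
      stop("column '", cl, "' must be numeric", call. = FALSE)
    }
  }
  invisible(table)
}

#' Read a schema-validated pipeline table
#'
#' @param path CSV file path.
#' @param schema Schema name (see [validate_table()]).
#' @return A validated tibble.
#' @export
read_table_csv <- function(path, schema) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, schema)
  tibble::as_tibble(df)
}

#' Write a pipeline table, validating first
#'
#' @param table Table matching the schema.
#' @param path Output CSV path.
#' @param schema Schema name.
#' @export
write_table_csv <- function(table, path, schema) {
  validate_table(table, schema)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read or write an averaged correlation curve as CSV
#'
#' Columns `lag_s, g, variance`; one file per averaged measurement.
#'
#' @param path File path.
#' @param curve A `correlation_curve` (for writing).
#' @param n_acquisitions Acquisition count to attach on read.
#' @export
read_correlation_curve <- function(path, n_acquisitions = 1L) {
  df <- read_table_csv(path, "curves")
  correlation_curve(df$lag_s, df$g, df$variance, n_acquisitions)
}

#' @rdname read_correlation_curve
#' @export
write_correlation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  df <- data.frame(lag_s = curve$lags, g = curve$g,
                   variance = curve$variance)
  write_table_csv(df, path, "curves")
}

#' Bundled relaxation-time summary table
#'
#' The published per-construct TMR self-quenching relaxation times
#' (mean +/- SD, microseconds) at pH 7.4 and 3.5 for all twelve
#' protein/construct combinations. These are measured inputs (the raw
#' instrument data were not deposited), bundled as a typed fixture.
#'
#' @return Tibble with schema `tau`.
#' @export
syn_relaxation_times <- function() {
  read_table_csv(system.file("extdata", "relaxation_times.csv",
                             package = "syndyn"), "tau")
}

#' Bundled mean transfer-efficiency summary table
#'
#' The published per-construct mean ET_eff values (mean +/- SD) at pH 7.4
#' and 3.5; measured inputs, bundled as a typed fixture.
#'
#' @return Tibble with schema `et`.
#' @export
syn_transfer_efficiencies <- function() {
  read_table_csv(system.file("extdata", "transfer_efficiencies.csv",
                             package = "syndyn"), "et")
}

#' Published relative diffusion coefficients
#'
#' The published relative intrachain diffusion coefficients
#' (mean +/- standard error, normalized to the alphaS LF construct at
#' pH 7.4), bundled for comparison against values recomputed by
#' [derive_dynamics()]. Exact agreement is not expected: the published
#' values include an unpublished dye-linker correction to the chain
#' dimensions.
#'
#' @return Tibble: `protein`, `construct`, `ph`, `d_rel`, `se`.
#' @export
syn_published_drel <- function() {
  df <- utils::read.csv(system.file("extdata",
                                    "relative_diffusion_published.csv",
                                    package = "syndyn"),
                        stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' End-to-end report: dynamics table and property tables
#'
#' Regenerates the derived outputs of the analysis from the bundled (or
#' user-supplied) measurement tables: the relative-diffusion summary table,
#' a long table of physico-chemical properties joined with the dynamics
#' (including the betaS CT2 construct, which has sequence properties but no
#' tabulated measurement), a long table of properties joined with the
#' per-construct relaxation times and efficiencies, and a provenance block
#' recording every constant that entered the calculation. Deterministic:
#' no randomness is involved.
#'
#' @param tau_table Relaxation-time table (schema `tau`); default the
#'   bundled fixture.
#' @param et_table Efficiency table (schema `et`); default the bundled
#'   fixture.
#' @param chain A [gaussian_chain()] model.
#' @param config A [dynamics_config()].
#' @return List of class `syn_report`: `dynamics`, `properties_vs_dynamics`,
#'   `properties_vs_measurements`, `provenance`.
#' @export
syn_report <- function(tau_table = syn_relaxation_times(),
                       et_table = syn_transfer_efficiencies(),
                       chain = gaussian_chain(),
                       config = dynamics_config()) {
  if (nrow(et_table) == 0) stop("et_table is empty", call. = FALSE)
  if (nrow(tau_table) == 0) stop("tau_table is empty", call. = FALSE)
  dyn <- derive_dynamics(tau_table, et_table, chain, config)
  props <- construct_properties(ph = sort(unique(dyn$ph), decreasing = TRUE))
  names(props)[names(props) == "protein"] <- "protein"
  prop_dyn <- merge(props,
                    dyn[, c("protein", "construct", "ph", "d_rel",
                            "delta_d_rel", "tau_rec_s")],
                    by.x = c("protein", "construct", "ph"),
                    by.y = c("protein", "construct", "ph"), all.x = TRUE)
  prop_meas <- merge(props,
                     dyn[, c("protein", "construct", "ph", "tau_r_us",
                             "sd_us", "eteff", "sd")],
                     by = c("protein", "construct", "ph"), all.x = TRUE)
  provenance <- list(
    R0_angstrom = chain$R0, linker_mode = chain$linker_mode,
    linker_delta_angstrom = chain$linker_delta,
    contact_distance_angstrom = config$contact_distance,
    sss_constant = config$sss_constant,
    reference = config$reference,
    tau_rec_formula = if (is.function(config$tau_rec_formula)) {
      "custom function"
    } else {
      config$tau_rec_formula
    },
    error_mode = config$error_mode)
  structure(list(dynamics = dyn,
                 properties_vs_dynamics = tibble::as_tibble(prop_dyn),
                 properties_vs_measurements = tibble::as_tibble(prop_meas),
                 provenance = provenance),
            class = "syn_report")
}

#' @export
print.syn_report <- function(x, ...) {
  cat("<syn_report>\n")
  cat(sprintf("  dynamics: %d records (reference %s %s pH %s)\n",
              nrow(x$dynamics), x$provenance$reference$protein,
              x$provenance$reference$construct, x$provenance$reference$ph))
  cat(sprintf("  properties_vs_dynamics: %d rows\n",
              nrow(x$properties_vs_dynamics)))
  cat(sprintf("  R0 = %g A, a = %g A, linker = %s\n",
              x$provenance$R0_angstrom,
              x$provenance$contact_distance_angstrom,
              x$provenance$linker_mode))
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits `dynamics.csv`, `properties_vs_dynamics.csv`,
#' `properties_vs_measurements.csv` and `provenance.json`.
#'
#' @param report A [syn_report()] result.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "syn_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$dynamics, file.path(dir, "dynamics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$properties_vs_dynamics,
                   file.path(dir, "properties_vs_dynamics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$properties_vs_measurements,
                   file.path(dir, "properties_vs_measurements.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
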