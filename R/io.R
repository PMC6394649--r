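## Plain-text interchange: NONMEM-dialect dataset CSV, CWRES table CSV,
## and the JSON bias/correction report.

#' Read a NONMEM-style dataset CSV
#'
#' Expects columns `ID, TIME, AMT, DV, DVID, EVID, MDV` (EVID 1 = dose,
#' 0 = observation; MDV 1 = missing). Missing `DVID`, `MDV` or `AMT`
#' columns default to 1-DV, non-missing, zero-amount.
#'
#' @param path CSV file path.
#' @return data.frame in the package's dataset layout.
#' @export
read_nm_dataset <- function(path) {
  d <- utils::read.csv(path, na.strings = c("NA", "."))
  names(d) <- toupper(names(d))
  if (!all(c("ID", "TIME", "DV", "EVID") %in% names(d)))
    stop("dataset must contain ID, TIME, DV, EVID")
  d$DV <- as.numeric(d$DV)
  if (is.null(d$DVID)) d$DVID <- 1L
  if (is.null(d$MDV)) d$MDV <- ifelse(d$EVID == 0, 0L, 1L)
  if (is.null(d$AMT)) d$AMT <- 0
  d[c("ID", "TIME", "AMT", "DV", "DVID", "EVID", "MDV")]
}

#' Write a dataset CSV
#' @param data dataset data.frame.
#' @param path output path.
#' @export
write_nm_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = ".")
  invisible(path)
}

#' Write / read a CWRES table CSV
#' @param cwres a `cwres_table` from [compute_cwres()].
#' @param path file path.
#' @export
write_cwres_table <- function(cwres, path) {
  utils::write.csv(as.data.frame(cwres), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cwres_table
#' @export
read_cwres_table <- function(path) {
  tab <- utils::read.csv(path)
  class(tab) <- c("cwres_table", "data.frame")
  attr(tab, "dv_labels") <- sub("^PRED_", "", grep("^PRED_", names(tab),
                                                   value = TRUE))
  tab
}

## Serialize a bin_spec for the JSON report.
binspec_json <- function(bins) {
  list(idv = bins$idv_name, boundaries = bins$boundaries,
       n_bins = bins$n_bins, min_per_bin = bins$min_per_bin)
}

#' Write the bias-analysis report
#'
#' JSON bundle holding, per (DV x IDV) combination: the bin specification,
#' bin means `b`, `Omega`, `Sigma`, both OFVs, `dOFV_bias`, the chi-square
#' critical value and significance flag, and when available the binned
#' `delta`, `%delta` and percent known bias. The run seed, configuration
#' and package version are embedded.
#'
#' @param qa a `cwres_qa` object from [run_qa()].
#' @param path output `.json` path.
#' @export
write_bias_report <- function(qa, path) {
  rep_one <- function(cell) {
    out <- list(
      dv = cell$dv, idv = cell$idv,
      bins = binspec_json(cell$bins),
      b = cell$extended$means,
      omega = cell$extended$omega, sigma = cell$extended$sigma,
      ofv_base = cell$test$ofv_base, ofv_extended = cell$test$ofv_extended,
      delta_ofv_bias = cell$test$delta_ofv, df = cell$test$df,
      critical_value = cell$test$critical_value,
      significant = cell$test$significant)
    if (!is.null(cell$correction)) out$binned <- cell$correction$binned
    if (!is.null(cell$known)) out$pct_known_bias <- cell$known$binned
    out
  }
  payload <- list(package = "cwresbias",
                  version = as.character(utils::packageVersion("cwresbias")),
                  seed = qa$seed, config = qa$config,
                  summary = qa$summary,
                  cells = lapply(qa$cells, rep_one))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
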