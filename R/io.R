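# Delimited-text interchange. Traces travel as long CSV (roi_id, time_s,
# fluorescence) with a YAML epoch sidecar (window name -> [start_s, end_s]);
# trial amplitudes as CSV (condition, bouton_id, trial_id, amplitude).

#' Write traces to CSV with a YAML epoch sidecar
#'
#' @param traces a \linkS4class{Trace} or list of them.
#' @param path output CSV path.
#' @param epochPath optional YAML sidecar path; defaults to \code{path}
#'   with extension \code{.epochs.yaml}. Epochs of the first trace are
#'   written (one acquisition protocol per file).
#' @return invisibly, the CSV path.
#' @export
writeTraceCsv <- function(traces, path, epochPath = NULL) {
  if (is(traces, "Trace")) traces <- list(traces)
  d <- do.call(rbind, lapply(traces, function(tr)
    data.frame(roi_id = roiId(tr), time_s = traceTime(tr),
               fluorescence = traceFluorescence(tr),
               stringsAsFactors = FALSE)))
  write.csv(d, path, row.names = FALSE)
  ep <- epochs(traces[[1]])
  if (length(ep)) {
    if (is.null(epochPath))
      epochPath <- sub("\\.csv$", "", path, ignore.case = TRUE)
    if (!grepl("\\.ya?ml$", epochPath))
      epochPath <- paste0(epochPath, ".epochs.yaml")
    yaml::write_yaml(lapply(ep, as.numeric), epochPath)
  }
  invisible(path)
}

#' Read traces from CSV (+ optional YAML epoch sidecar)
#'
#' @param path CSV with columns \code{roi_id}, \code{time_s},
#'   \code{fluorescence}.
#' @param epochPath optional epoch sidecar; auto-detected next to
#'   \code{path} when present.
#' @return list of \linkS4class{Trace} objects, one per ROI.
#' @export
readTraceCsv <- function(path, epochPath = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "time_s", "fluorescence")
  if (!all(need %in% names(d)))
    .stopParam("trace CSV '", path, "' needs columns: ",
               paste(need, collapse = ", "))
  if (is.null(epochPath)) {
    cand <- paste0(sub("\\.csv$", "", path, ignore.case = TRUE),
                   ".epochs.yaml")
    if (file.exists(cand)) epochPath <- cand
  }
  ep <- if (!is.null(epochPath))
    lapply(yaml::read_yaml(epochPath), as.numeric) else list()
  lapply(split(d, d$roi_id), function(s)
    Trace(s$time_s, s$fluorescence, epochs = ep, roiId = s$roi_id[1]))
}

#' Write a TrialTable to CSV
#'
#' @param table a \linkS4class{TrialTable}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeTrialTable <- function(table, path) {
  stopifnot(is(table, "TrialTable"))
  write.csv(trialData(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a TrialTable from CSV
#'
#' @param path CSV with columns \code{condition}, \code{bouton_id},
#'   \code{trial_id}, \code{amplitude}.
#' @return A \linkS4class{TrialTable}.
#' @export
readTrialTable <- function(path) {
  if (!file.exists(path)) .stopValidation("trials file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "bouton_id", "trial_id", "amplitude")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .stopValidation("trials CSV '", path, "' is missing column(s): ",
               paste(miss, collapse = ", "))
  TrialTable(d)
}
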