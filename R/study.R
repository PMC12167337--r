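#' Read a reader-study angulation table
#'
#' CSV with columns `sample, participant, modality, angle_deg`; an empty
#' `angle_deg` field is the no-fracture marker (the reader judged the image
#' healthy). Modalities are `"POCUS"` (merged ultrasound) and `"XRAY"`.
#'
#' @param path CSV file.
#' @return A data frame of class `reading_table` with `angle_deg` numeric
#'   (`NA` = no-fracture marker).
#' @export
read_reading_table <- function(path) {
  if (!file.exists(path)) stop("cannot read readings: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(angle_deg = "character"))
  reading_table(df)
}

#' @rdname read_reading_table
#' @param df Data frame with columns `sample, participant, modality,
#'   angle_deg`.
#' @export
reading_table <- function(df) {
  need <- c("sample", "participant", "modality", "angle_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("readings table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("readings table is empty")
  df$angle_deg <- suppressWarnings(as.numeric(ifelse(trimws(df$angle_deg) == "",
                                                     NA, df$angle_deg)))
  df$modality <- toupper(df$modality)
  bad <- !df$modality %in% c("POCUS", "XRAY")
  if (any(bad)) stop("unknown modality in row(s) ", paste(which(bad), collapse = ", "))
  df <- df[order(df$sample, df$participant, df$modality), ]
  rownames(df) <- NULL
  class(df) <- c("reading_table", "data.frame")
  df
}

#' Per-sample reference angulation from the X-ray readings
#'
#' The reference for each sample is the mean of the participants' X-ray
#' readings, with the no-fracture marker valued 0 degrees, rounded to one
#' decimal. A sample whose X-ray readings are all no-fracture keeps the
#' marker (`NA`): it carries a no-fracture reference and is excluded from
#' error statistics.
#'
#' @param tbl A [reading_table()].
#' @return Named numeric vector of references (degrees; `NA` =
#'   no-fracture), one per sample.
#' @export
reference_angulation <- function(tbl) {
  stopifnot(inherits(tbl, "reading_table"))
  xr <- tbl[tbl$modality == "XRAY", ]
  if (!nrow(xr)) stop("readings table has no X-ray modality")
  sp <- split(xr$angle_deg, xr$sample)
  vapply(sp, function(a) {
    if (all(is.na(a))) NA_real_
    else round(mean(ifelse(is.na(a), 0, a)), 1)
  }, numeric(1))
}

#' Mean absolute error of each participant and modality against the reference
#'
#' Samples with a no-fracture reference are excluded; within the remaining
#' samples a no-fracture reading is valued 0 degrees. References are taken
#' rounded to one decimal (as tabulated) and MAEs are reported to one
#' decimal.
#'
#' @param tbl A [reading_table()].
#' @param refs Output of [reference_angulation()]; recomputed when `NULL`.
#' @return Data frame with columns `participant, modality, mae`.
#' @export
mae <- function(tbl, refs = NULL) {
  stopifnot(inherits(tbl, "reading_table"))
  if (is.null(refs)) refs <- reference_angulation(tbl)
  keep <- names(refs)[!is.na(refs)]
  d <- tbl[as.character(tbl$sample) %in% keep, ]
  d$ref <- refs[as.character(d$sample)]
  d$err <- abs(ifelse(is.na(d$angle_deg), 0, d$angle_deg) - d$ref)
  agg <- stats::aggregate(err ~ participant + modality, data = d, FUN = mean)
  agg$mae <- round(agg$err, 1)
  agg$err <- NULL
  agg[order(agg$participant, agg$modality), ]
}

#' Mean POCUS-minus-X-ray MAE discrepancy across participants
#'
#' @param maes Output of [mae()] (all participant x modality cells present).
#' @return Degrees, one decimal.
#' @export
mean_discrepancy <- function(maes) {
  po <- maes$mae[maes$modality == "POCUS"][order(maes$participant[maes$modality == "POCUS"])]
  xr <- maes$mae[maes$modality == "XRAY"][order(maes$participant[maes$modality == "XRAY"])]
  if (length(po) != length(xr) || !length(po)) stop("need matching POCUS and X-ray MAEs")
  round(mean(po - xr), 1)
}

#' Pooled Pearson correlation between absolute errors and reference angulation
#'
#' Absolute errors of one modality's readings against the (rounded)
#' references, pooled over participants and fracture-reference samples, are
#' correlated with the corresponding repeated reference values. A low
#' correlation indicates that alignment error does not grow with fracture
#' severity.
#'
#' @param tbl A [reading_table()].
#' @param refs Optional precomputed references.
#' @param modality `"POCUS"` (default) or `"XRAY"`.
#' @return Pearson correlation coefficient.
#' @export
pooled_pearson <- function(tbl, refs = NULL, modality = "POCUS") {
  stopifnot(inherits(tbl, "reading_table"))
  if (is.null(refs)) refs <- reference_angulation(tbl)
  keep <- names(refs)[!is.na(refs)]
  if (length(unique(refs[keep])) < 2) stop("need >= 2 distinct reference values")
  d <- tbl[tbl$modality == toupper(modality) & as.character(tbl$sample) %in% keep, ]
  x <- refs[as.character(d$sample)]
  y <- abs(ifelse(is.na(d$angle_deg), 0, d$angle_deg) - x)
  if (stats::sd(y) == 0) stop("zero variance in absolute errors: correlation undefined")
  stats::cor(x, y)
}

#' Mean classification accuracy of a modality across participants
#'
#' @param acc Data frame with columns `participant, modality, accuracy`
#'   (per-reader fracture-classification accuracies against the
#'   majority-vote ground truth), e.g. from [read_accuracy_table()].
#' @param modality `"POCUS"` or `"XRAY"`.
#' @return Mean accuracy, two decimals.
#' @export
mean_accuracy <- function(acc, modality) {
  need <- c("participant", "modality", "accuracy")
  if (!all(need %in% names(acc))) stop("accuracy table lacks column(s)")
  a <- acc$accuracy[toupper(acc$modality) == toupper(modality)]
  if (!length(a)) stop("no accuracies for modality ", modality)
  round(mean(a), 2)
}

#' Read a per-participant accuracy table
#' @param path CSV with columns `participant, modality, accuracy`.
#' @export
read_accuracy_table <- function(path) {
  if (!file.exists(path)) stop("cannot read accuracies: no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Majority vote over three fracture labels
#'
#' @param labels Character vector of three labels from `{B, G, N}` (buckle,
#'   greenstick, none).
#' @return The label occurring at least twice; an error when all three
#'   differ.
#' @export
majority_vote <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) != 3 || !all(labels %in% c("B", "G", "N")))
    stop("need exactly three labels from {B, G, N}")
  tab <- sort(table(labels), decreasing = TRUE)
  if (tab[1] < 2) stop("no majority among labels ", paste(labels, collapse = ", "))
  names(tab)[1]
}

#' Run the full morphology-study report
#'
#' Computes per-sample reference angulations, per-participant MAEs for both
#' modalities, the mean POCUS-minus-X-ray discrepancy, the pooled Pearson
#' correlation of POCUS errors with reference angulation, and (when an
#' accuracy table is given) the mean classification accuracy per modality.
#'
#' @param readings A [reading_table()] or path to its CSV.
#' @param accuracies Optional accuracy data frame or CSV path.
#' @param out Optional path: write the report as JSON.
#' @return The report as a list (class `study_report`).
#' @export
run_study <- function(readings, accuracies = NULL, out = NULL) {
  tbl <- if (is.character(readings)) read_reading_table(readings) else reading_table(readings)
  refs <- reference_angulation(tbl)
  maes <- mae(tbl, refs)
  report <- list(
    reference_deg = as.list(refs),
    mae_deg = maes,
    mean_discrepancy_deg = mean_discrepancy(maes),
    pearson_pocus_error_vs_reference = round(pooled_pearson(tbl, refs), 2))
  if (!is.null(accuracies)) {
    acc <- if (is.character(accuracies)) read_accuracy_table(accuracies) else accuracies
    report$mean_accuracy <- list(POCUS = mean_accuracy(acc, "POCUS"),
                                 XRAY = mean_accuracy(acc, "XRAY"))
  }
  class(report) <- "study_report"
  if (!is.null(out)) {
    rep_json <- report
    rep_json$mae_deg <- as.list(stats::setNames(
      maes$mae, paste(maes$participant, maes$modality, sep = "_")))
    class(rep_json) <- NULL
    writeLines(as.character(jsonlite::toJSON(rep_json, auto_unbox = TRUE,
                                             digits = I(10), pretty = TRUE, na = "null")),
               out)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Morphology study report\n  references (deg):",
      paste(sprintf("%s=%s", names(x$reference_deg),
                    vapply(x$reference_deg, function(v)
                      if (is.na(v)) "-" else sprintf("%.1f", v), character(1))),
            collapse = " "), "\n")
  m <- x$mae_deg
  cat("  MAE (deg):", paste(sprintf("P%s/%s=%.1f", m$participant, m$modality, m$mae),
                            collapse = " "), "\n")
  cat(sprintf("  mean discrepancy: %.1f deg\n", x$mean_discrepancy_deg))
  cat(sprintf("  Pearson r (POCUS |err| vs reference): %.2f\n",
              x$pearson_pocus_error_vs_reference))
  if (!is.null(x$mean_accuracy))
    cat(sprintf("  mean accuracy: POCUS %.2f, X-ray %.2f\n",
                x$mean_accuracy$POCUS, x$mean_accuracy$XRAY))
  invisible(x)
}
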