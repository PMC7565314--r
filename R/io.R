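#' Path to the packaged study table
#'
#' A verbatim transcription of the published per-sample sequencing summary:
#' 59 patient rows and 7 negative-control rows, with both platforms' raw
#' read counts, percentage of reads classified, genera identified at >= 1%
#' and inverse Simpson index, plus the printed Average row. Thousands
#' separators are stripped, "NA" marks not-applicable entries, and the
#' printed below-cutoff footnote marks are preserved as an annotation
#' column (`below_cutoff_mark`) exactly where they were printed -- including
#' the row whose printed read count is above the cut-off; computations use
#' the counts, never the marks.
#'
#' @return file path of the CSV.
#' @export
studyTablePath <- function() {
  system.file("extdata", "study_table.csv", package = "nano16S", mustWork = TRUE)
}

#' Load the study table
#'
#' @param file CSV path (defaults to the packaged fixture).
#' @return data.frame with typed columns; `row_type` distinguishes
#'   `patient`, `average` (the printed Average row) and `control` rows.
#'   `copies_16s` stays character ("<1e+02" entries are not numbers).
#' @export
loadStudyTable <- function(file = studyTablePath()) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = c(sample = "character",
                                        copies_16s = "character"))
  need <- c("sample", "row_type", "infection", "age_years", "copies_16s",
            "ill_raw_reads", "ill_pct_classified", "ill_genera_1pct", "ill_isi",
            "np_raw_reads", "np_pct_classified", "np_genera_1pct", "np_isi",
            "below_cutoff_mark")
  if (!all(need %in% names(tab)))
    stop("study table missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  for (col in c("ill_pct_classified", "np_pct_classified")) {
    bad <- !is.na(tab[[col]]) & (tab[[col]] < 0 | tab[[col]] > 100)
    if (any(bad))
      stop("malformed row ", tab$sample[bad][1], ": ", col, " outside [0, 100]")
  }
  numCols <- c("age_years", "ill_raw_reads", "ill_pct_classified",
               "ill_genera_1pct", "ill_isi", "np_raw_reads",
               "np_pct_classified", "np_genera_1pct", "np_isi")
  for (col in numCols)
    if (!is.numeric(tab[[col]]))
      stop("malformed study table: non-numeric values in ", col)
  tab
}

#' @describeIn loadStudyTable the 59 patient rows.
#' @param table a loaded study table.
#' @export
patientRows <- function(table) table[table$row_type == "patient", , drop = FALSE]

#' @describeIn loadStudyTable the 7 negative-control rows.
#' @export
controlRows <- function(table) table[table$row_type == "control", , drop = FALSE]

#' @describeIn loadStudyTable the printed Average row (one row).
#' @export
averageRow <- function(table) table[table$row_type == "average", , drop = FALSE]

#' Column summaries of the study table
#'
#' Arithmetic summaries with the table's own rounding conventions. The
#' subset rule "patients" uses all patient rows; "patients_with_value"
#' drops not-applicable entries first (the convention of the nanopore
#' diversity columns, where below-cutoff samples carry NA); "controls" uses
#' the negative-control rows.
#'
#' @param table a loaded study table.
#' @param column a numeric column name.
#' @param subset one of "patients", "patients_with_value", "controls".
#' @param stat one of "mean", "max", "min", "count_below".
#' @param threshold threshold for `stat = "count_below"` (strictly below).
#' @param digits rounding digits for mean (default no rounding).
#' @return the summary value.
#' @export
summarizeColumns <- function(table, column,
                             subset = c("patients", "patients_with_value", "controls"),
                             stat = c("mean", "max", "min", "count_below"),
                             threshold = NULL, digits = NULL) {
  subset <- match.arg(subset)
  stat <- match.arg(stat)
  rows <- if (subset == "controls") controlRows(table) else patientRows(table)
  x <- rows[[column]]
  if (is.null(x)) stop("unknown column: ", column)
  if (subset == "patients_with_value") x <- x[!is.na(x)]
  if (!length(x) || all(is.na(x))) stop("empty subset for column ", column)
  val <- switch(stat,
                mean = mean(x),
                max = max(x),
                min = min(x),
                count_below = {
                  if (is.null(threshold)) stop("count_below needs a threshold")
                  sum(x < threshold)
                })
  if (!is.null(digits) && stat == "mean") val <- round(val, digits)
  val
}

#' Recompute the Average row from the per-sample rows
#'
#' Applies each printed column's rounding: whole numbers for read counts
#' and percentages, one decimal for age, genera counts and inverse Simpson.
#' Columns whose printed not-applicable entries must be dropped first
#' (nanopore genera and ISI) use the patients-with-value subset.
#'
#' @param table a loaded study table.
#' @return named numeric vector over the nine recomputable Average columns.
#' @export
recomputeAverageRow <- function(table) {
  c(age_years = summarizeColumns(table, "age_years", "patients", "mean", digits = 1),
    ill_raw_reads = round(summarizeColumns(table, "ill_raw_reads", "patients", "mean")),
    ill_pct_classified = round(summarizeColumns(table, "ill_pct_classified", "patients", "mean")),
    ill_genera_1pct = summarizeColumns(table, "ill_genera_1pct", "patients", "mean", digits = 1),
    ill_isi = summarizeColumns(table, "ill_isi", "patients", "mean", digits = 1),
    np_raw_reads = round(summarizeColumns(table, "np_raw_reads", "patients", "mean")),
    np_pct_classified = round(summarizeColumns(table, "np_pct_classified", "patients", "mean")),
    np_genera_1pct = summarizeColumns(table, "np_genera_1pct", "patients_with_value", "mean", digits = 1),
    np_isi = summarizeColumns(table, "np_isi", "patients_with_value", "mean", digits = 1))
}

#' Build a study-table-shaped run report from two platforms' summaries
#'
#' @param illumina,nanopore data.frames from [sampleSummary()] (columns
#'   sample, rawReads, pctClassified, generaAtLeast1pct, inverseSimpson)
#'   sharing sample ids.
#' @param file optional CSV output path; a JSON sidecar with the Average row
#'   is written next to it as `<file>.json`.
#' @return data.frame with one row per sample plus an `Average` row.
#' @export
runReport <- function(illumina, nanopore, file = NULL) {
  if (!nrow(illumina) || !nrow(nanopore)) stop("empty summaries")
  orphans <- c(setdiff(illumina$sample, nanopore$sample),
               setdiff(nanopore$sample, illumina$sample))
  if (length(orphans))
    stop("sample id mismatch, orphans: ", paste(unique(orphans), collapse = ", "))
  m <- merge(illumina, nanopore, by = "sample", suffixes = c("_ill", "_np"))
  m <- m[order(match(m$sample, illumina$sample)), , drop = FALSE]
  avg <- data.frame(sample = "Average",
                    rawReads_ill = round(mean(m$rawReads_ill)),
                    pctClassified_ill = round(mean(m$pctClassified_ill)),
                    generaAtLeast1pct_ill = round(mean(m$generaAtLeast1pct_ill, na.rm = TRUE), 1),
                    inverseSimpson_ill = round(mean(m$inverseSimpson_ill, na.rm = TRUE), 1),
                    rawReads_np = round(mean(m$rawReads_np)),
                    pctClassified_np = round(mean(m$pctClassified_np)),
                    generaAtLeast1pct_np = round(mean(m$generaAtLeast1pct_np, na.rm = TRUE), 1),
                    inverseSimpson_np = round(mean(m$inverseSimpson_np, na.rm = TRUE), 1),
                    stringsAsFactors = FALSE)
  out <- rbind(m[names(avg)], avg)
  rownames(out) <- NULL
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(as.list(avg), paste0(file, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
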