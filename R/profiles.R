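#' Build a genus-abundance profile from counts
#'
#' Normalizes genus counts to relative abundances in percent of classified
#' reads (summing to 100). A zero total yields an empty profile, mirroring
#' samples below the read cut-off whose diversity is reported as NA.
#'
#' @param counts named non-negative numeric vector (genus -> read count), or
#'   a data.frame with columns `genus` and `count`.
#' @param sampleId sample identifier.
#' @return a [GenusProfile-class] object.
#' @examples
#' buildProfile(c(A = 1, B = 2, C = 1), "s1")   # 25 / 50 / 25 %
#' @export
buildProfile <- function(counts, sampleId = "sample") {
  if (is.data.frame(counts))
    counts <- stats::setNames(counts$count, counts$genus)
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) stop("negative count in genus table")
  total <- sum(counts)
  ab <- if (total > 0) 100 * counts[counts > 0] / total else stats::setNames(numeric(0), character(0))
  new("GenusProfile", sampleId = as.character(sampleId),
      nClassified = as.numeric(total), abundance = ab)
}

#' @describeIn buildProfile genus -> relative abundance (%) vector.
#' @param profile a [GenusProfile-class] object.
#' @export
abundance <- function(profile) profile@abundance

#' @describeIn buildProfile sample identifier.
#' @export
sampleId <- function(profile) profile@sampleId

#' @describeIn buildProfile number of classified reads behind the profile.
#' @export
nClassified <- function(profile) profile@nClassified

#' Genus profile from filtered per-read classification records
#'
#' Resolves each record's taxid to its genus-rank ancestor and counts reads
#' per genus. Records whose taxid has no genus ancestor are counted under
#' their reported name when present (family fallback), else dropped.
#'
#' @param records data.frame of (filtered) read classification records.
#' @param tax a [Taxonomy-class] object.
#' @param sampleId sample identifier.
#' @param useGenusOfTaxid when TRUE (default) family-fallback records still
#'   contribute to their top-taxid genus, reproducing the re-inclusion of
#'   num_genus_taxid = 2 reads; when FALSE they are tallied under the family
#'   name.
#' @return a [GenusProfile-class] object.
#' @export
profileFromRecords <- function(records, tax, sampleId = "sample",
                               useGenusOfTaxid = TRUE) {
  if (!nrow(records)) return(buildProfile(numeric(0), sampleId))
  genus <- vapply(records$taxid, function(tid) {
    g <- ancestorAtRank(tax, tid, "genus")
    if (is.na(g)) NA_character_ else nameOf(tax, g)
  }, character(1))
  if (!useGenusOfTaxid)
    genus <- ifelse(records$num_genus_taxid == 1L, genus, records$name)
  genus[is.na(genus)] <- records$name[is.na(genus)]
  genus <- genus[!is.na(genus)]
  buildProfile(c(table(genus)), sampleId)
}

#' Observed genera at or above an abundance threshold
#'
#' @param profile a [GenusProfile-class] object.
#' @param threshold abundance threshold in percent, inclusive (default 1).
#' @return count of genera with abundance >= threshold.
#' @export
observedGenera <- function(profile, threshold = 1) {
  sum(profile@abundance >= threshold)
}

#' Inverse Simpson index of a genus profile
#'
#' \eqn{1 / \sum_g p_g^2} with proportions \eqn{p_g} = abundance / 100.
#' Ranges from 1 (monodominant) to the number of genera (uniform). Undefined
#' for an empty profile, returned as `NA` to mirror the study table.
#'
#' @param profile a [GenusProfile-class] object.
#' @return the index, or `NA_real_` for an empty profile.
#' @export
inverseSimpson <- function(profile) {
  p <- profile@abundance / 100
  if (!length(p)) return(NA_real_)
  1 / sum(p^2)
}

#' Shannon diversity of a count vector
#'
#' \eqn{-\sum p \log_b p} over nonzero proportions; base 2 by default for
#' comparability with the QIIME-era metric.
#'
#' @param counts non-negative counts (or abundances), total > 0.
#' @param base logarithm base (default 2).
#' @return the Shannon index.
#' @export
shannonIndex <- function(counts, base = 2) {
  counts <- counts[!is.na(counts) & counts > 0]
  if (!sum(counts)) stop("Shannon index undefined for zero total")
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Rarefaction curve of mean Shannon diversity
#'
#' For each requested depth, subsamples the reads without replacement
#' `repetitions` times and averages the Shannon index, to assess how many
#' reads are needed before diversity saturates.
#'
#' @param counts named genus counts for one sample.
#' @param depths integer depths, each <= total reads.
#' @param repetitions subsamples per depth (>= 1).
#' @param seed RNG seed (the generator state is restored afterwards).
#' @param base Shannon logarithm base.
#' @return data.frame with columns depth and meanShannon.
#' @export
rarefactionCurve <- function(counts, depths, repetitions = 10, seed = 1, base = 2) {
  counts <- round(counts[counts > 0])
  total <- sum(counts)
  if (any(depths > total)) stop("depth exceeds total reads (", total, ")")
  pool <- rep(names(counts), times = counts)
  withr::with_seed(seed, {
    mean_sh <- vapply(depths, function(d) {
      mean(vapply(seq_len(repetitions), function(r) {
        sub <- sample(pool, d, replace = FALSE)
        shannonIndex(c(table(sub)), base = base)
      }, numeric(1)))
    }, numeric(1))
  })
  data.frame(depth = depths, meanShannon = mean_sh)
}

#' Apply the minimum-read cut-off to sample summaries
#'
#' Samples with fewer than `cutoff` raw reads are excluded from downstream
#' analysis (the rarefaction-motivated 500-read rule; strictly-below
#' exclusion reproduces the published 2-of-59 count).
#'
#' @param summaries data.frame with columns `sample` and `rawReads`.
#' @param cutoff minimum raw reads (default 500).
#' @return list with `included` and `excluded` data.frames.
#' @export
applyReadCutoff <- function(summaries, cutoff = 500) {
  if (!nrow(summaries))
    return(list(included = summaries, excluded = summaries))
  drop <- summaries$rawReads < cutoff
  list(included = summaries[!drop, , drop = FALSE],
       excluded = summaries[drop, , drop = FALSE])
}

#' Prevalence of a genus across profiles
#'
#' @param profiles list of [GenusProfile-class] objects.
#' @param genus genus name.
#' @param threshold abundance threshold in percent, inclusive (default 1).
#' @return named integer vector c(present, total).
#' @export
prevalence <- function(profiles, genus, threshold = 1) {
  present <- vapply(profiles, function(p) {
    ab <- p@abundance[genus]
    !is.na(ab) && ab >= threshold
  }, logical(1))
  c(present = sum(present), total = length(profiles))
}

#' Sample summary in study-table shape
#'
#' @param profile a [GenusProfile-class] object.
#' @param rawReads raw read count for the sample (>= classified reads).
#' @return one-row data.frame: sample, rawReads, pctClassified,
#'   generaAtLeast1pct, inverseSimpson.
#' @export
sampleSummary <- function(profile, rawReads) {
  empty <- length(profile@abundance) == 0L
  data.frame(sample = profile@sampleId,
             rawReads = rawReads,
             pctClassified = if (rawReads > 0) 100 * profile@nClassified / rawReads else 0,
             generaAtLeast1pct = if (empty) NA_integer_ else observedGenera(profile),
             inverseSimpson = inverseSimpson(profile),
             stringsAsFactors = FALSE)
}

#' Assemble profiles into a samples-by-genera abundance matrix
#'
#' @param profiles list of [GenusProfile-class] objects.
#' @return numeric matrix, rows = samples, columns = union of genera,
#'   missing genera 0.
#' @export
profileMatrix <- function(profiles) {
  genera <- sort(unique(unlist(lapply(profiles, function(p) names(p@abundance)))))
  m <- matrix(0, nrow = length(profiles), ncol = length(genera),
              dimnames = list(vapply(profiles, sampleId, character(1)), genera))
  for (i in seq_along(profiles)) {
    ab <- profiles[[i]]@abundance
    m[i, names(ab)] <- ab
  }
  m
}

#' Read / write genus profile tables
#'
#' Wide CSV: rows are samples (first column `sample`), remaining columns
#' genus abundances in percent. `readProfiles` re-normalizes each row
#' through [buildProfile()] so stored rounding cannot break the sum-to-100
#' invariant.
#'
#' @param file CSV path.
#' @return `readProfiles`: named list of [GenusProfile-class] objects.
#' @export
readProfiles <- function(file) {
  tab <- utils::read.csv(file, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  stopifnot(names(tab)[1] == "sample")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    v <- as.numeric(tab[i, -1])
    names(v) <- names(tab)[-1]
    buildProfile(v[!is.na(v) & v > 0], tab$sample[i])
  })
  stats::setNames(out, tab$sample)
}

#' @rdname readProfiles
#' @param profiles list of [GenusProfile-class] objects.
#' @param comment optional provenance string written as a leading `#` line.
#' @export
writeProfiles <- function(profiles, file, comment = NULL) {
  m <- profileMatrix(profiles)
  con <- base::file(file, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(data.frame(sample = rownames(m), m, check.names = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(file)
}
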