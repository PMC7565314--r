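#' Parse a BLAST tabular (outfmt 6) hit table
#'
#' Reads a tab-separated BLAST outfmt-6 table and returns one row per hit
#' with canonical column names, ordered within each read by descending bit
#' score, ties broken by smaller e-value, then smaller subject taxid. The
#' default column layout is the standard 12 outfmt-6 fields with
#' `staxid`, `nident` and `qlen` appended (15 columns); `columnMap` remaps
#' any of the required fields to other column positions.
#'
#' @param file path to the TSV (or a connection). Lines starting with `#`
#'   are ignored.
#' @param columnMap named integer vector giving 1-based column positions for
#'   `qseqid`, `pident`, `evalue`, `bitscore`, `staxid`, `nident`, `qlen`.
#' @return data.frame with columns read_id, taxid, pident, nident, qlen,
#'   evalue, bitscore, sorted by read then hit rank. Empty input gives a
#'   zero-row frame.
#' @export
parseOutfmt6 <- function(file,
                         columnMap = c(qseqid = 1L, pident = 3L, evalue = 11L,
                                       bitscore = 12L, staxid = 13L,
                                       nident = 14L, qlen = 15L)) {
  need <- c("qseqid", "pident", "evalue", "bitscore", "staxid", "nident", "qlen")
  if (!all(need %in% names(columnMap)))
    stop("columnMap must name: ", paste(need, collapse = ", "))
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(read_id = character(), taxid = integer(),
                      pident = numeric(), nident = numeric(), qlen = numeric(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  maxCol <- max(columnMap)
  short <- lengths(parts) < maxCol
  if (any(short))
    stop("line ", which(short)[1], ": expected at least ", maxCol, " columns")
  getCol <- function(i) vapply(parts, `[[`, character(1), i)
  num <- function(field) {
    raw <- getCol(columnMap[[field]])
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val))
      stop("line ", which(is.na(val))[1], ": non-numeric ", field,
           " value '", raw[which(is.na(val))[1]], "'")
    val
  }
  hits <- data.frame(read_id = getCol(columnMap[["qseqid"]]),
                     taxid = as.integer(num("staxid")),
                     pident = num("pident"),
                     nident = num("nident"),
                     qlen = num("qlen"),
                     evalue = num("evalue"),
                     bitscore = num("bitscore"),
                     stringsAsFactors = FALSE)
  if (any(hits$nident > hits$qlen))
    stop("identical matches exceed query length at line ",
         which(hits$nident > hits$qlen)[1])
  # stable order: reads in first-appearance order, hits by score
  readOrder <- match(hits$read_id, unique(hits$read_id))
  hits[order(readOrder, -hits$bitscore, hits$evalue, hits$taxid), , drop = FALSE]
}

#' Classify one read from its ranked BLAST hits
#'
#' Emulates the EPI2ME 16S per-read logic: hits are first filtered for
#' identity > 77% and coverage (identical matches / query length) > 0.30 to
#' remove spurious alignments; the top surviving hit provides the
#' classification, its percent identity is reported as the read accuracy and
#' its coverage as the read coverage. `num_genus_taxid` counts the distinct
#' genus-rank ancestors among the first `k` surviving hits (a hit with no
#' genus ancestor counts as its own pseudo-genus). Reads whose top hits span
#' a single genus are reported at genus rank or below; otherwise the read
#' falls back to the family of the top hit (e.g. *Carnobacteriaceae* for
#' *Dolosigranulum* reads whose top 3 span two genera).
#'
#' @param hits data.frame of hits for one read, as ordered by
#'   [parseOutfmt6()].
#' @param tax a [Taxonomy-class] resolving every subject taxid.
#' @param k number of top hits entering the genus count (default 3).
#' @param minIdentity,minCoverage base filters, strict (> 77, > 0.30).
#' @return one-row data.frame with columns read_id, taxid, rank
#'   ("genus-or-below" or "family-fallback"), name, accuracy, coverage,
#'   mean_qscore (NA here), seq_len, num_genus_taxid, lca; or `NULL` when no
#'   hit passes the base filters (unclassified).
#' @export
classifyRead <- function(hits, tax, k = 3L, minIdentity = 77, minCoverage = 0.30) {
  if (!nrow(hits)) return(NULL)
  if (length(unique(hits$read_id)) != 1L) stop("hits must belong to one read")
  cov <- hits$nident / hits$qlen
  pass <- hits$pident > minIdentity & cov > minCoverage
  if (!any(pass)) return(NULL)
  hits <- hits[pass, , drop = FALSE]
  cov <- cov[pass]
  topK <- utils::head(seq_len(nrow(hits)), k)
  genus <- vapply(hits$taxid[topK], function(tid) ancestorAtRank(tax, tid, "genus"),
                  integer(1))
  genusKey <- ifelse(is.na(genus), paste0("pseudo:", seq_along(genus)),
                     as.character(genus))
  ngt <- length(unique(genusKey))
  topTaxid <- hits$taxid[1]
  if (ngt == 1L) {
    g <- genus[1]
    name <- if (is.na(g)) NA_character_ else nameOf(tax, g)
    rank <- "genus-or-below"
  } else {
    fam <- ancestorAtRank(tax, topTaxid, "family")
    name <- if (is.na(fam)) NA_character_ else nameOf(tax, fam)
    rank <- "family-fallback"
  }
  data.frame(read_id = hits$read_id[1], taxid = as.integer(topTaxid), rank = rank,
             name = name, accuracy = hits$pident[1], coverage = cov[1],
             mean_qscore = NA_real_, seq_len = hits$qlen[1],
             num_genus_taxid = as.integer(ngt),
             lca = as.integer(ngt != 1L), stringsAsFactors = FALSE)
}

#' Classify every read in a hit table
#'
#' @param hits data.frame from [parseOutfmt6()] (any number of reads).
#' @param tax a [Taxonomy-class] object.
#' @param meanQuality optional named numeric vector (read id -> mean Phred
#'   quality), e.g. from [meanQualityFromFastq()], merged into the records.
#' @param ... passed to [classifyRead()].
#' @return data.frame of per-read classification records, with an attribute
#'   `unclassified` holding the read ids removed by the base filters.
#' @export
classifyReads <- function(hits, tax, meanQuality = NULL, ...) {
  ids <- unique(hits$read_id)
  recs <- lapply(ids, function(id)
    classifyRead(hits[hits$read_id == id, , drop = FALSE], tax, ...))
  keep <- !vapply(recs, is.null, logical(1))
  out <- do.call(rbind, recs[keep])
  if (is.null(out))
    out <- data.frame(read_id = character(), taxid = integer(), rank = character(),
                      name = character(), accuracy = numeric(), coverage = numeric(),
                      mean_qscore = numeric(), seq_len = numeric(),
                      num_genus_taxid = integer(), lca = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(meanQuality) && nrow(out))
    out$mean_qscore <- unname(meanQuality[out$read_id])
  attr(out, "unclassified") <- ids[!keep]
  out
}

#' Mean per-read Phred quality from a FASTQ file
#'
#' Arithmetic mean of the per-base Phred scores of each read; read ids are
#' truncated at the first whitespace, matching BLAST query ids.
#'
#' @param file FASTQ path (uncompressed or gzip).
#' @return named numeric vector, read id -> mean quality.
#' @export
meanQualityFromFastq <- function(file) {
  reads <- Biostrings::readQualityScaledDNAStringSet(file)
  qs <- methods::as(Biostrings::quality(reads), "IntegerList")
  ids <- sub("\\s.*$", "", names(reads))
  stats::setNames(vapply(qs, function(q) mean(as.numeric(q)), numeric(1)), ids)
}

#' Albacore-era exclusion criteria
#'
#' Retain reads with accuracy >= 80%, mean quality >= 7, length within
#' 1400--1700 bp (inclusive) and num_genus_taxid 1 or 2.
#' @return a [FilterCriteria-class] object.
#' @export
albacoreCriteria <- function() {
  new("FilterCriteria", era = "albacore", minAccuracy = 80, minQuality = 7,
      lengthWindow = c(1400, 1700), ngtAdmissible = c(1L, 2L), useLca = FALSE)
}

#' Guppy-era exclusion criteria
#'
#' Retain reads with accuracy >= 85%, mean quality >= 9, length within
#' 1400--1700 bp (inclusive) and an lca score of 0 (top hits agree at genus
#' level).
#' @return a [FilterCriteria-class] object.
#' @export
guppyCriteria <- function() {
  new("FilterCriteria", era = "guppy", minAccuracy = 85, minQuality = 9,
      lengthWindow = c(1400, 1700), ngtAdmissible = integer(0), useLca = TRUE)
}

#' Apply per-read exclusion criteria
#'
#' A record is retained iff accuracy >= minimum accuracy AND mean quality >=
#' minimum quality AND read length within the inclusive window AND its
#' num_genus_taxid is admissible (or its lca score is 0 when the criteria
#' use the lca flag). Records missing a mean quality fail the quality
#' criterion. The tally counts, per criterion, how many records fail it; a
#' record may fail several criteria at once.
#'
#' @param records data.frame of read classification records (columns
#'   accuracy, mean_qscore, seq_len, and num_genus_taxid or lca).
#' @param criteria a [FilterCriteria-class] object.
#' @return list with `retained` and `excluded` data.frames and `tally`, a
#'   named integer vector (accuracy, quality, length, taxid_agreement,
#'   excluded, total).
#' @export
applyExclusionCriteria <- function(records, criteria) {
  stopifnot(is(criteria, "FilterCriteria"))
  n <- nrow(records)
  if (!n) {
    tally <- c(accuracy = 0L, quality = 0L, length = 0L,
               taxid_agreement = 0L, excluded = 0L, total = 0L)
    return(list(retained = records, excluded = records, tally = tally))
  }
  accOk <- !is.na(records$accuracy) & records$accuracy >= criteria@minAccuracy
  qOk <- !is.na(records$mean_qscore) & records$mean_qscore >= criteria@minQuality
  lenOk <- !is.na(records$seq_len) &
    records$seq_len >= criteria@lengthWindow[1] &
    records$seq_len <= criteria@lengthWindow[2]
  taxOk <- if (criteria@useLca) {
    lca <- if ("lca" %in% names(records)) records$lca
           else as.integer(records$num_genus_taxid != 1L)
    !is.na(lca) & lca == 0L
  } else {
    ngt <- if ("num_genus_taxid" %in% names(records)) records$num_genus_taxid
           else ifelse(records$lca == 0L, 1L, 2L)
    !is.na(ngt) & ngt %in% criteria@ngtAdmissible
  }
  keep <- accOk & qOk & lenOk & taxOk
  tally <- c(accuracy = sum(!accOk), quality = sum(!qOk), length = sum(!lenOk),
             taxid_agreement = sum(!taxOk), excluded = sum(!keep), total = n)
  list(retained = records[keep, , drop = FALSE],
       excluded = records[!keep, , drop = FALSE],
       tally = vapply(tally, as.integer, integer(1)))
}

#' Species-level call for a classified read
#'
#' The highest-scoring BLAST identification (top rank) is used for species
#' identification: the call reports the species-rank ancestor of the top
#' taxid, which is the top hit's species -- not necessarily the truth (a
#' *S. epidermidis* read whose top hit is *S. saccharolyticus* is reported
#' as the latter).
#'
#' @param record a one-row classification record (or list) with a `taxid`.
#' @param tax a [Taxonomy-class] object.
#' @return the species name.
#' @export
speciesCall <- function(record, tax) {
  sp <- ancestorAtRank(tax, record$taxid, "species")
  if (is.na(sp))
    stop("top taxid ", record$taxid, " has no species-rank ancestor")
  nameOf(tax, sp)
}

#' Read / write the EPI2ME-dialect per-read CSV
#'
#' Columns: read_id, taxid, accuracy, coverage, mean_qscore, seq_len and
#' num_genus_taxid and/or lca. When only one of num_genus_taxid / lca is
#' present the other is derived (lca = 0 exactly when num_genus_taxid = 1;
#' a derived num_genus_taxid of 2 stands for "more than one genus"). Lines
#' starting with `#` are provenance comments and are skipped.
#'
#' @param file CSV path.
#' @return data.frame of per-read records.
#' @export
readEpi2meCsv <- function(file) {
  rec <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("read_id", "taxid", "accuracy", "coverage", "mean_qscore", "seq_len")
  if (!all(need %in% names(rec)))
    stop("EPI2ME CSV missing column(s): ", paste(setdiff(need, names(rec)), collapse = ", "))
  if (!"num_genus_taxid" %in% names(rec) && !"lca" %in% names(rec))
    stop("EPI2ME CSV needs num_genus_taxid or lca")
  if (!"lca" %in% names(rec))
    rec$lca <- as.integer(rec$num_genus_taxid != 1L)
  if (!"num_genus_taxid" %in% names(rec))
    rec$num_genus_taxid <- ifelse(rec$lca == 0L, 1L, 2L)
  rec
}

#' @rdname readEpi2meCsv
#' @param records data.frame of per-read records.
#' @param comment optional provenance string written as a leading `#` line.
#' @export
writeEpi2meCsv <- function(records, file, comment = NULL) {
  con <- base::file(file, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a per-criterion exclusion tally as JSON
#' @param tally named integer vector from [applyExclusionCriteria()].
#' @param file output path.
#' @export
writeFilterTally <- function(tally, file) {
  jsonlite::write_json(as.list(tally), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
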