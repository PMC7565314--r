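#' Construct a Taxonomy from vectors
#'
#' Low-level constructor; most users will call [loadTaxonomy()] on files.
#'
#' @param taxid integer vector of node taxids.
#' @param parent integer vector of parent taxids (the root is its own parent).
#' @param rank character vector of rank labels.
#' @param name character vector of scientific names, parallel to `taxid`, or
#'   a named vector indexed by taxid.
#' @return a validated [Taxonomy-class] object.
#' @examples
#' tax <- taxonomy(taxid = c(1, 2, 3, 4), parent = c(1, 1, 2, 3),
#'                 rank = c("root", "family", "genus", "species"),
#'                 name = c("root", "Carnobacteriaceae", "Dolosigranulum",
#'                          "Dolosigranulum pigrum"))
#' nameOf(tax, ancestorAtRank(tax, 4, "genus"))
#' @export
taxonomy <- function(taxid, parent, rank, name) {
  taxid <- as.integer(taxid)
  parent <- as.integer(parent)
  if (is.null(names(name))) {
    stopifnot(length(name) == length(taxid))
    names(name) <- as.character(taxid)
  }
  p <- stats::setNames(parent, as.character(taxid))
  r <- stats::setNames(as.character(rank), as.character(taxid))
  new("Taxonomy", parent = p, rank = r, sciName = name)
}

#' Load an NCBI-style taxonomy from nodes and names tables
#'
#' Accepts either a minimal 3-column tab-separated table `(taxid, parent,
#' rank)` plus a 2-column `(taxid, name)` table, or the NCBI dump dialect
#' (`nodes.dmp` / `names.dmp`, fields separated by `\t|\t` and terminated by
#' `\t|`). The dialect is auto-detected per file by the presence of the
#' `|` field separator. In the dmp dialect only rows flagged
#' `scientific name` are used from names.dmp; for the minimal dialect every
#' row is a scientific name. Duplicate names for one taxid keep the last
#' occurrence, with a warning.
#'
#' @param nodesFile path to the nodes table.
#' @param namesFile path to the names table.
#' @return a validated [Taxonomy-class] object.
#' @export
loadTaxonomy <- function(nodesFile, namesFile) {
  nodes <- .readDumpish(nodesFile)
  if (ncol(nodes) < 3L) stop("nodes table needs at least 3 columns (taxid, parent, rank)")
  taxid <- suppressWarnings(as.integer(nodes[[1]]))
  parent <- suppressWarnings(as.integer(nodes[[2]]))
  if (anyNA(taxid) || anyNA(parent))
    stop("non-integer taxid in nodes table, first bad line ",
         which(is.na(taxid) | is.na(parent))[1])
  if (any(taxid <= 0L | parent <= 0L)) stop("taxids must be positive integers")
  rank <- trimws(as.character(nodes[[3]]))

  nm <- .readDumpish(namesFile)
  if (ncol(nm) < 2L) stop("names table needs at least 2 columns (taxid, name)")
  if (ncol(nm) >= 4L) {                       # names.dmp dialect: keep scientific names
    keep <- trimws(as.character(nm[[4]])) == "scientific name"
    nm <- nm[keep, , drop = FALSE]
  }
  nmTaxid <- suppressWarnings(as.integer(nm[[1]]))
  if (anyNA(nmTaxid)) stop("non-integer taxid in names table")
  nmName <- trimws(as.character(nm[[2]]))
  if (anyDuplicated(nmTaxid)) {
    warning("duplicate names for some taxids; keeping the last occurrence")
    lastIdx <- !duplicated(nmTaxid, fromLast = TRUE)
    nmTaxid <- nmTaxid[lastIdx]; nmName <- nmName[lastIdx]
  }
  missing <- setdiff(taxid, nmTaxid)
  if (length(missing))
    stop("name missing for referenced taxid(s): ", paste(missing, collapse = ", "))
  taxonomy(taxid, parent, rank, stats::setNames(nmName, as.character(nmTaxid)))
}

# Read a table in either minimal TSV or NCBI .dmp dialect.
.readDumpish <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty table: ", path)
  if (any(grepl("|", lines, fixed = TRUE))) {
    lines <- sub("\t\\|$", "", lines)
    parts <- strsplit(lines, "\t\\|\t")
  } else {
    parts <- strsplit(lines, "\t")
  }
  ncols <- max(lengths(parts))
  mat <- vapply(parts, function(p) c(p, rep(NA_character_, ncols - length(p))),
                character(ncols))
  as.data.frame(t(matrix(mat, nrow = ncols)), stringsAsFactors = FALSE)
}

#' @describeIn taxonomy taxids present in the taxonomy.
#' @param tax a [Taxonomy-class] object.
#' @export
taxids <- function(tax) as.integer(names(tax@parent))

#' @describeIn taxonomy taxid of the root node.
#' @export
taxonomyRoot <- function(tax) {
  ids <- names(tax@parent)
  as.integer(ids[tax@parent == as.integer(ids)][1])
}

.checkTaxid <- function(tax, taxid) {
  key <- as.character(taxid)
  if (!key %in% names(tax@parent)) stop("unknown taxid: ", taxid)
  key
}

#' Rank label of a taxid
#' @param tax a [Taxonomy-class] object.
#' @param taxid a taxid present in `tax`.
#' @export
rankOf <- function(tax, taxid) unname(tax@rank[[.checkTaxid(tax, taxid)]])

#' Scientific name of a taxid
#'
#' @inheritParams rankOf
#' @return the scientific name string; unknown taxids are an error.
#' @export
nameOf <- function(tax, taxid) unname(tax@sciName[[.checkTaxid(tax, taxid)]])

#' First ancestor (or self) at a requested rank
#'
#' Walks the parent chain from `taxid` towards the root and returns the
#' first node whose rank label equals `rank`, or `NA` if the chain reaches
#' the root without meeting it. A node already at the requested rank returns
#' itself, which makes the operation idempotent.
#'
#' @inheritParams rankOf
#' @param rank requested rank label, e.g. "genus" or "family".
#' @return the ancestor taxid, or `NA_integer_` when no ancestor has the rank.
#' @export
ancestorAtRank <- function(tax, taxid, rank) {
  cur <- .checkTaxid(tax, taxid)
  repeat {
    if (identical(unname(tax@rank[[cur]]), rank)) return(as.integer(cur))
    nxt <- as.character(tax@parent[[cur]])
    if (nxt == cur) return(NA_integer_)
    cur <- nxt
  }
}
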