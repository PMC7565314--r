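#' IUPAC degenerate base matching
#'
#' TRUE iff the template base is in the expansion of the (possibly
#' degenerate) primer code, e.g. M = A/C, R = A/G, B = C/G/T. An `N` in the
#' template matches nothing: an uncalled base cannot be claimed to pair.
#' Vectorized over both arguments.
#'
#' @param primerBase IUPAC nucleotide code(s) on the primer.
#' @param templateBase template base(s), one of A, C, G, T, N.
#' @return logical vector.
#' @export
iupacMatch <- function(primerBase, templateBase) {
  pb <- toupper(primerBase)
  tb <- toupper(templateBase)
  tab <- .iupacTable()
  if (any(bad <- !pb %in% rownames(tab)))
    stop("invalid IUPAC primer symbol: ", paste(unique(pb[bad]), collapse = ", "))
  if (any(bad <- !tb %in% colnames(tab)))
    stop("invalid template base: ", paste(unique(tb[bad]), collapse = ", "))
  unname(tab[cbind(pb, tb)])
}

# code x template lookup, built once from the Biostrings expansion map
.iupacCache <- new.env(parent = emptyenv())
.iupacTable <- function() {
  if (!is.null(.iupacCache$tab)) return(.iupacCache$tab)
  map <- Biostrings::IUPAC_CODE_MAP
  bases <- c("A", "C", "G", "T", "N")
  tab <- matrix(FALSE, length(map), length(bases),
                dimnames = list(names(map), bases))
  for (code in names(map))
    for (b in setdiff(bases, "N"))     # template N matches nothing
      tab[code, b] <- grepl(b, map[[code]], fixed = TRUE)
  .iupacCache$tab <- tab
  tab
}

#' Best ungapped annealing site of a primer on a reference
#'
#' Scans every ungapped placement of the primer along the reference (the
#' reverse complement of the reference for reverse-orientation primers) and
#' keeps the placement with the most matched positions, ties going to the
#' leftmost site of the scanned strand. The report carries the per-position
#' match mask in primer coordinates (1-based, 5' to 3'), the mismatch count,
#' the longest contiguous matched stretch with its primer-coordinate span,
#' and the matched run ending at the 3' terminus, which is what polymerase
#' extension cares about. The default annealing rule calls a site
#' productive when it has at most `maxMismatch` mismatches and a 3'-terminal
#' matched run of at least `minThreePrimeRun` bases.
#'
#' @param primer primer sequence, IUPAC alphabet, 5' to 3'.
#' @param reference reference sequence (character or
#'   [Biostrings::DNAString]), plus strand.
#' @param orientation `"forward"` or `"reverse"`.
#' @param primerId identifier carried into the report.
#' @param maxMismatch annealing rule: maximum mismatches (default 2).
#' @param minThreePrimeRun annealing rule: minimum 3'-terminal matched run
#'   (default 3).
#' @return a [PrimerMatch-class] object.
#' @export
bestAnnealing <- function(primer, reference, orientation = c("forward", "reverse"),
                          primerId = "primer", maxMismatch = 2L,
                          minThreePrimeRun = 3L) {
  orientation <- match.arg(orientation)
  primer <- toupper(as.character(primer))
  refChr <- toupper(as.character(reference))
  plen <- nchar(primer)
  tlen <- nchar(refChr)
  if (tlen < plen)
    stop("reference (", tlen, " nt) shorter than primer (", plen, " nt)")
  template <- if (orientation == "reverse")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(refChr)))
  else refChr

  pChars <- strsplit(primer, "", fixed = TRUE)[[1]]
  tChars <- strsplit(template, "", fixed = TRUE)[[1]]
  nStarts <- tlen - plen + 1L
  # okMat[s, j]: primer position j matches template position s + j - 1
  okMat <- vapply(seq_len(plen), function(j)
    iupacMatch(rep(pChars[j], nStarts), tChars[seq_len(nStarts) + j - 1L]),
    logical(nStarts))
  if (nStarts == 1L) okMat <- matrix(okMat, nrow = 1L)
  best <- which.max(rowSums(okMat))          # ties -> leftmost scanned site
  mask <- okMat[best, ]

  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  trueRuns <- which(runs$values)
  if (length(trueRuns)) {
    iBest <- trueRuns[which.max(runs$lengths[trueRuns])]
    longestRun <- runs$lengths[iBest]
    runSpan <- c(starts[iBest], ends[iBest])
  } else {
    longestRun <- 0L
    runSpan <- c(NA_integer_, NA_integer_)
  }
  threePrime <- if (mask[plen]) runs$lengths[length(runs$lengths)] else 0L
  mism <- plen - sum(mask)
  if (orientation == "reverse") {
    siteStart <- tlen - (best + plen - 1L) + 1L
    siteEnd <- tlen - best + 1L
  } else {
    siteStart <- best
    siteEnd <- best + plen - 1L
  }
  new("PrimerMatch", primerId = primerId, primer = primer,
      orientation = orientation, siteStart = as.integer(siteStart),
      siteEnd = as.integer(siteEnd), mask = mask, mismatches = as.integer(mism),
      longestRun = as.integer(longestRun), runSpan = as.integer(runSpan),
      threePrimeRun = as.integer(threePrime),
      anneals = mism <= maxMismatch && threePrime >= minThreePrimeRun)
}

#' In-silico PCR of a primer pair on one reference
#'
#' Amplification is predicted iff both primers anneal under the rule and the
#' forward site lies upstream of the reverse site; the amplicon spans from
#' the forward site start to the reverse site end, both primers included.
#' Non-amplification is a valid result, not an error.
#'
#' @param forward,reverse primer sequences, IUPAC, each 5' to 3'.
#' @param reference reference sequence, plus strand.
#' @param forwardId,reverseId primer identifiers.
#' @inheritParams bestAnnealing
#' @return list with `amplifies` (logical), `ampliconLength` (NA when not
#'   amplifying) and the two [PrimerMatch-class] reports `forwardMatch`,
#'   `reverseMatch`.
#' @export
inSilicoPcr <- function(forward, reverse, reference,
                        forwardId = "forward", reverseId = "reverse",
                        maxMismatch = 2L, minThreePrimeRun = 3L) {
  fm <- bestAnnealing(forward, reference, "forward", forwardId,
                      maxMismatch, minThreePrimeRun)
  rm_ <- bestAnnealing(reverse, reference, "reverse", reverseId,
                       maxMismatch, minThreePrimeRun)
  ok <- fm@anneals && rm_@anneals && fm@siteStart < rm_@siteStart
  list(amplifies = ok,
       ampliconLength = if (ok) rm_@siteEnd - fm@siteStart + 1L else NA_integer_,
       forwardMatch = fm, reverseMatch = rm_)
}

#' Degenerate-primer dropout screen over a labelled reference set
#'
#' Runs [inSilicoPcr()] on every reference and aggregates per taxon: a taxon
#' is flagged as a predicted dropout when none of its references is
#' predicted to amplify (the mechanism behind *Corynebacterium*
#' under-detection on the nanopore primer set).
#'
#' @param forward,reverse primer sequences, IUPAC, 5' to 3'.
#' @param references named character vector or
#'   [Biostrings::DNAStringSet] of reference sequences.
#' @param taxa taxon label per reference; defaults to the reference names.
#' @inheritParams bestAnnealing
#' @return data.frame with one row per taxon: nRefs, forwardAnneals,
#'   reverseAnneals, amplifies (any reference), worstPrimerMismatches (the
#'   best reference's max of forward/reverse mismatch counts) and `dropout`.
#'   An empty reference set gives an empty table. The per-reference detail
#'   is attached as attribute `perReference`.
#' @export
dropoutScreen <- function(forward, reverse, references, taxa = NULL,
                          maxMismatch = 2L, minThreePrimeRun = 3L) {
  refs <- stats::setNames(as.character(references), names(references))
  if (is.null(taxa)) taxa <- names(refs)
  if (!length(refs)) {
    out <- data.frame(taxon = character(), nRefs = integer(),
                      forwardAnneals = logical(), reverseAnneals = logical(),
                      amplifies = logical(), worstPrimerMismatches = integer(),
                      dropout = logical(), stringsAsFactors = FALSE)
    attr(out, "perReference") <- out
    return(out)
  }
  if (length(taxa) != length(refs)) stop("one taxon label per reference required")
  per <- do.call(rbind, lapply(seq_along(refs), function(i) {
    pcr <- inSilicoPcr(forward, reverse, refs[i],
                       maxMismatch = maxMismatch,
                       minThreePrimeRun = minThreePrimeRun)
    data.frame(reference = if (is.null(names(refs))) as.character(i) else names(refs)[i],
               taxon = taxa[i],
               forwardAnneals = pcr$forwardMatch@anneals,
               reverseAnneals = pcr$reverseMatch@anneals,
               amplifies = pcr$amplifies,
               forwardMismatches = pcr$forwardMatch@mismatches,
               reverseMismatches = pcr$reverseMatch@mismatches,
               ampliconLength = pcr$ampliconLength,
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(split(per, per$taxon)[unique(per$taxon)], function(g) {
    worst <- pmax(g$forwardMismatches, g$reverseMismatches)
    data.frame(taxon = g$taxon[1], nRefs = nrow(g),
               forwardAnneals = any(g$forwardAnneals),
               reverseAnneals = any(g$reverseAnneals),
               amplifies = any(g$amplifies),
               worstPrimerMismatches = min(worst),
               dropout = !any(g$amplifies), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "perReference") <- per
  out
}

#' The nanopore 16S primer pair (27F / 1492R)
#'
#' The full-length 16S pair used by the rapid amplicon barcoding kit:
#' 27F `AGAGTTTGATCMTGGCTCAG` and the canonical 1492R
#' `CGGTTACCTTGTTACGACTT` (printed as "149R" in some protocols; the
#' sequence is authoritative).
#'
#' @return data.frame with columns id, sequence, orientation.
#' @export
ontPrimers <- function() {
  data.frame(id = c("27F", "1492R"),
             sequence = c("AGAGTTTGATCMTGGCTCAG", "CGGTTACCTTGTTACGACTT"),
             orientation = c("forward", "reverse"), stringsAsFactors = FALSE)
}

#' The Illumina V5-V6 primer pair (785F / 1061R)
#'
#' Amplifies the 276-bp V5-V6 fragment: 785F `GGATTAGATACCCBRGTAGTC`,
#' 1061R `TCACGRCACGAGCTGACGAC`.
#'
#' @return data.frame with columns id, sequence, orientation.
#' @export
illuminaPrimers <- function() {
  data.frame(id = c("785F", "1061R"),
             sequence = c("GGATTAGATACCCBRGTAGTC", "TCACGRCACGAGCTGACGAC"),
             orientation = c("forward", "reverse"), stringsAsFactors = FALSE)
}

#' Read a primer set from a small text file
#'
#' Tab- or comma-separated columns: id, sequence, orientation.
#' @param file path.
#' @return data.frame with columns id, sequence, orientation.
#' @export
readPrimers <- function(file) {
  first <- readLines(file, n = 1L)
  sep <- if (grepl(",", first)) "," else "\t"
  tab <- utils::read.table(file, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "sequence", "orientation")
  if (!all(need %in% names(tab)))
    stop("primer file needs columns: ", paste(need, collapse = ", "))
  tab[need]
}
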