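#' @import methods
NULL

#' Taxonomy: a rank-labelled tree over integer taxids
#'
#' Holds an NCBI-style taxonomy as three parallel vectors indexed by taxid:
#' parent taxid, rank label and scientific name. The tree has exactly one
#' root (a node that is its own parent) and every parent chain reaches it.
#'
#' @slot parent named integer vector; names are taxids (as character),
#'   values the parent taxid.
#' @slot rank named character vector of rank labels ("genus", "family", ...).
#'   Unknown labels are preserved verbatim.
#' @slot sciName named character vector of scientific names.
#'
#' @seealso [loadTaxonomy()], [ancestorAtRank()], [nameOf()]
#' @exportClass Taxonomy
setClass("Taxonomy", representation(
  parent  = "integer",
  rank    = "character",
  sciName = "character"
))

setValidity("Taxonomy", function(object) {
  ids <- names(object@parent)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids))
    return("parent vector must be uniquely named by taxid")
  if (!identical(ids, names(object@rank)))
    return("rank vector must carry the same taxids as parent")
  if (!all(ids %in% names(object@sciName)))
    return(sprintf("name missing for taxid(s): %s",
                   paste(setdiff(ids, names(object@sciName)), collapse = ", ")))
  roots <- ids[object@parent == as.integer(ids)]
  if (length(roots) != 1L)
    return(sprintf("taxonomy must have exactly one root, found %d", length(roots)))
  if (!all(as.character(object@parent) %in% ids))
    return("every parent taxid must itself be a node")
  # cycle check: walk each chain, bounded by node count
  n <- length(ids)
  for (id in ids) {
    cur <- id
    for (step in seq_len(n + 1L)) {
      nxt <- as.character(object@parent[[cur]])
      if (nxt == cur) break
      if (step > n) return(sprintf("cycle detected in parent chain at taxid %s", id))
      cur <- nxt
    }
  }
  TRUE
})

setMethod("show", "Taxonomy", function(object) {
  rk <- table(object@rank)
  cat("Taxonomy with", length(object@parent), "nodes; root taxid",
      taxonomyRoot(object), "\n")
  cat("ranks:", paste(sprintf("%s (%d)", names(rk), rk), collapse = ", "), "\n")
})

#' GenusProfile: one sample's genus-level relative abundance profile
#'
#' Relative abundances are percentages of *classified* reads and sum to 100
#' (an empty profile, for a sample with zero classified reads, is allowed).
#'
#' @slot sampleId single character sample identifier.
#' @slot nClassified number of classified reads behind the profile.
#' @slot abundance named numeric vector of genus -> relative abundance (%).
#'
#' @seealso [buildProfile()], [inverseSimpson()], [observedGenera()]
#' @exportClass GenusProfile
setClass("GenusProfile", representation(
  sampleId    = "character",
  nClassified = "numeric",
  abundance   = "numeric"
))

setValidity("GenusProfile", function(object) {
  if (length(object@sampleId) != 1L) return("sampleId must be a single string")
  ab <- object@abundance
  if (length(ab)) {
    if (is.null(names(ab)) || any(names(ab) == ""))
      return("abundance must be named by genus")
    if (anyDuplicated(names(ab))) return("duplicated genus names in abundance")
    if (any(ab < 0)) return("abundances must be non-negative")
    if (abs(sum(ab) - 100) > 1e-9)
      return(sprintf("abundances must sum to 100, got %.12g", sum(ab)))
  }
  TRUE
})

setMethod("show", "GenusProfile", function(object) {
  cat(sprintf("GenusProfile '%s': %d genera from %g classified reads\n",
              object@sampleId, length(object@abundance), object@nClassified))
  if (length(object@abundance)) {
    top <- sort(object@abundance, decreasing = TRUE)
    top <- utils::head(top, 6L)
    cat(paste(sprintf("  %s %.1f%%", names(top), top), collapse = "\n"), "\n")
  }
})

#' FilterCriteria: read-level exclusion thresholds for one analysis era
#'
#' The Albacore-era criteria exclude reads with accuracy < 80, mean quality
#' < 7, length outside 1400--1700 bp (inclusive window) or a num_genus_taxid
#' other than 1 or 2. The Guppy-era criteria raise accuracy to 85 and
#' quality to 9 and require an lca score of 0.
#'
#' @slot era "albacore" or "guppy" (free label).
#' @slot minAccuracy minimum accuracy (%) to retain.
#' @slot minQuality minimum mean Phred quality to retain.
#' @slot lengthWindow inclusive read-length window, bases, length 2.
#' @slot ngtAdmissible admissible num_genus_taxid values (ignored when
#'   \code{useLca} is TRUE).
#' @slot useLca when TRUE, retain only reads with lca score 0.
#'
#' @seealso [albacoreCriteria()], [guppyCriteria()], [applyExclusionCriteria()]
#' @exportClass FilterCriteria
setClass("FilterCriteria", representation(
  era           = "character",
  minAccuracy   = "numeric",
  minQuality    = "numeric",
  lengthWindow  = "numeric",
  ngtAdmissible = "integer",
  useLca        = "logical"
))

setValidity("FilterCriteria", function(object) {
  if (length(object@lengthWindow) != 2L || object@lengthWindow[1] >= object@lengthWindow[2])
    return("lengthWindow must be c(min, max) with min < max")
  if (!object@useLca && !length(object@ngtAdmissible))
    return("ngtAdmissible must be non-empty unless useLca is TRUE")
  TRUE
})

setMethod("show", "FilterCriteria", function(object) {
  cat(sprintf("FilterCriteria [%s]: accuracy >= %g%%, quality >= %g, length in [%g, %g], %s\n",
              object@era, object@minAccuracy, object@minQuality,
              object@lengthWindow[1], object@lengthWindow[2],
              if (object@useLca) "lca == 0"
              else paste0("num_genus_taxid in {",
                          paste(object@ngtAdmissible, collapse = ","), "}")))
})

#' PrimerMatch: annealing report of one primer against one reference
#'
#' Produced by [bestAnnealing()]. Coordinates on the primer are 1-based
#' 5'->3'; the site start is 1-based on the reference plus strand.
#'
#' @slot primerId primer identifier.
#' @slot primer primer sequence, IUPAC alphabet, 5'->3'.
#' @slot orientation "forward" or "reverse".
#' @slot siteStart start of the best site on the reference plus strand.
#' @slot siteEnd end of the best site on the reference plus strand.
#' @slot mask logical per-primer-position match mask (5'->3').
#' @slot mismatches number of unmatched primer positions at the best site.
#' @slot longestRun length of the longest contiguous matched stretch.
#' @slot runSpan primer-coordinate span (start, end) of that stretch.
#' @slot threePrimeRun length of the matched run ending at the 3' terminus.
#' @slot anneals whether the site passes the annealing rule.
#'
#' @seealso [bestAnnealing()], [inSilicoPcr()], [dropoutScreen()]
#' @exportClass PrimerMatch
setClass("PrimerMatch", representation(
  primerId      = "character",
  primer        = "character",
  orientation   = "character",
  siteStart     = "integer",
  siteEnd       = "integer",
  mask          = "logical",
  mismatches    = "integer",
  longestRun    = "integer",
  runSpan       = "integer",
  threePrimeRun = "integer",
  anneals       = "logical"
))

setValidity("PrimerMatch", function(object) {
  if (length(object@mask) != nchar(object@primer))
    return("mask length must equal primer length")
  if (object@longestRun > nchar(object@primer))
    return("longest run cannot exceed primer length")
  TRUE
})

setMethod("show", "PrimerMatch", function(object) {
  cat(sprintf("PrimerMatch %s (%s): site %d-%d, %d mismatch(es), longest run %d (bp %d-%d), 3' run %d, anneals: %s\n",
              object@primerId, object@orientation, object@siteStart, object@siteEnd,
              object@mismatches, object@longestRun, object@runSpan[1], object@runSpan[2],
              object@threePrimeRun, object@anneals))
  cat(" ", object@primer, "\n ", paste(ifelse(object@mask, "|", "."), collapse = ""), "\n")
})

#' ScenarioSpec: the stated world of the two-platform simulator
#'
#' Describes a synthetic study: the genus roster with Dirichlet abundance
#' parameters, per-genus reference-database counts, confusability (the
#' probability that a read's top-3 hits span two genera) and nanopore
#' amplification efficiency; per-platform read-depth distributions; and the
#' per-read accuracy/quality/length/coverage distributions of the nanopore
#' records.
#'
#' @slot genera data.frame with columns genus, family, alpha (Dirichlet
#'   parameter > 0), nRefs (reference sequences in the mock database, >= 1),
#'   confusability (probability in [0,1]), efficiency (in [0,1]).
#' @slot nSamples number of paired samples to simulate.
#' @slot era "albacore" or "guppy"; selects default filter criteria and the
#'   accuracy/quality means.
#' @slot illuminaDepth,nanoporeDepth functions n -> integer read depths.
#' @slot accuracyMean,accuracySd,accuracyRange truncated-normal accuracy (%).
#' @slot qualityMean,qualitySd normal mean Phred quality.
#' @slot lengthMean,lengthSd normal read length (bases), truncated positive.
#' @slot coverageMean,coverageSd truncated-normal per-read coverage (0.3, 1].
#'
#' @seealso [scenarioSpec()], [scenarioPresets()], [simulateSamplePair()]
#' @exportClass ScenarioSpec
setClass("ScenarioSpec", representation(
  genera        = "data.frame",
  nSamples      = "integer",
  era           = "character",
  illuminaDepth = "function",
  nanoporeDepth = "function",
  accuracyMean  = "numeric",
  accuracySd    = "numeric",
  accuracyRange = "numeric",
  qualityMean   = "numeric",
  qualitySd     = "numeric",
  lengthMean    = "numeric",
  lengthSd      = "numeric",
  coverageMean  = "numeric",
  coverageSd    = "numeric"
))

setValidity("ScenarioSpec", function(object) {
  g <- object@genera
  need <- c("genus", "family", "alpha", "nRefs", "confusability", "efficiency")
  if (!all(need %in% names(g)))
    return(paste("genera must have columns:", paste(need, collapse = ", ")))
  if (any(g$alpha <= 0)) return("Dirichlet parameters must be > 0")
  if (any(g$nRefs < 1)) return("reference counts must be >= 1")
  if (any(g$confusability < 0 | g$confusability > 1))
    return("confusability must lie in [0, 1]")
  if (any(g$efficiency < 0 | g$efficiency > 1))
    return("efficiencies must lie in [0, 1]")
  if (anyDuplicated(g$genus)) return("duplicated genus in roster")
  if (object@nSamples < 1L) return("nSamples must be >= 1")
  TRUE
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec [%s era]: %d genera, %d samples\n",
              object@era, nrow(object@genera), object@nSamples))
  print(object@genera, row.names = FALSE)
})
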