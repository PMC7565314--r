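#' Construct a simulation scenario
#'
#' Builds a [ScenarioSpec-class] describing a paired two-platform study.
#' Era-dependent defaults follow the basecaller progression: Albacore-era
#' reads centre on ~85% accuracy and mean quality ~8, Guppy-era reads on
#' ~90% and ~10. Spread parameters (accuracy SD 3, quality SD 0.65, length
#' SD 75 around 1550 bp) are calibrated so that the era's own exclusion
#' criteria remove about 15% of reads (each criterion independently fails
#' ~5%).
#'
#' @param genera data.frame with columns genus, family, alpha, nRefs,
#'   confusability, efficiency (see [ScenarioSpec-class]).
#' @param nSamples number of paired samples.
#' @param era "albacore" or "guppy".
#' @param illuminaDepth,nanoporeDepth functions n -> integer depths; the
#'   defaults are lognormal with the heavy spread seen in clinical swabs
#'   (Illumina ~1.3e5 reads on average, nanopore ~2.2e4).
#' @param accuracyMean,accuracySd,accuracyRange,qualityMean,qualitySd
#'   per-read accuracy / quality distribution parameters.
#' @param lengthMean,lengthSd read length distribution (bases).
#' @param coverageMean,coverageSd per-read coverage distribution,
#'   truncated to (0.3, 1].
#' @return a validated [ScenarioSpec-class] object.
#' @export
scenarioSpec <- function(genera, nSamples = 10L, era = c("albacore", "guppy"),
                         illuminaDepth = NULL, nanoporeDepth = NULL,
                         accuracyMean = NULL, accuracySd = 3,
                         accuracyRange = c(70, 100),
                         qualityMean = NULL, qualitySd = 0.65,
                         lengthMean = 1550, lengthSd = 75,
                         coverageMean = 0.9, coverageSd = 0.05) {
  era <- match.arg(era)
  if (is.null(accuracyMean)) accuracyMean <- if (era == "albacore") 85 else 90
  if (is.null(qualityMean)) qualityMean <- if (era == "albacore") 8 else 10
  if (is.null(illuminaDepth))
    illuminaDepth <- function(n) pmax(1000L, as.integer(round(stats::rlnorm(n, log(8e4), 1))))
  if (is.null(nanoporeDepth))
    nanoporeDepth <- function(n) pmax(10L, as.integer(round(stats::rlnorm(n, log(1.5e4), 1))))
  genera$nRefs <- as.integer(genera$nRefs)
  new("ScenarioSpec", genera = genera, nSamples = as.integer(nSamples),
      era = era, illuminaDepth = illuminaDepth, nanoporeDepth = nanoporeDepth,
      accuracyMean = accuracyMean, accuracySd = accuracySd,
      accuracyRange = accuracyRange, qualityMean = qualityMean,
      qualitySd = qualitySd, lengthMean = lengthMean, lengthSd = lengthSd,
      coverageMean = coverageMean, coverageSd = coverageSd)
}

#' Named scenario presets
#'
#' Three stated worlds:
#' \describe{
#'   \item{nasal_community}{57 samples over the six established nasal
#'     genera. *Corynebacterium* has nanopore amplification efficiency 0.1
#'     (primer-mismatch dropout: its expected nanopore share is ~2% against
#'     ~19% on Illumina); *Dolosigranulum* has 2 reference sequences and
#'     confusability 0.97, so >95% of its reads report num_genus_taxid = 2
#'     and fall back to family (*Carnobacteriaceae*).}
#'   \item{pure_culture}{5 replicate runs of a single *Staphylococcus*
#'     species; `basecaller` switches accuracy 85 -> 90 and quality 8 -> 10
#'     to emulate the Albacore -> Guppy upgrade.}
#'   \item{negative_control}{7 sterile-swab samples with near-zero depth
#'     (nanopore 0--56 reads, Illumina 1--3408, uniform), matching the
#'     published control read ranges.}
#' }
#'
#' @param basecaller era for the pure_culture preset ("albacore" or
#'   "guppy"); the community preset reflects the initial Albacore-era
#'   analysis.
#' @return named list of [ScenarioSpec-class] objects.
#' @export
scenarioPresets <- function(basecaller = c("albacore", "guppy")) {
  basecaller <- match.arg(basecaller)
  conc <- 3   # Dirichlet concentration: strong sample-to-sample dominance shifts
  nasal <- data.frame(
    genus = c("Corynebacterium", "Dolosigranulum", "Haemophilus",
              "Moraxella", "Staphylococcus", "Streptococcus"),
    family = c("Corynebacteriaceae", "Carnobacteriaceae", "Pasteurellaceae",
               "Moraxellaceae", "Staphylococcaceae", "Streptococcaceae"),
    alpha = conc * c(0.19, 0.16, 0.16, 0.28, 0.11, 0.10),
    nRefs = c(6L, 2L, 5L, 6L, 8L, 10L),
    confusability = c(0.05, 0.97, 0.30, 0.05, 0.05, 0.05),
    efficiency = c(0.1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  pure <- data.frame(genus = "Staphylococcus", family = "Staphylococcaceae",
                     alpha = 1, nRefs = 8L, confusability = 0.02, efficiency = 1,
                     stringsAsFactors = FALSE)
  list(
    nasal_community = scenarioSpec(nasal, nSamples = 57L, era = "albacore"),
    pure_culture = scenarioSpec(
      pure, nSamples = 5L, era = basecaller,
      illuminaDepth = function(n) rep(5000L, n),
      nanoporeDepth = function(n) pmax(100L, as.integer(round(stats::rlnorm(n, log(5e3), 0.5))))),
    negative_control = scenarioSpec(
      nasal, nSamples = 7L, era = "albacore",
      illuminaDepth = function(n) sample(1:3408, n, replace = TRUE),
      nanoporeDepth = function(n) sample(0:56, n, replace = TRUE))
  )
}

#' Scale a scenario's read depths (testing convenience)
#'
#' Divides both platforms' simulated depths by `factor`, keeping every other
#' parameter of the stated world untouched, so that statistical recovery
#' checks can run quickly at reduced depth.
#'
#' @param spec a [ScenarioSpec-class] object.
#' @param factor depth divisor (> 0).
#' @return the modified spec.
#' @export
scaleDepth <- function(spec, factor) {
  stopifnot(factor > 0)
  ill <- spec@illuminaDepth
  np <- spec@nanoporeDepth
  spec@illuminaDepth <- function(n) pmax(1L, as.integer(round(ill(n) / factor)))
  spec@nanoporeDepth <- function(n) as.integer(round(np(n) / factor))
  spec
}

#' Build the mock taxonomy and reference database of a scenario
#'
#' Creates a taxonomy (root / family / genus / species ranks) holding, per
#' genus, the requested number of species-level reference entries -- the
#' lever behind the reference-sparsity failure: a genus with only 2 entries
#' (the *Dolosigranulum* situation) cannot yield 3 same-genus top hits from
#' distinct references. Each species gets a synthetic ~1.5 kb 16S-like
#' reference sequence carrying concrete binding sites for the nanopore
#' primer pair; genera with amplification efficiency < 0.5 instead carry a
#' corrupted forward site in which only primer positions 2--9 find a match
#' (the *C. propinquum* pattern), so the dropout screen flags them.
#'
#' Taxids are synthetic and deterministic: families from 100, genera from
#' 1000, species from 10000.
#'
#' @param spec a [ScenarioSpec-class] object.
#' @param seed RNG seed; identical spec + seed give an identical database.
#' @return list with `taxonomy` ([Taxonomy-class]), `references`
#'   ([Biostrings::DNAStringSet] named by reference id) and `refInfo`
#'   (data.frame: refId, taxid, species, genus, family, genusTaxid).
#' @export
makeMockDatabase <- function(spec, seed = 1) {
  g <- spec@genera
  families <- unique(g$family)
  famId <- stats::setNames(99L + seq_along(families), families)
  genusId <- stats::setNames(999L + seq_len(nrow(g)), g$genus)
  taxid <- 1L; parent <- 1L; rank <- "root"; name <- "root"
  for (f in families) {
    taxid <- c(taxid, famId[[f]]); parent <- c(parent, 1L)
    rank <- c(rank, "family"); name <- c(name, f)
  }
  for (i in seq_len(nrow(g))) {
    taxid <- c(taxid, genusId[[g$genus[i]]]); parent <- c(parent, famId[[g$family[i]]])
    rank <- c(rank, "genus"); name <- c(name, g$genus[i])
  }
  refRows <- list()
  spId <- 9999L
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(g$nRefs[i])) {
      spId <- spId + 1L
      taxid <- c(taxid, spId); parent <- c(parent, genusId[[g$genus[i]]])
      species <- sprintf("%s sp%02d", g$genus[i], j)
      rank <- c(rank, "species"); name <- c(name, species)
      refRows[[length(refRows) + 1L]] <-
        data.frame(refId = sprintf("ref_%05d", spId), taxid = spId,
                   species = species, genus = g$genus[i], family = g$family[i],
                   genusTaxid = genusId[[g$genus[i]]], stringsAsFactors = FALSE)
    }
  }
  tax <- taxonomy(taxid, parent, rank, name)
  refInfo <- do.call(rbind, refRows)
  primers <- ontPrimers()
  seqs <- withr::with_seed(seed, {
    vapply(seq_len(nrow(refInfo)), function(i) {
      eff <- g$efficiency[match(refInfo$genus[i], g$genus)]
      .mockReference(primers$sequence[1], primers$sequence[2],
                     corruptForward = eff < 0.5)
    }, character(1))
  })
  refs <- Biostrings::DNAStringSet(stats::setNames(seqs, refInfo$refId))
  list(taxonomy = tax, references = refs, refInfo = refInfo)
}

# One synthetic 16S-like reference: pad + forward site + core + reverse site
# + pad. A corrupted forward site keeps only primer positions 2-9 matched.
.mockReference <- function(forward, reverse, corruptForward = FALSE,
                           coreLength = 1410L, padLength = 30L) {
  bases <- c("A", "C", "G", "T")
  rand <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  concrete <- function(primer) {
    map <- Biostrings::IUPAC_CODE_MAP
    chars <- strsplit(toupper(primer), "")[[1]]
    paste(vapply(chars, function(ch) {
      opts <- strsplit(map[[ch]], "")[[1]]
      opts[sample.int(length(opts), 1L)]
    }, character(1)), collapse = "")
  }
  antiBase <- function(primerChar) {
    allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[primerChar]], "")[[1]]
    opts <- setdiff(bases, allowed)
    opts[sample.int(length(opts), 1L)]
  }
  fwdSite <- concrete(forward)
  if (corruptForward) {
    chars <- strsplit(fwdSite, "")[[1]]
    pchars <- strsplit(toupper(forward), "")[[1]]
    mutate <- setdiff(seq_along(chars), 2:9)
    chars[mutate] <- vapply(pchars[mutate], antiBase, character(1))
    fwdSite <- paste(chars, collapse = "")
  }
  revSite <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(concrete(reverse))))
  paste0(rand(padLength), fwdSite, rand(coreLength), revSite, rand(padLength))
}

#' Simulate one paired Illumina / nanopore sample
#'
#' The sample's true genus composition is drawn from the scenario's
#' Dirichlet; Illumina counts are a multinomial draw at the Illumina depth;
#' nanopore reads sample genera with probability proportional to
#' composition times amplification efficiency (renormalized), attach a
#' species taxid from the mock database, and draw accuracy, mean quality,
#' read length and coverage from the scenario distributions.
#' num_genus_taxid is 2 with the genus's confusability (else 1), and is
#' forced to 2 whenever the genus has fewer than 3 reference sequences and
#' confusability 1 -- the database-sparsity mechanism. All efficiencies zero
#' give a valid empty nanopore table.
#'
#' @param spec a [ScenarioSpec-class] object.
#' @param index sample index (used in sample and read ids).
#' @param db mock database from [makeMockDatabase()]; built on the fly when
#'   omitted.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (so [simulateStudy()] controls determinism).
#' @return list with `sample` id, `composition` (true genus proportions),
#'   `illumina` (named genus counts), `nanopore` (EPI2ME-dialect
#'   data.frame), and `truthGenus` (per-read true genus labels, carried
#'   alongside, never consumed by the pipeline).
#' @export
simulateSamplePair <- function(spec, index = 1L, db = NULL, seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, simulateSamplePair(spec, index, db, seed = NULL)))
  if (is.null(db)) db <- makeMockDatabase(spec)
  g <- spec@genera
  k <- nrow(g)
  comp <- stats::rgamma(k, shape = g$alpha, rate = 1)
  comp <- comp / sum(comp)
  names(comp) <- g$genus

  illDepth <- spec@illuminaDepth(1L)
  ill <- stats::rmultinom(1L, illDepth, comp)[, 1]
  names(ill) <- g$genus

  w <- comp * g$efficiency
  sampleName <- sprintf("S%03d", index)
  if (sum(w) == 0) {
    nano <- data.frame(read_id = character(), taxid = integer(),
                       accuracy = numeric(), coverage = numeric(),
                       mean_qscore = numeric(), seq_len = numeric(),
                       num_genus_taxid = integer(), lca = integer(),
                       stringsAsFactors = FALSE)
    return(list(sample = sampleName, composition = comp, illumina = ill,
                nanopore = nano, truthGenus = character()))
  }
  npDepth <- spec@nanoporeDepth(1L)
  gi <- sample.int(k, npDepth, replace = TRUE, prob = w / sum(w))
  # species taxid uniform among the genus's reference entries
  pools <- split(db$refInfo$taxid, db$refInfo$genus)[g$genus]
  taxid <- integer(npDepth)
  for (i in unique(gi)) {
    idx <- which(gi == i)
    pool <- pools[[i]]
    taxid[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
  }
  forced <- g$nRefs < 3L & g$confusability == 1
  ngt <- ifelse(forced[gi] | stats::runif(npDepth) < g$confusability[gi], 2L, 1L)
  acc <- .rtruncnorm(npDepth, spec@accuracyMean, spec@accuracySd,
                     spec@accuracyRange[1], spec@accuracyRange[2])
  qual <- stats::rnorm(npDepth, spec@qualityMean, spec@qualitySd)
  len <- round(.rtruncnorm(npDepth, spec@lengthMean, spec@lengthSd, 1, Inf))
  cov <- .rtruncnorm(npDepth, spec@coverageMean, spec@coverageSd, 0.300001, 1)
  nano <- data.frame(
    read_id = sprintf("%s_r%06d", sampleName, seq_len(npDepth)),
    taxid = taxid, accuracy = acc, coverage = cov, mean_qscore = qual,
    seq_len = len, num_genus_taxid = ngt, lca = as.integer(ngt != 1L),
    stringsAsFactors = FALSE)
  list(sample = sampleName, composition = comp, illumina = ill,
       nanopore = nano, truthGenus = g$genus[gi])
}

# inverse-CDF truncated normal
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate a full paired study
#'
#' Runs [simulateSamplePair()] for every sample of the scenario under one
#' seeded RNG stream: identical spec + seed reproduce the study exactly.
#'
#' @param spec a [ScenarioSpec-class] object.
#' @param seed RNG seed.
#' @param db optional mock database (defaults to `makeMockDatabase(spec,
#'   seed)`).
#' @return list with `db` and `samples` (list of sample-pair results).
#' @export
simulateStudy <- function(spec, seed = 1, db = NULL) {
  if (is.null(db)) db <- makeMockDatabase(spec, seed = seed)
  samples <- withr::with_seed(seed, lapply(seq_len(spec@nSamples), function(i)
    simulateSamplePair(spec, i, db)))
  list(db = db, samples = samples)
}
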