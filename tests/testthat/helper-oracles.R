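# Shared fixtures and brute-force oracles, independent of the package's
# implementation paths.

# Toy taxonomy: two families, three genera, five species.
toyTaxonomy <- function() {
  taxonomy(
    taxid  = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11),
    parent = c(1, 1, 2, 3, 3, 2, 6, 9, 1, 8, 8),
    rank   = c("root", "family", "genus", "species", "species", "genus",
               "species", "genus", "family", "species", "species"),
    name   = c("root", "Carnobacteriaceae", "Dolosigranulum",
               "Dolosigranulum pigrum", "Dolosigranulum sp2",
               "Alloiococcus", "Alloiococcus otitis",
               "Staphylococcus", "Staphylococcaceae",
               "Staphylococcus epidermidis", "Staphylococcus saccharolyticus"))
}

# One hit row in parseOutfmt6's canonical layout.
hitRow <- function(read_id, taxid, pident = 90, nident = 1400, qlen = 1550,
                   evalue = 1e-180, bitscore = 2500) {
  data.frame(read_id = read_id, taxid = taxid, pident = pident,
             nident = nident, qlen = qlen, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

# Random per-read classification records for filter properties.
randomRecords <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    taxid = sample(c(4L, 5L, 7L, 10L, 11L), n, replace = TRUE),
    accuracy = runif(n, 70, 100),
    coverage = runif(n, 0.31, 1),
    mean_qscore = runif(n, 5, 12),
    seq_len = round(runif(n, 1200, 1900)),
    num_genus_taxid = sample(1:3, n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# Record-by-record retention oracle mirroring the written criteria.
retentionOracle <- function(records, minAcc, minQ, lo, hi, ngtSet) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    keep[i] <- r$accuracy >= minAcc && r$mean_qscore >= minQ &&
      r$seq_len >= lo && r$seq_len <= hi && r$num_genus_taxid %in% ngtSet
  }
  keep
}

# Brute-force UPGMA: recompute all pair averages from the original leaf
# distances at each step; returns the ultrametric (cophenetic) distance
# matrix, i.e. each leaf pair's merge height.
upgmaOracle <- function(d) {
  dm <- as.matrix(d)
  labels <- rownames(dm)
  clusters <- as.list(labels)
  coph <- matrix(0, nrow(dm), ncol(dm), dimnames = dimnames(dm))
  clusterDist <- function(a, b) mean(dm[a, b])
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        dij <- clusterDist(clusters[[i]], clusters[[j]])
        if (dij < bestD) { bestD <- dij; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bestD; coph[b, a] <- bestD
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Exhaustive PERMANOVA p over distinct group assignments, using the pairwise
# sum-of-squares identities (no Gower centring).
permanovaExhaustiveOracle <- function(d, groups) {
  dm2 <- as.matrix(d)^2
  n <- nrow(dm2)
  groups <- as.factor(groups)
  a <- nlevels(groups)
  ssTotal <- sum(dm2[upper.tri(dm2)]) / n
  fOf <- function(g) {
    ssW <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ssW <- ssW + sum(dm2[idx, idx][upper.tri(dm2[idx, idx])]) / length(idx)
    }
    ((ssTotal - ssW) / (a - 1)) / (ssW / (n - a))
  }
  fObs <- fOf(groups)
  sizes <- table(groups)
  # enumerate distinct assignments of samples to the two group sizes
  stopifnot(a == 2)
  picks <- utils::combn(n, sizes[1])
  fAll <- apply(picks, 2, function(idx) {
    g <- factor(ifelse(seq_len(n) %in% idx, levels(groups)[1], levels(groups)[2]))
    fOf(g)
  })
  list(fObs = fObs, p = mean(fAll >= fObs - 1e-12))
}

# Independent IUPAC matcher with its own hand-written code table.
iupacOracleTable <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Brute-force best annealing + rule, independent scan.
annealOracle <- function(primer, template, maxMismatch = 2, minRun3 = 3) {
  p <- strsplit(toupper(primer), "")[[1]]
  t <- strsplit(toupper(template), "")[[1]]
  plen <- length(p)
  bestScore <- -1; bestMask <- NULL
  for (s in seq_len(length(t) - plen + 1)) {
    mask <- vapply(seq_len(plen), function(j) {
      tb <- t[s + j - 1]
      tb != "N" && tb %in% iupacOracleTable[[p[j]]]
    }, logical(1))
    if (sum(mask) > bestScore) { bestScore <- sum(mask); bestMask <- mask }
  }
  run3 <- 0
  for (j in rev(seq_len(plen))) {
    if (bestMask[j]) run3 <- run3 + 1 else break
  }
  list(mismatches = plen - bestScore, mask = bestMask, threePrimeRun = run3,
       anneals = (plen - bestScore) <= maxMismatch && run3 >= minRun3)
}

revcompChr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}
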