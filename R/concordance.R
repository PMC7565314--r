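#' Sum of agreement between two platform profiles
#'
#' The per-sample concordance of two normalized genus profiles: the sum over
#' the union of genera of the minimum shared percentage,
#' \eqn{\sum_g \min(A_g, B_g)}. Identical profiles score 100, profiles with
#' disjoint genus sets score 0; algebraically this equals
#' 100 - L1(A, B) / 2.
#'
#' @param a,b [GenusProfile-class] objects (normalized to 100, or empty).
#' @return agreement in percent, 0--100.
#' @export
sumOfAgreement <- function(a, b) {
  if (!length(a@abundance) || !length(b@abundance)) return(0)
  genera <- union(names(a@abundance), names(b@abundance))
  av <- ifelse(genera %in% names(a@abundance), a@abundance[genera], 0)
  bv <- ifelse(genera %in% names(b@abundance), b@abundance[genera], 0)
  sum(pmin(av, bv))
}

#' Bland-Altman agreement statistics for one genus
#'
#' Differences are taken as `a - b` (by convention Illumina minus nanopore,
#' so a genus under-detected by nanopore has a positive mean difference).
#' Limits of agreement are the 95% reference interval mean +/- 1.96 SD with
#' the sample (n-1) standard deviation.
#'
#' @param a,b paired abundance vectors (percent) across samples, length >= 2.
#' @return list with meanDifference, sd, lower, upper, n.
#' @export
blandAltman <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  d <- a[keep] - b[keep]
  if (length(d) < 2L) stop("Bland-Altman needs at least 2 complete pairs")
  m <- mean(d)
  s <- stats::sd(d)
  list(meanDifference = m, sd = s, lower = m - 1.96 * s, upper = m + 1.96 * s,
       n = length(d))
}

#' Per-genus Bland-Altman table for two profile sets
#'
#' @param profilesA,profilesB named lists of [GenusProfile-class] objects
#'   sharing sample ids (A conventionally Illumina, B nanopore).
#' @param genera genera to summarize; default the union over both sets.
#' @return data.frame with one row per genus: meanDifference, sd, lower,
#'   upper, n.
#' @export
blandAltmanTable <- function(profilesA, profilesB, genera = NULL) {
  shared <- intersect(names(profilesA), names(profilesB))
  if (length(shared) < 2L) stop("need >= 2 shared samples")
  mA <- profileMatrix(profilesA[shared])
  mB <- profileMatrix(profilesB[shared])
  if (is.null(genera)) genera <- union(colnames(mA), colnames(mB))
  getCol <- function(m, g) if (g %in% colnames(m)) m[, g] else rep(0, nrow(m))
  rows <- lapply(genera, function(g) {
    ba <- blandAltman(getCol(mA, g), getCol(mB, g))
    data.frame(genus = g, meanDifference = ba$meanDifference, sd = ba$sd,
               lower = ba$lower, upper = ba$upper, n = ba$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1, upper-tail p. Used for the
#' prevalence comparison (e.g. 22/57 vs 46/57 samples positive).
#'
#' @param a,b,c,d cell counts, rows = platforms, columns = present/absent.
#' @return list with statistic, df, p.
#' @export
chiSquare2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  n <- sum(cells)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("chi-square undefined: zero margin")
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Classic paired t-test
#'
#' Paired t on the differences with df = n - 1; pairs with a missing entry
#' are dropped. All-zero differences return t = 0, p = 1 rather than the
#' degenerate error.
#'
#' @param x,y paired numeric vectors of equal length (>= 2 complete pairs).
#' @return list with t, df, p (two-sided), meanDifference, n.
#' @export
pairedTTest <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2L) stop("paired t-test needs >= 2 complete pairs")
  s <- stats::sd(d)
  if (s == 0)
    return(list(t = 0, df = n - 1L, p = 1, meanDifference = mean(d), n = n))
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE),
       meanDifference = mean(d), n = n)
}

#' Pearson / UPGMA clustering of genus profiles
#'
#' Pairwise distance 1 - Pearson correlation of the abundance vectors over
#' the common genus set, agglomerated by unweighted average linkage (UPGMA).
#' Leaf-to-node heights are merge distance / 2, giving an ultrametric tree;
#' the result is returned as a newick string with branch lengths.
#'
#' @param profiles named list of >= 2 [GenusProfile-class] objects, each
#'   with nonzero abundance variance across the common genus set.
#' @return list with `newick` (string), `phylo` (ape tree) and `hclust`.
#' @export
pearsonUpgma <- function(profiles) {
  if (length(profiles) < 2L) stop("need >= 2 profiles to cluster")
  m <- profileMatrix(profiles)
  vr <- apply(m, 1, stats::var)
  if (any(vr == 0))
    stop("zero abundance variance for sample(s): ",
         paste(rownames(m)[vr == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = "average")
  tree <- ape::as.phylo(hc)      # heights halved: ultrametric branch lengths
  list(newick = ape::write.tree(tree), phylo = tree, hclust = hc)
}

#' PERMANOVA on a distance matrix
#'
#' Single-factor permutational multivariate ANOVA. The total sum of squares
#' is taken from the Gower-centred matrix \eqn{G = -\frac12 J D^2 J}
#' (equivalently \eqn{\sum_{i<j} d_{ij}^2 / n}); the between-group share is
#' R^2 = SS_between / SS_total, and the pseudo-F statistic is
#' (SS_b/(a-1)) / (SS_w/(n-a)). The permutation p-value is the fraction of
#' label permutations (the observed labelling included) whose pseudo-F is at
#' least the observed one.
#'
#' @param x either a `dist` object or a samples-by-features abundance matrix
#'   (rows summing to any constant); matrices are converted with the
#'   `method` distance.
#' @param groups factor-like group labels, >= 2 groups with >= 2 members.
#' @param permutations number of random permutations, or `"exhaustive"` to
#'   enumerate all label orders (n <= 8).
#' @param seed RNG seed for random permutations.
#' @param method distance for matrix input (default `"bray"`, Bray-Curtis
#'   via vegan).
#' @return list with pseudoF, R2 (fraction), R2pct (percent), p,
#'   ssBetween, ssWithin, ssTotal, nPermutations.
#' @export
permanova <- function(x, groups, permutations = 999, seed = 1, method = "bray") {
  d <- if (inherits(x, "dist")) x else vegan::vegdist(as.matrix(x), method = method)
  groups <- as.factor(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups length must match the number of samples")
  if (nlevels(droplevels(groups)) < 2L)
    stop("PERMANOVA undefined: need >= 2 distinct groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 members")

  D2 <- as.matrix(d)^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D2 %*% J
  ssTotal <- sum(diag(G))
  a <- nlevels(groups)

  ssWithinFor <- function(g) {
    sw <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1L)
        sw <- sw + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    sw
  }
  fFor <- function(g) {
    sw <- ssWithinFor(g)
    ((ssTotal - sw) / (a - 1)) / (sw / (n - a))
  }
  ssWithin <- ssWithinFor(groups)
  ssBetween <- ssTotal - ssWithin
  fObs <- fFor(groups)

  if (identical(permutations, "exhaustive")) {
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
    perms <- .allPermutations(n)
    fPerm <- vapply(perms, function(p) fFor(groups[p]), numeric(1))
    p <- mean(fPerm >= fObs - 1e-12)
    nPerm <- length(perms)
  } else {
    fPerm <- withr::with_seed(seed, vapply(seq_len(permutations), function(i)
      fFor(sample(groups)), numeric(1)))
    p <- (1 + sum(fPerm >= fObs - 1e-12)) / (1 + permutations)
    nPerm <- permutations
  }
  list(pseudoF = fObs, R2 = ssBetween / ssTotal, R2pct = 100 * ssBetween / ssTotal,
       p = p, ssBetween = ssBetween, ssWithin = ssWithin, ssTotal = ssTotal,
       nPermutations = nPerm)
}

.allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (i in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = i - 1L)
  }
  out
}

#' Full paired-platform concordance report
#'
#' @param profilesA,profilesB named lists of [GenusProfile-class] objects
#'   keyed by shared sample ids (A = Illumina, B = nanopore by convention).
#' @param genera genera for the Bland-Altman table (default all).
#' @param permutations,seed passed to [permanova()].
#' @return list with `agreement` (per-sample data.frame), `summary`
#'   (min/median/max), `blandAltman` (per-genus data.frame), `permanova`.
#' @export
concordanceReport <- function(profilesA, profilesB, genera = NULL,
                              permutations = 999, seed = 1) {
  shared <- intersect(names(profilesA), names(profilesB))
  if (!length(shared)) stop("no shared sample ids")
  soa <- vapply(shared, function(s)
    sumOfAgreement(profilesA[[s]], profilesB[[s]]), numeric(1))
  agreement <- data.frame(sample = shared, sumOfAgreement = soa,
                          stringsAsFactors = FALSE)
  summary <- c(min = min(soa), median = stats::median(soa), max = max(soa))
  ba <- blandAltmanTable(profilesA, profilesB, genera)
  # both platforms padded onto the common genus set before the distance
  mAraw <- profileMatrix(profilesA[shared])
  mBraw <- profileMatrix(profilesB[shared])
  allG <- union(colnames(mAraw), colnames(mBraw))
  mA <- matrix(0, length(shared), length(allG), dimnames = list(shared, allG))
  mB <- mA
  mA[, colnames(mAraw)] <- mAraw
  mB[, colnames(mBraw)] <- mBraw
  perm <- permanova(rbind(mA, mB),
                    rep(c("A", "B"), each = length(shared)),
                    permutations = permutations, seed = seed)
  list(agreement = agreement, summary = summary, blandAltman = ba,
       permanova = perm)
}
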