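test_that("sum of agreement: bounds, hand value, symmetry, L1 identity", {
  a <- buildProfile(c(X = 60, Y = 30, Z = 10), "a")
  b <- buildProfile(c(X = 50, Y = 30, W = 20), "b")
  expect_equal(sumOfAgreement(a, b), 80)
  expect_equal(sumOfAgreement(a, a), 100)
  disjoint <- buildProfile(c(Q = 100), "q")
  expect_equal(sumOfAgreement(a, disjoint), 0)
  expect_equal(sumOfAgreement(a, buildProfile(numeric(0), "e")), 0)

  withr::with_seed(7, {
    for (i in 1:15) {
      pa <- buildProfile(stats::setNames(runif(4), c("A", "B", "C", "D")), "pa")
      pb <- buildProfile(stats::setNames(runif(5), c("B", "C", "D", "E", "F")), "pb")
      s <- sumOfAgreement(pa, pb)
      expect_gte(s, 0); expect_lte(s, 100 + 1e-9)
      expect_equal(s, sumOfAgreement(pb, pa), tolerance = 1e-12)
      genera <- union(names(abundance(pa)), names(abundance(pb)))
      av <- sapply(genera, function(g) { x <- abundance(pa)[g]; ifelse(is.na(x), 0, x) })
      bv <- sapply(genera, function(g) { x <- abundance(pb)[g]; ifelse(is.na(x), 0, x) })
      expect_equal(s, 100 - sum(abs(av - bv)) / 2, tolerance = 1e-9)
    }
  })
})

test_that("Bland-Altman agrees with hand computation and the sign convention", {
  ba <- blandAltman(c(10, 20, 30), c(12, 18, 33))
  expect_equal(ba$meanDifference, -1)
  expect_equal(ba$sd, sqrt(7), tolerance = 1e-12)
  expect_equal(round(ba$sd, 4), 2.6458)
  expect_equal(ba$lower, -1 - 1.96 * sqrt(7), tolerance = 1e-12)
  expect_equal(round(c(ba$lower, ba$upper), 3), c(-6.186, 4.186))

  same <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$meanDifference, same$lower, same$upper), c(0, 0, 0))
  expect_error(blandAltman(1, 2), "2 complete pairs")

  # A = Illumina convention: nanopore under-detection -> positive mean diff
  ill <- c(20, 15, 25); np <- c(2, 1, 3)
  expect_gt(blandAltman(ill, np)$meanDifference, 0)

  # limits contain roughly 95% of differences for large normal samples
  withr::with_seed(8, {
    d <- rnorm(4000, 2, 5)
    ba2 <- blandAltman(d, rep(0, 4000))
    frac <- mean(d >= ba2$lower & d <= ba2$upper)
    expect_gt(frac, 0.93); expect_lt(frac, 0.97)
  })
})

test_that("chi-square 2x2 matches hand expecteds on all small tables", {
  res <- chiSquare2x2(22, 35, 46, 11)
  expect_equal(res$statistic, 20.99233, tolerance = 1e-5)
  expect_lt(res$p, 0.001)
  flat <- chiSquare2x2(10, 10, 10, 10)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_error(chiSquare2x2(0, 0, 5, 5), "zero margin")

  # formula oracle n(ad-bc)^2 / prod(margins) over a grid of small tables,
  # plus agreement with the uncorrected stats::chisq.test
  for (a in c(1, 3, 7)) for (b in c(2, 5)) for (c in c(1, 6)) for (d in c(2, 9)) {
    mine <- chiSquare2x2(a, b, c, d)
    n <- a + b + c + d
    oracle <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(mine$statistic, oracle, tolerance = 1e-12)
    ref <- suppressWarnings(stats::chisq.test(rbind(c(a, b), c(c, d)),
                                              correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("paired t-test matches hand computation and stats::t.test", {
  same <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  res <- pairedTTest(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(res$t, 4), 3.4641)
  swap <- pairedTTest(c(0, 0, 0), c(1, 2, 3))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)
  withr::with_seed(10, {
    x <- rnorm(25, 1); y <- rnorm(25)
    mine <- pairedTTest(x, y)
    ref <- stats::t.test(x, y, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  })
  # missing pairs dropped
  expect_equal(pairedTTest(c(1, 2, NA, 4), c(0, 0, 5, 0))$n, 3)
})

test_that("Pearson/UPGMA clustering equals a brute-force UPGMA oracle", {
  # two identical profiles merge at height 0
  p1 <- buildProfile(c(A = 60, B = 40), "s1")
  p2 <- buildProfile(c(A = 60, B = 40), "s2")
  p3 <- buildProfile(c(A = 5, B = 95), "s3")
  res <- pearsonUpgma(list(s1 = p1, s2 = p2, s3 = p3))
  expect_equal(min(res$hclust$height), 0, tolerance = 1e-12)
  expect_match(res$newick, "s1|s2")

  # random instances: cophenetic distances equal the oracle's merge heights
  withr::with_seed(12, {
    for (n in c(4, 6)) {
      m <- matrix(runif(n * 5), n, 5,
                  dimnames = list(paste0("s", 1:n), paste0("g", 1:5)))
      m <- m / rowSums(m) * 100
      profs <- lapply(seq_len(n), function(i) buildProfile(m[i, ], paste0("s", i)))
      names(profs) <- rownames(m)
      d <- stats::as.dist(1 - stats::cor(t(m)))
      res <- pearsonUpgma(profs)
      coph <- as.matrix(stats::cophenetic(res$hclust))
      oracle <- upgmaOracle(d)
      expect_equal(coph[rownames(oracle), colnames(oracle)], oracle,
                   tolerance = 1e-9)
      # ultrametric: newick branch lengths are half the merge heights and
      # node depths never decrease towards the root
      tr <- res$phylo
      depths <- ape::node.depth.edgelength(tr)
      expect_equal(max(depths), max(res$hclust$height) / 2, tolerance = 1e-9)
    }
  })

  flat <- buildProfile(c(A = 50, B = 50), "flat")
  expect_error(pearsonUpgma(list(flat = flat, flat2 = flat)), "flat")
})

test_that("hand-checkable 3-leaf UPGMA gives the expected newick heights", {
  # leaf distances d(A,B)=2, d(A,C)=8, d(B,C)=6 -> ((A:1,B:1):2.5,C:3.5)
  d <- stats::as.dist(matrix(c(0, 2, 8, 2, 0, 6, 8, 6, 0), 3,
                             dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  hc <- stats::hclust(d, method = "average")
  tr <- ape::as.phylo(hc)
  coph <- as.matrix(stats::cophenetic(hc))
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 7)     # (8 + 6) / 2
  lens <- stats::setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 1, 3.5))
})

test_that("PERMANOVA partitions variance correctly and matches oracles", {
  # duplicated identical profiles, distinct between groups -> R2 = 100%
  m <- rbind(c(80, 20, 0), c(80, 20, 0), c(5, 5, 90), c(5, 5, 90))
  rownames(m) <- paste0("s", 1:4)
  res <- permanova(m, c("a", "a", "b", "b"), permutations = 99, seed = 1)
  expect_equal(res$R2pct, 100, tolerance = 1e-9)

  expect_error(permanova(m, c("a", "a", "a", "a")), "2 distinct groups")
  expect_error(permanova(m, c("a", "b", "b", "b")), "2 members")

  withr::with_seed(13, {
    m6 <- matrix(runif(36), 6, 6); m6 <- m6 / rowSums(m6) * 100
    rownames(m6) <- paste0("s", 1:6)
    g6 <- rep(c("a", "b"), each = 3)
    d <- vegan::vegdist(m6 / 100)
    mine <- permanova(d, g6, permutations = "exhaustive")
    oracle <- permanovaExhaustiveOracle(d, g6)
    expect_equal(mine$pseudoF, oracle$fObs, tolerance = 1e-9)
    expect_equal(mine$p, oracle$p, tolerance = 1e-12)

    # cross-check F and R2 against vegan::adonis2
    m10 <- matrix(runif(60), 10, 6); m10 <- m10 / rowSums(m10)
    g10 <- rep(c("a", "b"), each = 5)
    mine10 <- permanova(m10, g10, permutations = 199, seed = 5)
    ref <- vegan::adonis2(vegan::vegdist(m10) ~ g10, permutations = 199)
    expect_equal(mine10$pseudoF, ref$F[1], tolerance = 1e-9)
    expect_equal(mine10$R2, ref$R2[1], tolerance = 1e-9)
  })

  # seeded permutation p is bit-reproducible
  p1 <- permanova(m, c("a", "a", "b", "b"), permutations = 199, seed = 42)$p
  p2 <- permanova(m, c("a", "a", "b", "b"), permutations = 199, seed = 42)$p
  expect_identical(p1, p2)
})

test_that("concordanceReport assembles agreement, Bland-Altman and PERMANOVA", {
  withr::with_seed(14, {
    genera <- c("Cory", "Dolo", "Morax")
    profsA <- profsB <- list()
    for (i in 1:6) {
      base <- runif(3, 10, 50)
      profsA[[paste0("s", i)]] <- buildProfile(stats::setNames(base, genera), paste0("s", i))
      profsB[[paste0("s", i)]] <- buildProfile(stats::setNames(base + runif(3, -2, 2), genera), paste0("s", i))
    }
  })
  rep <- concordanceReport(profsA, profsB, permutations = 99, seed = 2)
  expect_identical(nrow(rep$agreement), 6L)
  expect_true(all(rep$agreement$sumOfAgreement > 80))
  expect_identical(sort(rep$blandAltman$genus), sort(genera))
  expect_named(rep$summary, c("min", "median", "max"))
  expect_lte(rep$summary["min"], rep$summary["median"])
  expect_true(rep$permanova$R2pct < 50)   # nearly identical platforms
  expect_error(concordanceReport(profsA["s1"], list(zz = profsB$s1)), "shared")
})
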