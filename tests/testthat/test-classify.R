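test_that("parseOutfmt6 orders hits by score with documented tie-breaks", {
  f <- tempfile()
  writeLines(c(
    "r1\tacc1\t90.0\t1500\t50\t5\t1\t1500\t1\t1500\t1e-170\t2400\t4\t1400\t1550",
    "r1\tacc2\t92.0\t1500\t40\t5\t1\t1500\t1\t1500\t1e-180\t2500\t5\t1420\t1550",
    "r1\tacc3\t88.0\t1500\t60\t5\t1\t1500\t1\t1500\t1e-160\t2300\t7\t1380\t1550"), f)
  hits <- parseOutfmt6(f)
  expect_identical(hits$bitscore, c(2500, 2400, 2300))

  # equal bit score: smaller e-value first, then smaller taxid
  writeLines(c(
    "r1\ta\t90\t1500\t50\t5\t1\t1500\t1\t1500\t1e-170\t2400\t9\t1400\t1550",
    "r1\tb\t90\t1500\t50\t5\t1\t1500\t1\t1500\t1e-180\t2400\t8\t1400\t1550",
    "r1\tc\t90\t1500\t50\t5\t1\t1500\t1\t1500\t1e-180\t2400\t7\t1400\t1550"), f)
  hits <- parseOutfmt6(f)
  expect_identical(hits$evalue[1], 1e-180)
  expect_identical(hits$taxid, c(7L, 8L, 9L))

  writeLines(character(0), f)
  expect_identical(nrow(parseOutfmt6(f)), 0L)

  writeLines("r1\ta\tninety\t1500\t50\t5\t1\t1500\t1\t1500\t1e-170\t2400\t9\t1400\t1550", f)
  expect_error(parseOutfmt6(f), "line 1.*non-numeric pident")
})

test_that("classifyRead reproduces the num_genus_taxid / family-fallback logic", {
  tax <- toyTaxonomy()
  # top-3 all Dolosigranulum species -> confident genus call
  hits <- rbind(hitRow("r1", 4, bitscore = 2500), hitRow("r1", 5, bitscore = 2400),
                hitRow("r1", 4, bitscore = 2300))
  rec <- classifyRead(hits, tax)
  expect_identical(rec$num_genus_taxid, 1L)
  expect_identical(rec$lca, 0L)
  expect_identical(rec$rank, "genus-or-below")
  expect_identical(rec$name, "Dolosigranulum")

  # two genera in the top 3 -> family fallback to Carnobacteriaceae
  hits2 <- rbind(hitRow("r2", 4, bitscore = 2500), hitRow("r2", 5, bitscore = 2400),
                 hitRow("r2", 7, bitscore = 2300))
  rec2 <- classifyRead(hits2, tax)
  expect_identical(rec2$num_genus_taxid, 2L)
  expect_identical(rec2$lca, 1L)
  expect_identical(rec2$rank, "family-fallback")
  expect_identical(rec2$name, "Carnobacteriaceae")
  expect_identical(rec2$taxid, 4L)   # top hit still carried

  # coverage = identical matches / query length
  rec3 <- classifyRead(hitRow("r3", 10, nident = 1400, qlen = 1550), tax)
  expect_equal(rec3$coverage, 1400 / 1550, tolerance = 1e-12)
  expect_equal(round(rec3$coverage, 4), 0.9032)

  # base filters: identity must exceed 77, coverage must exceed 0.30
  expect_null(classifyRead(hitRow("r4", 4, pident = 77), tax))
  expect_null(classifyRead(hitRow("r5", 4, nident = 400, qlen = 1550), tax))
})

test_that("classifyRead respects k and base-filter ordering", {
  tax <- toyTaxonomy()
  hits <- rbind(hitRow("r1", 4, bitscore = 2500), hitRow("r1", 7, bitscore = 2400),
                hitRow("r1", 10, bitscore = 2300))
  # k = 1 always gives num_genus_taxid 1
  for (seed in 1:5) {
    shuffled <- withr::with_seed(seed, hits[sample(3), , drop = FALSE])
    shuffled <- shuffled[order(-shuffled$bitscore), , drop = FALSE]
    expect_identical(classifyRead(shuffled, tax, k = 1)$num_genus_taxid, 1L)
  }
  # a top hit failing base filters drops out; next passing hit leads
  hits$pident[1] <- 60
  rec <- classifyRead(hits, tax)
  expect_identical(rec$taxid, 7L)
  expect_identical(rec$num_genus_taxid, 2L)   # Alloiococcus + Staphylococcus
  expect_error(classifyRead(hitRow("r9", 999), tax), "unknown taxid")
})

test_that("exclusion criteria match the published thresholds and a brute-force oracle", {
  alb <- albacoreCriteria()
  rec <- data.frame(read_id = "a", taxid = 4L, accuracy = 79.5, coverage = 0.9,
                    mean_qscore = 8, seq_len = 1500, num_genus_taxid = 1L,
                    stringsAsFactors = FALSE)
  expect_identical(nrow(applyExclusionCriteria(rec, alb)$retained), 0L)  # accuracy < 80

  gup <- guppyCriteria()
  rec2 <- data.frame(read_id = "b", taxid = 4L, accuracy = 86, coverage = 0.9,
                     mean_qscore = 9.2, seq_len = 1450, num_genus_taxid = 1L,
                     lca = 0L, stringsAsFactors = FALSE)
  expect_identical(nrow(applyExclusionCriteria(rec2, gup)$retained), 1L)

  # inclusive window boundary
  rec3 <- rec; rec3$accuracy <- 90; rec3$seq_len <- 1400
  expect_identical(nrow(applyExclusionCriteria(rec3, alb)$retained), 1L)
  rec3$seq_len <- 1700
  expect_identical(nrow(applyExclusionCriteria(rec3, alb)$retained), 1L)
  rec3$seq_len <- 1399
  expect_identical(nrow(applyExclusionCriteria(rec3, alb)$retained), 0L)

  # empty input -> empty output, zero tallies
  res0 <- applyExclusionCriteria(rec[0, ], alb)
  expect_identical(nrow(res0$retained), 0L)
  expect_true(all(res0$tally == 0L))

  # retained fraction equals the record-by-record oracle, tallies consistent
  recs <- randomRecords(400, seed = 11)
  res <- applyExclusionCriteria(recs, alb)
  oracle <- retentionOracle(recs, 80, 7, 1400, 1700, c(1, 2))
  expect_identical(nrow(res$retained), sum(oracle))
  expect_identical(res$retained$read_id, recs$read_id[oracle])
  expect_identical(unname(res$tally["excluded"]), sum(!oracle))
  expect_identical(nrow(res$retained) + nrow(res$excluded), nrow(recs))
})

test_that("retention is monotone when any single threshold is relaxed", {
  recs <- randomRecords(300, seed = 5)
  base <- albacoreCriteria()
  kept <- function(cr) applyExclusionCriteria(recs, cr)$retained$read_id
  baseKept <- kept(base)
  relaxed <- list(
    { cr <- base; cr@minAccuracy <- 75; cr },
    { cr <- base; cr@minQuality <- 6; cr },
    { cr <- base; cr@lengthWindow <- c(1300, 1800); cr },
    { cr <- base; cr@ngtAdmissible <- c(1L, 2L, 3L); cr })
  for (cr in relaxed)
    expect_true(all(baseKept %in% kept(cr)))
})

test_that("genus report name matches the taxonomy lookup invariant", {
  tax <- toyTaxonomy()
  withr::with_seed(3, {
    for (i in 1:20) {
      tids <- sample(c(4L, 5L, 7L, 10L, 11L), 3, replace = TRUE)
      hits <- do.call(rbind, lapply(seq_along(tids), function(j)
        hitRow("r", tids[j], bitscore = 2500 - j)))
      rec <- classifyRead(hits, tax)
      if (rec$num_genus_taxid == 1L)
        expect_identical(rec$name,
                         nameOf(tax, ancestorAtRank(tax, rec$taxid, "genus")))
    }
  })
})

test_that("speciesCall reports the top hit's species, not the truth", {
  tax <- toyTaxonomy()
  expect_identical(speciesCall(list(taxid = 10), tax), "Staphylococcus epidermidis")
  expect_error(speciesCall(list(taxid = 8), tax), "no species")
  # read whose truth is S. epidermidis but whose top hit is S. saccharolyticus
  hits <- rbind(hitRow("r1", 11, bitscore = 2500), hitRow("r1", 10, bitscore = 2450))
  rec <- classifyRead(hits, tax)
  expect_identical(speciesCall(rec, tax), "Staphylococcus saccharolyticus")
})

test_that("EPI2ME CSV round-trips and derives num_genus_taxid / lca", {
  recs <- randomRecords(20, seed = 9)
  recs$lca <- as.integer(recs$num_genus_taxid != 1L)
  f <- tempfile(fileext = ".csv")
  writeEpi2meCsv(recs, f, comment = "test run")
  back <- readEpi2meCsv(f)
  expect_equal(back$accuracy, recs$accuracy, tolerance = 1e-9)
  expect_identical(back$num_genus_taxid, recs$num_genus_taxid)
  # lca-only file gains a derived num_genus_taxid
  recs2 <- recs[setdiff(names(recs), "num_genus_taxid")]
  writeEpi2meCsv(recs2, f)
  back2 <- readEpi2meCsv(f)
  expect_true(all(back2$num_genus_taxid[back2$lca == 0L] == 1L))
  expect_true(all(back2$num_genus_taxid[back2$lca == 1L] == 2L))
})
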