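genome <- testGenome()

test_that("merging follows the 1-bp-intersection rule on inclusive intervals", {
  # single call -> identity
  one <- buildCnvrs(mkCalls(100, 200), genome)
  expect_length(one, 1L)
  expect_equal(GenomicRanges::start(one), 100L)
  expect_equal(GenomicRanges::end(one), 200L)
  expect_equal(one$cnvr_type, "DEL")

  # one shared base (200) joins across samples
  sh <- buildCnvrs(c(mkCalls(100, 200, sample = "a"),
                     mkCalls(200, 300, sample = "b")), genome)
  expect_length(sh, 1L)
  expect_equal(c(GenomicRanges::start(sh), GenomicRanges::end(sh)),
               c(100L, 300L))

  # adjacency (201 follows 200) is NOT an intersection
  ad <- buildCnvrs(c(mkCalls(100, 200, sample = "a"),
                     mkCalls(201, 300, sample = "b")), genome)
  expect_length(ad, 2L)

  # mixed DEL + DUP membership classifies as BOTH
  mx <- buildCnvrs(c(mkCalls(100, 200, type = "DEL", sample = "a"),
                     mkCalls(150, 400, type = "DUP", sample = "b")), genome)
  expect_equal(mx$cnvr_type, "BOTH")
  expect_equal(c(GenomicRanges::start(mx), GenomicRanges::end(mx)),
               c(100L, 400L))
})

test_that("merging is transitive through chains of pairwise overlaps", {
  chain <- c(mkCalls(100, 200, sample = "a"),
             mkCalls(180, 320, sample = "b"),
             mkCalls(300, 500, sample = "c"))
  cnvrs <- buildCnvrs(chain, genome)
  expect_length(cnvrs, 1L)
  expect_equal(GenomicRanges::end(cnvrs), 500L)
  expect_equal(cnvrs$n_samples, 3L)
})

test_that("CNVRs equal the per-bp occupancy brute force on random call sets", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(2:25, 1)
    s <- sample.int(2e4 - 600L, n)
    e <- s + sample.int(500, n)
    calls <- mkCalls(s, e, sample = sample(letters[1:4], n, TRUE))
    got <- buildCnvrs(calls, genome)
    exp <- bruteMerge(s, e, 2e4)
    expect_equal(GenomicRanges::start(got), exp$start)
    expect_equal(GenomicRanges::end(got), exp$end)
  }
})

test_that("every call belongs to exactly one CNVR and order does not matter", {
  set.seed(5)
  n <- 60
  s <- sample.int(5e4, n); e <- s + sample.int(800, n)
  calls <- mkCalls(s, e, sample = sample(c("a", "b", "c"), n, TRUE))
  cnvrs <- buildCnvrs(calls, genome)
  expect_equal(sum(cnvrs$n_calls), n)
  idx <- callMembership(cnvrs, calls)
  expect_true(all(idx >= 1L & idx <= length(cnvrs)))
  perm <- sample(n)
  cnvrs2 <- buildCnvrs(calls[perm], genome)
  expect_identical(IRanges::ranges(cnvrs), IRanges::ranges(cnvrs2))
  expect_identical(cnvrs$cnvr_type, cnvrs2$cnvr_type)
})

test_that("ids follow chromosome order and serials restart per chromosome", {
  calls <- c(mkCalls(c(5000, 100), c(6000, 200), chrom = "2"),
             mkCalls(300, 400, chrom = "1"))
  cnvrs <- buildCnvrs(calls, genome)
  expect_equal(cnvrs$cnvr_id, c("CNVR_1_1", "CNVR_2_1", "CNVR_2_2"))
})

test_that("population views re-merge per population", {
  calls <- c(mkCalls(c(100, 700), c(800, 1500), sample = c("a1", "a2")),
             mkCalls(400, 1200, sample = "b1"))
  calls$population <- c("P1", "P1", "P2")
  views <- populationViews(calls, genome)
  expect_named(views, c("all", "P1", "P2"))
  expect_length(views$all, 1L)
  expect_length(views$P1, 1L)        # a1 and a2 overlap directly
  expect_length(views$P2, 1L)
  # population-specific envelopes differ from the joint one
  expect_equal(GenomicRanges::end(views$P1), 1500L)
  expect_equal(c(GenomicRanges::start(views$P2), GenomicRanges::end(views$P2)),
               c(400L, 1200L))
  # a CNVR whose members are all P1 is absent from the P2 view
  solo <- c(calls, mkCalls(9000, 9900, sample = "a1"))
  solo$population <- c(calls$population, "P1")
  v2 <- populationViews(solo, genome)
  expect_length(v2$P1, 2L)
  expect_length(v2$P2, 1L)
  # per-population views equal brute-force re-merges of the subsets
  for (p in c("P1", "P2"))
    expect_identical(IRanges::ranges(v2[[p]]),
                     IRanges::ranges(buildCnvrs(solo[solo$population == p],
                                                genome)))
})

test_that("chromosome summaries count, cover and flag empty chromosomes", {
  calls <- c(mkCalls(c(1001, 3001), c(2000, 4000), sample = c("a", "b")),
             mkCalls(5001, 7000, type = "DUP", sample = "a"))
  cnvrs <- buildCnvrs(calls, genome)
  smry <- summarizeCnvrs(cnvrs, genome)
  expect_equal(smry$chrom, c("1", "2"))
  expect_equal(smry$n_total, c(3L, 0L))
  expect_equal(smry$n_dup, c(1L, 0L))
  expect_equal(smry$n_del, c(2L, 0L))
  expect_equal(smry$covered_bp[1], 4000)
  expect_equal(smry$coverage_fraction[1], 4000 / 1e6)
  expect_equal(smry$density_per_mb[1], 3)
  expect_equal(smry$median_length_bp, c(1000, 0))
  expect_true(smry$no_cnvrs[2])
  tot <- aggregateChromSummaries(smry)
  expect_equal(tot$n_total, 3L)
  expect_equal(tot$density_per_mb, 3 / 1.5)
})

test_that("DUP/DEL ratio excludes BOTH and flags an empty denominator", {
  calls <- c(mkCalls(c(1001, 5001), c(2000, 6000), type = "DUP",
             sample = "a"),
             mkCalls(9001, 10000, type = "DEL", sample = "a"),
             mkCalls(c(20001, 20501), c(21000, 21400),
                     type = c("DEL", "DUP"), sample = c("a", "b")))
  cnvrs <- buildCnvrs(calls, genome)
  expect_equal(sort(table(cnvrs$cnvr_type))[["BOTH"]], 1L)
  expect_equal(dupDelRatio(cnvrs), 2)
  dels <- buildCnvrs(mkCalls(1001, 2000), genome)
  expect_warning(r <- dupDelRatio(buildCnvrs(mkCalls(1001, 2000,
                                                     type = "DUP"), genome)),
                 "undefined")
  expect_true(is.na(r))
  # brute-force recount on a random fixture
  set.seed(3)
  n <- 80
  s <- sort(sample(seq(1000, 9e5, by = 3000), n))
  rcalls <- mkCalls(s, s + 1500, type = sample(c("DEL", "DUP"), n, TRUE))
  rc <- buildCnvrs(rcalls, genome)
  expect_equal(dupDelRatio(rc),
               sum(rc$cnvr_type == "DUP") / sum(rc$cnvr_type == "DEL"))
})

test_that("length/count correlations match the sum-formula oracle", {
  set.seed(21)
  smry <- data.frame(length_bp = runif(12, 5e7, 3e8))
  smry$n_total <- as.integer(smry$length_bp / 1e6 * runif(12, 3, 6))
  smry$covered_bp <- smry$length_bp * runif(12, 0.05, 0.1)
  r <- lengthCountCorrelation(smry)
  expect_equal(r[["r_count"]], pearsonOracle(smry$length_bp, smry$n_total))
  expect_equal(r[["r_length"]], pearsonOracle(smry$length_bp, smry$covered_bp))
  # exact linearity
  smry$n_total <- as.integer(2 * smry$length_bp / 1e3)
  expect_equal(lengthCountCorrelation(smry)[["r_count"]], 1)
  # zero variance flagged
  smry$n_total <- 5L
  expect_warning(r0 <- lengthCountCorrelation(smry), "zero variance")
  expect_true(is.na(r0[["r_count"]]))
})

test_that("the packaged chromosome count table sums to its printed totals", {
  for (sc in c("all", "aq", "ss")) {
    df <- readChromCounts(table1Path(), scope = sc)
    expect_equal(nrow(df), 18L)
    expect_equal(df$n_total, df$n_dup + df$n_del + df$n_both)
  }
  all <- readChromCounts(table1Path(), scope = "all")
  expect_equal(sum(all$n_dup), 5111)
  expect_equal(sum(all$n_del), 4434)
})
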