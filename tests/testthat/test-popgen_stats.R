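genome <- testGenome()

mkManifest <- function(samples, pops) {
  data.frame(sample_id = samples, population = pops,
             call_file = NA_character_, stringsAsFactors = FALSE)
}

test_that("copy numbers are 2x the base-weighted mean read depth", {
  # one CNVR of 10 kb: s1 DUP rd 1.5 over the whole region, s2 DEL rd 0.5
  # over half of it, s3 no call
  calls <- c(mkCalls(10001, 20000, sample = "s1", type = "DUP", rd = 1.5),
             mkCalls(10001, 15000, sample = "s2", type = "DEL", rd = 0.5))
  man <- mkManifest(c("s1", "s2", "s3"), c("P1", "P1", "P2"))
  cnvrs <- buildCnvrs(calls, genome)
  cne <- buildCNMatrix(cnvrs, calls, man)
  cn <- cnMatrix(cne)
  expect_equal(dim(cn), c(1L, 3L))
  expect_equal(cn[1, "s1"], 3.0)                       # full cover: 2 * 1.5
  expect_equal(cn[1, "s2"], 2 * (0.5 * 5000 + 1 * 5000) / 10000)  # 1.5
  expect_equal(cn[1, "s3"], 2.0)                       # diploid default
  expect_equal(populations(cne), c(s1 = "P1", s2 = "P1", s3 = "P2"))
})

test_that("overlapping same-sample calls contribute their mean RD", {
  calls <- c(mkCalls(1001, 2000, sample = "s1", rd = 0.4),
             mkCalls(1501, 2000, sample = "s1", rd = 0.6))
  man <- mkManifest("s1", "P1")
  cnvrs <- buildCnvrs(calls, genome)
  cne <- buildCNMatrix(cnvrs, calls, man)
  # 500 bp at rd 0.4, 500 bp at mean(0.4, 0.6) = 0.5
  expect_equal(unname(cnMatrix(cne)[1, 1]), 2 * (0.4 * 500 + 0.5 * 500) / 1000)
})

test_that("the CNVRExperiment container validates its contract", {
  cn <- matrix(2, 2, 3)
  x <- mkExperiment(cn, c("P1", "P1", "P2"))
  expect_s4_class(x, "CNVRExperiment")
  expect_error(mkExperiment(matrix(-1, 1, 2), c("A", "B")), "non-negative")
  bad <- matrix(c(2, NA), 1, 2)
  expect_error(mkExperiment(bad, c("A", "B")), "missing")
  expect_output(show(x), "populations")
})

test_that("VST reproduces hand-computed values under the N convention", {
  # pop1 = (2,2,4,4), pop2 = (2,2,2,2): v1 = 1, v2 = 0, vt = 0.75 -> 1/3
  cn <- matrix(c(2, 2, 4, 4, 2, 2, 2, 2), nrow = 1)
  x <- mkExperiment(cn, rep(c("P1", "P2"), each = 4))
  rec <- computeVst(x)
  expect_equal(rec$vst, 1 / 3)
  expect_equal(rec$v_total, 0.75)
  expect_equal(rec$v_pop1, 1)
  expect_equal(rec$v_pop2, 0)
  expect_equal(rec$n_pop1 + rec$n_pop2, 8L)

  # zero within-population variance with real separation -> VST = 1
  one <- computeVst(mkExperiment(matrix(c(4, 4, 4, 2, 2, 2), 1),
                                 rep(c("A", "B"), each = 3)))
  expect_equal(one$vst, 1)

  # no variation at all -> degenerate, VST = 0
  zero <- computeVst(mkExperiment(matrix(2, 1, 6), rep(c("A", "B"), 3)))
  expect_equal(zero$vst, 0)
  expect_true(zero$degenerate)
})

test_that("VST is invariant to relabeling, shifts and rescaling", {
  set.seed(31)
  cn <- matrix(2 + abs(rnorm(30 * 8, sd = 0.7)), nrow = 30)
  pops <- rep(c("P1", "P2"), c(5, 3))
  a <- computeVst(mkExperiment(cn, pops))
  b <- computeVst(mkExperiment(cn, c("P2", "P1")[match(pops, c("P1", "P2"))]))
  expect_equal(a$vst, b$vst)
  shifted <- computeVst(mkExperiment(cn + 3, pops))
  expect_equal(a$vst, shifted$vst)
  scaled <- computeVst(mkExperiment(cn * 2.5, pops))
  expect_equal(a$vst, scaled$vst)
  expect_true(all(a$vst >= 0 & a$vst <= 1))
})

test_that("VST requires exactly two populations", {
  cn <- matrix(2, 2, 6)
  expect_error(computeVst(mkExperiment(cn, rep(c("A", "B", "C"), 2))),
               "exactly 2")
  expect_error(computeVst(mkExperiment(cn, rep("A", 6))), "exactly 2")
})

test_that("the N-1 convention is available and differs as expected", {
  cn <- matrix(c(2, 2, 4, 4, 2, 2, 2, 2), nrow = 1)
  x <- mkExperiment(cn, rep(c("P1", "P2"), each = 4))
  rec <- computeVst(x, denominator = "N-1")
  expect_equal(rec$v_pop1, var(c(2, 2, 4, 4)))
  expect_equal(rec$v_total, var(c(2, 2, 4, 4, 2, 2, 2, 2)))
})

test_that("top-percentile selection follows nearest-rank with ties included", {
  vals <- seq(0, 0.99, by = 0.01)          # 100 distinct values
  rec <- S4Vectors::DataFrame(cnvr_id = sprintf("r%03d", 1:100), vst = vals,
                              degenerate = FALSE)
  sel <- selectTop(rec, fractions = c(0.10, 0.01))
  thr <- S4Vectors::metadata(sel)$vst_thresholds
  expect_equal(thr[["top1"]], 0.98)        # rank ceiling(0.99 * 100) = 99
  expect_equal(sum(sel$top1), 2L)          # 0.98 and 0.99
  expect_equal(thr[["top10"]], 0.89)       # rank ceiling(0.90 * 100) = 90
  expect_equal(sum(sel$top10), 11L)        # ties-inclusive >= threshold
  expect_lte(thr[["top10"]], thr[["top1"]])

  # all-equal values: everything selected at every fraction
  eq <- selectTop(S4Vectors::DataFrame(cnvr_id = "a", vst = rep(0.4, 7),
                                       degenerate = FALSE))
  expect_true(all(eq$top1))
  # single record selected at all fractions
  single <- selectTop(S4Vectors::DataFrame(cnvr_id = "a", vst = 0.2,
                                           degenerate = FALSE))
  expect_true(single$top1 && single$top10)
})

test_that("an all-degenerate VST table selects nothing, with a warning", {
  rec <- S4Vectors::DataFrame(cnvr_id = c("a", "b"), vst = c(0, 0),
                              degenerate = TRUE)
  expect_warning(sel <- selectTop(rec), "degenerate")
  expect_false(any(sel$top1))
  expect_true(all(is.na(S4Vectors::metadata(sel)$vst_thresholds)))
})

test_that("PCA explains variance consistently and fixes signs", {
  # rank-1 matrix: first component carries all variance
  u <- c(1, 2, 3, 4); v <- c(1, 0, -1)
  cn <- 6 + outer(v, u)
  x <- mkExperiment(cn, c("A", "A", "B", "B"))
  p <- cnvPca(x)
  expect_equal(p$varianceExplained[[1]], 1)
  expect_equal(sum(p$varianceExplained, na.rm = TRUE), 1, tolerance = 1e-12)
  # sign convention: largest-magnitude loading positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)
  # constant matrix: variance explained undefined
  expect_warning(pc <- cnvPca(mkExperiment(matrix(2, 3, 4),
                                           c("A", "A", "B", "B"))),
                 "constant")
  expect_true(all(is.na(pc$varianceExplained)))
  expect_error(cnvPca(mkExperiment(matrix(2, 3, 1), "A")), "2 samples")
})

test_that("PCA coordinates reproduce centered data distances", {
  set.seed(13)
  cn <- matrix(2 + rnorm(40 * 6, sd = 0.5), nrow = 40)
  x <- mkExperiment(cn, rep(c("A", "B"), 3))
  p <- cnvPca(x)
  d2 <- dist(p$coordinates)
  expect_equal(as.vector(d2), as.vector(dist(t(cn))), tolerance = 1e-8)
  expect_equal(sum(p$varianceExplained), 1, tolerance = 1e-12)
})

test_that("UPGMA trees agglomerate by average linkage with correct leaves", {
  # 3-leaf: d(A,B) = 1, d(A,C) = d(B,C) = 4 -> ((A,B),C)
  d <- as.dist(matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tr <- upgmaTree(d)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  # ultrametric with root height d/2
  expect_true(ape::is.ultrametric(tr))
  # two samples: a single cherry with branch lengths d/2
  cn <- matrix(c(2, 4, 2, 2), nrow = 2,
               dimnames = list(NULL, c("s1", "s2")))
  x <- mkExperiment(cn, c("A", "B"))
  tr2 <- upgmaTree(x)
  expect_setequal(tr2$tip.label, c("s1", "s2"))
  expect_equal(unname(tr2$edge.length), rep(sqrt(4) / 2, 2))
})

test_that("tree leaves are exactly the sample ids", {
  set.seed(2)
  cn <- matrix(2 + rnorm(25 * 7, sd = 0.3), nrow = 25,
               dimnames = list(NULL, paste0("smp", 1:7)))
  x <- mkExperiment(cn, rep(c("A", "B"), c(4, 3)))
  expect_setequal(upgmaTree(x)$tip.label, paste0("smp", 1:7))
})
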