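test_that("TPM normalization follows the length-normalized rate and sums
           to one million", {
  # equal counts, equal lengths -> an even split
  expect_equal(unname(tpmFromCounts(c(10, 10), c(500, 500))),
               c(5e5, 5e5))
  # equal counts, 1 kb vs 2 kb -> 2:1 rate ratio
  tpm <- tpmFromCounts(c(100, 100), c(1000, 2000))
  expect_equal(unname(tpm[1] / tpm[2]), 2)
  # columns sum to 1e6
  set.seed(4)
  cnt <- matrix(rpois(60, 50), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), c("a", "b", "c")))
  lens <- sample(200:2000, 20)
  tpmM <- tpmFromCounts(cnt, lens)
  expect_equal(unname(colSums(tpmM)), rep(1e6, 3), tolerance = 1e-6)
  # all-zero column warns and stays zero
  expect_warning(z <- tpmFromCounts(c(0, 0), c(100, 100)), "zero")
  expect_equal(unname(z), c(0, 0))
  expect_error(tpmFromCounts(c(1, 1), c(0, 100)), "> 0")
})

test_that("expression tables carry counts, TPM and lengths", {
  cnt <- matrix(c(5, 10, 0, 20), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  se <- expressionTable(cnt, c(100, 200))
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(unname(colSums(SummarizedExperiment::assay(se, "tpm"))),
               c(1e6, 1e6))
  expect_equal(SummarizedExperiment::rowData(se)$length, c(100, 200))
  expect_equal(unname(countExpressedGenes(se, 1)), c(2L, 1L))
})

test_that("relative base count divides normalized depths and masks low
           control coverage", {
  ctrl <- rep(100L, 60)
  # identical tracks and equal factors -> ratio one everywhere
  pr <- relativeBaseCount(ctrl, ctrl, "t1")
  expect_true(all(relativeBaseCounts(pr) == 1))
  expect_equal(depletionEfficiency(pr), 0)
  # halved treated depth -> ratio 0.5, efficiency 0.5
  pr2 <- relativeBaseCount(ctrl %/% 2L, ctrl, "t1")
  expect_true(all(relativeBaseCounts(pr2) == 0.5))
  expect_equal(depletionEfficiency(pr2), 0.5)
  # zero or low control positions are masked, not infinite
  ctrl3 <- ctrl; ctrl3[10] <- 0L; ctrl3[11] <- 5L
  pr3 <- relativeBaseCount(ctrl, ctrl3, "t1", minCov = 10L)
  expect_true(all(is.na(relativeBaseCounts(pr3)[10:11])))
  expect_false(anyNA(relativeBaseCounts(pr3)[-(10:11)]))
  # mismatched lengths are an input error
  expect_error(relativeBaseCount(ctrl[-1], ctrl, "t1"), "length")
})

test_that("relative base count is invariant to rescaling treated depth and
           its size factor together", {
  set.seed(6)
  ctrl <- rpois(80, 50)
  trt <- rbinom(80, ctrl, 0.4)
  a <- relativeBaseCounts(relativeBaseCount(
    trt, ctrl, "t1", normFactors = c(treated = 2e4, control = 4e4)))
  b <- relativeBaseCounts(relativeBaseCount(
    trt * 7L, ctrl, "t1", normFactors = c(treated = 14e4, control = 4e4)))
  expect_equal(a, b)
})

test_that("window smoothing averages the ratio trace but keeps the mask", {
  ctrl <- rep(100L, 9)
  trt <- c(100L, 0L, 100L, 100L, 0L, 100L, 100L, 0L, 100L)
  pr <- relativeBaseCount(trt, ctrl, "t1", window = 3L)
  r <- relativeBaseCounts(pr)
  expect_equal(r[2], mean(c(1, 0, 1)))
  expect_error(relativeBaseCount(trt, ctrl, "t1", window = 2L), "odd")
})

test_that("TPM-level efficiency undoes the renormalization induced by
           depleting abundant targets", {
  # a synthetic table: one dominant target reduced 5-fold, references
  # untouched in read space; TPM renormalization inflates the references
  lens <- c(tgt = 1000, r1 = 1000, r2 = 1500, r3 = 800, r4 = 1200)
  reads <- c(tgt = 50000, r1 = 4000, r2 = 6000, r3 = 3200, r4 = 4800)
  treatedReads <- reads; treatedReads["tgt"] <- reads["tgt"] / 5
  tpm <- cbind(control = tpmFromCounts(reads, lens),
               treated = tpmFromCounts(treatedReads, lens))
  eff <- depletionEfficiencyFromTpm(tpm, targets = "tgt",
                                    reference = paste0("r", 1:4))
  expect_equal(unname(eff["tgt"]), 0.8, tolerance = 1e-12)

  # treated == control -> zero efficiency; full removal -> one
  same <- cbind(control = tpm[, "control"], treated = tpm[, "control"])
  expect_equal(unname(depletionEfficiencyFromTpm(
    same, "tgt", paste0("r", 1:4))["tgt"]), 0)
  gone <- reads; gone["tgt"] <- 0
  tpm2 <- cbind(control = tpm[, "control"],
                treated = tpmFromCounts(gone, lens))
  expect_equal(unname(depletionEfficiencyFromTpm(
    tpm2, "tgt", paste0("r", 1:4))["tgt"]), 1)

  expect_error(depletionEfficiencyFromTpm(tpm, "tgt", character()),
               "empty")
  expect_error(depletionEfficiencyFromTpm(tpm, "tgt", c("tgt", "r1")),
               "disjoint")
})

test_that("efficiency recovery from simulated count tables is within 0.02
           at a million reads", {
  set.seed(8)
  nGenes <- 50
  genes <- sprintf("g%02d", seq_len(nGenes))
  lens <- sample(500:3000, nGenes)
  # dominated abundance: the target consumes 40% of the library
  w <- c(0.4, rep(0.6 / (nGenes - 1), nGenes - 1))
  e <- 0.85
  ctrl <- as.vector(rmultinom(1, 1e6, w))
  trt <- ctrl
  trt[1] <- rbinom(1, ctrl[1], 1 - e)
  tpm <- cbind(control = tpmFromCounts(setNames(ctrl, genes), lens),
               treated = tpmFromCounts(setNames(trt, genes), lens))
  eff <- depletionEfficiencyFromTpm(tpm, genes[1], genes[-1])
  expect_lt(abs(unname(eff) - e), 0.02)
})

test_that("correlation QC works on log TPM and excludes depleted targets", {
  x <- setNames(c(10, 100, 1000, 5, 50), paste0("g", 1:5))
  expect_equal(unname(correlationQC(x, x)), c(1, 1))
  # exact 2-fold scaling is affine in log space -> Pearson 1
  expect_equal(unname(correlationQC(x, 2 * x,
                                    pseudocount = 0)["pearson"]), 1)
  # frozen hand computation on a 5-gene table
  y <- setNames(c(12, 80, 1500, 9, 30), paste0("g", 1:5))
  got <- correlationQC(x, y, pseudocount = 1)
  la <- log10(x + 1); lb <- log10(y + 1)
  expect_equal(unname(got["pearson"]), cor(la, lb))
  expect_equal(unname(got["spearman"]), cor(la, lb, method = "spearman"))
  # excluding the depleted target changes the gene set
  xz <- c(x, tgt = 1e5); yz <- c(y, tgt = 10)
  expect_equal(unname(correlationQC(xz, yz, exclude = "tgt")),
               unname(got))
  expect_error(correlationQC(x[1:2], y[1:2]), "at least 3")
})

test_that("pooled-variance t-test reproduces textbook arithmetic and
           df = n_a + n_b - 2", {
  # identical groups -> t = 0, p = 1
  same <- unpairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # hand arithmetic for (1,2,3) vs (4,5,6): pooled var 1, t = -3.674
  got <- unpairedTTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$df, 4L)  # n = 3 + 3
  expect_equal(got$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  # dual route: agrees with stats::t.test(var.equal = TRUE)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  # degenerate: zero pooled variance with unequal means
  inf <- unpairedTTest(c(2, 2), c(5, 5))
  expect_true(inf$infinite)
  expect_equal(inf$p, 0)
  expect_error(unpairedTTest(1, c(1, 2)), ">= 2")
})

test_that("library-size factors sum coverage over untargeted transcripts", {
  tracks1 <- list(a = rep(2L, 10), b = rep(3L, 10), t = rep(50L, 10))
  tracks2 <- list(a = rep(4L, 10), b = rep(6L, 10), t = rep(5L, 10))
  nf <- librarySizeFactors(tracks2, tracks1, untargeted = c("a", "b"))
  expect_equal(unname(nf), c(100, 50))
  expect_error(librarySizeFactors(tracks2, tracks1, "zz"), "missing")
})
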