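mk_profile <- function(n_t, loh = rep(FALSE, length(n_t))) {
  data.frame(probe_id = sprintf("p%03d", seq_along(n_t)),
             chrom = 1L, pos = seq_along(n_t) * 1000L, n_t = n_t, loh = loh)
}

test_that("per-probe statistics sum aberration levels over samples", {
  p1 <- mk_profile(c(2, 4, 1), loh = c(FALSE, FALSE, TRUE))
  p2 <- mk_profile(c(2, 3, 2), loh = c(FALSE, FALSE, FALSE))
  p3 <- mk_profile(c(2, 2, 0), loh = c(FALSE, TRUE, TRUE))
  st <- probe_statistics(list(p1, p2, p3))
  expect_equal(st$t$t_amp, c(0, 3, 0))   # max(4-2,0) + max(3-2,0)
  expect_equal(st$t$t_del, c(0, 0, 3))   # (2-1) + (2-0)
  expect_equal(st$t$t_loh, c(0, 1, 2))
  expect_error(probe_statistics(list(p1)), "M > 1")

  # all-diploid cohort: every statistic is zero
  st0 <- probe_statistics(list(mk_profile(rep(2, 5)), mk_profile(rep(2, 5))))
  expect_true(all(st0$t == 0))
})

test_that("misaligned probe grids reduce to the logged intersection", {
  p1 <- mk_profile(c(2, 3, 4))
  p2 <- mk_profile(c(2, 3, 4))[1:2, ]
  expect_message(st <- probe_statistics(list(p1, p2)), "dropped")
  expect_equal(nrow(st$probes), 2)
})

test_that("convolution null equals brute-force enumeration", {
  h1 <- statistic_histogram(c(0, 0, 1, 1))
  expect_equal(as.numeric(null_distribution(list(h1))), c(0.5, 0.5))
  h <- null_distribution(list(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(as.numeric(h), c(0.25, 0.5, 0.25))

  set.seed(31)
  hs <- lapply(1:3, function(i) {
    v <- runif(sample(2:5, 1)); v / sum(v)
  })
  H <- as.numeric(null_distribution(hs))
  expect_equal(sum(H), 1, tolerance = 1e-12)
  # exhaustive enumeration over all value triples
  sup <- lapply(hs, function(h) seq_along(h) - 1L)
  grid <- expand.grid(sup)
  pr <- expand.grid(hs[[1]], hs[[2]], hs[[3]])
  tot <- rowSums(grid)
  brute <- vapply(0:max(tot), function(t)
    sum(pr[tot == t, 1] * pr[tot == t, 2] * pr[tot == t, 3]), numeric(1))
  expect_equal(H, brute, tolerance = 1e-12)

  # convolution is order-invariant: bitwise on dyadic masses, to rounding
  # error when the summation order differs
  expect_identical(
    as.numeric(null_distribution(list(c(0.5, 0.5), c(0.25, 0.75)))),
    as.numeric(null_distribution(list(c(0.25, 0.75), c(0.5, 0.5)))))
  expect_equal(as.numeric(null_distribution(hs)),
               as.numeric(null_distribution(rev(hs))), tolerance = 1e-14)
  expect_error(null_distribution(list(numeric(0))), "empty")
  expect_error(null_distribution(list(c(0.3, 0.3))), "not normalized")
})

test_that("exact p-values are tail sums with the documented boundary rules", {
  H <- c(0.5, 0.3, 0.15, 0.05)
  surv <- rev(cumsum(rev(H)))
  expect_equal(exact_pvalues(0:3, H), surv)
  expect_equal(exact_pvalues(3, H), 0.05)              # inclusive default
  expect_equal(exact_pvalues(3, H, inclusive = FALSE), 0)
  expect_equal(exact_pvalues(-5, H), 1)                # below support
  expect_error(exact_pvalues(4, H), "outside")
  # non-increasing in t
  expect_true(all(diff(exact_pvalues(0:3, H)) <= 0))
  # random histogram against a direct-summation oracle
  set.seed(37)
  h <- runif(7); h <- h / sum(h)
  t <- sample(0:6, 20, replace = TRUE)
  oracle <- vapply(t, function(k) sum(h[(k + 1):7]), numeric(1))
  expect_equal(exact_pvalues(t, h), oracle, tolerance = 1e-12)
})

test_that("BH q-values match a hand-rolled step-up", {
  expect_equal(fdr_qvalues(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(41)
  p <- runif(50)^2
  expect_equal(fdr_qvalues(p), bh_stepup(p), tolerance = 1e-12)
  ps <- sort(p)
  expect_true(all(diff(fdr_qvalues(ps)) >= 0))
  expect_error(fdr_qvalues(c(0.5, 1.2)))
})

test_that("cohort-level test flags a shared aberration and writes files", {
  n <- 60
  mk <- function(seed) {
    set.seed(seed)
    n_t <- rep(2, n)
    n_t[25:30] <- 4                       # shared amplification
    n_t[sample(setdiff(1:n, 25:30), 3)] <- sample(c(1, 3), 3, replace = TRUE)
    mk_profile(n_t, loh = n_t == 1)
  }
  rec <- recurrence_test(list(mk(1), mk(2), mk(3), mk(4)))
  expect_true(all(rec$p_amp[rec$t_amp == 0] == 1))
  expect_equal(which.min(rec$q_amp + rank(rec$pos) * 1e-12), 25)
  expect_true(all(rec$q_amp >= 0 & rec$q_amp <= 1))
  prefix <- tempfile("rec")
  write_recurrence(rec, prefix, q_threshold = 0.5)
  tsv <- read.table(paste0(prefix, ".recurrence.tsv"), sep = "\t",
                    header = TRUE, comment.char = "#")
  expect_equal(nrow(tsv), n)
  expect_true(file.exists(paste0(prefix, ".recurrent.bed")))
})
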