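states <- state_catalogue()

test_that("the state catalogue enumerates 20 mirrored-unique genotypes", {
  expect_equal(nrow(states), 20)
  expect_equal(as.integer(table(states$n_t)), c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_true(any(states$m_t == 1 & states$n_t == 2))   # AB
  expect_true(any(states$m_t == 2 & states$n_t == 2))   # BB/AA
  expect_equal(sum(states$n_t == 0), 1)
  expect_true(all(states$m_t >= states$n_t - states$m_t))
  ab <- states[states$m_t == 1 & states$n_t == 2, ]
  expect_false(ab$is_loh)
  expect_true(states$is_loh[states$n_t == 0])
})

test_that("homozygous BAF spread follows the log-linear copy-number model", {
  par <- model_params(K = -0.18, sigma_bhom = 0.06)
  expect_equal(baf_hom_std(2, par), 0.06)
  expect_equal(baf_hom_std(4, par), 0.06 * exp(-0.36))
  expect_gt(baf_hom_std(1, par), par$sigma_bhom)  # variance rises as CN falls
  # log sigma(n) - log sigma(2) = K (n - 2) exactly
  n <- 1:7
  expect_equal(log(baf_hom_std(n, par)) - log(baf_hom_std(2, par)),
               par$K * (n - 2))
  expect_error(baf_hom_std(0, par))
})

test_that("LRR means contract with contamination and saturate at w = 1", {
  probe <- list(gc = 0)
  par0 <- model_params(w = 0.25, o = 0, h = 0, beta = 0.55)
  expect_equal(lrr_mean(list(n_t = 2), probe, par0), 0)
  par_pure <- model_params(w = 0, o = 0, h = 0, beta = 0.55)
  expect_equal(lrr_mean(list(n_t = 4), probe, par_pure), 0.55 * log10(2))
  par_norm <- model_params(w = 1 - 1e-12, o = -0.1, h = 0.02)
  mus <- vapply(c(0, 1, 2, 4, 7), function(n)
    lrr_mean(list(n_t = n), list(gc = 0.3), par_norm), numeric(1))
  expect_equal(mus, rep(-0.1 + 0.02 * 0.3, 5), tolerance = 1e-9)
  # strictly increasing in n_t for w < 1
  mus2 <- vapply(0:7, function(n) lrr_mean(list(n_t = n), probe, par0),
                 numeric(1))
  expect_true(all(diff(mus2) > 0))
})

test_that("BAF means mix tumor and normal alleles and mirror upward", {
  par <- model_params(w = 0.3)
  expect_equal(baf_mean(list(m_t = 1, n_t = 2), 1, par), 0.5)
  expect_equal(baf_mean(list(m_t = 3, n_t = 3), 1, par),
               (0.3 + 0.7 * 3) / (0.6 + 0.7 * 3))
  expect_equal(baf_mean(list(m_t = 3, n_t = 3), 1, par), 0.888888889,
               tolerance = 1e-6)
  par_norm <- model_params(w = 1 - 1e-15)
  expect_equal(baf_mean(list(m_t = 2, n_t = 4), 1, par_norm), 0.5,
               tolerance = 1e-6)
  expect_equal(baf_mean(list(m_t = 0, n_t = 0), 0, par_norm), 1,
               tolerance = 1e-6)
  expect_error(baf_mean(list(m_t = 0, n_t = 0), 1, model_params(w = 0)),
               "no alleles")
})

test_that("emission mixture collapses correctly at the p_f extremes", {
  st <- states[states$m_t == 1 & states$n_t == 2, ]
  probe <- list(lrr = 0.02, baf = 0.53, pfb = 0.4, gc = 0)

  par1 <- model_params(p_f = 1)
  lp <- emission_logprob(probe, st, par1)
  expect_equal(lp, log(1 / 10 * 2))
  # independent of state
  for (i in c(1, 5, 20))
    expect_equal(emission_logprob(probe, states[i, ], par1), lp)

  # p_f = 0 at both component modes: log of the product of the densities
  par0 <- model_params(w = 0, o = 0, h = 0, p_f = 0)
  mode_probe <- list(lrr = 0, baf = 0.5, pfb = 0.4, gc = 0)
  p_hom <- 0.4^2 + 0.6^2
  f_b <- p_hom * exp(waveCNA:::.log_folded_baf(0.5, 1, 0.06)) +
    (1 - p_hom) * exp(waveCNA:::.log_folded_baf(0.5, 0.5, 0.06))
  expect_equal(emission_logprob(mode_probe, st, par0),
               dnorm(0, 0, par0$sigma_l, log = TRUE) + log(f_b))

  # extreme LRR outlier: the fluctuation term dominates the mixture
  par <- model_params(p_f = 0.01)
  out_probe <- list(lrr = 4.9, baf = 0.7, pfb = 0.4, gc = 0)
  lp_out <- emission_logprob(out_probe, st, par)
  expect_equal(lp_out, log(par$p_f * (1 / 10) * 2), tolerance = 0.01)
})

test_that("BAF emission densities integrate to one on [0.5, 1]", {
  for (mu in c(0.5, 0.65, 0.8889, 1)) {
    for (sd in c(0.03, 0.06, 0.12)) {
      mass <- integrate(function(b)
        exp(waveCNA:::.log_folded_baf(b, mu, sd)), 0.5, 1,
        rel.tol = 1e-10)$value
      expect_equal(mass, 1, tolerance = 1e-7)
    }
  }
})

test_that("emission log-density responds smoothly to each parameter", {
  st <- states[states$m_t == 2 & states$n_t == 3, ]
  probe <- list(lrr = 0.1, baf = 0.8, pfb = 0.3, gc = 0.1)
  base <- model_params(w = 0.3)
  f0 <- emission_logprob(probe, st, base)
  for (nm in c("w", "h", "o", "sigma_l", "K", "sigma_bhom", "sigma_bhet")) {
    eps <- 1e-6
    par2 <- base
    par2[[nm]] <- par2[[nm]] + eps
    expect_lt(abs(emission_logprob(probe, st, par2) - f0), 1e-3,
              label = paste("continuity in", nm))
  }
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(model_params(w = 1))
  expect_error(model_params(sigma_l = 0))
  expect_error(model_params(p_f = 1.5))
})
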