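test_that("the transition matrix has the prescribed sparse-switch structure", {
  A0 <- transition_matrix(0, 5)
  expect_equal(A0, diag(5))
  A <- transition_matrix(1e-5, 20)
  expect_equal(unique(diag(A)), 1 - 1e-5)
  expect_equal(A[1, 2], 1e-5 / 19)
  expect_equal(rowSums(A), rep(1, 20))
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(42)
  for (rep in 1:5) {
    N <- sample(2:4, 1); S <- sample(2:3, 1)
    logE <- matrix(rnorm(N * S, sd = 2), N, S)
    A <- matrix(runif(S * S), S, S); A <- A / rowSums(A)
    fb <- waveCNA:::.fb_core(logE, A, 1L)
    oracle <- enumerate_posteriors(logE, A)
    expect_equal(fb$gamma, oracle$gamma, tolerance = 1e-10)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
  }
})

test_that("single probes, symmetric emissions and chain restarts behave", {
  # single-probe chain: posterior proportional to pi * emission
  logE <- matrix(c(log(0.2), log(0.5)), 1, 2)
  fb <- waveCNA:::.fb_core(logE, transition_matrix(0.1, 2), 1L)
  expect_equal(as.numeric(fb$gamma), c(0.2, 0.5) / 0.7)

  # emissions identical across states: uniform posteriors
  logE2 <- matrix(rep(rnorm(6), 2), 6, 2)
  fb2 <- waveCNA:::.fb_core(logE2, transition_matrix(1e-3, 2), 1L)
  expect_equal(fb2$gamma, matrix(0.5, 6, 2))

  # two chromosomes are independent chains
  set.seed(9)
  logE3 <- matrix(rnorm(12), 6, 2)
  A <- transition_matrix(0.05, 2)
  joint <- waveCNA:::.fb_core(logE3, A, c(1L, 4L))
  sep1 <- waveCNA:::.fb_core(logE3[1:3, ], A, 1L)
  sep2 <- waveCNA:::.fb_core(logE3[4:6, ], A, 1L)
  expect_equal(joint$gamma, rbind(sep1$gamma, sep2$gamma), tolerance = 1e-12)
  expect_equal(joint$loglik, sep1$loglik + sep2$loglik, tolerance = 1e-10)

  expect_error(waveCNA:::.fb_core(matrix(-Inf, 2, 2),
                                  transition_matrix(0.1, 2), 1L),
               "probe row 1")
})

test_that("posterior rows sum to one on a realistic track", {
  sim <- simulate_sample(sim_spec(n_probes = 1500, seed = 3))
  fb <- forward_backward(sim$track, model_params())
  expect_equal(rowSums(fb$gamma), rep(1, 1500), tolerance = 1e-9)
  expect_true(all(fb$gamma >= 0))
})

test_that("the K update's gradient and Hessian match finite differences", {
  sim <- simulate_sample(sim_spec(n_probes = 1200, seed = 5))
  pr <- waveCNA:::.prep_track(sim$track)
  states <- state_catalogue()
  par <- model_params()
  em <- waveCNA:::.emissions(pr$l, pr$b, pr$p_hom, pr$g, states, par)
  fb <- waveCNA:::.fb_core(em$log_mix, transition_matrix(par$p_t, 20),
                           pr$starts)
  gamma_f <- fb$gamma * exp(log(par$p_f) + em$log_fluct - em$log_mix)
  u <- fb$gamma - gamma_f
  ks <- waveCNA:::.k_stats(pr$b, u, em$tau_hom, states)

  for (K0 in c(-0.3, -0.15, 0.05)) {
    dv <- waveCNA:::.em_k_derivs(K0, par$sigma_bhom, ks)
    h <- 1e-5
    qp <- waveCNA:::.em_k_objective(K0 + h, par$sigma_bhom, ks)
    qm <- waveCNA:::.em_k_objective(K0 - h, par$sigma_bhom, ks)
    q0 <- waveCNA:::.em_k_objective(K0, par$sigma_bhom, ks)
    expect_equal(dv$grad, (qp - qm) / (2 * h),
                 tolerance = 1e-5)
    expect_equal(dv$hess, (qp - 2 * q0 + qm) / h^2,
                 tolerance = 1e-4)
  }
})

test_that("EM started at the generating truth stays there", {
  sim <- simulate_sample(sim_spec(n_probes = 6000, seed = 11))
  truth <- model_params()
  fit <- em_fit(sim$track, init = truth, max_iter = 3)
  expect_lt(abs(fit$params$w - truth$w), 0.05)
  expect_lt(abs(fit$params$K - truth$K), 0.05)
  expect_lt(abs(fit$params$o - truth$o), 0.02)
  expect_lt(abs(fit$params$sigma_l / truth$sigma_l - 1), 0.1)
  expect_lt(abs(fit$params$sigma_bhom / truth$sigma_bhom - 1), 0.15)
  expect_gt(mean(fit$calls$n_t == sim$truth$n_t), 0.99)
})

test_that("EM log-likelihood is monotone and the fit is self-consistent", {
  sim <- simulate_sample(sim_spec(n_probes = 3000, seed = 13))
  fit <- em_fit(sim$track, init = model_params(w = 0.1, o = 0, K = -0.05,
                                               sigma_l = 0.25))
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  expect_true(fit$converged)
  # ACN equals the posterior-weighted copy number of the decoded genome
  expect_gt(fit$acn, 1.5); expect_lt(fit$acn, 3.5)
})

test_that("estimated contamination ignores a constant LRR shift", {
  sim <- simulate_sample(sim_spec(n_probes = 5000, seed = 17))
  cfg <- run_config(hmm = list(multistart_w = c(0.1, 0.3)),
                    denoise = list(enabled = FALSE))
  fit1 <- fit_cna(sim$track, cfg)
  shifted <- sim$track
  shifted$probes$lrr <- shifted$probes$lrr + 0.4
  fit2 <- fit_cna(shifted, cfg)
  expect_lt(abs(fit1$params$w - fit2$params$w), 0.03)
  expect_equal(fit2$params$o - fit1$params$o, 0.4, tolerance = 0.05)
})

test_that("goodness scores quantify the observed-expected discrepancy", {
  par <- model_params(w = 0, o = 0, h = 0)
  states <- state_catalogue()
  st_ab <- which(states$m_t == 1 & states$n_t == 2)
  mk_calls <- function(track, s)
    data.frame(probe_id = track$probes$probe_id, state = s)

  # probe at both modes scores ~1 (BAF mode of the het branch at 0.5)
  tr0 <- make_track(lrr = 0, baf = 0.5, pfb = 0.5)
  s0 <- goodness_scores(tr0, mk_calls(tr0, st_ab), par)
  expect_gt(s0, 0.95)

  # LRR at mean + 1.96 sigma, BAF at mode: sqrt(0.05 * 1)
  tr1 <- make_track(lrr = 1.96 * par$sigma_l, baf = 0.5, pfb = 0.001)
  s1 <- goodness_scores(tr1, mk_calls(tr1, st_ab), par)
  expect_equal(s1, sqrt(2 * pnorm(-1.96)), tolerance = 0.02)

  # probes from a 50/50 mixture of two copy-number states score lower than
  # probes from the pure assigned state
  set.seed(23)
  n <- 2000
  pure_lrr <- rnorm(n, 0, par$sigma_l)
  sub_lrr <- rnorm(n, ifelse(runif(n) < 0.5, 0, 0.55 * log10(3 / 2)),
                   par$sigma_l)
  baf <- 0.5 + abs(rnorm(n, 0, par$sigma_bhet))
  tr_pure <- make_track(pure_lrr, baf)
  tr_sub <- make_track(sub_lrr, baf)
  g_pure <- goodness_scores(tr_pure, mk_calls(tr_pure, st_ab), par)
  g_sub <- goodness_scores(tr_sub, mk_calls(tr_sub, st_ab), par)
  expect_lt(median(g_sub), median(g_pure))
})

test_that("decoded states map onto aberration classes", {
  calls <- data.frame(m_t = c(2L, 1L, 3L, 1L, 0L, 2L),
                      n_t = c(2L, 2L, 3L, 1L, 0L, 4L))
  cl <- classify_calls(calls)
  expect_equal(cl$class, c("cnloh", "neutral", "amp", "del", "del", "amp"))
  expect_equal(cl$loh, c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("viterbi decoding agrees with MAP on clean segments", {
  sim <- simulate_sample(sim_spec(n_probes = 2000, seed = 29))
  f_map <- em_fit(sim$track, init = model_params(), max_iter = 5)
  f_vit <- em_fit(sim$track, init = model_params(), max_iter = 5,
                  decode = "viterbi")
  expect_gt(mean(f_map$calls$state == f_vit$calls$state), 0.98)
})
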