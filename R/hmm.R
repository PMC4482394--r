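#' Initial transition matrix
#'
#' Builds the S-state transition matrix with diagonal \eqn{1 - p_t} and
#' off-diagonal \eqn{p_t / (S - 1)}; it is held fixed during EM.
#'
#' @param p_t Probability of leaving the current state between adjacent
#'   probes (default `1e-5`).
#' @param S Number of hidden states.
#' @return An `S x S` stochastic matrix.
#' @export
transition_matrix <- function(p_t = 1e-5, S = 20) {
  stopifnot(p_t >= 0, p_t < 1, S >= 2)
  A <- matrix(p_t / (S - 1), S, S)
  diag(A) <- 1 - p_t
  A
}

# per-track preprocessed signal vectors used by the E-step
.prep_track <- function(track) {
  p <- track$probes
  b <- pmin(pmax(p$baf, 0), 1)
  list(l = p$lrr,
       b = pmax(b, 1 - b),                       # mirror BAF into [0.5, 1]
       p_hom = p$pfb^2 + (1 - p$pfb)^2,          # P(normal genotype homozygous)
       g = .gc_covariate(p),
       starts = c(1L, which(diff(p$chrom) != 0) + 1L))
}

#' Forward-backward posteriors and log-likelihood
#'
#' Runs the scaled forward-backward algorithm over the emission densities of
#' every hidden state, treating chromosomes as independent chains that each
#' restart from the uniform initial distribution.
#'
#' @param track A `"sample_track"`.
#' @param params A [model_params()] object.
#' @param A Transition matrix; default [transition_matrix()] for the state
#'   count.
#' @param states State catalogue (default [state_catalogue()]).
#' @return List with `gamma` (N x S posterior matrix, rows sum to 1) and
#'   `loglik`.
#' @export
forward_backward <- function(track, params, A = NULL,
                             states = state_catalogue()) {
  pr <- .prep_track(track)
  if (is.null(A)) A <- transition_matrix(params$p_t, nrow(states))
  em <- .emissions(pr$l, pr$b, pr$p_hom, pr$g, states, params)
  .fb_core(em$log_mix, A, pr$starts)
}

# ---- M-step helpers -------------------------------------------------------

# expected signal-branch objective as a function of w only (LRR part plus
# heterozygous-BAF part; terms constant in w dropped). u: signal weights
# gamma - gamma_f; tau: homozygous-branch responsibilities.
.q_w <- function(w, l, b, g, u, tau, states, par) {
  n_t <- states$n_t; m_t <- states$m_t
  mu_state <- par$beta * log10(.eff_cn(n_t, w) / 2) + par$o
  resid <- l - matrix(mu_state, length(l), length(n_t), byrow = TRUE) -
    par$h * g
  q <- -sum(u * resid^2) / (2 * par$sigma_l^2)
  den <- w * 2 + (1 - w) * n_t
  ok <- n_t >= 1
  mu_het <- ifelse(ok, (w + (1 - w) * m_t) / pmax(den, 1e-12), 0.5)
  mu_het <- pmax(mu_het, 1 - mu_het)
  uhet <- u * (1 - tau)
  rb <- (b - matrix(mu_het, length(b), length(n_t), byrow = TRUE))^2
  q - sum(uhet[, ok, drop = FALSE] * rb[, ok, drop = FALSE]) /
    (2 * par$sigma_bhet^2)
}

# sufficient statistics for the K update: per-state signal-branch homozygous
# weights W_s and weighted squared deviations B_s = sum_i u tau (b_i - 1)^2,
# for states with n_t >= 1
.k_stats <- function(b, u, tau, states) {
  keep <- states$n_t >= 1
  uh <- u[, keep, drop = FALSE] * tau[, keep, drop = FALSE]
  list(W = colSums(uh),
       B = colSums(uh * (b - 1)^2),
       d = states$n_t[keep] - 2)
}

# expected-log-likelihood objective restricted to K (additive constants in K
# dropped), with its analytic gradient and Hessian
.em_k_objective <- function(K, sigma_bhom, ks) {
  sum(-K * ks$d * ks$W - ks$B * exp(-2 * K * ks$d) / (2 * sigma_bhom^2))
}

.em_k_derivs <- function(K, sigma_bhom, ks) {
  e <- exp(-2 * K * ks$d)
  list(grad = sum(ks$B * ks$d * e / sigma_bhom^2 - ks$d * ks$W),
       hess = sum(-2 * ks$B * ks$d^2 * e / sigma_bhom^2))
}

# one safeguarded Newton step: halve towards the current value while the
# objective decreases; keep the current value if no improvement is found
.newton_safeguard <- function(x, step, obj, lower = -Inf, upper = Inf,
                              max_halving = 10) {
  f0 <- obj(x)
  for (k in 0:max_halving) {
    cand <- min(max(x + step / 2^k, lower), upper)
    if (is.finite(cand) && obj(cand) >= f0) return(cand)
  }
  x
}

.m_step <- function(l, b, g, u, tau, states, par, sigma_l_min = 0) {
  n_t <- states$n_t
  S <- length(n_t)
  N <- length(l)

  # (1) baseline offset o and GC coefficient h: weighted least squares of the
  # copy-number-corrected LRR residual on (1, g)
  base <- par$beta * log10(.eff_cn(n_t, par$w) / 2)
  resid0 <- l - matrix(base, N, S, byrow = TRUE)
  W_i <- rowSums(u)
  R_i <- rowSums(u * resid0)
  Sw <- sum(W_i)
  if (stats::var(g) > 0) {
    Sg <- sum(W_i * g); Sgg <- sum(W_i * g^2)
    Sr <- sum(R_i); Srg <- sum(R_i * g)
    det <- Sw * Sgg - Sg^2
    o_new <- (Sgg * Sr - Sg * Srg) / det
    h_new <- (Sw * Srg - Sg * Sr) / det
  } else {
    o_new <- sum(R_i) / Sw
    h_new <- 0
  }

  # (2) LRR noise scale
  resid <- resid0 - o_new - h_new * g
  sigma_l_new <- max(sqrt(max(sum(u * resid^2) / Sw, 1e-8)), sigma_l_min)

  par2 <- par
  par2$o <- o_new; par2$h <- h_new; par2$sigma_l <- sigma_l_new

  # (3) contamination fraction w: one safeguarded Newton step on the expected
  # log-likelihood profile, numeric derivatives; bisection-style local search
  # as fallback when the curvature is not usable
  qw <- function(w) .q_w(w, l, b, g, u, tau, states, par2)
  d <- 1e-4
  w0 <- min(max(par$w, d), 0.95 - d)
  q_lo <- qw(w0 - d); q_mid <- qw(w0); q_hi <- qw(w0 + d)
  grad <- (q_hi - q_lo) / (2 * d)
  hess <- (q_hi - 2 * q_mid + q_lo) / d^2
  if (is.finite(hess) && hess < 0) {
    step <- -grad / hess
    step <- sign(step) * min(abs(step), 0.2)
    par2$w <- .newton_safeguard(w0, step, qw, lower = 0, upper = 0.95)
  } else {
    opt <- stats::optimize(qw, c(max(0, w0 - 0.1), min(0.95, w0 + 0.1)),
                           maximum = TRUE, tol = 1e-4)
    if (opt$objective > q_mid) par2$w <- opt$maximum
  }

  # (4) heterozygous BAF scale (states with tumor alleles present)
  keep <- n_t >= 1
  den <- par2$w * 2 + (1 - par2$w) * n_t
  mu_het <- ifelse(keep, (par2$w + (1 - par2$w) * states$m_t) /
                     pmax(den, 1e-12), 0.5)
  mu_het <- pmax(mu_het, 1 - mu_het)
  uhet <- (u * (1 - tau))[, keep, drop = FALSE]
  rb_full <- (b - matrix(mu_het, N, S, byrow = TRUE))^2
  rb <- rb_full[, keep, drop = FALSE]
  swe <- sum(uhet)
  if (swe > 0)
    par2$sigma_bhet <- sqrt(max(sum(uhet * rb) / swe, 1e-8))

  # (5) homozygous BAF scale at copy number 2, given current K
  ks <- .k_stats(b, u, tau, states)
  swh <- sum(ks$W)
  if (swh > 0) {
    par2$sigma_bhom <-
      sqrt(max(sum(ks$B * exp(-2 * par$K * ks$d)) / swh, 1e-8))

    # (6) variance-increment coefficient K: safeguarded Newton with the
    # analytic gradient and Hessian, using the updated sigma_2Bhom
    dv <- .em_k_derivs(par$K, par2$sigma_bhom, ks)
    if (is.finite(dv$hess) && dv$hess < 0) {
      step <- -dv$grad / dv$hess
      step <- sign(step) * min(abs(step), 0.5)
      par2$K <- .newton_safeguard(
        par$K, step, function(K) .em_k_objective(K, par2$sigma_bhom, ks),
        lower = -2, upper = 2)
    }
  }
  par2
}

#' Fit the contamination-aware copy-number HMM by EM
#'
#' Iterates the forward-backward E-step (including the per-probe fluctuation
#' posteriors and the homozygous/heterozygous BAF branch responsibilities)
#' and an M-step updating the seven parameters
#' \eqn{\{w, h, o, \sigma_L, K, \sigma_2^{Bhom}, \sigma^{Bhet}\}}:
#' closed-form weighted updates for the offset, GC coefficient and the three
#' scales, and safeguarded Newton steps for `w` and `K`. Iteration stops when
#' the relative log-likelihood change drops below `tol`; the likelihood trace
#' is kept non-decreasing by step safeguards. Final states are decoded from
#' the last posteriors.
#'
#' @param track A `"sample_track"` (BAF mirroring handled internally).
#' @param init Initial [model_params()].
#' @param A Transition matrix; default built from `init$p_t`.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param decode `"map"` (per-probe maximum posterior, default) or
#'   `"viterbi"`.
#' @param states State catalogue.
#' @param sigma_l_min Lower bound on the fitted LRR noise scale. When the
#'   HMM consumes a de-noised track the residuals are autocorrelated, and an
#'   unconstrained \eqn{\sigma_L} overstates the per-probe information; the
#'   pipeline floors it at half the raw probe-to-probe noise scale.
#' @return A `"cna_fit"`: list with `params`, `loglik_trace`, `calls`
#'   (per-probe data.frame with decoded state, genotype, posterior,
#'   fluctuation posterior, goodness score and aberration class), `acn`
#'   (posterior-weighted average copy number), `n_iter`, `converged`.
#' @export
em_fit <- function(track, init = model_params(), A = NULL, max_iter = 50,
                   tol = 1e-3, decode = c("map", "viterbi"),
                   states = state_catalogue(), sigma_l_min = 0) {
  decode <- match.arg(decode)
  stopifnot(max_iter >= 1)
  pr <- .prep_track(track)
  if (is.null(A)) A <- transition_matrix(init$p_t, nrow(states))

  par <- init
  trace <- numeric(0)
  converged <- FALSE
  em <- NULL; fb <- NULL
  prev <- NULL

  for (iter in seq_len(max_iter)) {
    em_new <- .emissions(pr$l, pr$b, pr$p_hom, pr$g, states, par)
    fb_new <- .fb_core(em_new$log_mix, A, pr$starts)
    ll <- fb_new$loglik
    if (!is.finite(ll)) stop("non-finite log-likelihood at iteration ", iter)

    if (length(trace) && ll < trace[length(trace)] - 1e-8 * abs(trace[length(trace)])) {
      # approximate M-step overshot: keep the previous (better) parameters
      par <- prev$par; em <- prev$em; fb <- prev$fb
      converged <- TRUE
      break
    }
    em <- em_new; fb <- fb_new
    trace <- c(trace, ll)
    if (length(trace) >= 2) {
      rel <- abs(ll - trace[length(trace) - 1]) / abs(trace[length(trace) - 1])
      if (rel < tol) { converged <- TRUE; break }
    }
    if (iter == max_iter) break

    gamma <- fb$gamma
    gamma_f <- if (par$p_f > 0)
      gamma * exp(log(par$p_f) + em$log_fluct - em$log_mix)
    else matrix(0, nrow(gamma), ncol(gamma))
    u <- gamma - gamma_f

    prev <- list(par = par, em = em, fb = fb)
    par <- .m_step(pr$l, pr$b, pr$g, u, em$tau_hom, states, par,
                   sigma_l_min = sigma_l_min)
  }

  gamma <- fb$gamma
  gamma_f <- if (par$p_f > 0)
    gamma * exp(log(par$p_f) + em$log_fluct - em$log_mix)
  else matrix(0, nrow(gamma), ncol(gamma))

  map_state <- if (decode == "map") max.col(gamma, ties.method = "first")
  else .viterbi_core(em$log_mix, A, pr$starts)

  n <- length(pr$l)
  calls <- data.frame(probe_id = track$probes$probe_id,
                      state = map_state,
                      genotype = states$genotype[map_state],
                      m_t = states$m_t[map_state],
                      n_t = states$n_t[map_state],
                      posterior = gamma[cbind(seq_len(n), map_state)],
                      fluct_posterior = rowSums(gamma_f))
  cls <- classify_calls(calls)
  calls$class <- cls$class
  calls$loh <- cls$loh
  calls$goodness <- goodness_scores(track, calls, par, states = states)

  structure(list(params = par,
                 loglik_trace = trace,
                 calls = calls,
                 acn = sum(gamma %*% states$n_t) / n,
                 n_iter = length(trace),
                 converged = converged,
                 states = states),
            class = "cna_fit")
}

#' @export
print.cna_fit <- function(x, ...) {
  cat(sprintf("<cna_fit> %d probes, %d EM iterations (%s)\n",
              nrow(x$calls), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  ACN = %.3f  loglik = %.2f\n", x$acn,
              x$loglik_trace[length(x$loglik_trace)]))
  print(x$params)
  invisible(x)
}

#' Multi-start EM fit
#'
#' Runs [em_fit()] from several contamination-fraction starting values and
#' keeps the fit with the best final log-likelihood; EM on this model is
#' multi-modal in `w`, and the grid counters local optima.
#'
#' @param track A `"sample_track"`.
#' @param config A [run_config()] list.
#' @param sigma_l_min Lower bound on the fitted LRR noise scale (see
#'   [em_fit()]).
#' @return The best `"cna_fit"`, with a `starts` attribute summarising all
#'   starts.
#' @export
fit_cna <- function(track, config = run_config(), sigma_l_min = 0) {
  l <- track$probes$lrr
  sigma0 <- max(stats::mad(diff(l)) / sqrt(2), 0.01, sigma_l_min)
  states <- state_catalogue(config$model$max_cn)
  A <- transition_matrix(config$model$p_t, nrow(states))
  fits <- lapply(config$hmm$multistart_w, function(w0) {
    init <- model_params(w = w0, h = 0, o = stats::median(l),
                         sigma_l = sigma0, K = -0.1,
                         sigma_bhom = 0.06, sigma_bhet = 0.06,
                         beta = config$model$beta, p_f = config$model$p_f,
                         p_t = config$model$p_t)
    em_fit(track, init, A = A, max_iter = config$hmm$max_iter,
           tol = config$hmm$tol, decode = config$hmm$decode, states = states,
           sigma_l_min = sigma_l_min)
  })
  lls <- vapply(fits, function(f) f$loglik_trace[length(f$loglik_trace)],
                numeric(1))
  best <- fits[[which.max(lls)]]
  attr(best, "starts") <- data.frame(w0 = config$hmm$multistart_w,
                                     loglik = lls)
  best
}

#' Per-probe goodness-of-fit scores
#'
#' For each probe, combines (i) the two-sided Gaussian tail probability of
#' the observed LRR under the assigned state's LRR distribution and (ii) the
#' two-sided tail probability of the mirrored BAF under the assigned state's
#' best-matching BAF branch (homozygous or heterozygous), as a geometric
#' mean. A probe exactly at both expected values scores 1; scores near 0
#' flag probes whose signals fit no modelled state well — candidate
#' subclonal regions.
#'
#' @param track A `"sample_track"`.
#' @param calls Decoded calls aligned with `track$probes`.
#' @param params A [model_params()] object.
#' @param states State catalogue.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
goodness_scores <- function(track, calls, params,
                            states = state_catalogue()) {
  pr <- .prep_track(track)
  s <- calls$state
  n_t <- states$n_t[s]; m_t <- states$m_t[s]
  w <- params$w
  mu_l <- params$beta * log10(.eff_cn(n_t, w) / 2) + params$o +
    params$h * pr$g
  tail_l <- 2 * pnorm(-abs(pr$l - mu_l) / params$sigma_l)

  den <- w * 2 + (1 - w) * n_t
  sd_hom <- params$sigma_bhom * exp(params$K * (n_t - 2))
  mu_het <- ifelse(den > 0, (w + (1 - w) * m_t) / pmax(den, 1e-12), NA_real_)
  mu_het <- pmax(mu_het, 1 - mu_het)
  p_hom <- pr$p_hom

  tail_b <- rep(1, length(s))
  ok <- den > 0
  if (any(ok)) {
    lh <- log(p_hom[ok]) + .log_folded_baf(pr$b[ok], 1, sd_hom[ok])
    le <- log(1 - p_hom[ok]) +
      .log_folded_baf(pr$b[ok], mu_het[ok], params$sigma_bhet)
    use_hom <- lh >= le
    mu_c <- ifelse(use_hom, 1, mu_het[ok])
    sd_c <- ifelse(use_hom, sd_hom[ok], params$sigma_bhet)
    tail_b[ok] <- 2 * pnorm(-abs(pr$b[ok] - mu_c) / sd_c)
  }
  sqrt(tail_l * pmin(tail_b, 1))
}

#' Classify decoded states into aberration classes
#'
#' @param calls data.frame with `m_t` and `n_t` columns (decoded states).
#' @return data.frame with `class` (`amp` for \eqn{n_t > 2}, `del` for
#'   \eqn{n_t < 2}, `cnloh` for copy-neutral homozygosity, else `neutral`)
#'   and logical `loh` (homozygous with at least one copy, or the null
#'   state).
#' @export
classify_calls <- function(calls) {
  n <- calls$n_t; m <- calls$m_t
  class <- ifelse(n > 2, "amp",
                  ifelse(n < 2, "del",
                         ifelse(m == 2, "cnloh", "neutral")))
  data.frame(class = class, loh = (m == n & n >= 1) | n == 0)
}
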