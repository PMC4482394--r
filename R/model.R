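#' Emission-model parameters
#'
#' Bundles the seven EM-estimated parameters of the signal model together with
#' the fixed configuration constants. The LRR mean for a tumor state with
#' total copy number \eqn{n_t} under normal-cell fraction \eqn{w} is
#' \deqn{\mu_L = \beta \log_{10}\{(2w + (1-w) n_t)/2\} + o + h g_i,}
#' and the standard deviation of homozygous BAF follows the log-linear
#' copy-number model \eqn{\sigma^{Bhom}_{n_t} = \sigma^{Bhom}_2 e^{K (n_t-2)}}.
#'
#' @param w Normal-cell (contamination) fraction in `[0, 1)`.
#' @param h Coefficient of centered local GC content on LRR (GC waviness).
#' @param o LRR baseline offset (aneuploidy shift), log2-ratio units.
#' @param sigma_l Standard deviation of LRR noise (> 0).
#' @param K Variance-increment coefficient of homozygous BAF against copy
#'   number; negative values mean variance rises as copy number falls.
#' @param sigma_bhom Standard deviation of homozygous BAF at copy number 2.
#' @param sigma_bhet Standard deviation of heterozygous BAF (all copy numbers).
#' @param beta LRR contraction coefficient (fixed, not EM-estimated).
#' @param p_f Prior probability that a probe is a signal-fluctuation outlier.
#' @param p_t Prior probability of a hidden-state transition between adjacent
#'   probes.
#' @return An object of class `"cna_params"` (a validated named list).
#' @examples
#' model_params()                 # defaults
#' model_params(w = 0.7, K = -0.1)
#' @export
model_params <- function(w = 0.3, h = 0, o = -0.1, sigma_l = 0.17,
                         K = -0.15, sigma_bhom = 0.06, sigma_bhet = 0.06,
                         beta = 0.55, p_f = 0.01, p_t = 1e-5) {
  stopifnot(is.numeric(w), length(w) == 1L, w >= 0, w < 1,
            is.numeric(sigma_l), sigma_l > 0,
            is.numeric(sigma_bhom), sigma_bhom > 0,
            is.numeric(sigma_bhet), sigma_bhet > 0,
            is.numeric(beta), beta > 0,
            is.numeric(p_f), p_f >= 0, p_f <= 1,
            is.numeric(p_t), p_t >= 0, p_t < 1,
            is.finite(h), is.finite(o), is.finite(K))
  structure(list(w = w, h = h, o = o, sigma_l = sigma_l, K = K,
                 sigma_bhom = sigma_bhom, sigma_bhet = sigma_bhet,
                 beta = beta, p_f = p_f, p_t = p_t),
            class = "cna_params")
}

#' @export
print.cna_params <- function(x, ...) {
  cat("<cna_params>\n")
  cat(sprintf("  w = %.4f  o = %.4f  h = %.4f  sigma_L = %.4f\n",
              x$w, x$o, x$h, x$sigma_l))
  cat(sprintf("  K = %.4f  sigma_2Bhom = %.4f  sigma_Bhet = %.4f\n",
              x$K, x$sigma_bhom, x$sigma_bhet))
  cat(sprintf("  fixed: beta = %.3f  p_f = %.3g  p_t = %.3g\n",
              x$beta, x$p_f, x$p_t))
  invisible(x)
}

#' Catalogue of hidden tumor genotype states
#'
#' Enumerates the tumor genotypes \eqn{G = (m_t, n_t)} used as hidden states:
#' total copy number \eqn{n_t = 0, \dots,} `max_cn` with B-allele count
#' \eqn{m_t}, keeping only one representative of each pair that is
#' indistinguishable after BAF mirroring (\eqn{m_t \ge n_t - m_t}). With the
#' default `max_cn = 7` the per-copy-number counts are 1,1,2,2,3,3,4,4 giving
#' 20 states in total.
#'
#' @param max_cn Largest tumor total copy number modelled.
#' @return A data.frame with columns `index`, `m_t`, `n_t`, `genotype`
#'   (e.g. `"AAB"`, `"-"` for the null state) and `is_loh` (homozygous with
#'   \eqn{n_t \ge 1}, or the null state).
#' @examples
#' nrow(state_catalogue())  # 20
#' @export
state_catalogue <- function(max_cn = 7) {
  stopifnot(max_cn >= 2)
  rows <- list()
  for (n in 0:max_cn) {
    ms <- if (n == 0) 0L else seq.int(ceiling(n / 2), n)
    for (m in ms) rows[[length(rows) + 1L]] <- c(m, n)
  }
  mm <- do.call(rbind, rows)
  geno <- ifelse(mm[, 2] == 0, "-",
                 paste0(strrep("A", mm[, 2] - mm[, 1]), strrep("B", mm[, 1])))
  data.frame(index = seq_len(nrow(mm)),
             m_t = as.integer(mm[, 1]),
             n_t = as.integer(mm[, 2]),
             genotype = geno,
             is_loh = (mm[, 1] == mm[, 2] & mm[, 2] >= 1) | mm[, 2] == 0)
}

#' Copy-number-specific standard deviation of homozygous BAF
#'
#' Evaluates \eqn{\sigma^{Bhom}_{n_t} = \sigma^{Bhom}_2 e^{K (n_t - 2)}}:
#' the spread of mirrored BAF around 1 for homozygous tumor genotypes
#' grows (for `K < 0`) as the copy number decreases.
#'
#' @param n_t Tumor total copy number (>= 1).
#' @param params A [model_params()] object.
#' @return Standard deviation(s), same length as `n_t`.
#' @export
baf_hom_std <- function(n_t, params) {
  stopifnot(all(n_t >= 1))
  params$sigma_bhom * exp(params$K * (n_t - 2))
}

# effective total copies seen by the array: 2 from each normal cell, n_t from
# each tumor cell; floored so log10 stays finite at homozygous deletions
.eff_cn <- function(n_t, w) pmax(w * 2 + (1 - w) * n_t, 0.05)

#' Expected LRR for a hidden state at a probe
#'
#' @param state One row of [state_catalogue()] (or any list with `n_t`).
#' @param probe A list/row with a `gc` field (centered GC content; `NULL` or
#'   `NA` treated as 0).
#' @param params A [model_params()] object.
#' @return The model LRR mean \eqn{\beta \log_{10}(c_w/2) + o + h g_i} with
#'   \eqn{c_w = \max(2w + (1-w) n_t, 0.05)}.
#' @export
lrr_mean <- function(state, probe, params) {
  g <- probe$gc
  if (is.null(g) || all(is.na(g))) g <- 0
  params$beta * log10(.eff_cn(state$n_t, params$w) / 2) +
    params$o + params$h * g
}

#' Expected mirrored BAF for a hidden state
#'
#' Mixes tumor and contaminating normal alleles:
#' \eqn{(w\,m_n + (1-w)\,m_t) / (2w + (1-w)\,n_t)}, then mirrors the result
#' into `[0.5, 1]`. `normal_m` is the B-allele count of the underlying normal
#' genotype (1 for a heterozygous normal; 0 or 2 for homozygous normals, which
#' pair with the homozygous version of the tumor state and fold to mean 1).
#'
#' @param state One row of [state_catalogue()].
#' @param normal_m Normal-genotype B-allele count, 0, 1 or 2.
#' @param params A [model_params()] object.
#' @return Mean mirrored BAF in `[0.5, 1]`.
#' @export
baf_mean <- function(state, normal_m, params) {
  stopifnot(normal_m %in% 0:2)
  w <- params$w
  m_t <- if (normal_m == 1) state$m_t else if (normal_m == 2) state$n_t else 0
  den <- w * 2 + (1 - w) * state$n_t
  if (den == 0)
    stop("no alleles present (w = 0, n_t = 0): BAF modelled as uniform, no mean defined")
  mu <- (w * normal_m + (1 - w) * m_t) / den
  pmax(mu, 1 - mu)
}

# log density of a normal folded at 0.5 and truncated to [0.5, 1]:
# g(b) = [phi(b; mu, sd) + phi(1 - b; mu, sd)] / [Phi(1; mu, sd) - Phi(0; mu, sd)]
.log_folded_baf <- function(b, mu, sd) {
  z <- pnorm(1, mu, sd) - pnorm(0, mu, sd)
  log(dnorm(b, mu, sd) + dnorm(1 - b, mu, sd)) - log(z)
}

# Vectorized emission machinery. Returns N x S matrices used by both the
# forward-backward E-step and the M-step updates:
#   log_mix  - log f(l, b | theta, s), the full two-component mixture
#   log_sig  - log of the signal (non-fluctuation) component f(l|s) f(b|s)
#   tau_hom  - posterior responsibility of the homozygous BAF branch given
#              the state and the signal component
#   mu_l     - LRR means; resid_l - LRR residuals; mu_het - het BAF means
# b must already be mirrored into [0.5, 1]; g must be centered GC (vector or 0).
.emissions <- function(l, b, p_hom, g, states, par) {
  N <- length(l); S <- nrow(states)
  w <- par$w
  cw <- .eff_cn(states$n_t, w)
  mu_l_state <- par$beta * log10(cw / 2) + par$o
  mu_l <- matrix(mu_l_state, N, S, byrow = TRUE) + par$h * g
  log_fl <- dnorm(l, mu_l, par$sigma_l, log = TRUE)

  den <- w * 2 + (1 - w) * states$n_t     # total allele dosage, unfloored
  sd_hom <- par$sigma_bhom * exp(par$K * (states$n_t - 2))
  mu_het_raw <- ifelse(den > 0, (w + (1 - w) * states$m_t) / den, NA_real_)
  mu_het_state <- pmax(mu_het_raw, 1 - mu_het_raw)

  log_ghom <- matrix(0, N, S)
  log_ghet <- matrix(0, N, S)
  log_fb <- matrix(0, N, S)
  p_het <- 1 - p_hom
  for (s in seq_len(S)) {
    if (den[s] == 0) {                     # w = 0, n_t = 0: uniform on [0.5, 1]
      log_fb[, s] <- log(2)
      log_ghom[, s] <- log(2); log_ghet[, s] <- log(2)
    } else {
      lh <- .log_folded_baf(b, 1, sd_hom[s])
      le <- .log_folded_baf(b, mu_het_state[s], par$sigma_bhet)
      log_ghom[, s] <- lh
      log_ghet[, s] <- le
      mx <- pmax(lh, le)
      log_fb[, s] <- mx + log(p_hom * exp(lh - mx) + p_het * exp(le - mx))
    }
  }

  log_sig <- log_fl + log_fb
  log_fluct <- log(1 / 10) + log(2)        # uniform LRR on [-5,5] x mirrored-uniform BAF
  if (par$p_f > 0) {
    d <- log(par$p_f) + log_fluct
    log_mix <- d + log1p((1 - par$p_f) * exp(log_sig - d))
  } else {
    log_mix <- log_sig
  }

  tau_hom <- matrix(p_hom, N, S)
  ok <- den > 0
  for (s in which(ok)) {
    a <- log(p_hom) + log_ghom[, s]
    c2 <- log(p_het) + log_ghet[, s]
    m <- pmax(a, c2)
    tau_hom[, s] <- exp(a - m) / (exp(a - m) + exp(c2 - m))
  }

  list(log_mix = log_mix, log_sig = log_sig, tau_hom = tau_hom,
       mu_l = mu_l, mu_het_state = mu_het_state, sd_hom = sd_hom,
       den = den, log_fluct = log_fluct)
}

#' Log emission density of one probe under one hidden state
#'
#' Evaluates the two-component mixture
#' \deqn{f(l_i, b_i \mid \theta, s) = p_f f(l_i) f(b_i)
#'   + (1 - p_f) f(l_i \mid s)\, f(b_i \mid s),}
#' where the fluctuation densities are uniform (LRR on `[-5, 5]`, BAF uniform
#' folded to density 2 on `[0.5, 1]`) and the signal component is
#' Normal LRR times a BAF mixture over the normal genotype being homozygous
#' (probability \eqn{p^2 + (1-p)^2} from the PFB `p`) or heterozygous
#' (\eqn{2p(1-p)}), each a normal folded at 0.5 and truncated to `[0.5, 1]`.
#'
#' @param probe A list/row with fields `lrr`, `baf` (mirrored to `[0.5, 1]`),
#'   `pfb` and optionally `gc` (centered).
#' @param state One row of [state_catalogue()].
#' @param params A [model_params()] object.
#' @return The log emission density (scalar).
#' @export
emission_logprob <- function(probe, state, params) {
  stopifnot(is.finite(probe$lrr), is.finite(probe$baf),
            probe$baf >= 0.5 - 1e-12, probe$baf <= 1 + 1e-12)
  g <- probe$gc
  if (is.null(g) || is.na(g)) g <- 0
  p <- probe$pfb
  p_hom <- p^2 + (1 - p)^2
  st <- as.data.frame(state)[, c("m_t", "n_t")]
  e <- .emissions(probe$lrr, min(max(probe$baf, 0.5), 1), p_hom, g,
                  st, params)
  as.numeric(e$log_mix[1, 1])
}
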