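#' Default multi-chromosome segment layout for simulations
#'
#' Tiles `n_probes` probe indices into five equally sized chromosomes whose
#' segments span tumor copy numbers 1 to 5, mixing hemizygous deletion,
#' copy-neutral LOH, balanced and unbalanced gains with long stretches of
#' normal diploid genome (about half of all probes).
#'
#' @param n_probes Total probe count (>= 50).
#' @return data.frame with columns `chrom`, `start`, `end` (probe indices,
#'   inclusive), `m_t`, `n_t`.
#' @export
default_genome_segments <- function(n_probes = 50000) {
  stopifnot(n_probes >= 50)
  # fractions of each chromosome given to (m_t, n_t) blocks
  layout <- list(
    list(c(0.60, 1, 2), c(0.40, 1, 1)),                  # del arm
    list(c(0.30, 2, 2), c(0.40, 1, 2), c(0.30, 2, 3)),   # cnLOH + gain
    list(c(0.35, 1, 2), c(0.30, 2, 4), c(0.35, 1, 2)),   # balanced gain
    list(c(0.25, 2, 3), c(0.40, 1, 2), c(0.35, 3, 5)),   # unbalanced gains
    list(c(0.40, 1, 2), c(0.25, 1, 1), c(0.35, 1, 2)))   # interstitial del
  n_chr <- length(layout)
  per <- floor(n_probes / n_chr)
  segs <- list()
  at <- 0L
  for (ci in seq_len(n_chr)) {
    len <- if (ci < n_chr) per else n_probes - at
    fr <- vapply(layout[[ci]], function(v) v[1], numeric(1))
    sizes <- floor(fr * len)
    sizes[length(sizes)] <- len - sum(sizes[-length(sizes)])
    s0 <- at
    for (k in seq_along(sizes)) {
      segs[[length(segs) + 1L]] <-
        data.frame(chrom = ci, start = s0 + 1L, end = s0 + sizes[k],
                   m_t = layout[[ci]][[k]][2], n_t = layout[[ci]][[k]][3])
      s0 <- s0 + sizes[k]
    }
    at <- at + len
  }
  out <- do.call(rbind, segs)
  out$m_t <- as.integer(out$m_t); out$n_t <- as.integer(out$n_t)
  out
}

#' Simulation specification
#'
#' @param n_probes Number of probes.
#' @param segments Segment table (`chrom`, `start`, `end` probe indices,
#'   `m_t`, `n_t`) tiling `1:n_probes` without overlap; default
#'   [default_genome_segments()].
#' @param params Generating truth, a [model_params()] object.
#' @param gc_amplitude Amplitude of the slowly varying sinusoidal GC track
#'   (0 disables GC waviness).
#' @param seed Integer seed; simulation is deterministic given the spec.
#' @return A `"sim_spec"` list.
#' @export
sim_spec <- function(n_probes = 50000, segments = NULL,
                     params = model_params(), gc_amplitude = 0,
                     seed = 1) {
  if (is.null(segments)) segments <- default_genome_segments(n_probes)
  segments <- segments[order(segments$start), , drop = FALSE]
  if (segments$start[1] != 1L || segments$end[nrow(segments)] != n_probes ||
      (nrow(segments) > 1 &&
       any(segments$start[-1] != segments$end[-nrow(segments)] + 1L)))
    stop("segments must tile 1:n_probes without gaps or overlap")
  stopifnot(all(segments$m_t <= segments$n_t), all(segments$m_t >= 0))
  structure(list(n_probes = as.integer(n_probes), segments = segments,
                 params = params, gc_amplitude = gc_amplitude,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# reflect values at the [0, 1] boundaries (array BAF behaviour near the
# rails), then clip anything still outside
.reflect01 <- function(x) {
  x <- ifelse(x > 1, 2 - x, ifelse(x < 0, -x, x))
  pmin(pmax(x, 0), 1)
}

#' Simulate one tumor SNP-array sample
#'
#' Draws, per probe: a normal genotype from the PFB (AA/AB/BB with
#' \eqn{(1-p)^2, 2p(1-p), p^2}); an LRR value from the contamination-mixed
#' copy-number mean plus baseline, GC and Gaussian noise terms; a BAF value
#' from the contamination-mixed allele fraction with the
#' copy-number-specific homozygous noise scale (heterozygous scale
#' otherwise), reflected into `[0, 1]`. With probability `p_f` the probe is
#' replaced by a uniform fluctuation outlier (LRR on `[-5, 5]`, BAF on
#' `[0, 1]`).
#'
#' @param spec A [sim_spec()].
#' @return List with `track` (a `"sample_track"`; `gc` column present when
#'   `gc_amplitude > 0`) and `truth` (per-probe data.frame with the
#'   generating `m_t`, `n_t`, aberration class and fluctuation flag).
#' @examples
#' sim <- simulate_sample(sim_spec(n_probes = 2000, seed = 7))
#' head(sim$track$probes)
#' @export
simulate_sample <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  par <- spec$params
  n <- spec$n_probes
  seg <- spec$segments
  m_t <- integer(n); n_t <- integer(n); chrom <- integer(n)
  for (k in seq_len(nrow(seg))) {
    idx <- seg$start[k]:seg$end[k]
    m_t[idx] <- seg$m_t[k]; n_t[idx] <- seg$n_t[k]; chrom[idx] <- seg$chrom[k]
  }

  pos <- unlist(lapply(split(seq_len(n), chrom), function(ix)
    cumsum(sample(500:2500, length(ix), replace = TRUE))), use.names = FALSE)
  pfb <- runif(n, 0.01, 0.99)
  gc <- if (spec$gc_amplitude > 0)
    0.45 + spec$gc_amplitude * sin(2 * pi * seq_len(n) / 2000) else rep(NA_real_, n)
  g <- if (spec$gc_amplitude > 0) gc - mean(gc) else rep(0, n)

  p_hom_prior <- pfb^2 + (1 - pfb)^2
  r <- runif(n)
  normal_m <- ifelse(r < (1 - pfb)^2, 0L, ifelse(r < p_hom_prior, 2L, 1L))

  w <- par$w
  eff <- .eff_cn(n_t, w)
  lrr <- par$beta * log10(eff / 2) + par$o + par$h * g +
    rnorm(n, sd = par$sigma_l)

  den <- w * 2 + (1 - w) * n_t
  hom <- normal_m != 1L
  # homozygous normals pair with the homozygous version of the tumor state
  b_count <- ifelse(hom, ifelse(normal_m == 2L, n_t, 0L), m_t)
  mu <- ifelse(den > 0, (w * normal_m + (1 - w) * b_count) / pmax(den, 1e-12),
               NA_real_)
  sd_b <- ifelse(hom, par$sigma_bhom * exp(par$K * (n_t - 2)), par$sigma_bhet)
  baf <- ifelse(is.na(mu), runif(n), .reflect01(mu + rnorm(n, sd = sd_b)))

  fluct <- runif(n) < par$p_f
  lrr[fluct] <- runif(sum(fluct), -5, 5)
  baf[fluct] <- runif(sum(fluct))

  probes <- data.frame(probe_id = sprintf("snp%07d", seq_len(n)),
                       chrom = chrom, pos = pos, lrr = lrr, baf = baf,
                       pfb = pfb, gc = gc)
  truth <- data.frame(m_t = m_t, n_t = n_t,
                      classify_calls(data.frame(m_t = m_t, n_t = n_t)),
                      normal_m = normal_m, fluct = fluct)
  list(track = .new_sample_track(sprintf("sim_seed%d", spec$seed), probes),
       truth = truth)
}

#' Simulate a tumor cohort with one shared recurrent aberration
#'
#' Plants the aberration `effect` (a `(m_t, n_t)` pair) across
#' `shared_region` in every sample and adds `n_private` random private
#' aberrations per sample elsewhere; the rest of each genome is normal
#' diploid.
#'
#' @param spec_list List of [sim_spec()] objects (>= 2), one per sample;
#'   their segment tables are replaced by the cohort layout.
#' @param shared_region Probe-index range `c(start, end)` of the planted
#'   aberration.
#' @param effect Integer pair `c(m_t, n_t)` planted in the shared region.
#' @param n_private Number of private aberrations per sample (default 3).
#' @param private_len Probe length range of private aberrations.
#' @return List with `samples` (list of [simulate_sample()] results) and
#'   `shared_region`.
#' @export
simulate_cohort <- function(spec_list, shared_region, effect,
                            n_private = 3,
                            private_len = c(200, 1000)) {
  stopifnot(length(spec_list) >= 2, length(shared_region) == 2,
            length(effect) == 2, effect[1] <= effect[2])
  private_states <- list(c(1L, 1L), c(2L, 2L), c(2L, 3L), c(2L, 4L))
  samples <- lapply(spec_list, function(sp) {
    n <- sp$n_probes
    stopifnot(shared_region[2] <= n)
    set.seed(sp$seed + 10000L)
    occupied <- rep(FALSE, n)
    occupied[shared_region[1]:shared_region[2]] <- TRUE
    segs <- list(data.frame(chrom = 1L, start = shared_region[1],
                            end = shared_region[2],
                            m_t = as.integer(effect[1]),
                            n_t = as.integer(effect[2])))
    placed <- 0L
    tries <- 0L
    while (placed < n_private && tries < 200L) {
      tries <- tries + 1L
      len <- sample(private_len[1]:private_len[2], 1)
      st <- sample(seq_len(n - len), 1)
      if (any(occupied[st:(st + len - 1L)])) next
      occupied[st:(st + len - 1L)] <- TRUE
      eff <- private_states[[sample(length(private_states), 1)]]
      segs[[length(segs) + 1L]] <-
        data.frame(chrom = 1L, start = st, end = st + len - 1L,
                   m_t = eff[1], n_t = eff[2])
      placed <- placed + 1L
    }
    seg <- do.call(rbind, segs)
    seg <- seg[order(seg$start), , drop = FALSE]
    # fill the gaps with normal diploid
    fill <- list()
    at <- 1L
    for (k in seq_len(nrow(seg))) {
      if (seg$start[k] > at)
        fill[[length(fill) + 1L]] <- data.frame(chrom = 1L, start = at,
                                                end = seg$start[k] - 1L,
                                                m_t = 1L, n_t = 2L)
      at <- seg$end[k] + 1L
    }
    if (at <= n)
      fill[[length(fill) + 1L]] <- data.frame(chrom = 1L, start = at, end = n,
                                              m_t = 1L, n_t = 2L)
    seg <- rbind(seg, do.call(rbind, fill))
    seg <- seg[order(seg$start), , drop = FALSE]
    sp2 <- sim_spec(n_probes = n, segments = seg, params = sp$params,
                    gc_amplitude = sp$gc_amplitude, seed = sp$seed)
    simulate_sample(sp2)
  })
  list(samples = samples, shared_region = shared_region, effect = effect)
}

#' Synthetic chromosome for de-noising ROC diagnostics
#'
#' Builds the two-class LRR benchmark used by [level_diagnostics()]: a
#' chromosome mixing broad and focal amplified segments over a diploid
#' baseline, with Gaussian noise at the platform scale and uniform
#' fluctuation outliers — the features of real tumor LRR tracks that make
#' over-aggressive smoothing costly.
#'
#' @param seed Integer seed.
#' @param sigma_l LRR noise standard deviation.
#' @param p_f Fluctuation outlier rate.
#' @return List with `labels` (TRUE for amplified probes) and `lrr`.
#' @export
denoise_roc_fixture <- function(seed = 1, sigma_l = 0.17, p_f = 0.01) {
  set.seed(seed)
  segs <- list(c(3000, 0), c(300, 0.2), c(3000, 0), c(200, 0.15),
               c(3000, 0), c(250, 0.25), c(2000, 0), c(3000, 0.15),
               c(3000, 0), c(400, 0.2), c(2000, 0))
  truth <- unlist(lapply(segs, function(s) rep(s[2], s[1])))
  x <- truth + rnorm(length(truth), sd = sigma_l)
  fl <- runif(length(x)) < p_f
  x[fl] <- runif(sum(fl), -5, 5)
  list(labels = truth > 0, lrr = x)
}
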