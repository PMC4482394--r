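#' Pipeline configuration
#'
#' Nested configuration for the single-sample and cohort pipelines. QC
#' thresholds mirror automatic batch-mode sample elimination: samples whose
#' fitted LRR noise or GC coefficient is extreme, or whose EM did not
#' converge, are excluded from cohort analysis.
#'
#' @param denoise List: `wavelet`, `level`, `enabled`.
#' @param model List: `beta` (LRR contraction), `p_f`, `p_t`, `max_cn`.
#' @param hmm List: `max_iter`, `tol`, `multistart_w` (EM starting grid for
#'   the contamination fraction), `decode` (`"map"` or `"viterbi"`).
#' @param qc List: `max_sigma_l`, `max_abs_h`, `require_converged`.
#' @param recurrence List: `q_threshold`, `inclusive`.
#' @return A `"run_config"` nested list.
#' @export
run_config <- function(denoise = list(), model = list(), hmm = list(),
                       qc = list(), recurrence = list()) {
  merge <- function(defaults, user) {
    stopifnot(all(names(user) %in% names(defaults)))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    denoise = merge(list(wavelet = "sym8", level = 6L, enabled = TRUE),
                    denoise),
    model = merge(list(beta = 0.55, p_f = 0.01, p_t = 1e-5, max_cn = 7L),
                  model),
    hmm = merge(list(max_iter = 50L, tol = 1e-3,
                     multistart_w = c(0.1, 0.3, 0.5), decode = "map"), hmm),
    qc = merge(list(max_sigma_l = 0.35, max_abs_h = 0.2,
                    require_converged = TRUE), qc),
    recurrence = merge(list(q_threshold = 0.05, inclusive = TRUE),
                       recurrence))
  stopifnot(cfg$qc$max_sigma_l > 0, cfg$qc$max_abs_h > 0)
  structure(cfg, class = "run_config")
}

# stable FNV-1a style hash of the configuration, written into output headers
# so result files are traceable to their settings
.config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# pull isolated outlier probes back toward the running median before the
# wavelet transform, so single fluctuation spikes are not smeared into
# spurious local bumps by the smoothing
.winsorize_lrr <- function(x, window = 9, k = 4) {
  if (length(x) < window + 2) return(x)
  med <- stats::runmed(x, window)
  r <- x - med
  cap <- k * stats::mad(r)
  if (cap == 0) return(x)
  pmin(pmax(x, med - cap), med + cap)
}

# de-noise the LRR track chromosome by chromosome (or arm by arm when a
# centromere table chrom -> position is supplied)
.denoise_track <- function(track, cfg, centromeres = NULL) {
  p <- track$probes
  dcfg <- denoise_config(cfg$denoise$wavelet, cfg$denoise$level)
  grp <- p$chrom
  if (!is.null(centromeres)) {
    cen <- centromeres$pos[match(p$chrom, centromeres$chrom)]
    grp <- paste0(p$chrom, ifelse(!is.na(cen) & p$pos > cen, "q", "p"))
  }
  for (gi in split(seq_len(nrow(p)), grp))
    p$lrr[gi] <- suppressWarnings(denoise_lrr(.winsorize_lrr(p$lrr[gi]),
                                              dcfg))
  track$probes <- p
  track
}

#' Call one tumor sample end to end
#'
#' Reads a PennCNV-style signal file, mirrors BAF, wavelet de-noises the
#' LRR track per chromosome (or per arm), fits the contamination-aware HMM
#' by multi-start EM, classifies the decoded states and (optionally) writes
#' per-probe and segment result files plus a one-line summary.
#'
#' @param signal_path Signal file path.
#' @param pfb_path PFB file path.
#' @param cfg A [run_config()].
#' @param gc_path Optional GC track path.
#' @param out_prefix Optional output prefix for [write_calls()].
#' @param centromeres Optional data.frame (`chrom`, `pos`) splitting
#'   chromosomes into arms for de-noising.
#' @param track Alternative to `signal_path`/`pfb_path`: an in-memory
#'   `"sample_track"`.
#' @return The `"cna_fit"` (invisibly when files are written).
#' @export
run_sample <- function(signal_path = NULL, pfb_path = NULL,
                       cfg = run_config(), gc_path = NULL,
                       out_prefix = NULL, centromeres = NULL,
                       track = NULL) {
  if (is.null(track)) {
    track <- tryCatch(
      read_signal_file(signal_path, pfb_path, gc_path),
      error = function(e) stop("sample ", signal_path, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  # raw probe-to-probe noise scale, taken before smoothing: de-noised
  # residuals are autocorrelated and smoothing adds no information, so the
  # fitted sigma_L is floored at this scale to keep the HMM honest about
  # per-probe evidence
  raw_scale <- stats::mad(diff(track$probes$lrr)) / sqrt(2)
  sigma_l_min <- 0
  if (isTRUE(cfg$denoise$enabled)) {
    track <- .denoise_track(track, cfg, centromeres)
    sigma_l_min <- raw_scale
  }
  fit <- fit_cna(track, cfg, sigma_l_min = sigma_l_min)
  p <- fit$params
  message(sprintf(
    "%s: w=%.3f o=%.3f h=%.3f sigma_L=%.3f K=%.3f s2Bhom=%.3f sBhet=%.3f ACN=%.2f %s",
    track$sample_id, p$w, p$o, p$h, p$sigma_l, p$K, p$sigma_bhom,
    p$sigma_bhet, fit$acn,
    if (fit$converged) "converged" else "NOT converged"))
  if (!is.null(out_prefix)) {
    write_calls(track, fit$calls, out_prefix,
                header_extra = c(config = .config_hash(cfg)))
    return(invisible(fit))
  }
  fit
}

# QC verdict for one fitted sample; NULL when the sample passes
.qc_reason <- function(fit, qc) {
  p <- fit$params
  if (p$sigma_l > qc$max_sigma_l)
    return(sprintf("sigma_L %.3f exceeds %.3f", p$sigma_l, qc$max_sigma_l))
  if (abs(p$h) > qc$max_abs_h)
    return(sprintf("|h| %.3f exceeds %.3f (GC-related bias)", abs(p$h),
                   qc$max_abs_h))
  if (qc$require_converged && !fit$converged)
    return("EM did not converge")
  NULL
}

#' Cohort analysis: per-sample calling, QC and recurrence testing
#'
#' Fits every sample, eliminates samples failing quality control (noisy LRR,
#' strong GC bias or non-convergence; reasons are reported), and runs the
#' recurrence significance test over the survivors.
#'
#' @param signal_paths Character vector of signal file paths, or a directory
#'   containing them (`*.txt`/`*.tsv`). Ignored when `tracks` is given.
#' @param pfb_path PFB file path shared by the cohort.
#' @param cfg A [run_config()].
#' @param out_prefix Optional output prefix for recurrence files.
#' @param tracks Optional list of in-memory `"sample_track"` objects.
#' @return List with `fits` (surviving fits), `eliminated` (named character
#'   vector of reasons) and `recurrence` (the [recurrence_test()] table).
#' @export
run_cohort <- function(signal_paths = NULL, pfb_path = NULL,
                       cfg = run_config(), out_prefix = NULL,
                       tracks = NULL) {
  if (is.null(tracks)) {
    if (length(signal_paths) == 1 && dir.exists(signal_paths))
      signal_paths <- list.files(signal_paths, pattern = "\\.(txt|tsv)$",
                                 full.names = TRUE)
    if (length(signal_paths) < 2)
      stop("cohort analysis requires at least two samples")
    tracks <- lapply(signal_paths, read_signal_file, pfb_path = pfb_path)
  }
  if (length(tracks) < 2)
    stop("cohort analysis requires at least two samples")

  fits <- lapply(tracks, function(tr)
    run_sample(track = tr, cfg = cfg))
  names(fits) <- vapply(tracks, function(tr) tr$sample_id, character(1))

  reasons <- vapply(fits, function(f) {
    r <- .qc_reason(f, cfg$qc); if (is.null(r)) NA_character_ else r
  }, character(1))
  eliminated <- reasons[!is.na(reasons)]
  for (nm in names(eliminated))
    message("sample ", nm, " eliminated by QC: ", eliminated[nm])
  keep <- is.na(reasons)
  if (sum(keep) < 2)
    stop("fewer than two samples survive QC; cohort analysis aborted")

  profiles <- Map(function(tr, f)
    data.frame(probe_id = tr$probes$probe_id, chrom = tr$probes$chrom,
               pos = tr$probes$pos, n_t = f$calls$n_t, loh = f$calls$loh),
    tracks[keep], fits[keep])
  rec <- recurrence_test(profiles, inclusive = cfg$recurrence$inclusive)
  if (!is.null(out_prefix))
    write_recurrence(rec, out_prefix, q_threshold = cfg$recurrence$q_threshold,
                     header_extra = c(config = .config_hash(cfg)))
  list(fits = fits[keep], eliminated = eliminated, recurrence = rec)
}

#' Plot a fitted sample
#'
#' Simple three-panel genome plot: LRR with state means, mirrored BAF, and
#' the decoded copy number with LOH flagged.
#'
#' @param x A `"cna_fit"`.
#' @param track The `"sample_track"` the fit was computed from.
#' @param ... Ignored.
#' @return Invisibly `x`.
#' @export
plot.cna_fit <- function(x, track, ...) {
  p <- track$probes
  i <- seq_len(nrow(p))
  old <- graphics::par(mfrow = c(3, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(i, p$lrr, pch = ".", col = "grey40", ylab = "LRR",
                 xlab = "")
  graphics::abline(v = i[diff(p$chrom) != 0], col = "grey80")
  b <- pmax(p$baf, 1 - p$baf)
  graphics::plot(i, b, pch = ".", col = ifelse(x$calls$loh, "blue", "grey40"),
                 ylim = c(0.5, 1), ylab = "mirrored BAF", xlab = "")
  graphics::plot(i, x$calls$n_t, type = "s",
                 col = "red", ylab = "copy number", xlab = "probe index",
                 ylim = c(0, max(x$calls$n_t) + 0.5))
  invisible(x)
}
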