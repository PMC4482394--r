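# Recurrent-aberration significance across a tumor cohort: per-probe
# amplification/deletion/LOH statistics, an exact convolution null built
# from per-sample statistic histograms, tail p-values and BH q-values.

#' Per-probe recurrence statistics across samples
#'
#' Aligns all samples on their common probe grid and computes, per probe,
#' \deqn{T^{amp}_i = \sum_j \max(n_{i,j,t} - n_{i,j,n}, 0),\quad
#'       T^{del}_i = \sum_j \max(n_{i,j,n} - n_{i,j,t}, 0),\quad
#'       T^{LOH}_i = \sum_j 1[\mathrm{LOH}_{i,j}],}
#' with the normal copy number \eqn{n_{i,j,n} = 2} on autosomes.
#'
#' @param profiles List (length >= 2) of per-sample data.frames with columns
#'   `probe_id`, `chrom`, `pos`, `n_t`, `loh` (e.g. the `calls` of a
#'   `"cna_fit"` joined to its probes, or any per-probe table).
#' @return List with `probes` (the common grid), `t` (data.frame of
#'   `t_amp`, `t_del`, `t_loh`) and `per_sample` (list of per-sample
#'   contribution matrices used for the null histograms).
#' @export
probe_statistics <- function(profiles) {
  if (length(profiles) < 2)
    stop("recurrence testing requires more than one sample (M > 1)")
  ids <- Reduce(intersect, lapply(profiles, function(p) p$probe_id))
  if (length(ids) == 0) stop("samples share no probes")
  dropped <- max(vapply(profiles, nrow, integer(1))) - length(ids)
  if (dropped > 0)
    message(dropped, " probe(s) not shared by all samples dropped from the grid")
  ref <- profiles[[1]][match(ids, profiles[[1]]$probe_id), ]
  contrib <- lapply(profiles, function(p) {
    q <- p[match(ids, p$probe_id), ]
    cbind(amp = pmax(q$n_t - 2, 0),
          del = pmax(2 - q$n_t, 0),
          loh = as.integer(q$loh))
  })
  t_amp <- Reduce(`+`, lapply(contrib, function(m) m[, "amp"]))
  t_del <- Reduce(`+`, lapply(contrib, function(m) m[, "del"]))
  t_loh <- Reduce(`+`, lapply(contrib, function(m) m[, "loh"]))
  list(probes = data.frame(probe_id = ids, chrom = ref$chrom, pos = ref$pos),
       t = data.frame(t_amp = t_amp, t_del = t_del, t_loh = t_loh),
       per_sample = contrib)
}

#' Empirical histogram of an integer statistic
#'
#' @param x Non-negative integer statistic values for one sample.
#' @return Normalized density vector `h` where `h[k + 1] = P(T = k)`,
#'   class `"stat_histogram"`.
#' @export
statistic_histogram <- function(x) {
  stopifnot(length(x) > 0, all(x >= 0), all(x == round(x)))
  h <- tabulate(x + 1L, nbins = max(x) + 1L) / length(x)
  structure(h, class = "stat_histogram")
}

#' Exact null distribution by histogram convolution
#'
#' Under the null that aberrations occur at random positions independently
#' in each sample, the cohort statistic at a probe is the sum of M
#' independent draws, one from each sample's statistic histogram; its exact
#' distribution is the M-fold discrete convolution
#' \eqn{H = h_1 \otimes h_2 \otimes \dots \otimes h_M}.
#'
#' @param histograms List of per-sample histograms (vectors over integer
#'   support starting at 0; normalized to sum 1).
#' @return Normalized density vector over `0:sum(max_j)`.
#' @export
null_distribution <- function(histograms) {
  stopifnot(length(histograms) >= 1)
  for (h in histograms) {
    if (length(h) == 0) stop("empty histogram")
    if (abs(sum(h) - 1) > 1e-8) stop("histogram is not normalized")
  }
  out <- Reduce(function(a, b) {
    m <- length(a) + length(b) - 1L
    r <- numeric(m)
    for (j in seq_along(b)) {
      idx <- j:(j + length(a) - 1L)
      r[idx] <- r[idx] + a * b[j]
    }
    r
  }, lapply(histograms, as.numeric))
  structure(out / sum(out), class = "stat_histogram")
}

#' Exact tail p-values from the convolution null
#'
#' Computes \eqn{p_i = \Pr(T \ge t_i)} under the null histogram `H`
#' (`inclusive = TRUE`, the default exact-test convention) or the strict
#' \eqn{\Pr(T > t_i)} variant, under which the maximum attainable statistic
#' receives p = 0.
#'
#' @param t Integer statistic values (within the support of `H`).
#' @param H Null histogram from [null_distribution()].
#' @param inclusive Use the inclusive tail? Default `TRUE`.
#' @return p-values in `[0, 1]`.
#' @export
exact_pvalues <- function(t, H, inclusive = TRUE) {
  H <- as.numeric(H)
  if (any(t > length(H) - 1L))
    stop("statistic value outside the null support")
  surv <- rev(cumsum(rev(H)))            # surv[k + 1] = P(T >= k)
  k <- pmax(as.integer(round(t)), 0L)
  p <- if (inclusive) surv[k + 1L]
  else c(surv[-1L], 0)[k + 1L]           # P(T > k) = P(T >= k + 1)
  p[t < 0] <- 1
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment \eqn{q_{(i)} = \min_{k \ge i} m p_{(k)} / k},
#' clipped at 1 and mapped back to input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
fdr_qvalues <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Cohort-wide recurrence test
#'
#' Runs the full recurrence analysis for the three aberration families:
#' per-probe statistics, per-sample histogram convolution nulls, exact tail
#' p-values and BH q-values, each family corrected separately across probes.
#'
#' @param profiles As in [probe_statistics()].
#' @param inclusive Tail convention, see [exact_pvalues()].
#' @return data.frame with `probe_id`, `chrom`, `pos` and, per family
#'   (`amp`, `del`, `loh`), the statistic `t_*`, `p_*` and `q_*`.
#' @export
recurrence_test <- function(profiles, inclusive = TRUE) {
  st <- probe_statistics(profiles)
  out <- st$probes
  for (fam in c("amp", "del", "loh")) {
    hists <- lapply(st$per_sample, function(m) statistic_histogram(m[, fam]))
    H <- null_distribution(hists)
    t <- st$t[[paste0("t_", fam)]]
    p <- exact_pvalues(t, H, inclusive = inclusive)
    out[[paste0("t_", fam)]] <- t
    out[[paste0("p_", fam)]] <- p
    out[[paste0("q_", fam)]] <- fdr_qvalues(p)
  }
  out
}

#' Write recurrence results
#'
#' Writes the per-probe recurrence table as TSV and a BED file of probes
#' passing the q-value threshold in any family.
#'
#' @param rec Result of [recurrence_test()].
#' @param path Output prefix (`<path>.recurrence.tsv`,
#'   `<path>.recurrent.bed`).
#' @param q_threshold Significance threshold on q-values (default 0.05).
#' @param header_extra Optional named character vector of `# key: value`
#'   comment lines.
#' @return Invisibly `rec`.
#' @export
write_recurrence <- function(rec, path, q_threshold = 0.05,
                             header_extra = NULL) {
  hdr <- if (length(header_extra))
    sprintf("# %s: %s", names(header_extra), header_extra)
  .write_tsv(rec, paste0(path, ".recurrence.tsv"), hdr)
  sig <- rec[rec$q_amp <= q_threshold | rec$q_del <= q_threshold |
               rec$q_loh <= q_threshold, , drop = FALSE]
  fam <- apply(cbind(amp = sig$q_amp, del = sig$q_del, loh = sig$q_loh),
               1, function(r) paste(names(r)[r <= q_threshold], collapse = ","))
  bed <- data.frame(chrom = sig$chrom, start = sig$pos - 1L, end = sig$pos,
                    name = if (nrow(sig)) fam else character(0))
  .write_tsv(bed, paste0(path, ".recurrent.bed"), hdr, col.names = FALSE)
  invisible(rec)
}
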