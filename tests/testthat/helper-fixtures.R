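# in-memory track builder for unit tests
make_track <- function(lrr, baf, chrom = rep(1L, length(lrr)),
                       pfb = rep(0.5, length(lrr)), gc = NA_real_,
                       sample_id = "test") {
  n <- length(lrr)
  pos <- if (n > 0)
    unlist(lapply(split(seq_len(n), chrom), seq_along)) * 1000L else integer(0)
  waveCNA:::.new_sample_track(
    sample_id,
    data.frame(probe_id = sprintf("p%04d", seq_len(n)), chrom = chrom,
               pos = pos, lrr = lrr, baf = baf, pfb = pfb,
               gc = rep(gc, length.out = n)))
}

# PennCNV-style fixture files in a temporary directory
write_penncnv_fixture <- function(dir = NULL, rows = NULL, pfb_rows = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  if (is.null(rows))
    rows <- data.frame(Name = c("rs3", "rs1", "rs2"),
                       Chr = c(1, 1, 1), Position = c(3000, 1000, 2000),
                       lrr = c(0.1, -0.2, 0.05), baf = c(0.98, 0.5, 0.02))
  sig <- file.path(dir, "sample1.txt")
  df <- data.frame(Name = rows$Name, Chr = rows$Chr, Position = rows$Position)
  df[["s1.Log R Ratio"]] <- rows$lrr
  df[["s1.B Allele Freq"]] <- rows$baf
  write.table(df, sig, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(pfb_rows))
    pfb_rows <- data.frame(Name = rows$Name, Chr = rows$Chr,
                           Position = rows$Position, PFB = 0.4)
  pfb <- file.path(dir, "model.pfb")
  write.table(pfb_rows, pfb, sep = "\t", quote = FALSE, row.names = FALSE)
  list(signal = sig, pfb = pfb, dir = dir)
}

# brute-force forward-backward oracle: enumerate every state path
enumerate_posteriors <- function(logE, A) {
  N <- nrow(logE); S <- ncol(logE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), N)))
  lp <- apply(paths, 1, function(st) {
    v <- log(1 / S) + logE[1, st[1]]
    if (N > 1)
      for (i in 2:N) v <- v + log(A[st[i - 1], st[i]]) + logE[i, st[i]]
    v
  })
  mx <- max(lp)
  pp <- exp(lp - mx)
  loglik <- mx + log(sum(pp))
  pp <- pp / sum(pp)
  gamma <- matrix(0, N, S)
  for (i in seq_len(N))
    for (s in seq_len(S))
      gamma[i, s] <- sum(pp[paths[, i] == s])
  list(gamma = gamma, loglik = loglik)
}

# hand-rolled Benjamini-Hochberg step-up, independent of stats::p.adjust
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
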