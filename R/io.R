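#' @importFrom data.table fread fwrite
#' @importFrom stats dnorm pnorm mad median rnorm runif
#' @importFrom utils head tail
NULL

# chromosome labels -> integer order: strip "chr", X -> 23; Y (24) excluded
# by default because the BAF model assumes a diploid normal genome
.norm_chrom <- function(chr) {
  x <- sub("^chr", "", as.character(chr), ignore.case = TRUE)
  x[x %in% c("X", "x")] <- "23"
  x[x %in% c("Y", "y")] <- "24"
  suppressWarnings(as.integer(x))
}

.new_sample_track <- function(sample_id, probes) {
  probes <- probes[order(probes$chrom, probes$pos), , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(sample_id = sample_id, probes = probes),
            class = "sample_track")
}

#' @export
print.sample_track <- function(x, ...) {
  cat(sprintf("<sample_track> %s: %d probes on %d chromosome(s)\n",
              x$sample_id, nrow(x$probes), length(unique(x$probes$chrom))))
  invisible(x)
}

#' Read a PennCNV-style signal file
#'
#' Parses a tab-delimited signal file with a probe name column, chromosome,
#' position, and per-sample `<sample>.Log R Ratio` / `<sample>.B Allele Freq`
#' columns, joins the population B-allele frequency (PFB) track and an
#' optional GC-content track, and returns a per-sample probe table sorted by
#' genomic position.
#'
#' Probes with missing LRR or BAF are dropped (counted in a message); BAF
#' values outside `[0, 1]` are clipped; probes absent from the PFB file get
#' the uninformative default `pfb = 0.5`. Chromosome names are normalized by
#' stripping a leading `"chr"`, `X` becomes 23, and `Y` probes are excluded
#' unless `include_y = TRUE`.
#'
#' @param path Signal file path.
#' @param pfb_path PFB file path (columns Name, Chr, Position, PFB).
#' @param gc_path Optional GC track path (columns Name, GC), GC in `[0, 1]`
#'   or percent.
#' @param include_y Keep chromosome Y probes? Default `FALSE`.
#' @return A `"sample_track"`: list with `sample_id` and a data.frame
#'   `probes` with columns `probe_id`, `chrom`, `pos`, `lrr`, `baf`, `pfb`,
#'   `gc` (NA when no GC track given).
#' @export
read_signal_file <- function(path, pfb_path, gc_path = NULL,
                             include_y = FALSE) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  if (!file.exists(pfb_path)) stop("PFB file not found: ", pfb_path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", "NaN", ""))
  if (nrow(dt) == 0) stop("signal file is empty: ", path)
  cn <- names(dt)
  name_col <- cn[tolower(cn) %in% c("name", "snp name", "probe", "probeset id")][1]
  chr_col <- cn[tolower(cn) %in% c("chr", "chromosome")][1]
  pos_col <- cn[tolower(cn) %in% c("position", "pos")][1]
  lrr_col <- grep("\\.?Log R Ratio$", cn, value = TRUE)[1]
  baf_col <- grep("\\.?B Allele Freq$", cn, value = TRUE)[1]
  required <- c("probe name (Name)" = name_col, "chromosome (Chr)" = chr_col,
                "position (Position)" = pos_col, "Log R Ratio" = lrr_col,
                "B Allele Freq" = baf_col)
  if (anyNA(required))
    stop("signal file lacks a required column: ",
         paste(names(required)[is.na(required)], collapse = ", "))
  sample_id <- sub("\\.?(Log R Ratio)$", "", lrr_col)
  if (sample_id == "" || sample_id == lrr_col)
    sample_id <- sub("\\.[^.]*$", "", basename(path))

  probes <- data.frame(probe_id = as.character(dt[[name_col]]),
                       chrom = .norm_chrom(dt[[chr_col]]),
                       pos = as.integer(dt[[pos_col]]),
                       lrr = as.numeric(dt[[lrr_col]]),
                       baf = as.numeric(dt[[baf_col]]))
  probes <- probes[!is.na(probes$chrom) & !is.na(probes$pos), , drop = FALSE]
  if (!include_y) probes <- probes[probes$chrom != 24L, , drop = FALSE]

  miss <- !is.finite(probes$lrr) | !is.finite(probes$baf)
  if (any(miss))
    message(sum(miss), " probe(s) dropped for missing LRR/BAF")
  probes <- probes[!miss, , drop = FALSE]
  if (nrow(probes) == 0) stop("no usable probes in ", path)

  clipped <- probes$baf < 0 | probes$baf > 1
  if (any(clipped))
    message(sum(clipped), " BAF value(s) clipped into [0, 1]")
  probes$baf <- pmin(pmax(probes$baf, 0), 1)

  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe IDs in ", path)

  pfb <- data.table::fread(pfb_path, sep = "\t", header = TRUE)
  pfb_name <- names(pfb)[tolower(names(pfb)) %in% c("name", "snp name")][1]
  pfb_col <- names(pfb)[tolower(names(pfb)) == "pfb"][1]
  if (is.na(pfb_name) || is.na(pfb_col))
    stop("PFB file lacks a required column: Name/PFB")
  idx <- match(probes$probe_id, pfb[[pfb_name]])
  probes$pfb <- as.numeric(pfb[[pfb_col]])[idx]
  n_nopfb <- sum(is.na(probes$pfb))
  if (n_nopfb > 0)
    message(n_nopfb, " probe(s) absent from PFB file; pfb set to 0.5")
  probes$pfb[is.na(probes$pfb)] <- 0.5
  probes$pfb <- pmin(pmax(probes$pfb, 0.001), 0.999)

  probes$gc <- NA_real_
  if (!is.null(gc_path)) {
    gc <- data.table::fread(gc_path, sep = "\t", header = TRUE)
    gc_name <- names(gc)[tolower(names(gc)) %in% c("name", "snp name")][1]
    gc_col <- names(gc)[tolower(names(gc)) == "gc"][1]
    if (is.na(gc_name) || is.na(gc_col))
      stop("GC file lacks a required column: Name/GC")
    g <- as.numeric(gc[[gc_col]])[match(probes$probe_id, gc[[gc_name]])]
    if (max(g, na.rm = TRUE) > 1) g <- g / 100
    probes$gc <- g
    probes$gc[is.na(probes$gc)] <- mean(g, na.rm = TRUE)
  }
  .new_sample_track(sample_id, probes)
}

# centered GC covariate (0 when no GC track): centering makes the GC
# coefficient identifiable against the baseline offset
.gc_covariate <- function(probes) {
  g <- probes$gc
  if (is.null(g) || all(is.na(g))) return(rep(0, nrow(probes)))
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  g - mean(g)
}

# run-length merge of per-probe states into segments (row indices of probes)
.segments_from_states <- function(chrom, state_index) {
  r <- rle(paste(chrom, state_index, sep = ":"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(first = starts, last = ends)
}

#' Write per-probe calls and merged segments
#'
#' Writes three tab-delimited UTF-8 files rooted at `path`: `<path>.calls.tsv`
#' (one row per probe: state, genotype, copy numbers, posterior, goodness),
#' `<path>.segments.tsv` (run-length merged segments, 1-based inclusive
#' coordinates) and `<path>.segments.bed` (the same segments, BED-style
#' 0-based half-open).
#'
#' @param track A `"sample_track"`.
#' @param calls data.frame of per-probe calls aligned 1:1 with
#'   `track$probes` (as produced by [em_fit()]).
#' @param path Output prefix.
#' @param header_extra Optional named character vector written as `# key: value`
#'   comment lines (e.g. a config hash).
#' @return Invisibly, the segment data.frame.
#' @export
write_calls <- function(track, calls, path, header_extra = NULL) {
  probes <- track$probes
  if (nrow(calls) != nrow(probes))
    stop("calls (", nrow(calls), ") and probes (", nrow(probes),
         ") are not aligned 1:1")
  hdr <- c(sprintf("# sample: %s", track$sample_id),
           if (length(header_extra))
             sprintf("# %s: %s", names(header_extra), header_extra))

  per_probe <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                          pos = probes$pos, state = calls$state,
                          genotype = calls$genotype,
                          m_t = calls$m_t, n_t = calls$n_t,
                          class = calls$class, loh = calls$loh,
                          posterior = calls$posterior,
                          goodness = calls$goodness)
  .write_tsv(per_probe, paste0(path, ".calls.tsv"), hdr)

  if (nrow(probes) > 0) {
    seg_idx <- .segments_from_states(probes$chrom, calls$state)
    segs <- data.frame(chrom = probes$chrom[seg_idx$first],
                       start = probes$pos[seg_idx$first],
                       end = probes$pos[seg_idx$last],
                       n_probes = seg_idx$last - seg_idx$first + 1L,
                       n_t = calls$n_t[seg_idx$first],
                       m_t = calls$m_t[seg_idx$first],
                       class = calls$class[seg_idx$first],
                       loh = calls$loh[seg_idx$first])
  } else {
    segs <- data.frame(chrom = integer(), start = integer(), end = integer(),
                       n_probes = integer(), n_t = integer(), m_t = integer(),
                       class = character(), loh = logical())
  }
  .write_tsv(segs, paste0(path, ".segments.tsv"), hdr)

  bed <- data.frame(chrom = segs$chrom, start = segs$start - 1L,
                    end = segs$end,
                    name = if (nrow(segs)) paste0("cn", segs$n_t, "_",
                                                  segs$class) else character(0))
  .write_tsv(bed, paste0(path, ".segments.bed"), hdr, col.names = FALSE)
  invisible(segs)
}

.write_tsv <- function(df, path, header_lines = NULL, col.names = TRUE) {
  if (!dir.exists(dirname(path)))
    dir.create(dirname(path), recursive = TRUE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  if (col.names) writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    lines <- do.call(paste, c(lapply(df, function(x)
      if (is.numeric(x) && !is.integer(x)) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE)
      else as.character(x)), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a simulated sample in PennCNV signal-file layout
#'
#' @param track A `"sample_track"`.
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_signal_file <- function(track, path) {
  p <- track$probes
  df <- data.frame(Name = p$probe_id, Chr = p$chrom, Position = p$pos)
  df[[paste0(track$sample_id, ".Log R Ratio")]] <- p$lrr
  df[[paste0(track$sample_id, ".B Allele Freq")]] <- p$baf
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a PFB file
#'
#' @param track A `"sample_track"` whose `pfb` column is written.
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_pfb_file <- function(track, path) {
  p <- track$probes
  data.table::fwrite(data.frame(Name = p$probe_id, Chr = p$chrom,
                                Position = p$pos, PFB = p$pfb),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
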