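#' Read a per-sample fragment set from BED3
#'
#' @param path BED3 file (plain or gzip) of aligned-fragment intervals.
#' @param layout Optional [genome_layout()] for validation.
#' @return Tibble with columns chrom, start, end; one row per mapped fragment.
#' @export
read_fragments <- function(path, layout = NULL) {
  x <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end"),
    col_types = "cdd", col_select = 1:3, progress = FALSE
  )
  validate_intervals(x, layout, "fragment")
}

#' Per-window reads-per-million profile
#'
#' Tiles each chromosome into fixed-width windows (10 kb by default) and
#' counts, per window, the fragments overlapping it by at least 1 bp. A
#' fragment spanning a window boundary is counted in every window it touches.
#' RPM = count x 1e6 / N, with N the total mapped fragment count.
#'
#' @param fragments Fragment tibble (one sample).
#' @param layout A [genome_layout()].
#' @param width Window width in bp (> 0; default 10000).
#' @param n_total Total mapped fragments N; defaults to `nrow(fragments)`.
#' @return Tibble: chrom, start, end, count, rpm.
#' @export
window_rpm <- function(fragments, layout, width = 10000,
                       n_total = nrow(fragments)) {
  stopifnot(width > 0)
  if (n_total == 0) stop("empty sample: no mapped fragments")
  wins <- genome_windows(layout, width)
  cnt <- GenomicRanges::countOverlaps(
    gr_from_tbl(wins, layout), gr_from_tbl(fragments), minoverlap = 1
  )
  wins$count <- as.numeric(cnt)
  wins$rpm <- wins$count * 1e6 / n_total
  wins
}

genome_windows <- function(layout, width) {
  purrr::map2_dfr(layout$chrom, layout$length, function(ch, L) {
    starts <- seq(0, L - 1, by = width)
    tibble::tibble(chrom = ch, start = starts, end = pmin(starts + width, L))
  })
}

#' Metagene profile of fragment coverage around features
#'
#' Averages depth-normalised per-bp coverage over a feature set, rescaled
#' into a fixed number of bins: `flank_bins` bins over each fixed-width
#' flank, `body_bins` bins spanning proportional fractions of each feature
#' body (fractional binning, so features shorter than `body_bins` bp are
#' handled without error). Minus-strand features are reversed so bin order is
#' always 5' to 3'. Coverage is reported per million mapped fragments.
#'
#' @param fragments Fragment tibble (one sample or a pool).
#' @param features Interval tibble; optional `strand` column.
#' @param layout A [genome_layout()].
#' @param flank Flank width in bp (default 2000).
#' @param flank_bins,body_bins Bin counts (defaults 20 and 40).
#' @param n_total Total mapped fragments used for normalisation.
#' @return Tibble: bin (1..flank_bins+body_bins+flank_bins), zone
#'   (upstream/body/downstream), mean_coverage (per-bp depth per 1e6
#'   fragments, averaged over features).
#' @export
metagene_profile <- function(fragments, features, layout, flank = 2000,
                             flank_bins = 20, body_bins = 40,
                             n_total = nrow(fragments)) {
  stopifnot(flank_bins > 0, body_bins > 0, nrow(features) > 0)
  features <- validate_intervals(features, layout, "feature")
  cov <- GenomicRanges::coverage(gr_from_tbl(fragments, layout))
  strand <- if ("strand" %in% names(features)) features$strand else
    rep("+", nrow(features))
  nb <- 2 * flank_bins + body_bins
  acc <- matrix(0, nrow = nrow(features), ncol = nb)
  for (i in seq_len(nrow(features))) {
    ch <- features$chrom[i]
    L <- layout$length[match(ch, layout$chrom)]
    s <- features$start[i]; e <- features$end[i]
    v_at <- function(a, b) { # per-bp coverage over [a,b) with out-of-bounds 0
      n <- b - a
      out <- numeric(n)
      aa <- max(a, 0); bb <- min(b, L)
      if (bb > aa) {
        out[(aa - a + 1):(bb - a)] <- as.numeric(cov[[ch]][(aa + 1):bb])
      }
      out
    }
    up <- bin_means(v_at(s - flank, s), flank_bins)
    body <- bin_means(v_at(s, e), body_bins)
    down <- bin_means(v_at(e, e + flank), flank_bins)
    prof <- c(up, body, down)
    if (identical(strand[i], "-")) prof <- rev(prof)
    acc[i, ] <- prof
  }
  mean_cov <- colMeans(acc) * 1e6 / n_total
  tibble::tibble(
    bin = seq_len(nb),
    zone = rep(c("upstream", "body", "downstream"),
               c(flank_bins, body_bins, flank_bins)),
    mean_coverage = mean_cov
  )
}

# mean of v over nb equal fractional bins, linear interpolation of the
# cumulative sum at fractional boundaries
bin_means <- function(v, nb) {
  n <- length(v)
  if (n == 0) return(numeric(nb))
  cum <- c(0, cumsum(v))
  bounds <- n * (0:nb) / nb
  cval <- stats::approx(0:n, cum, xout = bounds, rule = 2)$y
  diff(cval) / (n / nb)
}

#' Call significant coverage peaks by a Poisson sliding-window scan
#'
#' A one-pass stand-in for a full peak caller: sliding windows are scored by
#' the upper-tail Poisson probability P(X >= k) of their fragment count under
#' the genome-wide background rate lambda = N x window / G (G = total genome
#' bp), and windows with p below the cutoff are merged (overlapping or
#' book-ended) into peaks.
#'
#' @param fragments Fragment tibble (one sample, or the pooled fragments of
#'   all samples in a comparison).
#' @param layout A [genome_layout()].
#' @param window,step Window and step in bp (window >= step > 0; defaults
#'   300 and 100).
#' @param p_cut Significance cutoff on the Poisson upper tail (default 1e-5).
#' @param n_total Total fragments N for the background rate.
#' @return Tibble of peaks: chrom, start, end, peak_id, sorted; deterministic
#'   and invariant to fragment input order.
#' @export
call_peaks_poisson <- function(fragments, layout, window = 300, step = 100,
                               p_cut = 1e-5, n_total = nrow(fragments)) {
  stopifnot(window >= step, step > 0, p_cut > 0, p_cut < 1)
  G <- sum(layout$length)
  lambda <- n_total * window / G
  if (lambda == 0) stop("background rate is zero: empty fragment set")
  wins <- sliding_windows(layout, window, step)
  cnt <- GenomicRanges::countOverlaps(
    gr_from_tbl(wins, layout), gr_from_tbl(fragments), minoverlap = 1
  )
  pval <- stats::ppois(cnt - 1, lambda, lower.tail = FALSE)
  sig <- wins[pval < p_cut, ]
  if (nrow(sig) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), peak_id = character()))
  }
  peaks <- sort_intervals(reduce_intervals(sig))
  peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  peaks
}

sliding_windows <- function(layout, window, step) {
  purrr::map2_dfr(layout$chrom, layout$length, function(ch, L) {
    if (L <= window) {
      starts <- 0
    } else {
      starts <- seq(0, L - window, by = step)
      if (max(starts) < L - window) starts <- c(starts, L - window)
    }
    tibble::tibble(chrom = ch, start = starts,
                   end = pmin(starts + window, L))
  })
}

#' Quantify peaks as RPKM per sample
#'
#' RPKM = n / ((l / 1000) x (N / 1e6)) where n is the number of fragments
#' overlapping the peak, l the peak length and N the sample's total mapped
#' fragment count. The default counting rule is overlap by >= 1 bp;
#' `rule = "midpoint"` counts a fragment in the peak containing its midpoint.
#'
#' @param peaks Peak tibble (chrom, start, end, and peak_id; ids are created
#'   if missing).
#' @param fragments Fragment tibble for all samples, with a `sample_id`
#'   column, or a named list of per-sample fragment tibbles.
#' @param rule Fragment-in-peak rule: "overlap" (default) or "midpoint".
#' @param n_total Optional named vector of per-sample totals N; defaults to
#'   per-sample fragment counts.
#' @param value "rpkm" (default) or "count".
#' @return A wide tibble: peak_id, chrom, start, end, length, then one column
#'   per sample. Attribute `n_total` carries the totals used.
#' @export
quantify_peak_rpkm <- function(peaks, fragments, rule = c("overlap", "midpoint"),
                               n_total = NULL, value = c("rpkm", "count")) {
  rule <- match.arg(rule)
  value <- match.arg(value)
  if (is.data.frame(fragments)) {
    stopifnot("sample_id" %in% names(fragments))
    fragments <- split(
      fragments[, c("chrom", "start", "end")],
      factor(fragments$sample_id, levels = unique(fragments$sample_id))
    )
  }
  peaks <- tibble::as_tibble(peaks)
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  }
  len <- peaks$end - peaks$start
  if (any(len <= 0)) stop("zero-length peak")
  if (is.null(n_total)) {
    n_total <- vapply(fragments, nrow, integer(1))
  }
  if (any(n_total <= 0)) stop("sample with zero mapped fragments")
  pgr <- gr_from_tbl(peaks)
  cols <- purrr::imap(fragments, function(fr, sid) {
    if (rule == "midpoint") {
      mid <- floor((fr$start + fr$end) / 2)
      fr <- tibble::tibble(chrom = fr$chrom, start = mid, end = mid + 1)
    }
    al <- align_seqlevels(pgr, gr_from_tbl(fr))
    n <- as.numeric(GenomicRanges::countOverlaps(al[[1]], al[[2]],
                                                 minoverlap = 1))
    if (value == "count") n else n / ((len / 1000) * (n_total[[sid]] / 1e6))
  })
  out <- tibble::tibble(
    peak_id = peaks$peak_id, chrom = peaks$chrom,
    start = peaks$start, end = peaks$end, length = len
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(cols))
  attr(out, "n_total") <- unlist(n_total)
  out
}

# sample columns of a methylation/feature matrix tibble
sample_columns <- function(x, meta = c("peak_id", "dmr_id", "feature_id",
                                       "gene_id", "chrom", "start", "end",
                                       "length", "direction")) {
  setdiff(names(x), meta)
}
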