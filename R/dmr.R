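#' Per-peak differential-methylation tests
#'
#' Tests every peak's RPKM between a case and a control group with a
#' two-sided t-test (Welch by default; pooled-variance optional). Direction
#' is the sign of mean(case) - mean(control). Degenerate peaks where both
#' groups are constant and equal get p = 1; constant-but-unequal groups get
#' p = 0 (infinite evidence under the test's model).
#'
#' @param mm Methylation matrix tibble from [quantify_peak_rpkm()] (peak
#'   metadata columns plus one RPKM column per sample).
#' @param samples Sample sheet tibble: `sample_id`, `group`, and optionally
#'   `region`. Compared samples must come from a single region.
#' @param case,control Group labels (either may be a vector, e.g.
#'   `c("SC", "BP")` for a combined case group); each side needs >= 2
#'   samples.
#' @param test "welch" (default) or "pooled".
#' @return `mm`'s metadata columns plus `mean_case`, `mean_control`,
#'   `direction` ("hyper"/"hypo"/NA), `statistic`, `df`, `p_value`, `q_value`
#'   (BH across peaks, reported for transparency; calling uses raw p).
#' @export
test_peaks <- function(mm, samples, case, control, test = c("welch", "pooled")) {
  test <- match.arg(test)
  case_ids <- intersect(samples$sample_id[samples$group %in% case],
                        names(mm))
  ctrl_ids <- intersect(samples$sample_id[samples$group %in% control],
                        names(mm))
  if ("region" %in% names(samples)) {
    used <- samples[samples$sample_id %in% c(case_ids, ctrl_ids), ]
    if (length(unique(used$region)) > 1) {
      stop("compared samples span more than one region; ",
           "comparisons must be within a single region")
    }
  }
  if (length(case_ids) < 2 || length(ctrl_ids) < 2) {
    stop("each compared group needs >= 2 samples in the matrix")
  }
  X <- as.matrix(mm[, case_ids]); Y <- as.matrix(mm[, ctrl_ids])
  if (anyNA(X) || anyNA(Y)) stop("methylation matrix contains missing values")
  res <- welch_rows(X, Y, pooled = (test == "pooled"))
  meta <- mm[, intersect(c("peak_id", "chrom", "start", "end", "length"),
                         names(mm))]
  dplyr::bind_cols(meta, tibble::tibble(
    mean_case = res$m1, mean_control = res$m2,
    direction = dplyr::case_when(
      res$m1 > res$m2 ~ "hyper",
      res$m1 < res$m2 ~ "hypo",
      TRUE ~ NA_character_
    ),
    statistic = res$t, df = res$df, p_value = res$p,
    q_value = stats::p.adjust(res$p, method = "BH")
  ))
}

# row-wise two-sample t-tests on matrices (vectorised)
welch_rows <- function(X, Y, pooled = FALSE) {
  n1 <- ncol(X); n2 <- ncol(Y)
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: both groups have zero variance
  zero <- se == 0 | !is.finite(se)
  if (any(zero)) {
    eq <- zero & (m1 == m2)
    p[eq] <- 1; t[eq] <- 0; df[eq] <- NA_real_
    ne <- zero & (m1 != m2)
    p[ne] <- 0; t[ne] <- Inf * sign(m1[ne] - m2[ne]); df[ne] <- NA_real_
  }
  list(m1 = m1, m2 = m2, t = t, df = df, p = p)
}

#' Merge significant peaks into differentially methylated regions
#'
#' Consecutive significant peaks on the same chromosome, with the same
#' direction and spacing strictly below `gap` bp, are merged transitively;
#' the merged span runs from the first start to the last end. Merging
#' opposite-direction peaks is never allowed.
#'
#' @param sig_peaks Tibble of significant peaks sorted by (chrom, start),
#'   with columns chrom, start, end, direction, peak_id, p_value.
#' @param gap Merge threshold in bp (spacing < gap merges; default 50).
#' @return Tibble of merged spans: dmr_id, chrom, start, end, direction,
#'   n_peaks, peak_ids (list), min_peak_p.
#' @export
merge_significant_peaks <- function(sig_peaks, gap = 50) {
  x <- tibble::as_tibble(sig_peaks)
  if (nrow(x) == 0) {
    return(tibble::tibble(dmr_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          direction = character(), n_peaks = integer(),
                          peak_ids = list(), min_peak_p = numeric()))
  }
  if (!identical(order(x$chrom, x$start), seq_len(nrow(x)))) {
    stop("significant peaks must be sorted by (chrom, start)")
  }
  new_run <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                 x$direction[-1] != x$direction[-nrow(x)] |
                 (x$start[-1] - x$end[-nrow(x)]) >= gap)
  run <- cumsum(new_run)
  out <- x |>
    dplyr::mutate(.run = run) |>
    dplyr::group_by(.data$.run) |>
    dplyr::summarise(
      chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
      direction = .data$direction[1], n_peaks = dplyr::n(),
      peak_ids = list(.data$peak_id),
      min_peak_p = min(.data$p_value), .groups = "drop"
    ) |>
    dplyr::select(-".run")
  out <- sort_intervals(out)
  out$dmr_id <- sprintf("dmr_%05d", seq_len(nrow(out)))
  out[, c("dmr_id", "chrom", "start", "end", "direction", "n_peaks",
          "peak_ids", "min_peak_p")]
}

#' Call differentially methylated regions
#'
#' The full DMR path: per-peak two-sided t-tests, raw-p thresholding at
#' `alpha`, and spacing-based same-direction merging. Merged-region
#' statistics (group means, p-value) are recomputed: when the per-sample
#' fragments are supplied the merged span is re-quantified as RPKM and
#' re-tested; otherwise the span RPKM is approximated by the length-weighted
#' mean of the component peaks' RPKM and re-tested on that.
#'
#' @inheritParams test_peaks
#' @param alpha Per-peak significance threshold on raw p (default 0.01).
#' @param gap Merge threshold in bp (default 50).
#' @param fragments Optional per-sample fragments (tibble with `sample_id`
#'   or named list) for exact merged-span re-quantification; totals are
#'   taken from `attr(mm, "n_total")` when present.
#' @return Object of class `dmr_calls`: list with `dmrs` (tibble: dmr_id,
#'   chrom, start, end, direction, p_value, mean_case, mean_control,
#'   n_peaks, peak_ids), `peak_tests`, and `params`. `tidy()` returns the
#'   DMR tibble; `glance()` the hyper/hypo counts.
#' @export
call_dmrs <- function(mm, samples, case, control, alpha = 0.01, gap = 50,
                      fragments = NULL, test = c("welch", "pooled")) {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1)
  tests <- test_peaks(mm, samples, case, control, test = test)
  sig <- tests[tests$p_value < alpha & !is.na(tests$direction), ]
  sig <- sort_intervals(sig)
  merged <- merge_significant_peaks(sig, gap = gap)
  if (nrow(merged) > 0) {
    spans <- merged[, c("dmr_id", "chrom", "start", "end")]
    if (!is.null(fragments)) {
      span_mm <- quantify_peak_rpkm(
        dplyr::rename(spans, peak_id = "dmr_id"), fragments,
        n_total = attr(mm, "n_total")
      )
    } else {
      span_mm <- weighted_span_rpkm(spans, mm, merged$peak_ids)
    }
    span_tests <- test_peaks(span_mm, samples, case, control, test = test)
    merged$p_value <- span_tests$p_value
    merged$mean_case <- span_tests$mean_case
    merged$mean_control <- span_tests$mean_control
    merged$direction <- ifelse(
      span_tests$mean_case > span_tests$mean_control, "hyper",
      ifelse(span_tests$mean_case < span_tests$mean_control, "hypo",
             merged$direction)
    )
    # keep the calling threshold honest after re-testing
    merged <- merged[merged$p_value < alpha, ]
  } else {
    merged$p_value <- numeric(0)
    merged$mean_case <- numeric(0)
    merged$mean_control <- numeric(0)
  }
  dmrs <- merged[, c("dmr_id", "chrom", "start", "end", "direction",
                     "p_value", "mean_case", "mean_control", "n_peaks",
                     "peak_ids")]
  structure(
    list(
      dmrs = dmrs, peak_tests = tests,
      params = list(case = case, control = control, alpha = alpha,
                    gap = gap, test = test,
                    requantified = !is.null(fragments))
    ),
    class = "dmr_calls"
  )
}

# length-weighted mean RPKM of component peaks over merged spans
weighted_span_rpkm <- function(spans, mm, peak_ids) {
  sc <- sample_columns(mm)
  rows <- purrr::map2(seq_len(nrow(spans)), peak_ids, function(i, ids) {
    sub <- mm[mm$peak_id %in% ids, ]
    w <- sub$length / sum(sub$length)
    vals <- colSums(as.matrix(sub[, sc]) * w)
    c(list(peak_id = spans$dmr_id[i], chrom = spans$chrom[i],
           start = spans$start[i], end = spans$end[i],
           length = spans$end[i] - spans$start[i]), as.list(vals))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.dmr_calls <- function(x, ...) {
  g <- generics::glance(x)
  cat("<dmr_calls> ", g$n_dmrs, " DMRs (", g$n_hyper, " hyper / ", g$n_hypo,
      " hypo) at alpha = ", x$params$alpha, ", merge gap ", x$params$gap,
      " bp\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname call_dmrs
#' @param x A `dmr_calls` object.
#' @param ... Unused.
#' @method tidy dmr_calls
#' @export
tidy.dmr_calls <- function(x, ...) x$dmrs

#' @rdname call_dmrs
#' @method glance dmr_calls
#' @export
glance.dmr_calls <- function(x, ...) {
  tibble::tibble(
    n_dmrs = nrow(x$dmrs),
    n_hyper = sum(x$dmrs$direction == "hyper"),
    n_hypo = sum(x$dmrs$direction == "hypo"),
    mean_length = if (nrow(x$dmrs)) mean(x$dmrs$end - x$dmrs$start) else NA_real_,
    alpha = x$params$alpha, gap = x$params$gap, test = x$params$test
  )
}

#' Map DMRs to genes by element overlap
#'
#' A gene is DMR-related when at least one of its elements (promoter, 5'UTR,
#' exon, intron, 3'UTR) overlaps a DMR by >= 1 bp. DMRs hitting only
#' intergenic space map to no gene.
#'
#' @param dmrs DMR tibble (or `dmr_calls` object).
#' @param elements An `element_map` from [derive_elements()].
#' @return Long tibble: gene_id, element, dmr_id (one row per gene x element
#'   class x DMR hit, de-duplicated).
#' @export
map_dmrs_to_genes <- function(dmrs, elements) {
  if (inherits(dmrs, "dmr_calls")) dmrs <- dmrs$dmrs
  empty <- tibble::tibble(gene_id = character(), element = character(),
                          dmr_id = character())
  if (nrow(dmrs) == 0) return(empty)
  genic <- elements[!is.na(elements$gene_id), ]
  if (nrow(genic) == 0) return(empty)
  al <- align_seqlevels(gr_from_tbl(dmrs), gr_from_tbl(genic))
  hits <- GenomicRanges::findOverlaps(al[[1]], al[[2]], minoverlap = 1)
  if (length(hits) == 0) return(empty)
  ids <- if ("dmr_id" %in% names(dmrs)) dmrs$dmr_id else
    sprintf("dmr_%05d", seq_len(nrow(dmrs)))
  tibble::tibble(
    gene_id = genic$gene_id[S4Vectors::subjectHits(hits)],
    element = genic$element[S4Vectors::subjectHits(hits)],
    dmr_id = ids[S4Vectors::queryHits(hits)]
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$gene_id, .data$element, .data$dmr_id)
}
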