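#' Gene-level RPKM from read counts
#'
#' RPKM = count / ((length / 1000) x (total / 1e6)).
#'
#' @param counts Tibble of raw counts: `gene_id` column plus one numeric
#'   column per sample.
#' @param lengths Named numeric vector of gene lengths in bp (> 0), or a
#'   tibble with `gene_id`, `length`. Transcript (exonic) lengths are the
#'   usual choice.
#' @param totals Optional named vector of per-sample mapped-read totals;
#'   defaults to the column sums of `counts`.
#' @return Tibble: gene_id, length, then one RPKM column per sample.
#' @export
compute_gene_rpkm <- function(counts, lengths, totals = NULL) {
  counts <- tibble::as_tibble(counts)
  stopifnot("gene_id" %in% names(counts))
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length, lengths$gene_id)
  }
  len <- unname(lengths[counts$gene_id])
  if (anyNA(len) || any(len <= 0)) stop("every gene needs a positive length")
  sc <- setdiff(names(counts), "gene_id")
  M <- as.matrix(counts[, sc])
  if (is.null(totals)) totals <- colSums(M)
  totals <- totals[sc]
  if (any(totals <= 0)) stop("sample totals must be positive")
  rpkm <- M / outer(len / 1000, totals / 1e6)
  dplyr::bind_cols(
    tibble::tibble(gene_id = counts$gene_id, length = len),
    tibble::as_tibble(rpkm)
  )
}

#' Call differentially expressed genes by fold change
#'
#' Fold change is computed on pseudocounted group-mean RPKM:
#' fc = (mean case + c) / (mean control + c). A gene is differentially
#' expressed when max(fc, 1/fc) exceeds the threshold; direction follows
#' fc relative to 1. BH-adjusted Welch t-test p-values are reported alongside
#' as a diagnostic only — calling is by fold change.
#'
#' @param rpkm Tibble from [compute_gene_rpkm()] (gene_id, length, samples).
#' @param samples Sample sheet: `sample_id`, `group` (and optionally
#'   `region`, checked for homogeneity).
#' @param case,control Group labels (vectors allowed); both must be
#'   non-empty.
#' @param fc_threshold Fold-change threshold (> 1, default 1.5).
#' @param pseudocount Pseudocount c in RPKM units (default 0.25), guarding
#'   fold changes of silent genes.
#' @return Tibble: gene_id, mean_case, mean_control, fc, log2_fc, de,
#'   direction ("up"/"down"/NA), p_value, q_value.
#' @export
call_de_genes <- function(rpkm, samples, case, control, fc_threshold = 1.5,
                          pseudocount = 0.25) {
  stopifnot(fc_threshold > 1, pseudocount >= 0)
  case_ids <- intersect(samples$sample_id[samples$group %in% case],
                        names(rpkm))
  ctrl_ids <- intersect(samples$sample_id[samples$group %in% control],
                        names(rpkm))
  if (length(case_ids) == 0 || length(ctrl_ids) == 0) {
    stop("empty case or control group")
  }
  X <- as.matrix(rpkm[, case_ids]); Y <- as.matrix(rpkm[, ctrl_ids])
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  fc <- (m1 + pseudocount) / (m2 + pseudocount)
  de <- pmax(fc, 1 / fc) > fc_threshold
  pq <- if (length(case_ids) >= 2 && length(ctrl_ids) >= 2) {
    p <- welch_rows(X, Y)$p
    list(p = p, q = stats::p.adjust(p, method = "BH"))
  } else list(p = rep(NA_real_, nrow(rpkm)), q = rep(NA_real_, nrow(rpkm)))
  tibble::tibble(
    gene_id = rpkm$gene_id,
    mean_case = m1, mean_control = m2,
    fc = fc, log2_fc = log2(fc), de = de,
    direction = ifelse(!de, NA_character_, ifelse(fc > 1, "up", "down")),
    p_value = pq$p, q_value = pq$q
  )
}

#' Methylation-expression fold-change correlation per element class
#'
#' Pairs each DMR's methylation fold change with the expression fold change
#' of the genes it maps to, stratified by the element class through which
#' the DMR hits the gene, and reports the Pearson correlation per class.
#' Both fold changes are log2-transformed by default (a raw-ratio mode is
#' available). A gene with several DMRs in a class contributes one pair per
#' DMR.
#'
#' @param dmr_fc Tibble with `dmr_id` and `log2_fc` (or `fc`): DMR
#'   methylation fold change, e.g. computed from `mean_case`/`mean_control`
#'   of [call_dmrs()] with a pseudocount.
#' @param gene_fc Tibble with `gene_id` and `log2_fc` (or `fc`): gene
#'   expression fold change from [call_de_genes()].
#' @param mapping Tibble from [map_dmrs_to_genes()] (gene_id, element,
#'   dmr_id).
#' @param classes Element classes to test (default the five genic classes).
#' @param min_pairs Classes with fewer pairs are skipped with a warning
#'   (default 3).
#' @param log2 Correlate log2 fold changes (default TRUE) or raw ratios.
#' @return Tibble: element, n_pairs, r, p_value (two-sided), tested.
#' @export
methylation_expression_correlation <- function(
    dmr_fc, gene_fc, mapping,
    classes = c("promoter", "utr5", "exon", "intron", "utr3"),
    min_pairs = 3, log2 = TRUE) {
  val <- function(x) {
    if (log2) {
      if ("log2_fc" %in% names(x)) x$log2_fc else base::log2(x$fc)
    } else {
      if ("fc" %in% names(x)) x$fc else 2^x$log2_fc
    }
  }
  dmr_tbl <- tibble::tibble(dmr_id = dmr_fc$dmr_id, dmr_val = val(dmr_fc))
  gene_tbl <- tibble::tibble(gene_id = gene_fc$gene_id,
                             gene_val = val(gene_fc))
  out <- purrr::map_dfr(classes, function(cl) {
    pairs <- mapping[mapping$element == cl, ] |>
      dplyr::inner_join(dmr_tbl, by = "dmr_id") |>
      dplyr::inner_join(gene_tbl, by = "gene_id")
    if (nrow(pairs) < min_pairs) {
      warning("element class '", cl, "' skipped: fewer than ", min_pairs,
              " methylation-expression pairs")
      return(tibble::tibble(element = cl, n_pairs = nrow(pairs),
                            r = NA_real_, p_value = NA_real_,
                            tested = FALSE))
    }
    ct <- stats::cor.test(pairs$dmr_val, pairs$gene_val, method = "pearson")
    tibble::tibble(element = cl, n_pairs = nrow(pairs),
                   r = unname(ct$estimate), p_value = ct$p.value,
                   tested = TRUE)
  })
  out
}

#' DMR methylation fold changes
#'
#' Convenience: pseudocounted fold change of merged-DMR mean RPKM, matching
#' the expression fold-change convention so the two scales are comparable in
#' [methylation_expression_correlation()].
#'
#' @param dmrs `dmr_calls` object or DMR tibble with mean_case/mean_control.
#' @param pseudocount Pseudocount in RPKM units (default 0.25).
#' @return Tibble: dmr_id, fc, log2_fc.
#' @export
dmr_fold_changes <- function(dmrs, pseudocount = 0.25) {
  if (inherits(dmrs, "dmr_calls")) dmrs <- dmrs$dmrs
  fc <- (dmrs$mean_case + pseudocount) / (dmrs$mean_control + pseudocount)
  tibble::tibble(dmr_id = dmrs$dmr_id, fc = fc, log2_fc = log2(fc))
}
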