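#' Generate matched pseudo-random regions
#'
#' Draws one random region per input region, preserving the chromosome and
#' length of each (the matched-random null used for overlap enrichment).
#' Starts are uniform on [0, chrom_length - length]; regions may overlap each
#' other. No exclusion masking is applied (none exists in the synthetic
#' genome); pass `mask` to forbid placements overlapping a region set.
#'
#' @param regions Interval tibble (e.g. DMRs).
#' @param layout A [genome_layout()]; every region must fit on its chromosome.
#' @param mask Optional interval tibble; placements overlapping it are
#'   redrawn (rejection sampling).
#' @return Tibble chrom, start, end with the identical multiset of
#'   (chrom, length). Reproducible under `set.seed()` /
#'   [withr::with_seed()].
#' @export
generate_matched_random_regions <- function(regions, layout, mask = NULL) {
  regions <- validate_intervals(regions, layout, "region")
  len <- regions$end - regions$start
  L <- layout$length[match(regions$chrom, layout$chrom)]
  if (any(len > L)) stop("region longer than its chromosome")
  draw <- function(idx) {
    floor(stats::runif(length(idx)) * (L[idx] - len[idx] + 1))
  }
  start <- draw(seq_len(nrow(regions)))
  out <- tibble::tibble(chrom = regions$chrom, start = start,
                        end = start + len)
  if (!is.null(mask) && nrow(mask) > 0) {
    for (iter in 1:100) {
      bad <- which(IRanges::overlapsAny(gr_from_tbl(out), gr_from_tbl(mask)))
      if (length(bad) == 0) break
      s <- draw(bad)
      out$start[bad] <- s
      out$end[bad] <- s + len[bad]
    }
  }
  out
}

#' Permutation test of DMR enrichment in genomic element classes
#'
#' For each element class, compares the observed overlap of the region set
#' with the class against the overlap of `n_perm` matched pseudo-random
#' region sets (same chromosome and length per region). The empirical
#' p-value is (g + 1) / (n_perm + 1) where g is the number of permutations
#' with overlap >= observed (enrichment) or <= observed (depletion), so the
#' smallest attainable p at n_perm = 1000 is 1/1001.
#'
#' @param dmrs Non-empty interval tibble (or `dmr_calls`).
#' @param elements An `element_map`, or a named list of interval tibbles
#'   (one per category).
#' @param layout A [genome_layout()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @param statistic "count" (default; number of regions overlapping the
#'   class by >= 1 bp) or "bp" (total region bp falling in the class).
#' @return Tibble: element, observed, n_exceed_enriched, n_exceed_depleted,
#'   n_perm, p_enriched, p_depleted, direction.
#' @export
permutation_element_enrichment <- function(dmrs, elements, layout,
                                           n_perm = 1000, seed = NULL,
                                           statistic = c("count", "bp")) {
  statistic <- match.arg(statistic)
  if (inherits(dmrs, "dmr_calls")) dmrs <- dmrs$dmrs
  if (nrow(dmrs) == 0) stop("empty region set")
  stopifnot(n_perm >= 1)
  if (inherits(elements, "element_map") || is.data.frame(elements)) {
    elements <- split(elements[, c("chrom", "start", "end")],
                      elements$element)
  }
  class_gr <- lapply(elements, function(e) {
    GenomicRanges::reduce(gr_from_tbl(e))
  })
  # statistic of one region set against one merged class: number of regions
  # overlapping >= 1 bp, or the summed per-region overlap bp
  stat_one <- function(set_gr, cg, perm_id, n_sets) {
    al <- align_seqlevels(set_gr, cg)
    set_gr <- al[[1]]; cg <- al[[2]]
    if (statistic == "count") {
      hit <- IRanges::overlapsAny(set_gr, cg, minoverlap = 1)
      unname(vapply(split(hit, factor(perm_id, levels = seq_len(n_sets))),
                    sum, numeric(1)))
    } else {
      hits <- GenomicRanges::findOverlaps(set_gr, cg, minoverlap = 1)
      qh <- S4Vectors::queryHits(hits)
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(set_gr)[qh],
        GenomicRanges::ranges(cg)[S4Vectors::subjectHits(hits)]
      ))
      out <- numeric(n_sets)
      agg <- rowsum(w, perm_id[qh])
      out[as.integer(rownames(agg))] <- agg[, 1]
      out
    }
  }
  k <- nrow(dmrs)
  len <- dmrs$end - dmrs$start
  L <- layout$length[match(dmrs$chrom, layout$chrom)]
  run <- function() {
    # all permutation sets drawn at once: row-major (perm 1 first)
    starts <- floor(stats::runif(n_perm * k) *
                      rep(L - len + 1, n_perm))
    GenomicRanges::GRanges(
      seqnames = rep(dmrs$chrom, n_perm),
      ranges = IRanges::IRanges(start = starts + 1,
                                width = rep(len, n_perm))
    )
  }
  perm_gr <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  perm_id <- rep(seq_len(n_perm), each = k)
  obs_gr <- gr_from_tbl(dmrs)
  ge <- numeric(length(class_gr)); gd <- numeric(length(class_gr))
  observed <- numeric(length(class_gr))
  for (ci in seq_along(class_gr)) {
    cg <- class_gr[[ci]]
    observed[ci] <- stat_one(obs_gr, cg, rep(1L, k), 1)
    s <- stat_one(perm_gr, cg, perm_id, n_perm)
    s[is.na(s)] <- 0
    ge[ci] <- sum(s >= observed[ci])
    gd[ci] <- sum(s <= observed[ci])
  }
  g <- list(ge = ge, gd = gd)
  p_enr <- unname(g$ge + 1) / (n_perm + 1)
  p_dep <- unname(g$gd + 1) / (n_perm + 1)
  tibble::tibble(
    element = names(class_gr), observed = unname(observed),
    n_exceed_enriched = unname(g$ge), n_exceed_depleted = unname(g$gd),
    n_perm = n_perm, p_enriched = unname(p_enr), p_depleted = unname(p_dep),
    direction = ifelse(p_enr <= p_dep, "enriched", "depleted")
  )
}

#' CGI-vs-shore association of a region set
#'
#' Builds a 2x2 table counting how many regions overlap a CpG island and how
#' many overlap a shore (island precedence for regions touching both), for
#' the real region set versus one matched pseudo-random set, and tests the
#' association with Fisher's exact test. The odds ratio is the cross-product,
#' with a 0.5 Haldane correction applied to all cells iff any cell is zero.
#'
#' @param dmrs Interval tibble (or `dmr_calls`).
#' @param cgi_context A `cgi_context` from [derive_cgi_context()].
#' @param layout A [genome_layout()] (for the matched random draw).
#' @param seed Integer seed for the matched random set.
#' @param random Optional pre-drawn comparison region set; overrides the
#'   internal draw.
#' @return A list of class `fisher_association`: `table` (2x2 matrix rows =
#'   real/random, cols = cgi/shore), `odds_ratio`, `p_value`.
#' @export
cgi_shore_association <- function(dmrs, cgi_context, layout, seed = NULL,
                                  random = NULL) {
  if (inherits(dmrs, "dmr_calls")) dmrs <- dmrs$dmrs
  if (is.null(random)) {
    random <- if (is.null(seed)) {
      generate_matched_random_regions(dmrs, layout)
    } else {
      withr::with_seed(seed, generate_matched_random_regions(dmrs, layout))
    }
  }
  count_ctx <- function(x) {
    gr <- gr_from_tbl(x)
    alc <- align_seqlevels(gr, gr_from_tbl(cgi_context$cgi))
    als <- align_seqlevels(gr, gr_from_tbl(cgi_context$shore))
    in_cgi <- IRanges::overlapsAny(alc[[1]], alc[[2]])
    in_shore <- IRanges::overlapsAny(als[[1]], als[[2]]) & !in_cgi
    c(cgi = sum(in_cgi), shore = sum(in_shore))
  }
  tab <- rbind(real = count_ctx(dmrs), random = count_ctx(random))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in CGI/shore contingency table")
  }
  fisher_2x2(tab)
}

#' Fisher's exact association for a 2x2 table
#'
#' @param tab 2x2 integer matrix.
#' @return List of class `fisher_association`: `table`, `odds_ratio`
#'   (cross-product, Haldane-corrected iff any zero cell), `p_value`
#'   (two-sided exact).
#' @export
fisher_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2))
  ct <- tab
  if (any(ct == 0)) ct <- ct + 0.5
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  p <- stats::fisher.test(round(tab))$p.value
  structure(list(table = tab, odds_ratio = unname(or), p_value = p),
            class = "fisher_association")
}

#' @export
print.fisher_association <- function(x, ...) {
  cat("<fisher_association> OR =", signif(x$odds_ratio, 4),
      ", two-sided p =", signif(x$p_value, 4), "\n")
  print(x$table)
  invisible(x)
}

#' Hypergeometric functional-term enrichment
#'
#' Upper-tail hypergeometric test of a gene set against each functional term
#' of a user-supplied gene-to-term map, with Benjamini-Hochberg adjustment
#' across the tested terms. Terms with no overlapping gene are skipped.
#'
#' @param genes Character vector: the selected gene set (must be a subset of
#'   `universe`).
#' @param universe Character vector: the background gene universe.
#' @param gene2term Tibble with columns `gene_id`, `term_id` (extra columns
#'   such as a term description are carried through).
#' @param fdr_cut Significance threshold on the BH FDR (default 0.05).
#' @return Tibble sorted by p: term_id, n_overlap, n_term, n_set,
#'   n_universe, p_value, fdr, significant, overlap_genes (list).
#' @export
term_enrichment <- function(genes, universe, gene2term, fdr_cut = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  genes <- unique(genes)
  if (!all(genes %in% universe)) stop("`genes` must be a subset of `universe`")
  g2t <- gene2term[gene2term$gene_id %in% universe, ]
  res <- g2t |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      n_term = dplyr::n_distinct(.data$gene_id),
      overlap_genes = list(sort(intersect(unique(.data$gene_id), genes))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_overlap = lengths(.data$overlap_genes),
      n_set = length(genes), n_universe = length(universe)
    ) |>
    dplyr::filter(.data$n_overlap >= 1)
  if (nrow(res) == 0) {
    return(tibble::tibble(term_id = character(), n_overlap = integer(),
                          n_term = integer(), n_set = integer(),
                          n_universe = integer(), p_value = numeric(),
                          fdr = numeric(), significant = logical(),
                          overlap_genes = list()))
  }
  res$p_value <- stats::phyper(res$n_overlap - 1, res$n_term,
                               res$n_universe - res$n_term, res$n_set,
                               lower.tail = FALSE)
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$fdr < fdr_cut
  res |>
    dplyr::arrange(.data$p_value, .data$term_id) |>
    dplyr::select("term_id", "n_overlap", "n_term", "n_set", "n_universe",
                  "p_value", "fdr", "significant", "overlap_genes")
}
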