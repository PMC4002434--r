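#' Intra-class pairwise correlations
#'
#' Pairwise Pearson correlations of log2(value + 1) sample profiles within
#' each class of samples — the standard replicate-consistency QC on 10 kb
#' window methylation levels or gene expression.
#'
#' @param fm Feature tibble: a feature-id column (first non-sample column)
#'   plus one numeric column per sample.
#' @param samples Sample sheet with `sample_id` and the class column.
#' @param class_col Name of the grouping column (default "group").
#' @return Tibble of off-diagonal pairs: class, sample_1, sample_2, r.
#'   Attribute `summary` holds per-class min/mean/max. Constant sample
#'   vectors yield NA with a warning.
#' @export
intra_class_correlation <- function(fm, samples, class_col = "group") {
  M <- feature_matrix(fm)
  out <- purrr::map_dfr(split(samples$sample_id, samples[[class_col]]),
    .id = "class", function(ids) {
      ids <- intersect(ids, colnames(M))
      if (length(ids) < 2) return(NULL)
      lm2 <- log2(M[, ids, drop = FALSE] + 1)
      sds <- apply(lm2, 2, stats::sd)
      if (any(sds == 0)) {
        warning("constant sample profile: correlation undefined, reported NA")
      }
      cc <- suppressWarnings(stats::cor(lm2, method = "pearson"))
      idx <- which(upper.tri(cc), arr.ind = TRUE)
      tibble::tibble(sample_1 = ids[idx[, 1]], sample_2 = ids[idx[, 2]],
                     r = cc[idx])
    })
  smry <- out |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n_pairs = dplyr::n(), min_r = min(.data$r),
                     mean_r = mean(.data$r), max_r = max(.data$r),
                     .groups = "drop")
  attr(out, "summary") <- smry
  out
}

#' Two-component PCA overview of samples
#'
#' Principal components of the feature-centered sample matrix, returned with
#' a deterministic sign convention: within each component the
#' largest-magnitude loading is forced positive, so output is reproducible
#' across runs and platforms.
#'
#' @param fm Feature tibble (feature-id column + sample columns); >= 3
#'   samples.
#' @return Tibble: sample_id, PC1, PC2; attribute `var_explained` gives the
#'   proportion of variance of each returned component.
#' @export
pca_overview <- function(fm) {
  M <- feature_matrix(fm)
  if (ncol(M) < 3) stop("PCA overview needs >= 3 samples")
  pc <- stats::prcomp(t(M), center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  out <- tibble::tibble(sample_id = colnames(M),
                        PC1 = unname(scores[, 1]),
                        PC2 = if (k >= 2) unname(scores[, 2]) else 0)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "var_explained") <- ve[seq_len(k)]
  out
}

#' Select the most variable features
#'
#' Ranks features by cross-sample variance (ties broken by feature id,
#' ascending) and keeps the top k — the "top 50 most variable" selection
#' used before sample clustering.
#'
#' @param fm Feature tibble (feature-id column first, then sample columns).
#' @param k Number of features to keep (default 50; must not exceed the
#'   feature count).
#' @return `fm` restricted to the k selected rows, most variable first.
#' @export
select_top_variable <- function(fm, k = 50) {
  stopifnot(k <= nrow(fm))
  M <- feature_matrix(fm)
  v <- apply(M, 1, stats::var)
  ord <- order(-v, rownames(M))
  fm[ord[seq_len(k)], ]
}

#' Hierarchical clustering of samples on correlation distance
#'
#' Features are z-scored across samples (zero-variance features dropped),
#' sample-sample distance is 1 - Pearson correlation of the z-scored
#' profiles, and trees are built with average linkage. The 2-way cut is
#' returned as the case/control candidate partition.
#'
#' @param fm Feature tibble (feature-id column + >= 2 sample columns).
#' @param method Linkage: "average" (default), "complete", ...
#' @param distance "pearson" (default; d = 1 - r) or "euclidean".
#' @param k Number of clusters to cut (default 2).
#' @return Object of class `sample_clustering`: list with `hclust`,
#'   `clusters` (named integer vector), `newick` (when ape is installed),
#'   `n_features_used`.
#' @export
hierarchical_cluster <- function(fm, method = "average",
                                 distance = c("pearson", "euclidean"),
                                 k = 2) {
  distance <- match.arg(distance)
  M <- feature_matrix(fm)
  if (ncol(M) < 2) stop("clustering needs >= 2 samples")
  Z <- zscore_rows(M)
  if (nrow(Z) < 2) stop("fewer than 2 usable (non-constant) features")
  if (distance == "pearson") {
    d <- stats::as.dist(1 - stats::cor(Z, method = "pearson"))
  } else {
    d <- stats::dist(t(Z))
  }
  hc <- stats::hclust(d, method = method)
  cl <- stats::cutree(hc, k = k)
  nwk <- if (requireNamespace("ape", quietly = TRUE)) {
    ape::write.tree(ape::as.phylo(hc))
  } else NA_character_
  structure(list(hclust = hc, clusters = cl, newick = nwk,
                 n_features_used = nrow(Z)),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering> ", length(x$clusters), " samples, ",
      x$n_features_used, " features; cut sizes: ",
      paste(table(x$clusters), collapse = "/"), "\n", sep = "")
  invisible(x)
}

zscore_rows <- function(M) {
  mu <- rowMeans(M)
  sd <- apply(M, 1, stats::sd)
  keep <- sd > 0
  (M[keep, , drop = FALSE] - mu[keep]) / sd[keep]
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 = identical partitions, ~0 for independent ones. Invariant to label
#' swapping.
#'
#' @param a,b Two label vectors of equal length.
#' @return Numeric ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(length(a))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

#' Cross-cohort separation diagnostic
#'
#' The headline transferability check: can features (DMRs or DE genes)
#' defined in one comparison separate cases from controls in an evaluation
#' cohort? The cohort's feature values are (optionally) restricted to the
#' top-k most variable features, clustered hierarchically, and the 2-way cut
#' is scored against the case/control labels by adjusted Rand index.
#' "Successful separation" is ARI = 1.
#'
#' @param fm Feature tibble quantified in the evaluation cohort (DMR spans
#'   re-quantified as RPKM, or genes looked up in the expression matrix).
#' @param labels Named vector (or vector aligned with the sample columns) of
#'   case/control labels for the cohort samples.
#' @param top_k Optional top-variable selection before clustering (e.g. 50);
#'   NULL uses all features.
#' @param feature_source,modality Free-text descriptors recorded in the
#'   report.
#' @param ... Passed to [hierarchical_cluster()].
#' @return Object of class `separation_report`: list with `ari`, `clusters`,
#'   `labels`, `separated` (ARI == 1), `n_features`, descriptors, and the
#'   `sample_clustering`. `tidy()` gives per-sample assignments, `glance()`
#'   the one-row summary.
#' @export
cross_cluster_separation <- function(fm, labels, top_k = NULL,
                                     feature_source = NA_character_,
                                     modality = NA_character_, ...) {
  M <- feature_matrix(fm)
  if (nrow(fm) == 0) stop("empty feature set")
  if (!is.null(names(labels))) labels <- labels[colnames(M)]
  if (!is.null(top_k)) fm <- select_top_variable(fm, min(top_k, nrow(fm)))
  sc <- hierarchical_cluster(fm, ...)
  ari <- adjusted_rand_index(sc$clusters, labels)
  structure(list(
    ari = ari, clusters = sc$clusters, labels = labels,
    separated = isTRUE(all.equal(ari, 1)),
    n_features = nrow(fm), feature_source = feature_source,
    modality = modality, clustering = sc
  ), class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("<separation_report> ARI =", round(x$ari, 3),
      if (x$separated) "(separated)" else "(not separated)", "\n")
  invisible(x)
}

#' @rdname cross_cluster_separation
#' @param x A `separation_report`.
#' @method tidy separation_report
#' @export
tidy.separation_report <- function(x, ...) {
  tibble::tibble(sample_id = names(x$clusters),
                 cluster = unname(x$clusters),
                 label = unname(x$labels))
}

#' @rdname cross_cluster_separation
#' @method glance separation_report
#' @export
glance.separation_report <- function(x, ...) {
  tibble::tibble(feature_source = x$feature_source, modality = x$modality,
                 n_features = x$n_features, ari = x$ari,
                 separated = x$separated)
}

# first column is the feature id; remaining numeric columns are samples
feature_matrix <- function(fm) {
  fm <- tibble::as_tibble(fm)
  num <- vapply(fm, is.numeric, logical(1))
  idcol <- names(fm)[!num][1]
  sc <- names(fm)[num]
  sc <- setdiff(sc, c("start", "end", "length"))
  M <- as.matrix(fm[, sc])
  rownames(M) <- if (!is.na(idcol)) as.character(fm[[idcol]]) else
    as.character(seq_len(nrow(fm)))
  if (anyNA(M)) stop("feature matrix contains missing values")
  M
}
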