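#' Run the full methylome-transcriptome analysis
#'
#' Orchestrates every stage for each declared comparison: pooled Poisson
#' peak calling per region, per-sample RPKM quantification, DMR calling,
#' gene mapping, genomic-context enrichment (matched-random permutation,
#' CGI-vs-shore Fisher, functional terms), fold-change differential
#' expression, per-element methylation-expression correlation, and the
#' cross-cohort separation diagnostic for both modalities. All thresholds
#' default to the pipeline's standard values (peak p < 1e-5, DMR alpha 0.01,
#' merge gap 50 bp, promoter -2500/+500, 1000 permutations, FC > 1.5,
#' top-50 features).
#'
#' @param bundle A bundle list (from [read_bundle()] or
#'   [simulate_bundle()]), or a bundle directory path.
#' @param comparisons Tibble with columns `case` (list or character),
#'   `control`, `region`; default: each disease group vs NORMAL in each
#'   region.
#' @param outdir Optional directory; when given, per-stage TSV/BED artifacts
#'   and a JSON manifest (parameter echo + output checksums) are written.
#' @param alpha,gap,peak_p,peak_window,peak_step,n_perm,fc_threshold,top_k
#'   Stage parameters (defaults above).
#' @param separation_top_k Top-variable restriction for the cross-cohort
#'   separation stage; the default (NULL) clusters on the full feature set
#'   of the source comparison, the convention of the cross-region
#'   transferability analysis. `top_k` only governs the within-comparison
#'   top-variable view.
#' @param seed Seed for the permutation/random-region stages.
#' @param requantify Re-quantify merged DMR spans from fragments (default
#'   TRUE).
#' @return Object of class `pipeline_result`: list with `peaks`,
#'   `methylation` (per region), `dmrs`, `dmr_genes`, `enrichment`,
#'   `cgi_shore`, `terms`, `expression`, `de`, `correlation` (per
#'   comparison), `separation` (per feature-source x cohort x modality),
#'   `params`.
#' @export
run_pipeline <- function(bundle, comparisons = NULL, outdir = NULL,
                         alpha = 0.01, gap = 50, peak_p = 1e-5,
                         peak_window = 300, peak_step = 100,
                         n_perm = 1000, fc_threshold = 1.5, top_k = 50,
                         separation_top_k = NULL, seed = 1,
                         requantify = TRUE) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  samples <- bundle$samples
  layout <- bundle$layout
  if (is.null(bundle$counts)) stop("transcriptome stage: counts are missing")
  if (is.null(comparisons)) {
    comparisons <- tidyr::crossing(
      case = c("SC", "BP"),
      region = unique(samples$region)
    )
    comparisons$control <- "NORMAL"
  }
  elements <- derive_elements(bundle$genes, layout)
  cgi_ctx <- derive_cgi_context(bundle$cgis, layout)

  # --- methylome quantification per region (pooled peak universe)
  regions <- unique(samples$region)
  meth <- stats::setNames(lapply(regions, function(reg) {
    ids <- samples$sample_id[samples$region == reg]
    pooled <- dplyr::bind_rows(bundle$fragments[ids])
    peaks <- call_peaks_poisson(pooled, layout, window = peak_window,
                                step = peak_step, p_cut = peak_p)
    mm <- quantify_peak_rpkm(peaks, bundle$fragments[ids])
    list(peaks = peaks, mm = mm, sample_ids = ids,
         fragments = bundle$fragments[ids])
  }), regions)

  # --- expression
  rpkm <- compute_gene_rpkm(bundle$counts, bundle$gene_lengths)

  comp_key <- function(case, region) {
    paste(paste(case, collapse = "+"), region, sep = ".")
  }
  results <- list()
  for (i in seq_len(nrow(comparisons))) {
    case <- unlist(comparisons$case[i])
    control <- unlist(comparisons$control[i])
    reg <- comparisons$region[i]
    key <- comp_key(case, reg)
    m <- meth[[reg]]
    frg <- if (requantify) bundle$fragments[m$sample_ids] else NULL
    dmrs <- call_dmrs(m$mm, samples, case, control, alpha = alpha,
                      gap = gap, fragments = frg)
    mapping <- map_dmrs_to_genes(dmrs, elements)
    enr <- if (nrow(dmrs$dmrs) > 0) {
      permutation_element_enrichment(dmrs, elements, layout,
                                     n_perm = n_perm, seed = seed)
    } else NULL
    fisher <- if (nrow(dmrs$dmrs) > 0) {
      tryCatch(cgi_shore_association(dmrs, cgi_ctx, layout, seed = seed),
               error = function(e) NULL)
    } else NULL
    de <- call_de_genes(rpkm, samples[samples$region == reg, ], case,
                        control, fc_threshold = fc_threshold)
    terms <- term_enrichment(unique(mapping$gene_id), rpkm$gene_id,
                             bundle$gene2term)
    corr <- if (nrow(dmrs$dmrs) >= 3) {
      suppressWarnings(methylation_expression_correlation(
        dmr_fold_changes(dmrs), de, mapping
      ))
    } else NULL
    results[[key]] <- list(
      case = case, control = control, region = reg,
      dmrs = dmrs, dmr_genes = mapping, enrichment = enr,
      cgi_shore = fisher, de = de, terms = terms, correlation = corr
    )
  }

  separation <- pipeline_separation(results, meth, samples, rpkm,
                                    control = "NORMAL",
                                    top_k = separation_top_k)

  out <- structure(list(
    elements = elements, cgi_context = cgi_ctx, methylation = meth,
    expression = rpkm, comparisons = results, separation = separation,
    params = list(alpha = alpha, gap = gap, peak_p = peak_p,
                  peak_window = peak_window, peak_step = peak_step,
                  n_perm = n_perm, fc_threshold = fc_threshold,
                  top_k = top_k, seed = seed, requantify = requantify)
  ), class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_outputs(out, bundle, outdir)
  out
}

# every feature source evaluated in every cohort, both modalities
pipeline_separation <- function(results, meth, samples, rpkm, control,
                                top_k) {
  cohorts <- purrr::map(results, function(r) {
    eval_ids <- samples$sample_id[
      samples$region == r$region & samples$group %in% c(r$case, control)
    ]
    labels <- stats::setNames(
      ifelse(samples$group[match(eval_ids, samples$sample_id)] %in% r$case,
             "case", "control"), eval_ids
    )
    list(region = r$region, ids = eval_ids, labels = labels)
  })
  rows <- list()
  for (src in names(results)) {
    r <- results[[src]]
    dmr_tbl <- r$dmrs$dmrs
    de_genes <- r$de$gene_id[r$de$de]
    for (coh in names(cohorts)) {
      c_ <- cohorts[[coh]]
      # methylation modality: re-quantify DMR spans in the cohort samples
      if (nrow(dmr_tbl) >= 2) {
        n_tot <- attr(meth[[c_$region]]$mm, "n_total")
        fm <- quantify_peak_rpkm(
          dplyr::rename(dmr_tbl[, c("dmr_id", "chrom", "start", "end")],
                        peak_id = "dmr_id"),
          meth[[c_$region]]$fragments[c_$ids],
          n_total = n_tot[c_$ids]
        )
        fm <- fm[, c("peak_id", c_$ids)]
        rep_m <- cross_cluster_separation(
          fm, c_$labels, top_k = top_k,
          feature_source = src, modality = "methylation"
        )
        rows[[paste(src, coh, "methylation", sep = "|")]] <-
          dplyr::mutate(glance(rep_m), cohort = coh)
      }
      # expression modality: DE genes looked up in the expression matrix
      if (length(de_genes) >= 2) {
        fm <- rpkm[rpkm$gene_id %in% de_genes, c("gene_id", c_$ids)]
        rep_e <- cross_cluster_separation(
          fm, c_$labels, top_k = top_k,
          feature_source = src, modality = "expression"
        )
        rows[[paste(src, coh, "expression", sep = "|")]] <-
          dplyr::mutate(glance(rep_e), cohort = coh)
      }
    }
  }
  dplyr::bind_rows(rows)[, c("feature_source", "cohort", "modality",
                             "n_features", "ari", "separated")]
}

write_pipeline_outputs <- function(res, bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(res$comparisons)) {
    r <- res$comparisons[[key]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
    d <- r$dmrs$dmrs
    if (nrow(d) > 0) {
      bed <- tibble::tibble(
        chrom = d$chrom, start = d$start, end = d$end, name = d$dmr_id,
        score = round(-log10(pmax(d$p_value, 1e-300)), 3), strand = ".",
        direction = d$direction, mean_case = d$mean_case,
        mean_control = d$mean_control, n_peaks = d$n_peaks
      )
      readr::write_tsv(bed, file.path(outdir, paste0(safe, ".dmrs.bed")),
                       col_names = FALSE, progress = FALSE)
    }
    readr::write_tsv(r$de, file.path(outdir, paste0(safe, ".de.tsv")),
                     progress = FALSE)
    if (!is.null(r$enrichment)) {
      readr::write_tsv(r$enrichment,
                       file.path(outdir, paste0(safe, ".enrichment.tsv")),
                       progress = FALSE)
    }
    if (!is.null(r$terms)) {
      readr::write_tsv(dplyr::select(r$terms, -"overlap_genes"),
                       file.path(outdir, paste0(safe, ".terms.tsv")),
                       progress = FALSE)
    }
    if (!is.null(r$correlation)) {
      readr::write_tsv(r$correlation,
                       file.path(outdir, paste0(safe, ".correlation.tsv")),
                       progress = FALSE)
    }
  }
  readr::write_tsv(res$separation, file.path(outdir, "separation.tsv"),
                   progress = FALSE)
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    params = res$params,
    comparisons = lapply(res$comparisons, function(r) {
      list(case = as.list(r$case), control = as.list(r$control),
           region = r$region, n_dmrs = nrow(r$dmrs$dmrs),
           n_de = sum(r$de$de))
    }),
    files = as.list(tools::md5sum(file.path(outdir, files))) |>
      stats::setNames(files)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (key in names(x$comparisons)) {
    r <- x$comparisons[[key]]
    g <- glance(r$dmrs)
    cat(sprintf("  %-14s %5d DMRs (%d hyper / %d hypo), %d DE genes\n",
                key, g$n_dmrs, g$n_hyper, g$n_hypo, sum(r$de$de)))
  }
  invisible(x)
}

#' Summarise a pipeline run
#'
#' Plain-text style summary tables: DMR and DE counts per comparison, the
#' element-distribution of DMRs (single-label precedence), and the
#' separation ARIs — the report companion to [run_pipeline()].
#'
#' @param result A `pipeline_result`.
#' @return List of tibbles: `counts`, `element_distribution`, `separation`.
#' @export
make_report <- function(result) {
  counts <- purrr::map_dfr(result$comparisons, .id = "comparison",
    function(r) {
      g <- glance(r$dmrs)
      tibble::tibble(region = r$region,
                     case = paste(r$case, collapse = "+"),
                     n_dmrs = g$n_dmrs, n_hyper = g$n_hyper,
                     n_hypo = g$n_hypo, mean_dmr_length = g$mean_length,
                     n_de_genes = sum(r$de$de))
    })
  eldist <- purrr::map_dfr(result$comparisons, .id = "comparison",
    function(r) {
      d <- r$dmrs$dmrs
      if (nrow(d) == 0) return(NULL)
      ann <- assign_primary_element(
        annotate_intervals(d[, c("chrom", "start", "end")],
                           result$elements, result$cgi_context)
      )
      dplyr::count(ann, .data$element_primary, name = "n_dmrs")
    })
  list(counts = counts, element_distribution = eldist,
       separation = result$separation)
}
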