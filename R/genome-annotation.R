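#' Read gene models from BED12 or GTF
#'
#' Gene models carry the transcript span, strand, exon structure and (when
#' present) CDS bounds used to derive promoter/UTR/exon/intron elements.
#' Coordinates are converted to the 0-based half-open BED convention on load.
#'
#' @param path BED12 file or minimal GTF (exon features carrying `gene_id`).
#' @param layout A [genome_layout()]. Records on chromosomes absent from the
#'   layout are dropped with a warning; malformed lines are a hard error.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `cds_start`, `cds_end` (NA when absent) and a list-column
#'   `exons` of tibbles (`start`, `end`), sorted by (chrom, start, gene_id).
#' @export
read_gene_models <- function(path, layout) {
  fmt <- if (grepl("\\.(gtf|gff)(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed"
  if (fmt == "bed") {
    models <- read_gene_models_bed12(path)
  } else {
    models <- read_gene_models_gtf(path)
  }
  if (nrow(models) == 0) return(models)
  known <- models$chrom %in% layout$chrom
  if (any(!known)) {
    warning(sum(!known), " gene model(s) on chromosomes absent from layout dropped")
    models <- models[known, ]
  }
  if (nrow(models) > 0) {
    idx <- match(models$chrom, layout$chrom)
    if (any(models$end > layout$length[idx])) {
      stop("gene model extends beyond chromosome end")
    }
  }
  dplyr::arrange(models, .data$chrom, .data$start, .data$gene_id)
}

read_gene_models_bed12 <- function(path) {
  empty <- tibble::tibble(
    gene_id = character(), chrom = character(), start = numeric(),
    end = numeric(), strand = character(), cds_start = numeric(),
    cds_end = numeric(), exons = list()
  )
  info <- file.info(path)
  if (is.na(info$size)) stop("file not found: ", path)
  if (info$size == 0) return(empty)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) return(empty)
  mc <- S4Vectors::mcols(gr)
  if (!all(c("name", "blocks") %in% names(mc))) {
    stop("gene-model BED must be BED12 (12 columns with block structure)")
  }
  blocks <- mc$blocks
  starts0 <- GenomicRanges::start(gr) - 1
  exons <- lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    ex <- tibble::tibble(
      start = starts0[i] + IRanges::start(b) - 1,
      end = starts0[i] + IRanges::end(b)
    )
    ex <- dplyr::arrange(ex, .data$start)
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exon blocks in gene ", mc$name[i])
    }
    ex
  })
  thick <- mc$thick
  cds_start <- IRanges::start(thick) - 1
  cds_end <- as.numeric(IRanges::end(thick))
  no_cds <- IRanges::width(thick) == 0 |
    (cds_start == starts0 & cds_end == as.numeric(GenomicRanges::end(gr)))
  tibble::tibble(
    gene_id = as.character(mc$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = starts0,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    cds_start = ifelse(no_cds, NA_real_, cds_start),
    cds_end = ifelse(no_cds, NA_real_, cds_end),
    exons = exons
  )
}

read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) {
    return(tibble::tibble(
      gene_id = character(), chrom = character(), start = numeric(),
      end = numeric(), strand = character(), cds_start = numeric(),
      cds_end = numeric(), exons = list()
    ))
  }
  if (is.null(ex$gene_id)) stop("GTF exon features must carry gene_id")
  tb <- tibble::tibble(
    gene_id = as.character(ex$gene_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1,
    end = as.numeric(GenomicRanges::end(ex)),
    strand = as.character(GenomicRanges::strand(ex))
  )
  tb |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(
      exons = list(dplyr::arrange(
        tibble::tibble(start = .data$start, end = .data$end), start
      )),
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    ) |>
    dplyr::mutate(cds_start = NA_real_, cds_end = NA_real_) |>
    dplyr::select("gene_id", "chrom", "start", "end", "strand",
                  "cds_start", "cds_end", "exons")
}

#' Derive the gene-element partition of the genome
#'
#' Elements follow the usual functional-genomics classes: the promoter is the
#' window from `up` bp upstream to `down` bp downstream of the transcription
#' start site (strand-aware; the TSS of a minus-strand gene is the transcript
#' 3' coordinate in genome space), introns are the transcript span minus the
#' exons, 5'/3' UTRs are exonic sequence outside the CDS when CDS bounds are
#' present, and intergenic space is the complement of everything else.
#'
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param layout A [genome_layout()]; promoters are clipped to chromosome
#'   bounds.
#' @param up,down Promoter extent upstream/downstream of the TSS in bp
#'   (defaults 2500 and 500).
#' @return A tibble of element intervals: `chrom`, `start`, `end`, `element`
#'   (one of promoter, utr5, exon, intron, utr3, intergenic), `gene_id`
#'   (`NA` for intergenic), with attributes `promoter_upstream_bp` and
#'   `promoter_downstream_bp`. Class `element_map`.
#' @export
derive_elements <- function(genes, layout, up = 2500, down = 500) {
  stopifnot(up >= 0, down >= 0)
  per_gene <- purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$start, genes$end, genes$strand,
         genes$cds_start, genes$cds_end, genes$exons),
    function(gid, chrom, gstart, gend, strand, cs, ce, exons) {
      L <- layout$length[match(chrom, layout$chrom)]
      if (strand == "+") {
        prom <- c(gstart - up, gstart + down)
      } else {
        prom <- c(gend - down, gend + up)
      }
      prom <- c(max(0, prom[1]), min(L, prom[2]))
      rows <- list()
      if (prom[2] > prom[1]) {
        rows$promoter <- tibble::tibble(start = prom[1], end = prom[2],
                                        element = "promoter")
      }
      ex <- exons
      # introns: span minus exons
      if (nrow(ex) > 1) {
        istart <- ex$end[-nrow(ex)]
        iend <- ex$start[-1]
        keep <- iend > istart
        if (any(keep)) {
          rows$intron <- tibble::tibble(start = istart[keep], end = iend[keep],
                                        element = "intron")
        }
      }
      if (!is.na(cs) && !is.na(ce) && ce > cs) {
        # exonic pieces split at CDS bounds
        exon_part <- function(s, e) {
          out <- list()
          if (s < cs) out <- c(out, list(c(s, min(e, cs), "left")))
          if (e > ce) out <- c(out, list(c(max(s, ce), e, "right")))
          mid_s <- max(s, cs); mid_e <- min(e, ce)
          if (mid_e > mid_s) out <- c(out, list(c(mid_s, mid_e, "cds")))
          out
        }
        parts <- purrr::list_flatten(purrr::map2(ex$start, ex$end, exon_part))
        ptbl <- tibble::tibble(
          start = as.numeric(purrr::map_chr(parts, 1)),
          end = as.numeric(purrr::map_chr(parts, 2)),
          side = purrr::map_chr(parts, 3)
        )
        ptbl$element <- ifelse(
          ptbl$side == "cds", "exon",
          ifelse((ptbl$side == "left") == (strand == "+"), "utr5", "utr3")
        )
        rows$exonic <- ptbl[, c("start", "end", "element")]
      } else {
        rows$exonic <- tibble::tibble(start = ex$start, end = ex$end,
                                      element = "exon")
      }
      out <- dplyr::bind_rows(rows)
      out$chrom <- chrom
      out$gene_id <- gid
      out
    }
  )
  em <- dplyr::bind_rows(per_gene)
  if (nrow(em) == 0) {
    em <- tibble::tibble(chrom = character(), start = numeric(),
                         end = numeric(), element = character(),
                         gene_id = character())
  }
  em <- em[, c("chrom", "start", "end", "element", "gene_id")]
  # intergenic = complement of the union of all gene-derived elements
  inter <- complement_intervals(em, layout)
  if (nrow(inter) > 0) {
    inter$element <- "intergenic"
    inter$gene_id <- NA_character_
    em <- dplyr::bind_rows(em, inter)
  }
  em <- sort_intervals(em)
  attr(em, "promoter_upstream_bp") <- up
  attr(em, "promoter_downstream_bp") <- down
  class(em) <- c("element_map", class(em))
  em
}

complement_intervals <- function(x, layout) {
  genome <- tibble::tibble(chrom = layout$chrom, start = 0,
                           end = layout$length)
  if (nrow(x) == 0) return(genome)
  ggr <- gr_from_tbl(genome)
  xgr <- GenomicRanges::reduce(gr_from_tbl(x[, c("chrom", "start", "end")]))
  tbl_from_gr(GenomicRanges::setdiff(ggr, xgr))
}

#' Derive CpG-island shore context
#'
#' Shores are the fixed-width flanks on both sides of each merged CpG island,
#' clipped to chromosome bounds, with any residual island overlap subtracted
#' so islands and shores are disjoint. The 2 kb default is the shore
#' convention of the CpG-island-shore literature.
#'
#' @param cgis Interval tibble of CpG islands (chrom, start, end).
#' @param layout A [genome_layout()].
#' @param shore_width Shore width in bp (> 0, default 2000).
#' @return A list of class `cgi_context` with tibbles `cgi` (merged islands)
#'   and `shore`, plus `shore_width_bp`.
#' @export
derive_cgi_context <- function(cgis, layout, shore_width = 2000) {
  stopifnot(shore_width > 0)
  cgis <- validate_intervals(cgis, layout, "CpG island")
  cgi <- reduce_intervals(cgis)
  if (nrow(cgi) == 0) {
    shore <- cgi
  } else {
    L <- layout$length[match(cgi$chrom, layout$chrom)]
    flanks <- dplyr::bind_rows(
      tibble::tibble(chrom = cgi$chrom,
                     start = pmax(0, cgi$start - shore_width),
                     end = cgi$start),
      tibble::tibble(chrom = cgi$chrom, start = cgi$end,
                     end = pmin(L, cgi$end + shore_width))
    )
    flanks <- flanks[flanks$end > flanks$start, ]
    shore_gr <- GenomicRanges::setdiff(
      GenomicRanges::reduce(gr_from_tbl(flanks)), gr_from_tbl(cgi)
    )
    shore <- tbl_from_gr(shore_gr)
  }
  structure(
    list(cgi = sort_intervals(cgi), shore = sort_intervals(shore),
         shore_width_bp = shore_width),
    class = "cgi_context"
  )
}

#' Annotate intervals against gene elements and CGI context
#'
#' Element membership is multi-label: a query is tagged with every element
#' class it overlaps by at least 1 bp, along with the gene identifiers whose
#' elements are hit. The CGI-context label is single, with precedence
#' cgi > shore > open-sea.
#'
#' @param x Query interval tibble (chrom, start, end).
#' @param elements An `element_map` from [derive_elements()].
#' @param cgi_context A `cgi_context` from [derive_cgi_context()], or NULL to
#'   skip context labelling.
#' @param layout Optional [genome_layout()] for validation; queries on unknown
#'   chromosomes are an error.
#' @return `x` with list-columns `elements` and `gene_ids` and a character
#'   column `cgi_context`.
#' @export
annotate_intervals <- function(x, elements, cgi_context = NULL, layout = NULL) {
  x <- validate_intervals(x, layout, "query")
  if (nrow(x) == 0) {
    x$elements <- list(); x$gene_ids <- list()
    x$cgi_context <- character()
    return(x)
  }
  al <- align_seqlevels(gr_from_tbl(x), gr_from_tbl(elements))
  qgr <- al[[1]]; egr <- al[[2]]
  hits <- GenomicRanges::findOverlaps(qgr, egr, minoverlap = 1)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  elems <- lapply(seq_len(nrow(x)), function(i) {
    sort(unique(elements$element[sh[qh == i]]))
  })
  genes <- lapply(seq_len(nrow(x)), function(i) {
    g <- elements$gene_id[sh[qh == i]]
    sort(unique(g[!is.na(g)]))
  })
  x$elements <- elems
  x$gene_ids <- genes
  if (!is.null(cgi_context)) {
    alc <- align_seqlevels(qgr, gr_from_tbl(cgi_context$cgi))
    als <- align_seqlevels(qgr, gr_from_tbl(cgi_context$shore))
    in_cgi <- IRanges::overlapsAny(alc[[1]], alc[[2]])
    in_shore <- IRanges::overlapsAny(als[[1]], als[[2]])
    x$cgi_context <- ifelse(in_cgi, "cgi",
                            ifelse(in_shore, "shore", "open-sea"))
  }
  x
}

#' Single-label element assignment by precedence
#'
#' Collapses multi-label element annotation to one class per interval for
#' stacked-bar summaries, using the fixed precedence
#' promoter > utr5 > exon > intron > utr3 > intergenic.
#'
#' @param x Output of [annotate_intervals()].
#' @return `x` with an `element_primary` character column.
#' @export
assign_primary_element <- function(x) {
  prec <- c("promoter", "utr5", "exon", "intron", "utr3", "intergenic")
  x$element_primary <- purrr::map_chr(x$elements, function(e) {
    if (length(e) == 0) return("intergenic")
    prec[min(match(e, prec), na.rm = TRUE)]
  })
  x
}
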