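#' Construct a genome layout
#'
#' A genome layout is the ordered set of chromosomes and their lengths. All
#' interval-valued tables in medipr are validated against a layout, and random
#' region placement draws positions from it.
#'
#' @param chrom Character vector of unique chromosome identifiers.
#' @param length Integer vector of chromosome lengths in bp (all > 0).
#' @return A tibble with columns `chrom` and `length`, class `genome_layout`.
#' @export
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome identifiers must be unique")
  if (length(chrom) != base::length(length)) {
    stop("`chrom` and `length` must have equal length")
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  out <- tibble::tibble(chrom = chrom, length = length)
  class(out) <- c("genome_layout", class(out))
  out
}

#' Read a genome layout from a two-column TSV (chrom, length)
#'
#' @param path Path to a tab-separated file with columns chrom, length.
#' @return A [genome_layout()] tibble.
#' @export
read_genome_layout <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), length = readr::col_double()
  ))
  genome_layout(x$chrom, x$length)
}

layout_seqlengths <- function(layout) {
  stats::setNames(as.integer(layout$length), layout$chrom)
}

#' Validate an interval tibble against a genome layout
#'
#' Intervals use the BED convention throughout: 0-based start, exclusive end.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param layout A [genome_layout()]; if supplied, chromosomes must exist and
#'   intervals must lie within chromosome bounds.
#' @param what Label used in error messages.
#' @return `x` as a tibble, invisibly validated.
#' @export
validate_intervals <- function(x, layout = NULL, what = "interval") {
  x <- tibble::as_tibble(x)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x))) {
    stop(what, " table must have columns chrom, start, end")
  }
  if (nrow(x) == 0) return(x)
  if (any(x$start < 0) || any(x$end <= x$start)) {
    stop(what, "s must satisfy 0 <= start < end")
  }
  if (!is.null(layout)) {
    idx <- match(x$chrom, layout$chrom)
    if (anyNA(idx)) {
      bad <- unique(x$chrom[is.na(idx)])
      stop(what, " on unknown chromosome: ", paste(bad, collapse = ", "))
    }
    if (any(x$end > layout$length[idx])) {
      stop(what, " extends beyond chromosome end")
    }
  }
  x
}

# 0-based half-open tibble -> GRanges (1-based closed internally)
gr_from_tbl <- function(x, layout = NULL) {
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges(seqlengths = if (!is.null(layout)) layout_seqlengths(layout)))
  }
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = strand
  )
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(gr) <- layout$chrom
    GenomeInfoDb::seqlengths(gr) <- layout_seqlengths(layout)
  }
  gr
}

tbl_from_gr <- function(gr) {
  if (length(gr) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

# merge overlapping/adjacent intervals within a tibble
reduce_intervals <- function(x) {
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  tbl_from_gr(GenomicRanges::reduce(gr_from_tbl(x)))
}

# number of query intervals (rows of x) overlapping >= 1 bp with subject set y
count_overlapping <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(0L)
  al <- align_seqlevels(gr_from_tbl(x), gr_from_tbl(y))
  sum(IRanges::overlapsAny(al[[1]], al[[2]]))
}

# total bp of x covered by subject set y
overlap_bp <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(0)
  al <- align_seqlevels(gr_from_tbl(x), gr_from_tbl(y))
  sum(GenomicRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(al[[1]]), GenomicRanges::reduce(al[[2]])
  )))
}

# put two GRanges on the union of their seqlevels so overlap operations do
# not warn when one set lacks a chromosome present in the other
align_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

# deterministic interval sort
sort_intervals <- function(x) {
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

#' Write intervals as BED
#'
#' Generic BED writer for the package's interval tibbles: peaks (BED4 via
#' `name`), element maps (BED6 with name = element:gene_id), DMRs (BED6+
#' with extra columns appended after the first six fields).
#'
#' @param x Interval tibble (chrom, start, end, ...).
#' @param path Output file.
#' @param name,score,strand Optional column names (or constants) for BED
#'   fields 4-6; `name` defaults to an `element:gene_id` composite for
#'   element maps, a `peak_id`/`dmr_id` column when present, else row
#'   numbers.
#' @param extra Character vector of additional columns to append (BED6+).
#' @return The path, invisibly.
#' @export
write_bed <- function(x, path, name = NULL, score = 0, strand = ".",
                      extra = character()) {
  x <- tibble::as_tibble(x)
  nm <- if (!is.null(name)) {
    x[[name]]
  } else if (inherits(x, "element_map") ||
             all(c("element", "gene_id") %in% names(x))) {
    paste0(x$element, ":", ifelse(is.na(x$gene_id), ".", x$gene_id))
  } else if ("dmr_id" %in% names(x)) {
    x$dmr_id
  } else if ("peak_id" %in% names(x)) {
    x$peak_id
  } else {
    as.character(seq_len(nrow(x)))
  }
  out <- tibble::tibble(
    chrom = x$chrom,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = nm,
    score = if (is.character(score) && score %in% names(x)) x[[score]] else
      score,
    strand = if (is.character(strand) && strand %in% names(x))
      x[[strand]] else strand
  )
  for (col in extra) out[[col]] <- x[[col]]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
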