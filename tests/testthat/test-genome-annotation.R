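test_that("promoter placement follows strand and clips at chromosome bounds", {
  layout <- tiny_layout()
  genes <- tiny_genes()
  em <- derive_elements(genes, layout)
  promA <- em[em$element == "promoter" & em$gene_id == "gA", ]
  expect_equal(c(promA$start, promA$end), c(10000 - 2500, 10000 + 500))
  promB <- em[em$element == "promoter" & em$gene_id == "gB", ]
  # minus-strand TSS is the transcript end (72000)
  expect_equal(c(promB$start, promB$end), c(72000 - 500, 72000 + 2500))

  near_edge <- genes[1, ]
  near_edge$start <- 1000; near_edge$end <- 5000
  near_edge$cds_start <- NA; near_edge$cds_end <- NA
  near_edge$exons <- list(tibble::tibble(start = c(1000, 4000),
                                         end = c(2000, 5000)))
  em2 <- derive_elements(near_edge, layout)
  prom <- em2[em2$element == "promoter", ]
  expect_equal(c(prom$start, prom$end), c(0, 1500))
})

test_that("gene-element partition tiles the genome and introns/UTRs are derived", {
  layout <- tiny_layout()
  em <- derive_elements(tiny_genes(), layout)
  # coverage: union of all classes equals total genome bp
  covered <- sum(GenomicRanges::width(GenomicRanges::reduce(
    medipr:::gr_from_tbl(em)
  )))
  expect_equal(covered, sum(layout$length))
  # gA: 3 exons -> 2 introns; CDS inside -> utr5 (left, + strand) and utr3
  intr <- em[em$element == "intron" & em$gene_id == "gA", ]
  expect_equal(nrow(intr), 2)
  expect_equal(intr$start, c(11000, 14000))
  expect_equal(intr$end, c(13000, 18000))
  utr5 <- em[em$element == "utr5" & em$gene_id == "gA", ]
  expect_equal(c(utr5$start, utr5$end), c(10000, 10500))
  # minus strand gene: utr5 at the high-coordinate end
  utr5B <- em[em$element == "utr5" & em$gene_id == "gB", ]
  expect_equal(c(utr5B$start, utr5B$end), c(71500, 72000))
})

test_that("BED12 round trip preserves gene structure; bad records handled", {
  layout <- tiny_layout()
  genes <- tiny_genes()
  path <- withr::local_tempfile(fileext = ".bed")
  medipr:::write_bed12(genes, path)
  back <- read_gene_models(path, layout)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$cds_start, genes$cds_start)
  expect_equal(nrow(back$exons[[1]]), 3)
  expect_equal(back$exons[[2]], genes$exons[[2]])

  # record on unknown chromosome dropped with one warning
  alien <- genes
  alien$chrom[2] <- "chrMystery"
  medipr:::write_bed12(alien, path)
  expect_warning(kept <- read_gene_models(path, layout), "dropped")
  expect_equal(kept$gene_id, "gA")

  # empty file -> empty model list, no error
  writeLines(character(0), path)
  expect_silent(empty <- read_gene_models(path, layout))
  expect_equal(nrow(empty), 0)
})

test_that("CGI shores flank merged islands, clipped and island-free", {
  layout <- tiny_layout()
  cc <- derive_cgi_context(
    tibble::tibble(chrom = "chr1", start = 100000, end = 101000), layout
  )
  expect_equal(cc$shore$start, c(98000, 101000))
  expect_equal(cc$shore$end, c(100000, 103000))

  # two CGIs 1 kb apart: the inter-CGI shore is exactly the 1 kb gap
  cc2 <- derive_cgi_context(
    tibble::tibble(chrom = "chr1", start = c(50000, 52000),
                   end = c(51000, 53000)), layout
  )
  gap <- cc2$shore[cc2$shore$start >= 51000 & cc2$shore$end <= 52000, ]
  expect_equal(c(gap$start, gap$end), c(51000, 52000))
  # no shore bp overlaps any island
  expect_equal(medipr:::overlap_bp(cc2$shore, cc2$cgi), 0)

  # island at chromosome start: left shore empty
  cc3 <- derive_cgi_context(
    tibble::tibble(chrom = "chr1", start = 0, end = 500), layout
  )
  expect_equal(nrow(cc3$shore), 1)
  expect_equal(c(cc3$shore$start, cc3$shore$end), c(500, 2500))
})

test_that("interval annotation is multi-label with CGI precedence", {
  layout <- tiny_layout()
  em <- derive_elements(tiny_genes(), layout)
  cc <- derive_cgi_context(
    tibble::tibble(chrom = "chr1", start = 30000, end = 31000), layout
  )
  q <- tibble::tibble(
    chrom = "chr1",
    start = c(11500, 10900, 30500, 32500, 40000),
    end = c(12000, 11200, 30600, 32600, 40100)
  )
  ann <- annotate_intervals(q, em, cc, layout)
  expect_equal(ann$elements[[1]], "intron")            # inside gA intron 1
  expect_setequal(ann$elements[[2]], c("exon", "intron")) # spans junction
  expect_equal(ann$cgi_context, c("open-sea", "open-sea", "cgi", "shore",
                                  "open-sea"))
  expect_equal(ann$gene_ids[[1]], "gA")
  expect_equal(ann$elements[[5]], "intergenic")
  # query overlapping both island and shore -> island wins
  q2 <- tibble::tibble(chrom = "chr1", start = 30900, end = 31500)
  expect_equal(annotate_intervals(q2, em, cc)$cgi_context, "cgi")
  # unknown chromosome is an error
  expect_error(annotate_intervals(
    tibble::tibble(chrom = "chrX", start = 0, end = 10), em, cc, layout
  ), "unknown")
})

test_that("annotation agrees with a per-bp membership scan on a random genome", {
  cfg <- small_cfg(seed = 42)
  genome <- simulate_genome(cfg)
  em <- derive_elements(genome$genes, genome$layout)
  withr::with_seed(7, {
    q <- random_fragments(60, genome$layout, len = 500)
  })
  ann <- annotate_intervals(q, em, layout = genome$layout)
  for (i in seq_len(nrow(q))) {
    rows <- em[em$chrom == q$chrom[i], ]
    # independent check: explicit per-bp membership over the query
    pos <- seq(q$start[i], q$end[i] - 1)
    hit <- vapply(seq_len(nrow(rows)), function(j) {
      any(pos >= rows$start[j] & pos < rows$end[j])
    }, logical(1))
    expect_setequal(ann$elements[[i]], unique(rows$element[hit]))
  }
})

test_that("reflecting the genome mirrors promoter placement exactly", {
  layout <- tiny_layout()
  genes <- tiny_genes()
  em <- derive_elements(genes, layout)
  L <- layout$length[1]
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  flipped$start <- L - genes$end
  flipped$end <- L - genes$start
  flipped$cds_start <- L - genes$cds_end
  flipped$cds_end <- L - genes$cds_start
  flipped$exons <- lapply(genes$exons, function(e) {
    tibble::tibble(start = rev(L - e$end), end = rev(L - e$start))
  })
  emf <- derive_elements(flipped, layout)
  p1 <- em[em$element == "promoter", ]
  p2 <- emf[emf$element == "promoter", ]
  p2 <- p2[order(match(p2$gene_id, p1$gene_id)), ]
  expect_equal(p2$start, L - p1$end)
  expect_equal(p2$end, L - p1$start)
})

test_that("primary-element collapse follows the documented precedence", {
  layout <- tiny_layout()
  em <- derive_elements(tiny_genes(), layout)
  q <- tibble::tibble(chrom = "chr1", start = c(7400, 10900, 40000),
                      end = c(10600, 11200, 40100))
  ann <- assign_primary_element(annotate_intervals(q, em, layout = layout))
  # promoter+utr5+... -> promoter; exon+intron -> exon; intergenic
  expect_equal(ann$element_primary, c("promoter", "exon", "intergenic"))
})

test_that("interval tibbles round-trip through the BED writer", {
  layout <- tiny_layout()
  em <- derive_elements(tiny_genes(), layout)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(em, path)
  back <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                              "name", "score", "strand"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(em))
  expect_equal(back$start, em$start)
  expect_true(all(grepl(":", back$name)))
  expect_equal(back$name[em$element == "intergenic"][1], "intergenic:.")
  # peaks come out as BED4-compatible (name = peak id)
  pk <- tibble::tibble(chrom = "chr1", start = 100, end = 600,
                       peak_id = "peak_00001")
  write_bed(pk, path)
  line <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(line[1:4], c("chr1", "100", "600", "peak_00001"))
})
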