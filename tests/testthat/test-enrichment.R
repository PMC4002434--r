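test_that("matched random regions preserve chromosome and length exactly", {
  layout <- tiny_layout()
  withr::with_seed(2, {
    regions <- random_fragments(40, layout, len = 700)
    rnd <- generate_matched_random_regions(regions, layout)
  })
  expect_equal(table(rnd$chrom), table(regions$chrom))
  expect_equal(sort(rnd$end - rnd$start), sort(regions$end - regions$start))
  expect_true(all(rnd$start >= 0))
  expect_true(all(rnd$end <= layout$length[match(rnd$chrom, layout$chrom)]))

  # region as long as its chromosome: forced placement at 0
  full <- tibble::tibble(chrom = "chr2", start = 0, end = 1e5)
  expect_equal(generate_matched_random_regions(full, layout)$start, 0)
  too_long <- tibble::tibble(chrom = "chr2", start = 0, end = 1e5 + 1)
  expect_error(generate_matched_random_regions(too_long, layout))
})

test_that("matched random starts are uniform over their support", {
  layout <- genome_layout("chr1", 1e5)
  region <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  many <- region[rep(1, 10000), ]
  withr::with_seed(8, rnd <- generate_matched_random_regions(many, layout))
  ks <- suppressWarnings(
    ks.test(rnd$start / (1e5 - 1000), "punif")
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation enrichment p follows the add-one estimator and its floor", {
  layout <- tiny_layout()
  # element covering everything: every permutation ties the observed count
  whole <- list(all = tibble::tibble(chrom = layout$chrom, start = 0,
                                     end = layout$length))
  dmrs <- tibble::tibble(chrom = "chr1", start = c(1000, 5000),
                         end = c(1500, 5500))
  res <- permutation_element_enrichment(dmrs, whole, layout, n_perm = 50,
                                        seed = 4)
  expect_equal(res$p_enriched, 1)
  expect_equal(res$observed, 2)

  # tiny target element, all regions inside it: no random set can match
  target <- list(intron = tibble::tibble(chrom = "chr1", start = 10000,
                                         end = 12000))
  inside <- tibble::tibble(chrom = "chr1",
                           start = seq(10000, 11800, length.out = 10),
                           end = seq(10100, 11900, length.out = 10))
  res2 <- permutation_element_enrichment(inside, target, layout,
                                         n_perm = 1000, seed = 4)
  expect_equal(res2$p_enriched, 1 / 1001)
  expect_equal(res2$direction, "enriched")

  # n_perm = 1 formula cases
  res3 <- permutation_element_enrichment(inside, target, layout, n_perm = 1,
                                         seed = 4)
  expect_true(res3$p_enriched %in% c(0.5, 1))
  expect_error(permutation_element_enrichment(inside[0, ], target, layout),
               "empty")
})

test_that("same seed reproduces enrichment bit-identically, p never zero", {
  layout <- tiny_layout()
  withr::with_seed(12, dmrs <- random_fragments(20, layout, len = 500))
  em <- derive_elements(tiny_genes(), layout)
  a <- permutation_element_enrichment(dmrs, em, layout, n_perm = 200,
                                      seed = 99)
  b <- permutation_element_enrichment(dmrs, em, layout, n_perm = 200,
                                      seed = 99)
  expect_identical(a, b)
  expect_true(all(a$p_enriched >= 1 / 201 & a$p_enriched <= 1))
  expect_true(all(a$p_depleted >= 1 / 201 & a$p_depleted <= 1))
})

test_that("Fisher association: balanced table, enumeration oracle, Haldane", {
  bal <- fisher_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(bal$odds_ratio, 1)
  expect_equal(bal$p_value, 1)

  skew <- matrix(c(1, 9, 9, 1), 2)
  fs <- fisher_2x2(skew)
  expect_equal(fs$odds_ratio, 1 / 81)
  expect_equal(fs$p_value, oracle_fisher_two_sided(skew), tolerance = 1e-9)

  withr::with_seed(77, {
    for (i in 1:30) {
      tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      ft <- fisher_2x2(tab)
      expect_equal(ft$p_value, oracle_fisher_two_sided(tab),
                   tolerance = 1e-9)
      expect_true(is.finite(ft$odds_ratio))   # Haldane guards zero cells
    }
  })
})

test_that("CGI/shore association builds the documented 2x2 with island precedence", {
  layout <- tiny_layout()
  cc <- derive_cgi_context(
    tibble::tibble(chrom = "chr1", start = c(50000, 120000),
                   end = c(52000, 122000)), layout
  )
  # all query regions inside shores; matched randoms mostly open sea
  dmrs <- tibble::tibble(chrom = "chr1",
                         start = c(48500, 52500, 118500, 122500),
                         end = c(49500, 53500, 119500, 123500))
  # explicit comparison set hitting both contexts keeps the margins non-empty
  random <- tibble::tibble(chrom = "chr1",
                           start = c(50500, 48200, 30000, 119000),
                           end = c(51500, 49200, 31000, 120000))
  res <- cgi_shore_association(dmrs, cc, layout, random = random)
  expect_s3_class(res, "fisher_association")
  expect_equal(res$table["real", "shore"], 4)
  expect_equal(res$table["real", "cgi"], 0)
  expect_equal(res$table["random", "cgi"], 1)
  # a region overlapping both island and shore counts as island
  both <- tibble::tibble(chrom = "chr1", start = 49500, end = 50500)
  res2 <- cgi_shore_association(dplyr::bind_rows(dmrs, both), cc, layout,
                                random = random)
  expect_equal(res2$table["real", "cgi"], 1)
  # a matched random draw that never touches island or shore is an error
  expect_error(cgi_shore_association(dmrs, cc, layout, seed = 5),
               "empty margin")
})

test_that("hypergeometric term enrichment matches enumeration and BH base cases", {
  g2t <- tibble::tibble(
    gene_id = c(paste0("g", 1:5), paste0("g", 1:10)),
    term_id = rep(c("t5", "t10"), c(5, 10))
  )
  universe <- paste0("g", 1:10)
  res <- term_enrichment(paste0("g", 1:3), universe, g2t)
  expect_equal(res$p_value[res$term_id == "t5"], 10 / 120, tolerance = 1e-12)
  expect_equal(res$p_value[res$term_id == "t5"],
               oracle_hyper_upper(3, 5, 10, 3), tolerance = 1e-12)
  # saturation: selected set = universe
  sat <- term_enrichment(universe, universe, g2t)
  expect_equal(sat$p_value, rep(1, 2))
  # single term: FDR equals p
  one <- term_enrichment(paste0("g", 1:3), universe,
                         g2t[g2t$term_id == "t5", ])
  expect_equal(one$fdr, one$p_value)
  expect_error(term_enrichment("g1", character(0), g2t), "empty")
  expect_error(term_enrichment("gX", universe, g2t), "subset")
})

test_that("hypergeometric p matches enumeration on random small universes", {
  withr::with_seed(31, {
    for (i in 1:40) {
      N <- sample(5:20, 1)
      universe <- paste0("g", seq_len(N))
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      g2t <- tibble::tibble(gene_id = sample(universe, K), term_id = "t")
      sel <- sample(universe, n)
      res <- term_enrichment(sel, universe, g2t)
      k <- length(intersect(sel, g2t$gene_id))
      if (k == 0) {
        expect_equal(nrow(res), 0)
      } else {
        expect_equal(res$p_value, oracle_hyper_upper(k, K, N, n),
                     tolerance = 1e-12)
      }
    }
  })
})
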