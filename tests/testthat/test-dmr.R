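# small helper to build a methylation matrix tibble directly
mk_mm <- function(values, starts = NULL) {
  np <- nrow(values)
  if (is.null(starts)) starts <- seq(1000, by = 2000, length.out = np)
  dplyr::bind_cols(
    tibble::tibble(
      peak_id = sprintf("peak_%05d", seq_len(np)), chrom = "chr1",
      start = starts, end = starts + 500, length = 500
    ),
    tibble::as_tibble(values)
  )
}

mk_samples <- function(n_case, n_ctrl) {
  tibble::tibble(
    sample_id = c(paste0("c", seq_len(n_case)), paste0("n", seq_len(n_ctrl))),
    group = rep(c("CASE", "NORMAL"), c(n_case, n_ctrl)),
    region = "R1"
  )
}

test_that("per-peak Welch test matches stats::t.test and handles degeneracy", {
  samples <- mk_samples(3, 3)
  mm <- mk_mm(data.frame(c1 = c(1, 10, 5), c2 = c(2, 12, 5), c3 = c(3, 11, 5),
                         n1 = c(1, 20, 5), n2 = c(2, 22, 5), n3 = c(3, 21, 5)))
  tt <- test_peaks(mm, samples, "CASE", "NORMAL")
  expect_equal(tt$p_value[1], 1)                  # identical groups
  expect_true(is.na(tt$direction[1]))
  expect_lt(tt$p_value[2], 0.01)                  # strong difference
  expect_equal(tt$direction[2], "hypo")
  ref <- t.test(c(10, 12, 11), c(20, 22, 21))
  expect_equal(tt$p_value[2], ref$p.value, tolerance = 1e-12)
  expect_equal(tt$p_value[3], 1)                  # both constant and equal

  # constant but unequal: certainty under the model
  mm2 <- mk_mm(data.frame(c1 = 5, c2 = 5, n1 = 7, n2 = 7))
  s2 <- mk_samples(2, 2)
  expect_equal(test_peaks(mm2, s2, "CASE", "NORMAL")$p_value, 0)
})

test_that("Welch and pooled tests agree with t.test on random matrices", {
  withr::with_seed(9, {
    X <- matrix(rnorm(50 * 5, 10, 2), 50)
    Y <- matrix(rnorm(50 * 7, 11, 3), 50)
  })
  colnames(X) <- paste0("c", 1:5); colnames(Y) <- paste0("n", 1:7)
  mm <- mk_mm(data.frame(X, Y))
  samples <- mk_samples(5, 7)
  tw <- test_peaks(mm, samples, "CASE", "NORMAL")
  tp <- test_peaks(mm, samples, "CASE", "NORMAL", test = "pooled")
  for (i in c(1, 17, 50)) {
    expect_equal(tw$p_value[i],
                 t.test(X[i, ], Y[i, ])$p.value, tolerance = 1e-12)
    expect_equal(tp$p_value[i],
                 t.test(X[i, ], Y[i, ], var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("group size and region-homogeneity guards fire", {
  samples <- mk_samples(1, 3)
  mm <- mk_mm(data.frame(c1 = 1:2, n1 = 1:2, n2 = 1:2, n3 = 1:2))
  expect_error(test_peaks(mm, samples, "CASE", "NORMAL"), ">= 2 samples")
  s_mixed <- mk_samples(2, 2)
  s_mixed$region <- c("R1", "R2", "R1", "R1")
  mm2 <- mk_mm(data.frame(c1 = 1:2, c2 = 1:2, n1 = 1:2, n2 = 1:2))
  expect_error(test_peaks(mm2, s_mixed, "CASE", "NORMAL"), "one region")
})

test_that("peak merging follows the strict < gap rule and direction guard", {
  base <- tibble::tibble(
    chrom = "chr1", peak_id = c("a", "b"), direction = "hyper",
    p_value = c(1e-4, 1e-3)
  )
  for (gap2 in c(49, 50, 51)) {
    x <- dplyr::mutate(base, start = c(100, 200 + gap2),
                       end = c(200, 300 + gap2))
    merged <- merge_significant_peaks(x[, c("chrom", "start", "end",
                                            "direction", "peak_id",
                                            "p_value")], gap = 50)
    if (gap2 == 49) {
      expect_equal(nrow(merged), 1)
      expect_equal(c(merged$start, merged$end), c(100, 300 + 49))
      expect_equal(merged$n_peaks, 2L)
    } else {
      expect_equal(nrow(merged), 2)
    }
  }
  # opposite directions never merge, even adjacent
  x <- tibble::tibble(chrom = "chr1", start = c(100, 210), end = c(200, 300),
                      direction = c("hyper", "hypo"), peak_id = c("a", "b"),
                      p_value = 1e-4)
  expect_equal(nrow(merge_significant_peaks(x)), 2)
  # unsorted input is an error
  expect_error(merge_significant_peaks(x[2:1, ]), "sorted")
})

test_that("merging is transitive and idempotent", {
  x <- tibble::tibble(
    chrom = "chr1", start = c(100, 240, 380, 900),
    end = c(200, 340, 480, 1000),
    direction = "hyper", peak_id = letters[1:4], p_value = 1e-4
  )
  m1 <- merge_significant_peaks(x)   # first three chain (gaps 40, 40)
  expect_equal(nrow(m1), 2)
  expect_equal(m1$n_peaks, c(3L, 1L))
  again <- m1 |>
    dplyr::mutate(peak_id = .data$dmr_id, p_value = .data$min_peak_p) |>
    dplyr::select("chrom", "start", "end", "direction", "peak_id", "p_value")
  m2 <- merge_significant_peaks(again)
  expect_equal(m2[, c("chrom", "start", "end", "direction")],
               m1[, c("chrom", "start", "end", "direction")])
})

test_that("call_dmrs output is invariant to sample column order and re-tests spans", {
  withr::with_seed(14, {
    X <- matrix(rnorm(30 * 5, 10, 1), 30)
    Y <- matrix(rnorm(30 * 6, 10, 1), 30)
    X[1:5, ] <- X[1:5, ] + 6      # strong planted hyper effect
  })
  colnames(X) <- paste0("c", 1:5); colnames(Y) <- paste0("n", 1:6)
  samples <- mk_samples(5, 6)
  mm <- mk_mm(data.frame(X, Y))
  res <- call_dmrs(mm, samples, "CASE", "NORMAL")
  expect_s3_class(res, "dmr_calls")
  expect_true(all(sprintf("peak_%05d", 1:5) %in%
                    unlist(res$dmrs$peak_ids)))
  expect_true(all(res$dmrs$p_value < 0.01))
  expect_true(all(res$dmrs$direction[res$dmrs$start < 10000] == "hyper"))
  # permuted columns -> identical DMRs
  perm <- mm[, c(names(mm)[1:5], sample(colnames(X)), sample(colnames(Y)))]
  res2 <- call_dmrs(perm, samples, "CASE", "NORMAL")
  expect_equal(res$dmrs, res2$dmrs)
  # glance/tidy surfaces
  expect_equal(tidy(res), res$dmrs)
  g <- glance(res)
  expect_equal(g$n_dmrs, nrow(res$dmrs))
  expect_equal(g$n_hyper + g$n_hypo, g$n_dmrs)
})

test_that("all-zero matrix yields zero DMRs", {
  samples <- mk_samples(3, 3)
  mm <- mk_mm(data.frame(c1 = numeric(5), c2 = 0, c3 = 0,
                         n1 = 0, n2 = 0, n3 = 0))
  expect_equal(nrow(call_dmrs(mm, samples, "CASE", "NORMAL")$dmrs), 0)
})

test_that("null peaks are called at about the nominal rate", {
  withr::with_seed(30, {
    X <- matrix(rnorm(4000 * 6, 10, 2), 4000)
    Y <- matrix(rnorm(4000 * 6, 10, 2), 4000)
  })
  colnames(X) <- paste0("c", 1:6); colnames(Y) <- paste0("n", 1:6)
  mm <- mk_mm(data.frame(X, Y))
  tt <- test_peaks(mm, mk_samples(6, 6), "CASE", "NORMAL")
  frac <- mean(tt$p_value < 0.01)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / 4000))
})

test_that("DMR-to-gene mapping is element-resolved and multi-gene", {
  layout <- tiny_layout()
  em <- derive_elements(tiny_genes(), layout)
  # one DMR inside gA intron, one purely intergenic
  dmrs <- tibble::tibble(dmr_id = c("d1", "d2"), chrom = "chr1",
                         start = c(11500, 40000), end = c(12500, 40500))
  mp <- map_dmrs_to_genes(dmrs, em)
  expect_equal(mp$gene_id, "gA")
  expect_equal(mp$element, "intron")
  expect_equal(mp$dmr_id, "d1")

  # overlapping genes: DMR spans promoter of one and exon of another
  genes2 <- tiny_genes()
  genes2$start[2] <- 6000; genes2$end[2] <- 9000
  genes2$cds_start[2] <- NA; genes2$cds_end[2] <- NA
  genes2$exons[[2]] <- tibble::tibble(start = c(6000, 8000),
                                      end = c(7000, 9000))
  em2 <- derive_elements(genes2, layout)
  d <- tibble::tibble(dmr_id = "d", chrom = "chr1", start = 8500, end = 9600)
  mp2 <- map_dmrs_to_genes(d, em2)
  # multi-gene: gA hit through its promoter, gB through its exon (gB's own
  # promoter, at its minus-strand TSS, is legitimately hit as well)
  expect_true(all(c("gA promoter", "gB exon") %in%
                    paste(mp2$gene_id, mp2$element)))
  expect_setequal(unique(mp2$gene_id), c("gA", "gB"))
})
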