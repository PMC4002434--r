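# shared fixtures and independent oracles, built in code at test time

tiny_layout <- function() genome_layout(c("chr1", "chr2"), c(2e5, 1e5))

# hand-built two-gene model set on tiny_layout: one gene per strand,
# multi-exon, with CDS bounds inside first/last exon
tiny_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB"),
    chrom = c("chr1", "chr1"),
    start = c(10000, 60000),
    end = c(20000, 72000),
    strand = c("+", "-"),
    cds_start = c(10500, 60500),
    cds_end = c(19500, 71500),
    exons = list(
      tibble::tibble(start = c(10000, 13000, 18000),
                     end = c(11000, 14000, 20000)),
      tibble::tibble(start = c(60000, 65000, 70000),
                     end = c(61000, 66000, 72000))
    )
  )
}

# uniform random fragments
random_fragments <- function(n, layout, len = 100) {
  ci <- sample(nrow(layout), n, replace = TRUE, prob = layout$length)
  start <- floor(runif(n) * (layout$length[ci] - len))
  tibble::tibble(chrom = layout$chrom[ci], start = start, end = start + len)
}

small_cfg <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chrom = 2, chrom_length = 2e6, n_genes = 50,
         n_cgi = 60, n_background_peaks = 120, n_truth_dmr = 30,
         n_noise_fragments = 4000, n_de = 25, n_terms = 8),
    list(...)
  )
  do.call(sim_config, args)
}

# the full-size study bundle used by the acceptance checks, generated once
# per test run and cached (study conditions: 200 truth DMRs per region at
# RPKM ratio 3, 5/7/6 subjects per group in both regions)
.fixture_cache <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- simulate_bundle(sim_config(seed = 1))
  }
  .fixture_cache$bundle
}

# combined-case DMR calls per region on the default bundle, cached
default_dmr_calls <- function(region) {
  key <- paste0("dmr_", region)
  if (is.null(.fixture_cache[[key]])) {
    b <- default_bundle()
    ids <- b$samples$sample_id[b$samples$region == region]
    pooled <- dplyr::bind_rows(b$fragments[ids])
    peaks <- call_peaks_poisson(pooled, b$layout)
    mm <- quantify_peak_rpkm(peaks, b$fragments[ids])
    .fixture_cache[[key]] <- list(
      mm = mm,
      calls = call_dmrs(mm, b$samples, c("SC", "BP"), "NORMAL",
                        fragments = b$fragments[ids])
    )
  }
  .fixture_cache[[key]]
}

# --- independent oracles -------------------------------------------------

# per-fragment overlap counting (no interval machinery)
oracle_overlap_count <- function(peak, frags) {
  sum(frags$chrom == peak$chrom & frags$start < peak$end &
        frags$end > peak$start)
}

# Pearson r by the textbook sum formulas
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# upper-tail hypergeometric by explicit enumeration over the support
oracle_hyper_upper <- function(k, K, N, n) {
  js <- max(0, n - (N - K)):min(n, K)
  p <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(p[js >= k])
}

# two-sided Fisher p for a 2x2 table by enumeration: sum of all table
# probabilities (margins fixed) not exceeding the observed one
oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  js <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- choose(c1, js) * choose(N - c1, r1 - js) / choose(N, r1)
  p_obs <- probs[js == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive average-linkage agglomeration over a distance matrix; returns the
# k=2 partition as an integer vector
oracle_average_linkage_cut2 <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > 2) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  out[clusters[[1]]] <- 1L
  out[clusters[[2]]] <- 2L
  out
}
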