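#' Simulation configuration
#'
#' Parameters of the synthetic two-region, three-group MeDIP-seq/RNA-seq
#' study. Defaults mirror the emulated design: 5 SC / 7 BP / 6 control
#' subjects sampled in two brain regions (BA9-like and BA24-like), a 5 x
#' 10 Mb autosome set, shared background coverage peaks with negative
#' binomial per-sample fragment counts, 200 injected truth DMRs per region
#' at RPKM ratio 3 (80% hypomethylated and chromosome-end-biased in region
#' BA9, 80% hypermethylated genome-wide in region BA24, with a fraction
#' placed in CGI shores), and partially DMR-coupled differential expression.
#'
#' @param seed Integer seed; the single RNG entry point — every simulation
#'   stage derives its stream deterministically from it.
#' @param n_chrom,chrom_length Genome layout (defaults 5 x 10 Mb).
#' @param n_genes Gene count (default 300, all multi-exon).
#' @param gene_length_range,exon_count_range,exon_length_range Gene
#'   structure ranges in bp / counts.
#' @param n_cgi,cgi_length_range,cgi_tss_frac CpG islands: count, length
#'   range, fraction placed at a TSS.
#' @param n_sc,n_bp,n_normal Subjects per group (defaults 5/7/6), each
#'   sampled in both regions.
#' @param regions Region labels (first is the hypo-dominant, end-biased
#'   one).
#' @param n_background_peaks,peak_width_range Shared methylation peak loci.
#' @param peak_mean_meanlog,peak_mean_sdlog Log-normal per-peak mean
#'   fragment counts.
#' @param nb_size_meth Negative binomial size (inverse overdispersion) of
#'   per-sample peak fragment counts.
#' @param n_noise_fragments Uniform background fragments per sample.
#' @param fragment_length Fragment length in bp (default 250, a typical
#'   sonication mean).
#' @param n_truth_dmr Truth DMRs injected per region (default 200).
#' @param effect_size RPKM ratio of the injected effect (default 3);
#'   hypomethylation divides the case mean, hypermethylation multiplies it;
#'   1 disables the effect (null simulation).
#' @param hypo_frac_region1,hyper_frac_region2 Direction mix per region
#'   (defaults 0.8/0.8).
#' @param end_bias Probability that a region-1 hypomethylated truth DMR is
#'   placed in the terminal decile of a chromosome (default 0.8).
#' @param terminal_frac Width of the terminal zone as a fraction of
#'   chromosome length, per end (default 0.1).
#' @param shore_frac Fraction of truth DMRs placed overlapping a CGI shore
#'   (default 0.3).
#' @param gene_frac Fraction of truth DMRs placed inside a gene body (mostly
#'   introns), the element-placement weight that makes intron-hosted
#'   methylation change — and hence DMR-coupled expression change —
#'   available (default 0.4).
#' @param gene_mean_meanlog,gene_mean_sdlog,nb_size_expr Expression count
#'   model.
#' @param expr_factor_sd Loading scale of a latent per-subject expression
#'   factor (default 0.6). Post-mortem brain expression is dominated by
#'   inter-individual heterogeneity (agonal state, PMI, pH, cellular
#'   composition); this correlated sample-level variation is what keeps
#'   fold-change gene lists from clustering samples by diagnosis. Set 0 to
#'   disable.
#' @param n_de DE genes injected per region (default 100).
#' @param de_fc Injected expression fold change (default 2).
#' @param de_penetrance Probability that an individual case subject expresses
#'   the injected fold change at a DE gene (default 0.6). Sub-unit
#'   penetrance emulates the inter-individual heterogeneity of expression
#'   change in brain disorders, which is what makes fold-change gene lists
#'   poor clustering features while fully penetrant methylation changes
#'   remain stable ones.
#' @param coupling_frac Fraction of DE genes drawn from genes whose
#'   promoters/introns host truth DMRs (default 0.5).
#' @param coupling_sign +1 couples hypermethylation to up-regulation
#'   (default), -1 inverts.
#' @param n_terms,term_size_range Synthetic functional-term map; one term is
#'   deliberately enriched in DMR-host genes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1,
    n_chrom = 5, chrom_length = 1e7,
    n_genes = 300, gene_length_range = c(5000, 30000),
    exon_count_range = c(3, 8), exon_length_range = c(150, 400),
    n_cgi = 400, cgi_length_range = c(500, 2000), cgi_tss_frac = 0.5,
    n_sc = 5, n_bp = 7, n_normal = 6,
    regions = c("BA9", "BA24"),
    n_background_peaks = 800, peak_width_range = c(400, 800),
    peak_mean_meanlog = log(20), peak_mean_sdlog = 0.3,
    nb_size_meth = 50, n_noise_fragments = 20000, fragment_length = 250,
    n_truth_dmr = 200, effect_size = 3,
    hypo_frac_region1 = 0.8, hyper_frac_region2 = 0.8,
    end_bias = 0.8, terminal_frac = 0.1, shore_frac = 0.3,
    gene_frac = 0.4,
    gene_mean_meanlog = log(200), gene_mean_sdlog = 1, nb_size_expr = 3,
    expr_factor_sd = 0.6,
    n_de = 100, de_fc = 2, de_penetrance = 0.6,
    coupling_frac = 0.5, coupling_sign = 1,
    n_terms = 20, term_size_range = c(10, 40)) {
  cfg <- as.list(environment())
  stopifnot(cfg$effect_size >= 1, cfg$de_fc >= 1,
            cfg$coupling_frac >= 0, cfg$coupling_frac <= 1,
            cfg$de_penetrance >= 0, cfg$de_penetrance <= 1,
            cfg$end_bias >= 0, cfg$end_bias <= 1,
            cfg$shore_frac >= 0, cfg$shore_frac <= 1,
            cfg$n_truth_dmr >= 0, cfg$n_de >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-stage seed derived from the single user seed
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + stage * 7919L) %% .Machine$integer.max
}

runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

#' Simulate the genome: layout, gene models, CpG islands
#'
#' Genes are placed without overlap by slotting them along each chromosome;
#' every gene is multi-exon with CDS bounds inside the first and last exon
#' (so 5'/3' UTRs are derivable). A configurable fraction of CGIs is placed
#' at a TSS, the rest uniformly.
#'
#' @param cfg A [sim_config()].
#' @return List: `layout` ([genome_layout()]), `genes` (gene-model tibble as
#'   from [read_gene_models()]), `cgis` (interval tibble).
#' @export
simulate_genome <- function(cfg) {
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    layout <- genome_layout(paste0("chr", seq_len(cfg$n_chrom)),
                            rep(cfg$chrom_length, cfg$n_chrom))
    genes <- place_genes(cfg, layout)
    cgis <- place_cgis(cfg, layout, genes)
    list(layout = layout, genes = genes, cgis = cgis)
  })
}

place_genes <- function(cfg, layout) {
  n <- cfg$n_genes
  per_chrom <- diff(c(0, round(cumsum(layout$length) / sum(layout$length) * n)))
  rows <- list()
  gid <- 0
  for (ci in seq_along(layout$chrom)) {
    k <- per_chrom[ci]
    if (k == 0) next
    L <- layout$length[ci]
    slot_w <- floor(L / k)
    if (slot_w <= max(cfg$gene_length_range) + 10) {
      stop("too many genes for genome: gene slots narrower than genes")
    }
    glen <- runif_int(k, cfg$gene_length_range[1], cfg$gene_length_range[2])
    offset <- floor(stats::runif(k) * (slot_w - glen - 1))
    gstart <- (seq_len(k) - 1) * slot_w + offset
    strand <- sample(c("+", "-"), k, replace = TRUE)
    for (i in seq_len(k)) {
      gid <- gid + 1
      st <- gene_structure(cfg, gstart[i], glen[i])
      rows[[gid]] <- tibble::tibble(
        gene_id = sprintf("gene_%04d", gid),
        chrom = layout$chrom[ci], start = gstart[i],
        end = gstart[i] + glen[i], strand = strand[i],
        cds_start = st$cds_start, cds_end = st$cds_end,
        exons = list(st$exons)
      )
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id)
}

gene_structure <- function(cfg, gstart, glen) {
  n_ex <- runif_int(1, cfg$exon_count_range[1], cfg$exon_count_range[2])
  esize <- runif_int(n_ex, cfg$exon_length_range[1], cfg$exon_length_range[2])
  intron_total <- glen - sum(esize)
  n_in <- n_ex - 1
  # proportional random split of intronic bp, each intron >= 60 bp
  w <- stats::runif(n_in)
  isize <- 60 + floor((intron_total - 60 * n_in) * w / sum(w))
  # absorb rounding slack into the last intron so exons tile the span
  isize[n_in] <- intron_total - sum(isize[-n_in])
  starts <- gstart + cumsum(c(0, esize[-n_ex] + isize))
  exons <- tibble::tibble(start = starts, end = starts + esize)
  list(
    exons = exons,
    cds_start = exons$start[1] + floor(esize[1] / 2),
    cds_end = exons$end[n_ex] - floor(esize[n_ex] / 2)
  )
}

place_cgis <- function(cfg, layout, genes) {
  n <- cfg$n_cgi
  width <- runif_int(n, cfg$cgi_length_range[1], cfg$cgi_length_range[2])
  at_tss <- stats::runif(n) < cfg$cgi_tss_frac
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  gidx <- sample(nrow(genes), n, replace = TRUE)
  chrom <- character(n); start <- numeric(n)
  Lmap <- stats::setNames(layout$length, layout$chrom)
  for (i in seq_len(n)) {
    if (at_tss[i]) {
      chrom[i] <- genes$chrom[gidx[i]]
      start[i] <- tss[gidx[i]] - floor(width[i] / 2)
    } else {
      ci <- sample(nrow(layout), 1, prob = layout$length)
      chrom[i] <- layout$chrom[ci]
      start[i] <- floor(stats::runif(1) * (layout$length[ci] - width[i]))
    }
    start[i] <- max(0, min(start[i], Lmap[[chrom[i]]] - width[i]))
  }
  sort_intervals(tibble::tibble(chrom = chrom, start = start,
                                end = start + width))
}

#' Simulate per-sample MeDIP-seq fragment sets with injected truth DMRs
#'
#' All samples share a common set of background peak loci with log-normal
#' base means; per-sample fragment counts per locus are negative binomial
#' (overdispersed replicates). Truth DMR loci multiply (hyper) or divide
#' (hypo) the case-group mean by the effect size, only in the matching
#' region. Region 1 truth is predominantly hypomethylated with
#' chromosome-terminal placement bias; region 2 truth is predominantly
#' hypermethylated and placed uniformly; a configured fraction of truth DMRs
#' in both regions overlaps CGI shores. Uniform genomic noise fragments are
#' added on top.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return List: `samples` (sample sheet: sample_id, group, region, sex,
#'   age), `fragments` (named list of per-sample fragment tibbles), `truth`
#'   (tibble of injected DMRs: truth_id, chrom, start, end, region,
#'   direction, effect_size).
#' @export
simulate_methylomes <- function(cfg, genome) {
  layout <- genome$layout
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    samples <- sample_sheet(cfg)
    bg <- place_loci_uniform(cfg$n_background_peaks, cfg$peak_width_range,
                             layout, occupied = NULL)
    cc <- derive_cgi_context(genome$cgis, layout)
    truth <- place_truth_dmrs(cfg, layout, cc, genome$genes, occupied = bg)
    # background peaks are shared by every sample; truth loci are
    # region-specific methylation peaks, present only in samples of the
    # matching brain region (methylomes differ between regions, so a locus
    # injected in one region is not part of the other region's peak
    # landscape)
    loci <- dplyr::bind_rows(
      dplyr::mutate(bg, truth_id = NA_character_, region = NA_character_),
      truth[, c("chrom", "start", "end", "truth_id", "region")]
    )
    mu <- stats::rlnorm(nrow(loci), cfg$peak_mean_meanlog,
                        cfg$peak_mean_sdlog)
    tmatch <- match(loci$truth_id, truth$truth_id)
    frags <- vector("list", nrow(samples))
    names(frags) <- samples$sample_id
    # libraries are sequenced to a common depth: the unstructured noise
    # pool absorbs the fragment mass gained/lost at truth loci, so total N
    # is identical across samples and null-peak RPKM carries no
    # library-composition artifact
    target_total <- stats::setNames(vapply(cfg$regions, function(reg) {
      round(sum(mu[is.na(loci$region) | loci$region == reg]))
    }, numeric(1)) + cfg$n_noise_fragments, cfg$regions)
    for (si in seq_len(nrow(samples))) {
      active <- is.na(loci$region) | loci$region == samples$region[si]
      mult <- as.numeric(active)
      if (samples$group[si] != "NORMAL") {
        hit <- active & !is.na(tmatch)
        dir_hyper <- hit & truth$direction[tmatch] == "hyper"
        dir_hypo <- hit & truth$direction[tmatch] == "hypo"
        mult[dir_hyper] <- truth$effect_size[tmatch][dir_hyper]
        mult[dir_hypo] <- 1 / truth$effect_size[tmatch][dir_hypo]
      }
      cnt <- stats::rnbinom(nrow(loci), mu = mu * mult,
                            size = cfg$nb_size_meth)
      n_noise <- max(0, target_total[[samples$region[si]]] - sum(cnt))
      frags[[si]] <- fragment_draw(cfg, layout, loci, cnt, n_noise)
    }
    list(samples = samples, fragments = frags, truth = truth)
  })
}

sample_sheet <- function(cfg) {
  subj <- tibble::tibble(
    group = rep(c("SC", "BP", "NORMAL"), c(cfg$n_sc, cfg$n_bp, cfg$n_normal))
  )
  subj$subject <- stats::ave(seq_len(nrow(subj)), subj$group,
                             FUN = seq_along)
  subj$sex <- sample(c("m", "f"), nrow(subj), replace = TRUE)
  subj$age <- round(stats::rnorm(nrow(subj), 45, 10))
  out <- tidyr::crossing(region = cfg$regions, subj) |>
    dplyr::mutate(sample_id = paste(.data$region, .data$group,
                                    .data$subject, sep = "_")) |>
    dplyr::select("sample_id", "group", "region", "sex", "age") |>
    dplyr::arrange(.data$region, .data$group, .data$sample_id)
  out
}

place_loci_uniform <- function(n, width_range, layout, occupied = NULL) {
  width <- runif_int(n, width_range[1], width_range[2])
  ci <- sample(nrow(layout), n, replace = TRUE, prob = layout$length)
  start <- floor(stats::runif(n) * (layout$length[ci] - width))
  out <- tibble::tibble(chrom = layout$chrom[ci], start = start,
                        end = start + width)
  sort_intervals(out)
}

place_truth_dmrs <- function(cfg, layout, cgi_context, genes, occupied) {
  n <- cfg$n_truth_dmr
  if (n == 0) {
    return(tibble::tibble(truth_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          region = character(), direction = character(),
                          effect_size = numeric()))
  }
  shores <- cgi_context$shore
  res <- list()
  # per-chromosome occupancy registry for fast rejection sampling
  occ <- new.env(parent = emptyenv())
  if (!is.null(occupied)) {
    for (ch in unique(occupied$chrom)) {
      sel <- occupied$chrom == ch
      assign(ch, cbind(occupied$start[sel], occupied$end[sel]), envir = occ)
    }
  }
  # placements keep a clear margin so separately injected loci can never be
  # merged into a single called peak by the sliding-window scan
  margin <- 1500
  occ_free <- function(ch, s, e) {
    m <- if (exists(ch, envir = occ)) get(ch, envir = occ) else NULL
    is.null(m) || !any(m[, 1] < e + margin & m[, 2] > s - margin)
  }
  occ_add <- function(ch, s, e) {
    m <- if (exists(ch, envir = occ)) get(ch, envir = occ) else
      matrix(numeric(0), ncol = 2)
    assign(ch, rbind(m, c(s, e)), envir = occ)
  }
  for (ri in 1:2) {
    region <- cfg$regions[ri]
    n_minor <- round(n * (1 - if (ri == 1) cfg$hypo_frac_region1 else
      cfg$hyper_frac_region2))
    major <- if (ri == 1) "hypo" else "hyper"
    minor <- if (ri == 1) "hyper" else "hypo"
    direction <- rep(c(major, minor), c(n - n_minor, n_minor))
    width <- runif_int(n, cfg$peak_width_range[1], cfg$peak_width_range[2])
    chrom <- character(n); start <- numeric(n)
    for (i in seq_len(n)) {
      for (try in 1:200) {
        pos <- draw_truth_position(cfg, layout, shores, genes, width[i],
                                   end_biased = (ri == 1 &&
                                                   direction[i] == "hypo"))
        if (occ_free(pos$chrom, pos$start, pos$start + width[i])) break
      }
      chrom[i] <- pos$chrom; start[i] <- pos$start
      occ_add(pos$chrom, pos$start, pos$start + width[i])
    }
    res[[ri]] <- tibble::tibble(
      chrom = chrom, start = start, end = start + width,
      region = region, direction = direction,
      effect_size = cfg$effect_size
    )
  }
  out <- dplyr::bind_rows(res)
  out$truth_id <- sprintf("truth_%04d", seq_len(nrow(out)))
  out[, c("truth_id", "chrom", "start", "end", "region", "direction",
          "effect_size")]
}

# placement order: the terminal-decile decision comes first for end-biased
# draws (the chromosome-end preference is the region's defining feature);
# the shore / gene-body targeting weights are then applied inside whatever
# zone was chosen, so both marginals are realised together
draw_truth_position <- function(cfg, layout, shores, genes, width,
                                end_biased) {
  if (end_biased && stats::runif(1) < cfg$end_bias) {
    ci <- sample(nrow(layout), 1, prob = layout$length)
    L <- layout$length[ci]
    zone_w <- floor(L * cfg$terminal_frac)
    left <- stats::runif(1) < 0.5
    zone <- if (left) c(0, zone_w) else c(L - zone_w, L)
    pos <- draw_targeted(cfg, layout$chrom[ci], zone, shores, genes, width)
    return(pos)
  }
  ci <- sample(nrow(layout), 1, prob = layout$length)
  draw_targeted(cfg, layout$chrom[ci], c(0, layout$length[ci]), shores,
                genes, width)
}

# draw a start within [zone) on chrom, targeting a CGI shore or a gene body
# inside the zone with the configured probabilities when one exists
draw_targeted <- function(cfg, chrom, zone, shores, genes, width) {
  u <- stats::runif(1)
  clip <- function(start) {
    list(chrom = chrom,
         start = max(zone[1], min(start, zone[2] - width)))
  }
  if (u < cfg$shore_frac) {
    sh <- shores[shores$chrom == chrom & shores$start < zone[2] &
                   shores$end > zone[1], ]
    if (nrow(sh) > 0) {
      i <- sample(nrow(sh), 1)
      anchor <- sh$start[i] +
        floor(stats::runif(1) * (sh$end[i] - sh$start[i]))
      return(clip(anchor - floor(width / 2)))
    }
  } else if (u < cfg$shore_frac + cfg$gene_frac) {
    gn <- genes[genes$chrom == chrom & genes$start < zone[2] &
                  genes$end > zone[1], ]
    if (nrow(gn) > 0) {
      i <- sample(nrow(gn), 1)
      lo <- max(zone[1], gn$start[i])
      hi <- min(zone[2], gn$end[i]) - width
      if (hi > lo) {
        return(clip(lo + floor(stats::runif(1) * (hi - lo))))
      }
    }
  }
  clip(zone[1] + floor(stats::runif(1) * (zone[2] - zone[1] - width)))
}

fragment_draw <- function(cfg, layout, loci, cnt, n_noise) {
  flen <- cfg$fragment_length
  idx <- rep.int(seq_len(nrow(loci)), cnt)
  center <- loci$start[idx] +
    floor(stats::runif(length(idx)) * (loci$end[idx] - loci$start[idx]))
  chrom <- loci$chrom[idx]
  # uniform genomic noise fragments
  nn <- n_noise
  nci <- sample(nrow(layout), nn, replace = TRUE, prob = layout$length)
  ncenter <- floor(stats::runif(nn) * layout$length[nci])
  chrom <- c(chrom, layout$chrom[nci])
  center <- c(center, ncenter)
  L <- layout$length[match(chrom, layout$chrom)]
  start <- pmax(0, center - floor(flen / 2))
  end <- pmin(L, start + flen)
  start <- pmax(0, pmin(start, end - 1))
  sort_intervals(tibble::tibble(chrom = chrom, start = start, end = end))
}

#' Simulate RNA-seq gene counts with injected, partially DMR-coupled DE
#'
#' Baseline counts are negative binomial around log-normal gene means.
#' Per region, `n_de` genes are differentially expressed in case samples at
#' the configured fold change; a configured fraction of them is drawn from
#' genes whose promoters or introns host truth DMRs of that region, with
#' expression direction coupled to methylation direction by
#' `coupling_sign`.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param methylomes Output of [simulate_methylomes()] (for the truth DMRs
#'   and sample sheet).
#' @return List: `counts` (tibble gene_id + one column per sample),
#'   `gene_lengths` (tibble gene_id, length; exonic length), `truth_de`
#'   (tibble gene_id, region, direction, coupled, truth_id).
#' @export
simulate_transcriptomes <- function(cfg, genome, methylomes) {
  genes <- genome$genes
  samples <- methylomes$samples
  truth <- methylomes$truth
  withr::with_seed(derive_seed(cfg$seed, 3L), {
    exlen <- vapply(genes$exons, function(e) sum(e$end - e$start), numeric(1))
    gene_lengths <- tibble::tibble(gene_id = genes$gene_id, length = exlen)
    base_mu <- stats::rlnorm(nrow(genes), cfg$gene_mean_meanlog,
                             cfg$gene_mean_sdlog)
    elements <- derive_elements(genes, genome$layout)
    host <- map_dmrs_to_genes(
      dplyr::rename(truth, dmr_id = "truth_id"), elements
    )
    host <- host[host$element %in% c("promoter", "intron"), ]
    used <- character() # DE truth sets are disjoint across regions
    truth_de <- purrr::map_dfr(cfg$regions, function(reg) {
      reg_truth <- truth[truth$region == reg, ]
      reg_host <- host[host$dmr_id %in% reg_truth$truth_id, ]
      cand <- setdiff(unique(reg_host$gene_id), used)
      n_coupled <- min(round(cfg$coupling_frac * cfg$n_de), length(cand))
      coupled <- if (n_coupled > 0) sample(cand, n_coupled) else character()
      pool <- setdiff(genes$gene_id, c(coupled, used))
      uncoupled <- sample(pool, cfg$n_de - n_coupled)
      used <<- c(used, coupled, uncoupled)
      cdir <- vapply(coupled, function(g) {
        tid <- reg_host$dmr_id[reg_host$gene_id == g][1]
        mdir <- reg_truth$direction[reg_truth$truth_id == tid]
        if ((mdir == "hyper") == (cfg$coupling_sign > 0)) "up" else "down"
      }, character(1))
      ctid <- vapply(coupled, function(g) {
        reg_host$dmr_id[reg_host$gene_id == g][1]
      }, character(1))
      dplyr::bind_rows(
        tibble::tibble(gene_id = coupled, region = reg, direction = cdir,
                       coupled = TRUE, truth_id = ctid),
        tibble::tibble(gene_id = uncoupled, region = reg,
                       direction = sample(c("up", "down"),
                                          length(uncoupled), replace = TRUE),
                       coupled = FALSE, truth_id = NA_character_)
      )
    })
    loading <- stats::rnorm(nrow(genes), 0, cfg$expr_factor_sd)
    factor_s <- stats::rnorm(nrow(samples))
    cols <- purrr::map(seq_len(nrow(samples)), function(si) {
      mult <- exp(loading * factor_s[si])
      if (samples$group[si] != "NORMAL") {
        td <- truth_de[truth_de$region == samples$region[si], ]
        gi <- match(td$gene_id, genes$gene_id)
        expressed <- stats::runif(nrow(td)) < cfg$de_penetrance
        fc <- ifelse(td$direction == "up", cfg$de_fc, 1 / cfg$de_fc)
        mult[gi] <- mult[gi] * ifelse(expressed, fc, 1)
      }
      stats::rnbinom(nrow(genes), mu = base_mu * mult,
                     size = cfg$nb_size_expr)
    })
    names(cols) <- samples$sample_id
    counts <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                               tibble::as_tibble(cols))
    list(counts = counts, gene_lengths = gene_lengths, truth_de = truth_de)
  })
}

#' Simulate a complete input bundle in memory
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_bundle`: layout, genes, cgis, samples,
#'   fragments, truth (DMRs), counts, gene_lengths, truth_de, gene2term,
#'   cfg.
#' @export
simulate_bundle <- function(cfg) {
  genome <- simulate_genome(cfg)
  meth <- simulate_methylomes(cfg, genome)
  expr <- simulate_transcriptomes(cfg, genome, meth)
  g2t <- withr::with_seed(derive_seed(cfg$seed, 4L), {
    simulate_gene2term(cfg, genome, meth)
  })
  structure(c(genome, meth, expr, list(gene2term = g2t, cfg = cfg)),
            class = "sim_bundle")
}

simulate_gene2term <- function(cfg, genome, meth) {
  genes <- genome$genes$gene_id
  elements <- derive_elements(genome$genes, genome$layout)
  host <- unique(map_dmrs_to_genes(
    dplyr::rename(meth$truth, dmr_id = "truth_id"), elements
  )$gene_id)
  terms <- purrr::map_dfr(seq_len(cfg$n_terms), function(ti) {
    size <- runif_int(1, cfg$term_size_range[1], cfg$term_size_range[2])
    tibble::tibble(gene_id = sample(genes, min(size, length(genes))),
                   term_id = sprintf("term_%02d", ti))
  })
  # one term deliberately enriched in DMR-host genes
  n_enr <- min(30, length(genes))
  n_host <- min(round(0.7 * n_enr), length(host))
  enr <- c(sample(host, n_host),
           sample(setdiff(genes, host), n_enr - n_host))
  dplyr::bind_rows(
    terms,
    tibble::tibble(gene_id = enr, term_id = "term_dmr_enriched")
  )[, c("gene_id", "term_id")]
}

#' Write a simulated bundle to disk
#'
#' Emits every pipeline input in standard plain-text formats: genome layout
#' TSV, gene models as BED12, CGIs as BED3, sample sheet TSV, per-sample
#' fragment BED3 files, gene counts TSV, gene-to-term TSV, truth tables, and
#' a JSON manifest echoing the configuration with per-file MD5 checksums.
#' Re-running with the same seed reproduces identical checksums.
#'
#' @param cfg A [sim_config()], or a pre-built `sim_bundle`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_bundle <- function(cfg, outdir) {
  bundle <- if (inherits(cfg, "sim_bundle")) cfg else simulate_bundle(cfg)
  cfg <- bundle$cfg
  dir.create(file.path(outdir, "fragments"), recursive = TRUE,
             showWarnings = FALSE)
  w <- function(x, path) {
    readr::write_tsv(x, file.path(outdir, path), progress = FALSE)
  }
  w(tibble::tibble(chrom = bundle$layout$chrom,
                   length = bundle$layout$length), "genome.tsv")
  write_bed12(bundle$genes, file.path(outdir, "genes.bed"))
  w_bed3(bundle$cgis, file.path(outdir, "cgi.bed"))
  w(bundle$samples, "samples.tsv")
  w(bundle$counts, "counts.tsv")
  w(bundle$gene_lengths, "gene_lengths.tsv")
  w(bundle$gene2term, "gene2term.tsv")
  w(bundle$truth, "truth_dmrs.tsv")
  w(bundle$truth_de, "truth_de.tsv")
  for (sid in names(bundle$fragments)) {
    w_bed3(bundle$fragments[[sid]],
           file.path(outdir, "fragments", paste0(sid, ".bed")))
  }
  all_files <- sort(list.files(outdir, recursive = TRUE))
  all_files <- setdiff(all_files, "manifest.json")
  sums <- tools::md5sum(file.path(outdir, all_files))
  manifest <- list(
    config = cfg[setdiff(names(cfg), "regions")] |>
      c(list(regions = as.list(cfg$regions))),
    files = as.list(stats::setNames(unname(sums), all_files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

w_bed3 <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  basename(path)
}

write_bed12 <- function(genes, path) {
  rows <- purrr::pmap_chr(
    list(genes$gene_id, genes$chrom, genes$start, genes$end, genes$strand,
         genes$cds_start, genes$cds_end, genes$exons),
    function(gid, chrom, s, e, strand, cs, ce, ex) {
      bs <- ex$end - ex$start
      bst <- ex$start - s
      paste(
        chrom, format(s, scientific = FALSE), format(e, scientific = FALSE),
        gid, 0, strand,
        format(if (is.na(cs)) s else cs, scientific = FALSE),
        format(if (is.na(ce)) s else ce, scientific = FALSE),
        "0", length(bs),
        paste0(paste(bs, collapse = ","), ","),
        paste0(paste(format(bst, scientific = FALSE, trim = TRUE),
                     collapse = ","), ","),
        sep = "\t"
      )
    }
  )
  writeLines(rows, path)
  basename(path)
}

#' Read a bundle directory back into memory
#'
#' @param dir Directory written by [write_bundle()].
#' @return A list with layout, genes, cgis, samples, fragments, counts,
#'   gene_lengths, gene2term, truth, truth_de (truth tables only when
#'   present).
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  need <- c("genome.tsv", "genes.bed", "cgi.bed", "samples.tsv",
            "counts.tsv", "gene_lengths.tsv", "gene2term.tsv")
  missing <- need[!file.exists(p(need))]
  if (length(missing) > 0) {
    stop("bundle is missing required file(s): ",
         paste(missing, collapse = ", "))
  }
  layout <- read_genome_layout(p("genome.tsv"))
  genes <- read_gene_models(p("genes.bed"), layout)
  cgis <- readr::read_tsv(p("cgi.bed"),
                          col_names = c("chrom", "start", "end"),
                          col_types = "cdd", progress = FALSE)
  samples <- readr::read_tsv(p("samples.tsv"), show_col_types = FALSE,
                             progress = FALSE)
  frag_files <- list.files(p("fragments"), pattern = "\\.bed$",
                           full.names = TRUE)
  fragments <- stats::setNames(
    lapply(frag_files, read_fragments, layout = layout),
    sub("\\.bed$", "", basename(frag_files))
  )
  counts <- readr::read_tsv(p("counts.tsv"), show_col_types = FALSE,
                            progress = FALSE)
  gene_lengths <- readr::read_tsv(p("gene_lengths.tsv"),
                                  show_col_types = FALSE, progress = FALSE)
  gene2term <- readr::read_tsv(p("gene2term.tsv"), show_col_types = FALSE,
                               progress = FALSE)
  out <- list(layout = layout, genes = genes, cgis = cgis,
              samples = samples, fragments = fragments, counts = counts,
              gene_lengths = gene_lengths, gene2term = gene2term)
  if (file.exists(p("truth_dmrs.tsv"))) {
    out$truth <- readr::read_tsv(p("truth_dmrs.tsv"),
                                 show_col_types = FALSE, progress = FALSE)
  }
  if (file.exists(p("truth_de.tsv"))) {
    out$truth_de <- readr::read_tsv(p("truth_de.tsv"),
                                    show_col_types = FALSE, progress = FALSE)
  }
  out
}
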