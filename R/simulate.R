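# Coupled tri-omics simulator with planted ground truth. One master seed
# drives genome, methylome, sRNA and expression through independent derived
# streams. Planted features live in disjoint gene "slots" so the truth is
# unambiguous: an RdDM locus couples a promoter TE, a CHH hypo-DMR window, a
# downregulated 24-nt cluster and an upregulated gene at one genomic window.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a cold-treatment microspore
#' time course: 0/5/10 dpt, two WGBS replicates and three sRNA/RNA
#' replicates per timepoint, genome-wide 0-dpt methylation means of
#' CG 57.55%, CHG 30.23% and CHH 4.6%, an elevated TE compartment,
#' beta-binomial site noise at Poisson(30) depth, negative-binomial counts
#' (dispersion 0.1), an 18-30 nt sRNA length mixture whose 24-nt fraction
#' rises with treatment, and planted effects of +/-40 percentage points
#' (DMRs) and |log2FC| = 2 (DSRs/DEGs), applied at half amplitude at 5 dpt
#' and full amplitude at 10 dpt.
#'
#' `base_levels` are genome-wide pooled targets: the background (non-TE)
#' mean is solved from the TE and planted-window site fractions so that the
#' expected pooled 0-dpt level per context equals the target. Planted DMR
#' windows get their own baselines (`hyper_base` low, `hypo_base` high) so
#' that a +/-40 pp shift is expressible and detectable under the DMR filter
#' cascade.
#'
#' @param seed Master RNG seed.
#' @param n_chrom,chrom_len Number and length (bp) of chromosomes.
#' @param n_genes,n_tes Number of gene models and TE intervals.
#' @param depth_lambda Mean WGBS site coverage (Poisson).
#' @param base_levels Genome-wide 0-dpt percent methylation per context.
#' @param te_levels TE-compartment percent methylation per context.
#' @param hyper_base,hypo_base Baseline percent methylation inside planted
#'   hyper/hypo DMR windows, per context.
#' @param overdispersion_rho Beta-binomial intra-class correlation (0 gives
#'   pure binomial noise).
#' @param nb_dispersion Negative-binomial dispersion for sRNA and gene
#'   counts.
#' @param n_planted_dmr,n_planted_dsr,n_planted_deg,n_planted_rddm Planted
#'   feature counts (the RdDM loci add their own DMR/DSR/DEG on top).
#' @param dmr_shift_pp,srna_log2fc,gene_log2fc Planted effect sizes.
#' @param timepoints Days post treatment (first entry is the control).
#' @param n_rep_meth,n_rep_srna,n_rep_rna Replicates per timepoint.
#' @param tile_width DMR tile / sRNA cluster width (bp).
#' @param n_clusters Background (unplanted) sRNA clusters.
#' @param cluster_mean,gene_mean Median NB mean counts.
#' @param w24,w2022 24-nt and pooled 20-22 nt mixture weights per timepoint.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 2, chrom_len = 500000,
                       n_genes = 500, n_tes = 300,
                       depth_lambda = 30,
                       base_levels = c(CG = 57.55, CHG = 30.23, CHH = 4.6),
                       te_levels = c(CG = 85, CHG = 60, CHH = 15),
                       hyper_base = c(CG = 18, CHG = 12, CHH = 4.6),
                       hypo_base = c(CG = 75, CHG = 60, CHH = 45),
                       overdispersion_rho = 0.05,
                       nb_dispersion = 0.1,
                       n_planted_dmr = 30, n_planted_dsr = 150,
                       n_planted_deg = 250, n_planted_rddm = 10,
                       dmr_shift_pp = 40, srna_log2fc = 2, gene_log2fc = 2,
                       timepoints = c(0, 5, 10),
                       n_rep_meth = 2, n_rep_srna = 3, n_rep_rna = 3,
                       tile_width = 1000, n_clusters = 140,
                       cluster_mean = 500, gene_mean = 300,
                       w24 = c(0.35, 0.45, 0.55),
                       w2022 = c(0.40, 0.30, 0.22)) {
  cfg <- list(seed = seed, n_chrom = n_chrom, chrom_len = chrom_len,
              n_genes = n_genes, n_tes = n_tes,
              depth_lambda = depth_lambda, base_levels = base_levels,
              te_levels = te_levels, hyper_base = hyper_base,
              hypo_base = hypo_base,
              overdispersion_rho = overdispersion_rho,
              nb_dispersion = nb_dispersion,
              n_planted_dmr = n_planted_dmr, n_planted_dsr = n_planted_dsr,
              n_planted_deg = n_planted_deg,
              n_planted_rddm = n_planted_rddm,
              dmr_shift_pp = dmr_shift_pp, srna_log2fc = srna_log2fc,
              gene_log2fc = gene_log2fc, timepoints = timepoints,
              n_rep_meth = n_rep_meth, n_rep_srna = n_rep_srna,
              n_rep_rna = n_rep_rna, tile_width = tile_width,
              n_clusters = n_clusters, cluster_mean = cluster_mean,
              gene_mean = gene_mean, w24 = w24, w2022 = w2022)
  if (any(c(base_levels, te_levels, hyper_base, hypo_base) < 0) ||
      any(c(base_levels, te_levels, hyper_base, hypo_base) > 100)) {
    abort("methylation levels must lie in [0, 100]")
  }
  class(cfg) <- "sim_config"
  cfg
}

treatment_frac <- function(tp, timepoints) {
  m <- max(timepoints)
  if (m == 0) rep(0, length(tp)) else tp / m
}

# slot geometry: genes live on a regular grid of slots whose width is a
# multiple of the tile width, so planted windows (first tile of a slot) are
# tile-aligned
slot_layout <- function(cfg) {
  gpc <- ceiling(cfg$n_genes / cfg$n_chrom)
  slot_w <- (cfg$chrom_len %/% gpc) %/% cfg$tile_width * cfg$tile_width
  if (slot_w < 2L * cfg$tile_width) {
    abort("requested features do not fit: need at least two tiles per gene slot")
  }
  slots <- tidyr::expand_grid(chrom_i = seq_len(cfg$n_chrom),
                              idx = seq_len(gpc)) %>%
    head(cfg$n_genes) %>%
    mutate(chrom = paste0("Chr", .data$chrom_i),
           slot_start = (.data$idx - 1L) * slot_w + 1L,
           slot = dplyr::row_number())
  list(slots = slots, slot_w = slot_w)
}

# pick planted slots: RdDM slots first (with a one-slot buffer on each side
# excluded from every other planted set), then DMR, DSR and DEG slots, all
# pairwise disjoint
plant_slots <- function(cfg, layout) {
  n_slot <- nrow(layout$slots)
  per_chrom <- split(layout$slots$slot, layout$slots$chrom)
  interior <- unlist(purrr::map(per_chrom, function(s) {
    if (length(s) <= 4L) s else s[c(-1L, -length(s))]
  }), use.names = FALSE)
  pick_spaced <- function(pool, n, min_gap) {
    pool <- sample(pool)
    chosen <- integer(0)
    for (s in pool) {
      if (length(chosen) == n) break
      if (all(abs(chosen - s) >= min_gap)) chosen <- c(chosen, s)
    }
    if (length(chosen) < n) {
      abort("requested planted features do not fit without overlap")
    }
    sort(chosen)
  }
  rddm <- pick_spaced(interior, cfg$n_planted_rddm, 3L)
  buffer <- unique(sort(c(rddm - 1L, rddm, rddm + 1L)))
  free <- setdiff(seq_len(n_slot), buffer)
  take <- function(free, n) {
    if (length(free) < n) {
      abort("requested planted features do not fit without overlap")
    }
    chosen <- sort(sample(free, n))
    list(chosen = chosen, free = setdiff(free, chosen))
  }
  dmr <- take(free, cfg$n_planted_dmr)
  # DSR clusters and DEG genes may share slots with each other (a locus can
  # be both), but never with planted DMR windows or RdDM loci/buffers, so a
  # decoy can only arise from a double false positive
  dsr <- take(dmr$free, cfg$n_planted_dsr)
  deg <- take(dmr$free, cfg$n_planted_deg)
  list(rddm = rddm, dmr = dmr$chosen, dsr = dsr$chosen, deg = deg$chosen)
}

#' Simulate a toy genome with gene models and TE annotation
#'
#' Draws random A/C/G/T chromosomes, lays non-overlapping gene models
#' (two exons, an intron and 80-bp UTRs) on a regular slot grid with random
#' strand, and places TE intervals, including one inside the promoter of
#' every planted RdDM gene. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (DNAStringSet), `genes` (gene-model tibble),
#'   `te` (interval tibble), `truth` (planted-feature tables) and `layout`.
#' @export
simulate_genome <- function(cfg) {
  layout <- slot_layout(cfg)
  slots <- layout$slots; slot_w <- layout$slot_w
  genome <- withr::with_seed(derive_seed(cfg$seed, "genome"), {
    seqs <- vapply(seq_len(cfg$n_chrom), function(i) {
      paste(sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE),
            collapse = "")
    }, character(1))
    gn <- Biostrings::DNAStringSet(seqs)
    names(gn) <- paste0("Chr", seq_len(cfg$n_chrom))
    gn
  })
  built <- withr::with_seed(derive_seed(cfg$seed, "genes"), {
    planted <- plant_slots(cfg, layout)
    lmax <- min(700L, slot_w - 1300L)
    glen <- sample(500:lmax, nrow(slots), replace = TRUE)
    strand <- sample(c("+", "-"), nrow(slots), replace = TRUE)
    strand[slots$slot %in% planted$rddm] <- "+"
    list(planted = planted, glen = glen, strand = strand)
  })
  planted <- built$planted
  gs <- slots$slot_start + 1200L
  ge <- gs + built$glen - 1L
  genes <- tibble(
    gene_id = sprintf("g%04d", slots$slot),
    chrom = slots$chrom, strand = built$strand,
    start = as.integer(gs), end = as.integer(ge)
  ) %>%
    mutate(tss = if_else(.data$strand == "+", .data$start, .data$end),
           tes = if_else(.data$strand == "+", .data$end, .data$start))
  gene_struct <- purrr::pmap(list(genes$start, genes$end, genes$strand),
                             function(s, e, str) {
    L <- e - s + 1L
    e1 <- as.integer(round(0.35 * L)); intr <- as.integer(round(0.2 * L))
    exons <- tibble(start = c(s, s + e1 + intr), end = c(s + e1 - 1L, e))
    if (str == "+") {
      list(exons = exons,
           five = tibble(start = s, end = s + 79L),
           three = tibble(start = e - 79L, end = e))
    } else {
      list(exons = exons,
           five = tibble(start = e - 79L, end = e),
           three = tibble(start = s, end = s + 79L))
    }
  })
  genes <- genes %>%
    mutate(exons = purrr::map(gene_struct, "exons"),
           five_utr = purrr::map(gene_struct, "five"),
           three_utr = purrr::map(gene_struct, "three"))

  # planted windows: the first tile of the slot
  win_of <- function(slot_ids) {
    sub <- filter(slots, .data$slot %in% slot_ids)
    tibble(slot = sub$slot, chrom = sub$chrom,
           start = as.integer(sub$slot_start),
           end = as.integer(sub$slot_start + cfg$tile_width - 1L))
  }
  rddm_win <- win_of(planted$rddm)
  dmr_win <- win_of(planted$dmr)
  te <- withr::with_seed(derive_seed(cfg$seed, "te"), {
    n_extra <- max(0L, cfg$n_tes - nrow(rddm_win))
    pool <- setdiff(slots$slot, c(planted$rddm, planted$dmr))
    extra_slots <- sample(pool, min(n_extra, length(pool)), replace = FALSE)
    sub <- filter(slots, .data$slot %in% extra_slots)
    len <- sample(200:600, nrow(sub), replace = TRUE)
    off <- vapply(len, function(l) sample.int(slot_w - l - 1L, 1L),
                  integer(1))
    bind_rows(
      tibble(chrom = rddm_win$chrom, start = rddm_win$start + 100L,
             end = rddm_win$start + 700L),
      tibble(chrom = sub$chrom, start = as.integer(sub$slot_start + off),
             end = as.integer(sub$slot_start + off + len - 1L))
    ) %>% arrange(.data$chrom, .data$start)
  })

  truth <- withr::with_seed(derive_seed(cfg$seed, "misc"), {
    ctxs <- rep(c("CG", "CHG", "CHH"), length.out = cfg$n_planted_dmr)
    pols <- rep(c("hyper", "hypo"), length.out = cfg$n_planted_dmr)
    dmr_truth <- bind_rows(
      mutate(dmr_win, context = sample(ctxs), polarity = sample(pols),
             kind = "dmr"),
      mutate(rddm_win, context = "CHH", polarity = "hypo", kind = "rddm")
    )
    # planted up and down counts are balanced including the RdDM loci
    # (all-down sRNA, all-up genes) so CPM normalisation stays
    # composition-neutral
    balanced_dirs <- function(n_other, n_rddm, rddm_dir) {
      n_tot <- n_other + n_rddm
      n_same <- max(0L, floor(n_tot / 2) - n_rddm)
      n_opp <- n_other - n_same
      opp <- if (rddm_dir == "down") "up" else "down"
      sample(rep(c(rddm_dir, opp), c(n_same, n_opp)))
    }
    dsr_win <- win_of(planted$dsr)
    dsr_truth <- bind_rows(
      mutate(dsr_win,
             direction = balanced_dirs(cfg$n_planted_dsr,
                                       cfg$n_planted_rddm, "down"),
             kind = "dsr"),
      mutate(rddm_win, direction = "down", kind = "rddm")
    ) %>%
      mutate(cluster_id = cluster_id(.data$chrom, .data$start, .data$end),
             size_class = "24nt")
    deg_truth <- bind_rows(
      tibble(slot = planted$deg,
             direction = balanced_dirs(cfg$n_planted_deg,
                                       cfg$n_planted_rddm, "up"),
             kind = "deg"),
      tibble(slot = planted$rddm, direction = "up", kind = "rddm")
    ) %>%
      mutate(gene_id = sprintf("g%04d", .data$slot))
    rddm_truth <- tibble(
      gene_id = sprintf("g%04d", planted$rddm),
      chrom = rddm_win$chrom, dmr_start = rddm_win$start,
      dmr_end = rddm_win$end,
      cluster_id = cluster_id(rddm_win$chrom, rddm_win$start, rddm_win$end))
    list(dmr = dmr_truth, dsr = dsr_truth, deg = deg_truth,
         rddm = rddm_truth)
  })
  list(genome = genome, genes = genes, te = te, truth = truth,
       layout = layout)
}

#' Simulate a WGBS methylome over a genome
#'
#' Per cytosine and sample: coverage is Poisson(`depth_lambda`) and the
#' methylated count beta-binomial with intra-class correlation
#' `overdispersion_rho` around the site's mean: the TE-compartment level for
#' sites inside TEs, a calibrated background level elsewhere, and the
#' planted-window baseline inside planted DMR windows, shifted by
#' `dmr_shift_pp` (half amplitude at the middle timepoint, clamped to
#' [0, 100]) in treatment samples.
#'
#' @param cfg A [sim_config()].
#' @param ref Output of [simulate_genome()].
#' @return List `sites` (long tibble with `sample_id`) and `samples`
#'   (sample sheet).
#' @export
simulate_methylome <- function(cfg, ref) {
  cyt <- enumerate_cytosines(ref$genome) %>% filter(!is.na(.data$context))
  in_te <- seq_len(nrow(cyt)) %in%
    overlap_pairs(mutate(cyt, start = .data$pos, end = .data$pos),
                  ref$te)$a_idx
  base <- unname(cfg$base_levels[cyt$context] / 100)
  te_mu <- unname(cfg$te_levels[cyt$context] / 100)
  mu0 <- ifelse(in_te, te_mu, base)
  shift <- rep(0, nrow(cyt))
  dmr_truth <- ref$truth$dmr
  for (i in seq_len(nrow(dmr_truth))) {
    sel <- cyt$context == dmr_truth$context[i] &
      cyt$chrom == dmr_truth$chrom[i] &
      cyt$pos >= dmr_truth$start[i] & cyt$pos <= dmr_truth$end[i]
    b <- if (dmr_truth$polarity[i] == "hyper") {
      cfg$hyper_base[[dmr_truth$context[i]]]
    } else {
      cfg$hypo_base[[dmr_truth$context[i]]]
    }
    mu0[sel] <- b / 100
    shift[sel] <- if (dmr_truth$polarity[i] == "hyper") {
      cfg$dmr_shift_pp / 100
    } else {
      -cfg$dmr_shift_pp / 100
    }
  }
  # calibrate the background so the expected pooled 0-dpt level per context
  # equals the configured genome-wide target
  fixed <- in_te | shift != 0
  for (ctx in unique(cyt$context)) {
    sel <- cyt$context == ctx
    n_all <- sum(sel)
    s_fixed <- sum(mu0[sel & fixed])
    n_bg <- sum(sel & !fixed)
    if (n_bg > 0L) {
      x <- (cfg$base_levels[[ctx]] / 100 * n_all - s_fixed) / n_bg
      if (x < 0 || x > 1) {
        abort(paste0("cannot calibrate background level for ", ctx,
                     ": TE/planted compartments already exceed the target"))
      }
      mu0[sel & !fixed] <- x
    }
  }
  rho <- cfg$overdispersion_rho
  samples <- tidyr::expand_grid(timepoint_dpt = cfg$timepoints,
                                replicate = seq_len(cfg$n_rep_meth)) %>%
    mutate(sample_id = sprintf("meth_%gdpt_r%d", .data$timepoint_dpt,
                               .data$replicate),
           assay = "wgbs") %>%
    select("sample_id", "timepoint_dpt", "replicate", "assay")
  sites <- withr::with_seed(derive_seed(cfg$seed, "meth"), {
    purrr::pmap(samples, function(sample_id, timepoint_dpt, replicate,
                                  assay) {
      frac <- treatment_frac(timepoint_dpt, cfg$timepoints)
      mu <- pmin(1, pmax(0, mu0 + shift * frac))
      depth <- rpois(length(mu), cfg$depth_lambda)
      p <- if (rho > 0) {
        ok <- mu > 0 & mu < 1
        out <- mu
        out[ok] <- rbeta(sum(ok), mu[ok] * (1 - rho) / rho,
                         (1 - mu[ok]) * (1 - rho) / rho)
        out
      } else mu
      meth <- rbinom(length(mu), depth, p)
      tibble(sample_id = sample_id, chrom = cyt$chrom, pos = cyt$pos,
             strand = cyt$strand, context = cyt$context,
             meth = meth, total = depth)
    }) %>% bind_rows()
  })
  list(sites = sites, samples = samples)
}

srna_length_weights <- function(cfg, tp) {
  # weights interpolate linearly with treatment amplitude between their
  # first (control) and last (full-treatment) values
  frac <- treatment_frac(tp, cfg$timepoints)
  w24 <- cfg$w24[1] + frac * (cfg$w24[length(cfg$w24)] - cfg$w24[1])
  w2022 <- cfg$w2022[1] +
    frac * (cfg$w2022[length(cfg$w2022)] - cfg$w2022[1])
  other <- setdiff(18:30, c(20, 21, 22, 24))
  w <- setNames(rep((1 - w24 - w2022) / length(other), 13), 18:30)
  w[c("20", "21", "22")] <- w2022 / 3
  w["24"] <- w24
  w
}

#' Simulate an sRNA read table over the genome's cluster grid
#'
#' Background clusters get NB total counts split over an 18-30 nt length
#' mixture whose 24-nt weight rises with timepoint; planted DSR clusters
#' (including the RdDM loci, which are downregulated) have every length
#' class's mean multiplied by `2^(+/- srna_log2fc * amplitude)` in
#' treatment samples, so the 24-nt class carries the planted fold change.
#'
#' @param cfg A [sim_config()].
#' @param ref Output of [simulate_genome()].
#' @return List `reads` (long tibble), `samples` (sample sheet).
#' @export
simulate_srna <- function(cfg, ref) {
  slots <- ref$layout$slots
  planted <- ref$truth$dsr
  samples <- tidyr::expand_grid(timepoint_dpt = cfg$timepoints,
                                replicate = seq_len(cfg$n_rep_srna)) %>%
    mutate(sample_id = sprintf("srna_%gdpt_r%d", .data$timepoint_dpt,
                               .data$replicate),
           assay = "srna") %>%
    select("sample_id", "timepoint_dpt", "replicate", "assay")
  withr::with_seed(derive_seed(cfg$seed, "srna"), {
    taken <- cluster_id(planted$chrom, planted$start, planted$end)
    pool <- slots %>%
      mutate(cl = cluster_id(.data$chrom, .data$slot_start,
                             .data$slot_start + cfg$tile_width - 1L)) %>%
      filter(!.data$cl %in% taken)
    bg <- pool[sample.int(nrow(pool), min(cfg$n_clusters, nrow(pool))), ]
    clusters <- bind_rows(
      tibble(chrom = bg$chrom, start = as.integer(bg$slot_start),
             direction = "none"),
      tibble(chrom = planted$chrom, start = planted$start,
             direction = planted$direction)
    ) %>%
      mutate(end = .data$start + cfg$tile_width - 1L,
             base = stats::rlnorm(dplyr::n(), log(cfg$cluster_mean), 0.6),
             # downregulated clusters start from a higher baseline so the
             # expected library mass is unchanged at full amplitude (keeps
             # CPM composition-neutral)
             base = if_else(.data$direction == "down",
                            .data$base * 2^cfg$srna_log2fc, .data$base))
    w0 <- srna_length_weights(cfg, cfg$timepoints[1])
    reads <- purrr::pmap(samples, function(sample_id, timepoint_dpt,
                                           replicate, assay) {
      w <- srna_length_weights(cfg, timepoint_dpt)
      frac <- treatment_frac(timepoint_dpt, cfg$timepoints)
      # planted regulation acts on the whole cluster, every length class,
      # so the three size-class tests of a planted cluster agree; planted
      # clusters keep the control-timepoint length mixture so their 24-nt
      # log2 fold change is exactly the configured effect size
      eff <- dplyr::case_when(
        clusters$direction == "up" ~ 2^(cfg$srna_log2fc * frac),
        clusters$direction == "down" ~ 2^(-cfg$srna_log2fc * frac),
        TRUE ~ 1)
      purrr::map(18:30, function(len) {
        wl <- if_else(clusters$direction == "none",
                      w[[as.character(len)]], w0[[as.character(len)]])
        mu <- clusters$base * wl * eff
        tibble(chrom = clusters$chrom,
               pos5 = as.integer(clusters$start + 10L * (len - 18L)),
               strand = "+", length = len, sample_id = sample_id,
               count = rnbinom(length(mu), mu = mu,
                               size = 1 / cfg$nb_dispersion))
      }) %>% bind_rows()
    }) %>% bind_rows()
    list(reads = arrange(reads, .data$chrom, .data$pos5, .data$length,
                         .data$sample_id),
         samples = samples)
  })
}

#' Simulate a gene count matrix
#'
#' NB counts per gene and sample; planted DEGs (and RdDM genes, which are
#' upregulated) have their mean multiplied by `2^(+/- gene_log2fc *
#' amplitude)` in treatment samples.
#'
#' @param cfg A [sim_config()].
#' @param ref Output of [simulate_genome()].
#' @return List `counts` (long tibble `feature_id`, `sample_id`, `count`),
#'   `samples` (sample sheet).
#' @export
simulate_expression <- function(cfg, ref) {
  genes <- ref$genes
  deg <- ref$truth$deg
  dir <- setNames(rep("none", nrow(genes)), genes$gene_id)
  dir[deg$gene_id] <- deg$direction
  samples <- tidyr::expand_grid(timepoint_dpt = cfg$timepoints,
                                replicate = seq_len(cfg$n_rep_rna)) %>%
    mutate(sample_id = sprintf("rna_%gdpt_r%d", .data$timepoint_dpt,
                               .data$replicate),
           assay = "rna") %>%
    select("sample_id", "timepoint_dpt", "replicate", "assay")
  counts <- withr::with_seed(derive_seed(cfg$seed, "expr"), {
    base <- stats::rlnorm(nrow(genes), log(cfg$gene_mean), 0.6)
    # downregulated genes start highly expressed so library mass (and hence
    # CPM composition) is preserved at full amplitude
    base <- ifelse(dir == "down", base * 2^cfg$gene_log2fc, base)
    purrr::pmap(samples, function(sample_id, timepoint_dpt, replicate,
                                  assay) {
      frac <- treatment_frac(timepoint_dpt, cfg$timepoints)
      eff <- dplyr::case_when(
        dir == "up" ~ 2^(cfg$gene_log2fc * frac),
        dir == "down" ~ 2^(-cfg$gene_log2fc * frac),
        TRUE ~ 1)
      tibble(feature_id = genes$gene_id, sample_id = sample_id,
             count = rnbinom(nrow(genes), mu = base * eff,
                             size = 1 / cfg$nb_dispersion))
    }) %>% bind_rows()
  })
  list(counts = counts, samples = samples)
}

#' Simulate a complete coupled tri-omics dataset
#'
#' Runs [simulate_genome()], [simulate_methylome()], [simulate_srna()] and
#' [simulate_expression()] from independent streams derived from one master
#' seed, and bundles the results with the planted truth.
#'
#' @param cfg A [sim_config()].
#' @return List: `config`, `genome`, `chrom_lengths`, `genes`, `te`,
#'   `meth` (sites), `srna` (reads), `expr` (counts), `samples` (combined
#'   sample sheet), `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  ref <- simulate_genome(cfg)
  meth <- simulate_methylome(cfg, ref)
  srna <- simulate_srna(cfg, ref)
  expr <- simulate_expression(cfg, ref)
  list(config = cfg,
       genome = ref$genome,
       chrom_lengths = chrom_lengths(ref$genome),
       genes = ref$genes, te = ref$te,
       meth = meth$sites, srna = srna$reads, expr = expr$counts,
       samples = bind_rows(meth$samples, srna$samples, expr$samples),
       truth = ref$truth)
}

# ---------------------------------------------------------------- file io

#' Write a simulated dataset to a directory of standard files
#'
#' Emits `genome.fa`, `genes.gff3`, `te.bed` (0-based half-open on disk),
#' `samples.tsv`, one CX report per WGBS sample under `cx/`, `srna.tsv`,
#' `gene_counts.tsv` and the planted truth under `truth/`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cx"), showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gene_models_gff3(sim$genes, file.path(dir, "genes.gff3"))
  rtracklayer::export(
    GenomicRanges::GRanges(sim$te$chrom,
                           IRanges::IRanges(sim$te$start, sim$te$end)),
    file.path(dir, "te.bed"), format = "bed")
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"),
                   progress = FALSE)
  for (sid in unique(sim$meth$sample_id)) {
    write_cx_report(filter(sim$meth, .data$sample_id == sid),
                    file.path(dir, "cx", paste0(sid, ".CX_report.txt")))
  }
  write_srna_table(sim$srna, file.path(dir, "srna.tsv"))
  wide <- tidyr::pivot_wider(sim$expr, names_from = "sample_id",
                             values_from = "count") %>%
    rename(gene_id = "feature_id")
  readr::write_tsv(wide, file.path(dir, "gene_counts.tsv"), progress = FALSE)
  write_truth(sim$truth, file.path(dir, "truth"))
  invisible(dir)
}

#' Write planted-truth tables
#'
#' Writes `dmr_truth.tsv` (and `dmr_truth.bed`), `dsr_truth.tsv`,
#' `deg_truth.tsv` and `rddm_truth.tsv` for consumption by recovery
#' metrics.
#'
#' @param truth Truth list from [simulate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(truth$dmr, file.path(dir, "dmr_truth.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    tibble(chrom = truth$dmr$chrom, start = truth$dmr$start - 1L,
           end = truth$dmr$end,
           name = paste0(truth$dmr$context, "_", truth$dmr$polarity)),
    file.path(dir, "dmr_truth.bed"), col_names = FALSE, progress = FALSE)
  readr::write_tsv(truth$dsr, file.path(dir, "dsr_truth.tsv"),
                   progress = FALSE)
  readr::write_tsv(truth$deg, file.path(dir, "deg_truth.tsv"),
                   progress = FALSE)
  readr::write_tsv(truth$rddm, file.path(dir, "rddm_truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read planted-truth tables back from disk
#' @param dir Directory written by [write_truth()].
#' @return Truth list (`dmr`, `dsr`, `deg`, `rddm`).
#' @export
read_truth <- function(dir) {
  list(dmr = readr::read_tsv(file.path(dir, "dmr_truth.tsv"),
                             show_col_types = FALSE, progress = FALSE),
       dsr = readr::read_tsv(file.path(dir, "dsr_truth.tsv"),
                             show_col_types = FALSE, progress = FALSE),
       deg = readr::read_tsv(file.path(dir, "deg_truth.tsv"),
                             show_col_types = FALSE, progress = FALSE),
       rddm = readr::read_tsv(file.path(dir, "rddm_truth.tsv"),
                              show_col_types = FALSE, progress = FALSE))
}

#' Write gene models as GFF3
#'
#' One `gene`, one `mRNA` and the exon/UTR children per gene, with
#' `ID`/`Parent` attributes, importable by [read_gene_models()].
#'
#' @param genes Gene-model tibble.
#' @param path Output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  rows <- purrr::pmap(genes, function(gene_id, chrom, strand, start, end,
                                      tss, tes, exons, five_utr, three_utr,
                                      ...) {
    tx <- paste0(gene_id, ".t1")
    bind_rows(
      tibble(chrom = chrom, type = "gene", start = start, end = end,
             strand = strand, ID = gene_id, Parent = NA_character_),
      tibble(chrom = chrom, type = "mRNA", start = start, end = end,
             strand = strand, ID = tx, Parent = gene_id),
      tibble(chrom = chrom, type = "exon", start = exons$start,
             end = exons$end, strand = strand, ID = NA_character_,
             Parent = tx),
      tibble(chrom = chrom, type = "five_prime_UTR", start = five_utr$start,
             end = five_utr$end, strand = strand, ID = NA_character_,
             Parent = tx),
      tibble(chrom = chrom, type = "three_prime_UTR",
             start = three_utr$start, end = three_utr$end, strand = strand,
             ID = NA_character_, Parent = tx)
    )
  }) %>% bind_rows()
  gr <- GenomicRanges::GRanges(rows$chrom,
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$ID <- rows$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(rows$Parent, function(p) if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
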