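# Methylome: per-site / global / per-region methylation levels and windowed
# DMR calling with the filter cascade (BH FDR <= 0.05, pooled window coverage
# >= 30 per group, level difference > 15 percentage points, fold change >= 2
# or <= 0.5).

#' Read a per-cytosine CX methylation report
#'
#' Expects the Bismark CX dialect: tab-separated columns chrom, 1-based
#' position, strand, count methylated, count unmethylated, context
#' (CG/CHG/CHH), trinucleotide; no header. Rows where the methylated count
#' exceeds the total are rejected with the offending file and line.
#'
#' @param path CX report file.
#' @param sample_id Optional sample id added as a column.
#' @return Tibble `chrom`, `pos`, `strand`, `context`, `meth`, `total`
#'   (and `sample_id` if given).
#' @export
read_cx_report <- function(path, sample_id = NULL) {
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "pos", "strand", "meth",
                                      "unmeth", "context", "trinucleotide"),
                        col_types = "ciciicc", progress = FALSE)
  bad <- which(df$meth < 0 | df$unmeth < 0)
  if (length(bad) > 0L) {
    abort(sprintf("negative count in CX report %s at line %d", path, bad[1]))
  }
  out <- tibble(chrom = df$chrom, pos = df$pos, strand = df$strand,
                context = df$context, meth = df$meth,
                total = df$meth + df$unmeth)
  if (!is.null(sample_id)) out <- mutate(out, sample_id = sample_id)
  out
}

#' Write a per-cytosine CX methylation report
#' @param sites Tibble with `chrom`, `pos`, `strand`, `context`, `meth`,
#'   `total` (and optionally `trinucleotide`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(sites, path) {
  assert_columns(sites, c("chrom", "pos", "strand", "context", "meth",
                          "total"), "sites")
  tri <- if ("trinucleotide" %in% names(sites)) sites$trinucleotide else
    paste0("C", substr(sites$context, 2, 3))
  out <- tibble(sites$chrom, sites$pos, sites$strand, sites$meth,
                sites$total - sites$meth, sites$context, tri)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Per-site methylation level
#'
#' The ratio of reads supporting a methylated C to the total reads at the
#' site; undefined (`NA`) for uncovered sites.
#'
#' @param meth,total Read counts (vectorised).
#' @return Fraction in `[0, 1]`, `NA` where `total == 0`.
#' @export
site_level <- function(meth, total) {
  if (any(meth > total, na.rm = TRUE)) abort("meth count exceeds total")
  if (any(meth < 0 | total < 0, na.rm = TRUE)) abort("negative read count")
  if_else(total > 0, meth / total, NA_real_)
}

#' Global methylation level per context
#'
#' The default is the coverage-weighted pooled estimate
#' `100 * sum(meth) / sum(total)` over covered sites of each context — the
#' read-ratio definition — with the unweighted mean of per-site levels
#' available via `weighted = FALSE`.
#'
#' @param sites Site tibble (`context`, `meth`, `total`, optionally
#'   `sample_id`).
#' @param context Optional subset of contexts to report.
#' @param weighted Pooled read-ratio (default) or mean of site fractions.
#' @return Tibble with `context` (and `sample_id` if present), `n_sites`
#'   (covered sites) and `level` in percent; contexts with no covered sites
#'   give `NA`.
#' @export
global_level <- function(sites, context = NULL, weighted = TRUE) {
  assert_columns(sites, c("context", "meth", "total"), "sites")
  if (!is.null(context)) sites <- filter(sites, .data$context %in% !!context)
  sites <- filter(sites, !is.na(.data$context))
  grp <- intersect(c("sample_id", "context"), names(sites))
  sites %>%
    group_by(across(dplyr::all_of(grp))) %>%
    summarise(
      n_sites = sum(.data$total > 0),
      level = if (sum(.data$total) > 0) {
        if (weighted) 100 * sum(.data$meth) / sum(.data$total)
        else 100 * mean(.data$meth[.data$total > 0] /
                          .data$total[.data$total > 0])
      } else NA_real_,
      .groups = "drop")
}

#' Pooled methylation level by functional region
#'
#' Assigns every covered cytosine of the requested context to a functional
#' region (see [assign_region()]) and reports the pooled level per region.
#'
#' @param sites Site tibble.
#' @param genes Gene models.
#' @param spec A [region_spec()].
#' @param context Context to profile (`"CG"`, `"CHG"` or `"CHH"`).
#' @param chrom_lengths Optional named chromosome lengths.
#' @return Tibble `region`, `n_sites`, `level` (percent; `NA` for regions
#'   with no covered sites, which are still listed).
#' @export
region_profile <- function(sites, genes, spec = region_spec(),
                           context = "CG", chrom_lengths = NULL) {
  assert_columns(sites, c("chrom", "pos", "context", "meth", "total"),
                 "sites")
  sub <- filter(sites, .data$context == !!context)
  pos <- distinct(sub, .data$chrom, .data$pos) %>%
    assign_region(genes, spec, chrom_lengths)
  sub <- left_join(sub, pos, by = c("chrom", "pos"))
  lv <- sub %>%
    group_by(region = .data$region) %>%
    summarise(n_sites = sum(.data$total > 0),
              level = if (sum(.data$total) > 0)
                100 * sum(.data$meth) / sum(.data$total) else NA_real_,
              .groups = "drop")
  all_regions <- c("upstream2k", "5UTR", "exon", "intron", "3UTR",
                   "downstream2k", "intergenic")
  tibble(region = all_regions) %>%
    left_join(lv, by = "region") %>%
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
}

#' Metagene methylation curves over gene flanks and body
#'
#' Bins the upstream flank, the gene body (scaled) and the downstream flank
#' into `n_bins` strand-oriented bins each and reports the pooled level per
#' bin, for metagene plots.
#'
#' @inheritParams region_profile
#' @param n_bins Bins per segment (default 20).
#' @return Tibble `segment` (upstream/body/downstream), `bin`, `level`.
#' @export
metagene_profile <- function(sites, genes, spec = region_spec(),
                             context = "CG", n_bins = 20) {
  assert_columns(sites, c("chrom", "pos", "context", "meth", "total"),
                 "sites")
  sub <- filter(sites, .data$context == !!context, .data$total > 0)
  segs <- purrr::pmap(list(genes$gene_id, genes$chrom, genes$strand,
                           genes$start, genes$end), function(gid, chr, str,
                                                             gs, ge) {
    up <- if (str == "+") c(gs - spec$upstream_flank, gs - 1L)
          else c(ge + 1L, ge + spec$upstream_flank)
    dn <- if (str == "+") c(ge + 1L, ge + spec$downstream_flank)
          else c(gs - spec$downstream_flank, gs - 1L)
    tibble(chrom = chr, strand = str,
           segment = c("upstream", "body", "downstream"),
           start = pmax(1L, as.integer(c(up[1], gs, dn[1]))),
           end = as.integer(c(up[2], ge, dn[2])))
  }) %>% bind_rows()
  pts <- tibble(chrom = sub$chrom, start = sub$pos, end = sub$pos)
  hits <- overlap_pairs(pts, segs)
  joined <- tibble(meth = sub$meth[hits$a_idx], total = sub$total[hits$a_idx],
                   pos = sub$pos[hits$a_idx],
                   segment = segs$segment[hits$b_idx],
                   strand = segs$strand[hits$b_idx],
                   s = segs$start[hits$b_idx], e = segs$end[hits$b_idx]) %>%
    mutate(frac = (.data$pos - .data$s) / pmax(1L, .data$e - .data$s),
           frac = if_else(.data$strand == "-", 1 - .data$frac, .data$frac),
           bin = pmin(n_bins, floor(.data$frac * n_bins) + 1L))
  joined %>%
    group_by(.data$segment, .data$bin) %>%
    summarise(level = 100 * sum(.data$meth) / sum(.data$total),
              .groups = "drop") %>%
    mutate(segment = factor(.data$segment,
                            levels = c("upstream", "body", "downstream"))) %>%
    arrange(.data$segment, .data$bin)
}

#' DMR calling parameters
#'
#' Defaults implement the filter cascade: non-overlapping 1-kb tiles, pooled
#' per-group window coverage of at least 30 reads, BH FDR at 0.05, absolute
#' level difference above 15 percentage points, and fold change at least 2
#' (or at most 0.5).
#'
#' @param tile_width Window width in bp (default 1000).
#' @param min_coverage Minimum pooled reads per group per window (default 30).
#' @param min_diff Minimum absolute level difference in percentage points,
#'   strict (default 15).
#' @param fc_hi,fc_lo Fold-change bounds (defaults 2 and 0.5).
#' @param fdr BH FDR threshold (default 0.05).
#' @return A `dmr_params` list.
#' @export
dmr_params <- function(tile_width = 1000, min_coverage = 30, min_diff = 15,
                       fc_hi = 2, fc_lo = 0.5, fdr = 0.05) {
  if (fdr <= 0 || fdr >= 1) abort("fdr must lie in (0, 1)")
  if (tile_width < 1) abort("tile_width must be positive")
  structure(list(tile_width = as.integer(tile_width),
                 min_coverage = min_coverage, min_diff = min_diff,
                 fc_hi = fc_hi, fc_lo = fc_lo, fdr = fdr),
            class = "dmr_params")
}

#' Call differentially methylated regions between two sample groups
#'
#' Tiles the genome into non-overlapping windows, pools replicate counts
#' within each group and window, drops windows where either group's pooled
#' coverage is below `min_coverage`, tests each remaining window with a
#' two-sided Fisher exact test on the 2x2 methylated/unmethylated table,
#' applies BH correction across all tested windows of the context, and
#' retains windows passing the FDR, level-difference and fold-change filters.
#' Polarity is `hyper` when the treatment level exceeds the control level.
#' Windows where the control level is zero but the treatment level positive
#' have infinite fold change (passing `fc_hi`); windows with both levels zero
#' are never DMRs.
#'
#' @param sites Long site tibble with a `sample_id` column covering both
#'   groups.
#' @param treat,ctrl Character vectors of sample ids forming the treatment
#'   and control groups.
#' @param context Context to test (one of `"CG"`, `"CHG"`, `"CHH"`).
#' @param params A [dmr_params()].
#' @param chrom_lengths Named chromosome lengths (used to bound windows).
#' @param comparison Label stored with the result (e.g. `"10dpt_vs_0dpt"`).
#' @param keep_all Return all tested windows (with a `dmr` flag) instead of
#'   DMRs only.
#' @return Tibble of DMRs: `chrom`, `start`, `end`, `context`,
#'   `level_treat`, `level_ctrl`, `diff` (percentage points), `fold_change`,
#'   `p`, `q`, `polarity`, `comparison`; class `rddm_dmr`, with the number of
#'   tested windows in `attr(, "n_tested")`.
#' @export
call_dmrs <- function(sites, treat, ctrl, context = "CHH",
                      params = dmr_params(), chrom_lengths = NULL,
                      comparison = "treat_vs_ctrl", keep_all = FALSE) {
  assert_columns(sites, c("sample_id", "chrom", "pos", "context", "meth",
                          "total"), "sites")
  if (length(treat) == 0L || length(ctrl) == 0L) {
    abort("both treat and ctrl must name at least one sample")
  }
  miss <- setdiff(c(treat, ctrl), unique(sites$sample_id))
  if (length(miss) > 0L) {
    abort(paste0("sample id(s) absent from sites: ",
                 paste(miss, collapse = ", ")))
  }
  w <- params$tile_width
  sub <- sites %>%
    filter(.data$context == !!context, .data$total > 0,
           .data$sample_id %in% c(treat, ctrl)) %>%
    mutate(group = if_else(.data$sample_id %in% treat, "t", "c"),
           win = (.data$pos - 1L) %/% w)
  pooled <- sub %>%
    group_by(.data$chrom, .data$win, .data$group) %>%
    summarise(meth = sum(.data$meth), total = sum(.data$total),
              .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("meth", "total"), values_fill = 0)
  for (colnm in c("meth_t", "meth_c", "total_t", "total_c")) {
    if (!colnm %in% names(pooled)) pooled[[colnm]] <- 0
  }
  tested <- filter(pooled, .data$total_t >= params$min_coverage,
                   .data$total_c >= params$min_coverage)
  n_tested <- nrow(tested)
  if (n_tested == 0L) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  context = character(), level_treat = double(),
                  level_ctrl = double(), diff = double(),
                  fold_change = double(), p = double(), q = double(),
                  polarity = character(), comparison = character())
    return(new_result_tbl(out, "rddm_dmr", params = params,
                          comparison = comparison, context = context,
                          n_tested = 0L))
  }
  tested <- tested %>%
    mutate(
      level_treat = 100 * .data$meth_t / .data$total_t,
      level_ctrl = 100 * .data$meth_c / .data$total_c,
      diff = .data$level_treat - .data$level_ctrl,
      fold_change = dplyr::case_when(
        .data$level_ctrl > 0 ~ .data$level_treat / .data$level_ctrl,
        .data$level_treat > 0 ~ Inf,
        TRUE ~ NaN),
      p = fisher_exact_2x2(.data$meth_t, .data$total_t - .data$meth_t,
                           .data$meth_c, .data$total_c - .data$meth_c),
      q = p.adjust(.data$p, method = "BH"),
      dmr = .data$q <= params$fdr &
        abs(.data$diff) > params$min_diff &
        !is.nan(.data$fold_change) &
        (.data$fold_change >= params$fc_hi |
           .data$fold_change <= params$fc_lo),
      start = as.integer(.data$win * w + 1L),
      end = as.integer((.data$win + 1L) * w),
      polarity = if_else(.data$diff > 0, "hyper", "hypo"))
  if (!is.null(chrom_lengths)) {
    tested <- mutate(tested,
                     end = pmin(.data$end,
                                as.integer(chrom_lengths[.data$chrom])))
  }
  out <- tested %>%
    mutate(context = !!context, comparison = !!comparison) %>%
    select("chrom", "start", "end", "context", "level_treat", "level_ctrl",
           "diff", "fold_change", "p", "q", "polarity", "comparison",
           "dmr") %>%
    arrange(.data$chrom, .data$start)
  if (!keep_all) out <- filter(out, .data$dmr) %>% select(-"dmr")
  new_result_tbl(out, "rddm_dmr", params = params, comparison = comparison,
                 context = context, n_tested = n_tested)
}

#' Genomic distribution of DMRs
#'
#' Classifies each DMR as genic vs intergenic (at least 1 bp overlap with any
#' gene span), TE vs non-TE (1 bp overlap with any TE interval), and by the
#' functional-region label of its midpoint; returns per-polarity counts and
#' fractions for each partition (fractions sum to 1 within each polarity and
#' partition).
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param genes Gene models.
#' @param te TE interval tibble (`chrom`, `start`, `end`).
#' @param spec A [region_spec()].
#' @return Tibble `partition`, `category`, `polarity`, `n`, `fraction`.
#' @export
dmr_distribution <- function(dmrs, genes, te, spec = region_spec()) {
  if (nrow(dmrs) == 0L) {
    return(tibble(partition = character(), category = character(),
                  polarity = character(), n = integer(),
                  fraction = double()))
  }
  gene_spans <- tibble(chrom = genes$chrom, start = genes$start,
                       end = genes$end)
  genic <- seq_len(nrow(dmrs)) %in%
    overlap_pairs(dmrs[c("chrom", "start", "end")], gene_spans)$a_idx
  in_te <- seq_len(nrow(dmrs)) %in%
    overlap_pairs(dmrs[c("chrom", "start", "end")], te)$a_idx
  mid <- tibble(chrom = dmrs$chrom,
                pos = (dmrs$start + dmrs$end) %/% 2L)
  reg <- assign_region(mid, genes, spec)$region
  # the TSS region is a derived label: midpoint within tss_window of any TSS
  tssr <- tibble(chrom = genes$chrom,
                 start = pmax(1L, genes$tss - spec$tss_window),
                 end = genes$tss + spec$tss_window)
  near_tss <- seq_len(nrow(dmrs)) %in%
    overlap_pairs(mutate(mid, start = .data$pos, end = .data$pos), tssr)$a_idx
  lab <- tibble(polarity = dmrs$polarity,
                genic = if_else(genic, "gene", "intergenic"),
                te = if_else(in_te, "TE", "non-TE"),
                region = reg,
                tss = if_else(near_tss, "TSS", "non-TSS"))
  one <- function(colnm, partition) {
    lab %>%
      count(.data$polarity, category = .data[[colnm]]) %>%
      group_by(.data$polarity) %>%
      mutate(fraction = .data$n / sum(.data$n)) %>%
      ungroup() %>%
      mutate(partition = partition, .before = 1)
  }
  bind_rows(one("genic", "genic"), one("te", "te"),
            one("region", "functional_region"), one("tss", "tss_region"))
}
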