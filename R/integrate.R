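# Integration: DMR-sRNA association by odds ratios, promoter DMR target
# genes, target/DEG intersection, hypergeometric term enrichment, and the
# RdDM candidate screen (promoter TE + CHH hypo-DMR + down 24-nt cluster +
# up gene, or its mirror).

#' Association between DMRs and differentially regulated sRNA clusters
#'
#' Builds, over the background of all tested clusters, the 2x2 table with
#' rows "cluster's DSR call has the stratum's direction / does not" and
#' columns "cluster overlaps at least one DMR of the stratum's polarity /
#' does not", and reports the odds ratio (Haldane-Anscombe +0.5 corrected
#' when any cell is zero), the two-sided Fisher p and `-log10(p)`.
#'
#' @param dsr `rddm_diff` result for the clusters (one size class).
#' @param clusters Cluster coordinates (from [cluster_coords()] or binned
#'   reads).
#' @param dmrs DMR tibble (already restricted to one context/comparison).
#' @param direction DSR direction of the stratum (`"up"` or `"down"`).
#' @param polarity DMR polarity of the stratum (`"hyper"` or `"hypo"`).
#' @return One-row tibble (class `rddm_assoc`): stratum labels, cells `a`,
#'   `b`, `c`, `d`, `odds_ratio`, `p`, `neg_log10_p`.
#' @export
associate_dmr_dsr <- function(dsr, clusters, dmrs, direction = "down",
                              polarity = "hypo") {
  if (nrow(dsr) == 0L) abort("empty association background")
  coords <- if ("cluster_id" %in% names(clusters)) {
    cluster_coords(clusters)
  } else clusters
  bg <- dsr %>%
    left_join(coords, by = c(feature_id = "cluster_id"))
  if (any(is.na(bg$start))) {
    abort("some tested clusters lack coordinates")
  }
  sub_dmr <- filter(dmrs, .data$polarity == !!polarity)
  ov <- overlap_pairs(bg[c("chrom", "start", "end")],
                      sub_dmr[c("chrom", "start", "end")])
  has_dmr <- seq_len(nrow(bg)) %in% ov$a_idx
  has_dir <- bg$direction == direction
  a <- sum(has_dir & has_dmr); b <- sum(has_dir & !has_dmr)
  c_ <- sum(!has_dir & has_dmr); d <- sum(!has_dir & !has_dmr)
  p <- fisher_exact_2x2(a, b, c_, d)
  out <- tibble(direction = direction, polarity = polarity,
                size_class = dsr$size_class[1] %||% NA_character_,
                a = a, b = b, c = c_, d = d,
                odds_ratio = odds_ratio_2x2(a, b, c_, d),
                p = p, neg_log10_p = -log10(p))
  new_result_tbl(out, "rddm_assoc",
                 comparison = result_attr(dsr, "comparison"),
                 context = result_attr(dmrs, "context"))
}

#' Association grid over DSR directions and DMR polarities
#'
#' Runs [associate_dmr_dsr()] for every combination of direction
#' (up/down) and polarity (hyper/hypo). A cluster overlapping both a hyper
#' and a hypo DMR contributes to both polarities' tables.
#'
#' @inheritParams associate_dmr_dsr
#' @return `rddm_assoc` tibble with one row per stratum.
#' @export
associate_all <- function(dsr, clusters, dmrs) {
  grid <- tidyr::expand_grid(direction = c("up", "down"),
                             polarity = c("hyper", "hypo"))
  out <- purrr::pmap(grid, function(direction, polarity) {
    associate_dmr_dsr(dsr, clusters, dmrs, direction, polarity)
  }) %>% bind_rows()
  new_result_tbl(out, "rddm_assoc",
                 comparison = result_attr(dsr, "comparison"),
                 context = result_attr(dmrs, "context"))
}

#' Genes whose promoter overlaps a DMR
#'
#' Emits every (gene, DMR) pair where the DMR overlaps the gene's
#' strand-aware promoter (2 kb upstream to 500 bp downstream of the TSS by
#' default) by at least 1 bp, optionally joined to DEG results by gene id.
#'
#' @param dmrs DMR tibble.
#' @param genes Gene models.
#' @param spec A [region_spec()].
#' @param degs Optional `rddm_diff` DEG tibble to join.
#' @param chrom_lengths Optional named chromosome lengths.
#' @return Tibble `gene_id`, DMR coordinates and statistics, `overlap_bp`,
#'   and (if `degs` given) `log2fc`, `q`, `direction`.
#' @export
dmr_target_genes <- function(dmrs, genes, spec = region_spec(),
                             degs = NULL, chrom_lengths = NULL) {
  prom <- promoters_of(genes, spec, chrom_lengths)
  hits <- overlap_pairs(prom[c("chrom", "start", "end")],
                        dmrs[c("chrom", "start", "end")])
  out <- tibble(
    gene_id = prom$gene_id[hits$a_idx],
    chrom = prom$chrom[hits$a_idx],
    promoter_start = prom$start[hits$a_idx],
    promoter_end = prom$end[hits$a_idx],
    dmr_start = dmrs$start[hits$b_idx],
    dmr_end = dmrs$end[hits$b_idx],
    context = dmrs$context[hits$b_idx],
    polarity = dmrs$polarity[hits$b_idx],
    dmr_diff = dmrs$diff[hits$b_idx],
    dmr_q = dmrs$q[hits$b_idx]
  ) %>%
    mutate(overlap_bp = overlap_width(.data$promoter_start,
                                      .data$promoter_end,
                                      .data$dmr_start, .data$dmr_end)) %>%
    arrange(.data$gene_id, .data$chrom, .data$dmr_start)
  if (!is.null(degs)) {
    out <- left_join(out,
                     select(as_tibble(degs), gene_id = "feature_id",
                            "log2fc", "q", "direction"),
                     by = "gene_id")
  }
  out
}

#' Intersection counts of DMR target genes with up/down DEGs
#'
#' @param target_genes Character vector (or tibble with `gene_id`) of DMR
#'   target genes.
#' @param degs_up,degs_down Character vectors of up- and downregulated gene
#'   ids; a gene may not appear in both.
#' @return Tibble `category`, `n` with categories `targets_up`,
#'   `targets_down`, `targets_only`, `up_only`, `down_only`.
#' @export
venn_counts <- function(target_genes, degs_up, degs_down) {
  if (is.data.frame(target_genes)) target_genes <- target_genes$gene_id
  targets <- unique(target_genes)
  degs_up <- unique(degs_up); degs_down <- unique(degs_down)
  if (length(intersect(degs_up, degs_down)) > 0L) {
    abort("a gene cannot be both up- and downregulated")
  }
  tibble(category = c("targets_up", "targets_down", "targets_only",
                      "up_only", "down_only"),
         n = c(length(intersect(targets, degs_up)),
               length(intersect(targets, degs_down)),
               length(setdiff(targets, union(degs_up, degs_down))),
               length(setdiff(degs_up, targets)),
               length(setdiff(degs_down, targets))))
}

#' Screen for RdDM-regulated candidate genes
#'
#' In canonical mode, returns genes satisfying the tri-omic RdDM signature
#' on one comparison: (i) the promoter overlaps a CHH hypomethylated DMR,
#' (ii) a 24-nt sRNA cluster overlapping that DMR or the promoter is a
#' downregulated DSR, and (iii) the gene is an upregulated DEG. The mirror
#' mode swaps all three polarities (hyper DMR, up DSR, down DEG). The
#' `te_in_promoter` flag records whether any TE interval overlaps the
#' promoter. One record is emitted per qualifying (gene, DMR) pair, keeping
#' the most significant qualifying cluster; `per_gene = TRUE` deduplicates
#' to one record per gene.
#'
#' @param dmrs CHH DMR tibble.
#' @param clusters Binned sRNA reads or cluster coordinates.
#' @param dsr24 `rddm_diff` for the 24-nt size class.
#' @param degs `rddm_diff` for genes.
#' @param genes Gene models.
#' @param te TE interval tibble.
#' @param spec A [region_spec()].
#' @param mode `"canonical"` or `"mirror"`.
#' @param chrom_lengths Optional named chromosome lengths.
#' @param per_gene Deduplicate to one row per gene (default `FALSE`).
#' @return Tibble (class `rddm_screen`) sorted by gene id: `gene_id`,
#'   promoter and DMR coordinates, `dmr_diff`, `cluster_id`,
#'   `srna_log2fc`, `gene_log2fc`, `te_in_promoter`, `mode`.
#' @export
screen_rddm <- function(dmrs, clusters, dsr24, degs, genes, te,
                        spec = region_spec(), mode = c("canonical", "mirror"),
                        chrom_lengths = NULL, per_gene = FALSE) {
  mode <- match.arg(mode)
  cmp <- c(result_attr(dmrs, "comparison"), result_attr(dsr24, "comparison"),
           result_attr(degs, "comparison"))
  if (length(unique(cmp)) > 1L) {
    abort(paste0("layers computed on different comparisons: ",
                 paste(unique(cmp), collapse = " vs ")))
  }
  want <- if (mode == "canonical") {
    list(polarity = "hypo", srna = "down", gene = "up")
  } else {
    list(polarity = "hyper", srna = "up", gene = "down")
  }
  dsr24 <- filter(as_tibble(dsr24), .data$size_class %in% c("24nt", "n/a"))
  hits_dmr <- filter(as_tibble(dmrs), .data$polarity == want$polarity)
  prom <- promoters_of(genes, spec, chrom_lengths)
  pairs <- overlap_pairs(prom[c("chrom", "start", "end")],
                         hits_dmr[c("chrom", "start", "end")])
  if (nrow(pairs) == 0L) {
    return(new_result_tbl(empty_screen(), "rddm_screen", mode = mode,
                          comparison = cmp[1] %||% NA_character_))
  }
  coords <- if ("cluster_id" %in% names(clusters)) cluster_coords(clusters)
            else clusters
  down_clusters <- dsr24 %>%
    filter(.data$direction == want$srna) %>%
    inner_join(coords, by = c(feature_id = "cluster_id"))
  deg_ok <- filter(as_tibble(degs), .data$direction == want$gene)
  cand <- purrr::pmap(list(pairs$a_idx, pairs$b_idx), function(gi, di) {
    gid <- prom$gene_id[gi]
    expr <- filter(deg_ok, .data$feature_id == gid)
    if (nrow(expr) == 0L) return(NULL)
    # sRNA linkage: cluster overlaps the DMR window or the promoter
    reach_start <- min(prom$start[gi], hits_dmr$start[di])
    reach_end <- max(prom$end[gi], hits_dmr$end[di])
    cl <- down_clusters %>%
      filter(.data$chrom == prom$chrom[gi],
             (interval_overlaps(.data$start, .data$end,
                                hits_dmr$start[di], hits_dmr$end[di]) |
              interval_overlaps(.data$start, .data$end,
                                prom$start[gi], prom$end[gi])))
    if (nrow(cl) == 0L) return(NULL)
    cl <- arrange(cl, .data$q, .data$feature_id) %>% dplyr::slice(1L)
    tibble(gene_id = gid,
           chrom = prom$chrom[gi],
           promoter_start = prom$start[gi], promoter_end = prom$end[gi],
           dmr_start = hits_dmr$start[di], dmr_end = hits_dmr$end[di],
           dmr_diff = hits_dmr$diff[di],
           cluster_id = cl$feature_id,
           srna_log2fc = cl$log2fc,
           gene_log2fc = expr$log2fc[1])
  }) %>% bind_rows()
  if (nrow(cand) == 0L) {
    return(new_result_tbl(empty_screen(), "rddm_screen", mode = mode,
                          comparison = cmp[1] %||% NA_character_))
  }
  te_hit <- overlap_pairs(cand[c("chrom", "promoter_start", "promoter_end")] %>%
                            rename(start = "promoter_start",
                                   end = "promoter_end"), te)
  cand <- cand %>%
    mutate(te_in_promoter = seq_len(nrow(cand)) %in% te_hit$a_idx,
           mode = mode) %>%
    arrange(.data$gene_id, .data$dmr_start)
  if (per_gene) {
    cand <- distinct(cand, .data$gene_id, .keep_all = TRUE)
  }
  new_result_tbl(cand, "rddm_screen", mode = mode,
                 comparison = cmp[1] %||% NA_character_)
}

empty_screen <- function() {
  tibble(gene_id = character(), chrom = character(),
         promoter_start = integer(), promoter_end = integer(),
         dmr_start = integer(), dmr_end = integer(), dmr_diff = double(),
         cluster_id = character(), srna_log2fc = double(),
         gene_log2fc = double(), te_in_promoter = logical(),
         mode = character())
}

#' Hypergeometric term enrichment for a gene selection
#'
#' For each term carried by at least one selected gene, tests whether the
#' term is over-represented in the selection relative to the background
#' using the hypergeometric upper tail
#' `P(X >= k)` with `K` carriers among `N` background genes and a selection
#' of size `n`; BH correction across tested terms. The term map is a flat
#' gene-to-term table; no ontology propagation is performed.
#'
#' @param selected Character vector of selected gene ids (must be a subset
#'   of the background).
#' @param background Character vector of background gene ids.
#' @param term_map Tibble `gene_id`, `term_id` and optionally `term_name`.
#' @return Tibble `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   ordered by p.
#' @export
term_enrichment <- function(selected, background, term_map) {
  selected <- unique(selected); background <- unique(background)
  if (length(selected) == 0L) abort("empty gene selection")
  if (!all(selected %in% background)) {
    abort("selected genes must be a subset of the background")
  }
  assert_columns(term_map, c("gene_id", "term_id"), "term_map")
  tm <- filter(term_map, .data$gene_id %in% background) %>%
    distinct(.data$gene_id, .data$term_id, .keep_all = TRUE)
  names_map <- if ("term_name" %in% names(tm)) {
    distinct(tm, .data$term_id, .data$term_name)
  } else {
    distinct(tm, .data$term_id) %>% mutate(term_name = .data$term_id)
  }
  n <- length(selected); N <- length(background)
  stats_tbl <- tm %>%
    group_by(.data$term_id) %>%
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = dplyr::n_distinct(intersect(.data$gene_id, selected)),
              .groups = "drop") %>%
    filter(.data$k >= 1L) %>%
    mutate(n = n, N = N,
           p = phyper(.data$k - 1L, .data$K, .data$N - .data$K, .data$n,
                      lower.tail = FALSE)) %>%
    mutate(q = p.adjust(.data$p, method = "BH")) %>%
    left_join(names_map, by = "term_id") %>%
    select("term_id", "term_name", "k", "K", "n", "N", "p", "q") %>%
    arrange(.data$p, .data$term_id)
  stats_tbl
}
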