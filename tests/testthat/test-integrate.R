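mk_dmr <- function(chrom, start, end, polarity, context = "CHH",
                   comparison = "10dpt_vs_0dpt", diff = -40) {
  out <- tibble::tibble(chrom = chrom, start = as.integer(start),
                        end = as.integer(end), context = context,
                        level_treat = 5, level_ctrl = 45, diff = diff,
                        fold_change = 0.11, p = 1e-8, q = 1e-7,
                        polarity = polarity, comparison = comparison)
  attr(out, "comparison") <- comparison
  attr(out, "context") <- context
  class(out) <- c("rddm_dmr", class(out))
  out
}

test_that("association odds ratios and Fisher p follow the 2x2 definition", {
  # background of 37 clusters realising the table [[10,5],[2,20]]
  coords <- tibble::tibble(cluster_id = sprintf("Chr1;%d;%d",
                                                (0:36) * 1000 + 1,
                                                (1:37) * 1000),
                           chrom = "Chr1", start = (0:36) * 1000 + 1,
                           end = (1:37) * 1000)
  dirs <- c(rep("down", 15), rep("ns", 22))
  has_dmr <- c(rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 2), rep(FALSE, 20))
  dsr <- fake_diff(coords$cluster_id, ifelse(dirs == "down", -2, 0), dirs)
  dmrs <- mk_dmr("Chr1", coords$start[has_dmr], coords$end[has_dmr],
                 "hypo")
  res <- associate_dmr_dsr(dsr, coords, dmrs, direction = "down",
                           polarity = "hypo")
  expect_equal(c(res$a, res$b, res$c, res$d), c(10, 5, 2, 20))
  expect_equal(res$odds_ratio, 20)
  expect_equal(res$p, oracle_fisher(10, 5, 2, 20), tolerance = 1e-12)
  expect_equal(res$neg_log10_p, -log10(res$p))
})

test_that("a balanced association table gives OR 1 and p 1", {
  coords <- tibble::tibble(cluster_id = sprintf("Chr1;%d;%d",
                                                (0:19) * 1000 + 1,
                                                (1:20) * 1000),
                           chrom = "Chr1", start = (0:19) * 1000 + 1,
                           end = (1:20) * 1000)
  dirs <- rep(c("up", "ns"), each = 10)
  has_dmr <- rep(c(TRUE, FALSE), 10)
  dsr <- fake_diff(coords$cluster_id, ifelse(dirs == "up", 2, 0), dirs)
  dmrs <- mk_dmr("Chr1", coords$start[has_dmr], coords$end[has_dmr],
                 "hyper")
  res <- associate_dmr_dsr(dsr, coords, dmrs, "up", "hyper")
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)
})

test_that("flipping one factor of the association table inverts the OR, keeps p", {
  a <- 9; b <- 57; cc <- 5; d <- 229
  # swapping the rows (direction yes <-> no) inverts the odds ratio
  expect_equal(odds_ratio_2x2(cc, d, a, b), 1 / odds_ratio_2x2(a, b, cc, d))
  expect_equal(fisher_exact_2x2(cc, d, a, b), fisher_exact_2x2(a, b, cc, d),
               tolerance = 1e-12)
  # swapping the columns (overlap yes <-> no) does the same
  expect_equal(odds_ratio_2x2(b, a, d, cc), 1 / odds_ratio_2x2(a, b, cc, d))
  expect_equal(fisher_exact_2x2(b, a, d, cc), fisher_exact_2x2(a, b, cc, d),
               tolerance = 1e-12)
  # the full transpose leaves both unchanged
  expect_equal(odds_ratio_2x2(a, cc, b, d), odds_ratio_2x2(a, b, cc, d))
  expect_equal(fisher_exact_2x2(a, cc, b, d), fisher_exact_2x2(a, b, cc, d),
               tolerance = 1e-12)
})

test_that("promoter-overlapping DMRs define target genes, strand-aware", {
  genes <- dplyr::bind_rows(
    toy_gene("gp", "Chr1", "+", 10001, 13000),
    toy_gene("gm", "Chr1", "-", 30001, 32000))
  # + gene: promoter [8001, 10501]
  hits <- dmr_target_genes(mk_dmr("Chr1", 7001, 8001, "hypo"), genes)
  expect_equal(hits$gene_id, "gp")
  expect_equal(hits$overlap_bp, 1L)
  # 3 kb into the gene body, past TSS + 500 -> not a target
  expect_equal(nrow(dmr_target_genes(mk_dmr("Chr1", 12500, 13000, "hypo"),
                                     genes)), 0L)
  # - gene tss at 32000: window [31500, 34000]; a DMR 1 kb downstream in
  # coordinates (33001..33500) is upstream in gene orientation -> target
  m1 <- dmr_target_genes(mk_dmr("Chr1", 33001, 33500, "hypo"), genes)
  expect_equal(m1$gene_id, "gm")
  # but 1 kb before the coordinate tss (30500..30900) is past tss+500 in
  # gene orientation -> not a target
  expect_equal(nrow(dmr_target_genes(mk_dmr("Chr1", 30500, 30900, "hypo"),
                                     genes)), 0L)
})

test_that("target-gene output is stable under permutation of inputs", {
  genes <- dplyr::bind_rows(
    toy_gene("gA", "Chr1", "+", 10001, 12000),
    toy_gene("gB", "Chr1", "+", 40001, 42000))
  dmrs <- mk_dmr("Chr1", c(8001, 38001, 9001), c(9000, 39000, 10000),
                 "hypo")
  t1 <- dmr_target_genes(dmrs, genes)
  t2 <- dmr_target_genes(dmrs[c(3, 1, 2), ], genes[c(2, 1), ])
  expect_equal(t1, t2)
})

test_that("venn counts intersect targets with DEG directions", {
  v <- venn_counts(c("a", "b", "c"), c("b", "c", "d"), c("e"))
  expect_equal(v$n[v$category == "targets_up"], 2L)
  expect_equal(v$n[v$category == "targets_only"], 1L)
  expect_equal(v$n[v$category == "up_only"], 1L)
  expect_equal(v$n[v$category == "down_only"], 1L)
  disj <- venn_counts("x", "y", "z")
  expect_equal(disj$n[disj$category == "targets_up"], 0L)
  sub <- venn_counts(c("a", "b"), c("a", "b", "c"), character(0))
  expect_equal(sub$n[sub$category == "targets_up"], 2L)
  expect_error(venn_counts("a", c("b"), c("b")), "both")
})

test_that("the tri-omic candidate screen requires all three layers", {
  # an upstream-TE locus: promoter CHH hypo-DMR, downregulated 24-nt
  # cluster in the same window, upregulated gene
  genes <- toy_gene("gRdDM1", "Chr6", "+", 2123001, 2124000)
  te <- tibble::tibble(chrom = "Chr6", start = 2121101L, end = 2121700L)
  dmrs <- mk_dmr("Chr6", 2121001, 2122000, "hypo")
  coords <- tibble::tibble(cluster_id = "Chr6;2121001;2122000",
                           chrom = "Chr6", start = 2121001L,
                           end = 2122000L)
  dsr <- fake_diff("Chr6;2121001;2122000", -2.3, "down")
  degs <- fake_diff("gRdDM1", 2.1, "up", size_class = "n/a")
  sc <- screen_rddm(dmrs, coords, dsr, degs, genes, te)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$gene_id, "gRdDM1")
  expect_equal(sc$cluster_id, "Chr6;2121001;2122000")
  expect_true(sc$te_in_promoter)
  expect_equal(sc$mode, "canonical")

  # conjunction: a non-significant sRNA cluster excludes the gene
  sc_ns <- screen_rddm(dmrs, coords, fake_diff("Chr6;2121001;2122000",
                                               -0.4, "ns"),
                       degs, genes, te)
  expect_equal(nrow(sc_ns), 0L)
  # and so does a non-DEG gene
  sc_nodeg <- screen_rddm(dmrs, coords, dsr,
                          fake_diff("gRdDM1", 0.2, "ns",
                                    size_class = "n/a"),
                          genes, te)
  expect_equal(nrow(sc_nodeg), 0L)
})

test_that("canonical and mirror screens are disjoint", {
  cfg <- small_sim_config(seed = 23)
  sim <- simulate_dataset(cfg)
  cl <- bin_srna_reads(sim$srna)
  dmrs <- call_dmrs(sim$meth, paste0("meth_10dpt_r", 1:2),
                    paste0("meth_0dpt_r", 1:2), context = "CHH",
                    chrom_lengths = sim$chrom_lengths,
                    comparison = "10dpt_vs_0dpt")
  dsr <- call_dsrs(cl, paste0("srna_10dpt_r", 1:3),
                   paste0("srna_0dpt_r", 1:3),
                   comparison = "10dpt_vs_0dpt")
  d24 <- dplyr::filter(tibble::as_tibble(dsr), size_class == "24nt")
  attr(d24, "comparison") <- "10dpt_vs_0dpt"
  degs <- call_degs(sim$expr, paste0("rna_10dpt_r", 1:3),
                    paste0("rna_0dpt_r", 1:3),
                    comparison = "10dpt_vs_0dpt")
  can <- screen_rddm(dmrs, cl, d24, degs, sim$genes, sim$te,
                     chrom_lengths = sim$chrom_lengths, mode = "canonical")
  mir <- screen_rddm(dmrs, cl, d24, degs, sim$genes, sim$te,
                     chrom_lengths = sim$chrom_lengths, mode = "mirror")
  expect_length(intersect(can$gene_id, mir$gene_id), 0L)
})

test_that("the screen rejects layers from different comparisons", {
  genes <- toy_gene("g1", "Chr1", "+", 10001, 11000)
  te <- tibble::tibble(chrom = "Chr1", start = 1L, end = 10L)
  dmrs <- mk_dmr("Chr1", 8001, 9000, "hypo", comparison = "10dpt_vs_0dpt")
  dsr <- fake_diff("Chr1;8001;9000", -2, "down",
                   comparison = "5dpt_vs_0dpt")
  degs <- fake_diff("g1", 2, "up", size_class = "n/a")
  coords <- tibble::tibble(cluster_id = "Chr1;8001;9000", chrom = "Chr1",
                           start = 8001L, end = 9000L)
  expect_error(screen_rddm(dmrs, coords, dsr, degs, genes, te),
               "different comparisons")
})

test_that("term enrichment matches closed-form hypergeometric corner cases", {
  background <- sprintf("g%03d", 1:100)
  tm_all <- tibble::tibble(gene_id = background, term_id = "T",
                           term_name = "everything")
  res_all <- term_enrichment(background[1:10], background, tm_all)
  expect_equal(res_all$p, 1)

  carriers <- background[1:5]
  tm <- tibble::tibble(gene_id = carriers, term_id = "T5",
                       term_name = "rare")
  res <- term_enrichment(carriers, background, tm)
  expect_equal(res$k, 5L)
  expect_equal(res$p, 1 / choose(100, 5), tolerance = 1e-12)

  # terms absent from the selection are not reported
  tm2 <- dplyr::bind_rows(tm, tibble::tibble(gene_id = background[50:60],
                                             term_id = "T6",
                                             term_name = "absent"))
  res2 <- term_enrichment(carriers, background, tm2)
  expect_false("T6" %in% res2$term_id)

  expect_error(term_enrichment(character(0), background, tm), "empty")
  expect_error(term_enrichment("not_there", background, tm), "subset")
})
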