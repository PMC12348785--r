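test_that("site level is the read ratio, NA when uncovered", {
  expect_equal(site_level(30, 60), 0.5)
  expect_equal(site_level(0, 10), 0)
  expect_true(is.na(site_level(0, 0)))
  expect_error(site_level(5, 3), "exceeds")
  expect_error(site_level(-1, 3), "negative")
})

test_that("global level pools reads by default, site means on request", {
  sites <- tibble::tibble(context = "CG", meth = c(9L, 1L),
                          total = c(10L, 10L))
  expect_equal(global_level(sites)$level, 50)
  expect_equal(global_level(sites, weighted = FALSE)$level,
               100 * mean(c(0.9, 0.1)))
  zeroes <- tibble::tibble(context = "CHH", meth = 0L, total = c(8L, 12L))
  expect_equal(global_level(zeroes)$level, 0)
  # unequal coverage separates the two estimators
  uneq <- tibble::tibble(context = "CG", meth = c(90L, 1L),
                         total = c(100L, 10L))
  expect_equal(global_level(uneq)$level, 100 * 91 / 110)
  expect_equal(global_level(uneq, weighted = FALSE)$level, 50)
})

test_that("region profile is flat on a uniform methylome and NA when empty", {
  genes <- toy_gene("gA", "Chr1", "+", 5001, 8000)
  pos <- seq(3001L, 10000L, by = 50L)
  sites <- tibble::tibble(chrom = "Chr1", pos = pos, strand = "+",
                          context = "CG", meth = 7L, total = 10L)
  prof <- region_profile(sites, genes, context = "CG")
  covered <- prof[!is.na(prof$level), ]
  expect_true(all(abs(covered$level - 70) < 1e-9))
  # 5UTR has no annotated interval here -> no covered sites -> NA
  expect_true(is.na(prof$level[prof$region == "5UTR"]))
})

test_that("region profile matches hand-pooled ratios on a toy", {
  genes <- toy_gene("gA", "Chr1", "+", 1001, 1200)
  sites <- tibble::tibble(
    chrom = "Chr1", pos = c(1050L, 1100L, 901L, 951L), strand = "+",
    context = "CHH", meth = c(3L, 1L, 0L, 5L), total = c(10L, 10L, 5L, 5L))
  # the toy gene is a single exon spanning its whole body
  prof <- region_profile(sites, genes, context = "CHH")
  expect_equal(prof$level[prof$region == "exon"], 100 * 4 / 20)
  expect_equal(prof$level[prof$region == "upstream2k"], 100 * 5 / 10)
})

test_that("DMR calling applies the full filter cascade", {
  params <- dmr_params()
  # strong window: 80% vs 20% -> hyper DMR with the enumeration-oracle p
  sites <- one_window_sites(48, 60, 12, 60)
  d <- call_dmrs(sites, "t1", "c1", context = "CHH", params = params)
  expect_equal(nrow(d), 1L)
  expect_equal(d$polarity, "hyper")
  expect_equal(d$diff, 60)
  expect_equal(d$fold_change, 4)
  expect_equal(d$p, oracle_fisher(48, 12, 12, 48), tolerance = 1e-12)
  expect_equal(d$start, 1L)
  expect_equal(d$end, 1000L)

  # pooled coverage 29 in treatment -> dropped before testing
  low <- one_window_sites(20, 29, 12, 60)
  d_low <- call_dmrs(low, "t1", "c1", context = "CHH", params = params)
  expect_equal(attr(d_low, "n_tested"), 0L)
  expect_equal(nrow(d_low), 0L)

  # diff 16 pp but fold change 1.67 < 2 -> rejected
  fc_fail <- one_window_sites(400, 1000, 240, 1000)
  expect_equal(nrow(call_dmrs(fc_fail, "t1", "c1", context = "CHH",
                              params = params)), 0L)

  # diff 8 pp <= 15 -> rejected regardless of p
  diff_fail <- one_window_sites(500, 1000, 420, 1000)
  expect_equal(nrow(call_dmrs(diff_fail, "t1", "c1", context = "CHH",
                              params = params)), 0L)
})

test_that("zero control level gives infinite fold change; both-zero is never a DMR", {
  inf_case <- one_window_sites(30, 60, 0, 60)
  d <- call_dmrs(inf_case, "t1", "c1", context = "CHH")
  expect_equal(nrow(d), 1L)
  expect_equal(d$fold_change, Inf)
  both0 <- one_window_sites(0, 60, 0, 60)
  expect_equal(nrow(call_dmrs(both0, "t1", "c1", context = "CHH")), 0L)
})

test_that("DMR q-values equal the BH step-up oracle over tested windows", {
  cfg <- small_sim_config(seed = 21)
  sim <- simulate_dataset(cfg)
  treat <- paste0("meth_10dpt_r", 1:2); ctrl <- paste0("meth_0dpt_r", 1:2)
  d <- call_dmrs(sim$meth, treat, ctrl, context = "CG", keep_all = TRUE,
                 chrom_lengths = sim$chrom_lengths)
  expect_equal(d$q, oracle_bh(d$p))
})

test_that("swapping treatment and control flips polarity but not p or q", {
  cfg <- small_sim_config(seed = 22)
  sim <- simulate_dataset(cfg)
  treat <- paste0("meth_10dpt_r", 1:2); ctrl <- paste0("meth_0dpt_r", 1:2)
  fwd <- call_dmrs(sim$meth, treat, ctrl, context = "CHH", keep_all = TRUE,
                   chrom_lengths = sim$chrom_lengths)
  rev <- call_dmrs(sim$meth, ctrl, treat, context = "CHH", keep_all = TRUE,
                   chrom_lengths = sim$chrom_lengths)
  key <- c("chrom", "start")
  fwd <- dplyr::arrange(tibble::as_tibble(fwd), chrom, start)
  rev <- dplyr::arrange(tibble::as_tibble(rev), chrom, start)
  expect_equal(fwd[key], rev[key])
  expect_equal(fwd$diff, -rev$diff)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  expect_equal(fwd$q, rev$q, tolerance = 1e-12)
  expect_equal(fwd$dmr, rev$dmr)
  called <- fwd$dmr
  expect_true(all(fwd$polarity[called] != rev$polarity[called]))
})

test_that("DMR distribution fractions are normalised within partitions", {
  genes <- toy_gene("gA", "Chr1", "+", 5001, 8000)
  te <- tibble::tibble(chrom = "Chr1", start = 1000L, end = 1000L)
  dmrs <- tibble::tibble(
    chrom = "Chr1", start = c(6001L, 1000L), end = c(7000L, 1999L),
    context = "CHH", level_treat = 50, level_ctrl = 10, diff = 40,
    fold_change = 5, p = 1e-6, q = 1e-5,
    polarity = "hyper", comparison = "x")
  dist <- dmr_distribution(dmrs, genes, te)
  genic <- dist[dist$partition == "genic", ]
  expect_equal(sort(genic$fraction), c(0.5, 0.5))
  te_part <- dist[dist$partition == "te", ]
  # the second DMR shares exactly 1 bp with the TE -> counted TE
  expect_equal(te_part$n[te_part$category == "TE"], 1L)
  for (p in unique(dist$partition)) {
    sub <- dist[dist$partition == p, ]
    for (pol in unique(sub$polarity)) {
      expect_equal(sum(sub$fraction[sub$polarity == pol]), 1)
    }
  }
})

test_that("CX reports round-trip and reject corrupt counts with line info", {
  sites <- tibble::tibble(chrom = "Chr1", pos = c(10L, 20L),
                          strand = c("+", "-"), context = c("CG", "CHH"),
                          meth = c(3L, 0L), total = c(10L, 7L))
  path <- withr::local_tempfile(fileext = ".CX_report.txt")
  write_cx_report(sites, path)
  back <- read_cx_report(path, sample_id = "s1")
  expect_equal(back[names(sites)], sites)
  expect_equal(unique(back$sample_id), "s1")

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Chr1\t10\t+\t3\t7\tCG\tCGA",
               "Chr1\t20\t+\t5\t-2\tCHH\tCAT"), bad)
  expect_error(read_cx_report(bad), "line 2")
})

test_that("metagene profile recovers a flat methylome and orients strands", {
  genes <- dplyr::bind_rows(toy_gene("gA", "Chr1", "+", 5001, 7000),
                            toy_gene("gB", "Chr1", "-", 15001, 17000))
  pos <- seq(3001L, 19000L, by = 25L)
  sites <- tibble::tibble(chrom = "Chr1", pos = pos, strand = "+",
                          context = "CG", meth = 4L, total = 10L)
  mg <- metagene_profile(sites, genes, context = "CG", n_bins = 5)
  expect_true(all(abs(mg$level - 40) < 1e-9))
  expect_setequal(as.character(unique(mg$segment)),
                  c("upstream", "body", "downstream"))
})
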