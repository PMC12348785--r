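dna <- function(...) {
  x <- c(...)
  Biostrings::DNAStringSet(setNames(x, names(x) %||% paste0("Chr",
                                                            seq_along(x))))
}

test_that("context calls follow the CG/CHG/CHH definition on both strands", {
  g <- dna(Chr1 = "ACGT")
  expect_equal(call_context(g, "Chr1", 2, "+"), "CG")
  expect_equal(call_context(dna(Chr1 = "CAGT"), "Chr1", 1, "+"), "CHG")
  expect_equal(call_context(dna(Chr1 = "CATT"), "Chr1", 1, "+"), "CHH")
  # C on the minus strand at the G of "ACGT": minus-oriented downstream is G
  expect_equal(call_context(g, "Chr1", 3, "-"), "CG")
  expect_equal(call_context(dna(Chr1 = "AAC"), "Chr1", 3, "+"),
               NA_character_)
  # N inside the needed window
  expect_equal(call_context(dna(Chr1 = "CNG"), "Chr1", 1, "+"),
               NA_character_)
})

test_that("context calling validates its inputs", {
  g <- dna(Chr1 = "ACGT")
  expect_error(call_context(g, "Chr1", 9, "+"), "bounds")
  expect_error(call_context(g, "Chr1", 1, "+"), "not a cytosine")
  expect_error(call_context(g, "Chr1", 2, "x"), "strand")
  expect_error(call_context(g, "ChrZ", 2, "+"), "unknown chromosome")
})

test_that("cytosine enumeration is exhaustive and NA-pads sequence ends", {
  cg <- enumerate_cytosines(dna(Chr1 = "CG"))
  expect_equal(nrow(cg), 2L)
  expect_equal(cg$context, c("CG", "CG"))
  expect_equal(cg$strand, c("+", "-"))

  ccc <- enumerate_cytosines(dna(Chr1 = "CCC"))
  expect_equal(ccc$context, c("CHH", NA, NA))

  set.seed(11)
  seq1 <- random_dna(1000)
  rec <- enumerate_cytosines(dna(Chr1 = seq1))
  chars <- strsplit(seq1, "")[[1]]
  expect_equal(nrow(rec), sum(chars == "C") + sum(chars == "G"))
})

test_that("context calls agree with the brute-force triplet oracle", {
  set.seed(12)
  for (i in 1:25) {
    seq1 <- random_dna(300)
    chars <- strsplit(seq1, "")[[1]]
    rec <- enumerate_cytosines(dna(Chr1 = seq1))
    want <- mapply(oracle_context, pos = rec$pos, strand = rec$strand,
                   MoreArgs = list(chars = chars))
    expect_identical(rec$context, unname(want))
  }
})

test_that("CG site count is even on every genome (palindromic dinucleotide)", {
  set.seed(13)
  for (i in 1:20) {
    rec <- enumerate_cytosines(dna(Chr1 = random_dna(500)))
    expect_equal(sum(rec$context == "CG", na.rm = TRUE) %% 2, 0)
  }
})

test_that("promoters are strand-aware and clamped to the chromosome", {
  spec <- region_spec()
  gplus <- toy_gene("gp", "Chr1", "+", 10001, 12000)
  gminus <- toy_gene("gm", "Chr1", "-", 8001, 10001)
  expect_equal(promoters_of(gplus, spec)[, c("start", "end")],
               tibble::tibble(start = 8001L, end = 10501L))
  expect_equal(promoters_of(gminus, spec)[, c("start", "end")],
               tibble::tibble(start = 9501L, end = 12001L))
  near <- toy_gene("gn", "Chr1", "+", 1000, 2000)
  expect_equal(promoters_of(near, spec)[, c("start", "end")],
               tibble::tibble(start = 1L, end = 1500L))
  capped <- promoters_of(gminus, spec, chrom_lengths = c(Chr1 = 11000L))
  expect_equal(capped$end, 11000L)
})

test_that("mirrored genes give mirrored promoters", {
  spec <- region_spec()
  L <- 50000L
  set.seed(14)
  for (i in 1:10) {
    tss <- sample(5000L:45000L, 1)
    tss_m <- L - tss + 1L
    p <- promoters_of(toy_gene("a", "Chr1", "+", tss, tss + 100L), spec)
    m <- promoters_of(toy_gene("a", "Chr1", "-", tss_m - 100L, tss_m),
                      spec)
    # the minus-strand promoter is the coordinate mirror of the plus one
    expect_equal(m$start, L - p$end + 1L)
    expect_equal(m$end, L - p$start + 1L)
  }
})

test_that("region assignment partitions positions with stable precedence", {
  genes <- dplyr::bind_rows(
    toy_gene("gA", "Chr1", "+", 5001, 8000,
             exons = tibble::tibble(start = c(5001L, 7001L),
                                    end = c(6000L, 8000L)),
             five_utr = tibble::tibble(start = 5001L, end = 5200L),
             three_utr = tibble::tibble(start = 7801L, end = 8000L)),
    toy_gene("gB", "Chr1", "+", 20001, 21000)
  )
  spec <- region_spec()
  pos <- tibble::tibble(
    chrom = "Chr1",
    pos = c(5100L, 5500L, 6500L, 7900L, 4900L, 8100L, 15000L))
  got <- assign_region(pos, genes, spec)
  expect_equal(got$region, c("5UTR", "exon", "intron", "3UTR",
                             "upstream2k", "downstream2k", "intergenic"))
  # exactly one label each, stable under gene-list permutation
  got2 <- assign_region(pos, genes[c(2, 1), ], spec)
  expect_identical(got$region, got2$region)
  expect_identical(got$region_gene, got2$region_gene)
})

test_that("gene-body labels beat flank labels of a neighbouring gene", {
  genes <- dplyr::bind_rows(
    toy_gene("gA", "Chr1", "+", 1001, 2000),
    toy_gene("gB", "Chr1", "+", 2500, 4000)
  )
  # inside gA's body (a single whole-span exon) and gB's upstream flank:
  # the body label wins over the neighbour's flank
  got <- assign_region(tibble::tibble(chrom = "Chr1", pos = 1500L), genes)
  expect_equal(got$region, "exon")
  expect_equal(got$region_gene, "gA")
})

test_that("interval overlap is 1-based closed arithmetic", {
  expect_true(interval_overlaps(1, 10, 10, 20))
  expect_false(interval_overlaps(1, 10, 11, 20))
  expect_true(interval_overlaps(5, 6, 1, 100))
  expect_false(interval_overlaps(1, 10, 5, 8, "Chr1", "Chr2"))
})

test_that("GFF3 gene models round-trip through write and read", {
  genes <- dplyr::bind_rows(
    toy_gene("gA", "Chr1", "+", 5001, 8000,
             exons = tibble::tibble(start = c(5001L, 7001L),
                                    end = c(6000L, 8000L)),
             five_utr = tibble::tibble(start = 5001L, end = 5200L),
             three_utr = tibble::tibble(start = 7801L, end = 8000L)),
    toy_gene("gB", "Chr1", "-", 20001, 21000)
  )
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(genes, path)
  back <- read_gene_models(path)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$tss, genes$tss)
  expect_equal(back$exons[[1]], genes$exons[[1]])
  expect_equal(back$five_utr[[1]], genes$five_utr[[1]])
})

test_that("BED TE intervals convert to 1-based inclusive on load", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("Chr1\t100\t200", path)
  te <- read_te_bed(path)
  expect_equal(te$start, 101L)
  expect_equal(te$end, 200L)
})
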