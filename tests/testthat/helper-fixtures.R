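# Shared fixtures built in code at test time.

# small but complete coupled simulation used by several integration tests
small_sim_config <- function(seed = 7, ...) {
  args <- list(seed = seed, n_chrom = 1, chrom_len = 100000, n_genes = 50,
               n_tes = 25, n_planted_dmr = 6, n_planted_dsr = 12,
               n_planted_deg = 16, n_planted_rddm = 3, n_clusters = 20)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# gene-model tibble builder for refmodel/integration unit tests
toy_gene <- function(gene_id, chrom, strand, start, end,
                     exons = NULL, five_utr = NULL, three_utr = NULL) {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(end),
    tss = as.integer(if (strand == "+") start else end),
    tes = as.integer(if (strand == "+") end else start),
    exons = list(exons %||% tibble::tibble(start = as.integer(start),
                                           end = as.integer(end))),
    five_utr = list(five_utr %||% tibble::tibble(start = integer(),
                                                 end = integer())),
    three_utr = list(three_utr %||% tibble::tibble(start = integer(),
                                                   end = integer())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-window methylome: two samples per group with the given pooled
# counts placed on CHH sites inside window [1, 1000] of a 2 kb chromosome
one_window_sites <- function(meth_t, total_t, meth_c, total_c,
                             context = "CHH") {
  mk <- function(sample_id, meth, total) {
    tibble::tibble(sample_id = sample_id, chrom = "Chr1",
                   pos = c(101L, 201L), strand = "+", context = context,
                   meth = c(meth %/% 2, meth - meth %/% 2),
                   total = c(total %/% 2, total - total %/% 2))
  }
  dplyr::bind_rows(mk("t1", meth_t, total_t), mk("c1", meth_c, total_c))
}

# a differential result with hand-set fields, for integrate tests
fake_diff <- function(feature_id, log2fc, direction, size_class = "24nt",
                      comparison = "10dpt_vs_0dpt", q = 0.01) {
  out <- tibble::tibble(feature_id = feature_id,
                        mean_treat = NA_real_, mean_ctrl = NA_real_,
                        log2fc = log2fc, p = q, q = q,
                        direction = direction, size_class = size_class,
                        underpowered = FALSE)
  attr(out, "comparison") <- comparison
  class(out) <- c("rddm_diff", class(out))
  out
}
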