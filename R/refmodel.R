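# Reference model: genome, cytosine contexts, gene models, promoters and
# functional-region assignment. All coordinates at the interface are 1-based
# inclusive; BED input is converted on load.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Read a reference genome from FASTA
#'
#' @param path FASTA file (multi-record, wrapped lines allowed).
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  validate_genome(genome)
}

validate_genome <- function(genome) {
  if (anyDuplicated(names(genome))) abort("duplicate chromosome names in genome")
  freq <- Biostrings::alphabetFrequency(genome)
  bad <- rowSums(freq[, setdiff(colnames(freq), c("A", "C", "G", "T", "N")),
                      drop = FALSE])
  if (any(bad > 0)) abort("genome sequences may contain only A, C, G, T, N")
  genome
}

#' Chromosome lengths of a genome
#' @param genome A [Biostrings::DNAStringSet].
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

# indexing into a character vector with out-of-range positions -> NA
chars_at <- function(ch, i) {
  out <- rep(NA_character_, length(i))
  ok <- i >= 1L & i <= length(ch)
  out[ok] <- ch[i[ok]]
  out
}

# context from the two strand-oriented downstream bases (NA where a base is
# missing). A CG call needs only the first downstream base; CHG/CHH need two.
context_from_downstream <- function(n1, n2) {
  ctx <- rep(NA_character_, length(n1))
  isH <- function(x) !is.na(x) & x %in% c("A", "C", "T")
  ctx[!is.na(n1) & n1 == "G"] <- "CG"
  ctx[isH(n1) & !is.na(n2) & n2 == "G"] <- "CHG"
  ctx[isH(n1) & isH(n2)] <- "CHH"
  ctx
}

genome_chars <- function(genome, chrom) {
  if (!chrom %in% names(genome)) abort(paste0("unknown chromosome: ", chrom))
  strsplit(as.character(genome[[chrom]]), "", fixed = TRUE)[[1]]
}

#' Call the cytosine context at given positions
#'
#' For a cytosine read 5'->3' on the given strand, returns `"CG"` if the next
#' base is G, `"CHG"` if the next base is H (A/C/T) and the following one G,
#' `"CHH"` if both following bases are H, and `NA` when the context cannot be
#' resolved (too close to the sequence end, or an N in the required window).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom,pos,strand Vectors (recycled) of chromosome, 1-based position
#'   and strand (`"+"` or `"-"`). The base at each position on the given
#'   strand must be a cytosine.
#' @return Character vector of `"CG"`, `"CHG"`, `"CHH"` or `NA`.
#' @export
call_context <- function(genome, chrom, pos, strand) {
  len <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, len); pos <- rep_len(as.integer(pos), len)
  strand <- rep_len(strand, len)
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  out <- rep(NA_character_, len)
  for (chr in unique(chrom)) {
    ch <- genome_chars(genome, chr)
    sel <- which(chrom == chr)
    p <- pos[sel]
    if (any(p < 1L | p > length(ch))) abort("position out of chromosome bounds")
    plus <- strand[sel] == "+"
    base <- ch[p]
    want <- ifelse(plus, "C", "G")
    if (any(base != want)) {
      abort("base is not a cytosine on the given strand")
    }
    n1 <- n2 <- rep(NA_character_, length(p))
    n1[plus] <- chars_at(ch, p[plus] + 1L)
    n2[plus] <- chars_at(ch, p[plus] + 2L)
    n1[!plus] <- unname(COMP[chars_at(ch, p[!plus] - 1L)])
    n2[!plus] <- unname(COMP[chars_at(ch, p[!plus] - 2L)])
    out[sel] <- context_from_downstream(n1, n2)
  }
  out
}

#' Enumerate every cytosine in a genome with its context
#'
#' Emits one record per C on the plus strand and one per G (a cytosine on the
#' minus strand), with the strand-oriented context call and trinucleotide.
#' Sites whose context cannot be resolved are retained with `context = NA`.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Tibble with columns `chrom`, `pos`, `strand`, `context`,
#'   `trinucleotide`.
#' @export
enumerate_cytosines <- function(genome) {
  out <- purrr::map(names(genome), function(chr) {
    ch <- genome_chars(genome, chr)
    plus <- which(ch == "C")
    minus <- which(ch == "G")
    p1 <- chars_at(ch, plus + 1L); p2 <- chars_at(ch, plus + 2L)
    m1 <- unname(COMP[chars_at(ch, minus - 1L)])
    m2 <- unname(COMP[chars_at(ch, minus - 2L)])
    df <- tibble(
      chrom = chr,
      pos = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      context = c(context_from_downstream(p1, p2),
                  context_from_downstream(m1, m2)),
      trinucleotide = paste0("C",
                             dplyr::coalesce(c(p1, m1), "N"),
                             dplyr::coalesce(c(p2, m2), "N"))
    )
    arrange(df, .data$pos, .data$strand)
  })
  bind_rows(out)
}

#' Region geometry parameters
#'
#' Defines the widths, in bp, of the gene-flank and promoter windows used
#' throughout: the promoter is 2 kb upstream through 500 bp downstream of the
#' TSS (strand-aware), and the "TSS region" used for DMR localisation is
#' `tss +/- tss_window`.
#'
#' @param upstream_flank,downstream_flank Gene flank widths for region
#'   profiles (bp, default 2000).
#' @param promoter_up,promoter_down Promoter extent up/downstream of the TSS
#'   (bp, defaults 2000 and 500).
#' @param tss_window Half-width of the TSS region (bp, default 1000).
#' @return A `region_spec` list.
#' @export
region_spec <- function(upstream_flank = 2000, downstream_flank = 2000,
                        promoter_up = 2000, promoter_down = 500,
                        tss_window = 1000) {
  vals <- c(upstream_flank, downstream_flank, promoter_up, promoter_down,
            tss_window)
  if (any(vals <= 0)) abort("all region_spec widths must be strictly positive")
  structure(list(upstream_flank = as.integer(upstream_flank),
                 downstream_flank = as.integer(downstream_flank),
                 promoter_up = as.integer(promoter_up),
                 promoter_down = as.integer(promoter_down),
                 tss_window = as.integer(tss_window)),
            class = "region_spec")
}

#' Strand-aware promoter windows for a set of genes
#'
#' The promoter of a gene runs `promoter_up` bp upstream of the TSS through
#' `promoter_down` bp downstream of it, in gene orientation, clamped to the
#' chromosome.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `strand`, `tss`.
#' @param spec A [region_spec()].
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   clamp the upper bound.
#' @return Tibble `gene_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
promoters_of <- function(genes, spec = region_spec(), chrom_lengths = NULL) {
  assert_columns(genes, c("gene_id", "chrom", "strand", "tss"), "genes")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - spec$promoter_up,
                  genes$tss - spec$promoter_down)
  end <- ifelse(plus, genes$tss + spec$promoter_down,
                genes$tss + spec$promoter_up)
  start <- pmax(1L, as.integer(start))
  end <- as.integer(end)
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, as.integer(chrom_lengths[genes$chrom]))
  }
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = start, end = end)
}

# Long table of labelled gene-anchored intervals with label precedence:
# 5UTR > 3UTR > exon > intron (gene span) > upstream2k > downstream2k.
# Gene-body labels therefore beat flank labels of a neighbouring gene; ties
# within a priority class are broken by smaller gene start, then gene_id.
gene_feature_table <- function(genes, spec = region_spec(),
                               chrom_lengths = NULL) {
  assert_columns(genes, c("gene_id", "chrom", "strand", "start", "end"),
                 "genes")
  unpack <- function(col, label, prio) {
    if (!col %in% names(genes)) return(NULL)
    purrr::pmap(list(genes$gene_id, genes$chrom, genes[[col]], genes$start),
                function(gid, chr, iv, gstart) {
      if (is.null(iv) || nrow(iv) == 0L) return(NULL)
      tibble(gene_id = gid, chrom = chr, start = iv$start, end = iv$end,
             label = label, priority = prio, gene_start = gstart)
    }) %>% bind_rows()
  }
  plus <- genes$strand == "+"
  up_start <- ifelse(plus, genes$start - spec$upstream_flank, genes$end + 1L)
  up_end <- ifelse(plus, genes$start - 1L, genes$end + spec$upstream_flank)
  dn_start <- ifelse(plus, genes$end + 1L, genes$start - spec$downstream_flank)
  dn_end <- ifelse(plus, genes$end + spec$downstream_flank, genes$start - 1L)
  flanks <- tibble(
    gene_id = rep(genes$gene_id, 2L),
    chrom = rep(genes$chrom, 2L),
    start = c(up_start, dn_start),
    end = c(up_end, dn_end),
    label = rep(c("upstream2k", "downstream2k"), each = nrow(genes)),
    priority = rep(c(5L, 6L), each = nrow(genes)),
    gene_start = rep(genes$start, 2L)
  )
  feats <- bind_rows(
    unpack("five_utr", "5UTR", 1L),
    unpack("three_utr", "3UTR", 2L),
    unpack("exons", "exon", 3L),
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           start = genes$start, end = genes$end, label = "intron",
           priority = 4L, gene_start = genes$start),
    flanks
  )
  feats <- mutate(feats, start = pmax(1L, as.integer(start)),
                  end = as.integer(end))
  if (!is.null(chrom_lengths)) {
    feats <- mutate(feats,
                    end = pmin(.data$end,
                               as.integer(chrom_lengths[.data$chrom])))
  }
  filter(feats, .data$end >= .data$start)
}

#' Assign genomic positions to functional regions
#'
#' Labels each position as one of `upstream2k`, `5UTR`, `exon`, `intron`,
#' `3UTR`, `downstream2k` or `intergenic`. Exactly one label is returned per
#' position; when memberships overlap, gene-body labels beat flank labels,
#' UTR beats exon, and ties among genes are broken by smaller gene start then
#' lexicographic `gene_id`, so the labelling is stable under permutation of
#' the gene list.
#'
#' @param positions Tibble with `chrom` and `pos` columns.
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param spec A [region_spec()].
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return `positions` with `region` and `region_gene` columns added.
#' @export
assign_region <- function(positions, genes, spec = region_spec(),
                          chrom_lengths = NULL) {
  assert_columns(positions, c("chrom", "pos"), "positions")
  feats <- gene_feature_table(genes, spec, chrom_lengths)
  pts <- tibble(chrom = positions$chrom, start = positions$pos,
                end = positions$pos)
  hits <- overlap_pairs(pts, feats)
  best <- hits %>%
    mutate(priority = feats$priority[.data$b_idx],
           gene_start = feats$gene_start[.data$b_idx],
           gene_id = feats$gene_id[.data$b_idx],
           label = feats$label[.data$b_idx]) %>%
    arrange(.data$a_idx, .data$priority, .data$gene_start, .data$gene_id) %>%
    distinct(.data$a_idx, .keep_all = TRUE)
  region <- rep("intergenic", nrow(positions))
  region_gene <- rep(NA_character_, nrow(positions))
  region[best$a_idx] <- best$label
  region_gene[best$a_idx] <- best$gene_id
  mutate(positions, region = region, region_gene = region_gene)
}

#' Read gene models from GFF3
#'
#' Uses `gene`, `mRNA`, `exon`, `five_prime_UTR` and `three_prime_UTR`
#' features; for genes with several mRNAs the first (smallest start, then ID)
#' is used. Genes without annotated UTRs get empty UTR sets; the gene body is
#' then exons plus introns.
#'
#' @param path GFF3 file.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`, `tes` and list-columns `exons`, `five_utr`, `three_utr` (each a
#'   tibble of `start`, `end`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr)) %>%
    mutate(seqnames = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           type = as.character(.data$type))
  genes <- filter(df, .data$type == "gene")
  if (nrow(genes) == 0L) abort("no gene features in GFF3")
  mrna <- filter(df, .data$type == "mRNA")
  # map every child Parent to a gene id (children may point at mRNA or gene)
  mrna_parent <- setNames(as.character(unlist(mrna$Parent)), mrna$ID)
  pick <- mrna %>%
    mutate(gene_id = mrna_parent[.data$ID]) %>%
    arrange(.data$gene_id, .data$start, .data$ID) %>%
    distinct(.data$gene_id, .keep_all = TRUE)
  keep_tx <- setNames(pick$ID, pick$gene_id)
  child_gene <- function(parent) {
    p <- as.character(parent)
    out <- ifelse(p %in% names(mrna_parent), unname(mrna_parent[p]), p)
    out
  }
  children <- filter(df, .data$type %in%
                       c("exon", "five_prime_UTR", "three_prime_UTR")) %>%
    mutate(parent = purrr::map_chr(.data$Parent, function(p)
      if (length(p) == 0L) NA_character_ else as.character(p)[1]),
           gene_id = child_gene(.data$parent)) %>%
    # keep only children of the selected transcript (or direct gene children)
    filter(is.na(.data$parent) | !.data$parent %in% names(mrna_parent) |
             .data$parent == unname(keep_tx[.data$gene_id]))
  iv_of <- function(gid, typ) {
    sub <- filter(children, .data$gene_id == gid, .data$type == typ) %>%
      arrange(.data$start)
    tibble(start = as.integer(sub$start), end = as.integer(sub$end))
  }
  genes %>%
    arrange(.data$seqnames, .data$start) %>%
    mutate(gene_id = as.character(.data$ID)) %>%
    (function(g) mutate(g,
       exons = purrr::map(.data$gene_id, iv_of, typ = "exon"),
       five_utr = purrr::map(.data$gene_id, iv_of, typ = "five_prime_UTR"),
       three_utr = purrr::map(.data$gene_id, iv_of, typ = "three_prime_UTR")
    )) %>%
    mutate(tss = if_else(.data$strand == "+", .data$start, .data$end),
           tes = if_else(.data$strand == "+", .data$end, .data$start)) %>%
    select(gene_id = "gene_id", chrom = "seqnames", strand = "strand",
           start = "start", end = "end", tss = "tss", tes = "tes",
           exons = "exons", five_utr = "five_utr", three_utr = "three_utr") %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end),
           tss = as.integer(.data$tss), tes = as.integer(.data$tes))
}

#' Read transposable-element intervals from BED
#'
#' BED is 0-based half-open on disk; intervals are converted to 1-based
#' inclusive on load.
#'
#' @param path BED file (first three columns used).
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_te_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr))
}
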