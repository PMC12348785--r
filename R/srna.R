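# Small-RNA quantification: the 18-30 nt length filter, per-sample length
# distributions, fixed-width (default 1 kb) genomic clusters keyed by the
# "chrom;start;end" id convention, and CPM normalisation.

#' Read an sRNA read table
#'
#' Expects a TSV with columns `chrom`, `pos5` (1-based 5' end), `strand`,
#' `length`, followed by one count column per sample (column name = sample
#' id). Reads outside the 18-30 nt window are removed, mirroring the standard
#' trimming filter.
#'
#' @param path TSV file.
#' @param length_range Kept length range in nt (default `c(18, 30)`).
#' @return Long tibble `chrom`, `pos5`, `strand`, `length`, `sample_id`,
#'   `count`.
#' @export
read_srna_table <- function(path, length_range = c(18L, 30L)) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos5 = "i", strand = "c", length = "i",
    .default = "d"), progress = FALSE)
  assert_columns(df, c("chrom", "pos5", "strand", "length"), "sRNA table")
  long <- tidyr::pivot_longer(df, -c("chrom", "pos5", "strand", "length"),
                              names_to = "sample_id", values_to = "count")
  filter_srna_lengths(long, length_range)
}

#' Write an sRNA read table (long to wide TSV)
#' @param reads Long read tibble (see [read_srna_table()]).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_srna_table <- function(reads, path) {
  wide <- tidyr::pivot_wider(reads, names_from = "sample_id",
                             values_from = "count", values_fill = 0)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Filter sRNA reads to a length window
#' @param reads Long read tibble with a `length` column.
#' @param length_range Inclusive nt bounds (default 18-30).
#' @return Filtered tibble.
#' @export
filter_srna_lengths <- function(reads, length_range = c(18L, 30L)) {
  filter(reads, .data$length >= length_range[1],
         .data$length <= length_range[2])
}

#' Count-weighted sRNA length distribution per sample
#'
#' @param reads Long read tibble (`length`, `sample_id`, `count`).
#' @return Tibble `sample_id`, `length`, `proportion`; proportions sum to 1
#'   within each sample.
#' @export
srna_length_distribution <- function(reads, length_range = c(18L, 30L)) {
  assert_columns(reads, c("length", "sample_id", "count"), "reads")
  if (nrow(reads) == 0L) abort("no sRNA reads")
  totals <- reads %>% group_by(.data$sample_id) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort(paste0("sample(s) with zero sRNA reads: ",
                 paste(totals$sample_id[totals$total <= 0], collapse = ", ")))
  }
  grid <- tidyr::expand_grid(sample_id = totals$sample_id,
                             length = seq(length_range[1], length_range[2]))
  reads %>%
    group_by(.data$sample_id, .data$length) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    dplyr::right_join(grid, by = c("sample_id", "length")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0)) %>%
    left_join(totals, by = "sample_id") %>%
    mutate(proportion = .data$count / .data$total) %>%
    select("sample_id", "length", "proportion") %>%
    arrange(.data$sample_id, .data$length)
}

#' Cluster id of a genomic bin
#' @param chrom,start,end Bin coordinates (1-based inclusive).
#' @return Character ids of the form `"Chr6;2121001;2122000"`.
#' @export
cluster_id <- function(chrom, start, end) {
  sprintf("%s;%d;%d", chrom, as.integer(start), as.integer(end))
}

#' Bin sRNA reads into fixed-width genomic clusters
#'
#' Each read is assigned to the bin containing its 5' end (so each read
#' counts exactly once); bin k covers positions `[k*w + 1, (k+1)*w]`
#' (1-based inclusive). Bins with no reads are omitted.
#'
#' @param reads Long read tibble.
#' @param bin_width Bin width in bp (default 1000).
#' @return Tibble `cluster_id`, `chrom`, `start`, `end`, `sample_id`,
#'   `length`, `count`.
#' @export
bin_srna_reads <- function(reads, bin_width = 1000L) {
  assert_columns(reads, c("chrom", "pos5", "sample_id", "length", "count"),
                 "reads")
  reads %>%
    mutate(start = as.integer(((.data$pos5 - 1L) %/% bin_width) * bin_width
                              + 1L),
           end = .data$start + as.integer(bin_width) - 1L,
           cluster_id = cluster_id(.data$chrom, .data$start, .data$end)) %>%
    group_by(.data$cluster_id, .data$chrom, .data$start, .data$end,
             .data$sample_id, .data$length) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$chrom, .data$start, .data$sample_id, .data$length)
}

# per-class feature x sample counts from binned clusters; "20-22nt" pools
# lengths 20-22, "24nt" is length 24 exactly, "all" pools every length
cluster_class_counts <- function(clusters, size_class = "all") {
  sel <- switch(size_class,
                "all" = clusters,
                "20-22nt" = filter(clusters, .data$length %in% 20:22),
                "24nt" = filter(clusters, .data$length == 24L),
                abort(paste0("unknown size class: ", size_class)))
  sel %>%
    group_by(feature_id = .data$cluster_id, .data$sample_id) %>%
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Cluster coordinate table from binned reads
#' @param clusters Output of [bin_srna_reads()].
#' @return One row per cluster: `cluster_id`, `chrom`, `start`, `end`.
#' @export
cluster_coords <- function(clusters) {
  distinct(clusters, .data$cluster_id, .data$chrom, .data$start, .data$end)
}

#' Counts-per-million normalisation
#'
#' Scales each sample (column) to one million: `count * 1e6 / column total`.
#'
#' @param counts Numeric matrix (features x samples) or a long tibble with
#'   `sample_id` and `count` columns.
#' @param libsize Optional named per-sample library sizes; defaults to the
#'   column totals. Useful when a size-class subset should be normalised by
#'   the full library.
#' @return Same shape as the input with counts replaced by CPM (long input
#'   gains a `cpm` column).
#' @export
cpm <- function(counts, libsize = NULL) {
  if (is.matrix(counts)) {
    tot <- libsize %||% colSums(counts)
    if (!is.null(colnames(counts)) && !is.null(names(tot))) {
      tot <- tot[colnames(counts)]
    }
    if (any(is.na(tot) | tot <= 0)) {
      bad <- colnames(counts)[is.na(tot) | tot <= 0]
      abort(paste0("zero (or missing) library size for sample(s): ",
                   paste(bad %||% which(tot <= 0), collapse = ", ")))
    }
    return(sweep(counts, 2L, tot, "/") * 1e6)
  }
  assert_columns(counts, c("sample_id", "count"), "counts")
  if (is.null(libsize)) {
    libsize <- counts %>% group_by(.data$sample_id) %>%
      summarise(libsize = sum(.data$count), .groups = "drop") %>%
      (function(d) setNames(d$libsize, d$sample_id))
  }
  tot <- libsize[counts$sample_id]
  if (any(is.na(tot) | tot <= 0)) {
    bad <- unique(counts$sample_id[is.na(tot) | tot <= 0])
    abort(paste0("zero (or missing) library size for sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  mutate(counts, cpm = .data$count * 1e6 / unname(tot))
}

#' Read a gene count matrix TSV
#' @param path TSV with a `gene_id` column then one column per sample.
#' @return Long tibble `feature_id`, `sample_id`, `count`.
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(gene_id = "c",
                                                      .default = "d"),
                        progress = FALSE)
  assert_columns(df, "gene_id", "count matrix")
  tidyr::pivot_longer(df, -"gene_id", names_to = "sample_id",
                      values_to = "count") %>%
    rename(feature_id = "gene_id")
}

#' Read a sample sheet TSV
#' @param path TSV with columns `sample_id`, `timepoint_dpt`, `replicate`,
#'   `assay`.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, col_types = "ciic", progress = FALSE)
  assert_columns(df, c("sample_id", "timepoint_dpt", "replicate", "assay"),
                 "sample sheet")
  df
}

#' Sample ids for an assay at a timepoint
#' @param samples Sample sheet tibble.
#' @param assay Assay name (`"wgbs"`, `"srna"`, `"rna"`).
#' @param timepoint_dpt Timepoint in days post treatment.
#' @return Character vector of sample ids.
#' @export
samples_at <- function(samples, assay, timepoint_dpt) {
  out <- samples %>%
    filter(.data$assay == !!assay,
           .data$timepoint_dpt == !!timepoint_dpt) %>%
    pull("sample_id")
  if (length(out) == 0L) {
    abort(sprintf("no %s samples at %s dpt", assay, timepoint_dpt))
  }
  out
}
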