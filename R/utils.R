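# Internal helpers shared across modules.

# let data.table's `[` dispatch work inside the package namespace
.datatable.aware <- TRUE

# 1-based inclusive interval overlap; different chromosomes never overlap.
# Exported because downstream joins and the candidate screen are defined in
# terms of ">= 1 bp overlap" and users may want the same predicate.

#' Do two 1-based inclusive intervals overlap?
#'
#' Intervals are closed, i.e. `[1, 10]` and `[10, 20]` share one base and
#' therefore overlap. Intervals on different chromosomes never overlap.
#' All arguments are vectorised and recycled.
#'
#' @param start1,end1 First interval bounds (1-based inclusive).
#' @param start2,end2 Second interval bounds (1-based inclusive).
#' @param chrom1,chrom2 Optional chromosome names; if supplied, positions on
#'   different chromosomes return `FALSE`.
#' @return Logical vector.
#' @examples
#' interval_overlaps(1, 10, 10, 20) # TRUE, one shared base
#' interval_overlaps(1, 10, 11, 20) # FALSE
#' @export
interval_overlaps <- function(start1, end1, start2, end2,
                              chrom1 = NULL, chrom2 = NULL) {
  hit <- start1 <= end2 & start2 <= end1
  if (!is.null(chrom1) || !is.null(chrom2)) {
    stopifnot(!is.null(chrom1), !is.null(chrom2))
    hit <- hit & (chrom1 == chrom2)
  }
  hit
}

# Width of the intersection of two closed intervals (0 if disjoint).
overlap_width <- function(start1, end1, start2, end2) {
  pmax(0L, pmin(end1, end2) - pmax(start1, start2) + 1L)
}

# Overlap join between two interval tables on (chrom, start, end), returning
# index pairs. Thin wrapper over IRanges::findOverlaps so every module shares
# one audited overlap definition (1-based closed, >= minoverlap bases).
overlap_pairs <- function(a, b, minoverlap = 1L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(a)),
            all(c("chrom", "start", "end") %in% names(b)))
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble(a_idx = integer(), b_idx = integer()))
  }
  gra <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
  grb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end))
  hits <- GenomicRanges::findOverlaps(gra, grb, minoverlap = minoverlap)
  tibble(a_idx = S4Vectors::queryHits(hits), b_idx = S4Vectors::subjectHits(hits))
}

# Derive a stage-specific RNG seed from a master seed, kept inside 32-bit
# integer range. Distinct stages get independent streams so, e.g., changing
# the number of genes does not perturb methylome draws.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- c(genome = 101L, genes = 211L, te = 307L, meth = 401L,
            srna = 503L, expr = 601L, misc = 701L)
  if (!stage %in% names(offs)) abort(paste0("unknown seed stage: ", stage))
  as.integer((abs(as.numeric(seed)) %% 2101000) * 1000 + offs[[stage]])
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# attribute helpers for result classes -------------------------------------

new_result_tbl <- function(df, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(df, nm) <- attrs[[nm]]
  class(df) <- c(class, class(df))
  df
}

result_attr <- function(x, name) attr(x, name, exact = TRUE)
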