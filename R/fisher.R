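#' Vectorised two-sided Fisher exact test for 2x2 tables
#'
#' Computes the two-sided Fisher exact p-value for tables
#' `[[a, b], [c, d]]` by summing, over the hypergeometric support defined by
#' the table margins, every outcome whose probability does not exceed that of
#' the observed table (with the conventional `1 + 1e-7` tie tolerance, the
#' same rule used by [stats::fisher.test()]). All four arguments are
#' vectorised; tables sharing margins share one support enumeration, so the
#' function stays fast for large batches of genomic windows.
#'
#' @param a,b,c,d Non-negative integer cell counts; `a` and `b` form the
#'   first row, `c` and `d` the second.
#' @return Numeric vector of two-sided p-values in `(0, 1]`.
#' @examples
#' fisher_exact_2x2(48, 12, 12, 48)
#' all.equal(fisher_exact_2x2(10, 5, 2, 20),
#'           stats::fisher.test(matrix(c(10, 2, 5, 20), 2))$p.value)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- as.numeric(rep_len(a, len)); b <- as.numeric(rep_len(b, len))
  c <- as.numeric(rep_len(c, len)); d <- as.numeric(rep_len(d, len))
  if (any(is.na(c(a, b, c, d)))) abort("NA cell counts in 2x2 table")
  if (any(c(a, b, c, d) < 0)) abort("negative cell counts in 2x2 table")

  q <- data.table::data.table(m = a + b, n = c + d, k = a + c, x = a,
                              qid = seq_len(len))
  sup <- fisher_support_p(unique(q[, list(m, n, k)]))
  res <- sup[q, on = c("m", "n", "k", "x")]
  data.table::setorder(res, qid)
  pmin(res$p, 1)
}

# Two-sided p for every point of the hypergeometric support of each margin
# triple (m = row1 total, n = row2 total, k = col1 total). Returns a
# data.table with columns m, n, k, x, p.
fisher_support_p <- function(u) {
  u <- data.table::as.data.table(u)
  u[, `:=`(lo = pmax(0, k - n), hi = pmin(k, m))]
  u[, s := hi - lo + 1]
  exp <- u[rep(seq_len(nrow(u)), u$s)]
  exp[, x := lo + sequence(u$s) - 1]
  exp[, pr := dhyper(x, m, n, k)]
  exp[, gid := rep(seq_len(nrow(u)), u$s)]
  relerr <- 1 + 1e-7
  exp[, p := {
    o <- order(pr)
    prs <- pr[o]
    cp <- cumsum(prs)
    idx <- findInterval(prs * relerr, prs)
    out <- numeric(.N)
    out[o] <- cp[idx]
    out
  }, by = gid]
  exp[, list(m, n, k, x, p)]
}

# Odds ratio of [[a,b],[c,d]] with the Haldane-Anscombe +0.5 correction
# applied to every cell iff any cell is zero.
odds_ratio_2x2 <- function(a, b, c, d) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  adj <- ifelse(zero, 0.5, 0)
  ((a + adj) * (d + adj)) / ((b + adj) * (c + adj))
}
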