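# Independent oracles used to check the package's computations. These are
# deliberately written as direct, brute-force implementations, separate from
# the package's code paths.

# character-by-character triplet scan for the cytosine context, 5'->3' on
# the given strand; NA where the context cannot be resolved
oracle_context <- function(chars, pos, strand) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  get <- function(i) {
    if (i >= 1 && i <= length(chars)) chars[i] else NA_character_
  }
  if (strand == "+") {
    n1 <- get(pos + 1); n2 <- get(pos + 2)
  } else {
    n1 <- unname(comp[get(pos - 1)]); n2 <- unname(comp[get(pos - 2)])
  }
  if (is.na(n1) || n1 == "N") return(NA_character_)
  if (n1 == "G") return("CG")
  if (is.na(n2) || n2 == "N") return(NA_character_)
  if (n2 == "G") return("CHG")
  "CHH"
}

# two-sided Fisher exact p by explicit enumeration of the hypergeometric
# support with lgamma-based log probabilities (no dhyper)
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  lprob <- function(x) {
    lgamma(m + 1) - lgamma(x + 1) - lgamma(m - x + 1) +
      lgamma(n + 1) - lgamma(k - x + 1) - lgamma(n - k + x + 1) -
      (lgamma(m + n + 1) - lgamma(k + 1) - lgamma(m + n - k + 1))
  }
  xs <- lo:hi
  pr <- exp(vapply(xs, lprob, numeric(1)))
  p_obs <- pr[match(a, xs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# textbook BH step-up by explicit sort
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

# closed-form Welch two-sample t-test
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
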