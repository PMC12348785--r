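# Differential testing shared by sRNA clusters (DSRs) and genes (DEGs):
# Welch t-test on log2(CPM + 1), BH correction per family, and the
# direction rule (up iff q <= alpha and log2FC >= 1; down mirrored).

# Welch t on log2(cpm + 1) per feature; returns lfc and raw p (q and
# direction are applied at family level so size classes can share a family).
welch_log2cpm <- function(counts, treat, ctrl, libsize = NULL) {
  assert_columns(counts, c("feature_id", "sample_id", "count"), "counts")
  miss <- setdiff(c(treat, ctrl), unique(counts$sample_id))
  if (length(miss) > 0L && is.null(libsize)) {
    abort(paste0("sample id(s) absent from counts: ",
                 paste(miss, collapse = ", ")))
  }
  norm <- cpm(filter(counts, .data$sample_id %in% c(treat, ctrl)),
              libsize = libsize)
  wide <- norm %>%
    mutate(val = log2(.data$cpm + 1)) %>%
    select("feature_id", "sample_id", "val") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "val",
                       values_fill = 0)
  for (s in setdiff(c(treat, ctrl), names(wide))) wide[[s]] <- 0
  xt <- as.matrix(wide[, treat, drop = FALSE])
  xc <- as.matrix(wide[, ctrl, drop = FALSE])
  mt <- rowMeans(xt); mc <- rowMeans(xc)
  lfc <- mt - mc
  underpowered <- length(treat) < 2L || length(ctrl) < 2L
  p <- rep(NA_real_, nrow(wide))
  if (!underpowered) {
    vt <- apply(xt, 1L, stats::var); vc <- apply(xc, 1L, stats::var)
    flat <- vt == 0 & vc == 0
    p[flat] <- if_else(lfc[flat] == 0, 1, 0)
    idx <- which(!flat)
    p[idx] <- vapply(idx, function(i) {
      tryCatch(t.test(xt[i, ], xc[i, ], var.equal = FALSE)$p.value,
               error = function(e) if (lfc[i] == 0) 1 else 0)
    }, numeric(1))
  }
  tibble(feature_id = wide$feature_id,
         mean_treat = mt, mean_ctrl = mc, log2fc = lfc, p = p,
         underpowered = underpowered)
}

# family-level BH + direction rule
finish_family <- function(df, alpha, min_abs_log2fc) {
  df %>%
    mutate(q = p.adjust(.data$p, method = "BH"),
           direction = dplyr::case_when(
             .data$underpowered & .data$log2fc >= min_abs_log2fc ~ "up",
             .data$underpowered & .data$log2fc <= -min_abs_log2fc ~ "down",
             !.data$underpowered & !is.na(.data$q) & .data$q <= alpha &
               .data$log2fc >= min_abs_log2fc ~ "up",
             !.data$underpowered & !is.na(.data$q) & .data$q <= alpha &
               .data$log2fc <= -min_abs_log2fc ~ "down",
             TRUE ~ "ns"))
}

#' Differential test between two groups of samples
#'
#' CPM-normalises the counts, takes `log2(CPM + 1)`, compares groups per
#' feature with a Welch two-sample t-test, applies BH correction across all
#' features of the call (one family), and labels each feature `up` (q <=
#' `alpha` and log2FC >= `min_abs_log2fc`), `down` (mirrored) or `ns`. The
#' log2 fold change is the difference of group means on the `log2(CPM + 1)`
#' scale. With fewer than two replicates in either group, p and q are `NA`
#' and the direction is decided by the fold change alone, flagged by the
#' `underpowered` column.
#'
#' @param counts Long tibble `feature_id`, `sample_id`, `count`.
#' @param treat,ctrl Character vectors of sample ids.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 1).
#' @param libsize Optional named library sizes for CPM (defaults to the
#'   per-sample totals of `counts`).
#' @param size_class Size-class label stored on the result (`"n/a"` for
#'   genes).
#' @param comparison Comparison label stored on the result.
#' @return Tibble (class `rddm_diff`): `feature_id`, `mean_treat`,
#'   `mean_ctrl` (group means of log2(CPM+1)), `log2fc`, `p`, `q`,
#'   `direction`, `size_class`, `underpowered`.
#' @export
call_diff <- function(counts, treat, ctrl, alpha = 0.05,
                      min_abs_log2fc = 1, libsize = NULL,
                      size_class = "n/a", comparison = "treat_vs_ctrl") {
  if (length(treat) == 0L || length(ctrl) == 0L) {
    abort("both treat and ctrl must name at least one sample")
  }
  res <- welch_log2cpm(counts, treat, ctrl, libsize) %>%
    mutate(size_class = size_class) %>%
    finish_family(alpha, min_abs_log2fc) %>%
    select("feature_id", "mean_treat", "mean_ctrl", "log2fc", "p", "q",
           "direction", "size_class", "underpowered")
  if (any(res$underpowered)) {
    warn("fewer than two replicates in a group: p/q are NA and direction is based on fold change only")
  }
  new_result_tbl(res, "rddm_diff", comparison = comparison,
                 alpha = alpha, min_abs_log2fc = min_abs_log2fc,
                 n_treat = length(treat), n_ctrl = length(ctrl))
}

#' Call differentially regulated sRNA clusters (DSRs)
#'
#' Tests binned sRNA clusters per size class (`all` lengths, `20-22nt`,
#' `24nt`) on CPM normalised by the full per-sample library (all lengths).
#' All size classes tested on the same clusters share one BH family; genes
#' are corrected separately (see [call_degs()]). Clusters with no reads in
#' the tested samples for a class are not tested in that class.
#'
#' @param clusters Binned reads from [bin_srna_reads()].
#' @param treat,ctrl Character vectors of sRNA sample ids.
#' @param size_classes Size classes to test.
#' @inheritParams call_diff
#' @return `rddm_diff` tibble with one row per cluster per size class.
#' @export
call_dsrs <- function(clusters, treat, ctrl,
                      size_classes = c("all", "20-22nt", "24nt"),
                      alpha = 0.05, min_abs_log2fc = 1,
                      comparison = "treat_vs_ctrl") {
  if (length(treat) == 0L || length(ctrl) == 0L) {
    abort("both treat and ctrl must name at least one sample")
  }
  lib <- clusters %>%
    filter(.data$sample_id %in% c(treat, ctrl)) %>%
    group_by(.data$sample_id) %>%
    summarise(libsize = sum(.data$count), .groups = "drop") %>%
    (function(d) setNames(d$libsize, d$sample_id))
  per_class <- purrr::map(size_classes, function(cl) {
    cc <- cluster_class_counts(clusters, cl) %>%
      filter(.data$sample_id %in% c(treat, ctrl))
    cc <- cc %>% group_by(.data$feature_id) %>%
      filter(sum(.data$count) > 0) %>% ungroup()
    if (nrow(cc) == 0L) return(NULL)
    welch_log2cpm(cc, treat, ctrl, libsize = lib) %>%
      mutate(size_class = cl)
  })
  res <- bind_rows(per_class) %>%
    finish_family(alpha, min_abs_log2fc) %>%
    select("feature_id", "mean_treat", "mean_ctrl", "log2fc", "p", "q",
           "direction", "size_class", "underpowered")
  new_result_tbl(res, "rddm_diff", comparison = comparison, alpha = alpha,
                 min_abs_log2fc = min_abs_log2fc, n_treat = length(treat),
                 n_ctrl = length(ctrl))
}

#' Call differentially expressed genes (DEGs)
#'
#' The gene-expression counterpart of [call_dsrs()]: Welch t on
#' log2(CPM + 1) with BH across genes (its own family) and the
#' |log2FC| >= 1, q <= 0.05 thresholds.
#'
#' @param counts Long gene count tibble (`feature_id`, `sample_id`,
#'   `count`).
#' @inheritParams call_diff
#' @param use_raw_p Threshold on raw p instead of BH q (off by default).
#' @return `rddm_diff` tibble.
#' @export
call_degs <- function(counts, treat, ctrl, alpha = 0.05,
                      min_abs_log2fc = 1, comparison = "treat_vs_ctrl",
                      use_raw_p = FALSE) {
  res <- call_diff(counts, treat, ctrl, alpha = alpha,
                   min_abs_log2fc = min_abs_log2fc,
                   size_class = "n/a", comparison = comparison)
  if (use_raw_p) {
    res <- res %>%
      mutate(direction = dplyr::case_when(
        .data$underpowered ~ .data$direction,
        !is.na(.data$p) & .data$p <= alpha &
          .data$log2fc >= min_abs_log2fc ~ "up",
        !is.na(.data$p) & .data$p <= alpha &
          .data$log2fc <= -min_abs_log2fc ~ "down",
        TRUE ~ "ns"))
  }
  res
}

#' Tabulate differential calls by size class and direction
#'
#' @param diff An `rddm_diff` tibble.
#' @return Tibble `size_class`, `up`, `down`, `ns`, `total`.
#' @export
dsr_summary <- function(diff) {
  if (nrow(diff) == 0L) {
    return(tibble(size_class = character(), up = integer(),
                  down = integer(), ns = integer(), total = integer()))
  }
  diff %>%
    count(.data$size_class, .data$direction) %>%
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L) %>%
    (function(d) {
      for (col in c("up", "down", "ns")) if (!col %in% names(d))
        d[[col]] <- 0L
      d
    }) %>%
    mutate(total = .data$up + .data$down + .data$ns) %>%
    select("size_class", "up", "down", "ns", "total")
}
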