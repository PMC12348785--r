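# Recovery metrics against a planted truth: used by the validation suite
# and the reproduction script to benchmark the callers on simulated data.

#' Recall and precision of DMR calls against a planted truth
#'
#' A called DMR matches a truth window when they overlap by at least 1 bp
#' and agree on context and polarity. Recall is the fraction of truth
#' windows matched by at least one call; precision the fraction of calls
#' matching at least one truth window.
#'
#' @param called DMR tibble (possibly several contexts bound together).
#' @param truth Truth tibble with `chrom`, `start`, `end`, `context`,
#'   `polarity`.
#' @return One-row tibble `recall`, `precision`, `n_truth`, `n_called`.
#' @export
dmr_recovery <- function(called, truth) {
  if (nrow(truth) == 0L) {
    return(tibble(recall = NA_real_, precision = NA_real_, n_truth = 0L,
                  n_called = nrow(called)))
  }
  hits <- overlap_pairs(called[c("chrom", "start", "end")],
                        truth[c("chrom", "start", "end")]) %>%
    filter(called$context[.data$a_idx] == truth$context[.data$b_idx],
           called$polarity[.data$a_idx] == truth$polarity[.data$b_idx])
  tibble(recall = length(unique(hits$b_idx)) / nrow(truth),
         precision = if (nrow(called) > 0L) {
           length(unique(hits$a_idx)) / nrow(called)
         } else NA_real_,
         n_truth = nrow(truth), n_called = nrow(called))
}

#' Recall and precision of differential calls against a planted truth
#'
#' Recall is the fraction of planted features whose called direction equals
#' the planted direction; precision the fraction of all up/down calls that
#' correspond to a planted feature with matching direction.
#'
#' @param diff `rddm_diff` tibble (filter to one size class first if
#'   needed).
#' @param truth Tibble with `feature_id` (or `gene_id`/`cluster_id`) and
#'   `direction`.
#' @return One-row tibble `recall`, `precision`, `n_truth`, `n_called`.
#' @export
diff_recovery <- function(diff, truth) {
  idcol <- intersect(c("feature_id", "cluster_id", "gene_id"), names(truth))
  if (length(idcol) == 0L) abort("truth must carry a feature id column")
  truth <- tibble(feature_id = truth[[idcol[1]]],
                  truth_direction = truth$direction)
  called <- filter(as_tibble(diff), .data$direction %in% c("up", "down"))
  joined <- inner_join(called, truth, by = "feature_id") %>%
    filter(.data$direction == .data$truth_direction)
  tibble(recall = nrow(joined) / nrow(truth),
         precision = if (nrow(called) > 0L) nrow(joined) / nrow(called)
                     else NA_real_,
         n_truth = nrow(truth), n_called = nrow(called))
}
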