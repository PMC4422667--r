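#' Percent unwinding of one helicase-assay replicate
#'
#' Gel-based unwinding assays report two band intensities per lane: the
#' displaced single strand (unwound product) and the remaining duplex
#' substrate. Percent unwinding is the per-lane normalization
#' `100 * ss / (ss + ds)`.
#'
#' @param signal_unwound,signal_duplex Non-negative band intensities;
#'   vectorized, pairwise.
#' @return Percent unwound in `[0, 100]`.
#' @examples
#' percent_unwound(50, 50)  # 50
#' @export
percent_unwound <- function(signal_unwound, signal_duplex) {
  ss <- as.numeric(signal_unwound)
  ds <- as.numeric(signal_duplex)
  if (anyNA(ss) || anyNA(ds) || any(ss < 0) || any(ds < 0))
    fv_stop("band signals must be non-negative numbers",
            "famvar_domain_error")
  if (any(ss + ds == 0))
    fv_stop("a lane with both signals zero has no defined unwinding fraction",
            "famvar_domain_error")
  100 * ss / (ss + ds)
}

#' Summarize a mutant's helicase activity against wild type
#'
#' Computes mean +/- SD percent unwinding over replicates, the activity
#' relative to wild type (`100 * mean_mut / mean_wt`), and a Welch
#' two-tailed p-value versus the wild-type replicates, then assigns the
#' three-class activity call used in carrier tables:
#'
#' * `complete_loss` — relative activity <= `complete_max` (default 5%);
#' * `partial_loss`  — relative activity in (`complete_max`,
#'   `partial_max`] (default 50%) *and* significantly below wild type
#'   (p < `alpha`);
#' * `normal`        — otherwise.
#'
#' The class thresholds are this package's operationalization of the
#' qualitative classes ("essentially undetectable" single strand;
#' "lost approximately 83.4% of the activity"); they are exposed so a
#' different calibration can be configured.
#'
#' @param reps Data.frame of the mutant's replicates with columns
#'   `ss_signal`, `ds_signal` (at least 3 rows; assays conventionally run
#'   three independent experiments).
#' @param wt The wild-type replicates, same contract.
#' @param mutant_label Label carried into the summary.
#' @param complete_max,partial_max Relative-activity thresholds (%).
#' @param alpha Significance level for the wild-type comparison.
#' @return A one-row data.frame: `mutant_label`, `percent_unwound_mean`,
#'   `percent_unwound_sd`, `relative_activity`, `p_vs_wt`,
#'   `activity_class`.
#' @export
summarize_mutant <- function(reps, wt, mutant_label = "mutant",
                             complete_max = 5, partial_max = 50,
                             alpha = 0.05) {
  need <- function(df, who) {
    if (!is.data.frame(df) || !all(c("ss_signal", "ds_signal") %in% names(df)))
      fv_stop(sprintf("%s replicates need ss_signal and ds_signal columns",
                      who), "famvar_validation_error")
    if (nrow(df) < 3L)
      fv_stop(sprintf("%s has %d replicate(s); at least 3 are required",
                      who, nrow(df)), "famvar_validation_error")
    percent_unwound(df$ss_signal, df$ds_signal)
  }
  pm <- need(reps, mutant_label)
  pw <- need(wt, "wild type")
  if (mean(pw) == 0)
    fv_stop("wild-type mean unwinding is zero; relative activity undefined",
            "famvar_domain_error")
  if (!(complete_max >= 0 && partial_max > complete_max))
    fv_stop("need 0 <= complete_max < partial_max",
            "famvar_validation_error")

  rel <- 100 * mean(pm) / mean(pw)
  # identical constant groups carry no Welch statistic; the difference in
  # means settles the comparison directly
  p <- if (stats::var(pm) == 0 && stats::var(pw) == 0) {
    as.numeric(mean(pm) == mean(pw))
  } else {
    welch_t_test(pm, pw)$p
  }
  cls <- if (rel <= complete_max) "complete_loss"
         else if (rel <= partial_max && p < alpha) "partial_loss"
         else "normal"
  data.frame(mutant_label = mutant_label,
             percent_unwound_mean = mean(pm),
             percent_unwound_sd = stats::sd(pm),
             relative_activity = rel,
             p_vs_wt = p,
             activity_class = cls,
             stringsAsFactors = FALSE)
}

#' Summarize every mutant in a replicate table
#'
#' @param replicates Data.frame with columns `mutant`, `replicate`,
#'   `ss_signal`, `ds_signal` (see [read_replicate_table()]).
#' @param wt_label Which `mutant` value is the wild-type reference.
#' @param ... Passed to [summarize_mutant()].
#' @return A data.frame with one [summarize_mutant()] row per non-WT
#'   mutant, in first-appearance order.
#' @examples
#' reps <- make_assay_replicates(seed = 1)
#' summarize_assay(reps)$activity_class
#' @export
summarize_assay <- function(replicates, wt_label = "WT", ...) {
  if (!is.data.frame(replicates) ||
      !all(c("mutant", "ss_signal", "ds_signal") %in% names(replicates)))
    fv_stop("replicate table needs mutant, ss_signal, ds_signal columns",
            "famvar_validation_error")
  if (!wt_label %in% replicates$mutant)
    fv_stop(sprintf("wild-type label '%s' not present in the table",
                    wt_label), "famvar_validation_error")
  wt <- replicates[replicates$mutant == wt_label, , drop = FALSE]
  labels <- setdiff(unique(replicates$mutant), wt_label)
  out <- do.call(rbind, lapply(labels, function(lab)
    summarize_mutant(replicates[replicates$mutant == lab, , drop = FALSE],
                     wt, mutant_label = lab, ...)))
  rownames(out) <- NULL
  out
}
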