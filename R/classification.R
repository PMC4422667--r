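#' Assemble a per-variant evidence record
#'
#' One screened variant's evidence bundle: its consequence class, the in
#' vitro helicase-assay outcome, the transcript (RT-PCR style) analysis
#' outcome, and carrier counts in cases and controls. Each variant
#' carries its *own* control denominator — screens often genotype a
#' recurrent variant in a subset of controls only.
#'
#' @param hgvs_c Variant string (key; must be unique within a table).
#' @param effect Consequence class (see [annotate_variant()]).
#' @param helicase_class One of `"normal"`, `"partial_loss"`,
#'   `"complete_loss"`, `"not_done"`.
#' @param splice_transcript Transcript-analysis outcome: one of
#'   `"aberrant_truncating"`, `"normal"`, `"not_done"`.
#' @param case_carriers,case_n,control_carriers,control_n Carrier counts.
#' @param protein_change Optional protein-level label.
#' @return A one-row data.frame of class `EvidenceRecord` columns.
#' @export
evidence_record <- function(hgvs_c, effect,
                            helicase_class = "not_done",
                            splice_transcript = "not_done",
                            case_carriers = NA_integer_,
                            case_n = NA_integer_,
                            control_carriers = NA_integer_,
                            control_n = NA_integer_,
                            protein_change = NA_character_) {
  helicase_class <- match.arg(helicase_class,
                              c("not_done", "normal", "partial_loss",
                                "complete_loss"))
  splice_transcript <- match.arg(splice_transcript,
                                 c("not_done", "normal",
                                   "aberrant_truncating"))
  data.frame(hgvs_c = hgvs_c, protein_change = protein_change,
             effect = effect, helicase_class = helicase_class,
             splice_transcript = splice_transcript,
             case_carriers = as.integer(case_carriers),
             case_n = as.integer(case_n),
             control_carriers = as.integer(control_carriers),
             control_n = as.integer(control_n),
             stringsAsFactors = FALSE)
}

#' Classify one variant by evidence precedence
#'
#' The rule engine formalizes how the screen's evidence was weighed,
#' in strict precedence order:
#'
#' * **R1 (truncation):** nonsense or frameshift consequences create a
#'   premature stop — pathogenic, no further evidence consulted.
#' * **R2 (transcript analysis):** a canonical-splice variant whose
#'   transcript analysis shows an aberrant truncating product is
#'   pathogenic; any splice-adjacent or intronic variant whose
#'   transcript analysis is normal is neutral. A canonical-splice
#'   variant *without* transcript evidence cannot be resolved and falls
#'   to VUS with a warning.
#' * **R3 (function):** a variant with helicase-assay evidence is
#'   pathogenic on complete or partial activity loss, neutral on normal
#'   activity. Functional evidence outranks control presence: a variant
#'   seen once in controls is still pathogenic if it kills the enzyme.
#' * **R4 (frequency):** with no functional evidence, carrier frequencies
#'   in cases and controls are compared by [fisher_exact_two_sided()]
#'   against the variant's own control denominator; "similar" frequency
#'   (p >= `alpha_sim`) is read as neutral, a significant difference
#'   remains a VUS (frequency alone cannot prove pathogenicity).
#' * **Default:** VUS.
#'
#' @param e An [evidence_record()] (or any one-row data.frame with the
#'   same columns).
#' @param alpha_sim Significance level for the R4 frequency-similarity
#'   test. The screen narrative gives no explicit test; 0.05 with a
#'   two-sided exact test is this package's formalization.
#' @return A list with `verdict` (`pathogenic`/`neutral`/`vus`),
#'   `rule_fired` (`R1_truncating`, `R2_splice`, `R3_function`,
#'   `R4_frequency`, `default`) and `p_similar` (the R4 p-value, `NA`
#'   when R4 was not consulted).
#' @export
classify_variant <- function(e, alpha_sim = 0.05) {
  if (is.data.frame(e)) {
    stopifnot(nrow(e) == 1L)
    e <- as.list(e)
  }
  effect <- e$effect
  hel <- e$helicase_class %||% "not_done"
  spl <- e$splice_transcript %||% "not_done"
  res <- function(verdict, rule, p = NA_real_)
    list(verdict = verdict, rule_fired = rule, p_similar = p)

  # R1: premature truncation
  if (effect %in% c("nonsense", "frameshift"))
    return(res("pathogenic", "R1_truncating"))

  # R2: transcript analysis of splice-adjacent variants
  splicey <- effect %in% c("splice_canonical", "splice_region", "intronic")
  if (splicey && spl == "normal")
    return(res("neutral", "R2_splice"))
  if (effect == "splice_canonical") {
    if (spl == "aberrant_truncating")
      return(res("pathogenic", "R2_splice"))
    fv_warn(sprintf(
      "canonical-splice variant %s has no transcript evidence; verdict is VUS",
      e$hgvs_c %||% "?"), "famvar_no_evidence_warning")
    return(res("vus", "default"))
  }

  # R3: functional (helicase) evidence
  if (hel %in% c("complete_loss", "partial_loss"))
    return(res("pathogenic", "R3_function"))
  if (hel == "normal")
    return(res("neutral", "R3_function"))

  # R4: carrier-frequency similarity
  counts_ok <- !anyNA(c(e$case_carriers, e$case_n, e$control_carriers,
                        e$control_n))
  if (counts_ok) {
    p <- fisher_exact_two_sided(cohort_counts(
      e$case_carriers, e$case_n, e$control_carriers, e$control_n))
    if (p >= alpha_sim) return(res("neutral", "R4_frequency", p))
    return(res("vus", "R4_frequency", p))
  }

  res("vus", "default")
}

#' Classify a table of evidence records
#'
#' Applies [classify_variant()] to every row and tabulates the verdicts.
#' Row order is preserved (carrier tables are reported in a fixed order),
#' and the result is order-invariant in its counts.
#'
#' @param records A data.frame of evidence records, one row per distinct
#'   variant (`hgvs_c` is the key; duplicates are an error).
#' @param alpha_sim Passed to [classify_variant()].
#' @return A list with `calls` (the input plus `verdict`, `rule_fired`,
#'   `p_similar`), `n_pathogenic`, `n_neutral`, `n_vus`, `by_rule`
#'   (verdict counts per rule) and `pathogenic_variants` (protein labels
#'   where present, else HGVS strings, in input order).
#' @examples
#' summary <- classify_table(screen_evidence())
#' summary$n_pathogenic  # 9
#' @export
classify_table <- function(records, alpha_sim = 0.05) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$hgvs_c))
    fv_stop(sprintf("duplicate variant key(s): %s",
                    paste(unique(records$hgvs_c[duplicated(records$hgvs_c)]),
                          collapse = ", ")),
            "famvar_validation_error")
  if (nrow(records) == 0L) {
    return(list(calls = cbind(records,
                              data.frame(verdict = character(0L),
                                         rule_fired = character(0L),
                                         p_similar = numeric(0L))),
                n_pathogenic = 0L, n_neutral = 0L, n_vus = 0L,
                by_rule = table(factor(character(0L))),
                pathogenic_variants = character(0L)))
  }
  calls <- lapply(seq_len(nrow(records)), function(i)
    classify_variant(records[i, , drop = FALSE], alpha_sim = alpha_sim))
  out <- records
  out$verdict <- vapply(calls, `[[`, character(1L), "verdict")
  out$rule_fired <- vapply(calls, `[[`, character(1L), "rule_fired")
  out$p_similar <- vapply(calls, `[[`, numeric(1L), "p_similar")

  path <- out$verdict == "pathogenic"
  label <- if ("protein_change" %in% names(out)) {
    ifelse(is.na(out$protein_change) | out$protein_change %in% c("", "-"),
           out$hgvs_c, out$protein_change)
  } else out$hgvs_c
  list(calls = out,
       n_pathogenic = sum(path),
       n_neutral = sum(out$verdict == "neutral"),
       n_vus = sum(out$verdict == "vus"),
       by_rule = table(rule = out$rule_fired, verdict = out$verdict),
       pathogenic_variants = label[path])
}
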