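#' Assess loss of heterozygosity at one variant site
#'
#' Compares tumor to germline allele balance at a site that is
#' heterozygous in the germline. Sanger-trace LOH reads are qualitative;
#' this function defines a quantitative contract instead: the site is
#' evaluable only if the germline alt-allele fraction lies inside
#' `het_band`; LOH is called when the tumor minor-allele fraction drops
#' below `loh_minor_max` *and* a two-sided exact test of the
#' (ref, alt) counts between germline and tumor rejects at `alpha`;
#' otherwise heterozygosity is retained. Peak heights from traces are
#' accepted as pseudo-counts after scaling (e.g. x100, rounded).
#'
#' @param germline_ref,germline_alt,tumor_ref,tumor_alt Non-negative
#'   allele counts (read depths or scaled peak heights); each tissue's
#'   total must be positive.
#' @param het_band Closed interval for the germline alt fraction that
#'   qualifies a site as heterozygous (default `c(0.3, 0.7)`).
#' @param loh_minor_max Ceiling on the tumor minor-allele fraction for an
#'   LOH call (default 0.15).
#' @param alpha Significance level of the exact allele-count test
#'   (default 0.01; conservative because depths can be pseudo-counts).
#' @return A list with `call` (`"retained_het"`, `"loh"`,
#'   `"not_evaluable"`), `lost_allele` (`"ref"`/`"alt"` when LOH, else
#'   `NA`), `germline_alt_fraction`, `tumor_minor_fraction`, `p_value`.
#' @examples
#' assess_loh(50, 50, 97, 3)$call  # "loh"
#' assess_loh(50, 50, 48, 52)$call # "retained_het"
#' @export
assess_loh <- function(germline_ref, germline_alt, tumor_ref, tumor_alt,
                       het_band = c(0.3, 0.7), loh_minor_max = 0.15,
                       alpha = 0.01) {
  cts <- vapply(list(germline_ref, germline_alt, tumor_ref, tumor_alt),
                function(x) as.integer(x)[1L], integer(1L))
  if (anyNA(cts) || any(cts < 0L))
    fv_stop("allele counts must be non-negative integers",
            "famvar_domain_error")
  g_tot <- cts[1L] + cts[2L]
  t_tot <- cts[3L] + cts[4L]
  if (g_tot == 0L || t_tot == 0L)
    fv_stop("germline and tumor totals must both be positive",
            "famvar_domain_error")
  gf <- cts[2L] / g_tot
  tf_minor <- min(cts[3L], cts[4L]) / t_tot
  out <- list(call = "not_evaluable", lost_allele = NA_character_,
              germline_alt_fraction = gf, tumor_minor_fraction = tf_minor,
              p_value = NA_real_)
  if (gf < het_band[1L] || gf > het_band[2L]) return(out)

  p <- fisher_exact_two_sided(
    cohort_counts(cts[2L], g_tot, cts[4L], t_tot))
  out$p_value <- p
  if (tf_minor < loh_minor_max && p < alpha) {
    out$call <- "loh"
    out$lost_allele <- if (cts[4L] < cts[3L]) "alt" else "ref"
  } else {
    out$call <- "retained_het"
  }
  out
}

#' Assess LOH over a tumor/germline allele-depth table
#'
#' @param depths Data.frame with columns `case_id`, `variant`, `g_ref`,
#'   `g_alt`, `t_ref`, `t_alt` (see [read_depth_table()]).
#' @param ... Passed to [assess_loh()].
#' @return The input with `call`, `lost_allele`, `germline_alt_fraction`,
#'   `tumor_minor_fraction`, `p_value` columns appended.
#' @examples
#' d <- read_depth_table(system.file("extdata", "loh_five_cases_synthetic.tsv",
#'                                   package = "famvar"))
#' table(assess_loh_table(d)$call)
#' @export
assess_loh_table <- function(depths, ...) {
  need <- c("case_id", "variant", "g_ref", "g_alt", "t_ref", "t_alt")
  if (!is.data.frame(depths) || !all(need %in% names(depths)))
    fv_stop(sprintf("depth table needs columns: %s",
                    paste(need, collapse = ", ")),
            "famvar_validation_error")
  res <- lapply(seq_len(nrow(depths)), function(i)
    assess_loh(depths$g_ref[i], depths$g_alt[i],
               depths$t_ref[i], depths$t_alt[i], ...))
  depths$call <- vapply(res, `[[`, character(1L), "call")
  depths$lost_allele <- vapply(res, `[[`, character(1L), "lost_allele")
  depths$germline_alt_fraction <-
    vapply(res, `[[`, numeric(1L), "germline_alt_fraction")
  depths$tumor_minor_fraction <-
    vapply(res, `[[`, numeric(1L), "tumor_minor_fraction")
  depths$p_value <- vapply(res, `[[`, numeric(1L), "p_value")
  depths
}
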