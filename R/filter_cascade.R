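#' Filter-cascade configuration
#'
#' Tunables of the exome candidate-gene discovery procedure. Defaults
#' follow the screen this package re-implements: variants present in
#' dbSNP 132 or the 1000 Genomes catalogue are excluded, only
#' heterozygous variants are retained, "truncating" means nonsense or
#' frameshift with canonical-splice changes kept as their own class, and
#' prediction-flagged (damaging) missense/start-loss variants are also
#' admitted — the screen's discovery set contained a damaging-predicted
#' missense alongside a nonsense variant. A gene is reported when two or
#' more cases carry qualifying variants and at least two of those
#' variants differ.
#'
#' @param excluded_databases Database labels whose membership disqualifies
#'   a variant.
#' @param required_zygosity Zygosity retained by [filter_functional()].
#' @param retained_effects Consequence classes retained unconditionally.
#' @param admit_damaging_missense Also retain `missense`/`start_loss`
#'   variants whose `damaging_prediction` flag is `TRUE`.
#' @param min_recurrent_cases Minimum number of distinct supporting cases
#'   for [recurrent_genes()]; must be `>= 2`.
#' @param require_distinct_variants Require at least two *different*
#'   variants among the supporting cases.
#' @return A list of class `FilterConfig`.
#' @export
filter_config <- function(excluded_databases = c("dbSNP132", "1000G"),
                          required_zygosity = "het",
                          retained_effects = c("nonsense", "frameshift",
                                               "splice_canonical"),
                          admit_damaging_missense = TRUE,
                          min_recurrent_cases = 2L,
                          require_distinct_variants = TRUE) {
  min_recurrent_cases <- as.integer(min_recurrent_cases)
  if (is.na(min_recurrent_cases) || min_recurrent_cases < 2L)
    fv_stop("min_recurrent_cases must be >= 2", "famvar_validation_error")
  structure(
    list(excluded_databases = as.character(excluded_databases),
         required_zygosity = match.arg(required_zygosity, c("het", "hom")),
         retained_effects = as.character(retained_effects),
         admit_damaging_missense = isTRUE(admit_damaging_missense),
         min_recurrent_cases = min_recurrent_cases,
         require_distinct_variants = isTRUE(require_distinct_variants)),
    class = "FilterConfig")
}

# canonical columns of a per-sample/cohort variant table
.variant_cols <- c("sample_id", "gene", "transcript_id", "hgvs_c", "kind",
                   "zygosity", "effect", "db_flags", "damaging_prediction")

.check_variant_table <- function(df, context = "variant table") {
  if (!is.data.frame(df))
    fv_stop(sprintf("%s must be a data.frame", context),
            "famvar_validation_error")
  missing <- setdiff(.variant_cols, names(df))
  if (length(missing))
    fv_stop(sprintf("%s lacks required column(s): %s", context,
                    paste(missing, collapse = ", ")),
            "famvar_validation_error")
  invisible(df)
}

# split a semicolon-joined flag field into a list of character vectors
.split_flags <- function(x) {
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

#' Remove variants present in excluded databases
#'
#' Drops every variant whose database-membership flags intersect the
#' configured exclusion set ("rare" at this stage of the cascade means
#' exactly: absent from those catalogues). Input row order is preserved.
#'
#' @param variants A variant table (see [read_variant_table()] for the
#'   column contract); `db_flags` is a semicolon-joined string of
#'   database labels, empty or `NA` for none.
#' @param cfg A [filter_config()].
#' @return The retained subset, same columns, original order.
#' @export
filter_known <- function(variants, cfg = filter_config()) {
  .check_variant_table(variants)
  if (nrow(variants) == 0L) return(variants)
  known <- vapply(.split_flags(variants$db_flags),
                  function(f) any(f %in% cfg$excluded_databases),
                  logical(1L))
  variants[!known, , drop = FALSE]
}

#' Retain heterozygous truncating or damaging-predicted variants
#'
#' Keeps variants whose zygosity matches the configured requirement and
#' whose consequence is either one of the unconditionally retained
#' classes (default nonsense, frameshift, canonical splice) or — when
#' `admit_damaging_missense` — a missense/start-loss change flagged as
#' damaging by in-silico prediction.
#'
#' @inheritParams filter_known
#' @return The retained subset, original order.
#' @export
filter_functional <- function(variants, cfg = filter_config()) {
  .check_variant_table(variants)
  if (nrow(variants) == 0L) return(variants)
  bad <- is.na(variants$effect) | variants$effect == ""
  if (any(bad))
    fv_stop(sprintf("missing consequence call for variant(s): %s",
                    paste(variants$hgvs_c[bad], collapse = ", ")),
            "famvar_validation_error")
  dmg <- variants$damaging_prediction
  keep <- variants$zygosity == cfg$required_zygosity &
    (variants$effect %in% cfg$retained_effects |
       (cfg$admit_damaging_missense &
          variants$effect %in% c("missense", "start_loss") &
          !is.na(dmg) & dmg))
  variants[keep, , drop = FALSE]
}

#' Run the full filtration cascade
#'
#' [filter_known()] followed by [filter_functional()]; the two filters
#' are row-wise predicates, so the order does not affect the result.
#'
#' @inheritParams filter_known
#' @return The retained subset.
#' @export
filter_cascade <- function(variants, cfg = filter_config()) {
  filter_functional(filter_known(variants, cfg), cfg)
}

#' Report genes with different qualifying variants in two or more cases
#'
#' The cross-case recurrence rule of the discovery procedure: after
#' per-sample filtration, a gene is a candidate iff at least
#' `min_recurrent_cases` distinct samples carry qualifying variants in it
#' and (by default) at least two of those variants differ. SNVs
#' (substitutions) and indels are evaluated as separate streams and the
#' results merged, mirroring pipelines that call the two variant types
#' with different tools.
#'
#' @param cohort Either a single variant table covering all samples, or a
#'   list of per-sample tables (each with a single, unique `sample_id`).
#' @param cfg A [filter_config()].
#' @return A data.frame with one row per candidate gene: `gene`,
#'   `n_samples`, `n_variants`, `samples` and `variants`
#'   (semicolon-joined), ranked by supporting-sample count (descending)
#'   with ties broken alphabetically by gene.
#' @export
recurrent_genes <- function(cohort, cfg = filter_config()) {
  if (is.data.frame(cohort)) {
    df <- .check_variant_table(cohort, "cohort table")
  } else if (is.list(cohort)) {
    ids <- vapply(cohort, function(s) {
      .check_variant_table(s, "per-sample table")
      u <- unique(s$sample_id)
      if (length(u) > 1L)
        fv_stop("a per-sample table contains multiple sample_ids",
                "famvar_validation_error")
      if (length(u) == 0L) NA_character_ else u
    }, character(1L))
    ids <- ids[!is.na(ids)]
    if (anyDuplicated(ids))
      fv_stop(sprintf("duplicate sample_id(s) across the cohort: %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "famvar_validation_error")
    df <- do.call(rbind, cohort)
  } else {
    fv_stop("cohort must be a variant table or a list of per-sample tables",
            "famvar_validation_error")
  }

  support_in_stream <- function(sub) {
    if (nrow(sub) == 0L) return(character(0L))
    per_gene <- split(sub, sub$gene)
    qual <- vapply(per_gene, function(g) {
      n_samp <- length(unique(g$sample_id))
      n_var <- length(unique(g$hgvs_c))
      n_samp >= cfg$min_recurrent_cases &&
        (!cfg$require_distinct_variants || n_var >= 2L)
    }, logical(1L))
    names(per_gene)[qual]
  }

  is_snv <- df$kind == "substitution"
  genes <- union(support_in_stream(df[is_snv, , drop = FALSE]),
                 support_in_stream(df[!is_snv, , drop = FALSE]))
  if (length(genes) == 0L)
    return(data.frame(gene = character(0L), n_samples = integer(0L),
                      n_variants = integer(0L), samples = character(0L),
                      variants = character(0L), stringsAsFactors = FALSE))

  rows <- lapply(genes, function(g) {
    sub <- df[df$gene == g, , drop = FALSE]
    samples <- sort(unique(sub$sample_id))
    variants <- sort(unique(sub$hgvs_c))
    data.frame(gene = g, n_samples = length(samples),
               n_variants = length(variants),
               samples = paste(samples, collapse = ";"),
               variants = paste(variants, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_samples, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
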