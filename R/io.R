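# Strict TSV reading with a known column contract. Required columns must
# be present; unknown extras are kept (with a warning) so foreign
# annotation columns survive a read/write round trip.
.read_tsv_contract <- function(path, required, context) {
  if (!file.exists(path))
    fv_stop(sprintf("%s file not found: '%s'", context, path),
            "famvar_parse_error")
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA"))
  missing <- setdiff(required, names(df))
  if (length(missing))
    fv_stop(sprintf("%s '%s' lacks required column(s): %s", context, path,
                    paste(missing, collapse = ", ")),
            "famvar_parse_error")
  extra <- setdiff(names(df), required)
  if (length(extra))
    fv_warn(sprintf("%s '%s' has unknown column(s) %s; preserved as-is",
                    context, path, paste(extra, collapse = ", ")),
            "famvar_dialect_warning")
  df
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

.check_rows <- function(df, bad, path, what) {
  if (any(bad))
    fv_stop(sprintf("%s in '%s' at line(s) %s", what, path,
                    paste(which(bad) + 1L, collapse = ", ")),
            "famvar_parse_error")
}

#' Read / write a per-sample or cohort variant table
#'
#' The canonical interchange format of the filter cascade: a TSV with
#' columns `sample_id`, `gene`, `transcript_id`, `hgvs_c`, `kind`,
#' `zygosity` (`het`/`hom`), `effect`, `db_flags` (semicolon-joined
#' database labels, empty for none) and `damaging_prediction`
#' (`0`/`1`/`NA`). Unknown extra columns are preserved with a warning.
#' Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @return A variant table data.frame (`damaging_prediction` as logical).
#' @export
read_variant_table <- function(path) {
  df <- .read_tsv_contract(path, .variant_cols, "variant table")
  df$db_flags <- ifelse(is.na(df$db_flags), "", as.character(df$db_flags))
  .check_rows(df, !df$zygosity %in% c("het", "hom"), path,
              "zygosity must be 'het' or 'hom'")
  dmg <- df$damaging_prediction
  if (!is.logical(dmg)) {
    parsed <- rep(NA, length(dmg))
    parsed[dmg %in% c("1", "TRUE", "true", 1)] <- TRUE
    parsed[dmg %in% c("0", "FALSE", "false", 0)] <- FALSE
    .check_rows(df, !is.na(dmg) & is.na(parsed) & dmg != "", path,
                "damaging_prediction must be 0, 1 or NA")
    dmg <- parsed
  }
  df$damaging_prediction <- dmg
  df
}

#' @rdname read_variant_table
#' @param variants A variant table.
#' @export
write_variant_table <- function(variants, path) {
  .check_variant_table(variants)
  out <- variants
  out$damaging_prediction <- ifelse(is.na(out$damaging_prediction), NA,
                                    as.integer(out$damaging_prediction))
  .write_tsv(out, path)
}

#' Read a minimal VCF into a variant table
#'
#' Reads a single-sample VCF whose INFO field carries `GENE`, `HGVSC`,
#' `DBFLAGS` (comma-joined within INFO, translated to the semicolon
#' dialect of the TSV) and `DMG` (0/1) keys, mapping each record onto
#' the variant-table contract. Zygosity is taken from the sample's GT
#' (`het` unless both alleles equal). Requires the vcfR package.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return A variant table (see [read_variant_table()]).
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    fv_stop("reading VCF requires the vcfR package", "famvar_parse_error")
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  n <- nrow(vcf@fix)
  if (is.null(n) || n == 0L)
    fv_stop(sprintf("no records in VCF '%s'", path), "famvar_parse_error")
  info_get <- function(key) {
    x <- vcfR::extract.info(vcf, element = key)
    if (all(is.na(x)))
      fv_stop(sprintf("VCF '%s' lacks required INFO key %s", path, key),
              "famvar_parse_error")
    x
  }
  gene <- info_get("GENE")
  hgvs <- info_get("HGVSC")
  dbflags <- vcfR::extract.info(vcf, element = "DBFLAGS")
  dbflags <- ifelse(is.na(dbflags), "", gsub(",", ";", dbflags))
  dmg <- suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "DMG")))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) != 1L)
    fv_stop(sprintf("VCF '%s' must contain exactly one sample", path),
            "famvar_parse_error")
  alleles <- strsplit(gsub("\\|", "/", gt[, 1L]), "/", fixed = TRUE)
  zyg <- vapply(alleles, function(a)
    if (length(unique(a)) == 1L) "hom" else "het", character(1L))

  kind <- vapply(hgvs, function(h)
    parse_hgvs_c(h)$kind, character(1L), USE.NAMES = FALSE)
  data.frame(sample_id = colnames(gt)[1L], gene = gene,
             transcript_id = NA_character_, hgvs_c = hgvs, kind = kind,
             zygosity = zyg, db_flags = dbflags,
             damaging_prediction = as.logical(dmg),
             effect = NA_character_,
             stringsAsFactors = FALSE)[, .variant_cols]
}

#' Read / write a transcript model as JSON
#'
#' Format: `{"gene": ..., "transcript_id": ..., "exons": [[first, last],
#' ...], "cds": "ATG..."}`. Reading validates every transcript invariant
#' (contiguous ascending exons, length a multiple of 3, start and stop
#' codons) via [transcript_model()].
#'
#' @param path JSON file path.
#' @return A `TranscriptModel`.
#' @export
read_transcript_json <- function(path) {
  if (!file.exists(path))
    fv_stop(sprintf("transcript file not found: '%s'", path),
            "famvar_parse_error")
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("gene", "transcript_id", "exons", "cds")
  missing <- setdiff(need, names(x))
  if (length(missing))
    fv_stop(sprintf("transcript JSON '%s' lacks field(s): %s", path,
                    paste(missing, collapse = ", ")),
            "famvar_parse_error")
  transcript_model(x$gene, x$transcript_id, x$exons, x$cds)
}

#' @rdname read_transcript_json
#' @param tm A `TranscriptModel`.
#' @export
write_transcript_json <- function(tm, path) {
  stopifnot(inherits(tm, "TranscriptModel"))
  jsonlite::write_json(
    list(gene = tm$gene_symbol, transcript_id = tm$transcript_id,
         exons = unname(tm$exon_cdna_bounds), cds = tm$cds_sequence),
    path, auto_unbox = TRUE)
  invisible(path)
}

.evidence_cols <- c("hgvs_c", "protein_change", "effect", "helicase_class",
                    "splice_transcript", "case_carriers", "case_n",
                    "control_carriers", "control_n")

#' Read / write an evidence table
#'
#' TSV mirroring a carrier-screen table: one row per distinct variant
#' with consequence, assay class, transcript-analysis outcome and
#' case/control carrier counts (see [evidence_record()]). Extra columns
#' (e.g. prediction flags, LOH status) are preserved.
#'
#' @param path File path.
#' @return An evidence data.frame ready for [classify_table()].
#' @export
read_evidence_table <- function(path) {
  df <- suppressWarnings(
    .read_tsv_contract(path, .evidence_cols, "evidence table"))
  for (col in c("case_carriers", "case_n", "control_carriers", "control_n")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    .check_rows(df, !is.na(df[[col]]) & is.na(v), path,
                sprintf("%s must be an integer", col))
    df[[col]] <- v
  }
  bad <- (!is.na(df$case_carriers) & df$case_carriers > df$case_n) |
    (!is.na(df$control_carriers) & df$control_carriers > df$control_n)
  .check_rows(df, bad, path, "carriers exceed the group size")
  df
}

#' @rdname read_evidence_table
#' @param records An evidence data.frame.
#' @export
write_evidence_table <- function(records, path) {
  missing <- setdiff(.evidence_cols, names(records))
  if (length(missing))
    fv_stop(sprintf("evidence table lacks column(s): %s",
                    paste(missing, collapse = ", ")),
            "famvar_validation_error")
  .write_tsv(records, path)
}

#' Read a helicase-assay replicate table
#'
#' TSV with columns `mutant`, `replicate`, `ss_signal`, `ds_signal`.
#'
#' @param path File path.
#' @return A replicate data.frame for [summarize_assay()].
#' @export
read_replicate_table <- function(path) {
  df <- .read_tsv_contract(
    path, c("mutant", "replicate", "ss_signal", "ds_signal"),
    "replicate table")
  .check_rows(df, is.na(suppressWarnings(as.numeric(df$ss_signal))) |
                is.na(suppressWarnings(as.numeric(df$ds_signal))), path,
              "signals must be numeric")
  df$ss_signal <- as.numeric(df$ss_signal)
  df$ds_signal <- as.numeric(df$ds_signal)
  df
}

#' Read a tumor/germline allele-depth table
#'
#' TSV with columns `case_id`, `variant`, `g_ref`, `g_alt`, `t_ref`,
#' `t_alt` (read depths, or Sanger peak heights scaled to pseudo-counts).
#'
#' @param path File path.
#' @return A depth data.frame for [assess_loh_table()].
#' @export
read_depth_table <- function(path) {
  df <- .read_tsv_contract(
    path, c("case_id", "variant", "g_ref", "g_alt", "t_ref", "t_alt"),
    "depth table")
  for (col in c("g_ref", "g_alt", "t_ref", "t_alt")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    .check_rows(df, is.na(v) | v < 0L, path,
                sprintf("%s must be a non-negative integer", col))
    df[[col]] <- v
  }
  df
}

#' Re-run the whole desk-scale analysis on the packaged fixtures
#'
#' Chains every stage of the package on in-package inputs: consequence
#' annotation of the fifteen screened variants against the RECQL-like
#' transcript, evidence classification of the packaged carrier table,
#' the carrier-burden statistics on the pathogenic carriers (9 of 448
#' cases versus 1 of 1,588 controls), activity classification of the
#' simulated assay replicates, and LOH assessment of the packaged
#' five-tumor depth table. The returned report juxtaposes each computed
#' quantity with the reference value the evidence fixture implies.
#'
#' @param seed Integer seed driving the simulated transcript fill and
#'   assay noise.
#' @param alpha_sim Passed to [classify_table()].
#' @return A list with `report` (data.frame: `quantity`, `computed`,
#'   `reference`) and the underlying stage outputs (`annotations`,
#'   `classification`, `burden`, `assay`, `loh`).
#' @examples
#' rep <- run_reproduce(seed = 1)
#' rep$report
#' @export
run_reproduce <- function(seed = 1L, alpha_sim = 0.05) {
  tm <- make_recql_like_transcript(seed)
  ev <- screen_evidence()

  anns <- lapply(ev$hgvs_c, function(h)
    annotate_variant(tm, parse_hgvs_c(h)))
  ann_df <- data.frame(
    hgvs_c = ev$hgvs_c,
    effect = vapply(anns, `[[`, character(1L), "effect"),
    protein_label = vapply(anns, function(a)
      a$protein_label %||% NA_character_, character(1L)),
    stringsAsFactors = FALSE)

  cls <- classify_table(ev, alpha_sim = alpha_sim)

  path <- cls$calls$verdict == "pathogenic"
  counts <- cohort_counts(sum(cls$calls$case_carriers[path]), ev$case_n[1L],
                          sum(cls$calls$control_carriers[path]), 1588L)
  p_burden <- fisher_exact_two_sided(counts)

  assay <- summarize_assay(make_assay_replicates(seed = seed))
  missense8 <- c("S63P", "A195S", "R215Q", "R455C", "M458K", "H461R",
                 "R539P", "T562I")
  n_complete <- sum(assay$activity_class[assay$mutant_label %in%
                                           missense8] == "complete_loss")

  loh <- assess_loh_table(read_depth_table(
    system.file("extdata", "loh_five_cases_synthetic.tsv",
                package = "famvar", mustWork = TRUE)))

  skip <- exon_skip_consequence(tm, 5L)
  report <- data.frame(
    quantity = c("fisher_p_burden", "carrier_frequency_pct",
                 "n_pathogenic", "n_nonsense_pathogenic",
                 "n_missense_pathogenic", "codon_796", "codon_644",
                 "exon5_skip_codon", "n_complete_loss",
                 "n_distinct_variants", "n_loh_calls"),
    computed = c(p_burden, carrier_frequency(counts), cls$n_pathogenic,
                 sum(path & cls$calls$effect == "nonsense"),
                 sum(path & cls$calls$effect == "missense"),
                 codon_index(796L), codon_index(644L), skip$codon_index,
                 n_complete, length(unique(ev$hgvs_c)),
                 sum(loh$call == "loh")),
    reference = c(9.14e-6, 2.0, 9, 3, 5, 266, 215, 132, 4, 15, 0),
    stringsAsFactors = FALSE)

  list(report = report, annotations = ann_df, classification = cls,
       burden = list(counts = counts, p = p_burden,
                     odds_ratio = odds_ratio(counts, haldane = TRUE)),
       assay = assay, loh = loh)
}
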