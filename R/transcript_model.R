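#' Construct a transcript model
#'
#' A transcript model is the frame of reference for every consequence
#' call: the exon segmentation of the coding sequence (in coding, i.e.
#' cDNA, coordinates) together with the CDS itself.
#'
#' @param gene_symbol Gene symbol, e.g. `"RECQL"`.
#' @param transcript_id Transcript identifier the coordinates refer to.
#' @param exon_cdna_bounds A list (or two-column matrix) of
#'   `(first, last)` coding positions per exon, 1-based inclusive.
#'   Intervals must be non-overlapping, ascending, and concatenate to
#'   `1..nchar(cds_sequence)` without gaps.
#' @param cds_sequence The coding DNA sequence including the stop codon.
#'   Must start with `ATG` and end with a stop codon, and have length a
#'   multiple of 3.
#'
#' @return An object of class `TranscriptModel`: a list with fields
#'   `gene_symbol`, `transcript_id`, `exon_cdna_bounds` (integer matrix,
#'   columns `first`/`last`), `cds_sequence`, `protein_length` (codons,
#'   excluding the stop).
#' @seealso [annotate_substitution()], [classify_splice()],
#'   [exon_skip_consequence()], [read_transcript_json()]
#' @examples
#' tm <- transcript_model("TOY", "TOY-001",
#'                        list(c(1, 9), c(10, 21)),
#'                        "ATGGGCTGGCTACGTCTTTGA")
#' tm$protein_length
#' @export
transcript_model <- function(gene_symbol, transcript_id,
                             exon_cdna_bounds, cds_sequence) {
  cds_sequence <- toupper(as.character(cds_sequence))
  if (!grepl("^[ACGT]+$", cds_sequence))
    fv_stop("cds_sequence must contain only A/C/G/T",
            "famvar_validation_error")
  len <- nchar(cds_sequence)
  if (len %% 3L != 0L)
    fv_stop("CDS length must be a multiple of 3 (stop codon included)",
            "famvar_validation_error")
  if (substr(cds_sequence, 1L, 3L) != "ATG")
    fv_stop("CDS must begin with ATG", "famvar_validation_error")
  last_codon <- substr(cds_sequence, len - 2L, len)
  if (!last_codon %in% c("TAA", "TAG", "TGA"))
    fv_stop("CDS must end with a stop codon (TAA/TAG/TGA)",
            "famvar_validation_error")

  ex <- exon_cdna_bounds
  if (is.list(ex)) ex <- do.call(rbind, lapply(ex, as.integer))
  ex <- matrix(as.integer(ex), ncol = 2L,
               dimnames = list(NULL, c("first", "last")))
  if (nrow(ex) < 1L || anyNA(ex))
    fv_stop("exon_cdna_bounds must be a non-empty list of (first, last) pairs",
            "famvar_validation_error")
  # exons must tile 1..len exactly, in order
  if (ex[1L, "first"] != 1L || ex[nrow(ex), "last"] != len ||
      any(ex[, "last"] < ex[, "first"]) ||
      (nrow(ex) > 1L && any(ex[-1L, "first"] != ex[-nrow(ex), "last"] + 1L)))
    fv_stop(sprintf(
      "exon intervals must ascend and concatenate to 1..%d with no gaps", len),
      "famvar_validation_error")

  structure(
    list(gene_symbol = as.character(gene_symbol),
         transcript_id = as.character(transcript_id),
         exon_cdna_bounds = ex,
         cds_sequence = cds_sequence,
         protein_length = len %/% 3L - 1L),
    class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s): %d exons, CDS %d nt, %d aa\n",
              x$gene_symbol, x$transcript_id, nrow(x$exon_cdna_bounds),
              nchar(x$cds_sequence), x$protein_length))
  invisible(x)
}

# HGVS c. grammar, offsets signed per HGVS: negative = intronic bases
# upstream of a splice acceptor, positive = downstream of a donor.
.hgvs_pos_re <- "(\\d+)([+-]\\d+)?"

#' Parse an HGVS coding-DNA (c.) variant string
#'
#' Accepts the notation of carrier-screen tables, with or without the
#' `c.` prefix: substitutions (`383T>G`, `c.395-2A>G`), deletions of a
#' single position or a range (`868-12_868-11del`, optionally followed by
#' the deleted bases), insertions (`100_101insA`) and deletion-insertions
#' (`100delinsTT`). Unicode dashes are normalized to ASCII `-` before
#' parsing. Protein-level (`p.`) strings are rejected with a distinct
#' error.
#'
#' @param raw The variant string.
#' @param gene_symbol,sample_id,zygosity Optional annotations attached to
#'   the returned record (`zygosity` one of `"het"`, `"hom"` or `NA`).
#' @return A `CodingVariant`: list with `position`, `intron_offset`,
#'   `end_position`, `end_offset` (the latter two `NA` for point
#'   changes), `ref_allele`, `alt_allele` (empty string for plain
#'   deletions), `kind` (`substitution`, `deletion`, `insertion`,
#'   `delins`), plus the annotation fields.
#' @examples
#' parse_hgvs_c("383T>G")
#' parse_hgvs_c("c.395-2A>G")
#' parse_hgvs_c("868-12_868-11del")
#' @export
parse_hgvs_c <- function(raw, gene_symbol = NA_character_,
                         sample_id = NA_character_,
                         zygosity = NA_character_) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    fv_stop("variant string must be a single character value",
            "famvar_parse_error")
  s <- gsub("[‐‑‒–—−]", "-", trimws(raw))
  if (grepl("^p\\.", s))
    fv_stop(sprintf(
      "'%s' is a protein-level (p.) change; expected coding-DNA (c.) notation",
      raw), "famvar_parse_error")
  s <- sub("^c\\.", "", s)

  m <- regexec(paste0("^", .hgvs_pos_re, "(?:_", .hgvs_pos_re, ")?(.*)$"), s)
  g <- regmatches(s, m)[[1L]]
  if (length(g) == 0L || g[2L] == "")
    fv_stop(sprintf("cannot parse coding position in '%s'", raw),
            "famvar_parse_error")
  position <- as.integer(g[2L])
  intron_offset <- if (g[3L] == "") 0L else as.integer(g[3L])
  has_range <- g[4L] != ""
  end_position <- if (has_range) as.integer(g[4L]) else NA_integer_
  end_offset <- if (has_range) {
    if (g[5L] == "") 0L else as.integer(g[5L])
  } else NA_integer_
  change <- g[6L]

  if (position < 1L || (has_range && end_position < 1L))
    fv_stop(sprintf("coding positions must be >= 1 in '%s'", raw),
            "famvar_parse_error")
  if (has_range) {
    before <- end_position < position ||
      (end_position == position && end_offset < intron_offset)
    if (before)
      fv_stop(sprintf("range end precedes range start in '%s'", raw),
              "famvar_parse_error")
  }

  base_re <- "[ACGTacgt]"
  kind <- ref <- alt <- NULL
  if (grepl(paste0("^", base_re, ">", base_re, "$"), change)) {
    if (has_range)
      fv_stop(sprintf("substitution cannot span a range in '%s'", raw),
              "famvar_parse_error")
    kind <- "substitution"
    ref <- toupper(substr(change, 1L, 1L))
    alt <- toupper(substr(change, 3L, 3L))
    if (ref == alt)
      fv_stop(sprintf("ref and alt alleles are identical in '%s'", raw),
              "famvar_parse_error")
  } else if (grepl(paste0("^delins", base_re, "+$"), change)) {
    kind <- "delins"
    ref <- ""
    alt <- toupper(sub("^delins", "", change))
  } else if (grepl(paste0("^del(", base_re, "+)?$"), change)) {
    kind <- "deletion"
    ref <- toupper(sub("^del", "", change))
    alt <- ""
  } else if (grepl(paste0("^ins", base_re, "+$"), change)) {
    if (!has_range)
      fv_stop(sprintf("insertion requires a flanking-position range in '%s'",
                      raw), "famvar_parse_error")
    kind <- "insertion"
    ref <- ""
    alt <- toupper(sub("^ins", "", change))
  } else {
    fv_stop(sprintf("unrecognized change token '%s' in '%s'", change, raw),
            "famvar_parse_error")
  }

  if (!is.na(zygosity) && !zygosity %in% c("het", "hom"))
    fv_stop(sprintf("zygosity must be 'het' or 'hom', got '%s'", zygosity),
            "famvar_validation_error")

  structure(
    list(gene_symbol = gene_symbol, position = position,
         intron_offset = intron_offset, end_position = end_position,
         end_offset = end_offset, ref_allele = ref, alt_allele = alt,
         kind = kind, zygosity = zygosity, sample_id = sample_id),
    class = "CodingVariant")
}

#' Format a coding variant back to HGVS c. notation
#'
#' Inverse of [parse_hgvs_c()] for the notation used in carrier-screen
#' tables (no `c.` prefix). `format(parse_hgvs_c(x)) == x` for strings in
#' that dialect.
#'
#' @param v A `CodingVariant`.
#' @return A single HGVS string.
#' @export
format_hgvs_c <- function(v) {
  stopifnot(inherits(v, "CodingVariant"))
  fmt_pos <- function(p, o) {
    paste0(p, if (o != 0L) sprintf("%+d", o) else "")
  }
  loc <- fmt_pos(v$position, v$intron_offset)
  if (!is.na(v$end_position))
    loc <- paste0(loc, "_", fmt_pos(v$end_position, v$end_offset))
  switch(v$kind,
    substitution = paste0(loc, v$ref_allele, ">", v$alt_allele),
    deletion = paste0(loc, "del", v$ref_allele),
    insertion = paste0(loc, "ins", v$alt_allele),
    delins = paste0(loc, "delins", v$alt_allele))
}

#' @export
format.CodingVariant <- function(x, ...) format_hgvs_c(x)

#' @export
print.CodingVariant <- function(x, ...) {
  cat(sprintf("CodingVariant %s (%s)\n", format_hgvs_c(x), x$kind))
  invisible(x)
}

#' Codon arithmetic on coding coordinates
#'
#' `codon_index()` maps a 1-based coding (cDNA) position to the 1-based
#' index of the codon containing it: `floor((p - 1) / 3) + 1`.
#' `codon_offset()` gives the within-codon position (1, 2 or 3).
#'
#' @param position Coding position(s), 1-based; must be `>= 1`.
#' @return Integer codon index (or offset), vectorized over `position`.
#' @examples
#' codon_index(796)  # 266
#' codon_offset(796) # 1
#' @export
codon_index <- function(position) {
  position <- as.integer(position)
  if (anyNA(position) || any(position < 1L))
    fv_stop("coding position must be an integer >= 1", "famvar_domain_error")
  (position - 1L) %/% 3L + 1L
}

#' @rdname codon_index
#' @export
codon_offset <- function(position) {
  position <- as.integer(position)
  if (anyNA(position) || any(position < 1L))
    fv_stop("coding position must be an integer >= 1", "famvar_domain_error")
  (position - 1L) %% 3L + 1L
}

#' Translate a single codon with the standard genetic code
#'
#' Uses the standard nuclear genetic code (`Biostrings::GENETIC_CODE`).
#' Stop codons are returned as `"*"`; protein labels produced elsewhere
#' in the package render stop as `"X"` (the carrier-table style, e.g.
#' `L128X`).
#'
#' @param codon A 3-base unambiguous DNA string.
#' @return Single-letter amino acid, or `"*"` for stop.
#' @examples
#' translate_codon("TGG") # "W"
#' translate_codon("TGA") # "*"
#' @export
translate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  if (length(codon) != 1L || is.na(codon) || !grepl("^[ACGT]{3}$", codon))
    fv_stop(sprintf("codon must be 3 unambiguous DNA bases, got '%s'",
                    paste(codon, collapse = ",")),
            "famvar_domain_error")
  unname(Biostrings::GENETIC_CODE[codon])
}

# Translate a full CDS codon-by-codon; returns a character vector of
# single-letter amino acids ("*" for stop), one per codon.
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  starts <- 3L * seq_len(n) - 2L
  unname(Biostrings::GENETIC_CODE[substring(cds, starts, starts + 2L)])
}

# stop is "X" in protein labels (carrier-table style)
aa_label <- function(aa) ifelse(aa == "*", "X", aa)

new_consequence <- function(effect, codon_index = NA_integer_,
                            ref_aa = NA_character_, alt_aa = NA_character_,
                            protein_label = NA_character_, ...) {
  structure(
    c(list(effect = effect, codon_index = as.integer(codon_index),
           ref_aa = ref_aa, alt_aa = alt_aa, protein_label = protein_label),
      list(...)),
    class = "ConsequenceCall")
}

#' @export
print.ConsequenceCall <- function(x, ...) {
  cat(sprintf("ConsequenceCall: %s%s\n", x$effect,
              if (!is.na(x$protein_label)) paste0(" (", x$protein_label, ")")
              else ""))
  invisible(x)
}

#' Annotate an exonic single-base substitution
#'
#' Extracts the codon containing the variant position, substitutes the
#' alternate base at the in-codon offset, and translates reference and
#' mutant codons with the standard genetic code. The effect follows from
#' the amino-acid pair: identical = `synonymous`; mutant stop =
#' `nonsense`; reference `ATG` at codon 1 changed away from Met =
#' `start_loss`; otherwise `missense`. The protein label is
#' `<refAA><codon><altAA>` with stop rendered `X` (`W172X`, `M458K`).
#'
#' @param tm A [transcript_model()].
#' @param v A `CodingVariant` of kind `substitution` with
#'   `intron_offset == 0`.
#' @return A `ConsequenceCall` with `effect`, `codon_index`, `ref_aa`,
#'   `alt_aa`, `protein_label`.
#' @examples
#' tm <- transcript_model("TOY", "TOY-001", list(c(1, 21)),
#'                        "ATGGGCTGGCTACGTCTTTGA")
#' annotate_substitution(tm, parse_hgvs_c("8G>A"))  # W3X
#' @export
annotate_substitution <- function(tm, v) {
  stopifnot(inherits(tm, "TranscriptModel"), inherits(v, "CodingVariant"))
  if (v$kind != "substitution")
    fv_stop(sprintf("expected a substitution, got kind '%s'", v$kind),
            "famvar_domain_error")
  if (v$intron_offset != 0L)
    fv_stop("intronic substitutions are classified by classify_splice()",
            "famvar_domain_error")
  if (v$position > nchar(tm$cds_sequence))
    fv_stop(sprintf("position %d beyond CDS of length %d", v$position,
                    nchar(tm$cds_sequence)), "famvar_domain_error")
  cds_base <- substr(tm$cds_sequence, v$position, v$position)
  if (cds_base != v$ref_allele)
    fv_stop(sprintf(
      "ref allele mismatch at c.%d: variant says %s, CDS has %s (transcript %s)",
      v$position, v$ref_allele, cds_base, tm$transcript_id),
      "famvar_ref_mismatch")

  ci <- codon_index(v$position)
  off <- codon_offset(v$position)
  ref_codon <- substr(tm$cds_sequence, 3L * ci - 2L, 3L * ci)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- v$alt_allele
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)

  effect <-
    if (alt_aa == ref_aa) "synonymous"
    else if (ci == 1L && ref_codon == "ATG" && alt_aa != "M") "start_loss"
    else if (alt_aa == "*") "nonsense"
    else "missense"

  new_consequence(effect, ci, ref_aa, alt_aa,
                  paste0(aa_label(ref_aa), ci, aa_label(alt_aa)))
}

# exon index whose acceptor (offset < 0) or donor (offset > 0) boundary
# sits at coding position `position`; NA if none.
.boundary_exon <- function(tm, position, offset) {
  col <- if (offset < 0L) "first" else "last"
  idx <- which(tm$exon_cdna_bounds[, col] == position)
  if (length(idx) == 1L) idx else NA_integer_
}

#' Classify an intronic variant by distance to the splice site
#'
#' Variants with a nonzero intron offset are binned by their distance to
#' the exon boundary: `|offset| <= 2` is `splice_canonical` (the
#' near-invariant GT/AG dinucleotides; donor for positive offsets,
#' acceptor for negative), `3..10` is `splice_region`, beyond 10 is
#' `intronic`. The anchoring coding position must be an exon boundary of
#' the transcript (exon start for acceptor-side offsets, exon end for
#' donor-side).
#'
#' @param tm A [transcript_model()].
#' @param v A `CodingVariant` with `intron_offset != 0`.
#' @return A `ConsequenceCall` with `effect`, plus `splice_site`
#'   (`"acceptor"`/`"donor"`) and `exon_index` (the adjacent exon).
#' @examples
#' tm <- make_recql_like_transcript(1)
#' classify_splice(tm, parse_hgvs_c("395-2A>G"))$effect  # splice_canonical
#' @export
classify_splice <- function(tm, v) {
  stopifnot(inherits(tm, "TranscriptModel"), inherits(v, "CodingVariant"))
  if (v$intron_offset == 0L)
    fv_stop("variant is exonic (intron offset 0); use annotate_substitution()",
            "famvar_domain_error")
  exon <- .boundary_exon(tm, v$position, v$intron_offset)
  if (is.na(exon))
    fv_stop(sprintf(
      "c.%d is not an exon %s boundary of transcript %s",
      v$position, if (v$intron_offset < 0L) "start (acceptor)" else "end (donor)",
      tm$transcript_id), "famvar_validation_error")
  d <- abs(v$intron_offset)
  effect <- if (d <= 2L) "splice_canonical"
            else if (d <= 10L) "splice_region"
            else "intronic"
  new_consequence(effect,
                  splice_site = if (v$intron_offset < 0L) "acceptor" else "donor",
                  exon_index = exon)
}

#' Consequence of skipping one internal exon
#'
#' Models the outcome of a splice-disrupting mutation that causes the
#' spliceosome to skip the adjacent exon. If the exon's coding length is
#' not a multiple of 3 the downstream reading frame shifts: the call is
#' `frameshift`, anchored at the codon containing the exon's first
#' coding position, labelled `<refAA><codon>fs` (e.g. `G132fs`), and the
#' exon-deleted CDS is re-translated to locate the premature stop. A
#' length divisible by 3 yields an `inframe_deletion` of `length/3`
#' codons.
#'
#' @param tm A [transcript_model()].
#' @param exon_index Index of the skipped exon; must be `> 1` (the first
#'   coding exon carries the start codon and cannot be skipped this way)
#'   and at most the number of exons.
#' @return A `ConsequenceCall`; for frameshifts it additionally carries
#'   `premature_stop_codon`, the 1-based codon index of the first stop in
#'   the exon-deleted CDS (`NA` if none before the transcript end), and
#'   for in-frame skips `deleted_codons`.
#' @examples
#' tm <- make_recql_like_transcript(1)
#' exon_skip_consequence(tm, 5)$protein_label  # "G132fs"
#' @export
exon_skip_consequence <- function(tm, exon_index) {
  stopifnot(inherits(tm, "TranscriptModel"))
  exon_index <- as.integer(exon_index)
  n_exon <- nrow(tm$exon_cdna_bounds)
  if (length(exon_index) != 1L || is.na(exon_index) ||
      exon_index <= 1L || exon_index > n_exon)
    fv_stop(sprintf(
      "exon_index must be in 2..%d (the first coding exon cannot be skipped)",
      n_exon), "famvar_domain_error")
  first <- unname(tm$exon_cdna_bounds[exon_index, "first"])
  last <- unname(tm$exon_cdna_bounds[exon_index, "last"])
  exon_len <- last - first + 1L
  ci <- codon_index(first)
  ref_aa <- translate_codon(
    substr(tm$cds_sequence, 3L * ci - 2L, 3L * ci))

  if (exon_len %% 3L != 0L) {
    skipped <- paste0(substr(tm$cds_sequence, 1L, first - 1L),
                      substr(tm$cds_sequence, last + 1L,
                             nchar(tm$cds_sequence)))
    aa <- translate_cds(substr(skipped, 1L, 3L * (nchar(skipped) %/% 3L)))
    stop_at <- which(aa == "*")[1L]
    new_consequence("frameshift", ci, ref_aa = ref_aa,
                    protein_label = paste0(aa_label(ref_aa), ci, "fs"),
                    premature_stop_codon =
                      if (is.na(stop_at)) NA_integer_ else as.integer(stop_at),
                    exon_index = exon_index)
  } else {
    new_consequence("inframe_deletion", ci, ref_aa = ref_aa,
                    protein_label = paste0(aa_label(ref_aa), ci, "del"),
                    deleted_codons = exon_len %/% 3L,
                    exon_index = exon_index)
  }
}

#' Annotate any coding variant against a transcript model
#'
#' Dispatcher: exonic substitutions go to [annotate_substitution()];
#' variants with a nonzero intron offset go to [classify_splice()].
#' Exonic indels are not modelled beyond the splice pathway and raise a
#' domain error.
#'
#' @inheritParams annotate_substitution
#' @return A `ConsequenceCall`.
#' @export
annotate_variant <- function(tm, v) {
  if (v$intron_offset != 0L) classify_splice(tm, v)
  else if (v$kind == "substitution") annotate_substitution(tm, v)
  else fv_stop(sprintf("exonic '%s' changes are not supported", v$kind),
               "famvar_domain_error")
}
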