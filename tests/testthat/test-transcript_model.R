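test_that("parse_hgvs_c handles screen notation, with and without c. prefix", {
  v <- parse_hgvs_c("383T>G")
  expect_s3_class(v, "CodingVariant")
  expect_equal(v$position, 383L)
  expect_equal(v$intron_offset, 0L)
  expect_equal(v$ref_allele, "T")
  expect_equal(v$alt_allele, "G")
  expect_equal(v$kind, "substitution")

  v <- parse_hgvs_c("c.395-2A>G")
  expect_equal(v$position, 395L)
  expect_equal(v$intron_offset, -2L)
  expect_equal(v$ref_allele, "A")
  expect_equal(v$alt_allele, "G")

  v <- parse_hgvs_c("868-12_868-11del")
  expect_equal(v$kind, "deletion")
  expect_equal(v$position, 868L)
  expect_equal(v$intron_offset, -12L)
  expect_equal(v$end_position, 868L)
  expect_equal(v$end_offset, -11L)

  # unicode en-dash, as carrier tables sometimes print it
  expect_equal(format_hgvs_c(parse_hgvs_c("868–12_868-11del")),
               "868-12_868-11del")

  v <- parse_hgvs_c("100_101insAT")
  expect_equal(v$kind, "insertion")
  expect_equal(v$alt_allele, "AT")
  expect_equal(parse_hgvs_c("100delinsTT")$kind, "delins")
})

test_that("parse_hgvs_c rejects malformed and protein-level strings", {
  expect_error(parse_hgvs_c("lorem"), class = "famvar_parse_error")
  expect_error(parse_hgvs_c("p.L128X"), regexp = "protein-level",
               class = "famvar_parse_error")
  expect_error(parse_hgvs_c("383T>T"), class = "famvar_parse_error")
  expect_error(parse_hgvs_c("383T>GG"), class = "famvar_parse_error")
  expect_error(parse_hgvs_c("0A>G"), class = "famvar_parse_error")
  expect_error(parse_hgvs_c("200_100del"), class = "famvar_parse_error")
  expect_error(parse_hgvs_c("100ins"), class = "famvar_parse_error")
  expect_error(parse_hgvs_c("100insA"), class = "famvar_parse_error")
  expect_error(parse_hgvs_c(42), class = "famvar_parse_error")
})

test_that("parse then format round-trips every screened variant string", {
  for (s in screen_strings())
    expect_identical(format_hgvs_c(parse_hgvs_c(s)), s)
})

test_that("codon arithmetic maps coding positions to codons", {
  expect_equal(codon_index(796), 266L)
  expect_equal(codon_index(644), 215L)
  expect_equal(codon_index(1685), 562L)
  expect_equal(codon_index(c(1, 3, 4)), c(1L, 1L, 2L))
  expect_equal(codon_offset(c(1, 2, 3, 4)), c(1L, 2L, 3L, 1L))
  expect_error(codon_index(0), class = "famvar_domain_error")
  expect_error(codon_offset(-5), class = "famvar_domain_error")

  # bracket invariant: 3*(ci-1) < p <= 3*ci for all p
  p <- 1:300
  ci <- codon_index(p)
  expect_true(all(3 * (ci - 1) < p & p <= 3 * ci))
})

test_that("translate_codon follows the standard genetic code", {
  expect_equal(translate_codon("TGG"), "W")
  expect_equal(translate_codon("TGA"), "*")
  expect_equal(translate_codon("atg"), "M")
  expect_error(translate_codon("TG"), class = "famvar_domain_error")
  expect_error(translate_codon("TGN"), class = "famvar_domain_error")

  bases <- c("A", "C", "G", "T")
  for (c1 in bases) for (c2 in bases) for (c3 in bases) {
    codon <- paste0(c1, c2, c3)
    ref <- seqinr::translate(strsplit(codon, "")[[1]])
    expect_identical(translate_codon(codon), ref,
                     label = paste("codon", codon))
  }
})

test_that("transcript_model enforces its structural invariants", {
  expect_error(transcript_model("G", "T1", list(c(1, 21)), "ATGAAATGA"),
               class = "famvar_validation_error") # exons don't tile CDS
  expect_error(transcript_model("G", "T1", list(c(1, 9)), "TTGAAATGA"),
               class = "famvar_validation_error") # no ATG start
  expect_error(transcript_model("G", "T1", list(c(1, 9)), "ATGAAAAAA"),
               class = "famvar_validation_error") # no stop
  expect_error(transcript_model("G", "T1", list(c(1, 8)), "ATGAAATG"),
               class = "famvar_validation_error") # length not multiple of 3
  tm <- transcript_model("G", "T1", list(c(1, 5), c(6, 9)), "ATGAAATGA")
  expect_equal(tm$protein_length, 2L)
})

test_that("annotate_substitution reproduces the screened protein labels", {
  tm <- make_recql_like_transcript(seed = 11)
  expected <- data.frame(
    hgvs = c("383T>G", "516G>A", "796C>T", "644G>A", "1363C>T", "1373T>A",
             "1685C>T", "583G>T", "1616G>C", "187T>C", "1382A>G", "2T>C",
             "1088A>G"),
    label = c("L128X", "W172X", "Q266X", "R215Q", "R455C", "M458K",
              "T562I", "A195S", "R539P", "S63P", "H461R", "M1T", "N363S"),
    effect = c("nonsense", "nonsense", "nonsense", "missense", "missense",
               "missense", "missense", "missense", "missense", "missense",
               "missense", "start_loss", "missense"))
  for (i in seq_len(nrow(expected))) {
    call <- annotate_substitution(tm, parse_hgvs_c(expected$hgvs[i]))
    expect_equal(call$protein_label, expected$label[i])
    expect_equal(call$effect, expected$effect[i])
  }
  # a substitution whose mutant codon encodes the same residue
  tm2 <- transcript_model("G", "T1", list(c(1, 9)), "ATGCTATAA")
  syn <- annotate_substitution(tm2, parse_hgvs_c("6A>G")) # CTA -> CTG, Leu
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$protein_label, "L2L")
})

test_that("annotate_substitution flags inconsistent input", {
  tm <- make_recql_like_transcript(seed = 11)
  expect_error(annotate_substitution(tm, parse_hgvs_c("383A>G")),
               class = "famvar_ref_mismatch")
  expect_error(annotate_substitution(tm, parse_hgvs_c("99999A>G")),
               class = "famvar_domain_error")
  expect_error(annotate_substitution(tm, parse_hgvs_c("395-2A>G")),
               class = "famvar_domain_error")
  expect_error(annotate_substitution(tm, parse_hgvs_c("100del")),
               class = "famvar_domain_error")
})

test_that("annotation agrees with the full-CDS retranslation oracle", {
  tm <- random_transcript(seed = 207, n_codon = 60)
  bases <- c("A", "C", "G", "T")
  len <- nchar(tm$cds_sequence) - 3 # leave the stop codon alone
  checks <- 0
  for (pos in seq_len(len)) {
    ref <- substr(tm$cds_sequence, pos, pos)
    for (alt in setdiff(bases, ref)) {
      got <- annotate_substitution(
        tm, parse_hgvs_c(paste0(pos, ref, ">", alt)))
      want <- retranslation_oracle(tm, pos, alt)
      expect_equal(got$effect, want$effect,
                   label = sprintf("effect at %d%s>%s", pos, ref, alt))
      expect_equal(got$codon_index, as.integer(want$codon))
      expect_equal(got$ref_aa, want$ref_aa)
      expect_equal(got$alt_aa, want$alt_aa)
      checks <- checks + 1
    }
  }
  expect_gte(checks, 500)
})

test_that("classify_splice bins variants by distance to the splice site", {
  tm <- make_recql_like_transcript(seed = 11)

  acc <- classify_splice(tm, parse_hgvs_c("395-2A>G"))
  expect_equal(acc$effect, "splice_canonical")
  expect_equal(acc$splice_site, "acceptor")
  expect_equal(acc$exon_index, 5L)

  deep <- classify_splice(tm, parse_hgvs_c("868-12_868-11del"))
  expect_equal(deep$effect, "intronic")
  expect_equal(deep$exon_index, 8L)

  expect_equal(classify_splice(tm, parse_hgvs_c("395-3C>T"))$effect,
               "splice_region")
  don <- classify_splice(tm, parse_hgvs_c("394+1G>A"))
  expect_equal(don$effect, "splice_canonical")
  expect_equal(don$splice_site, "donor")
  expect_equal(don$exon_index, 4L)

  expect_error(classify_splice(tm, parse_hgvs_c("400-2A>G")),
               class = "famvar_validation_error")
  expect_error(classify_splice(tm, parse_hgvs_c("395A>G")),
               class = "famvar_domain_error")
})

test_that("exon skipping frameshifts iff the exon length is not 0 mod 3", {
  tm <- make_recql_like_transcript(seed = 11)

  skip5 <- exon_skip_consequence(tm, 5)
  expect_equal(skip5$effect, "frameshift")
  expect_equal(skip5$codon_index, 132L)
  expect_equal(skip5$protein_label, "G132fs")

  # the reported premature stop equals the first stop of the brute-force
  # re-translated mutant CDS
  b <- tm$exon_cdna_bounds
  mutant <- paste0(substr(tm$cds_sequence, 1, b[5, "first"] - 1),
                   substr(tm$cds_sequence, b[5, "last"] + 1,
                          nchar(tm$cds_sequence)))
  aa <- vapply(seq_len(nchar(mutant) %/% 3), function(i)
    translate_codon(substr(mutant, 3 * i - 2, 3 * i)), character(1))
  expect_equal(skip5$premature_stop_codon, which(aa == "*")[1])

  # 90-nt exon 2 skips in frame
  skip2 <- exon_skip_consequence(tm, 2)
  expect_equal(skip2$effect, "inframe_deletion")
  expect_equal(skip2$deleted_codons, 30L)

  # a 99-nt exon deletes 33 codons
  toy <- random_transcript(seed = 5, n_codon = 60, n_exon = 1)
  toy2 <- transcript_model("SYN", "SYN-002", list(c(1, 60), c(61, 159),
                                                  c(160, 183)),
                           toy$cds_sequence)
  expect_equal(exon_skip_consequence(toy2, 2)$deleted_codons, 33L)

  # property over every skippable exon: frameshift iff length %% 3 != 0
  for (i in 2:nrow(b)) {
    len <- unname(b[i, "last"] - b[i, "first"] + 1)
    expect_equal(exon_skip_consequence(tm, i)$effect == "frameshift",
                 len %% 3 != 0, label = paste("exon", i))
  }

  expect_error(exon_skip_consequence(tm, 1), class = "famvar_domain_error")
  expect_error(exon_skip_consequence(tm, 99), class = "famvar_domain_error")
})
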