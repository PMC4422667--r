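# Independent oracles and fixture builders shared across test files.
# Oracles deliberately avoid the code paths they check.

# Two-sided Fisher p by direct factorial enumeration over all tables
# with the observed margins (valid for totals <= 170).
enum_fisher_p <- function(a, case_n, c, control_n) {
  b <- case_n - a
  d <- control_n - c
  n <- case_n + control_n
  k <- a + c
  point_p <- function(x) {
    factorial(case_n) * factorial(control_n) * factorial(k) *
      factorial(n - k) /
      (factorial(n) * factorial(x) * factorial(case_n - x) *
         factorial(k - x) * factorial(control_n - k + x))
  }
  support <- max(0, k - control_n):min(case_n, k)
  probs <- vapply(support, point_p, numeric(1))
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# A random valid transcript: n_codon sense codons + stop, partitioned
# into a few exons at random cut points.
random_transcript <- function(seed, n_codon = 60, n_exon = 4) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    sense <- setdiff(all64, c("TAA", "TAG", "TGA"))
    codons <- c("ATG", sample(sense, n_codon - 1, replace = TRUE))
    cds <- paste0(paste(codons, collapse = ""), "TAA")
    len <- nchar(cds)
    cuts <- sort(sample(2:(len - 1), n_exon - 1))
    first <- c(1L, cuts)
    last <- c(cuts - 1L, len)
    transcript_model("SYN", "SYN-001",
                     Map(c, first, last), cds)
  })
}

# Consequence of a substitution by whole-protein diffing: translate the
# full original and mutated CDS and compare residue by residue.
retranslation_oracle <- function(tm, position, alt) {
  aa_of <- function(cds) {
    n <- nchar(cds) %/% 3
    starts <- 3 * seq_len(n) - 2
    unname(Biostrings::GENETIC_CODE[substring(cds, starts, starts + 2)])
  }
  mut <- tm$cds_sequence
  substr(mut, position, position) <- alt
  ref_aa_seq <- aa_of(tm$cds_sequence)
  alt_aa_seq <- aa_of(mut)
  diff <- which(ref_aa_seq != alt_aa_seq)
  ci <- (position - 1) %/% 3 + 1
  if (length(diff) == 0) {
    list(effect = "synonymous", codon = ci,
         ref_aa = ref_aa_seq[ci], alt_aa = ref_aa_seq[ci])
  } else {
    ref_aa <- ref_aa_seq[diff]
    alt_aa <- alt_aa_seq[diff]
    effect <- if (ci == 1 && substr(tm$cds_sequence, 1, 3) == "ATG" &&
                  alt_aa != "M") "start_loss"
              else if (alt_aa == "*" && ref_aa != "*") "nonsense"
              else "missense"
    list(effect = effect, codon = diff, ref_aa = ref_aa, alt_aa = alt_aa)
  }
}

# Build a small qualifying variant-table row quickly.
vrow <- function(sample_id, gene, hgvs = "100A>G", kind = "substitution",
                 zygosity = "het", effect = "nonsense", db_flags = "",
                 damaging = NA) {
  data.frame(sample_id = sample_id, gene = gene,
             transcript_id = NA_character_, hgvs_c = hgvs, kind = kind,
             zygosity = zygosity, effect = effect, db_flags = db_flags,
             damaging_prediction = damaging, stringsAsFactors = FALSE)
}

# Recurrence recount by plain loops, mirroring the two-stream rule
# independently of recurrent_genes().
brute_recurrence <- function(df, min_cases = 2, distinct = TRUE) {
  qualifies <- function(sub) {
    length(unique(sub$sample_id)) >= min_cases &&
      (!distinct || length(unique(sub$hgvs_c)) >= 2)
  }
  out <- character(0)
  for (g in unique(df$gene)) {
    sub <- df[df$gene == g, ]
    snv <- sub[sub$kind == "substitution", ]
    ind <- sub[sub$kind != "substitution", ]
    if ((nrow(snv) > 0 && qualifies(snv)) ||
        (nrow(ind) > 0 && qualifies(ind)))
      out <- c(out, g)
  }
  sort(out)
}

screen_strings <- function() {
  c("383T>G", "516G>A", "796C>T", "395-2A>G", "644G>A", "1363C>T",
    "1373T>A", "1685C>T", "583G>T", "1616G>C", "187T>C", "1382A>G",
    "2T>C", "1088A>G", "868-12_868-11del")
}
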