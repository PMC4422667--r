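# --- reference layout of the RECQL-like transcript -----------------------
#
# 649 codons + stop over 13 exons. Exon 5's acceptor sits at coding
# position 395 and its length (172 nt) is not a multiple of 3, so
# skipping it shifts the frame from codon 132 (a glycine) onward; exon
# 8's acceptor sits at coding position 868 so deep-intronic changes
# upstream of it are classifiable. Constrained codons make the screen's
# fifteen cDNA changes reproduce their printed protein labels (e.g.
# TTA at codon 128 so 383T>G reads L128X); everything else is seeded
# random fill.
.recql_exons <- list(
  c(1L, 155L), c(156L, 245L), c(246L, 320L), c(321L, 394L),
  c(395L, 566L), c(567L, 720L), c(721L, 867L), c(868L, 1030L),
  c(1031L, 1240L), c(1241L, 1450L), c(1451L, 1650L),
  c(1651L, 1800L), c(1801L, 1950L))

.recql_fixed_codons <- c(
  `1` = "ATG",   # start; 2T>C -> ACG = M1T (start loss)
  `63` = "TCC",  # 187T>C -> CCC = S63P
  `128` = "TTA", # 383T>G -> TGA = L128X
  `132` = "GGT", # frameshift anchor: exon-5 skip reads G132fs
  `172` = "TGG", # 516G>A -> TGA = W172X
  `195` = "GCC", # 583G>T -> TCC = A195S
  `215` = "CGA", # 644G>A -> CAA = R215Q
  `266` = "CAA", # 796C>T -> TAA = Q266X
  `363` = "AAT", # 1088A>G -> AGT = N363S
  `455` = "CGC", # 1363C>T -> TGC = R455C
  `458` = "ATG", # 1373T>A -> AAG = M458K
  `461` = "CAT", # 1382A>G -> CGT = H461R
  `539` = "CGC", # 1616G>C -> CCC = R539P
  `562` = "ACC") # 1685C>T -> ATC = T562I

# the fifteen screened changes and what annotating them must yield
.screen_variants <- function() {
  data.frame(
    hgvs_c = c("383T>G", "516G>A", "796C>T", "395-2A>G", "644G>A",
               "1363C>T", "1373T>A", "1685C>T", "583G>T", "1616G>C",
               "187T>C", "1382A>G", "2T>C", "1088A>G",
               "868-12_868-11del"),
    protein_change = c("L128X", "W172X", "Q266X", "G132fs", "R215Q",
                       "R455C", "M458K", "T562I", "A195S", "R539P",
                       "S63P", "H461R", "M1T", "N363S", "-"),
    effect = c("nonsense", "nonsense", "nonsense", "splice_canonical",
               "missense", "missense", "missense", "missense", "missense",
               "missense", "missense", "missense", "start_loss",
               "missense", "intronic"),
    stringsAsFactors = FALSE)
}

#' Generate the RECQL-like transcript model
#'
#' Builds a 649-codon transcript over 13 exons emulating the RECQL
#' coding sequence to the extent the screen constrains it: exon 5's
#' splice acceptor at coding position 395 with an exon length that is
#' not a multiple of 3 (so skipping it frameshifts from codon 132, a
#' glycine), an exon acceptor at coding position 868, and codons fixed
#' at the fifteen screened sites so that each cDNA change yields its
#' printed protein label (`383T>G` reads `L128X`, `1373T>A` reads
#' `M458K`, ...). All remaining codons are random non-stop codons drawn
#' reproducibly from `seed`.
#'
#' @param seed Integer seed; the same seed always yields the same
#'   transcript.
#' @param validate Re-annotate the fifteen screened changes and fail if
#'   any label deviates (a guard against drift between the constraint
#'   table and the annotation code).
#' @return A [transcript_model()] with `gene_symbol = "RECQL"` and 649
#'   codons.
#' @examples
#' tm <- make_recql_like_transcript(1)
#' annotate_substitution(tm, parse_hgvs_c("796C>T"))$protein_label # "Q266X"
#' @export
make_recql_like_transcript <- function(seed = 1L, validate = TRUE) {
  n_codon <- 649L
  codons <- withr::with_seed(as.integer(seed), {
    bases <- c("A", "C", "G", "T")
    all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    sense <- setdiff(all64, c("TAA", "TAG", "TGA"))
    sample(sense, n_codon, replace = TRUE)
  })
  codons[as.integer(names(.recql_fixed_codons))] <- .recql_fixed_codons
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  tm <- transcript_model("RECQL", "RECQL-001", .recql_exons, cds)

  if (validate) {
    tab <- .screen_variants()
    for (i in seq_len(nrow(tab))) {
      v <- parse_hgvs_c(tab$hgvs_c[i])
      call <- annotate_variant(tm, v)
      label_ok <- if (call$effect %in% c("splice_canonical", "intronic")) {
        call$effect == tab$effect[i]
      } else {
        call$effect == tab$effect[i] &&
          identical(call$protein_label, tab$protein_change[i])
      }
      if (!label_ok)
        fv_stop(sprintf(
          "transcript constraints unsatisfiable: %s annotated as %s/%s, expected %s/%s",
          tab$hgvs_c[i], call$effect, call$protein_label %||% NA,
          tab$effect[i], tab$protein_change[i]),
          "famvar_validation_error")
    }
    skip <- exon_skip_consequence(tm, 5L)
    if (!identical(skip$protein_label, "G132fs"))
      fv_stop("transcript constraints unsatisfiable: exon-5 skip did not read G132fs",
              "famvar_validation_error")
  }
  tm
}

#' Simulation parameters for a case/control cohort
#'
#' Defaults mirror the screened study design: 448 cases and 1,588
#' controls, nine planted pathogenic-variant carriers among cases versus
#' one among controls, a Poisson background of 3 qualifying-scale
#' variants per exome after upstream quality filtration, half of
#' background variants catalogued in an excluded database, and a
#' 20,000-symbol gene universe.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param background_rate Mean background variants per case exome
#'   (Poisson).
#' @param known_db_fraction Probability a background variant carries an
#'   excluded-database flag.
#' @param planted_gene Gene symbol receiving the planted variants.
#' @param planted_case_carriers,planted_control_carriers Carriers of a
#'   planted pathogenic variant in each arm.
#' @param gene_universe_size Number of background gene symbols.
#' @param seed Integer seed.
#' @return A list of class `CohortSimParams`.
#' @export
cohort_sim_params <- function(n_cases = 448L, n_controls = 1588L,
                              background_rate = 3,
                              known_db_fraction = 0.5,
                              planted_gene = "RECQL",
                              planted_case_carriers = 9L,
                              planted_control_carriers = 1L,
                              gene_universe_size = 20000L,
                              seed = 1L) {
  p <- list(n_cases = as.integer(n_cases),
            n_controls = as.integer(n_controls),
            background_rate = as.numeric(background_rate),
            known_db_fraction = as.numeric(known_db_fraction),
            planted_gene = as.character(planted_gene),
            planted_case_carriers = as.integer(planted_case_carriers),
            planted_control_carriers = as.integer(planted_control_carriers),
            gene_universe_size = as.integer(gene_universe_size),
            seed = as.integer(seed))
  if (p$background_rate < 0 || p$known_db_fraction < 0 ||
      p$known_db_fraction > 1)
    fv_stop("rates must be non-negative (known_db_fraction in [0,1])",
            "famvar_validation_error")
  if (p$planted_case_carriers > p$n_cases ||
      p$planted_control_carriers > p$n_controls)
    fv_stop("planted carriers cannot exceed the cohort size",
            "famvar_validation_error")
  structure(p, class = "CohortSimParams")
}

# empty variant table with the canonical columns
vrow_template <- function() {
  data.frame(sample_id = character(0L), gene = character(0L),
             transcript_id = character(0L), hgvs_c = character(0L),
             kind = character(0L), zygosity = character(0L),
             effect = character(0L), db_flags = character(0L),
             damaging_prediction = logical(0L), stringsAsFactors = FALSE)
}

# planted-variant pool: the screen's pathogenic set, ordered so the
# first two carriers receive one nonsense and one damaging-predicted
# missense (the discovery configuration)
.planted_pool <- function() {
  data.frame(
    hgvs_c = c("383T>G", "644G>A", "516G>A", "796C>T", "395-2A>G",
               "1363C>T", "1373T>A", "1685C>T", "583G>T"),
    effect = c("nonsense", "missense", "nonsense", "nonsense",
               "splice_canonical", "missense", "missense", "missense",
               "missense"),
    stringsAsFactors = FALSE)
}

#' Simulate a case/control cohort with planted pathogenic variants
#'
#' Case exomes receive Poisson background variants over a gene universe
#' (database-flagged at the configured fraction, mostly heterozygous,
#' with a realistic mix of consequence classes) plus, for the planted
#' carriers, one heterozygous pathogenic variant each in the planted
#' gene, drawn in order from the screen's pathogenic set so that any two
#' carriers hold *different* variants. Controls enter only as carrier
#' counts (the discovery procedure never sees control exomes).
#'
#' @param params A [cohort_sim_params()].
#' @return A list: `cases` (a cohort variant table, see
#'   [read_variant_table()]), `control_counts` (a [cohort_counts()] of
#'   planted carriers), and `manifest` (ground truth: planted gene,
#'   carrier sample ids and their variants, and the parameters).
#' @examples
#' sim <- make_cohort(cohort_sim_params(n_cases = 9, seed = 7,
#'                                      planted_case_carriers = 2))
#' recurrent_genes(filter_cascade(sim$cases))$gene
#' @export
make_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "CohortSimParams"))
  withr::with_seed(params$seed, {
    bases <- c("A", "C", "G", "T")
    universe <- setdiff(
      sprintf("GENE%05d", seq_len(params$gene_universe_size)),
      params$planted_gene)
    sample_ids <- sprintf("CASE%04d", seq_len(params$n_cases))

    n_bg <- rpois(params$n_cases, params$background_rate)
    n <- sum(n_bg)
    background <- if (n > 0L) {
      eff <- sample(c("missense", "synonymous", "nonsense", "frameshift",
                      "splice_canonical", "intronic"), n, replace = TRUE,
                    prob = c(0.55, 0.25, 0.08, 0.05, 0.04, 0.03))
      pos <- sample.int(2000L, n, replace = TRUE)
      ref <- sample(bases, n, replace = TRUE)
      # shift ref by 1..3 within ACGT to get a different alt base
      alt <- bases[(match(ref, bases) - 1L +
                      sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
      kind <- ifelse(eff == "frameshift", "deletion", "substitution")
      data.frame(
        sample_id = rep(sample_ids, n_bg),
        gene = sample(universe, n, replace = TRUE),
        transcript_id = NA_character_,
        hgvs_c = ifelse(kind == "deletion", paste0(pos, "del"),
                        paste0(pos, ref, ">", alt)),
        kind = kind,
        zygosity = sample(c("het", "hom"), n, replace = TRUE,
                          prob = c(0.95, 0.05)),
        effect = eff,
        db_flags = ifelse(runif(n) < params$known_db_fraction,
                          "dbSNP132", ""),
        damaging_prediction = ifelse(eff == "missense",
                                     runif(n) < 0.3, NA),
        stringsAsFactors = FALSE)
    } else NULL

    carriers <- if (params$planted_case_carriers > 0L)
      sort(sample(sample_ids, params$planted_case_carriers)) else character(0L)
    pool <- .planted_pool()
    planted <- if (length(carriers)) {
      idx <- ((seq_along(carriers) - 1L) %% nrow(pool)) + 1L
      data.frame(
        sample_id = carriers,
        gene = params$planted_gene,
        transcript_id = "RECQL-001",
        hgvs_c = pool$hgvs_c[idx],
        kind = "substitution",
        zygosity = "het",
        effect = pool$effect[idx],
        db_flags = "",
        damaging_prediction = ifelse(pool$effect[idx] == "missense",
                                     TRUE, NA),
        stringsAsFactors = FALSE)
    } else NULL

    cases <- rbind(background, planted)
    if (is.null(cases))
      cases <- vrow_template()
    cases <- cases[order(match(cases$sample_id, sample_ids)), , drop = FALSE]
    rownames(cases) <- NULL

    list(cases = cases,
         control_counts = cohort_counts(params$planted_case_carriers,
                                        params$n_cases,
                                        params$planted_control_carriers,
                                        params$n_controls),
         manifest = list(planted_gene = params$planted_gene,
                         carrier_samples = carriers,
                         carrier_variants =
                           if (length(carriers)) planted$hgvs_c
                           else character(0L),
                         params = params))
  })
}

#' Simulate helicase-assay replicate tables
#'
#' Draws per-replicate percent-unwinding values from Gaussian noise
#' around per-mutant means (truncated to `[0, 100]`) and converts them to
#' band-intensity pairs on a 1000-unit lane scale. The default means
#' emulate the screen's quantified gels: wild type near 75% unwinding,
#' four missense mutants with essentially no detectable product, one at
#' 16.6% of the wild-type level (an ~83.4% activity loss), three
#' indistinguishable from wild type, and the helicase-dead K119A
#' negative control.
#'
#' @param class_means Named vector of mean percent unwinding per mutant
#'   (must include the wild-type label).
#' @param sd Replicate noise SD in percentage points (default 1.5, the
#'   scale of densitometry replicate spread in quantified gel assays;
#'   tight enough that lanes with essentially undetectable product stay
#'   within the complete-loss band).
#' @param n_reps Replicates per mutant (>= 3; three independent
#'   experiments is the assay convention).
#' @param seed Integer seed.
#' @return A replicate table: `mutant`, `replicate`, `ss_signal`,
#'   `ds_signal`.
#' @examples
#' summarize_assay(make_assay_replicates(seed = 1))
#' @export
make_assay_replicates <- function(class_means = NULL, sd = 1.5,
                                  n_reps = 3L, seed = 1L) {
  if (is.null(class_means)) {
    wt_mean <- 75
    class_means <- c(
      WT = wt_mean,
      R215Q = 0.8, R455C = 0.9, M458K = 1.1, T562I = 0.7,
      A195S = 0.166 * wt_mean,
      S63P = 0.97 * wt_mean, H461R = 1.01 * wt_mean,
      R539P = 0.95 * wt_mean,
      K119A = 0.6)
  }
  if (is.null(names(class_means)) || any(names(class_means) == ""))
    fv_stop("class_means must be a fully named vector",
            "famvar_validation_error")
  if (sd < 0)
    fv_stop("noise sd must be non-negative", "famvar_domain_error")
  n_reps <- as.integer(n_reps)
  if (n_reps < 3L)
    fv_stop("n_reps must be >= 3", "famvar_validation_error")

  withr::with_seed(as.integer(seed), {
    rows <- lapply(names(class_means), function(lab) {
      pct <- pmin(100, pmax(0, rnorm(n_reps, class_means[[lab]], sd)))
      ss <- round(pct * 10)
      data.frame(mutant = lab, replicate = seq_len(n_reps),
                 ss_signal = ss, ds_signal = 1000 - ss,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a tumor/germline allele-depth table
#'
#' Generates one heterozygous germline site per case (alt fraction near
#' 0.5) and a matched tumor read-out: balanced for cases retaining
#' heterozygosity, collapsed to a minor-allele fraction below 0.08 for
#' planted LOH cases. The default emulates the screen's LOH panel: five
#' evaluable tumors, none with allelic loss.
#'
#' @param n_cases Number of tumor/germline pairs.
#' @param loh_cases How many of them carry true allelic loss.
#' @param depth Sequencing depth (total allele count) per tissue.
#' @param variants Variant labels recycled across cases; defaults to the
#'   screen's five LOH-assayed changes.
#' @param seed Integer seed.
#' @return A depth table: `case_id`, `variant`, `g_ref`, `g_alt`,
#'   `t_ref`, `t_alt`.
#' @examples
#' table(assess_loh_table(make_loh_depths(seed = 3))$call)
#' @export
make_loh_depths <- function(n_cases = 5L, loh_cases = 0L, depth = 100L,
                            variants = c("395-2A>G", "583G>T", "796C>T",
                                         "1373T>A", "1685C>T"),
                            seed = 1L) {
  n_cases <- as.integer(n_cases)
  loh_cases <- as.integer(loh_cases)
  if (loh_cases > n_cases)
    fv_stop("loh_cases cannot exceed n_cases", "famvar_validation_error")
  withr::with_seed(as.integer(seed), {
    is_loh <- seq_len(n_cases) <= loh_cases
    g_alt <- round(depth * runif(n_cases, 0.45, 0.55))
    t_frac <- ifelse(is_loh, runif(n_cases, 0.0, 0.08),
                     runif(n_cases, 0.42, 0.58))
    t_alt <- round(depth * t_frac)
    data.frame(case_id = sprintf("LOH%02d", seq_len(n_cases)),
               variant = rep_len(variants, n_cases),
               g_ref = as.integer(depth - g_alt),
               g_alt = as.integer(g_alt),
               t_ref = as.integer(depth - t_alt),
               t_alt = as.integer(t_alt),
               stringsAsFactors = FALSE)
  })
}

#' The packaged carrier-screen evidence table
#'
#' Returns the fifteen-variant evidence table packaged with famvar: for
#' each germline variant found by screening the coding region in 448
#' familial breast cancer cases and up to 1,588 controls, its cDNA and
#' protein change, consequence class, in-silico prediction flags,
#' helicase-assay class, transcript-analysis outcome, tumor-LOH status
#' and per-arm carrier counts (one recurrent start-loss variant was
#' genotyped in 748 controls only, and keeps that denominator).
#'
#' @return A data.frame of 15 evidence rows (see [evidence_record()] for
#'   the core columns; `sift`, `polyphen` and `loh` ride along).
#' @examples
#' classify_table(screen_evidence())$n_pathogenic  # 9
#' @export
screen_evidence <- function() {
  read_evidence_table(system.file("extdata", "screen_evidence.tsv",
                                  package = "famvar", mustWork = TRUE))
}

#' Write the packaged evidence fixture to a file
#'
#' Byte-exact copy of the packaged fifteen-row evidence TSV (see
#' [screen_evidence()]), for use as input to external tools.
#'
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_screen_fixture <- function(path) {
  src <- system.file("extdata", "screen_evidence.tsv", package = "famvar",
                     mustWork = TRUE)
  if (!file.copy(src, path, overwrite = TRUE))
    fv_stop(sprintf("could not write fixture to '%s'", path),
            "famvar_validation_error")
  invisible(path)
}
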