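---
title: "Methods: candidate-gene discovery and evidence-based variant classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene discovery and evidence-based variant classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

famvar re-implements, as tested functions, the analysis chain of a
familial breast cancer candidate-gene screen: exome filtration and
cross-case recurrence, coding-consequence annotation, evidence-based
pathogenicity classification, exact carrier-burden statistics, helicase
assay quantification, and tumor loss-of-heterozygosity (LOH)
assessment. This vignette documents the models, every tunable that
matters, the numerical choices, and what the synthetic data do and do
not establish.

## Transcript model and consequence annotation

All annotation is performed in HGVS coding (c.) coordinates against a
`TranscriptModel`: an exon segmentation of the coding sequence (1-based,
inclusive, tiling `1..length(CDS)` with no gaps) plus the CDS itself,
stop codon included. Genomic coordinates, strand, and multi-transcript
annotation are deliberately out of scope: a carrier-screen table is
written against one reference transcript, and the c. frame makes every
operation a pure function of the CDS.

Codon arithmetic is exact integer arithmetic: position $p$ lies in codon
$\lfloor (p-1)/3 \rfloor + 1$ at in-codon offset $((p-1) \bmod 3) + 1$.
A substitution is annotated by editing the one affected codon and
translating reference and mutant codons with the standard genetic code
(`Biostrings::GENETIC_CODE`); the effect follows from the amino-acid
pair, with two special cases: a codon-1 `ATG` changed away from
methionine is `start_loss` (its own class, so classification rules can
treat it separately from missense), and a mutant stop is `nonsense`.
Protein labels use the carrier-table style with stop rendered `X`
(`L128X`, not `L128*` or `L128Ter`). A reference-allele mismatch between
variant and CDS raises an error rather than silently re-anchoring —
this catches drift between a variant table and the transcript it was
called against.

Intronic variants are binned by distance to the splice site: |offset|
≤ 2 is `splice_canonical` (the near-invariant GT/AG dinucleotides),
3–10 is `splice_region`, beyond 10 `intronic`. Only the ±2 window has a
mechanistic guarantee; the 10-nt boundary of the region class is a
conventional choice and both edges are visible in `classify_splice()`'s
contract rather than buried. The anchoring coding position must be an
actual exon boundary of the transcript, otherwise the variant and
transcript are inconsistent and the call errors.

Exon skipping is modelled literally: remove the exon's coding interval,
and if its length is not a multiple of three, the downstream frame
shifts. The call is anchored at the codon containing the exon's first
coding position (codon 132 for an exon starting at c.395), labelled
`<refAA><codon>fs`, and the premature stop is located by re-translating
the exon-deleted CDS — not by any shortcut formula. The package's
invariant suite checks, for every position and alternate base of a
random transcript, that single-codon annotation agrees with a
whole-protein diff of full re-translation, so the fast path can never
drift from the definitional one.

## The filter cascade and recurrence rule

Per-exome filtration is two row-wise predicates, applied in either
order with identical results (a property the tests assert):

1. **Database exclusion** — any variant whose membership flags intersect
   `excluded_databases` (default dbSNP 132 and 1000 Genomes) is
   removed. "Rare/novel" is operationalized as exactly this absence; no
   allele-frequency field exists at this stage.
2. **Functional retention** — keep heterozygous variants that are
   truncating (`nonsense`, `frameshift`), canonical-splice, or — when
   `admit_damaging_missense = TRUE` (default) — missense/start-loss
   flagged damaging by in-silico prediction. The flag exists because
   the discovery design this package models admitted a
   damaging-predicted missense variant alongside truncating ones; both
   readings of the retention rule are expressible through the
   configuration rather than hard-coded.

Recurrence then keeps genes in which at least `min_recurrent_cases`
(default 2, the minimum that makes "recurrence" meaningful) distinct
samples carry qualifying variants, requiring at least two *different*
variants among them (`require_distinct_variants = TRUE`); a single
variant observed twice is more parsimoniously explained by a shared
haplotype or a systematic artifact. SNVs and indels are evaluated as
separate streams and qualifying genes unioned — this package's reading
of pipelines that call the two variant types with different tools; one
SNV plus one indel in the same gene across two cases therefore does
*not* qualify. Ranking is by supporting-sample count with
lexicographic tie-break, so output order is deterministic.

## Evidence precedence for pathogenicity

`classify_variant()` encodes the order in which lines of evidence were
weighed, as four rules tried in sequence; every variant triggers
exactly one rule, and the tests sweep the full evidence grid to verify
totality and monotonicity (upgrading functional evidence from normal
through partial to complete loss can never demote pathogenic to
neutral):

* **R1 — truncation.** Nonsense and frameshift consequences are
  pathogenic outright.
* **R2 — transcript analysis.** A canonical-splice variant with an
  aberrant truncating RT-PCR product is pathogenic; *any*
  splice-adjacent or intronic variant with a demonstrably normal
  transcript is neutral. A canonical-splice variant with no transcript
  evidence falls to VUS with a warning — the consequence class alone is
  treated as insufficient.
* **R3 — function.** Complete or partial loss of helicase activity is
  pathogenic; normal activity is neutral. Functional evidence outranks
  control presence by construction: a variant seen once in 1,588
  controls is still pathogenic if it inactivates the enzyme, and a
  variant private to cases is still neutral if activity is normal. The
  rule is applied to any non-truncating, non-splice variant carrying
  assay evidence (a slight superset of "missense only" that keeps the
  engine total).
* **R4 — frequency similarity.** With no functional data, carrier
  frequencies in cases and controls are compared by the two-sided exact
  test, each variant against its *own* control denominator (screens
  often genotype recurrent variants in a control subset; the packaged
  table carries one variant genotyped in 748 controls). "Similar" is
  formalized as p ≥ `alpha_sim`, default 0.05. The narrative this rule
  formalizes gives no explicit test, so the threshold is an exposed
  parameter, not a constant. Note the asymmetry: similarity ⇒ neutral,
  but dissimilarity alone ⇒ VUS — frequency cannot prove
  pathogenicity.

On the packaged fifteen-variant evidence table this engine yields 9
pathogenic (3 by R1, 1 by R2, 5 by R3), 6 neutral, 0 VUS — computed,
not asserted; the test suite and `scripts/acceptance.R` recompute it.

## Burden statistics

`fisher_exact_two_sided()` is authored from first principles because
the exact test *is* the headline statistic here. Conditioning on the
margins of the 2×2 table (carrier status × case/control), the
case-carrier count is hypergeometric; point probabilities are evaluated
as `lchoose` sums in log space (stable for cohort-scale $n$), and the
two-sided p follows the method of small p-values — the sum over all
tables with the observed margins whose point probability is at most
that of the observed table, with a relative tie tolerance of $10^{-7}$.
Sidedness convention and tie handling match the dominant convention, and
the tests pin the implementation to two independent routes: direct
factorial enumeration for every non-degenerate table with $n \le 30$
(> 10,000 tables), and `stats::fisher.test` at cohort scale. Degenerate
margins (nobody, or everybody, a carrier) return p = 1 with a warning
rather than an error.

The burden unit is the carrier, not the allele: carrier tables count
people. The odds ratio is the cross-product with an optional
Haldane–Anscombe +0.5 correction when a cell is zero and a Wald CI on
the log scale. Group comparisons (assay replicates, age at diagnosis)
use the Welch unequal-variance t-statistic with Satterthwaite degrees
of freedom — the conventional "unpaired two-tailed t-test" of assay figure legends without the
pooled-variance assumption, which is the safer default when group
spreads differ.

## Assay quantification and LOH

Percent unwinding is normalized per lane, `100·ss/(ss+ds)`; the
substrate-level boiled/unboiled controls of a gel are not separately
modelled (band pairs are assumed already background-corrected, a
documented simplification). Relative activity is the ratio of mutant to
wild-type mean percent unwinding. The three-class call uses thresholds
exposed as arguments: `complete_loss` at ≤ 5% of wild type (the
"essentially undetectable" regime), `partial_loss` up to 50% when the
deficit is also statistically supported (Welch p < 0.05 versus wild
type), `normal` otherwise. The anchors available for calibration are
qualitative classes plus one quantified intermediate (~83% loss, i.e.
~16.6% residual activity, comfortably inside the partial band); the
5%/50% edges are choices, made once and exposed.

The LOH contract replaces a qualitative Sanger-trace comparison with
three explicit criteria: the germline must be credibly heterozygous
(alt fraction within `het_band`, default [0.3, 0.7]); the tumor
minor-allele fraction must fall below `loh_minor_max` (default 0.15);
and the germline-versus-tumor allele counts must differ by the exact
test at `alpha` (default 0.01, conservative because trace peak heights
enter as ×100 pseudo-counts whose effective sample size is inflated).
Homozygous germline input is never evaluable, and the verdict is
invariant under simultaneously relabelling ref/alt in both tissues.
Tumor purity is unmodelled: a heavily contaminated tumor can mask true
LOH, and no correction is attempted.

## Synthetic data: what it emulates, and what it does not

`make_recql_like_transcript()` builds the one transcript the screen
constrains: 649 codons over 13 exons, exon 5's acceptor at coding
position 395 with a 172-nt length (≢ 0 mod 3, so the skip frameshifts
from codon 132), an acceptor at c.868, and fixed codons at the fifteen
screened sites chosen so each cDNA change reproduces its printed
protein label (e.g. `TTA` at codon 128 makes `383T>G` read `L128X`;
`CGA` at 215 makes `644G>A` read `R215Q`). The real exon lengths of the
gene are not published in the source material, so the segmentation
outside those constraints — including the 172-nt choice for exon 5 —
is the package's own, and the generator re-annotates all fifteen
changes at build time, erroring on any drift. Everything unconstrained
is seeded random fill from the 61 sense codons (no internal stops), so
different seeds give genuinely different transcripts satisfying the
same contract.

`make_cohort()` emulates the discovery cohort at the level the filter
consumes: per-case Poisson background (default rate 3 qualifying-scale
variants per exome, a post-quality-filtration scale at which the
recurrence filter's false-positive behaviour is visible but small over
a 20,000-gene universe), database flags on half the background, mostly
heterozygous genotypes, and planted heterozygous pathogenic variants —
distinct across carriers by construction, the first two carriers
receiving one nonsense and one damaging-predicted missense, the
discovery configuration. Controls appear only as carrier counts; the
procedure never sees control exomes. The manifest records ground truth
for recovery tests. What this does **not** emulate: read-level error,
variant-calling artifacts, linkage between variants, population
structure, or relatedness — so planted-gene recall of 1 over 100
seeded nine-case cohorts (a property the suite asserts) demonstrates
the logic of the cascade, not its performance on real exomes.

`make_assay_replicates()` draws replicate percent-unwinding values as
Gaussian noise truncated to [0, 100] around per-mutant means (defaults:
wild type 75%, four dead mutants ≈ 1%, one at 16.6% of wild type,
three near wild type, a helicase-dead control) and converts them to
band pairs on a 1000-unit lane scale. The noise SD defaults to 1.5
percentage points — densitometry-replicate scale, and small enough that
zero-truncation bias on the near-zero lanes does not push a dead
mutant's three-replicate mean across the 5% class boundary except in
rare seeds. `make_loh_depths()` generates balanced germline sites and
either balanced (retained) or collapsed (LOH) tumor read-outs; the
packaged five-tumor table is a synthetic stand-in for trace data that
was never deposited, and is named accordingly.

## Numerical and engineering choices

* All randomness flows through a single integer seed per generator
  call (`withr::with_seed`), so every simulated object is reproducible
  and two calls with the same seed are identical.
* Exact-test ties are compared with relative tolerance $10^{-7}$;
  enumeration oracles in the tests use direct `factorial()` arithmetic,
  valid to $n = 170$.
* Errors are classed conditions (`famvar_parse_error`,
  `famvar_domain_error`, `famvar_ref_mismatch`,
  `famvar_validation_error`), so callers can distinguish malformed
  input from inconsistent input from out-of-domain arguments.
* Table readers validate required columns and report offending line
  numbers; unknown extra columns are preserved with a warning
  (round-trip fidelity over strictness). VCF input is read-only and
  minimal by design, mapping `GENE`/`HGVSC`/`DBFLAGS`/`DMG` INFO keys
  onto the same record the TSV reader produces.
* Problem sizes in the test suite are chosen for exactness at desk
  scale: the substitution oracle sweeps all ~540 position×alt pairs of
  a 60-codon transcript; the Fisher oracle enumerates every table with
  $n \le 30$; recall properties use 100 seeds of nine-case cohorts;
  the permutation cross-check of the Welch test uses $10^5$ shuffles.

## Known limitations

* Exonic indels are parsed but not consequence-annotated beyond the
  splice pathway; the discovery classes of interest here are
  substitutions and splice-adjacent changes.
* The classifier is a faithful formalization of one screen's evidence
  logic, not an ACMG/AMP implementation; co-segregation, de novo
  status, and quantitative integration are out of scope.
* Splice classification is positional only — no spliceosomal strength
  scoring; a `splice_region` call is a distance statement, not a
  prediction.
* The LOH caller assumes the pseudo-count scale is honest about
  uncertainty; with trace-derived peak heights the exact test's nominal
  alpha is approximate at best, which is why the default alpha is
  conservative and the minor-fraction criterion must agree before LOH
  is called.
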