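---
title: "Methods: homology-based miRNA discovery and sex-locus candidate mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based miRNA discovery and sex-locus candidate mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhunt)
```

## The problem

Dioecious plants such as willows carry a single genetically mapped sex
locus — in willow a centromeric region of chromosome XV, under a ZW
system in which the female is the heterogametic sex — yet no causal
gene has been pinned down there. Because plant miRNAs are deeply
conserved, a transcriptome of flower buds can be mined for miRNAs by
homology alone, their targets predicted from sequence complementarity,
and the intersection of three signals examined: a target gene that (i)
lies in the sex locus, (ii) carries a binding site for a miRNA detected
in only one sex, and (iii) is expressed in only one sex — the silencing
logic being that a male-specific miRNA suppressing its target in males
leaves female-only expression. `mirhunt` implements that entire chain as
testable, file-driven stages with a seeded synthetic generator so each
stage can be validated against planted truth.

## Discovery funnel

**Reference handling.** Reference mature miRNAs (miRBase-style,
species-prefixed names) are deduplicated to unique sequences with
`dedupe_reference()`; the species prefixes of merged entries are pooled,
which both halves the search work and retains cross-species conservation
counts. The family of a name is `miR` plus its leading number
(`family_of()`), so `ssu-miR472a` and `ssu-miR472c` share family
`miR472` even though they are distinct mature sequences — inventory
comparisons are therefore offered at both the family and the sequence
level, and the two can legitimately disagree.

**Homology scan.** `scan_homology()` reports every ungapped occurrence
of each unique reference on either strand of each EST within a Hamming
budget. The default budget is 2 mismatches — the literal reading of a
"fewer than three mismatches" contract — and the interpretation in force
is echoed in every run log because the phrase is genuinely ambiguous.
Matching is delegated to `Biostrings::vmatchPattern`; overlapping hits
of one reference on one EST closer than the mature length are merged to
the lowest-mismatch, leftmost representative so output is deterministic.

**Precursor windows.** Plant pre-miRNAs vary from roughly 50 to 350 nt
with no fixed boundary rule, so `extract_candidates()` enumerates a grid
of windows containing the mature span (lengths 50–350 by 10 nt, mature
offset varied by the same step, clipped to the EST). The grid step (10
nt) is also the coordinate tolerance used when synthetic recovery is
scored.

**Exclusion screen.** Candidate-bearing ESTs are screened against
user-supplied coding and ncRNA decoy databases with
`screen_candidates()`: an exact-word seed (8 nt, or 4 aa against the
six-frame translation) is extended along its diagonal, and the candidate
is dropped when some diagonal segment covers at least 60% of it at 80%
identity or better. The thresholds are explicit and configurable because
the classical BLAST-based step they replace publishes none; searching
segments of *any* length above the coverage floor (rather than one fixed
window) is what makes the filter monotone in both thresholds.

## Hairpin validation

`fold_hairpin()` is a hairpin-restricted folding: over all loop
placements, the 5' side is globally aligned against the reverse
complement of the 3' side. Aligned pairable columns score G:C −3,
A:U −2, G:U −1; aligned non-pairable columns (internal-loop mismatches)
cost 0; a bulge run of length *g* costs 4 + *g* (affine). The minimum
over all splits with loop ≥ 3 nt is the structure score, a
minimum-free-energy proxy. Ties prefer the smallest loop, then the
leftmost. This deliberately models only stem-loop topology — no
multiloops, no nearest-neighbor thermodynamics — because pre-miRNA
assessment needs the stem-loop and its relative stability, and a
self-contained quadratic DP is exhaustively testable: the test suite
checks it against an independent enumeration of nested pair stacks on
seeded short strings.

`evaluate_criteria()` applies the standard plant pre-miRNA rules to a
fold, all configurable: the mature must sit wholly in one arm; at most 6
mature positions unpaired against the star arm; no unpaired run longer
than 4 inside the mature; at least 60% of mature positions paired; both
mature ends within 2 nt of a paired stem position (a Dicer-cleavage-site
proxy — the concept is named in the literature without an operational
rule, so this package declares one); and MFEI ≥ 0.85, where
AMFE = score / length × 100 and MFEI = |AMFE| / GC%. The MFEI threshold
is the classical value used to separate miRNA precursors from other
RNAs; because the internal score is calibrated like a free energy
(negative, pair-weighted), the classical threshold transfers.

**Window selection.** Among passing windows of one homology hit,
`select_best()` ranks by lowest AMFE, then highest MFEI, then shortest
window. The primary key is per-length score rather than raw score by
design: appending random flank to a window can only add spurious
pairings, so the raw score improves monotonically with window size and
would always elect the widest window; the per-length score peaks when
the window matches the actual hairpin, which is what lets synthetic
recovery locate planted boundaries to within one grid step.

Borderline candidates are not silently dropped: rejections carry the
union of failed rule names, acknowledging that the classical
identification step involved human judgment not reducible to thresholds.

## Target prediction and expression

`find_targets()` scans each transcript with an antiparallel
complementarity alignment (at most one bulge per side) scored by the
expectation penalty scheme: mismatch 1.0, G:U wobble 0.5, each gap
position 2.0, all doubled at miRNA positions 2–13 from the 5' end; sites
with expectation ≤ 3.0 are reported, keeping the minimal-expectation
site per cluster of overlapping windows. A mismatch or gap at central
positions 9–11 classifies the site as translational inhibition,
otherwise cleavage. These defaults mirror the 2011-era psRNATarget
convention; target-accessibility (UPE) scoring is out of scope since it
requires ensemble folding of long mRNA context.

`count_reads()` assigns each read to its best (fewest-mismatch) ungapped
hit across targets and strands within a 2-mismatch budget; multi-mapping
ties go to the lexicographically smallest target id — deterministic
unique assignment rather than fractional counting, because the upstream
convention being mirrored states a mismatch contract but no multimapping
policy. TPM follows the rate definition (count/length, normalized to
10^6), and the per-sex TPM sum is asserted on every run. Log transforms
use log2(TPM + 1); the pseudocount keeps zeros finite and is
configurable. Expression detection is count > 0 — published target
counts of this kind state no minimum-count threshold, so the natural
zero/nonzero rule is used and exposed.

`anticorrelation_report()` contrasts, for each single-sex miRNA, the
mean log2 TPM of its targets in the miRNA-present versus miRNA-absent
sex; negative differences support the silencing expectation.

## Locus mapping and the candidate rule

Targets are placed from gene annotations when available, otherwise by
exact substring search on both genome strands (first chromosome in
assembly order, leftmost coordinate); an annotation that contradicts the
sequence search is an error, not a silent preference. The gender locus
is always a configuration parameter (`"chrom:start-end"`, 1-based
inclusive) — its real-world coordinates are assembly-specific and are
never baked in. Overlap is any ≥ 1 bp intersection. The candidate rule
is the three-way conjunction above; in the default `strict` mode the
expressed sex must differ from the regulator's sex, and a `lenient` mode
accepts any single-sex expression for exploration. Each flagged row
records which clauses fired. For the per-chromosome distribution each
target gets one regulator class: sex-specific if any sex-specific miRNA
targets it (the minimal-expectation such site decides ties), else
common.

## The synthetic generator

`generate_synthetic()` emits a complete dataset plus a truth table,
byte-deterministic under its seed. Defaults are the fixed study
conditions: 200 ESTs per sex of mean length ~389 nt; 20 unique reference
matures (20–22 nt) listed under 1–3 species names each; 15 planted
precursors (5 common, 3 female-specific, 7 male-specific — echoing a
male-skewed inventory) with lengths 51–138 nt and 0–2 mismatches to
their reference; 30 target transcripts carrying designed sites at
expectations 0, 0.5 and 2.0; 5,000 reads per sex (50 nt, multinomial
over designed weights) with an 8-fold suppression of a target in the sex
where its regulating miRNA is present; 8 decoys per database plus two
ESTs per sex that embed a mature copy inside an ncRNA decoy (so the
exclusion screen has true positives); and one locus candidate gene,
placed alone on the last chromosome inside the configured locus,
regulated by a male-specific miRNA and given a female-only read profile.

Planted precursors are perfect inverted repeats around a random loop;
the generator folds and criteria-checks each one before writing, so
planted truth is guaranteed discoverable under the default thresholds.
What the generator deliberately does **not** model: sequencing errors
and quality scores, imperfect star arms, repeat-rich centromeric
sequence, isomiR variation, or UTR structure. Passing recovery tests
therefore demonstrate the pipeline's correctness on data satisfying its
own assumptions, not its sensitivity on degraded real-world ESTs.

Reads are exact substrings of their source transcripts, so TPM recovery
is limited only by multinomial sampling noise; the suite checks observed
counts against designed weights at five standard deviations.

## Numerical and determinism choices

* All internal sequences are RNA-alphabet; DNA inputs are converted on
  read, IUPAC ambiguity codes collapse to N, and N never pairs.
* Coordinates are 1-based inclusive everywhere (reports format locations
  as `est:start..end:strand`).
* Every ordering has a documented tie-break (leftmost / lexicographic /
  plus-strand first), so reruns are byte-identical; the pipeline test
  suite checksums rerun outputs.
* LP averages are reported both raw and round-half-up to an integer, the
  convention used in the printed inventories this package reproduces.
* Problem sizes in the test suite: oracle folding comparisons run on
  seeded strings of length 8–24 (where exhaustive structure enumeration
  is feasible); scan/count oracles on toy instances of a few ESTs and
  reads; end-to-end recovery on the default generator conditions above.

## A worked run

```{r example, eval = FALSE}
syn <- generate_synthetic(synthetic_config(seed = 1))
cfg <- pipeline_config(
  reference = data.frame(id = syn$reference$name, seq = syn$reference$seq),
  ests_female = syn$ests_female, ests_male = syn$ests_male,
  protein_db = syn$protein_db, ncrna_db = syn$ncrna_db,
  transcripts = syn$transcripts, genome = syn$genome,
  annotations = syn$annotations, reads_female = syn$reads_female,
  reads_male = syn$reads_male, locus = syn$locus)
res <- run_full(cfg)
recovery_metrics(res, syn$truth)
res$locus_candidates
```

## Known limitations

The folding score is a calibrated proxy, not a thermodynamic free
energy; MFEI values are comparable within this package but not directly
to RNAfold output. The exclusion screen is a declared-threshold
substitute for statistical database search and reports no E-values.
Cross-species conservation counts are only meaningful against a real,
versioned reference set. The homology strategy finds conserved miRNA
families only — novel, lineage-specific miRNAs are invisible to it by
construction.
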