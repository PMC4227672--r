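---
title: "Methods: transcript triage, digital expression and qRT-PCR summarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript triage, digital expression and qRT-PCR summarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puttier)
```

`puttier` packages the bespoke computational stages that sit between a de
novo transcriptome assembly and its biological interpretation. This
vignette documents the model behind each stage, the parameters that
matter, the numerical conventions, and — because the package ships its
own synthetic benchmark — exactly what passing tests do and do not
demonstrate about real data.

## Read cleaning

A read is a sequence over `{A,C,G,T,N}` with one Phred score per base
(`Q = -10·log10(error probability)`). Cleaning applies three rules in a
fixed order:

1. **Terminal clipping** (`trim_threshold`, default Q21): the maximal
   prefix and suffix in which *every* base is below threshold are
   removed. Q21 corresponds to a per-base error rate just under 1%, so
   surviving read ends are forced below that rate. Interior low-quality
   bases are deliberately untouched — clipping is about untrustworthy
   ends, not overall quality.
2. **Purging** (`min_length` 36 nt; `bad_base_threshold` Q20;
   `bad_fraction` 0.10): evaluated on the *trimmed* read. The thresholds
   are read literally: "less than 21" is strict, "20 or less" and "10%
   or more" are inclusive, so a 40-base read with exactly 4 bases at Q20
   is purged.
3. **Masking** (`mask_threshold` Q21): remaining sub-threshold bases
   become `N`. Masked bases keep their recorded quality scores in output
   FASTQ — masking flags untrustworthy calls without destroying the
   evidence, and base counts are unchanged, so retention accounting is
   taken after trimming only.

Cleaning is idempotent: trimmed ends are already at or above threshold,
and re-masking a masked base is a no-op. The suite asserts this, along
with exact agreement against a brute-force per-read re-application of
the rules on 200 random reads whose lengths and qualities straddle every
threshold.

An adapter/artifact filter is deliberately not part of the default
pipeline: artifact removal is assembler- and chemistry-specific and has
no single defensible definition at this layer, so the package confines
itself to the three quality rules above.

## Three-tier homology triage

Input is one best protein hit per PUT, selected by maximal bit score
with deterministic tie-breaks (lower E-value, then lexicographically
smallest subject id). Tiers are tested in order of decreasing
stringency, so the partition is disjoint and complete:

| tier | criteria (all inclusive) |
|------|--------------------------|
| gold | single HSP; query ≥ 300 nt; subject ≥ 100 aa; positives/aligned ≥ 0.75; coverage ≥ 0.90 |
| silver | query ≥ 100 nt; coverage ≥ 0.75 |
| bronze | query ≥ 100 nt; coverage ≥ 0.30 |

**Coverage** is the best HSP's alignment length (in residues, gaps
included — the BLAST `length` column) divided by the subject protein's
length. A subject-span variant (`s_end − s_start + 1`) would be a
defensible alternative, but it is not computable from the tabular
dialect this package consumes, and best-HSP alignment length is the
conservative reading for the lower tiers as well; the single-HSP
requirement only ever applies to gold. No E-value or identity floor is
imposed at any tier (an optional `max_evalue` exists but defaults off).

Gold PUTs are clipped to the aligned query span (`q_start..q_end`,
reverse-complemented first when the hit frame is negative) and
translated in frame 1 of the clipped sequence with the standard genetic
code. Codons containing `N` translate to `X`; a trailing incomplete
codon is dropped (`length(protein) == floor(span/3)` is asserted as a
law); stop codons are kept as `*`, and *internal* stops raise a warning
rather than an error because chimeric assemblies make them expected.

## Annotation transfer

The live UniProt ID-mapping step of the original workflow is replaced by
a required offline TSV (`nr_id → uniprot_acc` plus semicolon-separated
GO/Pfam/KEGG lists) so the stage is reproducible with no network. All
statistics are per *distinct subject protein*, never per PUT — the tests
assert invariance under duplicating PUTs that hit the same protein.
Mapping rates are reported as `round(100·mapped/distinct)`.

Term frequencies (the "ten most frequent families" summaries) divide
per-term occurrence counts by **total term occurrences**, not by the
number of subjects; with that denominator the frequencies over all terms
sum to 1, which the suite checks to 1e-12. No GO-graph propagation to
ancestor terms is performed, so GO uniqueness counts are counts over the
literal annotated terms.

## Digital expression

A read may increment a count only if at least 95% of its length aligned
with 100% identity. The two clauses are reconciled by scope: identity is
enforced over the aligned span (zero mismatches, every aligned base a
match), while the 95% rule governs how much of the read the span must
cover — otherwise any clipped read would be uncountable. `N`-masked
bases that the aligner pairs are mismatches by this definition, which is
the conservative reading of masking's intent.

Each read then goes to its highest-scoring alignment; the PSL score used
for ranking is `matches − mismatches`. Score ties are resolved to the
lexicographically smallest PUT id — a deterministic stand-in for an
arbitrary representative that leaves all gene-level statistics unchanged
(tied PUTs of the same gene aggregate identically) while making output
independent of input order, which the suite verifies against a
brute-force per-read search.

Gene counts are sums over the PUTs attributed to the same protein;
normalized abundance is `count / total cleaned reads in the sample`.
Transcript-length normalization (TPM/FPKM) is deliberately absent: the
statistic compares the same gene across samples, where length cancels.
Zero-count genes are materialized so "absent" is distinguishable from
"unmeasured" downstream.

## Fold differences and reference-gene selection

For two samples the fold difference is `max(a,b)/min(a,b)`, hence ≥ 1
whenever the gene is detected on both sides. Genes detected on exactly
one side are *exclusive*: their fold is reported with the `0.00`
sentinel plus an explicit flag, so no downstream code divides by zero or
misreads the sentinel as "no change"; direction is `up` when the nonzero
side is the second sample. Genes absent from both sides are `flat` with
fold 1 so gene universes stay aligned across comparisons. Pooling (for
the nymph and adult composites) sums counts and totals and recomputes
the proportion — a count-weighted pool, not an average of proportions.
The ≥ 20-fold "highly differentially expressed" call is inclusive and
reports exclusive genes separately, so either tallying convention
(with or without exclusives) can be applied. No statistical test is
attached: with one library per condition there is no replication to
model, and the screen is a ranking device feeding qRT-PCR validation.

A candidate reference gene with absolute fold changes `(x, y, z)` in the
three comparisons is scored by its Euclidean distance from `(1,1,1)`;
only genes detected on both sides of all three comparisons are eligible,
and `distance == 0` iff all three folds are exactly 1.

## qRT-PCR summarization

Per biological replicate, technical-replicate Cts of target and control
are averaged first; ΔCt is the difference of those means and relative
expression is `2^(−ΔCt)` (efficiency fixed at perfect doubling). Mean
and `sd/sqrt(n)` SEM are then taken across biological replicates.
Averaging Cts before exponentiating is the dominant convention and makes
the estimator a geometric-type mean on the linear scale; the alternative
(exponentiate per well, then average) differs only at second order in
the technical noise. The two endogenous controls of the motivating
design (18S rRNA for RNA load, endoreticulocalbin for expression) are
processed independently; no geometric averaging of controls is done
because they play distinct roles. A uniform Ct shift across all wells
cancels exactly, which the suite asserts.

## The synthetic benchmark

The generator plants every structure the pipeline must detect, with the
bookkeeping to check recovery exactly:

* **Tiers.** Hit metrics are *constructed*, not sampled: each planted
  tier's recipe satisfies exactly its criteria and fails the next tier's
  by at least one unit, and the recipes include rows sitting exactly on
  the inclusive 0.90/0.75/0.30 coverage, 300/100 nt length and 0.75
  positives boundaries. Decoy lower-scoring hits and bit-score-tied hits
  with later-sorting subject ids exercise best-hit selection.
* **Default conditions.** 40 PUTs at a 10/20/10/0 tier mix. The ten gold
  PUTs represent nine genes (the stable gene carries two duplicate PUTs,
  giving multi-mapping ties that must not change gene counts): seven
  genes with planted 32–40-fold differences spread over the three
  comparisons (mixed up/down so no sample's library is dominated), one
  unperturbed reference gene, one adult-exclusive symbiont-like gene.
* **Abundances.** Planted gold proportions are fixed multiples of 5e-4;
  background genes get log-uniform relative weights over 1e-8..1e-4
  (the dynamic range digital-expression tables typically span) and are
  rescaled to absorb each sample's remainder, so per-sample totals are
  equal and the planted proportion ratios are the true fold changes
  exactly. Planted folds sit at ≥ 32 so that at the default 20,000-read
  budgets (a desk-scale stand-in within the 1e4–1e5 range; the study
  scale of 1e8 reads per sample is out of reach and unnecessary for
  verifying the rules) binomial noise cannot drag a planted gene below
  the 20-fold call nor lift a flat gene above it.
* **Reads and alignments.** Counts are drawn multinomially (or set to
  their integral expectations in `sampling = "expected"` mode, where
  fold recovery and the reference gene's zero distance are exact). The
  PSL a perfect aligner would produce is emitted directly — no aligner
  runs — so counting edge cases are deterministic: full-length perfect
  alignments, spans of exactly 95% (inclusive, must count), 94% spans
  and one-mismatch rows (must be rejected), and background reads with
  only rejected alignments. Raw FASTQ pools add planted failures for
  each cleaning rule at a known 10% rate, plus survivors with trimmable
  tails and maskable interior bases.
* **Ct tables.** `Ct = base − log2(rel. abundance) + N(0, sd)` per well,
  3×3 replication, with 4-fold (male) and 2-fold (female) planted
  inductions; `ct_noise_sd = 0.1` cycles reflects a well-behaved SYBR
  assay.
* **Determinism.** Every output file draws from its own stream derived
  from the master seed and a stable label, so outputs are byte-identical
  across runs and adding an output never perturbs another; the caller's
  RNG state is restored.

What passing these tests shows is that the *rules* are implemented
exactly and recover planted truth under the statistical structure they
assume. What it does not show: behavior under real sequencing error
models, isoform structure, rRNA contamination, adapter artifacts,
non-uniform coverage, or an imperfect aligner — the generator emulates
none of those, by design.

## Numerical conventions and degenerate inputs

* All threshold comparisons are inclusive where the procedure says "at
  least"/"or more", strict where it says "less than"; boundary fixtures
  pin each one.
* Output tables render doubles as upper-case scientific notation with 3
  significant digits (`1.76E-08`, zero as `0.00E+00`); parsing the
  rendering recovers values to 3 significant digits.
* PSL coordinates are 0-based half-open on disk and converted to the
  package's 1-based inclusive convention on ingest; BLAST coordinates
  are 1-based inclusive already. One internal convention avoids
  off-by-one drift.
* Empty inputs are defined, not errors: an empty FASTQ yields an empty
  read tibble; an empty tier yields empty subject sets; a fully
  low-quality read trims to length 0 and then simply fails the length
  filter. Genuine contract violations (quality/sequence length
  mismatch, `q_start > query_len`, non-dense replicate indices,
  duplicate ids, zero total reads) fail fast with the offending record
  named.
* Percentages on empty denominators are defined as 0.

## Problem sizes

The suite and the acceptance script run the benchmark at its default
conditions (40 PUTs, 4 × 20,000 reads, 200 qPCR noise repeats), with
smaller 2,000-read budgets for the orchestration round-trip, where only
plumbing — not a statistical property — is under test. These sizes were
chosen as the smallest at which every planted structure is comfortably
detectable; nothing in the package depends on them beyond noise margins.

## Known limitations

* Single-end reads only; pairing metadata is ignored by design.
* The BLAST tabular and PSL dialects are fixed and validated, not
  auto-detected; richer formats (XML, SAM/BAM) are out of scope.
* Silver/bronze annotation uses the same offline mapping mechanism as
  gold; tool-based annotation of unmapped tiers is out of scope.
* Multi-mapping reads are resolved to a single PUT, never fractionally
  allocated.
* The ≥ 20-fold screen is a ranking heuristic without error control;
  treat its output as candidates for validation, not calls.
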