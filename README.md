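# puttier

Post-assembly analysis of de novo insect RNA-Seq transcriptomes:
homology-based transcript triage, digital expression, reference-gene
selection and qRT-PCR summarization — with a synthetic benchmark
generator so the whole pipeline is testable offline.

## The problem

De novo transcriptome studies of non-model insects (the motivating case
is the brown marmorated stink bug, *Halyomorpha halys*) assemble hundreds
of millions of short reads into a large set of putatively unique
transcripts (PUTs), most of which are fragmentary or spurious. Before any
biology can be read off, the PUTs must be triaged by protein homology,
annotated by transfer from a curated database, quantified per life stage,
and screened for differential expression — and a stable endogenous
control must be chosen before qRT-PCR validation. `puttier` implements
those bespoke post-assembly stages as tested, composable R functions
operating on tidy tables. It is aimed at bioinformaticians who want the
procedure itself (the filters, thresholds, counting and normalization
rules) as reusable, inspectable code rather than a one-off scripted
analysis.

## The method

* **Read cleaning.** Terminal bases with Phred quality < 21 are clipped;
  trimmed reads shorter than 36 nt are purged, as are reads with ≥ 10% of
  bases at Q ≤ 20; surviving bases below Q21 are masked to `N`. Retention
  is reported per sample as reads and bases, raw vs cleaned.
* **Three-tier triage.** Each PUT's best protein hit (highest bit score;
  ties by E-value, then subject id) is tested against disjoint criteria.
  Gold: a single HSP, query ≥ 300 nt, subject ≥ 100 aa, positives/aligned
  ≥ 0.75, and subject coverage (alignment length / subject length)
  ≥ 0.90. Silver: query ≥ 100 nt and coverage ≥ 0.75. Bronze: query
  ≥ 100 nt and coverage ≥ 0.30. Gold PUTs are clipped to the aligned span
  and translated.
* **Annotation transfer.** An offline NR→UniProtKB mapping table carries
  GO (Molecular Function), Pfam and KEGG terms onto the distinct subject
  proteins of a tier; uniqueness counts and top-N relative term
  frequencies summarize the result.
* **Digital expression.** A read increments a PUT only if ≥ 95% of its
  length aligns at 100% identity; each read goes to its highest-scoring
  PUT; PUT counts are summed per protein-coding gene, then divided by the
  sample's total cleaned reads. No transcript-length normalization is
  applied, by design.
* **Fold-difference screening.** For each comparison (4th vs 2nd instar,
  female vs male, nymph vs adult with count-weighted pooling), the fold
  difference places the larger abundance in the numerator (so fold ≥ 1
  when detected on both sides; genes detected on one side only carry a
  `0.00` sentinel and an `exclusive` flag). Genes with fold ≥ 20 are
  called highly differentially expressed.
* **Reference-gene selection.** With x, y, z the absolute fold changes of
  a gene in the three comparisons, candidates are ranked by
  `d = sqrt((x-1)^2 + (y-1)^2 + (z-1)^2)`, the Euclidean distance from
  the unperturbed point (1,1,1).
* **qRT-PCR.** Per biological replicate, technical-mean Cts give
  ΔCt = Ct(target) − Ct(control) and relative expression 2^−ΔCt; means
  and standard errors are taken across biological replicates, and
  induction folds are ratios of means.

## Worked example

Everything below runs offline from the synthetic benchmark, which plants
known tiers, abundances, fold changes, an adult-exclusive gene and one
unperturbed reference gene:

```r
library(puttier)
library(dplyr)

cfg <- sim_config(seed = 1)
sim <- simulate_transcriptome(cfg)
ass <- classify_tiers(sim$puts, sim$hits)
tier_summary(ass)
#>   tier             n
#> 1 gold            10
#> 2 silver          20
#> 3 bronze          10
#> 4 unclassified     0
```

The planted 10/20/10 tier mix is recovered exactly, boundary cases
(coverage exactly 0.90/0.75/0.30, query length exactly 300/100 nt)
included. Quantify the four samples and rank fold differences:

```r
rd <- simulate_reads(cfg, sim, emit_reads = FALSE)
expr <- sapply(names(cfg$sample_budgets), function(s)
  quantify_sample(rd[[s]]$alignments, ass, rd[[s]]$total_reads, s),
  simplify = FALSE)
cmp <- compare_expression(expr$nymph2, expr$nymph4, "n4_vs_n2")
head(arrange(cmp, desc(fold_diff)), 3)
#>   gene_id       comparison abund_a abund_b fold_diff direction exclusive
#> 1 gb|SYNP001.1| n4_vs_n2   0.00335 0.157        47   up        FALSE
#> 2 gb|SYNP002.1| n4_vs_n2   0.155   0.00435      35.7 down      FALSE
#> 3 gb|SYNP007.1| n4_vs_n2   0.0036  0.127        35.4 up        FALSE
```

The genes planted with ≥ 32-fold differences top the ranking (sampling
noise moves a planted 40-fold to an observed 47). The reference-gene
scorer puts the planted stable gene first, close to the ideal point:

```r
ranked <- select_reference(list(
  cmp,
  compare_expression(expr$adult_male, expr$adult_female, "female_vs_male"),
  compare_expression(
    pool_samples(expr$nymph2, expr$nymph4, sample = "nymph"),
    pool_samples(expr$adult_male, expr$adult_female, sample = "adult"),
    "nymph_vs_adult")))
head(ranked, 3)
#>   gene_id           x     y     z distance
#> 1 gb|SYNP008.1|  1.06  1.02  1.01   0.0675
#> 2 gb|SYNP005.1|  1.13  1.02 30.8   29.8
#> 3 gb|SYNP003.1|  1.08 30.2   7.06  29.8
```

And the qRT-PCR module recovers the planted 4-fold immune induction from
a 3×3-replicated Ct table with 0.1-cycle noise:

```r
ct <- simulate_ct(cfg, sim)
rel <- rel_expression(ct, "tgt_clectin", "ctrl_endoreticulocalbin")
induction_fold(rel, "induced_male", "adult_male")
#> [1] 4.091332
```

`run_pipeline("run.yaml")` chains all stages (qc → tier → annotate →
quant → compare → refgene → qpcr) from a YAML config and writes each
stage's tables plus a `manifest.json`; `write_fixture(cfg, dir)` emits a
complete input set (FASTA, FASTQ, PSL, BLAST-tabular, mapping TSV, Ct
CSV) to feed it. A minimal shell front end lives in
`inst/cli/pipeline.R`.

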