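---
title: "Inferring hormone-responsive regulatory elements from histone-mark ChIP-seq"
author: "ecdreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring hormone-responsive regulatory elements from histone-mark ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdreg)
```

## The problem

Steroid hormones reprogram transcription through nuclear receptors that act
on *cis*-regulatory DNA. In insects, 20-hydroxyecdysone (20E) drives
molting and metamorphosis via the EcR/USP receptor heterodimer, which binds
ecdysone response elements (EcREs). Genome-wide maps of the regulatory
elements that mediate this response can be inferred from histone
modifications: H3K4me3 marks promoters, H3K4me1 marks enhancers, and
H3K27ac distinguishes *active* elements from *poised* ones. `ecdreg`
implements this inference for a two-condition (vehicle vs hormone) design
on a fragmented, scaffold-level genome such as the silkworm's, together
with a ground-truth simulator so that every stage of the pipeline can be
validated without external data.

## Element model

All coordinates inside the package are 0-based half-open; 1-based dialects
(GFF3, WIG) are converted at the I/O boundary only. Two intervals overlap
iff they share at least one base, so half-open abutment never counts.

**Five-way genome partition.** Each scaffold is tiled with exactly one
label per base: promoter-TSS (strand-oriented TSS − 1 kb to TSS + 200 bp),
exon, intron, TTS and intergenic. The TTS window is the strand-oriented
mirror of the promoter window (TTS − 200 bp to TTS + 1 kb); no standard
width exists for it, and the mirror keeps the two gene termini symmetric.
Where windows collide the label is resolved by the fixed priority
promoter-TSS > exon > intron > TTS > intergenic, chosen so that
promoter-proximal assignment dominates — the interpretation under which
"promoter" statements about peak location remain conservative. A peak that
touches several regions is assigned by the single base at its *summit*;
peaks without a recorded summit use the interval midpoint so the
assignment is total.

**Promoters and DREs.** A distal regulatory element (DRE, the operational
enhancer) is an H3K4me1 peak whose summit lies more than 1.5 kb from every
TSS. A promoter element is an H3K4me3 peak whose summit lies within 1.5 kb
of some TSS. H3K4me1 peaks inside the promoter zone are discarded rather
than reclassified — promoters are defined by H3K4me3 only — and distal
H3K4me3 peaks are likewise not elements. An element is *active* iff its
source peak overlaps (≥ 1 bp) at least one H3K27ac peak. Reciprocal
overlap fractions are deliberately not required: the activity call should
be monotone in the H3K27ac peak set, and a minimum-overlap fraction breaks
that property for fragmented acetylation domains.

**Nearest gene.** Each element is linked to the gene whose TSS is closest
to the element's summit, on the same scaffold only; the signed distance is
`summit − TSS` in genome orientation and ties go to the lexicographically
smallest gene id so results are independent of input order. Note that
interval-based tools (`closestBed`) measure from interval *ends*; the
summit-based distance is a deliberate deviation kept consistent with the
summit-based region assignment, and it is applied pipeline-wide.

## Two-condition dynamics

Differential testing on replicate counts is out of scope here; the
dynamics classification is the operational twofold rule. Peaks of the two
conditions are merged into *union regions* (connected components under
≥ 1-bp overlap), the mean per-base coverage of each region is scaled by
`1e6 / library_size` per track, and the fold change is

```
fold = (signal_treated + pseudocount) / (signal_control + pseudocount)
```

A region is `increased` when fold > 2, `decreased` when fold < 0.5, else
`stable`. Two boundary conventions coexist in this literature; the package
uses strict inequalities for the generic region classification and the
inclusive (≥ 2, ≤ 0.5) boundary for per-DRE acetylation dynamics, and
records the convention in every output header. The pseudocount (default
0.5) is expressed in density units; coverage tracks default to
`library_size = 1e6`, i.e. values are taken to be already depth-normalized
densities on the scale of read depth. With background densities around 3
at depth 30 the pseudocount then stabilizes zero-coverage regions without
flattening genuine twofold changes; scaling by raw coverage mass instead
would shrink all densities to order 0.2 and let the pseudocount dominate
every fold. Condition-specific peaks are reported separately as
`presence` calls (`treated_only` / `control_only` / `both`), which require
no coverage at all.

## Expression linkage

Genes are split into four categories: `none` below 1 RPKM (a conventional,
scale-free floor), and rank tertiles `low`/`medium`/`high` of the
remainder, ties broken by gene id and remainders pushed to the lower
tertiles. TSS metaprofiles average strand-oriented coverage windows
(default ± 2 kb in 50-bp bins) across the genes of each category; windows
truncated by scaffold ends contribute only their covered positions, and a
category with no genes is absent rather than zero. Class-level expression
uses `log2(RPKM + 1)` — the shrinking transform makes means robust to the
heavy right tail of RPKM — and deduplicates genes within a class so a gene
served by many enhancers is counted once; a flag restores per-element
weighting when the element, not the gene, is the unit of interest.

## Motif scanning

Position frequency matrices are normalized column-wise with a 0.01
per-cell pseudocount (avoiding infinite log-odds) and scored in bits
against a uniform background by default, or against mononucleotide
frequencies of the supplied genome. Both strands are scanned by reversing
and complementing the matrix; windows containing `N` are skipped. A window
is a hit when its score reaches `threshold_fraction` of the min–max score
range. The exploratory default is 0.80. Exact-closure checks use 0.85: for
a 13-column matrix the expected number of chance hits in a few hundred
motif-free 400-bp peaks is of order one at 0.80 but only a few hundredths
at 0.85, so 0.85 is the stringency at which "no planted motif, no hit" is
a meaningful exact assertion. Since the threshold is a fraction of the
min–max range, a 0.85 threshold tolerates about `0.15 × W` fully wrong
informative columns — roughly one mutated base for the bundled 13-column
matrix. The bundled matrix itself (`ecre_pwm()`) is a palindromic
nuclear-receptor-style inverted repeat (AGGTCA half-sites around a
degenerate spacer) intended *only* for simulation and testing; real
analyses must supply their own matrices in JASPAR text format.

## The synthetic-data generator

`simulate_dataset()` plants a complete, labeled dataset. Defaults are the
study conditions used by the test-suite, chosen once:

* genome: 4 scaffolds × 1 Mb; 300 non-overlapping stranded genes
  (2–5 kb, 1–4 exons), 600 distal elements (600–1000 bp), packed with
  ≥ 1.8 kb gaps so every distal summit is > 1.5 kb from every TSS;
* marks: every gene gets an H3K4me3 peak and an H3K27ac domain over its
  promoter window, scaled by its expression category; active DREs carry
  H3K27ac in both conditions; 30 % of poised DREs gain H3K27ac on
  treatment with a treated/control coverage ratio of exactly
  `fold_gain` (default 4);
* H3K27ac domains are emitted as two overlapping peak fragments per site,
  emulating the fragmentation of broad acetylation domains by peak
  callers; site-level counts are recovered through union regions;
* coverage: piecewise-constant intensity (background = 10 % of depth 30)
  with Poisson noise drawn per 10-bp bin; the H3K4me1 track has a bimodal
  bump (shoulders at ± 0.3–0.9 kb, dip at the TSS) so metaprofiles show
  the enhancer-mark shape;
* expression: log-normal RPKM with a quarter of genes below the 1-RPKM
  floor; genes nearest to active elements are multiplied by the coupling
  factor (default 4), and genes whose DRE gains acetylation get the same
  boost in the treated condition only;
* receptor peaks: 400-bp peaks centered on a sample of elements; the
  consensus of the bundled matrix, mutated at 5 % per base, is written
  into the genome sequence of a known 40 %; the truth table records the
  number of mutated informative bases per instance, which is what makes
  honest detection expectations derivable (a 0.85 scan tolerates exactly
  one such mutation);
* corruption: 5 % peak dropouts, 5 % decoy peaks, Normal(0, 50 bp) summit
  jitter — applied per peak record.

Everything is reproducible from the seed, and `noise_free()` switches off
*all* noise channels (dropouts, decoys, jitter, motif mutation, Poisson
noise), the limit in which every downstream module must reproduce the
truth table exactly.

What the generator does **not** emulate: replicate structure and
dispersion (so no differential-testing statistics), fragment-length
effects and read-level artifacts, GC or mappability bias, overlapping
genes and alternative TSSs, copy-number or input-normalization issues, and
realistic motif background composition. Passing the recovery tests
therefore demonstrates the correctness of the inference logic under the
stated noise model, not performance on real libraries. Two further
honest caveats: with 600 elements targeting 300 genes, many genes are
nearest-neighbors of both active and inactive elements, so the planted
expression contrast between element classes is diluted relative to the
per-gene coupling factor (the direction is stable, the magnitude is not
the naive `log2(coupling)`); and decoy peaks may by chance overlap real
acetylation, so noisy-recovery precision is expected slightly below 1.

## Numerical and reporting choices

* Reported percentages use half-up rounding to one decimal
  (`proportion_report()`), matching how such tables are conventionally
  printed; R's default round-half-even would turn 0.05 into 0.0.
* Denominators are always printed next to fractions, because published
  intergenic co-occurrence tables are internally inconsistent about them;
  the package never hard-codes a TSS universe or peak total.
* All randomness flows through a single seed; placements use integer
  arithmetic and sorts are radix (C-locale), so datasets and reports are
  byte-identical across runs.
* Degenerate inputs are contracts, not surprises: empty gene sets are an
  error for element calling (distances are undefined) but legal for the
  partition (everything intergenic); an empty peak set yields empty,
  well-typed results; a zero denominator yields an absent value, not NaN.

## Problem sizes used by the checks

The test-suite and the acceptance script run the generator at the study
scale (4 Mb genome, 300 genes, 600 elements, depth 30) for recovery
checks, a 1-Mb two-scaffold version for closure and determinism, 20
seeded replicates for the expression-coupling direction, and brute-force
oracle comparisons on at least a hundred random instances per set
operation (up to 1000 intervals each). These sizes were chosen so each
property is measured with comfortable statistical margin.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(sim_config(seed = 42), out_dir = "dataset")
res <- run_pipeline(file.path("dataset", "config.txt"), "out")
subset(res$summary, startsWith(key, "n_dres"))
```

## Known limitations

The pipeline classifies dynamics by fold change only — it produces no
p-values and is silent about effect reliability; the 1.5-kb promoter
radius and the twofold boundary are conventions inherited from the study
design, not optimized quantities; nearest-TSS target assignment ignores
chromatin topology, so long-range enhancer–gene pairs are only as good as
the nearest-gene heuristic; and the motif scanner is an occurrence
counter, not a discovery tool.
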