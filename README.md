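# ecdreg

Mapping hormone-responsive regulatory elements from histone-mark ChIP-seq.

`ecdreg` is an R package plus a small analysis workflow for inferring the
regulatory elements through which the insect steroid hormone
20-hydroxyecdysone (20E) reprograms transcription, from called ChIP-seq
peaks and coverage of three histone marks (H3K4me1, H3K4me3, H3K27ac),
receptor (EcR) binding peaks, gene models and RPKM expression tables. It is
written for genomicists working on scaffold-level genomes (the motivating
system is the silkworm *Bombyx mori*) who need the standard
histone-mark enhancer logic as tested, reusable functions rather than a
string of one-off bedtools calls.

## The inference

* **Genome partition.** Every base gets one of five labels — promoter-TSS
  (TSS − 1 kb … TSS + 200 bp, strand-oriented), exon, intron, TTS,
  intergenic — with priority promoter-TSS > exon > intron > TTS >
  intergenic. Peaks are located by their summit base.
* **Elements.** Distal regulatory elements (DREs, the operational
  enhancers) are H3K4me1 peaks with summit > 1.5 kb from every TSS;
  promoters are H3K4me3 peaks within 1.5 kb of a TSS. An element is
  *active* iff it overlaps an H3K27ac peak; each element is assigned the
  gene with the nearest TSS (signed summit-to-TSS distance).
* **Dynamics.** Two-condition comparison by the twofold rule on
  library-scaled coverage densities:
  `fold = (s_treated + c) / (s_control + c)` with pseudocount `c = 0.5`;
  `increased` iff fold > 2, `decreased` iff fold < 0.5 (per-DRE
  acetylation dynamics use the inclusive ≥ 2 / ≤ 0.5 boundary).
  Condition-specific peaks are reported as presence calls.
* **Expression linkage.** Four expression categories (none < 1 RPKM, then
  rank tertiles), strand-oriented TSS metaprofiles, and mean
  `log2(RPKM+1)` of nearest genes per element class.
* **Motif occurrence.** PWM log-odds scanning (bits, both strands) of
  receptor peak sequences; a peak "contains" the EcRE motif if some window
  scores above a fraction of the matrix's min–max score range
  (default 0.80).
* **Ground-truth simulator.** `simulate_dataset()` emits a complete
  synthetic dataset (FASTA, GFF3, narrowPeak, bedGraph, expression TSV,
  JASPAR PFM) with planted promoters, active/poised DREs, acetylation
  gains, expression coupling and motif instances, plus truth tables — so
  every stage has a download-free recovery test.

## Worked example

Generate a study-scale dataset and run the pipeline:

```r
library(ecdreg)
ds  <- simulate_dataset(sim_config(seed = 42), out_dir = "dataset")
res <- run_pipeline(file.path("dataset", "config.txt"), "out")
```

The same steps are laid out as a narrative workflow in `analysis/`
(`01_simulate.R` … `06_scan_motifs.R`, run in order from the repository
root; raw data land in `scratch/`, tables in `results/analysis/`). On the
seed-42 dataset the workflow prints, among other things:

```
intergenic fractions (treated): h3k4me1 96.8%; h3k4me3 3%; h3k27ac 55.9%
treated: 291 promoters, 586 DREs (368 active)
  active-DRE recovery vs truth: precision 0.989, recall 0.938
79 DREs gained H3K27ac (>= twofold) after treatment; 0 lost it
127 distal H3K27ac sites detected only after treatment
h3k27ac signal at the TSS by category: none=8.97 low=21.71 medium=35.81 high=46.67
93 of 244 receptor peaks (38.1%) contain a response-element motif at 0.8 stringency
```

Reading: the enhancer mark is almost entirely intergenic while the
promoter mark sits at TSSs; the element caller recovers the planted active
enhancers with high precision under 5 % peak dropout/decoy noise;
hormone treatment adds acetylation at a specific subset of distal
elements; TSS signal tracks expression category; and only a minority of
receptor peaks carry the response-element motif — receptor binding is not
explained by the motif alone.

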