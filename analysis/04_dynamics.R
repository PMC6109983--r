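#!/usr/bin/env Rscript
# Stage 4: hormone-induced H3K27ac dynamics.
#
# Union regions over the two conditions' H3K27ac peaks are classified by
# the twofold rule on library-scaled coverage densities; per-DRE dynamics
# use the at-least-twofold boundary. Distal treated-only acetylation is
# counted at site level.

library(ecdreg)

d <- "scratch/dataset"
lens <- read_scaffold_lengths(file.path(d, "scaffolds.tsv"))
genes <- read_gene_models(file.path(d, "genes.gff3"))
pk <- function(mark, cond)
  read_peaks(file.path(d, sprintf("peaks_%s_%s.narrowPeak", mark, cond)))
trk <- function(cond)
  read_coverage(file.path(d, sprintf("coverage_h3k27ac_%s.bedGraph", cond)),
                lens)

tc <- trk("control"); tt <- trk("treated")
regions <- union_regions(pk("h3k27ac", "control"), pk("h3k27ac", "treated"))
dyn <- classify_dynamics(regions, tc, tt)
write.table(dyn, "scratch/tables/04_h3k27ac_region_dynamics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(nrow(regions), " H3K27ac union regions: ",
        sum(dyn$klass == "increased"), " increased, ",
        sum(dyn$klass == "decreased"), " decreased, ",
        sum(dyn$klass == "stable"), " stable (twofold rule)")

el <- call_elements(pk("h3k4me1", "treated"), pk("h3k4me3", "treated"),
                    pk("h3k27ac", "treated"), genes)
dre_dyn <- dre_h3k27ac_dynamics(el, tc, tt)
write.table(dre_dyn, "results/analysis/04_dre_h3k27ac_dynamics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sum(dre_dyn$klass == "increased"),
        " DREs gained H3K27ac (>= twofold) after treatment; ",
        sum(dre_dyn$klass == "decreased"), " lost it")

## distal treated-only acetylation sites
distal <- function(cond) {
  p <- pk("h3k27ac", cond)
  nt <- distance_to_nearest_tss(p, genes)
  p[is.na(nt$distance) | abs(nt$distance) > 1500, ]
}
pres <- presence_calls(distal("control"), distal("treated"))
tr_only <- subset(pres, condition == "treated" & presence == "treated_only")
n_sites <- nrow(union_regions(tr_only, tr_only[0, ]))
message(n_sites, " distal H3K27ac sites detected only after treatment")
write.table(pres, "scratch/tables/04_distal_ac_presence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
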