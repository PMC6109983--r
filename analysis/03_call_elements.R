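#!/usr/bin/env Rscript
# Stage 3: promoter / DRE calling, activity by H3K27ac, co-occurrence and
# DRE-to-TSS distances.
#
# DREs are H3K4me1 peaks whose summit lies >1.5 kb from every TSS;
# promoters are H3K4me3 peaks within 1.5 kb of a TSS; an element is active
# iff it overlaps an H3K27ac peak. Elements are checked against the planted
# truth.

library(ecdreg)

d <- "scratch/dataset"
lens <- read_scaffold_lengths(file.path(d, "scaffolds.tsv"))
genes <- read_gene_models(file.path(d, "genes.gff3"))
partition <- build_partition(genes, lens)
truth <- read.delim(file.path(d, "truth_elements.tsv"))

pk <- function(mark, cond)
  read_peaks(file.path(d, sprintf("peaks_%s_%s.narrowPeak", mark, cond)))

for (cond in c("control", "treated")) {
  el <- call_elements(pk("h3k4me1", cond), pk("h3k4me3", cond),
                      pk("h3k27ac", cond), genes, condition = cond)
  write.table(el, sprintf("scratch/tables/03_elements_%s.tsv", cond),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tc <- truth_compare(el, truth, cond)
  message(cond, ": ", sum(el$kind == "promoter"), " promoters, ",
          sum(el$kind == "DRE"), " DREs (",
          sum(el$kind == "DRE" & el$active), " active)")
  act <- subset(tc$per_label, label == "active_DRE")
  message("  active-DRE recovery vs truth: precision ",
          round(act$precision, 3), ", recall ", round(act$recall, 3))
}

el_t <- call_elements(pk("h3k4me1", "treated"), pk("h3k4me3", "treated"),
                      pk("h3k27ac", "treated"), genes)
cooc <- rbind(
  cooccurrence_at_tss(pk("h3k4me1", "treated"), pk("h3k4me3", "treated"),
                      pk("h3k27ac", "treated"), genes),
  cooccurrence_intergenic(pk("h3k4me1", "treated"), pk("h3k4me3", "treated"),
                          pk("h3k27ac", "treated"), partition))
write.table(cooc, "results/analysis/03_cooccurrence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
hist <- tss_distance_histogram(el_t)
write.table(hist, "results/analysis/03_dre_tss_distance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("acetylation collaborates with the promoter mark at TSSs and with ",
        "the enhancer mark intergenically; DRE-TSS distances peak at ",
        hist$bin[which.max(hist$count)])
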