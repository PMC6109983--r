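# In-code fixtures: tiny gene models, random interval sets, and scaled-down
# simulation configurations shared across test files.

make_genes <- function(gene_id, scaffold, start, end, strand,
                       exons = NULL) {
  genes <- data.frame(gene_id = gene_id, scaffold = scaffold,
                      start = as.integer(start), end = as.integer(end),
                      strand = strand, stringsAsFactors = FALSE)
  if (is.null(exons))
    exons <- genes[, c("gene_id", "scaffold", "start", "end")]
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

rand_intervals <- function(n, scaffolds = c("s1", "s2"), max_pos = 10000,
                           max_width = 400) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(scaffold = sample(scaffolds, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

rand_peaks <- function(n, ...) {
  iv <- rand_intervals(n, ...)
  iv$name <- sprintf("p%04d", seq_len(n))
  iv$signal <- round(stats::runif(n, 1, 50), 3)
  iv$summit_offset <- as.integer(floor(stats::runif(n) * (iv$end - iv$start)))
  iv$strand <- "."
  iv
}

## A scaled-down simulation: two 400-kb scaffolds, 40 genes, 80 distal
## elements. Used where the full study-scale defaults are unnecessary.
small_cfg <- function(...) {
  sim_config(n_scaffolds = 2L, scaffold_length = 4e5, n_genes = 40L,
             n_active_enh = 40L, n_poised_enh = 40L, n_ecr = 40L, ...)
}
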