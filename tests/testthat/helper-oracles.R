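# Independent brute-force oracles. Deliberately naive (all-pairs loops,
# per-base labeling, per-window rescoring) and kept free of any code path
# they are used to check.

bf_overlap_pair <- function(a, b) {
  a$scaffold == b$scaffold && a$start < b$end && b$start < a$end
}

## All-pairs: for each query interval, test it against every subject.
bf_overlap_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(query$scaffold[i] == subject$scaffold &
          query$start[i] < subject$end & subject$start < query$end[i])
  }, logical(1))
}

bf_nearest_tss <- function(scaffold, pos, genes) {
  g <- genes$genes
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  best_gene <- NA_character_
  best_d <- NA_integer_
  for (k in seq_len(nrow(g))) {
    if (g$scaffold[k] != scaffold) next
    d <- pos - tss[k]
    better <- is.na(best_d) || abs(d) < abs(best_d) ||
      (abs(d) == abs(best_d) &&
         sort(c(g$gene_id[k], best_gene), method = "radix")[1] == g$gene_id[k])
    if (better) {
      best_gene <- g$gene_id[k]
      best_d <- d
    }
  }
  list(gene_id = best_gene, distance = best_d)
}

## Per-base five-way label by explicit priority, from raw gene models.
bf_partition_label <- function(scaffold, pos, genes) {
  g <- genes$genes
  e <- genes$exons
  in_any <- function(df, s0, e0) {
    any(df$scaffold == scaffold & s0 <= pos & pos < e0)
  }
  prom_s <- ifelse(g$strand == "+", g$start - 1000L, g$end - 200L)
  prom_e <- ifelse(g$strand == "+", g$start + 200L, g$end + 1000L)
  tts_s <- ifelse(g$strand == "+", g$end - 200L, g$start - 1000L)
  tts_e <- ifelse(g$strand == "+", g$end + 1000L, g$start + 200L)
  if (in_any(g, prom_s, prom_e)) return("promoter-TSS")
  if (in_any(e, e$start, e$end)) return("exon")
  in_gene <- any(g$scaffold == scaffold & g$start <= pos & pos < g$end)
  in_exon <- any(e$scaffold == scaffold & e$start <= pos & pos < e$end)
  if (in_gene && !in_exon) return("intron")
  if (in_any(g, tts_s, tts_e)) return("TTS")
  "intergenic"
}

## Connected components under >=1-bp overlap by naive all-pairs union-find.
bf_union_components <- function(iv) {
  n <- nrow(iv)
  sc <- iv$scaffold; s <- iv$start; e <- iv$end
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sc[i] == sc[j] && s[i] < e[j] && s[j] < e[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), roots)
  do.call(rbind, lapply(comp, function(idx) {
    data.frame(scaffold = iv$scaffold[idx[1]],
               start = min(iv$start[idx]), end = max(iv$end[idx]),
               stringsAsFactors = FALSE)
  }))
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Exhaustive rescoring of every window on both strands; the reverse strand
## is handled by scoring the reverse-complemented window directly.
bf_scan <- function(seq, lom, threshold_fraction) {
  W <- ncol(lom)
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  if (L < W) return(data.frame(offset = integer(), strand = character(),
                               score = numeric()))
  smax <- sum(apply(lom, 2, max)); smin <- sum(apply(lom, 2, min))
  thr <- smin + threshold_fraction * (smax - smin)
  score_win <- function(win) {
    if (any(!win %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(W), function(j) lom[win[j], j], numeric(1)))
  }
  rows <- list()
  for (o in 0:(L - W)) {
    win <- chars[(o + 1):(o + W)]
    sF <- score_win(win)
    sR <- score_win(rev(unname(REVCOMP[win])))
    if (!is.na(sF) && sF >= thr)
      rows[[length(rows) + 1]] <- data.frame(offset = o, strand = "+",
                                             score = sF)
    if (!is.na(sR) && sR >= thr)
      rows[[length(rows) + 1]] <- data.frame(offset = o, strand = "-",
                                             score = sR)
  }
  if (!length(rows)) return(data.frame(offset = integer(),
                                       strand = character(),
                                       score = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$offset, out$strand), , drop = FALSE]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
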