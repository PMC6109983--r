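# PWM log-odds scanning of peak sequences: EcRE occurrence counting in
# receptor-binding peaks. Scanning is exhaustive over both strands; the
# reverse strand is scanned by reversing and complementing the matrix.

BASES <- c("A", "C", "G", "T")

#' Log-odds scoring matrix from a PWM
#'
#' `cell(b, j) = log2(P(b at j) / background(b))`, in bits.
#'
#' @param pwm a `pwm` object (probabilities already pseudocounted).
#' @param background optional 4-vector overriding the PWM's background.
#' @return 4 x W numeric matrix with rows A, C, G, T.
#' @export
log_odds_matrix <- function(pwm, background = NULL) {
  bg <- background %||% pwm$background
  if (any(bg <= 0)) stop_("background probabilities must be positive")
  log2(pwm$prob / as.numeric(bg))
}

revcomp_lom <- function(lom) {
  out <- lom[c("T", "G", "C", "A"), rev(seq_len(ncol(lom))), drop = FALSE]
  rownames(out) <- BASES
  out
}

#' Score range of a log-odds matrix
#'
#' @param lom log-odds matrix.
#' @return c(min, max): the column-min and column-max sums.
#' @export
lom_score_range <- function(lom) {
  c(min = sum(apply(lom, 2, min)), max = sum(apply(lom, 2, max)))
}

scan_one_strand <- function(idx, lom) {
  W <- ncol(lom)
  L <- length(idx)
  nwin <- L - W + 1L
  s <- numeric(nwin)
  for (j in seq_len(W)) s <- s + lom[, j][idx[j:(nwin + j - 1L)]]
  s  # windows containing N score NA
}

#' Scan a sequence with a log-odds matrix
#'
#' Scores every window on both strands (reverse strand via matrix
#' reversal+complement) and reports windows whose score reaches
#' `min + threshold_fraction * (max - min)` of the matrix score range.
#' Windows containing `N` are skipped.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param lom log-odds matrix from [log_odds_matrix()].
#' @param threshold_fraction fraction of the min-max score range in `[0, 1]`.
#' @return data.frame of hits in coordinate order: `offset` (0-based within
#'   `seq`), `strand`, `score` (bits).
#' @export
scan_sequence <- function(seq, lom, threshold_fraction = 0.8) {
  if (threshold_fraction < 0 || threshold_fraction > 1)
    stop_("threshold_fraction must be in [0, 1]")
  W <- ncol(lom)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (nchar(seq) < W) return(empty)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, BASES)  # N and anything else -> NA
  rng <- lom_score_range(lom)
  thr <- rng[["min"]] + threshold_fraction * (rng[["max"]] - rng[["min"]])
  sF <- scan_one_strand(idx, lom)
  sR <- scan_one_strand(idx, revcomp_lom(lom))
  hitF <- which(!is.na(sF) & sF >= thr)
  hitR <- which(!is.na(sR) & sR >= thr)
  out <- data.frame(
    offset = c(hitF, hitR) - 1L,
    strand = c(rep("+", length(hitF)), rep("-", length(hitR))),
    score = c(sF[hitF], sR[hitR]),
    stringsAsFactors = FALSE
  )
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Count peaks containing a motif
#'
#' Extracts each peak's sequence from the genome, scans both strands, and
#' reports how many peaks contain at least one hit at the given stringency,
#' along with each peak's best hit.
#'
#' @param peaks peak data.frame.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param pwm a `pwm` object.
#' @param threshold_fraction scan stringency (fraction of min-max score
#'   range).
#' @param background `"uniform"` (0.25 each), `"genome"` (mononucleotide
#'   frequencies of the supplied sequences), or a numeric 4-vector.
#' @return list with `count`, `fraction` (`count / nrow(peaks)`), and
#'   `table`: per-peak `name`, `n_hits`, `has_motif`, `best_score`,
#'   `best_offset`, `best_strand`.
#' @export
peaks_with_motif <- function(peaks, genome, pwm, threshold_fraction = 0.8,
                             background = "uniform") {
  if (is.character(genome) && length(genome) == 1L) genome <- read_genome(genome)
  missing_sc <- setdiff(unique(peaks$scaffold), names(genome))
  if (length(missing_sc))
    stop_("peak scaffold missing from genome FASTA: ", missing_sc[1])
  bg <- if (is.numeric(background)) {
    background / sum(background)
  } else if (identical(background, "genome")) {
    f <- colSums(Biostrings::letterFrequency(genome, BASES))
    f / sum(f)
  } else {
    c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  }
  lom <- log_odds_matrix(pwm, background = bg)
  n <- nrow(peaks)
  n_hits <- integer(n)
  best_score <- rep(NA_real_, n)
  best_offset <- rep(NA_integer_, n)
  best_strand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- as.character(Biostrings::subseq(genome[[peaks$scaffold[i]]],
                                         start = peaks$start[i] + 1L,
                                         end = peaks$end[i]))
    hits <- scan_sequence(s, lom, threshold_fraction)
    n_hits[i] <- nrow(hits)
    if (nrow(hits)) {
      b <- which.max(hits$score)
      best_score[i] <- hits$score[b]
      best_offset[i] <- hits$offset[b]
      best_strand[i] <- hits$strand[b]
    }
  }
  tab <- data.frame(name = peaks$name, scaffold = peaks$scaffold,
                    start = peaks$start, end = peaks$end, n_hits = n_hits,
                    has_motif = n_hits > 0L, best_score = best_score,
                    best_offset = best_offset, best_strand = best_strand,
                    stringsAsFactors = FALSE)
  list(count = sum(tab$has_motif),
       fraction = if (n) sum(tab$has_motif) / n else NA_real_,
       table = tab)
}
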