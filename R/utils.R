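#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(...) stop(..., call. = FALSE)

#' Round half-up
#'
#' Deterministic half-up rounding (0.05 at one decimal always rounds away from
#' zero for positive input), as opposed to [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## Convert a 0-based half-open interval data.frame to GRanges (1-based closed).
as_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

## Canonical empty peak table.
peak_frame <- function(scaffold = character(), start = integer(), end = integer(),
                       name = character(), signal = numeric(),
                       summit_offset = integer(), strand = NULL) {
  data.frame(
    scaffold = as.character(scaffold),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    signal = as.numeric(signal),
    summit_offset = as.integer(summit_offset),
    strand = if (is.null(strand)) rep(".", length(scaffold)) else as.character(strand),
    stringsAsFactors = FALSE
  )
}

check_peaks <- function(peaks, what = "peaks") {
  need <- c("scaffold", "start", "end", "name", "signal", "summit_offset")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop_(what, " is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(peaks) && any(peaks$start >= peaks$end))
    stop_(what, ": found interval with start >= end")
  invisible(peaks)
}

#' Peak summit positions
#'
#' Absolute 0-based genome position of each peak's summit. Peaks without a
#' recorded summit fall back to the interval midpoint `floor((start+end)/2)`,
#' so summit-based assignment is total.
#'
#' @param peaks a peak data.frame (see [read_peaks()]).
#' @return integer vector of 0-based positions, one per peak.
#' @export
summit_pos <- function(peaks) {
  mid <- (peaks$start + peaks$end) %/% 2L
  off <- peaks$summit_offset
  out <- ifelse(is.na(off), mid, peaks$start + off)
  as.integer(out)
}

## Locale-independent lexicographic minimum of a character vector.
lex_min <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  sort(x, method = "radix")[1L]
}

## TSS base position (0-based) per gene: start on "+", end-1 on "-".
tss_table <- function(genes) {
  g <- genes$genes
  data.frame(
    gene_id = g$gene_id,
    scaffold = g$scaffold,
    pos = ifelse(g$strand == "+", g$start, g$end - 1L),
    strand = g$strand,
    stringsAsFactors = FALSE
  )
}
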