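# Generic genomic-interval computations shared by every downstream stage:
# overlap tests, the five-way genome partition, summit-based region assignment
# and nearest-TSS distances.

#' Pairwise interval overlap
#'
#' Two 0-based half-open intervals overlap iff they are on the same scaffold
#' and share at least one base (`a$start < b$end && b$start < a$end`);
#' half-open abutment does not count.
#'
#' @param a,b data.frames with `scaffold`, `start`, `end` (recycled to a
#'   common length).
#' @return logical vector.
#' @export
intervals_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  a$scaffold[ai] == b$scaffold[bi] &
    a$start[ai] < b$end[bi] & b$start[bi] < a$end[ai]
}

#' Any-overlap test of one interval set against another
#'
#' @param query,subject interval data.frames.
#' @return logical vector: for each query row, does it overlap (>= 1 shared
#'   base) any subject interval?
#' @export
overlap_any <- function(query, subject) {
  if (!nrow(query)) return(logical(0))
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  ## disjoint scaffold sets are a legitimate "no overlap", not a warning
  suppressWarnings(IRanges::overlapsAny(as_gr(query), as_gr(subject)))
}

#' Count and fraction of intervals in A overlapping B
#'
#' @param set_a,set_b interval data.frames.
#' @return list with `count` (intervals of A overlapping >= 1 interval of B)
#'   and `fraction` (`count / nrow(A)`, `NA` when A is empty).
#' @export
overlap_fraction <- function(set_a, set_b) {
  if (!nrow(set_a)) return(list(count = 0L, fraction = NA_real_))
  hit <- overlap_any(set_a, set_b)
  list(count = sum(hit), fraction = sum(hit) / nrow(set_a))
}

PARTITION_LABELS <- c("promoter-TSS", "exon", "intron", "TTS", "intergenic")

## Strand-oriented windows, 0-based half-open, anchored on the gene terminus
## coordinate. Promoter: 1 kb upstream to 200 bp downstream of the TSS;
## TTS window is the mirror (200 bp upstream to 1 kb downstream of the TTS).
promoter_windows <- function(genes, upstream = 1000L, downstream = 200L) {
  g <- genes$genes
  plus <- g$strand == "+"
  data.frame(
    scaffold = g$scaffold,
    start = ifelse(plus, g$start - upstream, g$end - downstream),
    end = ifelse(plus, g$start + downstream, g$end + upstream),
    gene_id = g$gene_id,
    stringsAsFactors = FALSE
  )
}

tts_windows <- function(genes, upstream = 200L, downstream = 1000L) {
  g <- genes$genes
  plus <- g$strand == "+"
  data.frame(
    scaffold = g$scaffold,
    start = ifelse(plus, g$end - upstream, g$start - downstream),
    end = ifelse(plus, g$end + downstream, g$start + upstream),
    gene_id = g$gene_id,
    stringsAsFactors = FALSE
  )
}

clip_ir <- function(start0, end0, L) {
  s <- pmax(start0, 0L); e <- pmin(end0, L)
  keep <- s < e
  IRanges::IRanges(s[keep] + 1L, e[keep])
}

#' Build the five-way genome partition
#'
#' Tiles every scaffold with exactly one label per base from
#' promoter-TSS (strand-oriented TSS - 1 kb to TSS + 200 bp), exon, intron,
#' TTS (strand-oriented TTS - 200 bp to TTS + 1 kb) and intergenic.
#' Conflicts are resolved by the fixed priority
#' promoter-TSS > exon > intron > TTS > intergenic.
#'
#' @param genes a `gene_models` object.
#' @param scaffold_lengths named vector covering all gene scaffolds.
#' @return a `genome_partition`: data.frame of labeled segments
#'   (`scaffold`, `start`, `end`, `label`) tiling each scaffold without gap
#'   or overlap, with `scaffold_lengths` attached as an attribute.
#' @export
build_partition <- function(genes, scaffold_lengths) {
  g <- genes$genes
  unknown <- setdiff(unique(g$scaffold), names(scaffold_lengths))
  if (length(unknown))
    stop_("gene on scaffold missing from scaffold_lengths: ", unknown[1])
  if (any(g$end > scaffold_lengths[g$scaffold]))
    stop_("gene beyond scaffold end: ",
          g$gene_id[which(g$end > scaffold_lengths[g$scaffold])[1]])
  pw <- promoter_windows(genes)
  tw <- tts_windows(genes)
  ex <- genes$exons
  segs <- vector("list", length(scaffold_lengths))
  names(segs) <- names(scaffold_lengths)
  for (sc in names(scaffold_lengths)) {
    L <- scaffold_lengths[[sc]]
    whole <- IRanges::IRanges(1L, L)
    gi <- g$scaffold == sc
    P <- IRanges::reduce(clip_ir(pw$start[pw$scaffold == sc],
                                 pw$end[pw$scaffold == sc], L))
    E <- IRanges::reduce(clip_ir(ex$start[ex$scaffold == sc],
                                 ex$end[ex$scaffold == sc], L))
    body <- IRanges::reduce(clip_ir(g$start[gi], g$end[gi], L))
    I <- IRanges::setdiff(body, E)
    T_ <- IRanges::reduce(clip_ir(tw$start[tw$scaffold == sc],
                                  tw$end[tw$scaffold == sc], L))
    E <- IRanges::setdiff(E, P)
    I <- IRanges::setdiff(I, IRanges::union(P, E))
    T_ <- IRanges::setdiff(T_, Reduce(IRanges::union, list(P, E, I)))
    G <- IRanges::setdiff(whole, Reduce(IRanges::union, list(P, E, I, T_)))
    part <- list(`promoter-TSS` = P, exon = E, intron = I, TTS = T_,
                 intergenic = G)
    df <- do.call(rbind, lapply(names(part), function(lab) {
      r <- part[[lab]]
      if (!length(r)) return(NULL)
      data.frame(scaffold = sc, start = BiocGenerics::start(r) - 1L,
                 end = BiocGenerics::end(r), label = lab,
                 stringsAsFactors = FALSE)
    }))
    df <- df[order(df$start), , drop = FALSE]
    stopifnot(sum(df$end - df$start) == L)  # total tiling invariant
    segs[[sc]] <- df
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  structure(out, scaffold_lengths = scaffold_lengths,
            class = c("genome_partition", "data.frame"))
}

#' Label peaks by the partition label at their summit
#'
#' Peaks overlapping several annotation regions are assigned by the single
#' base at the peak summit (midpoint when no summit is recorded).
#'
#' @param peaks peak data.frame.
#' @param partition a `genome_partition` from [build_partition()].
#' @return character vector of labels, one per peak.
#' @export
assign_peak_region <- function(peaks, partition) {
  if (!nrow(peaks)) return(character(0))
  lens <- attr(partition, "scaffold_lengths")
  pos <- summit_pos(peaks)
  out <- character(nrow(peaks))
  for (sc in unique(peaks$scaffold)) {
    sel <- peaks$scaffold == sc
    if (!sc %in% names(lens))
      stop_("peak summit on scaffold absent from partition: ", sc)
    if (any(pos[sel] >= lens[[sc]] | pos[sel] < 0))
      stop_("peak summit beyond scaffold end on ", sc)
    seg <- partition[partition$scaffold == sc, , drop = FALSE]
    idx <- findInterval(pos[sel], seg$start)
    out[sel] <- seg$label[idx]
  }
  out
}

#' Distance to the nearest TSS
#'
#' For each peak (reference point = summit, midpoint fallback) or point, the
#' same-scaffold gene whose TSS minimizes the absolute distance. The signed
#' distance is `point - TSS` in genome orientation; ties are broken by the
#' lexicographically smallest `gene_id`. Cross-scaffold genes are never
#' returned: points on gene-free scaffolds get `NA`.
#'
#' @param x a peak data.frame, or a data.frame with `scaffold` and `pos`.
#' @param genes a `gene_models` object.
#' @return data.frame with `scaffold`, `pos`, `gene_id`, `distance`.
#' @export
distance_to_nearest_tss <- function(x, genes) {
  pos <- if ("pos" %in% names(x)) as.integer(x$pos) else summit_pos(x)
  tss <- tss_table(genes)
  n <- length(pos)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  for (sc in unique(x$scaffold)) {
    sel <- which(x$scaffold == sc)
    tt <- tss[tss$scaffold == sc, , drop = FALSE]
    if (!nrow(tt)) next
    ## one representative per distinct TSS position: the lexicographically
    ## smallest gene_id at that position
    tt <- tt[order(tt$pos, tt$gene_id, method = "radix"), , drop = FALSE]
    first <- !duplicated(tt$pos)
    upos <- tt$pos[first]
    ugene <- tt$gene_id[first]
    i <- findInterval(pos[sel], upos)
    left_ok <- i >= 1L
    right_ok <- i < length(upos)
    dl <- ifelse(left_ok, pos[sel] - upos[pmax(i, 1L)], NA_integer_)
    dr <- ifelse(right_ok, pos[sel] - upos[pmin(i + 1L, length(upos))],
                 NA_integer_)
    gl <- ifelse(left_ok, ugene[pmax(i, 1L)], NA_character_)
    gr_ <- ifelse(right_ok, ugene[pmin(i + 1L, length(upos))], NA_character_)
    pick_left <- ifelse(
      is.na(dl), FALSE,
      ifelse(is.na(dr), TRUE,
             abs(dl) < abs(dr) |
               (abs(dl) == abs(dr) &
                  pmin(gl, gr_) == gl))  # tie -> smaller gene_id
    )
    ## pmin on character compares in collation order; enforce C-locale by radix
    tie <- !is.na(dl) & !is.na(dr) & abs(dl) == abs(dr)
    if (any(tie)) {
      pick_left[tie] <- vapply(which(tie), function(k) {
        lex_min(c(gl[k], gr_[k])) == gl[k]
      }, logical(1))
    }
    dist[sel] <- ifelse(pick_left, dl, dr)
    gene_id[sel] <- ifelse(pick_left, gl, gr_)
  }
  data.frame(scaffold = x$scaffold, pos = pos, gene_id = gene_id,
             distance = dist, stringsAsFactors = FALSE)
}
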