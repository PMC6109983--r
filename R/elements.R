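# Promoter / DRE calling from H3K4me3 / H3K4me1 peaks, activity by H3K27ac
# overlap, and the mark co-occurrence summaries.

#' Call promoters and distal regulatory elements (DREs)
#'
#' Implements the histone-mark element definitions: a DRE is an H3K4me1 peak
#' whose summit lies more than `max_promoter_distance` (default 1.5 kb) from
#' every TSS; a promoter is an H3K4me3 peak whose summit lies within that
#' distance of some TSS. H3K4me1 peaks within the promoter zone are dropped
#' entirely (promoters come only from H3K4me3), and distal H3K4me3 peaks are
#' likewise not elements. An element is *active* iff its source peak overlaps
#' at least one H3K27ac peak (>= 1 shared base). Every element carries its
#' nearest gene and signed summit-to-TSS distance; H3K4me1 peaks on gene-free
#' scaffolds are distal by definition and carry no target gene.
#'
#' @param me1_peaks,me3_peaks,ac_peaks peak data.frames for H3K4me1, H3K4me3
#'   and H3K27ac, all from one condition.
#' @param genes a `gene_models` object (must be non-empty).
#' @param condition condition label stored on the elements.
#' @param max_promoter_distance bp threshold separating promoter-proximal
#'   from distal summits.
#' @return data.frame of elements: the source peak columns plus `kind`
#'   (`"promoter"`/`"DRE"`), `active`, `condition`, `nearest_gene`,
#'   `tss_distance`.
#' @export
call_elements <- function(me1_peaks, me3_peaks, ac_peaks, genes,
                          condition = NA_character_,
                          max_promoter_distance = 1500L) {
  if (!nrow(genes$genes)) stop_("empty gene set: element distances undefined")
  check_peaks(me1_peaks, "me1_peaks")
  check_peaks(me3_peaks, "me3_peaks")
  check_peaks(ac_peaks, "ac_peaks")
  one <- function(peaks, kind) {
    if (!nrow(peaks)) {
      out <- cbind(peaks, kind = character(0), active = logical(0),
                   condition = character(0), nearest_gene = character(0),
                   tss_distance = integer(0))
      return(out)
    }
    nt <- distance_to_nearest_tss(peaks, genes)
    distal <- is.na(nt$distance) | abs(nt$distance) > max_promoter_distance
    keep <- if (kind == "DRE") distal else !distal
    out <- peaks[keep, , drop = FALSE]
    out$kind <- kind
    out$active <- overlap_any(out, ac_peaks)
    out$condition <- condition
    out$nearest_gene <- nt$gene_id[keep]
    out$tss_distance <- nt$distance[keep]
    out
  }
  res <- rbind(one(me3_peaks, "promoter"), one(me1_peaks, "DRE"))
  rownames(res) <- NULL
  res
}

cooccurrence_frame <- function(context, categories, counts, denominators) {
  data.frame(
    context = context,
    category = categories,
    count = as.integer(counts),
    denominator = as.integer(denominators),
    fraction = ifelse(denominators > 0, counts / denominators, NA_real_),
    percent = proportion_report(counts, denominators),
    stringsAsFactors = FALSE
  )
}

#' Mark co-occurrence at TSSs
#'
#' For every TSS, a mark is present iff some peak of that mark overlaps the
#' window `[TSS - window, TSS + window)`. Counts TSSs in each joint category;
#' the denominator is the number of TSSs in the supplied annotation (never
#' hard-coded).
#'
#' @inheritParams call_elements
#' @param window half-width of the TSS window in bp.
#' @return data.frame with one row per category (`me3_and_ac`, `me1_and_ac`,
#'   `me3_only`, `me1_only`) and columns `count`, `denominator`, `fraction`,
#'   `percent`.
#' @export
cooccurrence_at_tss <- function(me1_peaks, me3_peaks, ac_peaks, genes,
                                window = 1500L) {
  tss <- tss_table(genes)
  win <- data.frame(scaffold = tss$scaffold,
                    start = pmax(tss$pos - window, 0L),
                    end = tss$pos + window)
  me3 <- overlap_any(win, me3_peaks)
  me1 <- overlap_any(win, me1_peaks)
  ac <- overlap_any(win, ac_peaks)
  cooccurrence_frame(
    "TSS",
    c("me3_and_ac", "me1_and_ac", "me3_only", "me1_only"),
    c(sum(me3 & ac), sum(me1 & ac), sum(me3 & !ac), sum(me1 & !ac)),
    rep(nrow(win), 4L)
  )
}

#' Mark co-occurrence in intergenic regions
#'
#' Restricted to peaks whose summit falls in an intergenic segment of the
#' five-way partition. For each of H3K4me1 and H3K4me3, counts intergenic
#' peaks that do / do not overlap an H3K27ac peak; the denominator is that
#' mark's intergenic peak count (stated explicitly in the output because the
#' published intergenic denominators are mutually inconsistent).
#'
#' @inheritParams call_elements
#' @param partition a `genome_partition`.
#' @return data.frame as in [cooccurrence_at_tss()] with context
#'   `"intergenic"`.
#' @export
cooccurrence_intergenic <- function(me1_peaks, me3_peaks, ac_peaks, partition) {
  inter <- function(peaks) {
    if (!nrow(peaks)) return(peaks)
    peaks[assign_peak_region(peaks, partition) == "intergenic", , drop = FALSE]
  }
  m1 <- inter(me1_peaks)
  m3 <- inter(me3_peaks)
  h1 <- overlap_any(m1, ac_peaks)
  h3 <- overlap_any(m3, ac_peaks)
  cooccurrence_frame(
    "intergenic",
    c("me1_and_ac", "me1_only", "me3_and_ac", "me3_only"),
    c(sum(h1), sum(!h1), sum(h3), sum(!h3)),
    c(nrow(m1), nrow(m1), nrow(m3), nrow(m3))
  )
}

#' Histogram of DRE-to-TSS distances
#'
#' Bins the absolute summit-to-TSS distance of DREs that have a nearest gene.
#' Default edges follow the conventional 1.5/5/10/20/50/100 kb bands with an
#' open top bin.
#'
#' @param elements element data.frame from [call_elements()].
#' @param edges_kb increasing bin edges in kb.
#' @return data.frame with `bin` labels and `count`; counts sum to the number
#'   of DREs with a nearest gene.
#' @export
tss_distance_histogram <- function(elements,
                                   edges_kb = c(1.5, 5, 10, 20, 50, 100)) {
  if (is.unsorted(edges_kb, strictly = TRUE))
    stop_("edges_kb must be strictly increasing")
  d <- abs(elements$tss_distance[elements$kind == "DRE"])
  d <- d[!is.na(d)]
  edges <- edges_kb * 1000
  idx <- findInterval(d, edges)
  if (any(idx == 0)) {
    warning("dropping ", sum(idx == 0), " distance(s) below the first edge")
    idx <- idx[idx > 0]
  }
  labs <- c(paste0("[", edges_kb[-length(edges_kb)], ",",
                   edges_kb[-1], ")kb"),
            paste0(">=", edges_kb[length(edges_kb)], "kb"))
  data.frame(bin = labs,
             count = as.integer(tabulate(idx, nbins = length(labs))),
             stringsAsFactors = FALSE)
}
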