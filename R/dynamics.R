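# Two-condition comparison: union regions over called peaks, library-scaled
# signal densities, the twofold-change classification, and per-peak presence
# calls.

#' Union regions of two peak sets
#'
#' Connected components of the combined control+treated peak set under
#' >= 1-bp overlap, each emitted as the component's min-start/max-end
#' interval. Half-open abutting peaks are not joined.
#'
#' @param peaks_control,peaks_treated peak data.frames.
#' @return data.frame of regions (`scaffold`, `start`, `end`, `name`).
#' @export
union_regions <- function(peaks_control, peaks_treated) {
  cols <- c("scaffold", "start", "end")
  all <- rbind(peaks_control[, cols, drop = FALSE],
               peaks_treated[, cols, drop = FALSE])
  if (!nrow(all))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  red <- GenomicRanges::reduce(as_gr(all), min.gapwidth = 0L)
  out <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(red)),
    start = BiocGenerics::start(red) - 1L,
    end = BiocGenerics::end(red),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$scaffold, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out$name <- sprintf("region_%05d", seq_len(nrow(out)))
  out
}

#' Depth-normalized signal density over regions
#'
#' Mean per-base coverage over each region, scaled by
#' `1e6 / library_size` of the track (the identity under the default
#' `library_size = 1e6`).
#'
#' @param regions interval data.frame.
#' @param track a `coverage_track`.
#' @return numeric vector of densities, one per region.
#' @export
region_signal <- function(regions, track) {
  if (!nrow(regions)) return(numeric(0))
  out <- numeric(nrow(regions))
  for (sc in unique(regions$scaffold)) {
    sel <- which(regions$scaffold == sc)
    r <- track$cov[[sc]]
    if (is.null(r)) stop_("region on scaffold absent from track: ", sc)
    if (any(regions$start[sel] < 0 | regions$end[sel] > length(r)))
      stop_("region outside track bounds on ", sc)
    v <- IRanges::Views(r, start = regions$start[sel] + 1L,
                        end = regions$end[sel])
    out[sel] <- IRanges::viewMeans(v)
  }
  out * 1e6 / track$library_size
}

#' Two-condition twofold-change classification
#'
#' For each region, computes library-scaled densities in both conditions and
#' the pseudocounted fold change
#' `(signal_treated + pseudocount) / (signal_control + pseudocount)`.
#' With `boundary = "exclusive"` (the generic rule) a region is `increased`
#' iff fold > 2 and `decreased` iff fold < 0.5; `boundary = "inclusive"`
#' uses fold >= 2 / fold <= 0.5 (the at-least-twofold convention applied to
#' DRE acetylation dynamics).
#'
#' @param regions interval data.frame (e.g. from [union_regions()]).
#' @param track_control,track_treated `coverage_track`s, each normalized by
#'   its own library size.
#' @param pseudocount non-negative density pseudocount.
#' @param boundary `"exclusive"` or `"inclusive"` twofold boundary.
#' @return `regions` plus `signal_control`, `signal_treated`, `fold_change`
#'   and `klass` (`increased` / `decreased` / `stable`).
#' @export
classify_dynamics <- function(regions, track_control, track_treated,
                              pseudocount = 0.5,
                              boundary = c("exclusive", "inclusive")) {
  boundary <- match.arg(boundary)
  if (pseudocount < 0) stop_("pseudocount must be non-negative")
  sc <- region_signal(regions, track_control)
  st <- region_signal(regions, track_treated)
  fc <- (st + pseudocount) / (sc + pseudocount)
  klass <- if (boundary == "exclusive") {
    ifelse(fc > 2, "increased", ifelse(fc < 0.5, "decreased", "stable"))
  } else {
    ifelse(fc >= 2, "increased", ifelse(fc <= 0.5, "decreased", "stable"))
  }
  out <- regions
  out$signal_control <- sc
  out$signal_treated <- st
  out$fold_change <- fc
  out$klass <- klass
  out
}

#' Per-peak presence labels across conditions
#'
#' A treated peak is `treated_only` iff it overlaps no control peak, and
#' symmetrically for `control_only`; every other peak is `both`.
#'
#' @param peaks_control,peaks_treated peak data.frames.
#' @return data.frame: the peaks of both sets with a `condition` column
#'   (`control` / `treated`) and a `presence` label.
#' @export
presence_calls <- function(peaks_control, peaks_treated) {
  lab_c <- ifelse(overlap_any(peaks_control, peaks_treated),
                  "both", "control_only")
  lab_t <- ifelse(overlap_any(peaks_treated, peaks_control),
                  "both", "treated_only")
  ctl <- peaks_control
  trt <- peaks_treated
  ctl$condition <- rep("control", nrow(ctl))
  trt$condition <- rep("treated", nrow(trt))
  ctl$presence <- lab_c
  trt$presence <- lab_t
  out <- rbind(ctl, trt)
  rownames(out) <- NULL
  out
}

#' H3K27ac dynamics at DREs
#'
#' Applies the at-least-twofold classification to each DRE's source-peak
#' interval against the two H3K27ac coverage tracks.
#'
#' @param dres element data.frame (rows with `kind != "DRE"` are ignored).
#' @param track_control,track_treated H3K27ac `coverage_track`s.
#' @param pseudocount density pseudocount.
#' @return one [classify_dynamics()] row per DRE, keeping `name`,
#'   `nearest_gene` and `tss_distance`.
#' @export
dre_h3k27ac_dynamics <- function(dres, track_control, track_treated,
                                 pseudocount = 0.5) {
  d <- dres[dres$kind == "DRE", , drop = FALSE]
  regions <- data.frame(scaffold = d$scaffold, start = d$start, end = d$end,
                        name = d$name, stringsAsFactors = FALSE)
  out <- classify_dynamics(regions, track_control, track_treated,
                           pseudocount = pseudocount, boundary = "inclusive")
  out$nearest_gene <- d$nearest_gene
  out$tss_distance <- d$tss_distance
  out
}
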