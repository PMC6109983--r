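# Linking regulatory elements to transcription: expression categories,
# strand-oriented TSS metaprofiles, and mean log-expression per element class.

#' Four-way expression categories
#'
#' Genes below `none_threshold` RPKM are `none`; the remaining genes are
#' ranked by RPKM and split into equal-size tertiles `low` / `medium` /
#' `high` (ties broken by `gene_id`; remainder genes go to the lower
#' tertiles).
#'
#' @param expr expression data.frame from [read_expression()].
#' @param condition column of `expr` to categorize.
#' @param none_threshold RPKM below which a gene counts as not expressed.
#' @return named factor (levels `none < low < medium < high`) over all genes.
#' @export
categorize_expression <- function(expr, condition, none_threshold = 1) {
  if (!nrow(expr)) stop_("empty expression table")
  if (!condition %in% names(expr))
    stop_("condition '", condition, "' not in expression table")
  v <- stats::setNames(expr[[condition]], expr$gene_id)
  cat <- rep("none", length(v))
  names(cat) <- names(v)
  exp_idx <- which(v >= none_threshold)
  n <- length(exp_idx)
  if (n) {
    ord <- exp_idx[order(v[exp_idx], names(v)[exp_idx], method = "radix")]
    base <- n %/% 3L
    rem <- n %% 3L
    sizes <- c(low = base + (rem >= 1L), medium = base + (rem >= 2L),
               high = base)
    cat[ord] <- rep(c("low", "medium", "high"), times = sizes)
  }
  stats::setNames(
    factor(cat, levels = c("none", "low", "medium", "high"), ordered = TRUE),
    names(v)
  )
}

#' Strand-oriented TSS metaprofile
#'
#' For each gene, extracts the coverage window `[TSS - flank, TSS + flank)`
#' oriented 5'->3' (reversed for "-" genes), averages it in `bin`-bp bins,
#' and averages the bins across genes within each expression category.
#' Windows truncated by scaffold ends contribute only their covered
#' positions. Signal is scaled by `1e6 / library_size` like
#' [region_signal()].
#'
#' @param track a `coverage_track`.
#' @param genes a `gene_models` object.
#' @param categories named factor from [categorize_expression()]; genes
#'   missing from it are skipped.
#' @param flank half-window in bp (divisible by `bin`).
#' @param bin bin width in bp.
#' @return a `meta_profile`: list with `centers` (bp relative to the TSS,
#'   negative = upstream), `profile` (category x bin matrix of mean signal;
#'   categories with no genes are absent), and `n_genes` per category.
#' @export
tss_metaprofile <- function(track, genes, categories, flank = 2000L,
                            bin = 50L) {
  if (flank %% bin != 0) stop_("flank must be divisible by bin")
  tss <- tss_table(genes)
  nb <- as.integer(2L * flank / bin)
  levs <- levels(categories)
  sums <- matrix(0, nrow = length(levs), ncol = nb, dimnames = list(levs))
  cnts <- matrix(0, nrow = length(levs), ncol = nb, dimnames = list(levs))
  ngenes <- stats::setNames(integer(length(levs)), levs)
  scale <- 1e6 / track$library_size
  for (i in seq_len(nrow(tss))) {
    cat <- as.character(categories[tss$gene_id[i]])
    if (is.na(cat)) next
    r <- track$cov[[tss$scaffold[i]]]
    if (is.null(r)) next
    t0 <- tss$pos[i]
    ## genome positions covering oriented offsets -flank .. flank-1
    if (tss$strand[i] == "+") {
      lo <- t0 - flank; hi <- t0 + flank       # [lo, hi)
    } else {
      lo <- t0 - flank + 1L; hi <- t0 + flank + 1L
    }
    s <- max(lo, 0L); e <- min(hi, length(r))
    if (s >= e) next
    vals <- rep(NA_real_, 2L * flank)
    vals[(s - lo + 1L):(e - lo)] <- as.numeric(S4Vectors::window(r, s + 1L, e))
    if (tss$strand[i] == "-") vals <- rev(vals)
    ok <- !is.na(vals)
    sums[cat, ] <- sums[cat, ] + colSums(matrix(ifelse(ok, vals, 0),
                                                nrow = bin))
    cnts[cat, ] <- cnts[cat, ] + colSums(matrix(as.numeric(ok), nrow = bin))
    ngenes[cat] <- ngenes[cat] + 1L
  }
  keep <- ngenes > 0L
  prof <- (sums / cnts)[keep, , drop = FALSE] * scale
  structure(
    list(centers = seq(-flank + bin / 2, flank - bin / 2, by = bin),
         profile = prof, n_genes = ngenes[keep], flank = flank, bin = bin),
    class = "meta_profile"
  )
}

#' Mean log-expression per element class
#'
#' For each class (a set of target gene ids, e.g. the nearest genes of
#' active DREs), computes the mean of `log2(RPKM + 1)`. Genes are
#' deduplicated within a class by default so multi-enhancer genes do not
#' dominate; genes with no expression record are excluded and counted in the
#' reported drop tally.
#'
#' @param classes named list of character vectors of gene ids.
#' @param expr expression data.frame.
#' @param condition expression column to use.
#' @param dedup deduplicate gene ids within each class?
#' @return data.frame with `class`, `n_genes` (used), `n_dropped`,
#'   `mean_log2_expr` (`NA`, with a warning, for a class with no mapped
#'   genes).
#' @export
expression_by_element_class <- function(classes, expr, condition,
                                        dedup = TRUE) {
  if (!condition %in% names(expr))
    stop_("condition '", condition, "' not in expression table")
  v <- stats::setNames(expr[[condition]], expr$gene_id)
  rows <- lapply(names(classes), function(cl) {
    g <- classes[[cl]]
    g <- g[!is.na(g)]
    if (dedup) g <- unique(g)
    known <- g %in% names(v)
    if (!any(known)) {
      warning("class '", cl, "' has no genes with expression records")
      return(data.frame(class = cl, n_genes = 0L,
                        n_dropped = sum(!known),
                        mean_log2_expr = NA_real_))
    }
    data.frame(class = cl, n_genes = sum(known), n_dropped = sum(!known),
               mean_log2_expr = mean(log2(v[g[known]] + 1)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build element target-gene classes
#'
#' Convenience grouping used by the expression comparisons: nearest genes of
#' active DREs, of inactive (poised) DREs, of all DREs, plus all genes.
#'
#' @param elements element data.frame from [call_elements()].
#' @param expr expression data.frame (for the all-genes class).
#' @return named list of gene-id vectors.
#' @export
element_target_classes <- function(elements, expr) {
  dre <- elements[elements$kind == "DRE", , drop = FALSE]
  list(
    active_DRE = dre$nearest_gene[dre$active],
    inactive_DRE = dre$nearest_gene[!dre$active],
    all_DRE = dre$nearest_gene,
    all_genes = expr$gene_id
  )
}
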