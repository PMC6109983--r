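# Ground-truth synthetic-data generator. Emulates the statistical structure
# of a two-condition (vehicle vs hormone) histone-mark ChIP-seq experiment on
# a multi-scaffold genome: promoters carry H3K4me3+H3K27ac, distal elements
# carry H3K4me1 with H3K27ac on the active subset, a configurable fraction of
# poised elements gain H3K27ac on treatment, expression is coupled to element
# activity, and receptor-binding peaks carry a planted response-element motif
# in a known fraction of their sequences.

SIM_MARKS <- c("H3K4me1", "H3K4me3", "H3K27ac")
CAT_SCALE <- c(none = 0.2, low = 0.6, medium = 1.0, high = 1.6)

#' Simulation configuration
#'
#' All knobs of the synthetic dataset. Defaults are the study conditions used
#' throughout the test-suite: mean coverage depth 30, 50-bp summit jitter,
#' 5\% false peaks and 5\% dropouts, 30\% of poised elements activated at a
#' fourfold coverage gain, fourfold expression coupling for active-element
#' target genes, and a response-element motif planted in 40\% of receptor
#' peaks with 5\% per-base mutation.
#'
#' @param seed integer RNG seed; the whole dataset is reproducible from it.
#' @param n_scaffolds,scaffold_length genome shape (length must be a
#'   multiple of `cov_step`).
#' @param n_genes number of non-overlapping stranded genes.
#' @param n_active_enh,n_poised_enh planted distal elements with / without
#'   H3K27ac in the control condition.
#' @param activation_fraction fraction of poised elements gaining H3K27ac on
#'   treatment.
#' @param fold_gain coverage fold (>= 1) of the treated H3K27ac signal over
#'   background at gained elements.
#' @param depth mean peak coverage depth.
#' @param background_rate background coverage as a fraction of `depth`.
#' @param summit_jitter_sd sd (bp) of Normal summit jitter in corrupted peak
#'   lists.
#' @param false_peak_rate,miss_rate decoy and dropout probabilities for
#'   corrupted peak lists.
#' @param n_ecr number of receptor (EcR) peaks, placed on a subset of
#'   elements.
#' @param ecre_plant_fraction fraction of receptor peaks with a planted
#'   response-element instance.
#' @param ecre_mut_rate per-base mutation rate of planted instances.
#' @param expression_coupling RPKM multiplier for genes nearest to active
#'   (or, in the treated condition, gained) elements.
#' @param none_expr_fraction fraction of genes simulated as not expressed.
#' @param cov_step bin width (bp) at which coverage noise is drawn.
#' @param poisson_noise draw Poisson counts per coverage bin? `FALSE` emits
#'   the exact piecewise-constant intensity (the noise-free limit).
#' @param make_sequence,make_coverage generate genome sequence / coverage
#'   tracks? Both can be switched off for fast element-level replicates.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 4L,
                       scaffold_length = 1e6,
                       n_genes = 300L,
                       n_active_enh = 300L,
                       n_poised_enh = 300L,
                       activation_fraction = 0.3,
                       fold_gain = 4,
                       depth = 30,
                       background_rate = 0.1,
                       summit_jitter_sd = 50,
                       false_peak_rate = 0.05,
                       miss_rate = 0.05,
                       n_ecr = 250L,
                       ecre_plant_fraction = 0.4,
                       ecre_mut_rate = 0.05,
                       expression_coupling = 4,
                       none_expr_fraction = 0.25,
                       cov_step = 10L,
                       poisson_noise = TRUE,
                       make_sequence = TRUE,
                       make_coverage = TRUE) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_length = as.integer(scaffold_length),
              n_genes = as.integer(n_genes),
              n_active_enh = as.integer(n_active_enh),
              n_poised_enh = as.integer(n_poised_enh),
              activation_fraction = activation_fraction,
              fold_gain = fold_gain, depth = depth,
              background_rate = background_rate,
              summit_jitter_sd = summit_jitter_sd,
              false_peak_rate = false_peak_rate, miss_rate = miss_rate,
              n_ecr = as.integer(n_ecr),
              ecre_plant_fraction = ecre_plant_fraction,
              ecre_mut_rate = ecre_mut_rate,
              expression_coupling = expression_coupling,
              none_expr_fraction = none_expr_fraction,
              cov_step = as.integer(cov_step),
              poisson_noise = isTRUE(poisson_noise),
              make_sequence = isTRUE(make_sequence),
              make_coverage = isTRUE(make_coverage))
  probs <- c("activation_fraction", "false_peak_rate", "miss_rate",
             "ecre_plant_fraction", "ecre_mut_rate", "none_expr_fraction")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_(p, " must be in [0, 1]")
  if (cfg$fold_gain < 1) stop_("fold_gain must be >= 1")
  if (cfg$depth <= 0) stop_("depth must be positive")
  if (cfg$summit_jitter_sd < 0) stop_("summit_jitter_sd must be >= 0")
  if (cfg$scaffold_length %% cfg$cov_step != 0)
    stop_("scaffold_length must be a multiple of cov_step")
  structure(cfg, class = "sim_config")
}

#' Noise-free variant of a configuration
#'
#' Switches off every noise channel: dropouts, decoys, summit jitter, motif
#' mutation and Poisson coverage noise. In this limit every downstream
#' module's output equals the truth table's implied answer.
#'
#' @param config a `sim_config`.
#' @return modified `sim_config`.
#' @export
noise_free <- function(config) {
  config$miss_rate <- 0
  config$false_peak_rate <- 0
  config$summit_jitter_sd <- 0
  config$ecre_mut_rate <- 0
  config$poisson_noise <- FALSE
  config
}

#' Bundled response-element PFM for simulation
#'
#' A 13-column palindromic nuclear-receptor-like position frequency matrix
#' (inverted-repeat AGGTCA half-sites around a degenerate spacer) used only
#' for simulation and testing. Real analyses must supply their own matrix
#' file.
#'
#' @param pseudocount per-cell pseudocount for normalization.
#' @return a `pwm` object.
#' @export
ecre_pwm <- function(pseudocount = 0.01) {
  cons <- ECRE_CONSENSUS
  W <- length(cons)
  counts <- matrix(5, nrow = 4, ncol = W, dimnames = list(BASES, NULL))
  for (j in seq_len(W)) {
    if (cons[j] == "N") counts[, j] <- 25 else counts[cons[j], j] <- 85
  }
  prob <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  structure(list(motif_id = "ECRE_SIM", name = "synthetic EcRE (IR1-like)",
                 counts = counts, prob = prob,
                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                 pseudocount = pseudocount),
            class = "pwm")
}

ECRE_CONSENSUS <- c("A", "G", "G", "T", "C", "A", "N",
                    "T", "G", "A", "C", "C", "T")

## ---- internal generator pieces -------------------------------------------

mk_peaks <- function(scaffold, start, end, name, signal) {
  if (!length(scaffold)) return(peak_frame())
  w <- end - start
  peak_frame(scaffold, start, end, name, rep_len(signal, length(scaffold)),
             w %/% 2L)
}

## Sequentially pack genes and distal elements onto scaffolds with gaps of at
## least 1.8 kb, which guarantees >1.5 kb summit-to-TSS clearance for every
## distal element.
place_items <- function(cfg) {
  widths_g <- sample(2000:5000, cfg$n_genes, replace = TRUE)
  n_dre <- cfg$n_active_enh + cfg$n_poised_enh
  widths_d <- sample(600:1000, n_dre, replace = TRUE)
  items <- data.frame(
    type = c(rep("gene", cfg$n_genes), rep("dre", n_dre)),
    width = c(widths_g, widths_d),
    stringsAsFactors = FALSE
  )
  items <- items[sample(nrow(items)), , drop = FALSE]
  scafs <- paste0("scaf", seq_len(cfg$n_scaffolds))
  margin <- 2500L
  cursor <- stats::setNames(rep(margin, cfg$n_scaffolds), scafs)
  sc_i <- 1L
  items$scaffold <- NA_character_
  items$start <- NA_integer_
  for (k in seq_len(nrow(items))) {
    placed <- FALSE
    tries <- 0L
    while (!placed) {
      gap <- sample(1800:3000, 1L)
      pos <- cursor[[sc_i]] + gap
      if (pos + items$width[k] <= cfg$scaffold_length - margin) {
        items$scaffold[k] <- scafs[sc_i]
        items$start[k] <- pos
        cursor[[sc_i]] <- pos + items$width[k]
        placed <- TRUE
      } else {
        sc_i <- sc_i + 1L
        tries <- tries + 1L
        if (sc_i > cfg$n_scaffolds) sc_i <- 1L
        if (tries > cfg$n_scaffolds)
          stop_("cannot place all genes/elements: genome too small; ",
                "increase scaffold_length or n_scaffolds")
      }
    }
  }
  items$end <- items$start + items$width
  items
}

## Exon/intron structure: 1-4 exons on a 60-bp boundary grid.
make_exons <- function(gene_id, scaffold, start, end) {
  w <- end - start
  k <- sample(1:4, 1L)
  if (k == 1L)
    return(data.frame(gene_id = gene_id, scaffold = scaffold,
                      start = start, end = end, stringsAsFactors = FALSE))
  grid <- seq(60L, w - 60L, by = 60L)
  bnd <- sort(sample(grid, 2L * k - 2L))
  edges <- c(0L, bnd, w)
  ex <- seq(1L, 2L * k - 1L, by = 2L)
  data.frame(gene_id = gene_id, scaffold = scaffold,
             start = start + edges[ex], end = start + edges[ex + 1L],
             stringsAsFactors = FALSE)
}

corrupt_peaks <- function(peaks, cfg, scaffold_lengths, prefix) {
  out <- peaks
  if (cfg$miss_rate > 0 && nrow(out))
    out <- out[stats::runif(nrow(out)) >= cfg$miss_rate, , drop = FALSE]
  if (cfg$summit_jitter_sd > 0 && nrow(out)) {
    w <- out$end - out$start
    off <- out$summit_offset +
      as.integer(round(stats::rnorm(nrow(out), 0, cfg$summit_jitter_sd)))
    out$summit_offset <- pmin(pmax(off, 0L), w - 1L)
  }
  if (cfg$false_peak_rate > 0 && nrow(peaks)) {
    nd <- stats::rbinom(1L, nrow(peaks), cfg$false_peak_rate)
    if (nd > 0) {
      dw <- (peaks$end - peaks$start)[sample.int(nrow(peaks), nd,
                                                 replace = TRUE)]
      dsc <- sample(names(scaffold_lengths), nd, replace = TRUE)
      dst <- vapply(seq_len(nd), function(i) {
        sample(1000:(scaffold_lengths[[dsc[i]]] - 1000L - dw[i]), 1L)
      }, integer(1))
      dec <- mk_peaks(dsc, dst, dst + dw,
                      sprintf("%s_decoy_%04d", prefix, seq_len(nd)),
                      stats::runif(nd, 1, cfg$depth))
      out <- rbind(out, dec)
    }
  }
  out <- out[order(out$scaffold, out$start, out$name, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

## Piecewise-constant intensity via a difference array: O(L + contributions).
lambda_vector <- function(bg, starts, ends, heights, L) {
  delta <- numeric(L + 1L)
  s <- pmax(starts, 0L) + 1L
  e <- pmin(ends, L) + 1L
  keep <- s < e
  for (i in which(keep)) {
    delta[s[i]] <- delta[s[i]] + heights[i]
    delta[e[i]] <- delta[e[i]] - heights[i]
  }
  bg + cumsum(delta[seq_len(L)])
}

#' Generate a complete synthetic dataset
#'
#' Builds (and optionally writes to disk) a ground-truth-labeled dataset:
#' genome FASTA, GFF3 gene models, per-mark/per-condition narrowPeak lists
#' and bedGraph coverage, a receptor peak list with planted motif instances,
#' an expression table coupled to element activity, and truth tables. The
#' whole dataset is reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir if non-`NULL`, directory to write the dataset into
#'   (created if needed); a `config.txt` consumable by [run_pipeline()] is
#'   included.
#' @return a `sim_dataset` list: `config`, `scaffold_lengths`, `genes`,
#'   `expression`, `peaks` (nested `[[mark]][[condition]]` plus
#'   `$ecr$treated`), `tracks` (same nesting; `NULL` unless
#'   `make_coverage`), `genome` (`NULL` unless `make_sequence`), `pwm`, and
#'   `truth` (`$elements`, `$ecr`).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  scaffold_lengths <- stats::setNames(
    rep(cfg$scaffold_length, cfg$n_scaffolds),
    paste0("scaf", seq_len(cfg$n_scaffolds))
  )
  items <- place_items(cfg)

  ## --- gene models ---------------------------------------------------------
  gi <- which(items$type == "gene")
  genes_df <- data.frame(
    gene_id = sprintf("gene%04d", seq_along(gi)),
    scaffold = items$scaffold[gi],
    start = items$start[gi],
    end = items$end[gi],
    strand = sample(c("+", "-"), length(gi), replace = TRUE),
    stringsAsFactors = FALSE
  )
  exons <- do.call(rbind, lapply(seq_len(nrow(genes_df)), function(i) {
    make_exons(genes_df$gene_id[i], genes_df$scaffold[i],
               genes_df$start[i], genes_df$end[i])
  }))
  genes <- structure(list(genes = genes_df, exons = exons),
                     class = "gene_models")
  tss <- tss_table(genes)

  ## --- distal element truth ------------------------------------------------
  di <- which(items$type == "dre")
  n_dre <- length(di)
  dre <- data.frame(
    element_id = sprintf("dre%04d", seq_len(n_dre)),
    scaffold = items$scaffold[di],
    start = items$start[di],
    end = items$end[di],
    stringsAsFactors = FALSE
  )
  dre$summit <- (dre$start + dre$end) %/% 2L
  dre$status <- sample(rep(c("active", "poised"),
                           c(cfg$n_active_enh, cfg$n_poised_enh)))
  gain <- dre$status == "poised" &
    stats::runif(n_dre) < cfg$activation_fraction
  dre$dynamics <- ifelse(gain, "gain", "stable")
  nt <- distance_to_nearest_tss(
    data.frame(scaffold = dre$scaffold, pos = dre$summit), genes)
  dre$gene_id <- nt$gene_id
  dre$tss_distance <- nt$distance

  ## --- expression coupled to element activity ------------------------------
  none <- stats::runif(nrow(genes_df)) < cfg$none_expr_fraction
  base <- ifelse(none, stats::runif(nrow(genes_df), 0, 0.5),
                 stats::rlnorm(nrow(genes_df), meanlog = 1.5, sdlog = 1) + 1)
  ctl <- base
  active_targets <- unique(dre$gene_id[dre$status == "active"])
  ctl[genes_df$gene_id %in% active_targets] <-
    ctl[genes_df$gene_id %in% active_targets] * cfg$expression_coupling
  trt <- ctl
  gain_targets <- unique(dre$gene_id[dre$dynamics == "gain"])
  trt[genes_df$gene_id %in% gain_targets] <-
    trt[genes_df$gene_id %in% gain_targets] * cfg$expression_coupling
  expr <- data.frame(gene_id = genes_df$gene_id,
                     control = round(ctl, 4), treated = round(trt, 4),
                     stringsAsFactors = FALSE)
  categories <- categorize_expression(expr, "control", none_threshold = 1)
  gene_scale <- CAT_SCALE[as.character(categories[genes_df$gene_id])]

  ## --- truth peak lists ----------------------------------------------------
  pw <- promoter_windows(genes)
  pw$start <- pmax(pw$start, 0L)
  prom_me3 <- mk_peaks(pw$scaffold, pw$start, pw$end,
                       sprintf("me3_%s", genes_df$gene_id),
                       cfg$depth * gene_scale)
  frag_ac <- function(scaffold, start, end, tag, signal) {
    w <- end - start
    cut1 <- start + as.integer(ceiling(0.6 * w))
    cut2 <- start + as.integer(floor(0.4 * w))
    rbind(
      mk_peaks(scaffold, start, cut1, paste0(tag, "_f1"), signal),
      mk_peaks(scaffold, cut2, end, paste0(tag, "_f2"), signal)
    )
  }
  prom_ac <- frag_ac(pw$scaffold, pw$start, pw$end,
                     sprintf("ac_%s", genes_df$gene_id),
                     cfg$depth * gene_scale)
  dre_me1 <- mk_peaks(dre$scaffold, dre$start, dre$end,
                      sprintf("me1_%s", dre$element_id), cfg$depth)
  act <- dre$status == "active"
  dre_ac_both <- frag_ac(dre$scaffold[act], dre$start[act], dre$end[act],
                         sprintf("ac_%s", dre$element_id[act]), cfg$depth)
  dre_ac_gain <- frag_ac(dre$scaffold[gain], dre$start[gain], dre$end[gain],
                         sprintf("ac_%s", dre$element_id[gain]), cfg$depth)
  truth_peaks <- list(
    H3K4me1 = list(control = dre_me1, treated = dre_me1),
    H3K4me3 = list(control = prom_me3, treated = prom_me3),
    H3K27ac = list(control = rbind(prom_ac, dre_ac_both),
                   treated = rbind(prom_ac, dre_ac_both, dre_ac_gain))
  )

  ## --- receptor peaks + planted motif instances ----------------------------
  sites <- rbind(
    data.frame(id = dre$element_id, scaffold = dre$scaffold,
               center = dre$summit, stringsAsFactors = FALSE),
    data.frame(id = genes_df$gene_id,
               scaffold = pw$scaffold,
               center = (pw$start + pw$end) %/% 2L,
               stringsAsFactors = FALSE)
  )
  n_ecr <- min(cfg$n_ecr, nrow(sites))
  picked <- sites[sample(nrow(sites), n_ecr), , drop = FALSE]
  ecr <- mk_peaks(picked$scaffold, picked$center - 200L, picked$center + 200L,
                  sprintf("ecr_%04d", seq_len(n_ecr)),
                  stats::runif(n_ecr, cfg$depth / 2, cfg$depth * 2))
  n_plant <- round(n_ecr * cfg$ecre_plant_fraction)
  planted <- rep(FALSE, n_ecr)
  planted[sample(n_ecr, n_plant)] <- TRUE
  W <- length(ECRE_CONSENSUS)
  inst <- data.frame(name = ecr$name, planted = planted,
                     pos = NA_integer_, n_mut = NA_integer_,
                     stringsAsFactors = FALSE)
  inst_seq <- vector("list", n_ecr)
  info_col <- which(ECRE_CONSENSUS != "N")
  for (i in which(planted)) {
    off <- sample(60:(400L - W - 60L), 1L)
    s <- ECRE_CONSENSUS
    s[s == "N"] <- sample(BASES, sum(s == "N"), replace = TRUE)
    mut <- stats::runif(W) < cfg$ecre_mut_rate
    for (j in which(mut)) s[j] <- sample(setdiff(BASES, s[j]), 1L)
    inst$pos[i] <- ecr$start[i] + off
    inst$n_mut[i] <- sum(mut[info_col])
    inst_seq[[i]] <- s
  }

  ## --- genome sequence -----------------------------------------------------
  genome <- NULL
  if (cfg$make_sequence) {
    seqs <- lapply(names(scaffold_lengths), function(sc) {
      sample(BASES, scaffold_lengths[[sc]], replace = TRUE)
    })
    names(seqs) <- names(scaffold_lengths)
    for (i in which(planted)) {
      sc <- ecr$scaffold[i]
      at <- inst$pos[i]
      seqs[[sc]][(at + 1L):(at + W)] <- inst_seq[[i]]
    }
    genome <- Biostrings::DNAStringSet(
      vapply(seqs, paste0, character(1), collapse = ""))
    names(genome) <- names(scaffold_lengths)
  }

  ## --- coverage tracks -----------------------------------------------------
  tracks <- NULL
  if (cfg$make_coverage) {
    bg <- cfg$depth * cfg$background_rate
    contribs <- list()
    for (cond in c("control", "treated")) {
      ## H3K4me3: promoter windows, expression-scaled
      contribs[[paste0("H3K4me3.", cond)]] <- data.frame(
        scaffold = pw$scaffold, start = pw$start, end = pw$end,
        h = cfg$depth * gene_scale)
      ## H3K27ac: promoters + active DREs; gains only when treated
      ac <- rbind(
        data.frame(scaffold = pw$scaffold, start = pw$start, end = pw$end,
                   h = cfg$depth * gene_scale),
        data.frame(scaffold = dre$scaffold[act], start = dre$start[act],
                   end = dre$end[act], h = cfg$depth)
      )
      if (cond == "treated" && any(gain))
        ac <- rbind(ac, data.frame(
          scaffold = dre$scaffold[gain], start = dre$start[gain],
          end = dre$end[gain], h = bg * (cfg$fold_gain - 1)))
      contribs[[paste0("H3K27ac.", cond)]] <- ac
      ## H3K4me1: distal elements + bimodal shoulders around the TSS
      sh <- rbind(
        data.frame(scaffold = tss$scaffold, start = tss$pos - 900L,
                   end = tss$pos - 300L, h = 0.5 * cfg$depth * gene_scale),
        data.frame(scaffold = tss$scaffold, start = tss$pos + 300L,
                   end = tss$pos + 900L, h = 0.5 * cfg$depth * gene_scale)
      )
      contribs[[paste0("H3K4me1.", cond)]] <- rbind(
        data.frame(scaffold = dre$scaffold, start = dre$start,
                   end = dre$end, h = cfg$depth), sh)
    }
    tracks <- list()
    for (key in names(contribs)) {
      cc <- contribs[[key]]
      cov <- list()
      for (sc in names(scaffold_lengths)) {
        L <- scaffold_lengths[[sc]]
        sub <- cc[cc$scaffold == sc, , drop = FALSE]
        lam <- lambda_vector(bg, sub$start, sub$end, sub$h, L)
        lam_bin <- colMeans(matrix(lam, nrow = cfg$cov_step))
        val <- if (cfg$poisson_noise) {
          stats::rpois(length(lam_bin), lam_bin * cfg$cov_step) / cfg$cov_step
        } else lam_bin
        cov[[sc]] <- S4Vectors::Rle(val, rep(cfg$cov_step, length(val)))
      }
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      tracks[[parts[1]]][[parts[2]]] <- new_coverage_track(cov)
    }
  }

  ## --- corrupted observed peak lists ---------------------------------------
  peaks <- list()
  for (mark in SIM_MARKS) {
    for (cond in c("control", "treated")) {
      peaks[[mark]][[cond]] <- corrupt_peaks(
        truth_peaks[[mark]][[cond]], cfg, scaffold_lengths,
        paste0(tolower(mark), "_", cond))
    }
  }
  ecr_obs <- corrupt_peaks(ecr, cfg, scaffold_lengths, "ecr_treated")
  peaks$ecr <- list(treated = ecr_obs)

  ## --- truth tables --------------------------------------------------------
  prom_truth <- data.frame(
    element_id = sprintf("prom_%s", genes_df$gene_id),
    kind = "promoter",
    scaffold = pw$scaffold, start = pw$start, end = pw$end,
    summit = (pw$start + pw$end) %/% 2L,
    gene_id = genes_df$gene_id,
    status = "active", dynamics = "stable",
    active_control = TRUE, active_treated = TRUE,
    stringsAsFactors = FALSE
  )
  dre_truth <- data.frame(
    element_id = dre$element_id, kind = "DRE",
    scaffold = dre$scaffold, start = dre$start, end = dre$end,
    summit = dre$summit, gene_id = dre$gene_id,
    status = dre$status, dynamics = dre$dynamics,
    active_control = dre$status == "active",
    active_treated = dre$status == "active" | dre$dynamics == "gain",
    stringsAsFactors = FALSE
  )
  truth_elements <- rbind(prom_truth, dre_truth)
  truth_ecr <- data.frame(
    name = ecr_obs$name, stringsAsFactors = FALSE
  )
  truth_ecr$planted <- inst$planted[match(truth_ecr$name, inst$name)]
  truth_ecr$planted[is.na(truth_ecr$planted)] <- FALSE  # decoys
  truth_ecr$n_mut <- inst$n_mut[match(truth_ecr$name, inst$name)]

  ds <- structure(
    list(config = cfg, scaffold_lengths = scaffold_lengths, genes = genes,
         expression = expr, categories = categories, peaks = peaks,
         tracks = tracks, genome = genome, pwm = ecre_pwm(),
         truth = list(elements = truth_elements, ecr = truth_ecr)),
    class = "sim_dataset"
  )
  if (!is.null(out_dir)) write_sim_dataset(ds, out_dir)
  ds
}

#' Write a simulated dataset to disk
#'
#' Emits standard text formats (FASTA, GFF3, narrowPeak, bedGraph, TSV,
#' JASPAR PFM) plus truth tables and a `config.txt` consumable by
#' [run_pipeline()]. All writers are deterministic, so identical seeds give
#' byte-identical datasets.
#'
#' @param ds a `sim_dataset`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_sim_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_scaffold_lengths(ds$scaffold_lengths, p("scaffolds.tsv"))
  write_gene_models(ds$genes, p("genes.gff3"))
  write_expression(ds$expression, p("expression.tsv"))
  write_pwm(ds$pwm, p("ecre_pwm.jaspar"))
  if (!is.null(ds$genome)) write_genome(ds$genome, p("genome.fa"))
  for (mark in SIM_MARKS) {
    for (cond in names(ds$peaks[[mark]])) {
      write_peaks(ds$peaks[[mark]][[cond]],
                  p(sprintf("peaks_%s_%s.narrowPeak", tolower(mark), cond)))
    }
  }
  write_peaks(ds$peaks$ecr$treated, p("peaks_ecr_treated.narrowPeak"))
  if (!is.null(ds$tracks)) {
    for (mark in names(ds$tracks)) {
      for (cond in names(ds$tracks[[mark]])) {
        write_coverage(ds$tracks[[mark]][[cond]],
                       p(sprintf("coverage_%s_%s.bedGraph",
                                 tolower(mark), cond)))
      }
    }
  }
  data.table::fwrite(ds$truth$elements, p("truth_elements.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(ds$truth$ecr, p("truth_ecr.tsv"), sep = "\t",
                     quote = FALSE)
  keys <- c(
    scaffold_lengths = "scaffolds.tsv", gff = "genes.gff3",
    expression = "expression.tsv", pwm = "ecre_pwm.jaspar",
    genome_fasta = if (!is.null(ds$genome)) "genome.fa" else NULL,
    peaks_h3k4me1_control = "peaks_h3k4me1_control.narrowPeak",
    peaks_h3k4me1_treated = "peaks_h3k4me1_treated.narrowPeak",
    peaks_h3k4me3_control = "peaks_h3k4me3_control.narrowPeak",
    peaks_h3k4me3_treated = "peaks_h3k4me3_treated.narrowPeak",
    peaks_h3k27ac_control = "peaks_h3k27ac_control.narrowPeak",
    peaks_h3k27ac_treated = "peaks_h3k27ac_treated.narrowPeak",
    peaks_ecr_treated = "peaks_ecr_treated.narrowPeak"
  )
  if (!is.null(ds$tracks)) {
    for (mark in names(ds$tracks)) {
      for (cond in names(ds$tracks[[mark]])) {
        keys[sprintf("coverage_%s_%s", tolower(mark), cond)] <-
          sprintf("coverage_%s_%s.bedGraph", tolower(mark), cond)
      }
    }
  }
  writeLines(paste0(names(keys), " = ", unname(keys)), p("config.txt"))
  invisible(out_dir)
}

#' Compare called elements against the planted truth
#'
#' A predicted element matches a planted one iff their summits are within
#' `tol` bp on the same scaffold and their labels agree, where the label of
#' a DRE folds in its activity for the given condition
#' (`active_DRE` / `poised_DRE`; promoters are `promoter`).
#'
#' @param elements element data.frame from [call_elements()].
#' @param truth the `truth$elements` table of a `sim_dataset`.
#' @param condition `"control"` or `"treated"`: which condition's planted
#'   activity defines the truth label.
#' @param tol summit matching tolerance in bp.
#' @return list with `per_label` (data.frame: label, n_truth, n_pred,
#'   precision, recall; precision is `NA` when nothing was predicted),
#'   `unmatched_pred` and `unmatched_truth` (row indices).
#' @export
truth_compare <- function(elements, truth,
                          condition = c("treated", "control"), tol = 500L) {
  condition <- match.arg(condition)
  active_col <- paste0("active_", condition)
  truth_lab <- ifelse(truth$kind == "promoter", "promoter",
                      ifelse(truth[[active_col]], "active_DRE", "poised_DRE"))
  pred_lab <- ifelse(elements$kind == "promoter", "promoter",
                     ifelse(elements$active, "active_DRE", "poised_DRE"))
  pred_sum <- summit_pos(elements)
  labels <- c("promoter", "active_DRE", "poised_DRE")
  match_sets <- function(pos_a, sc_a, pos_b, sc_b) {
    ## for each a: any b on same scaffold within tol?
    out <- logical(length(pos_a))
    for (sc in unique(sc_a)) {
      bi <- which(sc_b == sc)
      ai <- which(sc_a == sc)
      if (!length(bi)) next
      pb <- sort(pos_b[bi])
      i <- findInterval(pos_a[ai], pb)
      dl <- ifelse(i >= 1L, pos_a[ai] - pb[pmax(i, 1L)], Inf)
      dr <- ifelse(i < length(pb), pb[pmin(i + 1L, length(pb))] - pos_a[ai],
                   Inf)
      out[ai] <- pmin(dl, dr) <= tol
    }
    out
  }
  rows <- lapply(labels, function(lab) {
    ti <- which(truth_lab == lab)
    pi <- which(pred_lab == lab)
    p_matched <- if (length(pi))
      match_sets(pred_sum[pi], elements$scaffold[pi],
                 truth$summit[ti], truth$scaffold[ti]) else logical(0)
    t_matched <- if (length(ti))
      match_sets(truth$summit[ti], truth$scaffold[ti],
                 pred_sum[pi], elements$scaffold[pi]) else logical(0)
    data.frame(
      label = lab, n_truth = length(ti), n_pred = length(pi),
      precision = if (length(pi)) mean(p_matched) else NA_real_,
      recall = if (length(ti)) mean(t_matched) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  per_label <- do.call(rbind, rows)
  all_p <- match_sets(pred_sum, elements$scaffold, truth$summit,
                      truth$scaffold)
  all_t <- match_sets(truth$summit, truth$scaffold, pred_sum,
                      elements$scaffold)
  list(per_label = per_label,
       unmatched_pred = which(!all_p), unmatched_truth = which(!all_t))
}
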