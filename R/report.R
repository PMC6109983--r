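# Pipeline driver: reads a plain-text key=value configuration, runs
# annotate -> call-elements -> dynamics -> link-expression -> scan-motif, and
# writes per-stage TSV tables plus a machine-readable summary and a run log.

#' Percentage for reporting
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal; used by
#' every fraction field in the report. A zero denominator yields `NA`
#' (absent), never `NaN`.
#'
#' @param numerator,denominator counts.
#' @return numeric vector of percentages with one decimal.
#' @export
proportion_report <- function(numerator, denominator) {
  n <- max(length(numerator), length(denominator))
  num <- rep_len(as.numeric(numerator), n)
  den <- rep_len(as.numeric(denominator), n)
  out <- rep(NA_real_, n)
  ok <- !is.na(den) & den > 0
  out[ok] <- round_half_up(100 * num[ok] / den[ok], 1)
  out
}

PIPELINE_KEYS <- c(
  "scaffold_lengths", "gff", "expression", "pwm", "genome_fasta",
  "peaks_h3k4me1_control", "peaks_h3k4me1_treated",
  "peaks_h3k4me3_control", "peaks_h3k4me3_treated",
  "peaks_h3k27ac_control", "peaks_h3k27ac_treated",
  "peaks_ecr_treated",
  "coverage_h3k4me1_control", "coverage_h3k4me1_treated",
  "coverage_h3k4me3_control", "coverage_h3k4me3_treated",
  "coverage_h3k27ac_control", "coverage_h3k27ac_treated",
  "promoter_max_distance", "cooccurrence_window", "flank", "bin",
  "pseudocount", "motif_threshold", "none_threshold"
)

#' Read a pipeline configuration file
#'
#' Plain-text `key = value` lines; `#` starts a comment. Unknown keys are an
#' error naming the key. Relative paths are resolved against the config
#' file's directory.
#'
#' @param path config file.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop_("malformed config line: '", lines[bad[1]], "'")
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[[`, character(1), 3L))
  unknown <- setdiff(keys, PIPELINE_KEYS)
  if (length(unknown)) stop_("unknown config key: ", unknown[1])
  if (anyDuplicated(keys)) stop_("duplicated config key: ",
                                 keys[duplicated(keys)][1])
  cfg <- stats::setNames(as.list(vals), keys)
  ## resolve paths relative to the config file
  base <- dirname(normalizePath(path))
  path_keys <- grep("^(peaks_|coverage_)|^(gff|expression|pwm|genome_fasta|scaffold_lengths)$",
                    keys, value = TRUE)
  for (k in path_keys) {
    v <- cfg[[k]]
    if (!grepl("^/", v)) cfg[[k]] <- file.path(base, v)
  }
  num_keys <- c("promoter_max_distance", "cooccurrence_window", "flank",
                "bin", "pseudocount", "motif_threshold", "none_threshold")
  for (k in intersect(num_keys, keys)) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg
}

write_tsv_commented <- function(df, path, header_lines) {
  con <- file(path, open = "wt")
  writeLines(paste0("# ", header_lines), con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes annotate -> call-elements -> dynamics -> link-expression ->
#' scan-motif on the inputs named in a configuration (file path or named
#' list as returned by [read_run_config()]), writing per-stage TSV tables, a
#' machine-readable `summary.tsv` of counts and fractions, and a
#' `run_log.txt` capturing the package version, parameters and input
#' checksums. All inputs are checked before any stage runs. Output is
#' deterministic: rerunning with the same config gives identical files.
#'
#' @param config config file path or named list.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the per-stage in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown)) stop_("unknown config key: ", unknown[1])
  defaults <- list(promoter_max_distance = 1500, cooccurrence_window = 1500,
                   flank = 2000, bin = 50, pseudocount = 0.5,
                   motif_threshold = 0.8, none_threshold = 1)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  required <- c("scaffold_lengths", "gff", "expression",
                "peaks_h3k4me1_control", "peaks_h3k4me1_treated",
                "peaks_h3k4me3_control", "peaks_h3k4me3_treated",
                "peaks_h3k27ac_control", "peaks_h3k27ac_treated")
  miss <- setdiff(required, names(cfg))
  if (length(miss)) stop_("config is missing required key: ", miss[1])
  input_keys <- intersect(names(cfg),
                          grep("^(peaks_|coverage_)|^(gff|expression|pwm|genome_fasta|scaffold_lengths)$",
                               names(cfg), value = TRUE))
  for (k in input_keys)
    if (!file.exists(cfg[[k]])) stop_("input file missing (", k, "): ",
                                      cfg[[k]])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## ---- load ---------------------------------------------------------------
  lens <- read_scaffold_lengths(cfg$scaffold_lengths)
  genes <- read_gene_models(cfg$gff)
  expr <- read_expression(cfg$expression)
  pk <- list()
  for (mark in c("h3k4me1", "h3k4me3", "h3k27ac")) {
    for (cond in c("control", "treated")) {
      pk[[mark]][[cond]] <- read_peaks(cfg[[paste0("peaks_", mark, "_", cond)]])
    }
  }
  summary_rows <- list()
  note <- function(key, value) summary_rows[[length(summary_rows) + 1L]] <<-
    data.frame(key = key, value = as.character(value),
               stringsAsFactors = FALSE)

  ## ---- annotate: five-way genome partition + peak location ---------------
  partition <- build_partition(genes, lens)
  loc_rows <- list()
  for (mark in names(pk)) {
    for (cond in c("control", "treated")) {
      lab <- assign_peak_region(pk[[mark]][[cond]], partition)
      tab <- table(factor(lab, levels = PARTITION_LABELS))
      loc_rows[[paste(mark, cond)]] <- data.frame(
        mark = mark, condition = cond, region = names(tab),
        count = as.integer(tab),
        percent = proportion_report(as.integer(tab), length(lab)),
        stringsAsFactors = FALSE
      )
    }
  }
  peak_location <- do.call(rbind, c(loc_rows, make.row.names = FALSE))
  write_tsv_commented(peak_location, file.path(out_dir, "peak_location.tsv"),
                      "peak counts by five-way genome region (summit-based)")

  ## ---- elements per condition --------------------------------------------
  elements <- list()
  for (cond in c("control", "treated")) {
    elements[[cond]] <- call_elements(
      pk$h3k4me1[[cond]], pk$h3k4me3[[cond]], pk$h3k27ac[[cond]], genes,
      condition = cond,
      max_promoter_distance = cfg$promoter_max_distance)
    write_tsv_commented(
      elements[[cond]],
      file.path(out_dir, paste0("elements_", cond, ".tsv")),
      paste0("regulatory elements, condition=", cond,
             "; DRE: H3K4me1 summit >", cfg$promoter_max_distance,
             " bp from every TSS; active: >=1 bp overlap with H3K27ac"))
    el <- elements[[cond]]
    note(paste0("n_promoters_", cond), sum(el$kind == "promoter"))
    note(paste0("n_dres_", cond), sum(el$kind == "DRE"))
    note(paste0("n_active_dres_", cond), sum(el$kind == "DRE" & el$active))
    note(paste0("pct_active_dres_", cond),
         proportion_report(sum(el$kind == "DRE" & el$active),
                           sum(el$kind == "DRE")))
  }

  ## ---- co-occurrence + distance histogram (treated) ----------------------
  cooc <- rbind(
    cooccurrence_at_tss(pk$h3k4me1$treated, pk$h3k4me3$treated,
                        pk$h3k27ac$treated, genes,
                        window = cfg$cooccurrence_window),
    cooccurrence_intergenic(pk$h3k4me1$treated, pk$h3k4me3$treated,
                            pk$h3k27ac$treated, partition)
  )
  write_tsv_commented(
    cooc, file.path(out_dir, "cooccurrence.tsv"),
    c("mark co-occurrence, treated condition",
      "fraction = count / denominator; denominators are per context/mark"))
  hist <- tss_distance_histogram(elements$treated)
  write_tsv_commented(hist, file.path(out_dir, "dre_tss_distance.tsv"),
                      "absolute DRE summit-to-nearest-TSS distance histogram")

  ## ---- dynamics (needs H3K27ac coverage) ----------------------------------
  dyn <- NULL
  if (!is.null(cfg$coverage_h3k27ac_control) &&
      !is.null(cfg$coverage_h3k27ac_treated)) {
    trk_c <- read_coverage(cfg$coverage_h3k27ac_control, lens)
    trk_t <- read_coverage(cfg$coverage_h3k27ac_treated, lens)
    regions <- union_regions(pk$h3k27ac$control, pk$h3k27ac$treated)
    dyn <- classify_dynamics(regions, trk_c, trk_t,
                             pseudocount = cfg$pseudocount,
                             boundary = "exclusive")
    write_tsv_commented(
      dyn, file.path(out_dir, "h3k27ac_region_dynamics.tsv"),
      c("H3K27ac union-region dynamics (fold-class, no p-value)",
        "increased: fold > 2; decreased: fold < 0.5",
        paste0("pseudocount = ", cfg$pseudocount, " density units")))
    dre_dyn <- dre_h3k27ac_dynamics(elements$treated, trk_c, trk_t,
                                    pseudocount = cfg$pseudocount)
    write_tsv_commented(
      dre_dyn, file.path(out_dir, "dre_h3k27ac_dynamics.tsv"),
      c("per-DRE H3K27ac dynamics (at-least-twofold boundary)",
        "increased: fold >= 2; decreased: fold <= 0.5"))
    note("n_dre_ac_increased", sum(dre_dyn$klass == "increased"))
    note("n_dre_ac_decreased", sum(dre_dyn$klass == "decreased"))
    note("n_dre_ac_stable", sum(dre_dyn$klass == "stable"))
    ## distal H3K27ac presence (promoter-zone peaks filtered out)
    distal_ac <- function(cond) {
      p <- pk$h3k27ac[[cond]]
      nt <- distance_to_nearest_tss(p, genes)
      p[is.na(nt$distance) |
          abs(nt$distance) > cfg$promoter_max_distance, , drop = FALSE]
    }
    pres <- presence_calls(distal_ac("control"), distal_ac("treated"))
    note("n_distal_ac_treated_only",
         sum(pres$condition == "treated" & pres$presence == "treated_only"))
    note("n_distal_ac_control_only",
         sum(pres$condition == "control" & pres$presence == "control_only"))
  }

  ## ---- expression linkage -------------------------------------------------
  categories <- categorize_expression(expr, "treated",
                                      none_threshold = cfg$none_threshold)
  profiles <- list()
  for (mark in c("h3k4me1", "h3k4me3", "h3k27ac")) {
    ck <- paste0("coverage_", mark, "_treated")
    if (is.null(cfg[[ck]])) next
    trk <- read_coverage(cfg[[ck]], lens)
    mp <- tss_metaprofile(trk, genes, categories,
                          flank = cfg$flank, bin = cfg$bin)
    profiles[[mark]] <- mp
    out <- data.frame(center = mp$centers, t(mp$profile))
    write_tsv_commented(
      out, file.path(out_dir, paste0("metaprofile_", mark, ".tsv")),
      c(paste0("TSS metaprofile, ", mark, ", treated condition"),
        paste0("flank=", cfg$flank, " bin=", cfg$bin),
        paste0("genes per category: ",
               paste(names(mp$n_genes), mp$n_genes, sep = "=",
                     collapse = " "))))
  }
  classes <- element_target_classes(elements$treated, expr)
  expr_by_class <- expression_by_element_class(classes, expr, "treated")
  write_tsv_commented(
    expr_by_class, file.path(out_dir, "expression_by_class.tsv"),
    c("mean log2(RPKM+1) of nearest genes per element class, treated",
      "genes deduplicated within class"))
  for (i in seq_len(nrow(expr_by_class)))
    note(paste0("mean_log2_expr_", expr_by_class$class[i]),
         signif(expr_by_class$mean_log2_expr[i], 6))

  ## ---- motif scan ---------------------------------------------------------
  motif <- NULL
  if (!is.null(cfg$peaks_ecr_treated) && !is.null(cfg$genome_fasta) &&
      !is.null(cfg$pwm)) {
    ecr <- read_peaks(cfg$peaks_ecr_treated)
    pwm <- read_pwm(cfg$pwm)[[1]]
    motif <- peaks_with_motif(ecr, cfg$genome_fasta, pwm,
                              threshold_fraction = cfg$motif_threshold)
    write_tsv_commented(
      motif$table, file.path(out_dir, "ecr_motif_hits.tsv"),
      c(paste0("per-peak best motif hit, matrix=", pwm$motif_id),
        paste0("threshold_fraction=", cfg$motif_threshold,
               " of min-max log-odds range")))
    note("n_ecr_peaks", nrow(ecr))
    note("n_ecr_peaks_with_motif", motif$count)
    note("pct_ecr_peaks_with_motif",
         proportion_report(motif$count, nrow(ecr)))
    ## overlap of receptor peaks with called elements
    el <- elements$treated
    note("n_ecr_overlap_dre",
         overlap_fraction(ecr, el[el$kind == "DRE", ])$count)
    note("n_ecr_overlap_promoter",
         overlap_fraction(ecr, el[el$kind == "promoter", ])$count)
  }

  ## ---- summary + log ------------------------------------------------------
  summary_df <- do.call(rbind, summary_rows)
  write_tsv_commented(summary_df, file.path(out_dir, "summary.tsv"),
                      "pipeline summary: counts and half-up percentages")
  files <- unlist(cfg[input_keys])
  log_lines <- c(
    paste0("ecdreg version: ",
           as.character(utils::packageVersion("ecdreg"))),
    "parameters:",
    paste0("  ", names(defaults), " = ",
           vapply(cfg[names(defaults)], as.character, character(1))),
    "input checksums (md5):",
    paste0("  ", names(files), " = ", unname(tools::md5sum(files)))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(partition = partition, peak_location = peak_location,
                 elements = elements, cooccurrence = cooc,
                 distance_histogram = hist, dynamics = dyn,
                 profiles = profiles, expression_by_class = expr_by_class,
                 motif = motif, summary = summary_df))
}
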