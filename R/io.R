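# Readers and writers for the external formats the pipeline touches.
# All in-memory coordinates are 0-based half-open; conversions from 1-based
# dialects (GFF3, WIG) happen here and only here.

split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

num_or_stop <- function(x, line_no, what, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop_("malformed line ", line_no[bad[1]], " in ", path,
          ": non-numeric ", what, " '", x[bad[1]], "'")
  v
}

#' Read called ChIP-seq peaks
#'
#' Reads an ENCODE narrowPeak (10-column) or BED6 file into the canonical peak
#' table. Coordinates are kept 0-based half-open. For narrowPeak, column 10 is
#' the summit offset from the interval start; `-1` means "not reported" and is
#' stored as `NA`. For BED6 the score column is used as the signal and no
#' summit is recorded.
#'
#' @param path path to the peak file.
#' @param dialect `"narrowPeak"` or `"bed6"`; must match the column count.
#' @return a data.frame with columns `scaffold`, `start`, `end`, `name`,
#'   `signal`, `summit_offset` (`NA` when absent) and `strand`.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed6")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("peak file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") & !startsWith(lines, "track")
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(peak_frame())
  fields <- split_fields(lines)
  need <- if (dialect == "narrowPeak") 10L else 6L
  nf <- lengths(fields)
  bad <- which(nf != need)
  if (length(bad))
    stop_("malformed ", dialect, " line ", line_no[bad[1]], " in ", path,
          ": expected ", need, " fields, got ", nf[bad[1]])
  m <- matrix(unlist(fields), ncol = need, byrow = TRUE)
  start <- num_or_stop(m[, 2], line_no, "start", path)
  end <- num_or_stop(m[, 3], line_no, "end", path)
  bad <- which(!(start < end) | start < 0)
  if (length(bad))
    stop_("malformed ", dialect, " line ", line_no[bad[1]], " in ", path,
          ": need 0 <= start < end, got [", start[bad[1]], ", ", end[bad[1]], ")")
  if (dialect == "narrowPeak") {
    signal <- num_or_stop(m[, 7], line_no, "signalValue", path)
    summit <- as.integer(num_or_stop(m[, 10], line_no, "summit", path))
    summit[summit < 0L] <- NA_integer_
    bad <- which(!is.na(summit) & summit >= (end - start))
    if (length(bad))
      stop_("malformed narrowPeak line ", line_no[bad[1]], " in ", path,
            ": summit offset ", summit[bad[1]], " outside peak of width ",
            end[bad[1]] - start[bad[1]])
  } else {
    signal <- num_or_stop(m[, 5], line_no, "score", path)
    summit <- rep(NA_integer_, nrow(m))
  }
  if (any(signal < 0))
    stop_("negative signal in ", path)
  peak_frame(m[, 1], start, end, m[, 4], signal, summit, m[, 6])
}

#' Write peaks
#'
#' Inverse of [read_peaks()]; round-trips losslessly.
#'
#' @param peaks peak data.frame.
#' @param path output path.
#' @param dialect `"narrowPeak"` or `"bed6"`.
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowPeak", "bed6")) {
  dialect <- match.arg(dialect)
  check_peaks(peaks)
  if (dialect == "narrowPeak") {
    out <- data.frame(
      peaks$scaffold, peaks$start, peaks$end, peaks$name, 0L,
      peaks$strand, peaks$signal, -1, -1,
      ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset)
    )
  } else {
    out <- data.frame(
      peaks$scaffold, peaks$start, peaks$end, peaks$name, peaks$signal,
      peaks$strand
    )
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features (via \pkg{rtracklayer}) into stranded gene
#' models. GFF3's 1-based inclusive coordinates are converted to 0-based
#' half-open. Exons are grouped under their parent gene and must be sorted,
#' non-overlapping and contained in the gene; a gene with no exon features is
#' treated as a single-exon gene spanning its whole body.
#'
#' @param path path to a GFF3 file.
#' @return an object of class `gene_models`: a list with data.frames `genes`
#'   (`gene_id`, `scaffold`, `start`, `end`, `strand`) and `exons`
#'   (`gene_id`, `scaffold`, `start`, `end`).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop_("GFF3 file not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- tolower(as.character(gff$type))
  gg <- gff[type == "gene"]
  if (!length(gg)) stop_("no gene features in ", path)
  strand <- as.character(BiocGenerics::strand(gg))
  if (any(strand %in% c(".", "*")))
    stop_("gene without strand in ", path,
          " (gene models must be '+' or '-'): ",
          paste(utils::head(gg$ID[strand %in% c(".", "*")], 3), collapse = ", "))
  ids <- as.character(gg$ID)
  if (anyNA(ids) || any(!nzchar(ids))) stop_("gene feature without ID in ", path)
  if (anyDuplicated(ids)) stop_("duplicated gene ID in ", path)
  genes <- data.frame(
    gene_id = ids,
    scaffold = as.character(GenomicRanges::seqnames(gg)),
    start = BiocGenerics::start(gg) - 1L,
    end = BiocGenerics::end(gg),
    strand = strand,
    stringsAsFactors = FALSE
  )
  ee <- gff[type == "exon"]
  if (length(ee)) {
    parents <- gff$Parent[type == "exon"]
    np <- lengths(parents)
    if (any(np == 0L)) stop_("exon without parent gene in ", path)
    parent <- vapply(parents, `[[`, character(1), 1L)
    parent <- sub("^gene:", "", parent)
    unknown <- setdiff(unique(parent), ids)
    if (length(unknown))
      stop_("exon parented to unknown gene in ", path, ": ",
            paste(utils::head(unknown, 3), collapse = ", "))
    exons <- data.frame(
      gene_id = parent,
      scaffold = as.character(GenomicRanges::seqnames(ee)),
      start = BiocGenerics::start(ee) - 1L,
      end = BiocGenerics::end(ee),
      stringsAsFactors = FALSE
    )
  } else {
    exons <- genes[0, c("gene_id", "scaffold", "start", "end")]
  }
  ## genes lacking exon records become single-exon genes
  noex <- setdiff(ids, unique(exons$gene_id))
  if (length(noex)) {
    gsub <- genes[match(noex, genes$gene_id), ]
    exons <- rbind(exons, data.frame(
      gene_id = gsub$gene_id, scaffold = gsub$scaffold,
      start = gsub$start, end = gsub$end, stringsAsFactors = FALSE
    ))
  }
  exons <- exons[order(exons$gene_id, exons$start, method = "radix"), ]
  rownames(exons) <- NULL
  ## validate structure
  g <- genes[match(exons$gene_id, genes$gene_id), ]
  if (any(exons$start < g$start | exons$end > g$end))
    stop_("exon outside its gene body in ", path)
  by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
  for (idx in by_gene) {
    if (length(idx) > 1L && any(exons$start[idx][-1] < exons$end[idx][-length(idx)]))
      stop_("overlapping exons within gene ", exons$gene_id[idx[1]], " in ", path)
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write gene models as GFF3
#'
#' @param genes a `gene_models` object.
#' @param path output path.
#' @param source source column value.
#' @export
write_gene_models <- function(genes, path, source = "ecdreg") {
  g <- genes$genes
  e <- genes$exons
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- g[order(g$scaffold, g$start, method = "radix"), ]
  for (i in seq_len(nrow(g))) {
    writeLines(paste(g$scaffold[i], source, "gene", g$start[i] + 1L, g$end[i],
                     ".", g$strand[i], ".", paste0("ID=", g$gene_id[i]),
                     sep = "\t"), con)
    ei <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
    ei <- ei[order(ei$start), , drop = FALSE]
    for (j in seq_len(nrow(ei))) {
      writeLines(paste(ei$scaffold[j], source, "exon", ei$start[j] + 1L,
                       ei$end[j], ".", g$strand[i], ".",
                       paste0("ID=", g$gene_id[i], ".e", j,
                              ";Parent=", g$gene_id[i]),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a two-column scaffold-length table
#'
#' @param path TSV with columns scaffold, length (no header).
#' @return named integer vector of scaffold lengths.
#' @export
read_scaffold_lengths <- function(path) {
  if (!file.exists(path)) stop_("scaffold length file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("scaffold", "length"),
                           colClasses = c("character", "numeric"))
  if (any(tab$length <= 0)) stop_("non-positive scaffold length in ", path)
  if (anyDuplicated(tab$scaffold)) stop_("duplicated scaffold in ", path)
  stats::setNames(as.integer(tab$length), tab$scaffold)
}

#' @rdname read_scaffold_lengths
#' @param lengths named vector of scaffold lengths.
#' @export
write_scaffold_lengths <- function(lengths, path) {
  data.table::fwrite(data.frame(names(lengths), as.integer(lengths)),
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

new_coverage_track <- function(cov, library_size = 1e6) {
  if (library_size <= 0) stop_("library_size must be positive")
  structure(list(cov = cov, library_size = library_size),
            class = "coverage_track")
}

#' Read a coverage track
#'
#' Reads a bedGraph (0-based half-open) or WIG (1-based; fixedStep or
#' variableStep, parsed by \pkg{rtracklayer}) file into a dense per-scaffold
#' run-length vector at 1-bp resolution; uncovered bases are 0.
#'
#' @param path track file.
#' @param scaffold_lengths named vector of scaffold lengths; every covered
#'   interval must fit inside its scaffold.
#' @param dialect `"bedGraph"` or `"wig"`.
#' @param library_size positive real used by [region_signal()] to scale
#'   densities (`signal = mean coverage * 1e6 / library_size`). The default
#'   `1e6` makes the scaling the identity, i.e. values are taken to be already
#'   depth-normalized.
#' @return a `coverage_track`: list with `cov` (named list of
#'   [S4Vectors::Rle] vectors) and `library_size`.
#' @export
read_coverage <- function(path, scaffold_lengths,
                          dialect = c("bedGraph", "wig"),
                          library_size = 1e6) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("coverage file not found: ", path)
  if (dialect == "bedGraph") {
    tab <- data.table::fread(path, header = FALSE, sep = "\t",
                             col.names = c("scaffold", "start", "end", "value"),
                             colClasses = list(character = 1))
    tab <- as.data.frame(tab)
    if (nrow(tab) && any(tab$value < 0)) stop_("negative coverage value in ", path)
    if (nrow(tab) && any(tab$start < 0 | tab$start >= tab$end))
      stop_("invalid bedGraph interval in ", path)
  } else {
    gr <- rtracklayer::import(path, format = "wig")
    if (any(gr$score < 0)) stop_("negative coverage value in ", path)
    tab <- data.frame(
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      value = gr$score, stringsAsFactors = FALSE
    )
  }
  unknown <- setdiff(unique(tab$scaffold), names(scaffold_lengths))
  if (length(unknown))
    stop_("coverage on unknown scaffold in ", path, ": ", unknown[1])
  if (nrow(tab) && any(tab$end > scaffold_lengths[tab$scaffold]))
    stop_("coverage interval beyond scaffold end in ", path)
  cov <- vector("list", length(scaffold_lengths))
  names(cov) <- names(scaffold_lengths)
  for (sc in names(scaffold_lengths)) {
    sub <- tab[tab$scaffold == sc, , drop = FALSE]
    L <- scaffold_lengths[[sc]]
    if (!nrow(sub)) {
      cov[[sc]] <- S4Vectors::Rle(0, L)
      next
    }
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop_("overlapping coverage intervals on ", sc, " in ", path)
    ir <- IRanges::IRanges(sub$start + 1L, sub$end)
    cov[[sc]] <- IRanges::coverage(ir, weight = sub$value, width = L)
  }
  new_coverage_track(cov, library_size)
}

#' Write a coverage track as bedGraph
#'
#' Zero runs are omitted; [read_coverage()] restores them, so the pair
#' round-trips losslessly.
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @export
write_coverage <- function(track, path) {
  parts <- lapply(names(track$cov), function(sc) {
    r <- track$cov[[sc]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (!any(keep)) return(NULL)
    data.frame(scaffold = sc, start = starts[keep], end = ends[keep],
               value = vals[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- data.frame(scaffold = character(), start = integer(),
                                      end = integer(), value = numeric())
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' TSV with header `gene_id<TAB><condition>...`; RPKM values must be
#' non-negative and gene ids unique.
#'
#' @param path TSV path.
#' @return data.frame with `gene_id` plus one numeric column per condition.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(tab)) stop_("empty expression table: ", path)
  if (names(tab)[1] != "gene_id")
    stop_("expression table must start with a 'gene_id' column: ", path)
  if (anyDuplicated(tab$gene_id)) stop_("duplicated gene_id in ", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0))
    stop_("RPKM values must be non-negative numbers: ", path)
  tab
}

#' @rdname read_expression
#' @param expr expression data.frame.
#' @export
write_expression <- function(expr, path) {
  data.table::fwrite(expr, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read position weight matrices (JASPAR text)
#'
#' Parses JASPAR-style PFM text (`>ID name` header, four base rows, with or
#' without `A [ ... ]` brackets/base labels). Counts are normalized to column
#' probabilities after adding a per-cell pseudocount.
#'
#' @param path PFM file.
#' @param pseudocount per-cell pseudocount added before normalization.
#' @param background background base probabilities (A, C, G, T).
#' @return list of `pwm` objects, each with `motif_id`, `name`, `counts`
#'   (4 x W), `prob` (4 x W column-stochastic), `background`, `pseudocount`.
#' @export
read_pwm <- function(path, pseudocount = 0.01,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!file.exists(path)) stop_("PWM file not found: ", path)
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-6)
    stop_("background must be positive probabilities summing to 1")
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop_("no '>' header in PWM file ", path)
  bounds <- c(heads, length(lines) + 1L)
  pwms <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(block) != 4L)
      stop_("PWM block ", k, " in ", path, " must have 4 base rows, got ",
            length(block))
    header <- sub("^>\\s*", "", lines[heads[k]])
    toks <- strsplit(header, "[ \t]+")[[1]]
    motif_id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else motif_id
    rows <- lapply(block, function(ln) {
      ln <- gsub("[][]", " ", ln)
      tk <- strsplit(trimws(ln), "[ \t]+")[[1]]
      base <- NA_character_
      if (toupper(tk[1]) %in% c("A", "C", "G", "T")) {
        base <- toupper(tk[1]); tk <- tk[-1]
      }
      v <- suppressWarnings(as.numeric(tk))
      if (anyNA(v)) stop_("non-numeric PWM row in ", path, ": '", ln, "'")
      list(base = base, v = v)
    })
    widths <- lengths(lapply(rows, `[[`, "v"))
    if (length(unique(widths)) != 1L)
      stop_("PWM rows of unequal width for motif ", motif_id, " in ", path)
    counts <- do.call(rbind, lapply(rows, `[[`, "v"))
    labels <- vapply(rows, `[[`, character(1), "base")
    rownames(counts) <- if (all(!is.na(labels))) labels else c("A", "C", "G", "T")
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    if (any(counts < 0)) stop_("negative PWM count for motif ", motif_id)
    prob <- sweep(counts + pseudocount, 2,
                  colSums(counts) + 4 * pseudocount, "/")
    pwms[[k]] <- structure(
      list(motif_id = motif_id, name = name, counts = counts, prob = prob,
           background = background, pseudocount = pseudocount),
      class = "pwm"
    )
  }
  pwms
}

#' Write position weight matrices (JASPAR text)
#'
#' Writes the raw count matrices; a round trip through [read_pwm()] restores
#' them exactly.
#'
#' @param pwms list of `pwm` objects (or a single one).
#' @param path output path.
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$motif_id, " ", p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, "  [ ", paste(format(p$counts[b, ], trim = TRUE),
                                         collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return a [Biostrings::DNAStringSet] named by the first word of each header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_("FASTA file not found: ", path)
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  dna
}

#' @rdname read_genome
#' @param genome a [Biostrings::DNAStringSet].
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}
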