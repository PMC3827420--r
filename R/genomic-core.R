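# Domain types and I/O for intervals, genes, sequences and expression tables.
#
# Coordinates are 0-based half-open throughout, matching BED. Peaks are plain
# data.frames (chrom, start, end, name, score, and optionally sample); gene
# models are data.frames (gene_id, symbol, chrom, strand, tss, tes). GRanges
# is used internally as the overlap engine.

#' Read a BED file of peaks
#'
#' Accepts BED3/BED4/BED5. Columns 4 and 5, when present, map to `name` and
#' `score`. Records are validated (integer coordinates, end > start) and
#' returned sorted by (chrom, start).
#'
#' @param path Path to a tab-separated BED file.
#' @return A data.frame with columns chrom, start, end, name, score.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("BED file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                 which(nf < 3L)[1L]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: coordinates do not parse as integers", bad[1L]),
         call. = FALSE)
  }
  bad <- which(end <= start | start < 0L)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: end <= start (or negative start)", bad[1L]),
         call. = FALSE)
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, ""),
                 NA_character_)
  name[is.na(name)] <- paste0("peak_", which(is.na(name)))
  score <- rep(NA_real_, length(lines))
  has5 <- nf >= 5L
  if (any(has5)) {
    score[has5] <- suppressWarnings(as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  }
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    score = score, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write peaks to a BED file
#'
#' Writes BED5 when any score is present, BED4 otherwise; `read_bed()` on the
#' result round-trips canonical records.
#'
#' @param peaks Peak data.frame (chrom, start, end, optional name/score).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  check_peaks(peaks)
  name <- peaks$name %||% paste0("peak_", seq_len(nrow(peaks)))
  if (!is.null(peaks$score) && any(!is.na(peaks$score))) {
    score <- ifelse(is.na(peaks$score), 0, peaks$score)
    lines <- sprintf("%s\t%d\t%d\t%s\t%s", peaks$chrom, peaks$start, peaks$end,
                     name, format(score, trim = TRUE, scientific = FALSE))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s", peaks$chrom, peaks$start, peaks$end, name)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with a header; required columns are gene_id, symbol, chrom,
#' strand, tss, tes. Duplicate gene ids are rejected.
#'
#' @param path Path to the TSV.
#' @return A data.frame of gene models.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("gene table not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "symbol", "chrom", "strand", "tss", "tes")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("gene table is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup)) {
    stop(sprintf("duplicate gene_id(s) in annotation: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  if (!all(tab$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'", call. = FALSE)
  if (any(tab$tss == tab$tes)) stop("gene with tss == tes in annotation", call. = FALSE)
  tab[need]
}

#' Write a gene annotation table
#'
#' @param genes Gene model data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse duplicate gene symbols, keeping the longest gene
#'
#' Gene-level overlap analyses need unique identifiers; when an annotation
#' carries several models per symbol the longest span wins.
#'
#' @param genes Gene model data.frame.
#' @return The de-duplicated data.frame.
#' @export
collapse_symbols <- function(genes) {
  if (!nrow(genes)) return(genes)
  len <- abs(genes$tes - genes$tss)
  ord <- order(genes$symbol, -len, method = "radix")
  g <- genes[ord, , drop = FALSE]
  g <- g[!duplicated(g$symbol), , drop = FALSE]
  g <- g[order(match(g$gene_id, genes$gene_id)), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Overlap in base pairs between two genomic intervals
#'
#' Half-open convention: adjacent intervals share 0 bp. Vectorised with
#' recycling over rows.
#'
#' @param a,b Data.frames (or one-row records) with chrom, start, end.
#' @return Integer vector of shared base pairs (0 on different chromosomes).
#' @export
interval_overlap_bp <- function(a, b) {
  ov <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  ov[as.character(a$chrom) != as.character(b$chrom)] <- 0L
  as.integer(ov)
}

#' All pairs of overlapping peaks between two sorted sets
#'
#' Reports every (i, j) index pair with at least 1 bp of shared sequence,
#' each exactly once. Inputs must be sorted by (chrom, start).
#'
#' @param a,b Sorted peak data.frames.
#' @return Data.frame with columns `i` (row in `a`) and `j` (row in `b`).
#' @export
intersect_sets <- function(a, b) {
  check_peaks(a, "a"); check_peaks(b, "b")
  if (!is_sorted_peaks(a) || !is_sorted_peaks(b)) {
    stop("peak sets must be sorted by (chrom, start); sort before calling intersect_sets()",
         call. = FALSE)
  }
  if (!nrow(a) || !nrow(b)) return(data.frame(i = integer(), j = integer()))
  hits <- GenomicRanges::findOverlaps(peaks_gr(a), peaks_gr(b))
  out <- data.frame(i = S4Vectors::queryHits(hits), j = S4Vectors::subjectHits(hits))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Read a genome FASTA into a named character vector
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path, width = 70L)
  invisible(path)
}

#' Read an expression matrix with its sample sheet
#'
#' The matrix TSV has gene ids in the first column and one column per array;
#' the sample sheet TSV maps each sample to a group (WT/KO) plus free
#' metadata (cell type, state).
#'
#' @param path Expression TSV path.
#' @param sample_sheet Sample-sheet TSV path (columns sample, group, ...).
#' @return List with `values` (numeric matrix, rownames = gene ids) and
#'   `samples` (data.frame).
#' @export
read_expression_matrix <- function(path, sample_sheet) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("expression matrix needs a gene column plus samples", call. = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab[[1L]]
  if (anyNA(values)) stop("expression matrix contains missing values", call. = FALSE)
  sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  need <- c("sample", "group")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop(sprintf("sample sheet missing column(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  if (!setequal(sheet$sample, colnames(values))) {
    stop("sample sheet and matrix columns disagree", call. = FALSE)
  }
  sheet <- sheet[match(colnames(values), sheet$sample), , drop = FALSE]
  if (!all(sheet$group %in% c("WT", "KO"))) stop("group must be WT or KO", call. = FALSE)
  list(values = values, samples = sheet)
}

#' Write an expression matrix and its sample sheet
#'
#' @param values Numeric matrix (rownames = gene ids).
#' @param samples Sample-sheet data.frame (columns sample, group, ...).
#' @param path Expression TSV path.
#' @param sample_sheet Sample-sheet TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(values, samples, path, sample_sheet) {
  tab <- data.frame(gene_id = rownames(values), values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(samples, sample_sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
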