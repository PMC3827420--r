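# IUPAC consensus scanning, Z-score enrichment against sampled genomic
# background, and two-motif module detection.
#
# The scanner compiles a consensus to a regex of character classes and uses a
# zero-width lookahead so overlapping occurrences are all reported. An N in
# the scanned sequence matches only the N code, never a concrete base class.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Define an IUPAC consensus motif
#'
#' @param name Motif name.
#' @param iupac Consensus string over the 15 IUPAC nucleotide codes.
#' @return A list of class `motif_consensus`.
#' @export
motif_consensus <- function(name, iupac) {
  iupac <- toupper(iupac)
  if (!nzchar(iupac)) stop("empty motif consensus", call. = FALSE)
  letters_ <- strsplit(iupac, "")[[1]]
  bad <- setdiff(letters_, names(IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC letter(s) in motif '%s': %s", name,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  structure(list(name = name, iupac = iupac, length = nchar(iupac)),
            class = "motif_consensus")
}

#' Canonical RUNX consensus and its concrete variants
#'
#' The canonical RUNX recognition sequence TGt/cGGt/c, i.e. consensus TGYGGY
#' expanding to the four variants TGTGGT, TGTGGC, TGCGGT and TGCGGC.
#'
#' @return `runx_motif()`: a `motif_consensus`; `runx_variants()`: character
#'   vector of the four variants.
#' @export
runx_motif <- function() motif_consensus("RUNX", "TGYGGY")

#' @rdname runx_motif
#' @export
runx_variants <- function() c("TGTGGT", "TGTGGC", "TGCGGT", "TGCGGC")

#' Default motif set for module analysis
#'
#' RUNX = TGYGGY, ETS core = MGGAA, AP-1 = TGASTCA. All are ordinary
#' `motif_consensus` objects and can be replaced freely.
#'
#' @return Named list of `motif_consensus` objects.
#' @export
default_motifs <- function() {
  list(RUNX = runx_motif(),
       ETS = motif_consensus("ETS", "MGGAA"),
       AP1 = motif_consensus("AP1", "TGASTCA"))
}

iupac_regex <- function(iupac) {
  letters_ <- strsplit(toupper(iupac), "")[[1]]
  classes <- vapply(letters_, function(l) {
    set <- IUPAC_SETS[[l]]
    if (l == "N") set <- c(set, "N")  # N alone may match an N in the subject
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, "")
  paste0(classes, collapse = "")
}

revcomp_iupac <- function(s) {
  letters_ <- rev(strsplit(toupper(s), "")[[1]])
  paste0(IUPAC_COMPLEMENT[letters_], collapse = "")
}

scan_strand <- function(seq, pattern_regex, width) {
  m <- gregexpr(paste0("(?=", pattern_regex, ")"), seq, perl = TRUE)[[1]]
  starts <- as.integer(m)
  if (length(starts) == 1L && starts[1L] == -1L) return(integer())
  starts - 1L  # 0-based offsets
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Reports every start offset (0-based) on the forward strand and, when
#' `both_strands`, on the reverse strand (as forward-strand offsets of the
#' reverse-complement match). Overlapping occurrences are all reported; the
#' matched variant is given in motif-strand orientation.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param motif A [motif_consensus()] (or IUPAC string).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @return Data.frame: offset, strand, match.
#' @export
scan_motif <- function(seq, motif, both_strands = TRUE) {
  if (is.character(motif)) motif <- motif_consensus(motif, motif)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over A/C/G/T/N", call. = FALSE)
  w <- motif$length
  substr_many <- function(off) {
    if (!length(off)) character() else substring(seq, off + 1L, off + w)
  }
  fwd <- scan_strand(seq, iupac_regex(motif$iupac), w)
  res <- list(data.frame(offset = fwd, strand = rep("+", length(fwd)),
                         match = substr_many(fwd)))
  if (both_strands) {
    rev_off <- scan_strand(seq, iupac_regex(revcomp_iupac(motif$iupac)), w)
    res[[2]] <- data.frame(offset = rev_off, strand = rep("-", length(rev_off)),
                           match = vapply(substr_many(rev_off), revcomp_iupac, "",
                                          USE.NAMES = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Extract peak sequences from a genome, with bounds checking.
peak_sequences <- function(peaks, genome) {
  check_peaks(peaks)
  pname <- peaks$name %||% paste0("peak_", seq_len(nrow(peaks)))
  chr <- as.character(peaks$chrom)
  miss <- setdiff(unique(chr), names(genome))
  if (length(miss)) stop(sprintf("chromosome(s) absent from genome: %s", paste(miss, collapse = ", ")), call. = FALSE)
  len <- nchar(genome)[chr]
  bad <- which(peaks$end > len)
  if (length(bad)) {
    stop(sprintf("peak '%s' extends beyond the end of %s", pname[bad[1L]], chr[bad[1L]]),
         call. = FALSE)
  }
  stats::setNames(substring(genome[chr], peaks$start + 1L, peaks$end), pname)
}

#' Per-region motif occurrence summary
#'
#' Counts occurrences of each motif (both strands) in every peak region and
#' reports the fraction of regions carrying at least one hit of any motif.
#'
#' @param peaks Peak data.frame.
#' @param genome Named character vector of chromosome sequences.
#' @param motifs A `motif_consensus`, IUPAC string, or list of these.
#' @param both_strands Scan both strands (default TRUE).
#' @return List: `counts` (region x motif matrix), `hits` (data.frame of all
#'   occurrences), `fraction_with_hit`.
#' @export
region_motif_summary <- function(peaks, genome, motifs = runx_variants(),
                                 both_strands = TRUE) {
  if (inherits(motifs, "motif_consensus")) motifs <- list(motifs)
  if (is.character(motifs)) motifs <- as.list(motifs)
  motifs <- lapply(motifs, function(m) {
    if (is.character(m)) motif_consensus(m, m) else m
  })
  mnames <- vapply(motifs, `[[`, "", "name")
  seqs <- peak_sequences(peaks, genome)
  counts <- matrix(0L, nrow = length(seqs), ncol = length(motifs),
                   dimnames = list(names(seqs), mnames))
  hit_rows <- list()
  for (j in seq_along(motifs)) {
    for (i in seq_along(seqs)) {
      h <- scan_motif(seqs[[i]], motifs[[j]], both_strands)
      counts[i, j] <- nrow(h)
      if (nrow(h)) {
        h$region <- names(seqs)[i]; h$motif <- mnames[j]
        hit_rows[[length(hit_rows) + 1L]] <- h
      }
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(offset = integer(), strand = character(), match = character(),
               region = character(), motif = character())
  list(counts = counts, hits = hits,
       fraction_with_hit = if (length(seqs)) mean(rowSums(counts) > 0) else NA_real_)
}

#' Sample background regions matched for length
#'
#' Places `n_regions` intervals uniformly on the genome with lengths
#' resampled from `length_source`, rejecting overlap with `exclusion`.
#' Deterministic per seed.
#'
#' @param genome Named character vector of chromosome sequences (or named
#'   numeric vector of lengths).
#' @param n_regions Number of regions to draw.
#' @param length_source Vector of lengths to resample (e.g. observed peak
#'   widths), or a single length.
#' @param seed Integer seed.
#' @param exclusion Optional peak data.frame to avoid.
#' @param max_tries Placement attempts per region before giving up.
#' @return Peak data.frame of sampled regions.
#' @export
sample_background <- function(genome, n_regions, length_source, seed,
                              exclusion = NULL, max_tries = 200L) {
  sizes <- if (is.numeric(genome)) genome else nchar(genome)
  if (max(length_source) > max(sizes)) stop("genome shorter than the longest region", call. = FALSE)
  excl_gr <- if (!is.null(exclusion) && nrow(exclusion)) peaks_gr(exclusion)
  with_seed(seed, {
    lens <- sample(rep(length_source, length.out = max(n_regions, length(length_source))),
                   n_regions, replace = TRUE)
    chrom <- rep(NA_character_, n_regions)
    start <- rep(NA_integer_, n_regions)
    todo <- seq_len(n_regions)
    for (round_ in seq_len(max_tries)) {
      if (!length(todo)) break
      ch <- sample(names(sizes), length(todo), replace = TRUE,
                   prob = sizes / sum(sizes))
      room <- unname(sizes[ch]) - lens[todo]
      s <- ifelse(room > 0, floor(stats::runif(length(todo)) * room), NA_real_)
      ok <- !is.na(s)
      if (!is.null(excl_gr) && any(ok)) {
        cand <- GenomicRanges::GRanges(
          ch[ok], IRanges::IRanges(s[ok] + 1L, s[ok] + lens[todo][ok]))
        clash <- GenomicRanges::countOverlaps(cand, excl_gr) > 0L
        ok[ok] <- !clash
      }
      chrom[todo[ok]] <- ch[ok]
      start[todo[ok]] <- as.integer(s[ok])
      todo <- todo[!ok]
    }
    if (length(todo)) {
      stop("could not place background region outside the exclusion set", call. = FALSE)
    }
    data.frame(chrom = chrom, start = start, end = start + lens,
               name = paste0("bg_", seq_len(n_regions)),
               stringsAsFactors = FALSE)
  })
}

#' Motif enrichment Z-score against sampled background
#'
#' Total motif occurrences in the observed regions are compared with the
#' distribution of totals over B independently sampled, length-matched
#' background region sets: z = (observed - mean) / sd.
#'
#' @param peaks Observed peak data.frame.
#' @param genome Named character vector of chromosome sequences.
#' @param motif A [motif_consensus()] or IUPAC string.
#' @param n_background Number of background sets B (>= 30).
#' @param seed Integer seed (mandatory).
#' @param exclusion Regions to exclude from background placement (defaults
#'   to the observed peaks).
#' @param both_strands Scan both strands (default TRUE).
#' @return List of class `enrichment_z`: observed, background_mean,
#'   background_sd, z (NA when sd is 0), n_background_samples, seed.
#' @export
motif_zscore <- function(peaks, genome, motif, n_background = 100L, seed,
                         exclusion = peaks, both_strands = TRUE) {
  motif_zscore_table(peaks, genome, list(motif), n_background, seed,
                     exclusion, both_strands)[[1L]]
}

#' @rdname motif_zscore
#' @param motifs List of motifs; the background region sets are sampled once
#'   and shared across them.
#' @export
motif_zscore_table <- function(peaks, genome, motifs, n_background = 100L,
                               seed, exclusion = peaks, both_strands = TRUE) {
  if (n_background < 30L) stop("need at least 30 background samples", call. = FALSE)
  if (missing(seed)) stop("a seed is required for background sampling", call. = FALSE)
  if (inherits(motifs, "motif_consensus") || is.character(motifs)) motifs <- as.list(motifs)
  obs <- colSums(region_motif_summary(peaks, genome, motifs, both_strands)$counts)
  widths <- peaks$end - peaks$start
  totals <- vapply(seq_len(n_background), function(b) {
    bg <- sample_background(genome, nrow(peaks), widths,
                            seed = derive_seed(seed, b), exclusion = exclusion)
    colSums(region_motif_summary(bg, genome, motifs, both_strands)$counts)
  }, numeric(length(motifs)))
  totals <- matrix(totals, nrow = length(motifs))
  out <- lapply(seq_along(motifs), function(j) {
    m <- mean(totals[j, ]); s <- stats::sd(totals[j, ])
    mm <- motifs[[j]]
    structure(list(name = if (is.character(mm)) mm else mm$name,
                   observed = unname(obs[j]), background_mean = m,
                   background_sd = s,
                   z = if (s > 0) (unname(obs[j]) - m) / s else NA_real_,
                   degenerate_sd = s == 0,
                   n_background_samples = n_background, seed = seed),
              class = "enrichment_z")
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Find two-motif modules within a gap limit
#'
#' Pairs one hit of motif A with one hit of motif B in the same region when
#' their edge-to-edge gap is at most `max_gap` bp (overlapping occurrences
#' count as gap 0). When both hit sets are the same motif, two distinct hits
#' are required and each unordered pair is reported once.
#'
#' @param hits_a,hits_b Hit data.frames (columns region, offset, strand,
#'   match), as returned in `region_motif_summary()$hits`.
#' @param max_gap Maximum allowed gap in bp (default 50).
#' @return Data.frame: region, offset_a, strand_a, offset_b, strand_b, gap.
#' @export
find_modules <- function(hits_a, hits_b, max_gap = 50L) {
  empty <- data.frame(region = character(), offset_a = integer(),
                      strand_a = character(), offset_b = integer(),
                      strand_b = character(), gap = integer())
  if (!nrow(hits_a) || !nrow(hits_b)) return(empty)
  same <- identical(hits_a, hits_b)
  wa <- nchar(hits_a$match); wb <- nchar(hits_b$match)
  out <- list()
  for (reg in intersect(unique(hits_a$region), unique(hits_b$region))) {
    ia <- which(hits_a$region == reg); ib <- which(hits_b$region == reg)
    grid <- expand.grid(i = ia, j = ib)
    if (same) grid <- grid[grid$i < grid$j, , drop = FALSE]
    if (!nrow(grid)) next
    s1 <- hits_a$offset[grid$i]; e1 <- s1 + wa[grid$i]
    s2 <- hits_b$offset[grid$j]; e2 <- s2 + wb[grid$j]
    gap <- pmax(0L, pmax(s2 - e1, s1 - e2))
    keep <- gap <= max_gap
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      region = reg,
      offset_a = s1[keep], strand_a = hits_a$strand[grid$i][keep],
      offset_b = s2[keep], strand_b = hits_b$strand[grid$j][keep],
      gap = as.integer(gap[keep]), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Module enrichment per peak partition
#'
#' Fold enrichment of a two-motif module in each partition of peaks
#' (e.g. resting-unique / shared / de novo) relative to a matched background:
#' fold = (modules per kb in partition) / (modules per kb in background).
#'
#' @param partitions Named list of disjoint peak data.frames.
#' @param genome Named character vector of chromosome sequences.
#' @param motif_a,motif_b Motifs forming the module.
#' @param background Background peak data.frame (e.g. from
#'   [sample_background()]).
#' @param max_gap Module gap limit in bp (default 50).
#' @return Data.frame: partition, n_modules, kb, density, fold (NA for an
#'   empty partition).
#' @export
module_enrichment <- function(partitions, genome, motif_a, motif_b,
                              background, max_gap = 50L) {
  module_density <- function(peaks) {
    if (is.null(peaks) || !nrow(peaks)) return(c(n = NA_real_, kb = NA_real_, d = NA_real_))
    sa <- region_motif_summary(peaks, genome, motif_a)
    sb <- if (identical(motif_a, motif_b)) sa else region_motif_summary(peaks, genome, motif_b)
    mods <- find_modules(sa$hits, if (identical(motif_a, motif_b)) sa$hits else sb$hits, max_gap)
    kb <- sum(peaks$end - peaks$start) / 1000
    c(n = nrow(mods), kb = kb, d = nrow(mods) / kb)
  }
  bg <- module_density(background)
  rows <- lapply(names(partitions), function(nm) {
    d <- module_density(partitions[[nm]])
    data.frame(partition = nm, n_modules = d[["n"]], kb = d[["kb"]],
               density = d[["d"]],
               fold = if (is.na(d[["d"]]) || bg[["d"]] == 0) NA_real_ else d[["d"]] / bg[["d"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
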