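# Synthetic-data generator with planted ground truth.
#
# Emulates a two-cell-type x two-state TF occupancy study on one shared toy
# genome: peak sets with a controlled cross-cell-type overlap fraction,
# consensus motifs overwritten into a controlled fraction of peaks, a
# histone-mark-like track covering a controlled fraction of peaks, tag
# libraries with fold enrichment inside peaks, and WT/KO log2 expression
# matrices with planted fold-change effects. Every generator is a pure
# function of (config, seed) and updates a truth table used by recovery
# tests.

#' Simulation configuration
#'
#' Defaults describe the study conditions every benchmark runs under: a
#' 2 x 1.5 Mb genome with 300 well-separated genes, 200 peaks per sample
#' whose midpoints sit in the basal window of a known gene (so peak-to-gene
#' truth is exact), a 0.62 cross-cell-type overlap at the resting state, a
#' 0.9 motif plant rate, 10x tag enrichment over a 0.005/bp background, and
#' 3-replicate WT/KO expression with 2-4-fold planted effects (60% down) and
#' 0.25 log2 replicate noise.
#'
#' @param seed Default seed used when generator calls omit one.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Total genes (split evenly across chromosomes).
#' @param n_peaks Peaks per sample.
#' @param peak_length_mean,peak_length_sd,peak_length_min,peak_length_max
#'   Normal peak-length distribution, clipped.
#' @param cross_sample_peak_overlap_fraction Fraction of cell-A resting
#'   peaks sharing >= 1 bp with a cell-B resting peak.
#' @param state_maintained_fraction Fraction of resting peaks kept (jittered)
#'   in the activated state; the rest of the activated set is de novo.
#' @param motif_plant_rate Fraction of peak loci receiving one planted
#'   consensus instance.
#' @param motif_variants Concrete variants planted (uniformly chosen).
#' @param tag_enrichment Treatment tag rate inside peaks, as a fold over
#'   background.
#' @param background_tag_rate Background tag rate per bp.
#' @param control_depth Control library depth as a multiple of the
#'   treatment background (exercises library scaling).
#' @param de_fraction Fraction of bound genes given a KO expression shift.
#' @param de_fraction_unbound Same for unbound genes.
#' @param de_effect Linear fold-effect range; effects are drawn uniformly
#'   on the log2 scale between the two values.
#' @param de_down_fraction Probability a planted effect is down in KO.
#' @param replicate_sd Replicate noise sd in log2 units.
#' @param n_replicates Replicates per group (>= 2).
#' @param expr_mean,expr_sd Baseline log2 intensity distribution.
#' @param above_background_floor Log2 floor used by the DE filter.
#' @param below_floor_fraction Fraction of genes forced below the floor in
#'   all samples.
#' @param track_cover_rate Fraction of cell-A resting peaks covered by the
#'   histone-mark-like track.
#' @param n_track_background Track intervals placed away from peaks.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       n_chroms = 2L, chrom_length = 1.7e6, n_genes = 300L,
                       n_peaks = 200L,
                       peak_length_mean = 300, peak_length_sd = 60,
                       peak_length_min = 200, peak_length_max = 500,
                       cross_sample_peak_overlap_fraction = 0.62,
                       state_maintained_fraction = 0.6,
                       motif_plant_rate = 0.9,
                       motif_variants = runx_variants(),
                       tag_enrichment = 10, background_tag_rate = 0.0067,
                       control_depth = 1.25,
                       de_fraction = 0.3, de_fraction_unbound = 0.03,
                       de_effect = c(2, 4), de_down_fraction = 0.6,
                       replicate_sd = 0.25, n_replicates = 3L,
                       expr_mean = 8, expr_sd = 1.5,
                       above_background_floor = 5, below_floor_fraction = 0.08,
                       track_cover_rate = 0.85, n_track_background = 100L) {
  fr <- c(cross_sample_peak_overlap_fraction, state_maintained_fraction,
          motif_plant_rate, de_fraction, de_fraction_unbound,
          de_down_fraction, below_floor_fraction, track_cover_rate)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]", call. = FALSE)
  stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 0, n_peaks >= 1,
            peak_length_min >= 50, peak_length_max >= peak_length_min,
            tag_enrichment >= 1, background_tag_rate > 0,
            n_replicates >= 2, replicate_sd >= 0,
            length(de_effect) %in% c(1L, 2L), all(de_effect > 1))
  if (length(de_effect) == 1L) de_effect <- c(de_effect, de_effect)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy genome and gene annotation
#'
#' Uniform i.i.d. A/C/G/T background; genes are placed on a jittered grid
#' with alternating strands and enough separation that basal regulatory
#' windows never overlap (peak-to-gene truth stays exact).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List: genome (named character), genes (data.frame), chrom_sizes.
#' @export
simulate_genome <- function(config = sim_config(), seed = config$seed) {
  margin <- 6000
  # Alternating strands put divergent 5 kb upstream basal windows on every
  # second intergenic gap; TSS spacing must exceed 10 kb so basal windows
  # never overlap and basal-placed peaks map to exactly one gene.
  min_spacing <- 10600
  chroms <- paste0("chr", seq_len(config$n_chroms))
  with_seed(seed, {
    genome <- stats::setNames(
      vapply(chroms, function(ch) random_sequence(config$chrom_length), ""),
      chroms)
    chrom_sizes <- stats::setNames(rep(config$chrom_length, length(chroms)), chroms)
    if (config$n_genes == 0L) {
      genes <- data.frame(gene_id = character(), symbol = character(),
                          chrom = character(), strand = character(),
                          tss = numeric(), tes = numeric())
      return(list(genome = genome, genes = genes, chrom_sizes = chrom_sizes))
    }
    per <- ceiling(config$n_genes / config$n_chroms)
    spacing <- (config$chrom_length - 2 * margin) / per
    if (spacing < min_spacing) {
      stop("genes do not fit the chromosome at the required spacing; reduce n_genes or enlarge chrom_length",
           call. = FALSE)
    }
    jitter_max <- min(2000, spacing - min_spacing)
    rows <- list()
    gi <- 0L
    for (ch in chroms) {
      n_here <- min(per, config$n_genes - gi)
      if (n_here <= 0L) break
      tss <- margin + (seq_len(n_here) - 1L) * spacing +
        stats::runif(n_here, 0, max(jitter_max, 0))
      tss <- round(tss)
      strand <- rep(c("+", "-"), length.out = n_here)
      glen <- sample(2000:6000, n_here, replace = TRUE)
      tes <- ifelse(strand == "+", pmin(tss + glen, config$chrom_length - 1),
                    pmax(tss - glen, 0))
      rows[[ch]] <- data.frame(
        gene_id = sprintf("g%04d", gi + seq_len(n_here)),
        symbol = sprintf("Gene%d", gi + seq_len(n_here)),
        chrom = ch, strand = strand, tss = tss, tes = tes,
        stringsAsFactors = FALSE)
      gi <- gi + n_here
    }
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
    list(genome = genome, genes = genes, chrom_sizes = chrom_sizes)
  })
}

# Place one peak per selected gene, with a gene-oriented midpoint offset
# drawn from [off_lo, off_hi] (negative = upstream of the TSS).
place_peaks <- function(genes, idx, off_range, config, prefix) {
  n <- length(idx)
  if (n == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(), sample = character(),
                      gene_id = character(), stringsAsFactors = FALSE))
  }
  len <- round(pmin(pmax(stats::rnorm(n, config$peak_length_mean, config$peak_length_sd),
                         config$peak_length_min), config$peak_length_max))
  off <- round(stats::runif(n, off_range[1], off_range[2]))
  dir <- ifelse(genes$strand[idx] == "+", 1, -1)
  mid <- genes$tss[idx] + dir * off
  start <- mid - floor(len / 2)
  data.frame(chrom = genes$chrom[idx], start = start, end = start + len,
             name = sprintf("%s_%04d", prefix, seq_len(n)), score = NA_real_,
             sample = prefix, gene_id = genes$gene_id[idx],
             stringsAsFactors = FALSE)
}

jitter_peaks <- function(peaks, prefix, shift_max = 40L) {
  shift <- sample(seq.int(-shift_max, shift_max), nrow(peaks), replace = TRUE)
  peaks$start <- peaks$start + shift
  peaks$end <- peaks$end + shift
  peaks$name <- sprintf("%s_%04d", prefix, seq_len(nrow(peaks)))
  peaks$sample <- prefix
  rownames(peaks) <- NULL
  peaks
}

sort_peaks <- function(peaks) {
  peaks <- peaks[order(peaks$chrom, peaks$start, method = "radix"), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

# Offset windows (gene-oriented, relative to the TSS) for resting and
# de novo peaks. Both lie inside the basal window of the gene; they are far
# enough apart that a resting and a de novo peak at the same gene never
# overlap (max peak length 500 => half-length 250 plus 75 bp jitter).
RESTING_OFFSETS <- c(-3800, -800)
DENOVO_OFFSETS <- c(600, 950)

IUPAC_REVCOMP_BASE <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_seq <- function(s) {
  paste(rev(IUPAC_REVCOMP_BASE[strsplit(s, "")[[1]]]), collapse = "")
}

#' Plant peak sets and consensus motifs on a simulated genome
#'
#' Builds four peak sets (two cell types x resting/activated). A configured
#' fraction of cell-A resting peaks is copied (with small jitter) into the
#' cell-B resting set so the measured cross-sample overlap equals
#' `cross_sample_peak_overlap_fraction`; activated sets keep a configured
#' fraction of their resting peaks and add de novo peaks in a disjoint
#' offset window. A fraction `motif_plant_rate` of physical peak loci
#' receives one planted motif variant (uniform variant and strand) written
#' into the genome; incidental consensus matches inside peak loci are then
#' mutated away so the per-sample fraction of motif-bearing peaks equals
#' the plant rate.
#'
#' @param sim Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List: genome (modified), peaks (named list of 4 peak
#'   data.frames, each with a truth `gene_id` and `has_motif` column),
#'   motif_table (planted instances), track (histone-mark-like intervals).
#' @export
plant_peaks_and_motifs <- function(sim, config = sim_config(), seed = config$seed) {
  genes <- sim$genes
  n <- config$n_peaks
  if (n > nrow(genes)) stop("requested peaks exceed genome capacity (need one gene per peak)", call. = FALSE)
  with_seed(seed, {
    # --- resting peak sets with controlled cross-cell overlap ---
    a_genes <- sample.int(nrow(genes), n)
    a_rest <- place_peaks(genes, a_genes, RESTING_OFFSETS, config, "cellA_resting")
    n_shared <- round(config$cross_sample_peak_overlap_fraction * n)
    shared_idx <- if (n_shared > 0) sample.int(n, n_shared) else integer()
    b_unique_pool <- setdiff(seq_len(nrow(genes)), a_genes)
    n_b_unique <- n - n_shared
    if (n_b_unique > length(b_unique_pool)) {
      stop("requested peaks exceed genome capacity (not enough genes for the unique cell-B set)",
           call. = FALSE)
    }
    b_shared <- jitter_peaks(a_rest[shared_idx, , drop = FALSE], "cellB_resting")
    b_own <- place_peaks(genes, sample(b_unique_pool, n_b_unique), RESTING_OFFSETS,
                         config, "cellB_restingU")
    b_own$sample <- rep("cellB_resting", nrow(b_own))
    b_rest <- rbind(b_shared, b_own)
    b_rest$name <- sprintf("cellB_resting_%04d", seq_len(nrow(b_rest)))
    # --- activated sets: maintained subset + de novo in a disjoint window ---
    n_maint <- round(config$state_maintained_fraction * n)
    n_dn <- n - n_maint
    if (2L * n_dn > nrow(genes)) {
      stop("requested peaks exceed genome capacity (de novo sets need distinct genes)",
           call. = FALSE)
    }
    # distinct de novo genes per cell type, so motif-bearing truth per locus
    # never mixes records from unrelated placements
    dn_all <- sample.int(nrow(genes), 2L * n_dn)
    activated <- function(rest, prefix, dn_genes) {
      keep <- sample.int(nrow(rest), n_maint)
      maint <- jitter_peaks(rest[keep, , drop = FALSE], prefix)
      dn <- place_peaks(genes, dn_genes, DENOVO_OFFSETS, config, prefix)
      out <- rbind(maint, dn)
      out$name <- sprintf("%s_%04d", prefix, seq_len(nrow(out)))
      out$sample <- prefix
      out
    }
    a_act <- activated(a_rest, "cellA_activated", dn_all[seq_len(n_dn)])
    b_act <- activated(b_rest, "cellB_activated", dn_all[n_dn + seq_len(n_dn)])
    all_peaks <- rbind(a_rest, b_rest, a_act, b_act)
    # --- cluster physically-overlapping records into loci ---
    gr <- peaks_gr(all_peaks)
    red <- GenomicRanges::reduce(gr)
    comp <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, red))
    n_comp <- length(red)
    planted <- stats::runif(n_comp) < config$motif_plant_rate
    genome <- sim$genome
    motif_rows <- list()
    mlen <- nchar(config$motif_variants[1])
    for (ci in which(planted)) {
      members <- which(comp == ci)
      istart <- max(all_peaks$start[members])
      iend <- min(all_peaks$end[members])
      if (iend - istart < mlen) { istart <- min(all_peaks$start[members]); iend <- istart + mlen }
      pos <- istart + sample.int(iend - istart - mlen + 1L, 1L) - 1L
      variant <- sample(config$motif_variants, 1L)
      strand <- sample(c("+", "-"), 1L)
      written <- if (strand == "+") variant else revcomp_seq(variant)
      chr <- all_peaks$chrom[members[1]]
      substr(genome[[chr]], pos + 1L, pos + mlen) <- written
      motif_rows[[length(motif_rows) + 1L]] <- data.frame(
        chrom = chr, pos = pos, variant = variant, strand = strand,
        component = ci, stringsAsFactors = FALSE)
    }
    motif_table <- if (length(motif_rows)) do.call(rbind, motif_rows) else
      data.frame(chrom = character(), pos = integer(), variant = character(),
                 strand = character(), component = integer())
    # --- sterilise incidental consensus matches inside peak loci ---
    genome <- scrub_incidental_motifs(genome, red, motif_table)
    all_peaks$has_motif <- planted[comp]
    out_peaks <- lapply(
      stats::setNames(nm = c("cellA_resting", "cellB_resting",
                             "cellA_activated", "cellB_activated")),
      function(s) sort_peaks(all_peaks[all_peaks$sample == s, , drop = FALSE]))
    # --- histone-mark-like track covering a fraction of cell-A resting peaks ---
    src <- out_peaks$cellA_resting
    covered <- stats::runif(nrow(src)) < config$track_cover_rate
    track_peaks <- data.frame(chrom = src$chrom[covered],
                              start = pmax(0, src$start[covered] - 500L),
                              end = src$end[covered] + 500L,
                              stringsAsFactors = FALSE)
    bg_track <- sample_background(sim$chrom_sizes, config$n_track_background,
                                  1000L, seed = derive_seed(seed, 991L),
                                  exclusion = all_peaks)
    track <- sort_peaks(rbind(track_peaks, bg_track[c("chrom", "start", "end")]))
    track$name <- paste0("track_", seq_len(nrow(track)))
    list(genome = genome, peaks = out_peaks, motif_table = motif_table,
         track = track)
  })
}

# Mutate away consensus matches inside peak loci that were not planted, so
# that motif-bearing truth is exact. Works on the reduced loci spans.
scrub_incidental_motifs <- function(genome, loci, motif_table) {
  consensus <- runx_motif()
  mlen <- consensus$length
  fwd_re <- iupac_regex(consensus$iupac)
  rev_re <- iupac_regex(revcomp_iupac(consensus$iupac))
  # forward-strand IUPAC sets per motif position, for both orientations
  break_base <- function(seq_chunk, off, orientation) {
    sets <- lapply(strsplit(if (orientation == "+") consensus$iupac else
      revcomp_iupac(consensus$iupac), "")[[1]], function(l) IUPAC_SETS[[l]])
    j <- off  # 1-based position within the match to mutate
    repl <- setdiff(c("A", "C", "G", "T"), sets[[j]])[1]
    repl
  }
  loci_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(loci)),
                        start = GenomicRanges::start(loci) - 1L,
                        end = GenomicRanges::end(loci))
  for (i in seq_len(nrow(loci_df))) {
    chr <- loci_df$chrom[i]
    s0 <- loci_df$start[i]; e0 <- loci_df$end[i]
    planted_here <- motif_table[motif_table$chrom == chr &
                                  motif_table$pos >= s0 - mlen &
                                  motif_table$pos < e0 + mlen, , drop = FALSE]
    for (iter in 1:40) {
      chunk <- substr(genome[[chr]], s0 + 1L, e0)
      hits_f <- scan_strand(chunk, fwd_re, mlen)
      hits_r <- scan_strand(chunk, rev_re, mlen)
      hits <- rbind(
        data.frame(off = hits_f, ori = rep("+", length(hits_f))),
        data.frame(off = hits_r, ori = rep("-", length(hits_r))))
      if (!nrow(hits)) break
      gpos <- s0 + hits$off
      keep <- !(gpos %in% planted_here$pos)
      hits <- hits[keep, , drop = FALSE]
      if (!nrow(hits)) break
      h <- hits[1L, ]
      hstart <- s0 + h$off  # genomic 0-based start of the offending match
      # mutate the first base of the match that is outside every planted span
      j <- NA_integer_
      for (cand in seq_len(mlen)) {
        p <- hstart + cand - 1L
        inside <- nrow(planted_here) &&
          any(p >= planted_here$pos & p < planted_here$pos + mlen)
        if (!inside) { j <- cand; break }
      }
      if (is.na(j)) break  # fully inside a planted span; leave it
      repl <- break_base(chunk, j, h$ori)
      substr(genome[[chr]], hstart + j, hstart + j) <- repl
    }
  }
  genome
}

#' Generate treatment and control tag libraries
#'
#' Control tags are Poisson-uniform at `background_tag_rate * control_depth`
#' per bp; treatment tags are Poisson-uniform at the background rate plus
#' `(tag_enrichment - 1) * background_tag_rate` inside peaks.
#'
#' @param peaks Peak data.frame (the planted truth set).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List: treatment and control `tag_library` objects.
#' @export
generate_tags <- function(peaks, chrom_sizes, config = sim_config(),
                          seed = config$seed) {
  with_seed(seed, {
    draw_uniform <- function(rate) {
      rows <- lapply(names(chrom_sizes), function(ch) {
        L <- unname(chrom_sizes[ch])
        k <- stats::rpois(1L, rate * L)
        data.frame(chrom = ch, pos = sample.int(L, k, replace = TRUE) - 1L,
                   strand = sample(c("+", "-"), k, replace = TRUE),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    control <- draw_uniform(config$background_tag_rate * config$control_depth)
    treat <- draw_uniform(config$background_tag_rate)
    extra_rate <- (config$tag_enrichment - 1) * config$background_tag_rate
    if (extra_rate > 0 && nrow(peaks)) {
      lens <- peaks$end - peaks$start
      k <- stats::rpois(nrow(peaks), extra_rate * lens)
      idx <- rep(seq_len(nrow(peaks)), k)
      if (length(idx)) {
        off <- floor(stats::runif(length(idx)) * lens[idx])
        treat <- rbind(treat, data.frame(
          chrom = peaks$chrom[idx], pos = peaks$start[idx] + off,
          strand = sample(c("+", "-"), length(idx), replace = TRUE),
          stringsAsFactors = FALSE))
      }
    }
    list(treatment = tag_library(treat, chrom_sizes),
         control = tag_library(control, chrom_sizes))
  })
}

#' Generate WT/KO expression matrices with planted effects
#'
#' Baseline log2 means are drawn per gene; a fraction of bound genes (and a
#' smaller fraction of unbound genes) is shifted by a signed log2 effect in
#' the KO group; replicate noise is Normal(0, replicate_sd); a configured
#' fraction of genes sits below the above-background floor in all samples.
#'
#' @param universe Character vector of gene ids on the platform.
#' @param bound_genes Character vector of bound gene ids.
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param condition Label recorded in the sample sheet.
#' @return List: wt, ko (log2 matrices), samples (sheet), truth (data.frame
#'   gene_id, sign, log2_effect), below_floor (gene ids).
#' @export
generate_expression <- function(universe, bound_genes, config = sim_config(),
                                seed = config$seed, condition = "cond") {
  if (config$de_fraction > 1) stop("de_fraction must not exceed 1", call. = FALSE)
  universe <- unique(as.character(universe))
  bound_genes <- intersect(unique(as.character(bound_genes)), universe)
  n <- length(universe)
  nrep <- config$n_replicates
  with_seed(seed, {
    baseline <- stats::rnorm(n, config$expr_mean, config$expr_sd)
    names(baseline) <- universe
    baseline <- pmax(baseline, config$above_background_floor + 0.5)
    n_low <- round(config$below_floor_fraction * n)
    low_genes <- if (n_low > 0) sample(universe, n_low) else character()
    baseline[low_genes] <- config$above_background_floor -
      stats::runif(n_low, 1, 3)
    eligible_bound <- setdiff(bound_genes, low_genes)
    eligible_unbound <- setdiff(universe, union(bound_genes, low_genes))
    pick <- function(pool, frac) {
      k <- round(frac * length(pool))
      if (k > 0) sample(pool, k) else character()
    }
    de_genes <- c(pick(eligible_bound, config$de_fraction),
                  pick(eligible_unbound, config$de_fraction_unbound))
    sign_ <- ifelse(stats::runif(length(de_genes)) < config$de_down_fraction, -1, 1)
    eff <- stats::runif(length(de_genes),
                        log2(config$de_effect[1]), log2(config$de_effect[2]))
    shift <- stats::setNames(rep(0, n), universe)
    shift[de_genes] <- sign_ * eff
    noise <- function() matrix(stats::rnorm(n * nrep, 0, config$replicate_sd),
                               nrow = n)
    wt <- baseline + noise()
    ko <- baseline + shift + noise()
    dimnames(wt) <- list(universe, sprintf("%s_WT_%d", condition, seq_len(nrep)))
    dimnames(ko) <- list(universe, sprintf("%s_KO_%d", condition, seq_len(nrep)))
    samples <- data.frame(
      sample = c(colnames(wt), colnames(ko)),
      group = rep(c("WT", "KO"), each = nrep),
      condition = condition, stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = de_genes, sign = sign_, log2_effect = eff,
                        stringsAsFactors = FALSE)
    list(wt = wt, ko = ko, samples = samples, truth = truth,
         below_floor = low_genes)
  })
}

#' Simulate a complete two-cell-type, two-state study
#'
#' Runs [simulate_genome()], [plant_peaks_and_motifs()], [generate_tags()]
#' (for the cell-A resting sample) and [generate_expression()] for each of
#' the four cell-type x state conditions, collecting the full truth tables.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List of class `sim_study`: genome, genes, chrom_sizes, peaks,
#'   motif_table, track, tags, expression, truth, config.
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed) {
  base <- simulate_genome(config, derive_seed(seed, 1L))
  planted <- plant_peaks_and_motifs(base, config, derive_seed(seed, 2L))
  tags <- generate_tags(planted$peaks$cellA_resting, base$chrom_sizes,
                        config, derive_seed(seed, 3L))
  universe <- base$genes$gene_id
  conditions <- names(planted$peaks)
  expression <- stats::setNames(vector("list", length(conditions)), conditions)
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    bound <- unique(planted$peaks[[cond]]$gene_id)
    expression[[cond]] <- generate_expression(
      universe, bound, config, derive_seed(seed, 10L + i), condition = cond)
  }
  truth <- list(
    bound_genes = lapply(planted$peaks, function(p) unique(p$gene_id)),
    bound_with_motif = lapply(planted$peaks, function(p)
      unique(p$gene_id[p$has_motif])),
    de_genes = lapply(expression, function(e) e$truth),
    regulated = stats::setNames(lapply(conditions, function(cond) {
      intersect(expression[[cond]]$truth$gene_id,
                unique(planted$peaks[[cond]]$gene_id[planted$peaks[[cond]]$has_motif]))
    }), conditions),
    motif_table = planted$motif_table
  )
  structure(list(genome = planted$genome, genes = base$genes,
                 chrom_sizes = base$chrom_sizes, peaks = planted$peaks,
                 motif_table = planted$motif_table, track = planted$track,
                 tags = tags, expression = expression, truth = truth,
                 config = config, seed = seed),
            class = "sim_study")
}
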