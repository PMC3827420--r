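# End-to-end orchestration: simulate -> callpeaks -> annotate -> motifs ->
# de -> integrate -> gsea -> report, from one config with one global seed.
# Every number in the report is recomputed from the stage outputs it
# bundles, and reruns with the same config and seed are identical.

PIPELINE_STAGES <- c("simulate", "callpeaks", "annotate", "motifs", "de",
                     "integrate", "gsea")

STAGE_DEPS <- list(
  simulate = character(),
  callpeaks = "simulate",
  annotate = "simulate",
  motifs = "simulate",
  de = "simulate",
  integrate = c("annotate", "motifs", "de"),
  gsea = c("de", "integrate")
)

#' Pipeline configuration
#'
#' Bundles the stage configurations and the global seed. `seed` drives every
#' stochastic stage (simulation, background sampling, GSEA permutations)
#' through derived per-stage seeds.
#'
#' @param seed Global integer seed (mandatory).
#' @param sim A [sim_config()].
#' @param caller A [peak_caller_config()].
#' @param domains A [domain_config()].
#' @param de A [de_config()]; defaults to the filter at the simulation's
#'   background floor.
#' @param gsea A [gsea_config()].
#' @param motifs Named list of `motif_consensus` objects (first entry is the
#'   primary consensus used for gene-set derivation).
#' @param n_motif_background Background sets for motif Z-scores.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            sim = sim_config(),
                            caller = peak_caller_config(),
                            domains = domain_config(),
                            de = de_config(background_floor = sim$above_background_floor),
                            gsea = gsea_config(),
                            motifs = default_motifs(),
                            n_motif_background = 50L) {
  if (missing(seed) || is.null(seed)) stop("a global seed is mandatory", call. = FALSE)
  structure(list(seed = as.integer(seed), sim = sim, caller = caller,
                 domains = domains, de = de, gsea = gsea, motifs = motifs,
                 n_motif_background = as.integer(n_motif_background)),
            class = "pipeline_config")
}

check_stage_deps <- function(stages) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  for (s in stages) {
    missing_dep <- setdiff(STAGE_DEPS[[s]], stages)
    if (length(missing_dep)) {
      stop(sprintf("stage '%s' requires prior stage(s): %s", s,
                   paste(missing_dep, collapse = ", ")), call. = FALSE)
    }
  }
  stages[order(match(stages, PIPELINE_STAGES))]
}

#' Run the integrative occupancy/expression pipeline
#'
#' @param config A [pipeline_config()].
#' @param stages Ordered subset of
#'   simulate/callpeaks/annotate/motifs/de/integrate/gsea; dependencies are
#'   checked and an informative error names any missing prior stage.
#' @return List of class `pipeline_report` with one element per executed
#'   stage plus `summary` (the headline counts, fractions and ratios).
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- check_stage_deps(stages)
  res <- list(seed = config$seed, stages = stages)
  cells <- c("cellA", "cellB")

  if ("simulate" %in% stages) {
    study <- simulate_study(config$sim, seed = config$seed)
    res$study <- study
  }
  study <- res$study

  if ("callpeaks" %in% stages) {
    called <- call_peaks(study$tags$treatment, study$tags$control, config$caller)
    truth_peaks <- study$peaks$cellA_resting
    recovered <- if (nrow(called)) {
      GenomicRanges::countOverlaps(peaks_gr(truth_peaks), peaks_gr(called)) > 0L
    } else rep(FALSE, nrow(truth_peaks))
    res$callpeaks <- list(
      called = called,
      n_called = nrow(called),
      sensitivity = mean(recovered),
      scale_factor = scale_libraries(study$tags$treatment, study$tags$control))
  }

  if ("annotate" %in% stages) {
    doms <- build_domains(study$genes, study$chrom_sizes, config$domains)
    assignments <- lapply(study$peaks, assign_peaks, domains = doms,
                          genes = study$genes)
    bins <- lapply(assignments, distance_bin_fractions)
    rest_overlap <- peak_set_overlap(study$peaks$cellA_resting,
                                     study$peaks$cellB_resting)
    act_overlap <- peak_set_overlap(study$peaks$cellA_activated,
                                    study$peaks$cellB_activated)
    gene_overlap <- gene_set_overlap(
      unique(assignments$cellA_resting$gene_id),
      unique(assignments$cellB_resting$gene_id))
    states <- lapply(cells, function(cl) {
      list(region = compare_states(study$peaks[[paste0(cl, "_resting")]],
                                   study$peaks[[paste0(cl, "_activated")]],
                                   level = "region"),
           gene = compare_states(unique(assignments[[paste0(cl, "_resting")]]$gene_id),
                                 unique(assignments[[paste0(cl, "_activated")]]$gene_id),
                                 level = "gene"))
    })
    names(states) <- cells
    track_ov <- track_overlap_fraction(study$peaks$cellA_resting, study$track,
                                       assignments$cellA_resting)
    res$annotate <- list(domains = doms, assignments = assignments,
                         bin_fractions = bins,
                         peak_overlap_resting = rest_overlap,
                         peak_overlap_activated = act_overlap,
                         gene_overlap_resting = gene_overlap,
                         states = states, track_overlap = track_ov)
  }

  if ("motifs" %in% stages) {
    primary <- config$motifs[[1L]]
    summaries <- lapply(study$peaks, region_motif_summary,
                        genome = study$genome, motifs = runx_variants())
    zs <- motif_zscore_table(study$peaks$cellA_resting, study$genome,
                             as.list(runx_variants()),
                             n_background = config$n_motif_background,
                             seed = derive_seed(config$seed, 101L))
    res$motifs <- list(summaries = summaries,
                       fraction_with_motif = vapply(summaries, `[[`, 0, "fraction_with_hit"),
                       zscores = zs, primary = primary$name)
  }

  if ("de" %in% stages) {
    de_results <- lapply(study$expression, function(e)
      differential_genes(e$wt, e$ko, config$de))
    res$de <- list(results = de_results,
                   n_responsive = vapply(de_results, function(d) sum(d$status != "ns"), 0),
                   direction = lapply(de_results, direction_split))
  }

  if ("integrate" %in% stages) {
    universe <- study$genes$gene_id
    sets <- lapply(names(study$peaks), function(cond) {
      derive_gene_sets(res$annotate$assignments[[cond]],
                       res$motifs$summaries[[cond]],
                       res$de$results[[cond]], universe)
    })
    names(sets) <- names(study$peaks)
    assoc <- lapply(sets, function(s)
      contingency_association(s$bound, s$responsive, s$universe))
    # cross-cell-type common regulated genes, per state
    common <- lapply(c(resting = "resting", activated = "activated"), function(st) {
      a <- sets[[paste0("cellA_", st)]]$regulated
      b <- sets[[paste0("cellB_", st)]]$regulated
      ov <- expected_overlap(a, b, universe)
      conc <- if (ov$k > 0) direction_concordance(
        intersect(a, b), res$de$results[[paste0("cellA_", st)]],
        res$de$results[[paste0("cellB_", st)]]) else NULL
      list(overlap = ov, concordance = conc)
    })
    n_reg <- vapply(sets, function(s) length(s$regulated), 0)
    ratios <- summarize_ratios(
      numerator = c(n_reg[["cellA_activated"]], n_reg[["cellB_activated"]]),
      denominator = c(n_reg[["cellA_resting"]], n_reg[["cellB_resting"]]),
      type = "ratio",
      label = c("cellA activated/resting", "cellB activated/resting"))
    # recovery of the planted regulated truth
    recovery <- lapply(names(sets), function(cond) {
      found <- sets[[cond]]$regulated
      truth <- study$truth$regulated[[cond]]
      tp <- length(intersect(found, truth))
      list(precision = if (length(found)) tp / length(found) else NA_real_,
           recall = if (length(truth)) tp / length(truth) else NA_real_)
    })
    names(recovery) <- names(sets)
    res$integrate <- list(sets = sets, association = assoc, common = common,
                          ratios = ratios, recovery = recovery)
  }

  if ("gsea" %in% stages) {
    gcfg <- config$gsea
    gcfg$seed <- gcfg$seed %||% derive_seed(config$seed, 201L)
    gsea <- lapply(paste0(cells, "_activated"), function(cond) {
      ranked <- rank_by_abs_fc(res$de$results[[cond]], gcfg$tie_policy)
      nes_and_pvalue(ranked, res$integrate$sets[[cond]]$bound_with_motif, gcfg)
    })
    names(gsea) <- paste0(cells, "_activated")
    res$gsea <- gsea
  }

  res$summary <- pipeline_summary(res)
  structure(res, class = "pipeline_report")
}

# Headline numbers, all recomputed from the bundled stage outputs.
pipeline_summary <- function(res) {
  s <- list(seed = res$seed)
  if (!is.null(res$callpeaks)) {
    s$peak_recovery_sensitivity <- res$callpeaks$sensitivity
    s$n_called_peaks <- res$callpeaks$n_called
  }
  if (!is.null(res$annotate)) {
    s$peak_overlap_fraction_resting <- res$annotate$peak_overlap_resting$fraction
    s$gene_overlap_percent_resting <- res$annotate$gene_overlap_resting$percent_of_a
    s$track_overlap_fraction <- res$annotate$track_overlap$fraction
    s$bin_fractions_cellA_resting <- res$annotate$bin_fractions$cellA_resting
  }
  if (!is.null(res$motifs)) {
    s$fraction_with_motif <- res$motifs$fraction_with_motif
    s$zscores <- vapply(res$motifs$zscores, `[[`, 0, "z")
  }
  if (!is.null(res$de)) {
    s$n_responsive <- res$de$n_responsive
    s$fraction_down <- vapply(res$de$direction, `[[`, 0, "fraction_down")
  }
  if (!is.null(res$integrate)) {
    s$n_regulated <- vapply(res$integrate$sets, function(x) length(x$regulated), 0)
    s$regulated_precision <- vapply(res$integrate$recovery, `[[`, 0, "precision")
    s$regulated_recall <- vapply(res$integrate$recovery, `[[`, 0, "recall")
    s$common_regulated_resting <- res$integrate$common$resting$overlap$k
    s$common_regulated_activated <- res$integrate$common$activated$overlap$k
    s$activated_vs_resting_fold <- res$integrate$ratios$printed
  }
  if (!is.null(res$gsea)) {
    s$gsea_nes <- vapply(res$gsea, `[[`, 0, "nes")
    s$gsea_p <- vapply(res$gsea, `[[`, 0, "nominal_p")
  }
  s
}

#' Write a pipeline report to disk
#'
#' Serialises the summary as JSON and the main tables as TSV/BED under
#' `outdir`.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$callpeaks)) {
    write_bed(report$callpeaks$called, file.path(outdir, "called_peaks.bed"))
  }
  if (!is.null(report$annotate)) {
    utils::write.table(report$annotate$assignments$cellA_resting,
                       file.path(outdir, "assignments_cellA_resting.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$de)) {
    for (cond in names(report$de$results)) {
      utils::write.table(report$de$results[[cond]],
                         file.path(outdir, sprintf("de_%s.tsv", cond)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(outdir)
}
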