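#' Run the full calibration pipeline end to end
#'
#' Executes both study arms on simulated (or supplied) data: fractionation
#' arm — non-normalized preprocessing, contaminant catalogue from the
#' cellular fractions, fraction/contaminant concordance map and replicate
#' stability; cohort arm — normalized preprocessing, contaminant
#' filtering, detection-based class partition with CV comparison, and SAM
#' gender differential expression with complete-linkage clustering. All
#' stage outputs and a manifest (parameters, seeds, per-stage feature
#' counts) are written under `out_dir`.
#'
#' @param out_dir run directory (created; stage subfolders inside).
#' @param params [sim_params()] controlling the simulation and seed.
#' @param fractions,cohort optional pre-simulated arm bundles (as returned
#'   by [simulate_fractions()] / [simulate_cohort()]); simulated from
#'   `params` when NULL.
#' @param alpha detection threshold.
#' @param offset log-transform offset.
#' @param rate cohort detection-proportion threshold for the partition.
#' @param strata intensity stratum sizes for the concordance analyses.
#' @param fdr_target nominal FDR for SAM.
#' @param n_perm SAM permutation count.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(out_dir,
                         params = sim_params(),
                         fractions = NULL, cohort = NULL,
                         alpha = 0.06, offset = 16, rate = 0.5,
                         strata = c(20L, 35L, 50L, 100L),
                         fdr_target = 0.05, n_perm = 1000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  annotation <- make_annotation(params)
  if (is.null(fractions)) fractions <- simulate_fractions(params, annotation)
  if (is.null(cohort)) cohort <- simulate_cohort(params, annotation)
  manifest <- list(params = unclass(params), alpha = alpha, offset = offset,
                   rate = rate, strata = strata, fdr_target = fdr_target,
                   n_perm = n_perm, counts = list())
  count <- function(stage, ...) {
    manifest$counts[[stage]] <<- list(...)
  }

  # --- fractionation arm ----------------------------------------------------
  frac_dir <- file.path(out_dir, "fractionation")
  dir.create(frac_dir, showWarnings = FALSE)
  write_simulation(fractions, file.path(frac_dir, "input"))
  pp_frac <- preprocess(fractions$matrix, annotation, mode = "non_normalized",
                        samples = fractions$samples, alpha = alpha,
                        offset = offset)
  write_probeset_matrix(pp_frac$expr, file.path(frac_dir, "expr.tsv"))
  write_intensity_matrix(pp_frac$detection$pvalues,
                         file.path(frac_dir, "detection_p.tsv"))
  count("preprocess_fractionation",
        probes_in = nrow(fractions$matrix), features_out = nrow(pp_frac$expr))

  catalog <- build_catalog(pp_frac$detection, fractions$samples)
  write_catalog(catalog, file.path(frac_dir, "catalog.txt"))
  count("catalog", members = length(catalog$members),
        per_class = lapply(catalog$per_class, length))

  human <- sort(rownames(pp_frac$expr))
  retained <- filter_contaminants(human, catalog)
  count("filter", features_in = length(human),
        removed = length(human) - length(retained),
        retained = length(retained))

  plasma_ids <- fractions$samples$sample_id[
    fractions$samples$fraction %in% PLASMA_FRACTIONS]
  top100 <- top_n_features(pp_frac$expr[, plasma_ids, drop = FALSE],
                           min(100L, nrow(pp_frac$expr)))
  cmap <- fraction_correlation_map(pp_frac$expr, fractions$samples, top100,
                                   include_lwr = TRUE)
  utils::write.table(round(cmap, 6), file.path(frac_dir, "concordance.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  s1_ids <- fractions$samples$sample_id[fractions$samples$fraction == "S1"]
  s1_expr <- set_scale(pp_frac$expr[retained, s1_ids, drop = FALSE], "log2")
  stab_sizes <- unique(pmin(strata, nrow(s1_expr)))
  stability <- replicate_stability(s1_expr, c(stab_sizes, nrow(s1_expr)))
  count("concordance", reference_features = length(top100),
        stability_strata = length(stability$means))

  # --- cohort arm -----------------------------------------------------------
  coh_dir <- file.path(out_dir, "cohort")
  dir.create(coh_dir, showWarnings = FALSE)
  write_simulation(cohort, file.path(coh_dir, "input"))
  pp_coh <- preprocess(cohort$matrix, annotation, mode = "normalized",
                       samples = cohort$samples, alpha = alpha,
                       offset = offset)
  write_probeset_matrix(pp_coh$expr, file.path(coh_dir, "expr.tsv"))
  expr_filt <- filter_contaminants(pp_coh$expr, catalog)
  expr_filt <- set_scale(expr_filt, "log2")
  write_probeset_matrix(expr_filt, file.path(coh_dir, "expr.filtered.tsv"))
  count("preprocess_cohort", features_in = nrow(pp_coh$expr),
        removed = nrow(pp_coh$expr) - nrow(expr_filt),
        retained = nrow(expr_filt))

  part <- partition_classes(pp_coh$detection, catalog, rate = rate)
  cv_cmp <- if (length(part$s_plus_l) >= 2L && length(part$s_only) >= 2L) {
    class_cv_compare(pp_coh$expr, part)
  } else NULL
  count("partition", s_plus_l = length(part$s_plus_l),
        s_only = length(part$s_only))

  groups <- factor(cohort$samples$sex, levels = c("M", "F"))
  fit <- sam(expr_filt, groups, fdr_target = fdr_target, n_perm = n_perm,
             seed = params$seed, detection = pp_coh$detection)
  utils::write.table(as.data.frame(fit), file.path(coh_dir, "sam_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  count("diffexp", tested = length(fit$d),
        significant = length(fit$significant),
        removed_undetected = length(fit$removed_undetected))
  clust <- if (length(fit$significant) >= 2L) {
    cl <- cluster_features(expr_filt, fit$significant)
    jsonlite::write_json(list(order = cl$order, heights = cl$heights,
                              merge = cl$hclust$merge),
                         file.path(coh_dir, "clustering.json"),
                         auto_unbox = TRUE, digits = NA)
    cl
  } else NULL

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(annotation = annotation, fractions = fractions,
                 cohort = cohort, preprocess_fractionation = pp_frac,
                 preprocess_cohort = pp_coh, catalog = catalog,
                 retained = retained, correlation_map = cmap,
                 stability = stability, partition = part,
                 class_cv = cv_cmp, sam = fit, clustering = clust,
                 manifest = manifest))
}
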