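#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis in one flat list.
#' With `cohort = NULL` a synthetic cohort is generated from `cohort_config`.
#'
#' @param cohort_config A [cohort_config()] used when simulating.
#' @param promoter_window Promoter half-window bp (default 5000).
#' @param logfc_cut,fdr_cut Differential thresholds (defaults 0.7, 0.05).
#' @param n_iter Resampling iterations for the expected-by-chance analysis
#'   (default 100); set to 0 to skip.
#' @param low_cut Low-penetrance band upper bound (default 14).
#' @param min_pi_disease,max_healthy_ci_fraction,min_ci_delta Dynamic-CRE
#'   selection thresholds (defaults 15, 1/3, 20).
#' @param k Number of CRE clusters (default 4).
#' @param proximity_window Enhancer-gene proximity fallback bp (default
#'   10000).
#' @param top_fraction Dependency-rank most-dependent fraction (default 0.10).
#' @param seed Master seed for the stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_config = clonalCRE::cohort_config(),
                            promoter_window = 5000, logfc_cut = 0.7,
                            fdr_cut = 0.05, n_iter = 100L, low_cut = 14L,
                            min_pi_disease = 15L, max_healthy_ci_fraction = 1 / 3,
                            min_ci_delta = 20, k = 4L,
                            proximity_window = 10000, top_fraction = 0.10,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full clonality/penetrance pipeline on a synthetic cohort
#'
#' Executes the stages in analysis order: cohort simulation, master-list
#' construction, count matrix, Clonality/Penetrance scoring, differential
#' accessibility with the resampling null, dynamic-CRE selection and
#' clustering, eRNA quantification and productive-CRE calling, enhancer-tier
#' classification, loop classification and enhancer-gene target linking, and
#' dependency-screen ranking. Per-stage artifacts are written under
#' `out_dir` when given.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for per-stage TSV/BED artifacts.
#' @return Object of class `cre_pipeline`: list of per-stage results plus a
#'   `gates` data.frame of region counts along the selection funnel.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  res <- tryCatch({
    sim <- simulate_cohort(config$cohort_config)
    groups <- split(sim$metadata$sample_id, sim$metadata$stage)
    groups <- groups[intersect(.stages, names(groups))]

    stage <- "masterlist"
    master <- build_master_list(sim$repertoires)
    counts <- build_count_matrix(master, sim$repertoires)

    stage <- "score"
    ct <- clonality_table(sim$repertoires, master)
    pres <- presence_matrix(master, sim$metadata$sample_id)
    pi_all <- rowSums(pres)
    comp <- penetrance_composition(pres, groups, low_cut = config$low_cut)
    oe <- penetrance_oe(pres, groups$healthy, groups$onset)

    stage <- "differential"
    tmm <- tmm_normalize(counts)
    diff_ho <- differential_accessibility(tmm$log2_norm, groups$healthy,
                                          groups$onset, config$logfc_cut,
                                          config$fdr_cut)
    null_ho <- if (config$n_iter > 0)
      resampling_expected(tmm$log2_norm, groups$healthy, groups$onset,
                          n_iter = config$n_iter, seed = config$seed,
                          logfc_cut = config$logfc_cut,
                          fdr_cut = config$fdr_cut) else NULL

    stage <- "select"
    sel <- select_dynamic_cres(ct$ci, pres, groups,
                               min_pi_disease = config$min_pi_disease,
                               max_healthy_ci_fraction = config$max_healthy_ci_fraction,
                               min_ci_delta = config$min_ci_delta)
    clusters <- cluster_cres(tmm$log2_norm[sel, , drop = FALSE],
                             k = config$k, groups = groups)
    modules <- split(clusters$region_id, clusters$cluster)
    mod_scores <- vapply(modules, chromatin_module_score,
                         numeric(ncol(tmm$log2_norm)),
                         mat = tmm$log2_norm, seed = config$seed)

    stage <- "erna"
    sel_regions <- master$regions[master$regions$id %in% sel, , drop = FALSE]
    # truth-side productive set: planted onset+relapse dynamic peaks, mapped
    # onto master ids (the fixture peaks are disjoint so the map is 1:1)
    planted <- sim$peaks[!is.na(sim$peaks$pattern) &
                           sim$peaks$pattern == "onset_relapse", , drop = FALSE]
    map <- GenomicRanges::findOverlaps(.as_gr(planted), .as_gr(master$regions),
                                       minoverlap = 1L)
    planted_ids <- master$regions$id[S4Vectors::subjectHits(map)]
    frags <- simulate_rna_erna(config$cohort_config, sel_regions,
                               sim$gene_model, sim$metadata,
                               productive_ids = intersect(planted_ids, sel_regions$id))
    erna <- erna_quantify(sel_regions, sim$gene_model$exons, frags)
    prod <- productive_cres(erna, groups$healthy, groups$onset,
                            logfc_cut = config$logfc_cut,
                            fdr_cut = config$fdr_cut)

    stage <- "tiers"
    cl12 <- clusters$region_id[clusters$cluster %in% c("C1", "C2")]
    shared_peaks <- sim$peaks$id[!is.na(sim$peaks$pattern) &
                                   sim$peaks$pattern %in% c("onset_relapse", "onset_only")]
    ann <- simulate_annotations(sim, shared_ids = shared_peaks,
                                erna_ids = planted$id)
    tiers <- classify_enhancer_tiers(sel_regions, clusters,
                                     ann$erna_annotation, ann$super_enhancers,
                                     ann$cellline_peaks)
    candidates <- tiers$region_id[tiers$tier == "candidate_productive_enhancer"]

    stage <- "loops"
    cand_regions <- master$regions[master$regions$id %in% candidates, , drop = FALSE]
    annot <- annotate_regions(master, sim$gene_model, config$promoter_window)
    planted_link_df <- data.frame(
      cre_id = cand_regions$id,
      gene_id = annot$nearest_gene[match(cand_regions$id, annot$region_id)],
      stringsAsFactors = FALSE)
    planted_link_df <- planted_link_df[!is.na(planted_link_df$gene_id), , drop = FALSE]
    ld <- simulate_loops_and_dependency(config$cohort_config, cand_regions,
                                        sim$gene_model,
                                        planted_links = planted_link_df,
                                        planted_genes = unique(planted_link_df$gene_id))
    loop_cls <- classify_loops(ld$loops, sim$gene_model, cand_regions,
                               promoter_window = config$promoter_window)
    links <- link_targets(cand_regions, ld$loops, sim$gene_model,
                          proximity_window = config$proximity_window,
                          promoter_window = config$promoter_window)

    stage <- "depmap-rank"
    dep <- dependency_rank(ld$dependency$scores, ld$dependency$lineage,
                           "B-ALL", top_fraction = config$top_fraction)

    gates <- data.frame(
      stage = c("master_list", "selected_dynamic", "clustered",
                "candidate_tier", "linked_genes"),
      n = c(nrow(master$regions), length(sel), nrow(clusters),
            length(candidates),
            length(unique(links$gene_id[links$evidence == "loop"]))))

    list(config = config, sim = sim, master = master, counts = counts,
         clonality = ct, presence = pres, pi = pi_all, composition = comp,
         penetrance_oe = oe, tmm = tmm, differential = diff_ho,
         resampling = null_ho, selected = sel, clusters = clusters,
         module_scores = mod_scores, erna = erna, productive = prod,
         tiers = tiers, annotations = annot, loop_classes = loop_cls,
         links = links, dependency = dep, gates = gates)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  class(res) <- "cre_pipeline"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write all per-stage pipeline artifacts
#'
#' @param x A `cre_pipeline`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(x, out_dir) {
  stopifnot(inherits(x, "cre_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(x$master$regions, file.path(out_dir, "master_list.bed"))
  wt(data.frame(region_id = rownames(x$counts), x$counts, check.names = FALSE),
     "counts.tsv")
  wt(data.frame(region_id = rownames(x$clonality$ci), x$clonality$ci,
                check.names = FALSE), "clonality_index.tsv")
  wt(data.frame(region_id = names(x$pi), pi = x$pi), "penetrance_index.tsv")
  wt(x$composition, "penetrance_composition.tsv")
  wt(x$penetrance_oe, "penetrance_oe.tsv")
  wt(x$differential, "differential_healthy_vs_onset.tsv")
  if (!is.null(x$resampling))
    wt(data.frame(iteration = seq_along(x$resampling$null_counts),
                  n_significant = x$resampling$null_counts), "resampling_null.tsv")
  write_bed(x$master$regions[x$master$regions$id %in% x$selected, ],
            file.path(out_dir, "selected_cres.bed"))
  wt(x$clusters, "clusters.tsv")
  wt(data.frame(sample_id = rownames(x$module_scores), x$module_scores,
                check.names = FALSE), "module_scores.tsv")
  wt(data.frame(region_id = rownames(x$erna$counts), x$erna$counts,
                check.names = FALSE), "erna_counts.tsv")
  wt(x$tiers, "enhancer_tiers.tsv")
  wt(x$loop_classes$loops, "loops_classified.tsv")
  wt(x$links, "enhancer_gene_links.tsv")
  wt(x$dependency, "dependency_rank.tsv")
  wt(x$gates, "stage_gates.tsv")
  invisible(out_dir)
}

#' @export
print.cre_pipeline <- function(x, ...) {
  cat("CRE clonality/penetrance pipeline\n")
  cat("  samples:", nrow(x$sim$metadata), "  master regions:",
      nrow(x$master$regions), "\n")
  cat("  selection funnel:\n")
  for (i in seq_len(nrow(x$gates)))
    cat(sprintf("    %-18s %6d\n", x$gates$stage[i], x$gates$n[i]))
  invisible(x)
}

#' @export
summary.cre_pipeline <- function(object, ...) {
  x <- object
  sig <- sum(x$differential$call != "ns")
  cat("Pipeline summary\n")
  cat("  master regions:", nrow(x$master$regions), "\n")
  cat("  differential healthy vs onset:", sig, "significant (|logFC| >",
      x$config$logfc_cut, ", FDR <", x$config$fdr_cut, ")\n")
  if (!is.null(x$resampling))
    cat("  observed/expected by resampling:", round(x$resampling$oe_ratio, 1), "\n")
  cat("  dynamic CREs selected:", length(x$selected), "\n")
  cat("  cluster sizes:", paste(names(table(x$clusters$cluster)),
                                table(x$clusters$cluster), sep = "=",
                                collapse = ", "), "\n")
  cat("  productive CREs (up at onset):", length(x$productive), "\n")
  cat("  candidate productive enhancers:",
      sum(x$tiers$tier == "candidate_productive_enhancer"), "\n")
  cat("  loop classes:", paste(names(x$loop_classes$class_counts),
                               as.integer(x$loop_classes$class_counts),
                               sep = "=", collapse = ", "), "\n")
  cat("  loop-linked genes:",
      length(unique(x$links$gene_id[x$links$evidence == "loop"])), "\n")
  invisible(x)
}
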