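#' Select dynamic, highly penetrant, healthy-silent CREs
#'
#' A master region is retained when (a) its penetrance over the disease-stage
#' samples (onset, remission, relapse) reaches `min_pi_disease`, (b) it is
#' detected (CI > 0) in at most `max_healthy_ci_fraction` of the healthy
#' samples, and (c) its per-stage median clonal activity changes by at least
#' `min_ci_delta` CI bins between some pair of stages (max minus min of the
#' four stage medians). For criterion (c) the CI is mapped onto an activity
#' scale where 0 means absent and `101 - CI` means present (so 100 is the
#' most enriched percentile): on the raw CI scale an absent region (0) and a
#' top-enriched region (1) would be one bin apart and the most dynamic
#' regions would never satisfy the delta. The thresholds are deliberate
#' stand-ins for an unpublished selection rule and are fully configurable;
#' tightening any of them can only shrink the selected set.
#'
#' @param ci Integer CI matrix (regions x samples), 0 = absent.
#' @param presence Logical presence matrix (same region universe and samples).
#' @param groups Named list mapping stage name (healthy/onset/remission/
#'   relapse) to sample ids.
#' @param min_pi_disease Minimum penetrance over disease samples (default 15).
#' @param max_healthy_ci_fraction Maximum fraction of healthy samples with
#'   CI > 0 (default 1/3).
#' @param min_ci_delta Minimum between-stage range of median CI (default 20).
#' @return Character vector of selected region ids, sorted.
#' @export
select_dynamic_cres <- function(ci, presence, groups,
                                min_pi_disease = 15L,
                                max_healthy_ci_fraction = 1 / 3,
                                min_ci_delta = 20) {
  if (!identical(rownames(ci), rownames(presence)))
    stop("inconsistent region universes between ci and presence")
  disease <- unlist(groups[setdiff(names(groups), "healthy")], use.names = FALSE)
  healthy <- groups[["healthy"]]
  pi_dis <- rowSums(presence[, disease, drop = FALSE])
  healthy_frac <- rowMeans(ci[, healthy, drop = FALSE] > 0L)
  activity <- ifelse(ci > 0L, 101L - ci, 0L)
  dimnames(activity) <- dimnames(ci)
  stage_med <- vapply(groups, function(s)
    apply(activity[, s, drop = FALSE], 1L, stats::median), numeric(nrow(ci)))
  delta <- apply(stage_med, 1L, max) - apply(stage_med, 1L, min)
  keep <- pi_dis >= min_pi_disease &
    healthy_frac <= max_healthy_ci_fraction &
    delta >= min_ci_delta
  sort(rownames(ci)[keep])
}

#' Cluster selected CREs on z-scaled normalized accessibility
#'
#' Rows of the log2 TMM-normalized matrix (restricted to the selected CREs)
#' are z-scaled to mean 0 and sd 1, then clustered by hierarchical
#' agglomerative clustering with Euclidean distance and Ward linkage
#' (`ward.D2`). The tree is cut at `k` clusters (labels C1..Ck) and at 2 for
#' the clade assignment. Constant rows (sd 0 after centering) are dropped with
#' a warning.
#'
#' When `groups` is supplied, clusters are relabeled so that C1, C2, ... are
#' ordered by decreasing disease activity, the mean z-score in onset+relapse
#' samples minus the mean in healthy+remission samples; with the default
#' labeling the onset/relapse-active clusters come first, mirroring the
#' convention that C1 and C2 form the disease-active clade. Without `groups`
#' the labels follow row order of first appearance.
#'
#' @param norm_matrix Numeric matrix (selected regions x samples).
#' @param k Number of clusters (default 4).
#' @param groups Optional named list of stage -> sample ids used to orient the
#'   cluster labels.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"ward.D2"`).
#' @return data.frame `region_id`, `cluster` ("C1".."Ck"), `clade` (1 or 2),
#'   with attribute `"tree"` holding the `hclust` object.
#' @export
cluster_cres <- function(norm_matrix, k = 4L, groups = NULL, linkage = "ward.D2") {
  if (nrow(norm_matrix) < k) stop("need at least k regions to form k clusters")
  m <- norm_matrix
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant row(s) dropped before z-scaling")
    m <- m[sds > 0, , drop = FALSE]
    if (nrow(m) < k) stop("fewer than k non-constant regions")
  }
  z <- t(scale(t(m)))
  tree <- stats::hclust(stats::dist(z, method = "euclidean"), method = linkage)
  raw_k <- stats::cutree(tree, k = k)
  raw_2 <- stats::cutree(tree, k = 2L)
  if (!is.null(groups)) {
    act <- c(unlist(groups[intersect(c("onset", "relapse"), names(groups))],
                    use.names = FALSE))
    rest <- setdiff(colnames(z), act)
    score <- vapply(seq_len(k), function(cl) {
      rows <- raw_k == cl
      mean(z[rows, act, drop = FALSE]) - mean(z[rows, rest, drop = FALSE])
    }, 0)
    ord <- order(-score)
  } else {
    ord <- unique(raw_k)  # order of first appearance in row order
  }
  relab <- integer(k); relab[ord] <- seq_len(k)
  out <- data.frame(
    region_id = rownames(z),
    cluster = paste0("C", relab[raw_k]),
    clade = as.integer(raw_2),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "tree") <- tree
  out
}

#' Chromatin module score per sample or cell
#'
#' For each unit (a sample or a cell: one column of the accessibility matrix),
#' the matrix column is z-scored across regions and the module score is the
#' mean z-score over the module's region set minus the mean over a
#' size-matched background set drawn without replacement from the remaining
#' rows with a fixed seed. Columns with zero spread score 0. The score is
#' invariant to adding a constant to every entry of a unit's column.
#'
#' @param region_set Character vector of module region ids (rows of `mat`).
#' @param mat Numeric accessibility matrix (regions x units), log-normalized.
#' @param background Draw a size-matched background set (default TRUE). With
#'   `FALSE` the score is just the mean module z-score.
#' @param seed Seed for the background draw (default 1).
#' @return Named numeric vector of scores, one per unit.
#' @export
chromatin_module_score <- function(region_set, mat, background = TRUE, seed = 1L) {
  if (length(region_set) == 0L) stop("empty region set")
  if (!all(region_set %in% rownames(mat)))
    stop("region set not contained in matrix rows")
  sds <- apply(mat, 2L, stats::sd)
  z <- scale(mat)                      # per-unit (column) z-scoring
  z[, sds == 0] <- 0
  mod <- colMeans(z[region_set, , drop = FALSE])
  if (background) {
    pool <- setdiff(rownames(mat), region_set)
    if (length(pool) == 0L) stop("no background regions available")
    nbg <- min(length(region_set), length(pool))
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    bg <- sample(pool, nbg)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    mod <- mod - colMeans(z[bg, , drop = FALSE])
  }
  stats::setNames(as.numeric(mod), colnames(mat))
}
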