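#' Per-sample Clonality Index over the master list
#'
#' For one sample, each master region covered by that sample's peaks receives
#' an enrichment Nscore,
#' \deqn{Nscore = ((count / size) \cdot 10^{-6}) \cdot 10^{-3} / total\_mapped\_reads,}
#' where `count` and `size` are the read count and width of the sample's
#' contributing peaks (summed when several peaks hit one region). Present
#' regions are ranked from highest to lowest Nscore and the ordered list is
#' divided into percentiles: the Clonality Index (CI) is
#' `ceiling(100 * rank / n_present)`, ranging from 1 (highest enrichment) to
#' 100 (lowest enrichment). Ties share the bin of their minimum rank (stable
#' order by region id). Master regions absent from the sample get CI 0.
#'
#' The CI is a pure rank statistic: it is invariant to the multiplicative
#' constants in the Nscore and to the sequencing depth of the sample.
#'
#' @param repertoire One sample repertoire (see [read_cohort()]).
#' @param master A `master_list`.
#' @param invert Report `101 - CI` for present regions instead, so that larger
#'   values mean higher enrichment. Default `FALSE` (verbatim orientation).
#' @return data.frame `region_id`, `nscore` (NA when absent), `ci`.
#' @export
clonality_index <- function(repertoire, master, invert = FALSE) {
  stopifnot(inherits(master, "master_list"))
  if (repertoire$total_mapped_reads <= 0) stop("zero total mapped reads")
  p <- repertoire$peaks
  reg <- master$regions
  nscore <- rep(NA_real_, nrow(reg))
  names(nscore) <- reg$id
  if (nrow(p) > 0L) {
    if (any(p$end - p$start <= 0)) stop("zero-size peak")
    hits <- GenomicRanges::findOverlaps(.as_gr(p), .as_gr(reg), minoverlap = 1L)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    cnt <- tapply(p$read_count[qi], si, sum)
    size <- tapply((p$end - p$start)[qi], si, sum)
    idx <- as.integer(names(cnt))
    nscore[idx] <- ((as.numeric(cnt) / as.numeric(size)) * 1e-6) * 1e-3 /
      repertoire$total_mapped_reads
  }
  ci <- integer(nrow(reg))
  present <- which(!is.na(nscore))
  if (length(present)) {
    ns <- nscore[present]
    # ties share the bin of their minimum rank
    min_rank <- rank(-ns, ties.method = "min")
    ci[present] <- as.integer(ceiling(100 * min_rank / length(ns)))
  }
  if (invert) ci[present] <- 101L - ci[present]
  data.frame(region_id = reg$id, nscore = unname(nscore), ci = ci,
             stringsAsFactors = FALSE)
}

#' Clonality Index matrix for a whole cohort
#'
#' Applies [clonality_index()] to every sample and assembles region-by-sample
#' CI and Nscore matrices.
#'
#' @inheritParams clonality_index
#' @param repertoires List of sample repertoires.
#' @return List with integer matrix `ci` and numeric matrix `nscore`
#'   (regions x samples).
#' @export
clonality_table <- function(repertoires, master, invert = FALSE) {
  cols <- lapply(repertoires, clonality_index, master = master, invert = invert)
  ci <- vapply(cols, `[[`, integer(nrow(master$regions)), "ci")
  ns <- vapply(cols, `[[`, numeric(nrow(master$regions)), "nscore")
  rownames(ci) <- rownames(ns) <- master$regions$id
  colnames(ci) <- colnames(ns) <- vapply(repertoires, `[[`, "", "sample_id")
  list(ci = ci, nscore = ns)
}

#' Presence matrix from master-list provenance
#'
#' A region is present in a sample when at least one of that sample's peaks
#' overlaps the master region by >= 1 bp (read from the provenance recorded at
#' master-list construction).
#'
#' @param master A `master_list`.
#' @param sample_ids Sample ids defining column order.
#' @return Logical matrix, regions x samples.
#' @export
presence_matrix <- function(master, sample_ids) {
  stopifnot(inherits(master, "master_list"))
  m <- matrix(FALSE, nrow = nrow(master$regions), ncol = length(sample_ids),
              dimnames = list(master$regions$id, sample_ids))
  pv <- master$provenance
  pv <- pv[pv$sample_id %in% sample_ids, , drop = FALSE]
  m[cbind(pv$region_id, pv$sample_id)] <- TRUE
  m
}

#' Penetrance Index
#'
#' The Penetrance Index (PI) of a master region is the number of samples in
#' scope sharing it, ranging from 1 (private to one sample) to the number of
#' samples in scope. Regions with no in-scope carrier are dropped from the
#' output.
#'
#' @param presence Logical region-by-sample presence matrix (see
#'   [presence_matrix()]).
#' @param scope Character vector of sample ids to count over, or `NULL` for
#'   the full cohort.
#' @return Named integer vector of PI values for regions present in scope.
#' @export
penetrance_index <- function(presence, scope = NULL) {
  if (!is.null(scope)) {
    missing <- setdiff(scope, colnames(presence))
    if (length(missing)) stop("unknown sample(s) in scope: ",
                              paste(missing, collapse = ", "))
    if (length(scope) == 0L) stop("empty scope")
    presence <- presence[, scope, drop = FALSE]
  }
  if (ncol(presence) == 0L) stop("empty scope")
  pi <- rowSums(presence)
  storage.mode(pi) <- "integer"
  pi[pi > 0L]
}

#' Penetrance composition per sample group
#'
#' For each group, among the regions detected in at least one sample of that
#' group, the fraction whose cohort-wide PI falls in each penetrance band:
#' private (PI = 1), low (2 <= PI <= `low_cut`), high (PI > `low_cut`).
#' Band fractions sum to 1 within each group.
#'
#' @param presence Logical region-by-sample presence matrix (full cohort).
#' @param groups Named list mapping group name to sample ids (a partition of
#'   the samples).
#' @param low_cut Upper bound of the low-penetrance band (default 14).
#' @return data.frame `group`, `band`, `n_regions`, `fraction`.
#' @export
penetrance_composition <- function(presence, groups, low_cut = 14L) {
  pi_all <- rowSums(presence)
  out <- list()
  for (g in names(groups)) {
    det <- rowSums(presence[, groups[[g]], drop = FALSE]) > 0L
    if (!any(det)) stop("group '", g, "' has zero detected regions")
    pig <- pi_all[det]
    n <- c(private = sum(pig == 1L),
           low = sum(pig >= 2L & pig <= low_cut),
           high = sum(pig > low_cut))
    out[[g]] <- data.frame(group = g, band = names(n), n_regions = as.integer(n),
                           fraction = as.numeric(n) / sum(n),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Observed/expected region counts by penetrance between two groups
#'
#' For each cohort-wide PI value, the observed number of regions detected in
#' group A at that PI is compared with the count expected under proportional
#' allocation: the pooled per-PI counts (regions detected in A plus regions
#' detected in B, with multiplicity) scaled by A's overall detected-region
#' share. PI values with expected count 0 are reported as `NA` (missing, not
#' 0).
#'
#' @param presence Logical region-by-sample presence matrix (full cohort; PI
#'   is computed cohort-wide).
#' @param groupA,groupB Sample id vectors (non-empty, disjoint groups).
#' @return data.frame `pi`, `observed_A`, `expected_A`, `oe` for every PI
#'   value realized in the pooled detected regions.
#' @export
penetrance_oe <- function(presence, groupA, groupB) {
  if (length(groupA) == 0L || length(groupB) == 0L) stop("empty group")
  pi_all <- rowSums(presence)
  detA <- rowSums(presence[, groupA, drop = FALSE]) > 0L
  detB <- rowSums(presence[, groupB, drop = FALSE]) > 0L
  shareA <- sum(detA) / (sum(detA) + sum(detB))
  pis <- sort(unique(pi_all[detA | detB]))
  obs <- vapply(pis, function(p) sum(detA & pi_all == p), 0)
  pooled <- vapply(pis, function(p) sum(detA & pi_all == p) + sum(detB & pi_all == p), 0)
  expd <- pooled * shareA
  oe <- ifelse(expd == 0, NA_real_, obs / expd)
  data.frame(pi = as.integer(pis), observed_A = as.integer(obs),
             expected_A = expd, oe = oe)
}
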