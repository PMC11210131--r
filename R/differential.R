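#' TMM normalization of a count matrix
#'
#' Trimmed mean of M-values scaling. The reference sample is the one whose
#' 75th-percentile count fraction is closest to the mean across samples. For
#' each sample, per-region log ratios M and log abundances A against the
#' reference are computed over regions with nonzero counts in both; the upper
#' and lower 30% of M-values and 5% of A-values are trimmed; the scale factor
#' is 2 to the power of the weighted mean of the remaining M-values with
#' inverse asymptotic (delta-method binomial) variance weights. Factors are
#' rescaled to geometric mean 1. Normalized values are
#' `log2((count + 0.5) / (library_size * factor) * 1e6)` (log2 of
#' effective-library CPM with a 0.5 pseudocount).
#'
#' @param counts Non-negative integer matrix, regions x samples (>= 2
#'   samples).
#' @param lib_sizes Optional library sizes; default column sums.
#' @param logratio_trim,abundance_trim Two-sided trim fractions for M and A
#'   (defaults 0.3 and 0.05).
#' @return List with `factors` (named per-sample scale factors), `lib_sizes`,
#'   and `log2_norm` (numeric matrix of log2 normalized values).
#' @export
tmm_normalize <- function(counts, lib_sizes = NULL,
                          logratio_trim = 0.3, abundance_trim = 0.05) {
  if (ncol(counts) < 2L) stop("TMM needs >= 2 samples")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  zero_col <- colSums(counts > 0) == 0L
  if (any(zero_col))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero_col], collapse = ", "))
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j], 0.75, names = FALSE) / lib_sizes[j], 0)
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]; nr <- lib_sizes[ref]
  fac <- vapply(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]; n <- lib_sizes[j]
    keep0 <- y > 0 & yr > 0
    if (!any(keep0)) return(1)
    m <- log2((y[keep0] / n) / (yr[keep0] / nr))
    a <- 0.5 * log2((y[keep0] / n) * (yr[keep0] / nr))
    w <- 1 / ((n - y[keep0]) / (n * y[keep0]) + (nr - yr[keep0]) / (nr * yr[keep0]))
    k <- length(m)
    loM <- floor(k * logratio_trim) + 1; hiM <- k + 1 - loM
    loA <- floor(k * abundance_trim) + 1; hiA <- k + 1 - loA
    rm_ <- rank(m); ra_ <- rank(a)
    keep <- rm_ >= loM & rm_ <= hiM & ra_ >= loA & ra_ <= hiA
    if (!any(keep)) return(1)
    f <- sum(w[keep] * m[keep]) / sum(w[keep])
    if (!is.finite(f) || abs(f) < 1e-10) f <- 0
    2^f
  }, 0)
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(counts)
  eff <- lib_sizes * fac
  log2_norm <- log2(sweep(counts + 0.5, 2L, eff, "/") * 1e6)
  dimnames(log2_norm) <- dimnames(counts)
  list(factors = fac, lib_sizes = lib_sizes, log2_norm = log2_norm)
}

#' Differential accessibility between two sample groups
#'
#' Per-region Welch two-sample t statistic on log2-normalized accessibility,
#' two-sided p-values, Benjamini-Hochberg adjustment across regions, and calls
#' at log fold-change and FDR thresholds. The log fold change is
#' `mean(groupB) - mean(groupA)`; a region is called `up_in_B` when
#' `log_fc > logfc_cut` and `fdr < fdr_cut`, `up_in_A` when
#' `log_fc < -logfc_cut` and `fdr < fdr_cut`, otherwise `ns`.
#'
#' @param norm_matrix Numeric matrix of log2-normalized values (regions x
#'   samples), e.g. `tmm_normalize(counts)$log2_norm`.
#' @param groupA,groupB Disjoint sample id vectors, each of size >= 2.
#' @param logfc_cut Absolute log2 fold-change threshold (default 0.7).
#' @param fdr_cut FDR threshold (default 0.05).
#' @return data.frame `region_id`, `log_fc`, `mean_log`, `p_value`, `fdr`,
#'   `call`.
#' @export
differential_accessibility <- function(norm_matrix, groupA, groupB,
                                       logfc_cut = 0.7, fdr_cut = 0.05) {
  if (length(intersect(groupA, groupB))) stop("groups overlap")
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs >= 2 samples")
  missing <- setdiff(c(groupA, groupB), colnames(norm_matrix))
  if (length(missing)) stop("unknown sample(s): ", paste(missing, collapse = ", "))
  xa <- norm_matrix[, groupA, drop = FALSE]
  xb <- norm_matrix[, groupB, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  lfc <- mb - ma
  tt <- lfc / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate rows: zero variance in both groups
  degen <- se2 == 0
  p[degen] <- ifelse(lfc[degen] == 0, 1, 0)
  fdr <- stats::p.adjust(p, method = "BH")
  call <- rep("ns", length(p))
  call[lfc > logfc_cut & fdr < fdr_cut] <- "up_in_B"
  call[lfc < -logfc_cut & fdr < fdr_cut] <- "up_in_A"
  data.frame(
    region_id = if (!is.null(rownames(norm_matrix))) rownames(norm_matrix)
                else as.character(seq_along(p)),
    log_fc = lfc, mean_log = (ma + mb) / 2, p_value = p, fdr = fdr,
    call = call, stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Expected-by-chance differential peaks via cohort resampling
#'
#' Repeats the differential analysis on pseudo-groups drawn from the cohort:
#' in each iteration, sample labels are resampled without replacement into two
#' disjoint groups whose sizes match the true comparison, the differential
#' test is re-run, and the number of significant regions is recorded. The
#' observed-to-expected ratio is the significant-region count under the true
#' labels divided by the mean count over the resampled null.
#'
#' @param norm_matrix Log2-normalized matrix (regions x samples).
#' @param groupA,groupB True group sample ids (sizes define the pseudo-group
#'   sizes).
#' @param n_iter Number of resampling iterations (default 100).
#' @param seed Integer seed (mandatory, for reproducible resampling).
#' @param logfc_cut,fdr_cut Significance thresholds passed to
#'   [differential_accessibility()].
#' @return Object of class `resampling_null`: list with `observed`,
#'   `null_counts` (length `n_iter`), `oe_ratio`, `n_iter`, `thresholds`.
#' @export
resampling_expected <- function(norm_matrix, groupA, groupB, n_iter = 100,
                                seed, logfc_cut = 0.7, fdr_cut = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  nA <- length(groupA); nB <- length(groupB)
  samples <- colnames(norm_matrix)
  if (nA + nB > length(samples)) stop("group sizes exceed cohort")
  obs <- sum(differential_accessibility(norm_matrix, groupA, groupB,
                                        logfc_cut, fdr_cut)$call != "ns")
  set.seed(seed)
  null_counts <- vapply(seq_len(n_iter), function(i) {
    lab <- sample(samples, nA + nB)
    sum(differential_accessibility(norm_matrix, lab[seq_len(nA)],
                                   lab[nA + seq_len(nB)],
                                   logfc_cut, fdr_cut)$call != "ns")
  }, 0L)
  out <- list(observed = obs, null_counts = null_counts,
              oe_ratio = if (mean(null_counts) == 0) Inf else obs / mean(null_counts),
              n_iter = n_iter,
              thresholds = c(logfc_cut = logfc_cut, fdr_cut = fdr_cut))
  class(out) <- "resampling_null"
  out
}

#' @export
print.resampling_null <- function(x, ...) {
  cat("Resampling differential null (", x$n_iter, " iterations)\n", sep = "")
  cat("  observed significant regions:", x$observed, "\n")
  cat("  expected by chance (mean):", round(mean(x$null_counts), 2), "\n")
  cat("  observed/expected ratio:", round(x$oe_ratio, 2), "\n")
  invisible(x)
}

#' Stage-wise group comparison of a score
#'
#' Generic utility comparing a per-region score (for example the Clonality
#' Index of selected CREs) across stage groups with either a Kruskal-Wallis
#' test followed by pairwise Wilcoxon tests, or pairwise Welch t-tests.
#'
#' @param values Numeric vector of scores.
#' @param groups Factor or character vector of group labels, same length.
#' @param method `"kruskal"` (default) or `"t"`.
#' @return List with `global_p` (Kruskal-Wallis p, or NA for method "t") and
#'   `pairwise` (matrix of BH-adjusted pairwise p-values).
#' @export
compare_groups <- function(values, groups, method = c("kruskal", "t")) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  if (method == "kruskal") {
    gp <- stats::kruskal.test(values, groups)$p.value
    pw <- stats::pairwise.wilcox.test(values, groups, p.adjust.method = "BH")$p.value
  } else {
    gp <- NA_real_
    pw <- stats::pairwise.t.test(values, groups, pool.sd = FALSE,
                                 p.adjust.method = "BH")$p.value
  }
  list(global_p = gp, pairwise = pw)
}
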