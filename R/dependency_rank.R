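#' Rank genes by lineage-restricted dependency
#'
#' For each gene, cell lines are sorted ascending by dependency score (lower =
#' more dependent, as in CRISPR-knockout fitness scores) and the most-dependent
#' set is taken: either the `top_k` lines or the top `top_fraction` of the
#' lines scored for that gene. Ties at the boundary are included, so the set
#' may exceed its nominal size. The gene's statistic is the number of
#' lineage-of-interest lines in that set; genes are ranked by this count
#' (descending), ties broken by the mean score of the lineage-of-interest
#' lines (ascending, i.e. more dependent first). Missing scores exclude a
#' line from that gene's ranking.
#'
#' @param scores Numeric matrix, genes x cell lines.
#' @param lineage Named character vector mapping cell line to lineage label.
#' @param lineage_of_interest Lineage label(s) to count (e.g. `"B-ALL"`).
#' @param top_k Size of the most-dependent set (mutually exclusive with
#'   `top_fraction`).
#' @param top_fraction Fraction of scored lines in the set (default 0.10 when
#'   neither argument is given).
#' @return data.frame `gene_id`, `n_lineage_top`, `top_set_size`,
#'   `mean_lineage_score`, `rank`, sorted by rank.
#' @export
dependency_rank <- function(scores, lineage, lineage_of_interest,
                            top_k = NULL, top_fraction = NULL) {
  if (!is.null(top_k) && !is.null(top_fraction))
    stop("supply exactly one of top_k or top_fraction")
  if (is.null(top_k) && is.null(top_fraction)) top_fraction <- 0.10
  lines <- colnames(scores)
  if (!all(lines %in% names(lineage)))
    stop("lineage label missing for some cell lines")
  known <- unique(lineage)
  bad <- setdiff(lineage_of_interest, known)
  if (length(bad))
    stop("unknown lineage label: ", paste(bad, collapse = ", "))
  if (!is.null(top_k) && top_k > length(lines))
    stop("top_k exceeds the number of cell lines")
  interest <- lines[lineage[lines] %in% lineage_of_interest]
  n_genes <- nrow(scores)
  cnt <- integer(n_genes); setsize <- integer(n_genes); msc <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    x <- scores[i, ]
    ok <- !is.na(x)
    xs <- x[ok]
    k <- if (!is.null(top_k)) min(top_k, length(xs)) else
      max(1L, ceiling(top_fraction * length(xs)))
    thr <- sort(xs, partial = k)[k]
    top <- names(xs)[xs <= thr]      # boundary ties included
    cnt[i] <- length(intersect(top, interest))
    setsize[i] <- length(top)
    msc[i] <- if (length(intersect(names(xs), interest)))
      mean(xs[intersect(names(xs), interest)]) else NA_real_
  }
  out <- data.frame(
    gene_id = rownames(scores), n_lineage_top = cnt, top_set_size = setsize,
    mean_lineage_score = msc, stringsAsFactors = FALSE)
  ord <- order(-out$n_lineage_top, out$mean_lineage_score, out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a dependency-score matrix with lineage labels
#'
#' @param scores_path TSV of genes (rows) x cell lines (columns); first column
#'   `gene_id`.
#' @param lineage_path TSV with columns `cell_line`, `lineage`.
#' @return List with `scores` matrix and `lineage` named vector.
#' @export
read_dependency <- function(scores_path, lineage_path) {
  tab <- utils::read.table(scores_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  lin <- utils::read.table(lineage_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  list(scores = m, lineage = stats::setNames(lin$lineage, lin$cell_line))
}
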