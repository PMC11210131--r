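#' Quantify eRNA over the non-exonic portion of CREs
#'
#' For each CRE the eligible intervals are the CRE bases not covered by any
#' annotated exon (base-level subtraction of the exon union). The eRNA count
#' for a (CRE, sample) pair is the number of RNA fragments overlapping the
#' CRE's eligible intervals by >= 1 bp; fragments touching only exonic bases
#' of the CRE are not counted. CPM values are computed against each sample's
#' total fragment count.
#'
#' @param cres data.frame of CRE regions (`chrom`, `start`, `end`, `id`),
#'   disjoint.
#' @param exons data.frame of exon intervals (`chrom`, `start`, `end`).
#' @param rna_fragments Named list (by sample id) of fragment data.frames
#'   (`chrom`, `start`, `end`).
#' @return List with `counts` (integer CRE x sample matrix), `cpm`,
#'   `eligible_length` (named bp vector; 0 for fully exonic CREs).
#' @export
erna_quantify <- function(cres, exons, rna_fragments) {
  .check_regions(cres, "cres")
  cre_gr <- .as_gr(cres)
  elig <- cre_gr
  if (nrow(exons) > 0L) {
    .check_regions(exons, "exons")
    exu <- GenomicRanges::reduce(.as_gr(exons))
    elig <- GenomicRanges::setdiff(cre_gr, exu, ignore.strand = TRUE)
  }
  # map eligible pieces back to their CRE; setdiff reduces its input, so a
  # piece can span adjacent CREs and must be re-intersected with each one
  hits <- GenomicRanges::findOverlaps(elig, cre_gr, minoverlap = 1L)
  piece_cre <- cres$id[S4Vectors::subjectHits(hits)]
  elig <- GenomicRanges::pintersect(elig[S4Vectors::queryHits(hits)],
                                    cre_gr[S4Vectors::subjectHits(hits)])
  el_len <- stats::setNames(rep(0, nrow(cres)), cres$id)
  if (length(elig)) {
    w <- tapply(GenomicRanges::width(elig), piece_cre, sum)
    el_len[names(w)] <- as.numeric(w)
  }
  counts <- matrix(0L, nrow = nrow(cres), ncol = length(rna_fragments),
                   dimnames = list(cres$id, names(rna_fragments)))
  for (s in names(rna_fragments)) {
    fr <- rna_fragments[[s]]
    if (is.null(fr) || nrow(fr) == 0L || length(elig) == 0L) next
    fh <- GenomicRanges::findOverlaps(.as_gr(fr), elig, minoverlap = 1L)
    if (length(fh) == 0L) next
    # one fragment counts once per CRE even when it spans several pieces
    pairs <- unique(data.frame(f = S4Vectors::queryHits(fh),
                               cre = piece_cre[S4Vectors::subjectHits(fh)]))
    tab <- table(pairs$cre)
    counts[names(tab), s] <- as.integer(tab)
  }
  totals <- vapply(rna_fragments, function(fr) if (is.null(fr)) 0L else nrow(fr), 0L)
  cpm <- sweep(counts, 2L, pmax(totals, 1L), "/") * 1e6
  list(counts = counts, cpm = cpm, eligible_length = el_len)
}

#' CREs significantly more eRNA-productive in one group
#'
#' Runs the differential test of [differential_accessibility()] on
#' log2-CPM-transformed eRNA counts and returns the CREs called up in
#' `groupB` (typically the onset group).
#'
#' @param erna An eRNA quantification from [erna_quantify()] (or a count
#'   matrix).
#' @param groupA,groupB Sample id vectors (>= 2 samples each).
#' @param logfc_cut,fdr_cut Thresholds (defaults 0.7 and 0.05).
#' @return Character vector of productive CRE ids, with the full differential
#'   table in attribute `"table"`.
#' @export
productive_cres <- function(erna, groupA, groupB, logfc_cut = 0.7, fdr_cut = 0.05) {
  counts <- if (is.list(erna)) erna$counts else erna
  if (length(groupB) == 0L) stop("empty groupB")
  lib <- pmax(colSums(counts), 1L)
  logcpm <- log2(sweep(counts + 0.5, 2L, lib, "/") * 1e6)
  res <- differential_accessibility(logcpm, groupA, groupB, logfc_cut, fdr_cut)
  out <- res$region_id[res$call == "up_in_B"]
  attr(out, "table") <- res
  out
}

#' Overlap frequency of target regions against feature sets
#'
#' For each named feature set, the fraction of target regions with >= 1 bp
#' overlap; the union row reports the fraction overlapped by any of the sets.
#'
#' @param targets data.frame of target regions.
#' @param feature_sets Named list of region data.frames.
#' @param combinations Optional list of character vectors naming feature-set
#'   combinations whose union frequency should also be reported.
#' @return data.frame `feature`, `n_overlap`, `frequency`.
#' @export
overlap_frequency <- function(targets, feature_sets, combinations = NULL) {
  if (nrow(targets) == 0L) stop("empty target set")
  .check_regions(targets, "targets")
  hits <- lapply(feature_sets, function(fs) .overlaps_any(targets, fs))
  rows <- lapply(names(feature_sets), function(nm)
    data.frame(feature = nm, n_overlap = sum(hits[[nm]]),
               frequency = mean(hits[[nm]]), stringsAsFactors = FALSE))
  combos <- c(list(union = names(feature_sets)), combinations)
  for (i in seq_along(combos)) {
    nm <- names(combos)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste(combos[[i]], collapse = "+")
    any_hit <- Reduce(`|`, hits[combos[[i]]])
    rows[[length(rows) + 1L]] <- data.frame(
      feature = nm, n_overlap = sum(any_hit), frequency = mean(any_hit),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify CREs into enhancer tiers
#'
#' Sets per-CRE flags by >= 1 bp overlap with an eRNA annotation catalog, a
#' super-enhancer catalog, and a cell-line peak set, then derives a tier: a
#' CRE is a "candidate_productive_enhancer" when it belongs to the
#' disease-active clusters (C1 or C2) and is shared with the cell line;
#' otherwise "super_enhancer" when flagged in the super-enhancer catalog,
#' "erna_annotated" when in the eRNA catalog, else "unclassified".
#'
#' @param cres data.frame of CRE regions with an `id` column.
#' @param clusters data.frame `region_id`, `cluster` from [cluster_cres()].
#' @param erna_annotation,super_enhancers,cellline_peaks Region data.frames
#'   (any may be empty).
#' @param active_clusters Clusters gating the candidate tier (default C1, C2).
#' @return data.frame `region_id`, `cluster`, `erna_annotated`,
#'   `super_enhancer`, `cellline_shared`, `tier`; per-tier counts in
#'   attribute `"tier_counts"`.
#' @export
classify_enhancer_tiers <- function(cres, clusters, erna_annotation,
                                    super_enhancers, cellline_peaks,
                                    active_clusters = c("C1", "C2")) {
  cl <- stats::setNames(clusters$cluster, clusters$region_id)
  if (!all(cres$id %in% names(cl))) stop("cluster labels missing for some CREs")
  flags <- data.frame(
    region_id = cres$id,
    cluster = unname(cl[cres$id]),
    erna_annotated = .overlaps_any(cres, erna_annotation),
    super_enhancer = .overlaps_any(cres, super_enhancers),
    cellline_shared = .overlaps_any(cres, cellline_peaks),
    stringsAsFactors = FALSE
  )
  flags$tier <- ifelse(
    flags$cluster %in% active_clusters & flags$cellline_shared,
    "candidate_productive_enhancer",
    ifelse(flags$super_enhancer, "super_enhancer",
           ifelse(flags$erna_annotated, "erna_annotated", "unclassified")))
  attr(flags, "tier_counts") <- table(flags$tier)
  flags
}
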