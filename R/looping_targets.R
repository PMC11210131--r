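#' Read chromatin loops from a BEDPE file
#'
#' Anchors are 0-based half-open; columns beyond the six anchor coordinates
#' are kept as `name`, `score` and further opaque tag columns when present.
#'
#' @param path BEDPE file path.
#' @param resolution Optional resolution tag (bp) recorded on every loop.
#' @return data.frame `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`,
#'   plus optional `name`, `score`, `resolution`.
#' @export
read_bedpe <- function(path, resolution = NA_integer_) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stop("BEDPE needs >= 6 columns")
  names(tab)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (ncol(tab) >= 7L) names(tab)[7] <- "name"
  if (ncol(tab) >= 8L) names(tab)[8] <- "score"
  tab$resolution <- resolution
  tab
}

#' Write loops as BEDPE
#' @param loops Loop data.frame (see [read_bedpe()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  extra <- intersect(c("name", "score"), names(loops))
  utils::write.table(loops[c(cols, extra)], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.promoter_windows <- function(gene_model, promoter_window = 5000) {
  g <- gene_model$genes
  data.frame(chrom = g$chrom,
             start = pmax(0L, g$tss - promoter_window),
             end = g$tss + promoter_window,
             id = g$gene_id, stringsAsFactors = FALSE)
}

#' Classify loops by anchor annotation and distance
#'
#' Each anchor is tested for >= 1 bp overlap with a promoter window
#' (TSS +/- `promoter_window`); an anchor overlapping both a promoter window
#' and a CRE counts as promoter. Loops are labeled promoter-promoter,
#' promoter-CRE, or CRE-CRE (the three labels partition all loops). The
#' distance between anchor midpoints is binned with a dedicated < 50 kb bin;
#' trans-chromosomal loops are labeled but excluded from the histogram.
#'
#' @param loops Loop data.frame (see [read_bedpe()]).
#' @param gene_model Gene model (for promoter windows).
#' @param cres data.frame of CRE regions (annotation only; non-promoter
#'   anchors are treated as CRE anchors regardless).
#' @param promoter_window Promoter half-window bp (default 5000).
#' @param distance_breaks Histogram bin edges in bp (first bin < 50 kb by
#'   default).
#' @return List with `loops` (input plus `class` and `distance` columns),
#'   `class_counts` (named), and `distance_histogram` (data.frame `bin`, `n`).
#' @export
classify_loops <- function(loops, gene_model, cres, promoter_window = 5000,
                           distance_breaks = c(0, 5e4, 1e5, 5e5, 1e6, Inf)) {
  prom <- .promoter_windows(gene_model, promoter_window)
  a1 <- data.frame(chrom = loops$chrom1, start = loops$start1, end = loops$end1)
  a2 <- data.frame(chrom = loops$chrom2, start = loops$start2, end = loops$end2)
  p1 <- .overlaps_any(a1, prom)
  p2 <- .overlaps_any(a2, prom)
  cls <- ifelse(p1 & p2, "promoter-promoter",
                ifelse(p1 | p2, "promoter-CRE", "CRE-CRE"))
  cis <- loops$chrom1 == loops$chrom2
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  dist <- ifelse(cis, abs(mid2 - mid1), NA_real_)
  labs <- paste0("<", format(distance_breaks[-1], big.mark = "", scientific = FALSE,
                             trim = TRUE))
  labs[length(labs)] <- paste0(">=", format(distance_breaks[length(distance_breaks) - 1],
                                            scientific = FALSE, trim = TRUE))
  bin <- cut(dist[cis], breaks = distance_breaks, labels = labs, right = FALSE)
  out <- loops
  out$class <- cls
  out$distance <- dist
  list(
    loops = out,
    class_counts = table(factor(cls, levels = c("promoter-promoter",
                                                "promoter-CRE", "CRE-CRE"))),
    distance_histogram = as.data.frame(table(bin), responseName = "n")
  )
}

#' Assign enhancer-gene targets from loops with a proximity fallback
#'
#' For each CRE, loop evidence links it to every gene whose promoter window
#' (TSS +/- `promoter_window`) overlaps one loop anchor while the other anchor
#' overlaps the CRE (>= 1 bp each; an anchor spanning two promoters links both
#' genes). CREs without loop evidence fall back to proximity: a link to every
#' gene with |CRE midpoint - TSS| <= `proximity_window`. When both kinds of
#' evidence exist for the same (CRE, gene) pair, the loop link is reported.
#' CREs with neither are reported with gene `NA` and evidence "none".
#'
#' @param cres data.frame of CRE regions with `id`.
#' @param loops Loop data.frame.
#' @param gene_model Gene model.
#' @param proximity_window Proximity fallback window bp (default 10000).
#' @param promoter_window Promoter half-window bp for loop anchors (default
#'   5000).
#' @return data.frame `cre_id`, `gene_id`, `evidence` (loop/proximity/none),
#'   `distance` (|CRE midpoint - TSS| bp, NA when unlinked).
#' @export
link_targets <- function(cres, loops, gene_model, proximity_window = 10000,
                         promoter_window = 5000) {
  .check_regions(cres, "cres")
  genes <- gene_model$genes
  prom <- .promoter_windows(gene_model, promoter_window)
  mid <- (cres$start + cres$end) / 2
  links <- list()
  if (!is.null(loops) && nrow(loops) > 0L) {
    a1 <- data.frame(chrom = loops$chrom1, start = loops$start1, end = loops$end1)
    a2 <- data.frame(chrom = loops$chrom2, start = loops$start2, end = loops$end2)
    cre_gr <- .as_gr(cres); prom_gr <- .as_gr(prom)
    for (side in 1:2) {
      ca <- if (side == 1) a1 else a2
      ga <- if (side == 1) a2 else a1
      ch <- GenomicRanges::findOverlaps(.as_gr(ca), cre_gr, minoverlap = 1L)
      gh <- GenomicRanges::findOverlaps(.as_gr(ga), prom_gr, minoverlap = 1L)
      cdf <- data.frame(loop = S4Vectors::queryHits(ch),
                        cre = S4Vectors::subjectHits(ch))
      gdf <- data.frame(loop = S4Vectors::queryHits(gh),
                        gene = S4Vectors::subjectHits(gh))
      mm <- merge(cdf, gdf, by = "loop")
      if (nrow(mm)) {
        links[[length(links) + 1L]] <- data.frame(
          cre_id = cres$id[mm$cre],
          gene_id = prom$id[mm$gene],
          evidence = "loop",
          distance = abs(mid[mm$cre] - genes$tss[match(prom$id[mm$gene], genes$gene_id)]),
          stringsAsFactors = FALSE)
      }
    }
  }
  loop_links <- if (length(links)) unique(do.call(rbind, links)) else
    data.frame(cre_id = character(), gene_id = character(),
               evidence = character(), distance = numeric())
  looped <- unique(loop_links$cre_id)
  prox <- list()
  for (i in which(!(cres$id %in% looped))) {
    gi <- which(genes$chrom == cres$chrom[i] &
                  abs(genes$tss - mid[i]) <= proximity_window)
    if (length(gi)) {
      prox[[length(prox) + 1L]] <- data.frame(
        cre_id = cres$id[i], gene_id = genes$gene_id[gi],
        evidence = "proximity", distance = abs(genes$tss[gi] - mid[i]),
        stringsAsFactors = FALSE)
    } else {
      prox[[length(prox) + 1L]] <- data.frame(
        cre_id = cres$id[i], gene_id = NA_character_,
        evidence = "none", distance = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- rbind(loop_links, if (length(prox)) do.call(rbind, prox))
  out <- out[order(out$cre_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
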