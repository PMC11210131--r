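# Shared fixtures and naive reference implementations used as oracles.

# random disjoint-or-not peak set on one or two chromosomes
rand_regions <- function(n, chroms = c("chrA", "chrB"), max_pos = 1e5,
                         max_width = 500) {
  st <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = st, end = st + sample.int(max_width, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

make_repertoire <- function(sample_id, peaks, stage = "onset",
                            total = 1e6L, counts = NULL) {
  peaks$id <- if (is.null(peaks$id)) paste0(sample_id, "_p", seq_len(nrow(peaks))) else peaks$id
  peaks$read_count <- if (is.null(counts)) rep(10L, nrow(peaks)) else counts
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  rownames(peaks) <- NULL
  list(sample_id = sample_id, stage = stage, total_mapped_reads = total,
       peaks = peaks)
}

# naive transitive union-merge of intervals (>= 1 bp overlap): sort by start
# within chromosome, then a linear sweep (book-ended intervals stay separate)
naive_union <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    iv <- df[df$chrom == ch, c("start", "end")]
    iv <- iv[order(iv$start, iv$end), ]
    cur <- c(iv$start[1], iv$end[1])
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] < cur[2]) {
        cur[2] <- max(cur[2], iv$end[i])
      } else {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur[1], end = cur[2])
        cur <- c(iv$start[i], iv$end[i])
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur[1], end = cur[2])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), ]
}

# naive >= 1 bp overlap test between one interval and a set
naive_overlaps <- function(chrom, start, end, set) {
  any(set$chrom == chrom & set$start < end & set$end > start)
}

naive_overlap_count <- function(region, frags) {
  sum(frags$chrom == region$chrom & frags$start < region$end &
        frags$end > region$start)
}

# naive loop classifier: promoter = anchor overlapping any TSS +/- window
naive_loop_class <- function(loop, tss_df, window) {
  prom <- function(ch, s, e) any(tss_df$chrom == ch &
                                   pmax(0, tss_df$tss - window) < e &
                                   (tss_df$tss + window) > s)
  p1 <- prom(loop$chrom1, loop$start1, loop$end1)
  p2 <- prom(loop$chrom2, loop$start2, loop$end2)
  if (p1 && p2) "promoter-promoter" else if (p1 || p2) "promoter-CRE" else "CRE-CRE"
}

# naive dependency count: sort, threshold at k-th value, include ties
naive_dep_count <- function(x, interest, k) {
  x <- x[!is.na(x)]
  thr <- sort(x)[min(k, length(x))]
  top <- names(x)[x <= thr]
  length(intersect(top, interest))
}

# adjusted Rand index (closed form over the contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}

tiny_gene_model <- function(tss = c(5000L, 40000L), chrom = "chrA",
                            strand = NULL) {
  n <- length(tss)
  if (is.null(strand)) strand <- rep("+", n)
  list(
    genes = data.frame(gene_id = paste0("G", seq_len(n)), chrom = chrom,
                       strand = strand, tss = tss, stringsAsFactors = FALSE),
    exons = data.frame(gene_id = paste0("G", seq_len(n)), chrom = chrom,
                       start = tss, end = tss + 200L, stringsAsFactors = FALSE)
  )
}
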