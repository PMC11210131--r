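#' Read a cohort of per-sample peak files with metadata
#'
#' Loads one BED peak file per sample together with a metadata table and
#' returns a list of sample repertoires: the per-sample peak sets (with read
#' counts) on which the clonality scoring operates.
#'
#' @param peak_paths Character vector of BED3/BED6/narrowPeak file paths, one
#'   per sample, in the same order as the rows of the metadata table.
#' @param metadata_path Path to a TSV with columns `sample_id`, `stage`
#'   (one of healthy/onset/remission/relapse) and `total_mapped_reads`.
#' @param count_column Which BED column carries the per-peak read count:
#'   `"score"` (column 5, the default for the BED6 files this package writes)
#'   or `"signal"` (column 7, the narrowPeak signal slot).
#'
#' @return A list of repertoires; each element is a list with `sample_id`,
#'   `stage`, `total_mapped_reads` and `peaks` (a data.frame with `chrom`,
#'   `start`, `end`, `id`, `read_count`, sorted by chrom then start;
#'   coordinates 0-based half-open).
#' @export
read_cohort <- function(peak_paths, metadata_path, count_column = c("score", "signal")) {
  count_column <- match.arg(count_column)
  if (length(peak_paths) == 0L) stop("empty cohort")
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "total_mapped_reads")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  if (nrow(meta) != length(peak_paths))
    stop("metadata has ", nrow(meta), " rows but ", length(peak_paths),
         " peak files were given")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  .check_stage(meta$stage)
  if (any(meta$total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")

  reps <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    peaks <- read_peak_bed(peak_paths[i], count_column = count_column)
    reps[[i]] <- list(
      sample_id = meta$sample_id[i],
      stage = meta$stage[i],
      total_mapped_reads = meta$total_mapped_reads[i],
      peaks = peaks
    )
  }
  names(reps) <- meta$sample_id
  reps
}

#' Read a BED peak file
#'
#' Strict line-validated reader for BED3/BED6/narrowPeak peak calls; malformed
#' lines are rejected with their line numbers. Columns beyond the requested
#' count column are ignored.
#'
#' @param path File path.
#' @param count_column `"score"` (BED column 5) or `"signal"` (narrowPeak
#'   column 7); missing columns yield a read count of 0.
#' @return data.frame with `chrom`, `start`, `end`, `id`, `read_count`,
#'   sorted by (chrom, start).
#' @export
read_peak_bed <- function(path, count_column = c("score", "signal")) {
  count_column <- match.arg(count_column)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      id = character(), read_count = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_cols <- 3L
  bad <- which(nf < min_cols)
  starts <- suppressWarnings(as.integer(vapply(fields, function(f) f[2], "")))
  ends <- suppressWarnings(as.integer(vapply(fields, function(f) f[3], "")))
  bad <- sort(unique(c(bad, which(is.na(starts) | is.na(ends) | starts >= ends))))
  if (length(bad))
    stop("malformed BED line(s) in ", path, " at line number(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  cidx <- if (count_column == "score") 4L + 1L else 7L
  counts <- vapply(fields, function(f) {
    if (length(f) >= cidx) {
      v <- suppressWarnings(as.numeric(f[cidx]))
      if (is.na(v)) 0 else v
    } else 0
  }, numeric(1))
  ids <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 4L && nzchar(f[4])) f[4] else paste0("peak_", i)
  }, "")
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = starts, end = ends, id = ids,
    read_count = as.integer(round(counts)),
    stringsAsFactors = FALSE
  )
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Build the cohort master list of accessible regions
#'
#' Single-linkage union-merge of all sample peaks: peaks overlapping by at
#' least `min_overlap` bp merge transitively into one master region, giving a
#' disjoint, sorted, cohort-wide region set with stable identifiers.
#' Provenance records which sample peaks contributed to each region.
#'
#' @param repertoires List of sample repertoires from [read_cohort()] or
#'   [simulate_cohort()].
#' @param min_overlap Minimum overlap (bp) for two peaks to merge; default 1
#'   (book-ended peaks stay separate).
#' @return An object of class `master_list`: list with `regions` (data.frame
#'   `chrom`, `start`, `end`, `id`) and `provenance` (data.frame `region_id`,
#'   `sample_id`, `peak_id`).
#' @export
build_master_list <- function(repertoires, min_overlap = 1L) {
  if (length(repertoires) == 0L) stop("empty cohort")
  all_peaks <- do.call(rbind, lapply(repertoires, function(r) {
    p <- r$peaks
    if (nrow(p) == 0L) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               sample_id = r$sample_id, peak_id = p$id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_peaks) || nrow(all_peaks) == 0L)
    stop("no peaks in any repertoire")
  .check_regions(all_peaks, "peaks")
  gr <- .as_gr(all_peaks)
  # min.gapwidth = 1 - min_overlap: with min_overlap = 1 only truly
  # overlapping ranges merge (gap 0 i.e. book-ended stays separate)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L - as.integer(min_overlap))
  merged <- GenomicRanges::sort(merged)
  ids <- sprintf("CRE_%06d", seq_along(merged))
  names(merged) <- ids
  hits <- GenomicRanges::findOverlaps(gr, merged, minoverlap = 1L)
  prov <- data.frame(
    region_id = ids[S4Vectors::subjectHits(hits)],
    sample_id = all_peaks$sample_id[S4Vectors::queryHits(hits)],
    peak_id = all_peaks$peak_id[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE
  )
  out <- list(regions = .as_bed_df(merged), provenance = prov)
  class(out) <- "master_list"
  out
}

#' @export
print.master_list <- function(x, ...) {
  cat("Master list of accessible regions\n")
  cat("  regions:", nrow(x$regions), "on",
      length(unique(x$regions$chrom)), "chromosome(s)\n")
  cat("  contributing peaks:", nrow(x$provenance), "from",
      length(unique(x$provenance$sample_id)), "sample(s)\n")
  invisible(x)
}

#' Region-by-sample count matrix over the master list
#'
#' If per-sample fragment intervals are supplied, the count is the number of
#' fragments overlapping the master region by at least 1 bp (a fragment
#' spanning two disjoint master regions increments both). Otherwise the
#' per-peak read counts of each sample are transferred to the master region
#' they overlap (summed when several peaks hit one region).
#'
#' @param master A `master_list`.
#' @param repertoires List of sample repertoires.
#' @param fragments Optional named list (by sample_id) of fragment interval
#'   data.frames (`chrom`, `start`, `end`).
#' @return Integer matrix, regions x samples, with region ids as rownames.
#' @export
build_count_matrix <- function(master, repertoires, fragments = NULL) {
  stopifnot(inherits(master, "master_list"))
  mgr <- .as_gr(master$regions)
  samples <- vapply(repertoires, `[[`, "", "sample_id")
  mat <- matrix(0L, nrow = length(mgr), ncol = length(samples),
                dimnames = list(names(mgr), samples))
  if (!is.null(fragments)) {
    unknown <- setdiff(names(fragments), samples)
    if (length(unknown))
      stop("fragment file for unknown sample: ", paste(unknown, collapse = ", "))
    for (s in names(fragments)) {
      fr <- fragments[[s]]
      if (nrow(fr) == 0L) next
      mat[, s] <- GenomicRanges::countOverlaps(mgr, .as_gr(fr), minoverlap = 1L)
    }
  } else {
    for (i in seq_along(repertoires)) {
      p <- repertoires[[i]]$peaks
      if (nrow(p) == 0L) next
      hits <- GenomicRanges::findOverlaps(.as_gr(p), mgr, minoverlap = 1L)
      if (length(hits) == 0L) next
      agg <- tapply(p$read_count[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits), sum)
      mat[as.integer(names(agg)), i] <- as.integer(agg)
    }
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Annotate master regions as promoter-like or distal
#'
#' Computes the signed distance from each region midpoint to the nearest
#' transcription start site and classifies the region as promoter-like when
#' that distance is within the promoter window (0 when a TSS falls inside the
#' region). The sign is positive when the TSS lies downstream of the midpoint
#' on the gene's strand.
#'
#' @param master A `master_list`.
#' @param gene_model A gene model as returned by [simulate_cohort()] or
#'   [read_gene_model()]: list with `genes` (data.frame `gene_id`, `chrom`,
#'   `strand`, `tss`) and `exons`.
#' @param promoter_window Promoter half-window in bp (default 5000: regions
#'   within 5 kb of the closest TSS are promoter-like).
#' @return data.frame `region_id`, `class` (promoter-like/distal),
#'   `nearest_gene`, `tss_distance`.
#' @export
annotate_regions <- function(master, gene_model, promoter_window = 5000) {
  stopifnot(inherits(master, "master_list"))
  genes <- gene_model$genes
  if (is.null(genes) || nrow(genes) == 0L) stop("empty gene model")
  reg <- master$regions
  mid <- (reg$start + reg$end) / 2
  n <- nrow(reg)
  nearest_gene <- character(n)
  tss_dist <- numeric(n)
  for (ch in unique(reg$chrom)) {
    ri <- which(reg$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0L) {
      nearest_gene[ri] <- NA_character_
      tss_dist[ri] <- NA_real_
      next
    }
    # all-pairs is fine at master-list scale; nearest by absolute distance
    d <- outer(mid[ri], genes$tss[gi], function(m, t) t - m)
    j <- apply(abs(d), 1L, which.min)
    raw <- d[cbind(seq_along(ri), j)]
    g <- gi[j]
    nearest_gene[ri] <- genes$gene_id[g]
    signed <- ifelse(genes$strand[g] == "-", -raw, raw)
    inside <- genes$tss[g] >= reg$start[ri] & genes$tss[g] < reg$end[ri]
    tss_dist[ri] <- ifelse(inside, 0, signed)
  }
  data.frame(
    region_id = reg$id,
    class = ifelse(is.na(tss_dist), "distal",
                   ifelse(abs(tss_dist) <= promoter_window, "promoter-like", "distal")),
    nearest_gene = nearest_gene,
    tss_distance = tss_dist,
    stringsAsFactors = FALSE
  )
}

#' Summarize a cohort metadata table
#'
#' Per-group cohort summary in the style of a clinical Table 1: group sizes,
#' per-category counts with integer percentages (rounded half-up), and
#' mean/median/min/max for numeric columns (NA values dropped).
#'
#' @param metadata data.frame of per-patient rows.
#' @param group_col Name of the grouping column.
#' @return List with `n` (named group sizes), `categorical` (data.frame
#'   `group`, `variable`, `level`, `n`, `pct`) and `numeric` (data.frame
#'   `group`, `variable`, `mean`, `median`, `min`, `max`).
#' @export
summarize_cohort <- function(metadata, group_col = "group") {
  if (!is.data.frame(metadata) || nrow(metadata) == 0L) stop("empty metadata")
  if (!group_col %in% names(metadata))
    stop("grouping column '", group_col, "' not present")
  groups <- split(metadata, metadata[[group_col]])
  n <- vapply(groups, nrow, 0L)
  vars <- setdiff(names(metadata), group_col)
  cat_rows <- list(); num_rows <- list()
  for (g in names(groups)) {
    dg <- groups[[g]]
    for (v in vars) {
      x <- dg[[v]]
      if (is.numeric(x)) {
        x <- x[!is.na(x)]
        if (length(x) == 0L) next
        num_rows[[length(num_rows) + 1L]] <- data.frame(
          group = g, variable = v, mean = mean(x), median = stats::median(x),
          min = min(x), max = max(x), stringsAsFactors = FALSE)
      } else {
        x <- x[!is.na(x)]
        if (length(x) == 0L) next
        tab <- table(x)
        cat_rows[[length(cat_rows) + 1L]] <- data.frame(
          group = g, variable = v, level = names(tab), n = as.integer(tab),
          pct = as.integer(floor(100 * as.integer(tab) / nrow(dg) + 0.5)),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(
    n = n,
    categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else
      data.frame(group = character(), variable = character(), level = character(),
                 n = integer(), pct = integer()),
    numeric = if (length(num_rows)) do.call(rbind, num_rows) else
      data.frame(group = character(), variable = character(), mean = numeric(),
                 median = numeric(), min = numeric(), max = numeric())
  )
}

#' Read a gene model TSV
#'
#' Expects a TSV with columns `gene_id`, `chrom`, `strand`, `tss`,
#' `exon_starts`, `exon_ends` (comma-separated 0-based half-open exon
#' coordinates, BED12-style).
#'
#' @param path File path.
#' @return List with `genes` (gene_id, chrom, strand, tss) and `exons`
#'   (gene_id, chrom, start, end).
#' @export
read_gene_model <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "exon_starts", "exon_ends")
  if (!all(need %in% names(tab)))
    stop("gene model must have columns ", paste(need, collapse = ", "))
  exons <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    s <- as.integer(strsplit(as.character(tab$exon_starts[i]), ",")[[1]])
    e <- as.integer(strsplit(as.character(tab$exon_ends[i]), ",")[[1]])
    if (length(s) != length(e)) stop("exon_starts/exon_ends length mismatch at row ", i)
    data.frame(gene_id = tab$gene_id[i], chrom = tab$chrom[i],
               start = s, end = e, stringsAsFactors = FALSE)
  }))
  list(genes = tab[c("gene_id", "chrom", "strand", "tss")], exons = exons)
}

#' Write a gene model TSV
#' @param gene_model List with `genes` and `exons` as in [read_gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(gene_model, path) {
  genes <- gene_model$genes
  ex <- split(gene_model$exons, gene_model$exons$gene_id)
  tab <- genes
  tab$exon_starts <- vapply(genes$gene_id, function(g)
    paste(ex[[g]]$start, collapse = ","), "")
  tab$exon_ends <- vapply(genes$gene_id, function(g)
    paste(ex[[g]]$end, collapse = ","), "")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write regions as BED
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally `id`
#'   and `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  .check_regions(regions)
  out <- data.frame(chrom = regions$chrom, start = regions$start, end = regions$end)
  out$name <- if (!is.null(regions$id)) regions$id else "."
  out$score <- if (!is.null(regions$score)) regions$score else 0
  out$strand <- if (!is.null(regions$strand)) regions$strand else "."
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
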