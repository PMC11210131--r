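# Internal interval helpers.
#
# All user-facing coordinates are BED-style 0-based half-open [start, end).
# GenomicRanges/IRanges are 1-based closed, so conversion is start+1 at entry
# and start-1 at exit. These helpers are the only place that conversion lives.

# data.frame(chrom, start, end, ...) -> GRanges (names kept from `id` if present)
.as_gr <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (!is.null(df$id)) names(gr) <- df$id
  gr
}

# GRanges -> data.frame(chrom, start, end[, id]) in 0-based half-open coords
.as_bed_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(names(gr))) df$id <- names(gr)
  rownames(df) <- NULL
  df
}

.check_regions <- function(df, what = "regions") {
  if (!is.data.frame(df) || !all(c("chrom", "start", "end") %in% names(df)))
    stop(what, " must be a data.frame with columns chrom, start, end")
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop(what, ": start must be < end (rows ", paste(utils::head(bad, 5), collapse = ", "), ")")
  invisible(df)
}

# index of regions in `query` with >= 1 bp overlap against `subject`
.overlaps_any <- function(query_df, subject_df) {
  if (nrow(subject_df) == 0L) return(rep(FALSE, nrow(query_df)))
  # disjoint seqlevel sets are a legitimate "no overlap", not a warning
  suppressWarnings(
    IRanges::overlapsAny(.as_gr(query_df), .as_gr(subject_df), minoverlap = 1L))
}

.stages <- c("healthy", "onset", "remission", "relapse")

.check_stage <- function(stage) {
  bad <- setdiff(unique(stage), .stages)
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(.stages, collapse = ", "), ")")
  invisible(stage)
}
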