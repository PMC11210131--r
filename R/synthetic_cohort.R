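#' Configuration for the synthetic disease-stage cohort generator
#'
#' Defines the statistical structure of a simulated ATAC-seq cohort spanning
#' the four disease stages (healthy, onset, remission, relapse). Defaults
#' emulate the study design the package targets: 32 samples (6 healthy, 11
#' onset, 7 remission, 8 relapse), an onset group enriched for private and
#' low-penetrance peaks (60% of onset-detected peaks at PI <= 14), and
#' negative-binomial peak read counts.
#'
#' Peak classes generated:
#' \itemize{
#'   \item core: shared high-penetrance peaks (carriers drawn cohort-wide with
#'     penetrance above `low_penetrance_cut`);
#'   \item onset private/low: peaks carried only by onset samples at
#'     penetrance `<= low_penetrance_cut`, sized so the realized fraction of
#'     onset-detected peaks in the private/low band matches
#'     `frac_private_low_onset`;
#'   \item per-stage peaks for healthy/remission/relapse (carriers within the
#'     stage, a `private_peak_rate` fraction of them private);
#'   \item dynamic peaks: healthy-silent, disease-penetrant peaks in four
#'     activity patterns (onset+relapse elevated, onset-only, relapse-only,
#'     flat across disease), with the accessibility fold change `effect_fold`
#'     planted multiplicatively on the negative-binomial mean in the elevated
#'     stages. The onset+relapse pattern is the planted "dynamic productive"
#'     class downstream recovery tests look for.
#' }
#'
#' @param n_healthy,n_onset,n_remission,n_relapse Stage sample counts.
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param n_core_peaks Number of shared high-penetrance peaks.
#' @param n_dynamic_peaks Number of dynamic (healthy-silent) peaks, split
#'   evenly over the four activity patterns.
#' @param n_stage_peaks Named vector: per-stage peak counts for healthy,
#'   remission, relapse (onset-specific peaks are governed by
#'   `frac_private_low_onset`).
#' @param private_peak_rate Named vector in [0,1]: fraction of each stage's
#'   stage peaks that are private to one sample.
#' @param peak_width_mean Mean peak width (bp).
#' @param nb_mean,nb_dispersion Negative-binomial count model: mean and
#'   dispersion (variance = mu + dispersion * mu^2).
#' @param promoter_fraction Fraction of peaks placed within 5 kb of a
#'   synthetic TSS.
#' @param frac_private_low_onset Target fraction of onset-detected peaks with
#'   cohort PI <= `low_penetrance_cut` (default 0.6).
#' @param effect_fold Multiplicative accessibility effect planted in the
#'   elevated stages of dynamic peaks (default 4).
#' @param low_penetrance_cut Upper PI bound of the private/low band (default
#'   14).
#' @param pi_mean_coupling Optional coupling (>= 0) of NB mean to penetrance:
#'   mu is scaled by `1 + pi_mean_coupling * (PI / n_samples)`; default 0.
#' @param n_genes Number of synthetic genes.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_healthy = 6L, n_onset = 11L, n_remission = 7L,
                          n_relapse = 8L,
                          genome = c(chrS1 = 12e6, chrS2 = 8e6),
                          n_core_peaks = 1200L,
                          n_dynamic_peaks = 200L,
                          n_stage_peaks = c(healthy = 120L, remission = 100L,
                                            relapse = 150L),
                          private_peak_rate = c(healthy = 0.2, onset = 0.4,
                                                remission = 0.2, relapse = 0.3),
                          peak_width_mean = 500,
                          nb_mean = 50, nb_dispersion = 0.3,
                          promoter_fraction = 0.2,
                          frac_private_low_onset = 0.6,
                          effect_fold = 4,
                          low_penetrance_cut = 14L,
                          pi_mean_coupling = 0,
                          n_genes = 120L,
                          seed = 1L) {
  cfg <- list(n_healthy = as.integer(n_healthy), n_onset = as.integer(n_onset),
              n_remission = as.integer(n_remission), n_relapse = as.integer(n_relapse),
              genome = genome, n_core_peaks = as.integer(n_core_peaks),
              n_dynamic_peaks = as.integer(n_dynamic_peaks),
              n_stage_peaks = n_stage_peaks,
              private_peak_rate = private_peak_rate,
              peak_width_mean = peak_width_mean,
              nb_mean = nb_mean, nb_dispersion = nb_dispersion,
              promoter_fraction = promoter_fraction,
              frac_private_low_onset = frac_private_low_onset,
              effect_fold = effect_fold,
              low_penetrance_cut = as.integer(low_penetrance_cut),
              pi_mean_coupling = pi_mean_coupling,
              n_genes = as.integer(n_genes), seed = as.integer(seed))
  ns <- c(cfg$n_healthy, cfg$n_onset, cfg$n_remission, cfg$n_relapse)
  if (any(ns < 0)) stop("sample counts must be >= 0")
  if (sum(ns) == 0) stop("empty cohort")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  rates <- c(cfg$private_peak_rate, cfg$promoter_fraction,
             cfg$frac_private_low_onset)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (any(cfg$genome <= 0)) stop("chromosome lengths must be > 0")
  class(cfg) <- "cohort_config"
  cfg
}

# draw one element from a vector (safe for length-1 vectors, unlike sample())
.sample1 <- function(v) v[sample.int(length(v), 1L)]

# disjoint peak placement: uniform over chromosomes, rejection-sampled to a
# >= 1 bp gap so the master-list merge of the fixture is unambiguous
.place_peaks <- function(n, genome, width_mean, tss = NULL, promoter_fraction = 0) {
  chroms <- names(genome)
  placed <- data.frame(chrom = character(), start = numeric(), end = numeric())
  guard <- 0L
  while (nrow(placed) < n && guard < 50L) {
    guard <- guard + 1L
    m <- 2L * (n - nrow(placed)) + 10L
    w <- pmax(100L, round(stats::rnorm(m, width_mean, 0.2 * width_mean)))
    near_tss <- !is.null(tss) && promoter_fraction > 0
    use_tss <- if (near_tss) stats::runif(m) < promoter_fraction else rep(FALSE, m)
    ch <- character(m); st <- numeric(m)
    ridx <- which(!use_tss)
    if (length(ridx)) {
      ch[ridx] <- sample(chroms, length(ridx), replace = TRUE,
                         prob = genome / sum(genome))
      st[ridx] <- floor(stats::runif(length(ridx)) * (genome[ch[ridx]] - w[ridx] - 1))
    }
    tidx <- which(use_tss)
    if (length(tidx)) {
      gi <- sample(nrow(tss), length(tidx), replace = TRUE)
      ch[tidx] <- tss$chrom[gi]
      st[tidx] <- pmax(0, tss$tss[gi] + round(stats::runif(length(tidx), -5000, 5000)) -
                         round(w[tidx] / 2))
    }
    cand <- data.frame(chrom = ch, start = st, end = st + w)
    cand <- cand[cand$start >= 0, , drop = FALSE]
    # drop candidates overlapping or book-ended with an already-placed peak
    if (nrow(placed) > 0L && nrow(cand) > 0L) {
      clash <- IRanges::overlapsAny(
        GenomicRanges::GRanges(cand$chrom, IRanges::IRanges(cand$start + 1, cand$end)),
        GenomicRanges::GRanges(placed$chrom, IRanges::IRanges(placed$start + 1, placed$end)),
        maxgap = 0L)
      cand <- cand[!clash, , drop = FALSE]
    }
    # resolve clashes among candidates by a sorted greedy scan (gap >= 1 bp)
    if (nrow(cand) > 1L) {
      cand <- cand[order(cand$chrom, cand$start), , drop = FALSE]
      keep <- logical(nrow(cand))
      last_end <- -Inf; last_chrom <- ""
      for (ii in seq_len(nrow(cand))) {
        if (cand$chrom[ii] != last_chrom || cand$start[ii] > last_end) {
          keep[ii] <- TRUE
          last_chrom <- cand$chrom[ii]; last_end <- cand$end[ii]
        }
      }
      cand <- cand[keep, , drop = FALSE]
    }
    placed <- rbind(placed, utils::head(cand, n - nrow(placed)))
  }
  if (nrow(placed) < n) stop("could not place ", n, " disjoint peaks; genome too small")
  placed <- placed[order(placed$chrom, placed$start), , drop = FALSE]
  rownames(placed) <- NULL
  placed$start <- as.integer(placed$start)
  placed$end <- as.integer(placed$end)
  placed
}

.sim_gene_model <- function(cfg) {
  chroms <- names(cfg$genome)
  ch <- sample(chroms, cfg$n_genes, replace = TRUE,
               prob = cfg$genome / sum(cfg$genome))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  tss <- floor(stats::runif(cfg$n_genes, 1e4, cfg$genome[ch] - 1e4))
  genes <- data.frame(gene_id = sprintf("GENE_%04d", seq_len(cfg$n_genes)),
                      chrom = ch, strand = strand, tss = as.integer(tss),
                      stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(cfg$n_genes), function(i) {
    dir <- if (strand[i] == "+") 1 else -1
    offs <- cumsum(c(0, 500 + round(stats::runif(2, 0, 1500))))
    s <- tss[i] + dir * offs - (if (dir < 0) 200 else 0)
    data.frame(gene_id = genes$gene_id[i], chrom = ch[i],
               start = as.integer(pmax(0, pmin(s, s + 200) - 0)),
               end = as.integer(pmax(s, s + 200)),
               stringsAsFactors = FALSE)
  }))
  exons$start <- pmin(exons$start, exons$end - 200L)
  list(genes = genes, exons = exons)
}

#' Simulate a disease-stage ATAC-seq cohort
#'
#' Generates the full cohort: a gene model, a disjoint master set of peaks
#' with class labels, a region-by-sample presence matrix with the configured
#' penetrance architecture, negative-binomial read counts (present peaks only;
#' absent peaks are omitted from a sample's repertoire), per-sample
#' repertoires and a metadata table.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `config`, `metadata`,
#'   `repertoires`, `peaks` (truth table with `class` and `pattern`),
#'   `presence`, `counts`, `gene_model`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  stages <- rep(.stages, c(cfg$n_healthy, cfg$n_onset, cfg$n_remission, cfg$n_relapse))
  sample_ids <- sprintf("S%02d_%s", seq_along(stages), toupper(substr(stages, 1, 3)))
  n_samp <- length(stages)
  by_stage <- split(sample_ids, stages)

  gene_model <- .sim_gene_model(cfg)

  # class bookkeeping ----------------------------------------------------
  f <- cfg$frac_private_low_onset
  n_low_onset <- if (cfg$n_onset > 0)
    as.integer(round(f / (1 - f) * (cfg$n_core_peaks + cfg$n_dynamic_peaks))) else 0L
  other_stages <- intersect(names(cfg$n_stage_peaks), setdiff(.stages, "onset"))
  other_stages <- other_stages[vapply(other_stages, function(s)
    length(by_stage[[s]]) > 0, TRUE)]
  n_other <- sum(cfg$n_stage_peaks[other_stages])
  n_total <- cfg$n_core_peaks + cfg$n_dynamic_peaks + n_low_onset + n_other

  loc <- .place_peaks(n_total, cfg$genome, cfg$peak_width_mean,
                      tss = gene_model$genes, promoter_fraction = cfg$promoter_fraction)
  loc <- loc[sample(nrow(loc)), , drop = FALSE]  # decouple class from position
  peaks <- loc
  peaks$id <- sprintf("PK_%05d", seq_len(n_total))
  peaks$class <- c(rep("core", cfg$n_core_peaks),
                   rep("dynamic", cfg$n_dynamic_peaks),
                   rep("onset_low", n_low_onset),
                   rep(paste0("stage_", other_stages), cfg$n_stage_peaks[other_stages]))
  patterns <- c("onset_relapse", "onset_only", "relapse_only", "disease_flat")
  peaks$pattern <- NA_character_
  if (cfg$n_dynamic_peaks > 0) {
    di <- which(peaks$class == "dynamic")
    peaks$pattern[di] <- rep(patterns, length.out = length(di))
  }

  # presence and per-cell NB mean fold -----------------------------------
  presence <- matrix(FALSE, n_total, n_samp, dimnames = list(peaks$id, sample_ids))
  fold <- matrix(1, n_total, n_samp, dimnames = list(peaks$id, sample_ids))
  low_cut <- cfg$low_penetrance_cut
  for (i in seq_len(n_total)) {
    cl <- peaks$class[i]
    if (cl == "core") {
      m <- .sample1(seq(min(low_cut + 1L, n_samp), n_samp))
      presence[i, sample(sample_ids, m)] <- TRUE
    } else if (cl == "onset_low") {
      n_on <- length(by_stage$onset)
      if (stats::runif(1) < cfg$private_peak_rate["onset"] || n_on == 1L) {
        presence[i, .sample1(by_stage$onset)] <- TRUE
      } else {
        m <- .sample1(seq(2L, min(n_on, low_cut)))
        presence[i, sample(by_stage$onset, m)] <- TRUE
      }
    } else if (cl == "dynamic") {
      pat <- peaks$pattern[i]
      onset <- by_stage$onset; relapse <- by_stage$relapse; rem <- by_stage$remission
      if (pat == "onset_relapse") {
        presence[i, c(onset, relapse)] <- TRUE
        presence[i, rem[stats::runif(length(rem)) < 0.6]] <- TRUE
        fold[i, c(onset, relapse)] <- cfg$effect_fold
      } else if (pat == "onset_only") {
        presence[i, onset] <- TRUE
        presence[i, relapse[stats::runif(length(relapse)) < 0.6]] <- TRUE
        presence[i, rem[stats::runif(length(rem)) < 0.6]] <- TRUE
        fold[i, onset] <- cfg$effect_fold
      } else if (pat == "relapse_only") {
        presence[i, relapse] <- TRUE
        presence[i, onset[stats::runif(length(onset)) < 0.8]] <- TRUE
        presence[i, rem[stats::runif(length(rem)) < 0.6]] <- TRUE
        fold[i, relapse] <- cfg$effect_fold
      } else {  # disease_flat
        presence[i, c(onset, relapse)] <- TRUE
        presence[i, rem[stats::runif(length(rem)) < 0.6]] <- TRUE
      }
    } else {  # stage_<s>
      s <- sub("stage_", "", cl)
      ss <- by_stage[[s]]
      if (stats::runif(1) < cfg$private_peak_rate[s] || length(ss) == 1L) {
        presence[i, .sample1(ss)] <- TRUE
      } else {
        m <- .sample1(seq(2L, length(ss)))
        presence[i, sample(ss, m)] <- TRUE
      }
    }
  }

  # NB counts (present cells only); detected peaks have count >= 1 --------
  pi_true <- rowSums(presence)
  mu_base <- cfg$nb_mean * (1 + cfg$pi_mean_coupling * pi_true / n_samp)
  counts <- matrix(0L, n_total, n_samp, dimnames = list(peaks$id, sample_ids))
  pres_idx <- which(presence)
  mu <- (mu_base[row(presence)] * fold)[pres_idx]
  counts[pres_idx] <- pmax(1L, stats::rnbinom(length(pres_idx), mu = mu,
                                              size = 1 / cfg$nb_dispersion))

  metadata <- data.frame(
    sample_id = sample_ids, stage = stages,
    total_mapped_reads = as.integer(round(3e7 * stats::runif(n_samp, 0.8, 1.2))),
    stringsAsFactors = FALSE)

  repertoires <- lapply(seq_len(n_samp), function(j) {
    idx <- which(presence[, j])
    p <- peaks[idx, c("chrom", "start", "end", "id"), drop = FALSE]
    p$read_count <- counts[idx, j]
    p <- p[order(p$chrom, p$start), , drop = FALSE]
    rownames(p) <- NULL
    list(sample_id = sample_ids[j], stage = stages[j],
         total_mapped_reads = metadata$total_mapped_reads[j], peaks = p)
  })
  names(repertoires) <- sample_ids

  out <- list(config = cfg, metadata = metadata, repertoires = repertoires,
              peaks = peaks, presence = presence, counts = counts,
              gene_model = gene_model)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic disease-stage cohort\n")
  cat("  samples:", nrow(x$metadata), "(",
      paste(names(table(x$metadata$stage)), table(x$metadata$stage),
            sep = "=", collapse = ", "), ")\n")
  cat("  peaks:", nrow(x$peaks), "(",
      paste(names(table(x$peaks$class)), table(x$peaks$class),
            sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one BED6 peak file per sample (name = peak id, score = read count),
#' the metadata TSV, the counts TSV and the gene model TSV.
#'
#' @param sim A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  peak_paths <- vapply(sim$repertoires, function(r) {
    path <- file.path(dir, paste0(r$sample_id, "_peaks.bed"))
    p <- r$peaks
    write_bed(data.frame(chrom = p$chrom, start = p$start, end = p$end,
                         id = p$id, score = p$read_count), path)
    path
  }, "")
  meta_path <- file.path(dir, "metadata.tsv")
  utils::write.table(sim$metadata, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts_path <- file.path(dir, "counts.tsv")
  utils::write.table(data.frame(region_id = rownames(sim$counts), sim$counts,
                                check.names = FALSE),
                     counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  gm_path <- write_gene_model(sim$gene_model, file.path(dir, "gene_model.tsv"))
  invisible(list(peaks = peak_paths, metadata = meta_path,
                 counts = counts_path, gene_model = gm_path))
}

#' Simulate RNA fragments with planted eRNA productivity
#'
#' Generates per-sample RNA fragment intervals (75 bp, paired ends collapsed
#' to one interval): baseline gene-derived fragments over exons in every
#' sample, baseline non-exonic fragments over every CRE, and elevated
#' non-exonic coverage (factor `fold`) at the designated productive CREs in
#' onset-stage samples.
#'
#' @param config A [cohort_config()] (supplies the seed).
#' @param cre_regions data.frame of disjoint CRE regions with `id`.
#' @param gene_model Gene model (exons receive baseline fragments).
#' @param metadata Cohort metadata (`sample_id`, `stage`).
#' @param productive_ids CRE ids flagged as eRNA-productive (must be a subset
#'   of `cre_regions$id`).
#' @param fold Productivity fold change in onset samples (default 4).
#' @param base_rate Expected baseline fragments per CRE (default 8).
#' @param exon_rate Expected fragments per exon (default 20).
#' @return Named list (by sample id) of fragment data.frames (`chrom`,
#'   `start`, `end`).
#' @export
simulate_rna_erna <- function(config, cre_regions, gene_model, metadata,
                              productive_ids = character(), fold = 4,
                              base_rate = 8, exon_rate = 20) {
  stopifnot(inherits(config, "cohort_config"))
  if (!all(productive_ids %in% cre_regions$id))
    stop("productive subset not contained in cre_regions")
  set.seed(config$seed + 104729L)  # decoupled stream from the count generator
  frag_len <- 75L
  exons <- gene_model$exons
  # eligible (non-exonic) pieces of each CRE
  cre_gr <- .as_gr(cre_regions)
  elig <- GenomicRanges::setdiff(cre_gr, GenomicRanges::reduce(.as_gr(exons)),
                                 ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(elig, cre_gr, minoverlap = 1L)
  piece <- .as_bed_df(GenomicRanges::pintersect(
    elig[S4Vectors::queryHits(hits)], cre_gr[S4Vectors::subjectHits(hits)]))
  piece$cre <- cre_regions$id[S4Vectors::subjectHits(hits)]
  pieces_by_cre <- split(piece, piece$cre)

  out <- vector("list", nrow(metadata))
  names(out) <- metadata$sample_id
  for (j in seq_len(nrow(metadata))) {
    frs <- list()
    # exonic background in all samples
    n_ex <- stats::rpois(nrow(exons), exon_rate)
    keep <- which(n_ex > 0 & (exons$end - exons$start) >= frag_len)
    if (length(keep)) {
      starts <- unlist(lapply(keep, function(e)
        exons$start[e] + floor(stats::runif(n_ex[e]) *
                                 (exons$end[e] - exons$start[e] - frag_len + 1))))
      frs[[1]] <- data.frame(
        chrom = rep(exons$chrom[keep], n_ex[keep]),
        start = as.integer(starts), end = as.integer(starts + frag_len),
        stringsAsFactors = FALSE)
    }
    # CRE (non-exonic) fragments
    is_onset <- metadata$stage[j] == "onset"
    lam <- rep(base_rate, nrow(cre_regions))
    names(lam) <- cre_regions$id
    if (is_onset && length(productive_ids)) lam[productive_ids] <- base_rate * fold
    n_cre <- stats::rpois(nrow(cre_regions), lam)
    for (i in which(n_cre > 0)) {
      pc <- pieces_by_cre[[cre_regions$id[i]]]
      if (is.null(pc) || nrow(pc) == 0L) next  # fully exonic CRE: no eRNA
      w <- pc$end - pc$start
      pk <- sample(nrow(pc), n_cre[i], replace = TRUE, prob = w)
      st <- pc$start[pk] + floor(stats::runif(n_cre[i]) * pmax(1, w[pk] - frag_len))
      frs[[length(frs) + 1L]] <- data.frame(
        chrom = pc$chrom[pk], start = as.integer(st),
        end = as.integer(st + frag_len), stringsAsFactors = FALSE)
    }
    fr <- if (length(frs)) do.call(rbind, frs) else
      data.frame(chrom = character(), start = integer(), end = integer())
    fr <- fr[order(fr$chrom, fr$start), , drop = FALSE]
    rownames(fr) <- NULL
    out[[j]] <- fr
  }
  out
}

#' Simulate chromatin loops and a dependency-screen matrix
#'
#' Records planted CRE-to-promoter loops as BEDPE anchor pairs (plus random
#' promoter-promoter and CRE-CRE loops) and generates a gene-by-cell-line
#' dependency-score matrix with a labeled lineage-of-interest subset whose
#' scores for the planted essential genes are shifted downward by `offset`.
#'
#' @param config A [cohort_config()] (supplies the seed).
#' @param cre_regions data.frame of CRE regions with `id`.
#' @param gene_model Gene model (non-empty).
#' @param planted_links data.frame `cre_id`, `gene_id` of CRE-promoter loops
#'   to plant (default: none).
#' @param n_random_loops Number of random promoter-promoter / CRE-CRE loops
#'   (default 60).
#' @param n_cell_lines Number of cell lines (default 300).
#' @param n_lineage Number of lineage-of-interest ("B-ALL") lines (default
#'   11).
#' @param planted_genes Gene ids whose lineage-of-interest scores are shifted
#'   by `-offset` (default: none).
#' @param offset Downward dependency shift for planted genes (default 1.5).
#' @return List with `loops` (BEDPE-style data.frame with `name`) and
#'   `dependency` (list `scores`, `lineage`).
#' @export
simulate_loops_and_dependency <- function(config, cre_regions, gene_model,
                                          planted_links = NULL,
                                          n_random_loops = 60L,
                                          n_cell_lines = 300L, n_lineage = 11L,
                                          planted_genes = character(),
                                          offset = 1.5) {
  stopifnot(inherits(config, "cohort_config"))
  genes <- gene_model$genes
  if (is.null(genes) || nrow(genes) == 0L) stop("gene model is empty")
  if (!is.null(planted_links) &&
      nrow(planted_links) > nrow(cre_regions) * nrow(genes))
    stop("requested loops exceed CRE x gene combinations")
  set.seed(config$seed + 224737L)
  mk_loop <- function(c1, s1, e1, c2, s2, e2, nm) {
    flip <- c1 == c2 & s2 < s1
    data.frame(chrom1 = ifelse(flip, c2, c1),
               start1 = as.integer(ifelse(flip, s2, s1)),
               end1 = as.integer(ifelse(flip, e2, e1)),
               chrom2 = ifelse(flip, c1, c2),
               start2 = as.integer(ifelse(flip, s1, s2)),
               end2 = as.integer(ifelse(flip, e1, e2)),
               name = nm, stringsAsFactors = FALSE)
  }
  loops <- list()
  if (!is.null(planted_links) && nrow(planted_links) > 0L) {
    ci <- match(planted_links$cre_id, cre_regions$id)
    gi <- match(planted_links$gene_id, genes$gene_id)
    if (anyNA(ci) || anyNA(gi)) stop("planted link references unknown CRE or gene")
    loops[[1]] <- mk_loop(cre_regions$chrom[ci], cre_regions$start[ci],
                          cre_regions$end[ci],
                          genes$chrom[gi], pmax(0L, genes$tss[gi] - 1000L),
                          genes$tss[gi] + 1000L,
                          paste0("planted_", planted_links$cre_id))
  }
  if (n_random_loops > 0L) {
    half <- floor(n_random_loops / 2)
    gi1 <- sample(nrow(genes), half, replace = TRUE)
    gi2 <- sample(nrow(genes), half, replace = TRUE)
    same <- genes$chrom[gi1] == genes$chrom[gi2] & gi1 != gi2
    if (any(same))
      loops[[length(loops) + 1L]] <- mk_loop(
        genes$chrom[gi1[same]], pmax(0L, genes$tss[gi1[same]] - 1000L),
        genes$tss[gi1[same]] + 1000L,
        genes$chrom[gi2[same]], pmax(0L, genes$tss[gi2[same]] - 1000L),
        genes$tss[gi2[same]] + 1000L, "random_pp")
    m <- n_random_loops - half
    ci1 <- sample(nrow(cre_regions), m, replace = TRUE)
    ci2 <- sample(nrow(cre_regions), m, replace = TRUE)
    same <- cre_regions$chrom[ci1] == cre_regions$chrom[ci2] & ci1 != ci2
    if (any(same))
      loops[[length(loops) + 1L]] <- mk_loop(
        cre_regions$chrom[ci1[same]], cre_regions$start[ci1[same]],
        cre_regions$end[ci1[same]],
        cre_regions$chrom[ci2[same]], cre_regions$start[ci2[same]],
        cre_regions$end[ci2[same]], "random_cc")
  }
  loops <- if (length(loops)) do.call(rbind, loops) else
    data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
               chrom2 = character(), start2 = integer(), end2 = integer(),
               name = character())
  rownames(loops) <- NULL

  lines <- sprintf("CL_%03d", seq_len(n_cell_lines))
  lineage <- stats::setNames(rep("other", n_cell_lines), lines)
  lineage[sample(n_cell_lines, min(n_lineage, n_cell_lines))] <- "B-ALL"
  scores <- matrix(stats::rnorm(nrow(genes) * n_cell_lines, 0, 0.3),
                   nrow = nrow(genes),
                   dimnames = list(genes$gene_id, lines))
  pg <- intersect(planted_genes, rownames(scores))
  if (length(pg))
    scores[pg, lineage == "B-ALL"] <- scores[pg, lineage == "B-ALL"] - offset
  list(loops = loops, dependency = list(scores = scores, lineage = lineage))
}

#' Simulate annotation region sets for tier classification
#'
#' Builds synthetic stand-ins for external annotation catalogs: an eRNA
#' annotation set, a super-enhancer set (wide regions), and a cell-line peak
#' set. The cell-line set contains the given shared CRE regions (plus noise)
#' so that tier classification has true positives to find.
#'
#' @param sim A `synthetic_cohort`.
#' @param shared_ids Peak ids to include in the cell-line set.
#' @param erna_ids Peak ids to include in the eRNA catalog.
#' @param n_noise Number of random extra regions per set (default 50).
#' @return Named list of region data.frames: `erna_annotation`,
#'   `super_enhancers`, `cellline_peaks`.
#' @export
simulate_annotations <- function(sim, shared_ids = character(),
                                 erna_ids = character(), n_noise = 50L) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  set.seed(sim$config$seed + 479909L)
  peaks <- sim$peaks
  genome <- sim$config$genome
  rand_regions <- function(n, width) {
    ch <- sample(names(genome), n, replace = TRUE, prob = genome / sum(genome))
    st <- floor(stats::runif(n) * (genome[ch] - width - 1))
    data.frame(chrom = ch, start = as.integer(st), end = as.integer(st + width),
               stringsAsFactors = FALSE)
  }
  pick <- function(ids) peaks[peaks$id %in% ids, c("chrom", "start", "end")]
  list(
    erna_annotation = rbind(pick(erna_ids), rand_regions(n_noise, 600L)),
    super_enhancers = rand_regions(max(5L, n_noise %/% 5L), 20000L),
    cellline_peaks = rbind(pick(shared_ids), rand_regions(n_noise, 500L))
  )
}
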