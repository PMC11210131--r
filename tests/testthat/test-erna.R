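test_that("eRNA counting excludes exonic bases of a CRE", {
  cres <- data.frame(chrom = "chrA", start = 0L, end = 1000L, id = "cre1")
  exons <- data.frame(chrom = "chrA", start = 400L, end = 600L)
  frags <- list(s1 = data.frame(chrom = "chrA", start = c(100L, 450L),
                                end = c(175L, 525L)))
  q <- erna_quantify(cres, exons, frags)
  expect_identical(unname(q$eligible_length["cre1"]), 800)
  expect_identical(q$counts["cre1", "s1"], 1L)   # the 450-525 fragment is exonic

  # CRE fully inside an exon: zero eligible bases, zero counts
  cres2 <- data.frame(chrom = "chrA", start = 450L, end = 550L, id = "cre2")
  q2 <- erna_quantify(cres2, exons, frags)
  expect_identical(unname(q2$eligible_length["cre2"]), 0)
  expect_identical(q2$counts["cre2", "s1"], 0L)

  # no fragments at all: all-zero matrix
  q3 <- erna_quantify(cres, exons, list(s1 = frags$s1[0, ]))
  expect_true(all(q3$counts == 0L))
})

test_that("eRNA counts are additive over a partition at fragment-free cut points", {
  set.seed(51)
  whole <- data.frame(chrom = "chrA", start = 0L, end = 2000L, id = "w")
  halves <- data.frame(chrom = "chrA", start = c(0L, 1000L),
                       end = c(1000L, 2000L), id = c("h1", "h2"))
  exons <- data.frame(chrom = "chrA", start = 1500L, end = 1700L)
  # fragments that never span position 1000
  st <- c(sample(0:900, 30, replace = TRUE), sample(1001:1900, 30, replace = TRUE))
  frags <- list(s1 = data.frame(chrom = "chrA", start = st, end = st + 75L))
  qw <- erna_quantify(whole, exons, frags)
  qh <- erna_quantify(halves, exons, frags)
  expect_identical(qw$counts["w", "s1"],
                   qh$counts["h1", "s1"] + qh$counts["h2", "s1"])
})

test_that("productive CREs recover planted fold-4 signal and control the null", {
  cfg <- cohort_config(seed = 61L)
  sim <- simulate_cohort(cfg)
  onset <- sim$metadata$sample_id[sim$metadata$stage == "onset"]
  healthy <- sim$metadata$sample_id[sim$metadata$stage == "healthy"]
  prod_ids <- sim$peaks$id[!is.na(sim$peaks$pattern) &
                             sim$peaks$pattern == "onset_relapse"]
  # 500 CREs of which 50 are productive, so the top ratio decile has 50 slots
  keep <- sim$peaks$class %in% c("dynamic", "core")
  cres <- sim$peaks[keep, c("chrom", "start", "end", "id")][1:500, ]
  cres <- unique(rbind(cres, sim$peaks[sim$peaks$id %in% prod_ids,
                                       c("chrom", "start", "end", "id")]))
  frags <- simulate_rna_erna(cfg, cres, sim$gene_model, sim$metadata,
                             productive_ids = prod_ids, fold = 4)
  q <- erna_quantify(cres, sim$gene_model$exons, frags)
  got <- productive_cres(q, healthy, onset)
  expect_gte(mean(prod_ids %in% got), 0.9)
  # planted CREs sit in the top decile of onset/healthy count ratios
  ratio <- (rowMeans(q$counts[, onset]) + 0.5) /
    (rowMeans(q$counts[, healthy]) + 0.5)
  cut <- quantile(ratio, 1 - length(prod_ids) / nrow(cres))
  expect_gte(mean(ratio[prod_ids] >= cut), 0.9)
  expect_error(productive_cres(q, healthy, character()), "empty groupB")
})

test_that("without planted productivity no stage difference emerges", {
  cfg <- cohort_config(seed = 63L)
  sim <- simulate_cohort(cfg)
  onset <- sim$metadata$sample_id[sim$metadata$stage == "onset"]
  healthy <- sim$metadata$sample_id[sim$metadata$stage == "healthy"]
  cres <- sim$peaks[sim$peaks$class == "dynamic", c("chrom", "start", "end", "id")]
  frags <- simulate_rna_erna(cfg, cres, sim$gene_model, sim$metadata,
                             productive_ids = character())
  q <- erna_quantify(cres, sim$gene_model$exons, frags)
  got <- productive_cres(q, healthy, onset, fdr_cut = 0.05)
  expect_lte(length(got) / nrow(cres), 0.05 + 0.03)
  # determinism of the fragment generator
  frags2 <- simulate_rna_erna(cfg, cres, sim$gene_model, sim$metadata,
                              productive_ids = character())
  expect_identical(frags, frags2)
})

test_that("overlap frequency matches brute-force recounts", {
  set.seed(53)
  # disjoint targets on a jittered grid, so subset overlaps are exact
  st <- seq(0L, by = 5000L, length.out = 108) + sample.int(2000L, 108, replace = TRUE)
  targets <- data.frame(chrom = "chrA", start = st, end = st + 400L,
                        id = paste0("t", 1:108))
  expect_equal(overlap_frequency(targets, list(self = targets))$frequency[1], 1)
  far <- data.frame(chrom = "chrB", start = 1L, end = 2L)
  expect_equal(overlap_frequency(targets, list(far = far))$frequency[1], 0)
  # feature overlapping exactly 76 of the 108 targets
  feat <- targets[1:76, c("chrom", "start", "end")]
  of <- overlap_frequency(targets, list(f = feat))
  expect_equal(of$frequency[of$feature == "f"], 76 / 108)
  expect_error(overlap_frequency(targets[0, ], list(f = feat)), "empty target")

  for (rep in 1:10) {
    fs <- rand_regions(40, chroms = c("chrA", "chrB"), max_pos = 1e6)
    got <- overlap_frequency(targets, list(f = fs))
    manual <- mean(vapply(seq_len(nrow(targets)), function(i)
      naive_overlaps(targets$chrom[i], targets$start[i], targets$end[i], fs), TRUE))
    expect_equal(got$frequency[got$feature == "f"], manual)
  }
})

test_that("overlap frequency is monotone in the feature set", {
  set.seed(55)
  targets <- rand_regions(60, chroms = "chrA")
  targets$id <- paste0("t", 1:60)
  small <- rand_regions(15, chroms = "chrA")
  big <- rbind(small, rand_regions(30, chroms = "chrA"))
  fs <- overlap_frequency(targets, list(small = small, big = big))
  expect_gte(fs$frequency[fs$feature == "big"],
             fs$frequency[fs$feature == "small"])
  # union row is at least the per-set maximum
  expect_gte(fs$frequency[fs$feature == "union"],
             max(fs$frequency[fs$feature != "union"]))
})

test_that("tier classification applies the cluster gate and matches set logic", {
  cres <- data.frame(chrom = "chrA", start = c(0L, 1000L, 2000L, 3000L),
                     end = c(500L, 1500L, 2500L, 3500L),
                     id = paste0("cre", 1:4))
  clusters <- data.frame(region_id = paste0("cre", 1:4),
                         cluster = c("C1", "C3", "C2", "C4"))
  cellline <- cres[c(1, 2), c("chrom", "start", "end")]
  se <- cres[2, c("chrom", "start", "end")]
  ern <- cres[4, c("chrom", "start", "end")]
  tiers <- classify_enhancer_tiers(cres, clusters, ern, se, cellline)
  expect_identical(tiers$tier[tiers$region_id == "cre1"],
                   "candidate_productive_enhancer")
  # C3 with every flag set is still not a candidate
  expect_identical(tiers$tier[tiers$region_id == "cre2"], "super_enhancer")
  expect_identical(tiers$tier[tiers$region_id == "cre4"], "erna_annotated")
  expect_identical(tiers$tier[tiers$region_id == "cre3"], "unclassified")
  counts <- attr(tiers, "tier_counts")
  expect_identical(sum(counts), 4L)
  # order independence
  tiers2 <- classify_enhancer_tiers(cres[4:1, ], clusters, ern, se, cellline)
  expect_equal(tiers2[order(tiers2$region_id), ]$tier,
               tiers[order(tiers$region_id), ]$tier)
})

test_that("random tier fixtures match a brute-force intersection oracle", {
  set.seed(57)
  for (rep in 1:10) {
    cres <- rand_regions(50, chroms = "chrA", max_pos = 5e5)
    cres$id <- paste0("c", 1:50)
    clusters <- data.frame(region_id = cres$id,
                           cluster = sample(paste0("C", 1:4), 50, replace = TRUE))
    cell <- rand_regions(20, chroms = "chrA", max_pos = 5e5)
    tiers <- classify_enhancer_tiers(cres, clusters,
                                     erna_annotation = cres[0, 1:3],
                                     super_enhancers = cres[0, 1:3],
                                     cellline_peaks = cell)
    manual <- vapply(seq_len(nrow(cres)), function(i)
      naive_overlaps(cres$chrom[i], cres$start[i], cres$end[i], cell), TRUE)
    expect_identical(tiers$cellline_shared, manual)
    expect_identical(
      sum(tiers$tier == "candidate_productive_enhancer"),
      sum(manual & clusters$cluster %in% c("C1", "C2")))
  }
})
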