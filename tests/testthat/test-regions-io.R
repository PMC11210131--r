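test_that("read_cohort validates inputs and preserves repertoire sizes", {
  dir <- withr::local_tempdir()
  sizes <- c(10L, 20L, 30L)
  paths <- character(3)
  for (i in 1:3) {
    set.seed(i)
    st <- sort(sample.int(1e5, sizes[i])) * 10L
    df <- data.frame(chrom = "chrA", start = st, end = st + 200L,
                     id = paste0("p", seq_len(sizes[i])), score = 5L)
    paths[i] <- file.path(dir, paste0("s", i, ".bed"))
    write_bed(df, paths[i])
  }
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     stage = c("healthy", "onset", "relapse"),
                     total_mapped_reads = 1e6L)
  mp <- file.path(dir, "meta.tsv")
  write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)

  reps <- read_cohort(paths, mp)
  expect_identical(vapply(reps, function(r) nrow(r$peaks), 0L),
                   c(a = 10L, b = 20L, c = 30L))
  expect_identical(vapply(reps, `[[`, "", "stage"),
                   c(a = "healthy", b = "onset", c = "relapse"))

  expect_error(read_cohort(character(), mp), "empty cohort")
  meta_bad <- meta; meta_bad$stage[2] <- "weird"
  write.table(meta_bad, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(paths, mp), "unknown stage")
  meta_dup <- meta; meta_dup$sample_id[2] <- "a"
  write.table(meta_dup, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(paths, mp), "duplicate sample_id")
})

test_that("malformed BED lines are rejected with line numbers", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA\t100\t200\tp1\t3",
               "chrA\t500\tnotanumber\tp2\t3",
               "chrA\t900\t800\tp3\t3"), f)
  expect_error(read_peak_bed(f), "line number.*2, 3")
})

test_that("master list merges by >= 1 bp overlap, transitively", {
  # one sample, disjoint peaks: identity
  p <- data.frame(chrom = "chrA", start = c(100L, 400L), end = c(200L, 500L))
  ml <- build_master_list(list(make_repertoire("s1", p)))
  expect_equal(ml$regions[c("chrom", "start", "end")],
               p, ignore_attr = TRUE)

  # overlapping peaks from two samples merge into one region
  r1 <- make_repertoire("s1", data.frame(chrom = "chrA", start = 100L, end = 200L))
  r2 <- make_repertoire("s2", data.frame(chrom = "chrA", start = 150L, end = 250L))
  ml2 <- build_master_list(list(r1, r2))
  expect_identical(nrow(ml2$regions), 1L)
  expect_identical(ml2$regions$start, 100L)
  expect_identical(ml2$regions$end, 250L)
  expect_setequal(ml2$provenance$sample_id, c("s1", "s2"))

  # book-ended peaks do not merge (gap 0, overlap 0 bp)
  r3 <- make_repertoire("s1", data.frame(chrom = "chrA",
                                         start = c(100L, 200L),
                                         end = c(200L, 300L)))
  expect_identical(nrow(build_master_list(list(r3))$regions), 2L)
})

test_that("master-list merge matches the naive union oracle on random peaks", {
  set.seed(42)
  for (rep in 1:20) {
    peaks <- rand_regions(50)
    rep1 <- make_repertoire("s1", peaks[1:25, ])
    rep2 <- make_repertoire("s2", peaks[26:50, ])
    ml <- build_master_list(list(rep1, rep2))
    oracle <- naive_union(peaks)
    expect_equal(ml$regions$start, oracle$start)
    expect_equal(ml$regions$end, oracle$end)
    expect_equal(ml$regions$chrom, oracle$chrom)
  }
})

test_that("master-list regions are disjoint and cover every input peak", {
  set.seed(7)
  peaks <- rand_regions(200)
  reps <- list(make_repertoire("s1", peaks[1:100, ]),
               make_repertoire("s2", peaks[101:200, ]))
  ml <- build_master_list(reps)
  reg <- ml$regions
  by_ch <- split(reg, reg$chrom)
  for (b in by_ch) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  # every contributing peak appears in provenance exactly once
  expect_identical(nrow(ml$provenance), 200L)
  expect_identical(anyDuplicated(ml$provenance[c("sample_id", "peak_id")]), 0L)
})

test_that("count matrix from fragments matches brute-force overlap counting", {
  master <- build_master_list(list(make_repertoire(
    "s1", data.frame(chrom = "chrA", start = c(100L, 1000L), end = c(300L, 1200L)))))
  reps <- list(make_repertoire("s1", data.frame(chrom = "chrA", start = 100L, end = 300L)))
  frags <- data.frame(chrom = "chrA",
                      start = c(150L, 180L, 250L, 299L, 90L, 500L, 2000L),
                      end = c(220L, 260L, 320L, 380L, 101L, 580L, 2100L))
  m <- build_count_matrix(master, reps, fragments = list(s1 = frags))
  r1 <- master$regions[1, ]
  expect_identical(m[1, "s1"], naive_overlap_count(r1, frags))
  expect_identical(m[1, "s1"], 5L)
  expect_identical(m[2, "s1"], 0L)

  # random fixture against the oracle
  set.seed(11)
  for (rep in 1:10) {
    fr <- rand_regions(80, chroms = "chrA", max_width = 100)
    mm <- build_count_matrix(master, reps, fragments = list(s1 = fr))
    for (i in 1:2)
      expect_identical(mm[i, "s1"], naive_overlap_count(master$regions[i, ], fr))
  }
})

test_that("a fragment spanning two master regions is counted in both", {
  reps <- list(make_repertoire("s1", data.frame(
    chrom = "chrA", start = c(100L, 300L), end = c(200L, 400L))))
  master <- build_master_list(reps)
  frag <- data.frame(chrom = "chrA", start = 150L, end = 350L)
  m <- build_count_matrix(master, reps, fragments = list(s1 = frag))
  expect_identical(as.integer(m[, "s1"]), c(1L, 1L))
  expect_error(build_count_matrix(master, reps, fragments = list(zz = frag)),
               "unknown sample")
})

test_that("peak-count transfer sums multiple contributing peaks", {
  r1 <- make_repertoire("s1", data.frame(chrom = "chrA",
                                         start = c(100L, 180L),
                                         end = c(190L, 260L)),
                        counts = c(7L, 8L))
  master <- build_master_list(list(r1))
  expect_identical(nrow(master$regions), 1L)
  m <- build_count_matrix(master, list(r1))
  expect_identical(m[1, "s1"], 15L)
})

test_that("counting is invariant to fragment and sample order", {
  set.seed(5)
  peaks <- rand_regions(30, chroms = "chrA")
  r1 <- make_repertoire("s1", peaks[1:15, ])
  r2 <- make_repertoire("s2", peaks[16:30, ])
  master <- build_master_list(list(r1, r2))
  fr <- rand_regions(100, chroms = "chrA", max_width = 80)
  m1 <- build_count_matrix(master, list(r1, r2),
                           fragments = list(s1 = fr, s2 = fr[nrow(fr):1, ]))
  m2 <- build_count_matrix(master, list(r2, r1),
                           fragments = list(s2 = fr, s1 = fr[sample(nrow(fr)), ]))
  expect_identical(m1, m2[, colnames(m1)])
})

test_that("promoter classification respects the 5 kb midpoint window", {
  gm <- tiny_gene_model(tss = 10000L)
  # midpoint 4999 bp upstream of the TSS: promoter-like
  reps <- list(make_repertoire("s1", data.frame(
    chrom = "chrA", start = c(4901L, 4899L), end = c(5101L, 5099L))))
  # midpoints 5001 and 4999
  master <- build_master_list(list(make_repertoire("s1", data.frame(
    chrom = "chrA", start = c(4899L, 100L), end = c(5103L, 300L)))))
  ann <- annotate_regions(master, gm, promoter_window = 5000)
  # region 2 midpoint 200 -> distance 9800 -> distal
  expect_identical(ann$class[ann$tss_distance == 9800], "distal")

  m1 <- build_master_list(list(make_repertoire("s1", data.frame(
    chrom = "chrA", start = 4901L, end = 5101L))))  # midpoint 5001
  a1 <- annotate_regions(m1, gm, promoter_window = 5000)
  expect_identical(a1$tss_distance, 4999)
  expect_identical(a1$class, "promoter-like")

  m2 <- build_master_list(list(make_repertoire("s1", data.frame(
    chrom = "chrA", start = 4897L, end = 5101L))))  # midpoint 4999
  a2 <- annotate_regions(m2, gm, promoter_window = 5000)
  expect_identical(a2$tss_distance, 5001)
  expect_identical(a2$class, "distal")

  expect_error(annotate_regions(m2, list(genes = NULL)), "empty gene model")
})

test_that("nearest-gene assignment matches the exhaustive oracle", {
  set.seed(9)
  tss <- sort(sample.int(2e5, 20))
  gm <- tiny_gene_model(tss = as.integer(tss))
  peaks <- rand_regions(200, chroms = "chrA", max_pos = 2e5, max_width = 300)
  master <- build_master_list(list(make_repertoire("s1", peaks)))
  ann <- annotate_regions(master, gm)
  for (i in seq_len(nrow(master$regions))) {
    mid <- (master$regions$start[i] + master$regions$end[i]) / 2
    expect_identical(ann$nearest_gene[i],
                     gm$genes$gene_id[which.min(abs(tss - mid))])
  }
})

test_that("TSS inside a region gives distance 0", {
  gm <- tiny_gene_model(tss = 150L)
  m <- build_master_list(list(make_repertoire("s1", data.frame(
    chrom = "chrA", start = 100L, end = 900L))))
  ann <- annotate_regions(m, gm)
  expect_identical(ann$tss_distance, 0)
  expect_identical(ann$class, "promoter-like")
})

test_that("cohort summary reproduces the clinical-table worked examples", {
  tab <- example_cohort_table()
  s <- summarize_cohort(tab, group_col = "group")
  expect_identical(unname(s$n["newly_diagnosed"]), 30L)
  male <- subset(s$categorical, group == "newly_diagnosed" &
                   variable == "sex" & level == "M")
  expect_identical(male$n, 21L)
  expect_identical(male$pct, 70L)
  t1221 <- subset(s$categorical, group == "newly_diagnosed" &
                    variable == "abnormality" & level == "t(12;21)")
  expect_identical(t1221$pct, 20L)
  ages <- subset(s$numeric, group == "relapsed" & variable == "age_at_relapse")
  expect_equal(ages$mean, 11.7)
  expect_identical(c(ages$min, ages$max), c(5, 23))
  expect_error(summarize_cohort(tab[0, ]), "empty")
  expect_error(summarize_cohort(tab, "nope"), "not present")
})

test_that("gene model TSV round-trips", {
  gm <- tiny_gene_model(tss = c(5000L, 40000L), strand = c("+", "-"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_model(gm, f)
  back <- read_gene_model(f)
  expect_equal(back$genes, gm$genes, ignore_attr = TRUE)
  expect_equal(back$exons[order(back$exons$gene_id), ],
               gm$exons[order(gm$exons$gene_id), ], ignore_attr = TRUE)
})
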