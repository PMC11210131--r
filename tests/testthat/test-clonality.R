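make_master_and_rep <- function(n, counts, total = 1e6L, width = 200L) {
  st <- seq(0L, by = 1000L, length.out = n)
  peaks <- data.frame(chrom = "chrA", start = st, end = st + width)
  rep1 <- make_repertoire("s1", peaks, counts = counts, total = total)
  list(master = build_master_list(list(rep1)), rep = rep1)
}

test_that("CI percentile bins follow ceil(100 * rank / n) with 1 = highest", {
  x <- make_master_and_rep(5, counts = c(50L, 40L, 30L, 20L, 10L))
  ci <- clonality_index(x$rep, x$master)
  # peaks are equal-width so rank follows read count descending
  ord <- order(-ci$nscore)
  expect_identical(ci$ci[ord], c(20L, 40L, 60L, 80L, 100L))
})

test_that("Nscore follows the size- and depth-normalized formula", {
  x <- make_master_and_rep(2, counts = c(30L, 10L), total = 2e6L, width = 250L)
  ci <- clonality_index(x$rep, x$master)
  expect_equal(ci$nscore, ((c(30, 10) / 250) * 1e-6) * 1e-3 / 2e6)
})

test_that("CI is invariant to positive rescaling of the Nscore", {
  set.seed(3)
  counts <- sample(10:500, 50)
  a <- make_master_and_rep(50, counts = as.integer(counts), total = 1e6L)
  b <- make_master_and_rep(50, counts = as.integer(counts * 7L), total = 5e8L)
  expect_identical(clonality_index(a$rep, a$master)$ci,
                   clonality_index(b$rep, b$master)$ci)
})

test_that("absent master regions get CI 0 and NA Nscore", {
  peaks <- data.frame(chrom = "chrA", start = c(0L, 1000L), end = c(200L, 1200L))
  r1 <- make_repertoire("s1", peaks, counts = c(5L, 9L))
  r2 <- make_repertoire("s2", peaks[1, , drop = FALSE], counts = 5L)
  master <- build_master_list(list(r1, r2))
  ci2 <- clonality_index(r2, master)
  expect_identical(ci2$ci[2], 0L)
  expect_true(is.na(ci2$nscore[2]))
  expect_identical(ci2$ci[1], 100L)  # sole present peak: ceil(100*1/1)
  expect_error(clonality_index(list(sample_id = "x", total_mapped_reads = 0L,
                                    peaks = peaks), master), "total mapped")
})

test_that("ties share the bin of their minimum rank", {
  x <- make_master_and_rep(4, counts = c(50L, 50L, 20L, 10L))
  ci <- clonality_index(x$rep, x$master)
  ord <- order(x$master$regions$start)
  expect_identical(ci$ci[ord], c(25L, 25L, 75L, 100L))
})

test_that("penetrance equals presence row sums and respects bounds", {
  set.seed(21)
  pres <- matrix(runif(200 * 32) < 0.3, 200, 32,
                 dimnames = list(paste0("r", 1:200), paste0("s", 1:32)))
  pres[1, ] <- TRUE              # universally shared
  pres[2, ] <- FALSE; pres[2, 5] <- TRUE  # private
  pi <- penetrance_index(pres)
  expect_identical(unname(pi["r1"]), 32L)
  expect_identical(unname(pi["r2"]), 1L)
  manual <- rowSums(pres)
  manual <- manual[manual > 0]
  expect_equal(unname(pi), unname(as.integer(manual[names(pi)])))
  expect_true(all(pi >= 1 & pi <= 32))
  expect_error(penetrance_index(pres, scope = character()), "empty scope")
  # double-counting identity: sum of PI = sum of per-sample detections
  expect_identical(sum(rowSums(pres)), sum(colSums(pres)))
})

test_that("penetrance composition bands sum to one and recover edge cases", {
  pres <- matrix(FALSE, 10, 3, dimnames = list(paste0("r", 1:10), c("a", "b", "c")))
  pres[1:5, 1] <- TRUE           # private to sample a
  pres[6:10, 2:3] <- TRUE        # shared between b and c
  comp <- penetrance_composition(pres, list(g1 = "a", g2 = c("b", "c")), low_cut = 2L)
  g1 <- comp[comp$group == "g1", ]
  expect_equal(g1$fraction[g1$band == "private"], 1.0)
  sums <- tapply(comp$fraction, comp$group, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_error(penetrance_composition(pres, list(g1 = "a", bad = "b"),
                                      low_cut = 2L), NA)
  pres2 <- pres; pres2[, 2:3] <- FALSE
  expect_error(penetrance_composition(pres2, list(g1 = "a", g2 = c("b", "c"))),
               "zero detected")
})

test_that("synthetic onset composition recovers the configured 60% target", {
  cfg <- cohort_config(seed = 11L)
  sim <- simulate_cohort(cfg)
  groups <- split(sim$metadata$sample_id, sim$metadata$stage)
  comp <- penetrance_composition(sim$presence, groups, low_cut = 14L)
  onset <- comp[comp$group == "onset", ]
  got <- sum(onset$fraction[onset$band %in% c("private", "low")])
  expect_lt(abs(got - 0.6), 0.05)
})

test_that("O/E is 1 for duplicated groups and matches the closed form", {
  set.seed(13)
  base <- matrix(runif(300 * 4) < 0.4, 300, 4)
  pres <- cbind(base, base)
  colnames(pres) <- c(paste0("a", 1:4), paste0("b", 1:4))
  rownames(pres) <- paste0("r", 1:300)
  pres <- pres[rowSums(pres) > 0, ]
  oe <- penetrance_oe(pres, paste0("a", 1:4), paste0("b", 1:4))
  expect_true(all(abs(oe$oe - 1) < 1e-12, na.rm = TRUE))

  # constructed: A holds all PI=1 regions, B none -> O/E at PI=1 is 1/shareA
  pres2 <- matrix(FALSE, 40, 4, dimnames = list(paste0("r", 1:40),
                                                c("a1", "a2", "b1", "b2")))
  pres2[1:10, "a1"] <- TRUE                     # PI=1, A only
  pres2[11:40, c("a1", "a2", "b1", "b2")] <- TRUE  # PI=4 everywhere
  oe2 <- penetrance_oe(pres2, c("a1", "a2"), c("b1", "b2"))
  shareA <- 40 / (40 + 30)
  expect_equal(oe2$oe[oe2$pi == 1], 1 / shareA)
})

test_that("empty expected bins are reported as missing, not zero", {
  pres <- matrix(FALSE, 3, 4, dimnames = list(paste0("r", 1:3),
                                              c("a1", "a2", "b1", "b2")))
  pres[1, "a1"] <- TRUE
  pres[2, c("a1", "b1")] <- TRUE
  pres[3, c("a1", "a2", "b1")] <- TRUE
  oe <- penetrance_oe(pres, c("a1", "a2"), c("b1", "b2"))
  expect_false(any(oe$expected_A == 0 & !is.na(oe$oe)))
  expect_error(penetrance_oe(pres, character(), "b1"), "empty group")
})

test_that("clonality and penetrance are positively associated when the NB mean rises with penetrance", {
  cfg <- cohort_config(n_core_peaks = 600L, n_dynamic_peaks = 0L,
                       pi_mean_coupling = 8, seed = 5L)
  sim <- simulate_cohort(cfg)
  master <- build_master_list(sim$repertoires)
  ct <- clonality_table(sim$repertoires, master)
  pres <- presence_matrix(master, sim$metadata$sample_id)
  pi <- rowSums(pres)
  # mean activity (101 - CI over present cells) should rise with PI
  act <- ifelse(ct$ci > 0, 101 - ct$ci, NA)
  mean_act <- rowMeans(act, na.rm = TRUE)
  keep <- pi > 0 & !is.na(mean_act)
  expect_gt(stats::cor(pi[keep], mean_act[keep], method = "spearman"), 0.2)
})
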