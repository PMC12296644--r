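lay <- genome_layout("chr1", 1e5)

test_that("feature counting sums value x bp and guards units", {
  depth1 <- coverage_track("chr1", 0, 1e4, 1, lay, units = "raw_count")
  rs <- region_set("chr1", 1000, 1300, "r1")
  cm <- count_features(list(s1 = depth1), rs)
  expect_equal(cm["r1", "s1"], 300L)
  empty <- coverage_track(character(), numeric(), numeric(), numeric(),
                          lay, units = "raw_count")
  expect_equal(count_features(list(s1 = empty), rs)["r1", "s1"], 0L)
  rpkm <- coverage_track("chr1", 0, 10, 1, lay, units = "rpkm")
  expect_error(count_features(list(s1 = rpkm), rs), "raw_count")
})

test_that("feature counts match the dense per-base sum oracle", {
  set.seed(71)
  for (i in 1:20) {
    tr <- random_track(lay, 40, units = "raw_count")
    start <- sort(sample(0:90000, 4))
    rs <- region_set("chr1", start,
                     start + sample(500:5000, 4, replace = TRUE),
                     paste0("r", 1:4))
    got <- count_features(list(s = tr), rs)[, "s"]
    want <- vapply(1:4, function(k)
      round(sum(dense_values(tr, "chr1", rs$start[k], rs$end[k]))), 0)
    expect_equal(unname(got), as.integer(want))
  }
})

test_that("size factors are medians of ratios to the geometric mean", {
  m <- matrix(c(10, 20, 40, 10, 20, 40, 20, 40, 80), ncol = 3,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:3)))
  sf <- size_factors(m)
  expect_equal(unname(sf[1]), unname(sf[2]))
  expect_equal(unname(sf[3] / sf[1]), 2)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "positive")
})

test_that("size factors recover known depth multipliers within 5%", {
  sim <- simulate_nb_counts(n_features = 3000, n_per_group = 3,
                            dispersion = 0.05, frac_up = 0, frac_down = 0,
                            depth_range = c(1, 1), seed = 73)
  depths <- c(1, 1.5, 2, 1, 1.5, 2)
  scaled <- round(sweep(sim$counts, 2, depths, "*"))
  sf <- size_factors(scaled)
  sf <- sf / exp(mean(log(sf)))
  want <- depths / exp(mean(log(depths)))
  expect_true(all(abs(sf / want - 1) < 0.05))
})

test_that("dispersion estimation recovers simulated regimes", {
  pois <- simulate_nb_counts(n_features = 1500, n_per_group = 10,
                             dispersion = 0, frac_up = 0, frac_down = 0,
                             seed = 79)
  cond <- pois$condition
  a0 <- estimate_dispersion(pois$counts, size_factors(pois$counts), cond)
  expect_lte(median(a0, na.rm = TRUE), 0.01)
  nb <- simulate_nb_counts(n_features = 2000, n_per_group = 10,
                           dispersion = 0.2, frac_up = 0, frac_down = 0,
                           seed = 83)
  a2 <- estimate_dispersion(nb$counts, size_factors(nb$counts),
                            nb$condition)
  expect_gte(median(a2, na.rm = TRUE), 0.1)
  expect_lte(median(a2, na.rm = TRUE), 0.3)
})

test_that("all-zero features get NA dispersion and are skipped in testing", {
  sim <- simulate_nb_counts(n_features = 200, n_per_group = 3, seed = 87)
  counts <- sim$counts
  counts[5, ] <- 0L
  sf <- size_factors(counts)
  a <- estimate_dispersion(counts, sf, sim$condition)
  expect_true(is.na(a[5]))
  res <- nb_wald_test(counts, sf, a, sim$condition)
  expect_true(is.na(res$wald_p[5]))
  expect_false(anyNA(res$wald_p[-5]))
})

test_that("constant normalised counts hit the dispersion floor", {
  m <- matrix(rep(c(100L, 200L), each = 60), nrow = 30)
  colnames(m) <- paste0("s", 1:4); rownames(m) <- paste0("f", 1:30)
  cond <- factor(c("day7", "day7", "day10", "day10"),
                 levels = c("day7", "day10"))
  a <- estimate_dispersion(m, size_factors(m), cond)
  expect_true(all(a <= 1e-6))
})

test_that("the NB Wald test recovers planted fold changes", {
  # known unit depths: with every feature changed, median-of-ratios size
  # factors would absorb the shift, so the engine is tested with true ones
  sim <- simulate_nb_counts(n_features = 500, n_per_group = 3,
                            base_mean_range = c(400, 600),
                            dispersion = 0.1, frac_up = 1, frac_down = 0,
                            lfc = 2, depth_range = c(1, 1), seed = 91)
  sf <- stats::setNames(rep(1, 6), colnames(sim$counts))
  res <- nb_wald_test(sim$counts, sf,
                      estimate_dispersion(sim$counts, sf, sim$condition),
                      sim$condition)
  expect_lt(abs(median(res$log2_fold_change) - 2), 0.3)
})

test_that("null features give small fold changes and p near uniform", {
  sim <- simulate_nb_counts(n_features = 1000, n_per_group = 4,
                            dispersion = 0.1, frac_up = 0, frac_down = 0,
                            seed = 93)
  sf <- size_factors(sim$counts)
  res <- nb_wald_test(sim$counts, sf,
                      estimate_dispersion(sim$counts, sf, sim$condition),
                      sim$condition)
  expect_lt(abs(median(res$log2_fold_change)), 0.05)
  expect_gt(stats::ks.test(res$wald_p, "punif")$p.value, 0.01)
})

test_that("swapping condition labels negates fold changes, keeps p", {
  sim <- simulate_nb_counts(n_features = 300, n_per_group = 3,
                            frac_up = 0.2, seed = 97)
  sf <- size_factors(sim$counts)
  a <- estimate_dispersion(sim$counts, sf, sim$condition)
  res <- nb_wald_test(sim$counts, sf, a, sim$condition)
  flipped <- factor(sim$condition,
                    levels = rev(levels(sim$condition)))
  res2 <- nb_wald_test(sim$counts, sf, a, flipped)
  expect_equal(res2$log2_fold_change, -res$log2_fold_change,
               tolerance = 1e-6)
  expect_equal(res2$wald_p, res$wald_p, tolerance = 1e-6)
})

test_that("scaling a sample and its size factor leaves results unchanged", {
  sim <- simulate_nb_counts(n_features = 300, n_per_group = 3,
                            frac_up = 0.1, seed = 101)
  sf <- size_factors(sim$counts)
  a <- estimate_dispersion(sim$counts, sf, sim$condition)
  res <- nb_wald_test(sim$counts, sf, a, sim$condition)
  counts2 <- sim$counts
  counts2[, 2] <- counts2[, 2] * 2L
  sf2 <- sf
  sf2[2] <- sf2[2] * 2
  res2 <- nb_wald_test(counts2, sf2, a, sim$condition)
  # exact only in the Poisson limit: NB weights mu/(1 + alpha mu) shift
  # slightly under a joint count/size-factor rescaling
  expect_equal(res2$log2_fold_change, res$log2_fold_change,
               tolerance = 0.02)
  expect_equal(res2$wald_p, res$wald_p, tolerance = 0.05)
})

test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(103)
  p <- runif(200)
  adj <- bh_adjust(p)
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  perm <- sample(200)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("differential calls require both fold change and significance", {
  res <- structure(
    data.frame(feature = c("a", "b", "c", "d"),
               base_mean = rep(100, 4),
               log2_fold_change = c(2, 2, -2, 0.3),
               se = rep(0.2, 4), wald_stat = c(10, 10, -10, 1.5),
               wald_p = c(1e-8, 0.15, 1e-8, 0.13)),
    class = c("differential_result", "data.frame"))
  cls <- classify_differential(res, lfc_threshold = 1.5, alpha = 0.05)
  expect_equal(cls$call, c("increased", "unchanged", "decreased",
                           "unchanged"))
  expect_true(all(cls$adjusted_p >= cls$wald_p))
  rna <- region_scores(c(100, 100, 10, 100), c("a", "b", "c", "d"))
  gated <- classify_differential(res, rna_day7 = rna, min_expression = 25)
  expect_equal(gated$call[3], "excluded")
  expect_true(is.na(gated$adjusted_p[3]))
})

test_that("planted calls reach stated sensitivity and FDR on NB panels", {
  sim <- simulate_nb_counts(n_features = 1000, n_per_group = 3,
                            dispersion = 0.1, frac_up = 0.1,
                            frac_down = 0.1, lfc = 2, seed = 107)
  sf <- size_factors(sim$counts)
  res <- classify_differential(
    nb_wald_test(sim$counts, sf,
                 estimate_dispersion(sim$counts, sf, sim$condition),
                 sim$condition))
  up <- res$call == "increased"; dn <- res$call == "decreased"
  tp <- sum((up & sim$true_lfc > 0) | (dn & sim$true_lfc < 0))
  fp <- sum(up | dn) - tp
  expect_lte(fp / max(tp + fp, 1), 0.10)
  expect_gte(tp / sum(sim$true_lfc != 0), 0.7)
})
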