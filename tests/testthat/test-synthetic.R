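tiny_cfg <- function(...) synthetic_config(seed = 9, n_chrom = 1,
                                           chrom_length = 1.2e6,
                                           n_genes = 40, ...)

test_that("the generator is a pure function of its configuration", {
  a <- generate_dataset(tiny_cfg())
  b <- generate_dataset(tiny_cfg())
  expect_identical(as.data.frame(a$genes[, 1:7]),
                   as.data.frame(b$genes[, 1:7]))
  expect_identical(a$truth$genes, b$truth$genes)
  expect_identical(lapply(a$tracks, as.data.frame),
                   lapply(b$tracks, as.data.frame))
  c <- generate_dataset(synthetic_config(seed = 10, n_chrom = 1,
                                         chrom_length = 1.2e6,
                                         n_genes = 40))
  expect_false(identical(a$genes$start, c$genes$start))
})

test_that("generated genes never overlap and respect the length range", {
  g <- make_genome(synthetic_config(seed = 21, n_chrom = 2,
                                    chrom_length = 5e6,
                                    n_genes = 300))$genes
  for (ch in unique(g$chrom)) {
    s <- g[g$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  expect_true(all(g$end - g$start >= 2000 & g$end - g$start <= 50000))
  expect_true(all(vapply(g$exons, nrow, 0L) >= 1))
  expect_error(make_genome(synthetic_config(n_genes = 500, n_chrom = 1,
                                            chrom_length = 1e6)),
               "packing")
})

test_that("zero noise gives identical replicates; classes separate cleanly", {
  ds <- small_noisefree_dataset()
  r1 <- ds$tracks$me1_day7_rep1
  r2 <- ds$tracks$me1_day7_rep2
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  ds_noisy <- small_noisy_dataset()
  # active-class gene bodies carry > 5x background H4K20me1 per replicate
  truth <- ds_noisy$truth$genes
  active <- truth$gene_id[truth$class == "active_body_me1"]
  body <- bodies_of(ds_noisy$genes, ds_noisy$layout)
  for (k in 1:3) {
    sc <- score_regions(ds_noisy$tracks[[paste0("me1_day7_rep", k)]], body)
    bg_genes <- truth$gene_id[truth$class == "background"]
    expect_true(all(sc[active] > 5 * mean(sc[bg_genes])))
  }
})

test_that("simulated NB counts match their moments and planted nulls", {
  lim <- simulate_nb_counts(n_features = 400, n_per_group = 10,
                            dispersion = 0, frac_up = 0, frac_down = 0,
                            depth_range = c(1, 1), seed = 15)
  m <- rowMeans(lim$counts)
  v <- apply(lim$counts, 1, var)
  # Poisson limit: variance tracks the mean
  expect_lt(abs(median(v / m) - 1), 0.2)
  nullsim <- simulate_nb_counts(n_features = 2000, n_per_group = 10,
                                dispersion = 0.05, frac_up = 0,
                                frac_down = 0, depth_range = c(1, 1),
                                seed = 16)
  emp_lfc <- log2(rowMeans(nullsim$counts[, 11:20]) /
                    rowMeans(nullsim$counts[, 1:10]))
  expect_lt(abs(mean(emp_lfc)), 0.05)
  again <- simulate_nb_counts(n_features = 400, n_per_group = 10,
                              dispersion = 0, frac_up = 0, frac_down = 0,
                              depth_range = c(1, 1), seed = 15)
  expect_identical(lim$counts, again$counts)
})

test_that("truth-linked count simulation carries the planted fold changes", {
  cfg <- tiny_cfg()
  genome <- make_genome(cfg)
  truth <- plant_truth(cfg, genome)
  sim <- simulate_counts(cfg, genome, truth)
  expect_equal(dim(sim$counts), c(40, 6))
  expect_equal(sim$true_lfc[truth$genes$gene_id],
               stats::setNames(truth$genes$true_lfc_me1_body,
                               truth$genes$gene_id))
  gain <- truth$genes$gene_id[truth$genes$class == "dynamic_gain_me1"]
  if (length(gain)) {
    emp <- log2(rowMeans(sim$counts[gain, 4:6, drop = FALSE]) /
                  rowMeans(sim$counts[gain, 1:3, drop = FALSE]))
    expect_gt(mean(emp), 1)
  }
})

test_that("fixtures round-trip through the on-disk layout", {
  ds <- generate_dataset(tiny_cfg())
  dir <- file.path(tempdir(), "fixture_roundtrip")
  unlink(dir, recursive = TRUE)
  write_fixture(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("chrom.sizes",
                                               "annotation.bed12",
                                               "truth.tsv",
                                               "config.yaml",
                                               "manifest.json")))))
  back <- read_fixture(dir)
  expect_equal(back$layout$chrom_lengths, ds$layout$chrom_lengths)
  expect_equal(back$genes$gene_id, ds$genes$gene_id)
  expect_equal(back$genes$tss, ds$genes$tss)
  nm <- "me1_day7_rep1"
  expect_equal(as.data.frame(back$tracks[[nm]])[, c("start", "end")],
               as.data.frame(ds$tracks[[nm]])[, c("start", "end")])
  expect_equal(back$tracks[[nm]]$value, ds$tracks[[nm]]$value,
               tolerance = 1e-9)
  expect_equal(back$truth$class, ds$truth$genes$class)
  expect_equal(back$track_meta$total_reads,
               ds$depths$total_reads[match(back$track_meta$track,
                                           ds$depths$track)])
})

test_that("planted me1/me3 peak regions overlap only at paused TSSs", {
  ds <- small_noisefree_dataset()
  cut <- ds$config$peak_cutoffs
  me1 <- call_peaks_threshold(merged_rpkm(ds, "me1", "day7"), cut[["me1"]])
  me3 <- call_peaks_threshold(merged_rpkm(ds, "me3", "day7"), cut[["me3"]])
  v <- venn_overlap(peaks_as_regions(me1), peaks_as_regions(me3))
  truth <- ds$truth$genes
  paused <- truth$gene_id[truth$class == "paused_tss_me3"]
  expect_equal(v$both_a, length(paused))
  paused_prom <- promoters_of(
    ds$genes[ds$genes$gene_id %in% paused, ], 500, ds$layout)
  off <- venn_overlap(v$shared_regions, paused_prom)
  expect_equal(off$only_a, 0)  # every shared peak sits at a paused TSS
})
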