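lay <- genome_layout("chr1", 1e5)

test_that("bedGraph round trip is exact after canonicalisation", {
  tr <- coverage_track(c("chr1", "chr1", "chr1"), c(0, 100, 400),
                       c(100, 200, 500), c(2.5, 2.5, 1), lay)
  # adjacent equal values were merged on construction
  expect_equal(nrow(tr), 2)
  expect_equal(tr$end[1], 200)
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, lay)
  expect_equal(as.data.frame(back), as.data.frame(tr))
  set.seed(7)
  for (i in 1:20) {
    t2 <- random_track(lay, 25)
    write_bedgraph(t2, path)
    expect_equal(as.data.frame(read_bedgraph(path, lay)),
                 as.data.frame(t2))
  }
})

test_that("malformed bedGraph input is rejected", {
  expect_error(coverage_track(c("chr1", "chr1"), c(0, 50), c(100, 150),
                              c(1, 2), lay), "overlap")
  bad <- tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t100\tnot_a_number", bad)
  expect_error(read_bedgraph(bad, lay), "parse|invalid|numeric")
})

test_that("rpkm normalisation follows the deepTools convention", {
  tr <- coverage_track("chr1", 0, 1000, 2, lay, units = "raw_count")
  r <- rpkm_normalize(tr, total_reads = 1e6, read_bin = 50)
  expect_equal(r$value, 40)  # 2 * 1e9 / (50 * 1e6)
  r2 <- rpkm_normalize(tr, total_reads = 2e6, read_bin = 50)
  expect_equal(r2$value, 20)
  expect_error(rpkm_normalize(r, 1e6), "raw_count")
  expect_error(rpkm_normalize(tr, 0), "total_reads")
})

test_that("rpkm normalisation is linear over track addition", {
  set.seed(11)
  a <- random_track(lay, 20, units = "raw_count")
  b <- random_track(lay, 20, units = "raw_count")
  summed <- merge_replicates(list(a, b), method = "sum")
  lhs <- rpkm_normalize(summed, 1e6)
  rhs <- merge_replicates(list(rpkm_normalize(a, 1e6),
                               rpkm_normalize(b, 1e6)), method = "sum")
  pos <- seq(0, 1e5 - 1, by = 17)
  expect_equal(h4k20dyn:::value_at(lhs[lhs$chrom == "chr1", ], pos),
               h4k20dyn:::value_at(rhs[rhs$chrom == "chr1", ], pos),
               tolerance = 1e-12)
})

test_that("replicate merging averages per base and checks units", {
  t1 <- coverage_track("chr1", 100, 200, 2, lay)
  t2 <- coverage_track("chr1", 150, 250, 4, lay)
  m <- merge_replicates(list(t1, t2))
  expect_equal(oracle_region_mean(m, "chr1", 150, 200), 3)
  ident <- merge_replicates(list(t1, t1))
  expect_equal(as.data.frame(ident), as.data.frame(t1))
  raw <- coverage_track("chr1", 0, 10, 1, lay, units = "raw_count")
  expect_error(merge_replicates(list(t1, raw)), "units")
  expect_error(merge_replicates(list(t1)), "two tracks")
})

test_that("merging matches the dense per-base mean oracle", {
  set.seed(13)
  for (i in 1:25) {
    tracks <- lapply(1:3, function(k) random_track(lay, 30))
    m <- merge_replicates(tracks)
    dense <- rowMeans(vapply(tracks, dense_values, numeric(1e5),
                             chrom = "chr1", from = 0, to = 1e5))
    expect_equal(dense_values(m, "chr1", 0, 1e5), dense, tolerance = 1e-9)
  }
})

test_that("region scores are length-weighted means", {
  tr <- coverage_track("chr1", 0, 500, 10, lay)  # implicit 0 beyond 500
  rs <- region_set("chr1", 0, 1000, "r1")
  expect_equal(as.numeric(score_regions(tr, rs)), 5)
  uni <- coverage_track("chr1", 0, 1000, 5, lay)
  expect_equal(as.numeric(score_regions(uni, rs)), 5)
})

test_that("region scores match the dense oracle on random instances", {
  set.seed(17)
  for (i in 1:60) {
    tr <- random_track(lay, 40)
    start <- sort(sample(0:99000, 5))
    rs <- region_set("chr1", start,
                     start + sample(100:900, 5, replace = TRUE),
                     paste0("r", 1:5))
    got <- as.numeric(score_regions(tr, rs))
    want <- vapply(seq_len(5), function(k)
      oracle_region_mean(tr, "chr1", rs$start[k], rs$end[k]), 0)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("grouped merged-exon scores use the summed exon length", {
  tr <- coverage_track("chr1", c(0, 1000), c(100, 1300), c(6, 3), lay)
  g <- gene_models("g1", "chr1", "+", 0, 1300,
                   list(cbind(c(0, 1000), c(100, 1300))), layout = lay)
  sc <- score_regions(tr, merged_exons_of(g))
  expect_equal(as.numeric(sc), (100 * 6 + 300 * 3) / 400)
  expect_equal(names(sc), "g1")
})

test_that("metagene matrices anchor, scale and strand-flip correctly", {
  g <- gene_models("g1", "chr1", "+", 10000, 14000,
                   list(cbind(10000, 14000)), layout = lay)
  uni <- coverage_track("chr1", 0, 1e5, 7, lay)
  m <- metagene_matrix(uni, g, body_bins = 10, flank = 1000,
                       flank_bins = 10)
  expect_equal(dim(m), c(1, 30))
  expect_true(all(abs(m - 7) < 1e-12))
  step <- coverage_track("chr1", 10000, 14000, 5, lay)
  ms <- metagene_matrix(step, g, body_bins = 10, flank = 1000,
                        flank_bins = 10)
  expect_equal(as.numeric(ms[1, 11:20]), rep(5, 10))
  expect_equal(as.numeric(ms[1, c(1:10, 21:30)]), rep(0, 20))
  # minus-strand row is the reverse of the plus-strand one
  ramp <- coverage_track("chr1", seq(9000, 14900, 100),
                         seq(9100, 15000, 100), 1:60, lay)
  gm <- gene_models("g1m", "chr1", "-", 10000, 14000,
                    list(cbind(10000, 14000)), layout = lay)
  mp <- metagene_matrix(ramp, g, body_bins = 8, flank = 1000,
                        flank_bins = 5)
  mm <- metagene_matrix(ramp, gm, body_bins = 8, flank = 1000,
                        flank_bins = 5)
  expect_equal(as.numeric(mm[1, ]), rev(as.numeric(mp[1, ])))
})

test_that("center_tss metagenes window the TSS and drop short genes", {
  g <- gene_models("g1", "chr1", "+", 10000, 14000,
                   list(cbind(10000, 14000)), layout = lay)
  step <- coverage_track("chr1", 10000, 14000, 5, lay)
  mc <- metagene_matrix(step, g, flank = 1000, flank_bins = 10,
                        anchor = "center_tss")
  expect_equal(dim(mc), c(1, 20))
  expect_equal(as.numeric(mc[1, ]), c(rep(0, 10), rep(5, 10)))
  tiny <- gene_models("t", "chr1", "+", 500, 550, list(cbind(500, 550)),
                      layout = lay)
  expect_warning(md <- metagene_matrix(step, tiny, body_bins = 100),
                 "shorter")
  expect_equal(nrow(md), 0)
})

test_that("metagene bins match the dense per-base oracle", {
  set.seed(23)
  for (i in 1:10) {
    tr <- random_track(lay, 50)
    start <- sample(5000:50000, 1)
    len <- sample(2000:20000, 1)
    strand <- sample(c("+", "-"), 1)
    g <- gene_models("g", "chr1", strand, start, start + len,
                     list(cbind(start, start + len)), layout = lay)
    m <- metagene_matrix(tr, g, body_bins = 20, flank = 500,
                         flank_bins = 10)
    bounds <- c(seq(start - 500, start, length.out = 11)[-11],
                floor(seq(start, start + len, length.out = 21)),
                seq(start + len, start + len + 500, length.out = 11)[-1])
    want <- vapply(seq_len(40), function(k)
      oracle_region_mean(tr, "chr1", bounds[k], bounds[k + 1]), 0)
    if (strand == "-") want <- rev(want)
    expect_equal(as.numeric(m[1, ]), want, tolerance = 1e-9)
  }
})

test_that("deciles are balanced, ordered and deterministic under ties", {
  sc <- region_scores(1:20, sprintf("g%02d", 1:20), "body")
  d <- assign_deciles(sc)
  expect_equal(as.numeric(table(as.integer(d))), rep(2, 10))
  sc100 <- region_scores(1:100, sprintf("g%03d", 1:100), "body")
  d100 <- assign_deciles(sc100)
  expect_equal(names(d100)[as.integer(d100) == 10], sprintf("g%03d", 91:100))
  tied <- region_scores(rep(1, 30), sprintf("t%02d", 30:1), "body")
  expect_identical(assign_deciles(tied), assign_deciles(tied))
  expect_equal(as.integer(assign_deciles(tied)[["t01"]]), 1)
  expect_error(assign_deciles(region_scores(1:5, letters[1:5])), "10")
})

test_that("decile mean scores are non-decreasing by construction", {
  set.seed(29)
  sc <- region_scores(rlnorm(137), paste0("g", 1:137), "body")
  d <- assign_deciles(sc)
  means <- tapply(as.numeric(sc), as.integer(d), mean)
  expect_true(all(diff(means) >= 0))
})

test_that("pearson correlations match the direct formula and filters", {
  x <- region_scores(c(1, 2, 3, 4, 5), letters[1:5])
  y <- region_scores(c(2, 3, 4, 5, 6), letters[1:5])
  neg <- region_scores(10 - c(1, 2, 3, 4, 5), letters[1:5])
  m <- pearson_correlation_matrix(list(x = x, y = y, neg = neg))
  expect_equal(unname(diag(m)), c(1, 1, 1))
  expect_equal(m["x", "y"], 1)
  expect_equal(m["x", "neg"], -1)
  set.seed(31)
  a <- region_scores(runif(50), paste0("g", 1:50))
  b <- region_scores(runif(50), paste0("g", 1:50))
  got <- pearson_correlation_matrix(list(a = a, b = b))["a", "b"]
  av <- as.numeric(a); bv <- as.numeric(b)
  want <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(got, want, tolerance = 1e-12)
  # positive filter restricts to labels positive in both sets
  c1 <- region_scores(c(0, 0, 1, 2, 3), paste0("g", 1:5))
  c2 <- region_scores(c(5, 1, 2, 4, 6), paste0("g", 1:5))
  mf <- pearson_correlation_matrix(list(c1 = c1, c2 = c2),
                                   positive_filter = TRUE)
  expect_equal(mf["c1", "c2"], stats::cor(c(1, 2, 3), c(2, 4, 6)))
  # fewer than 3 shared labels is undefined
  s1 <- region_scores(1:2, c("a", "b"))
  s2 <- region_scores(2:1, c("a", "b"))
  expect_true(is.na(pearson_correlation_matrix(list(s1 = s1,
                                                    s2 = s2))["s1", "s2"]))
})
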