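# Independent dense per-base oracles and small random-instance generators.
# Oracles materialise signal base by base and never share code with the
# interval-arithmetic implementation they check.

# per-base signal vector of a track over [from, to) on one chromosome
dense_values <- function(track, chrom, from, to) {
  v <- numeric(to - from)
  rows <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(rows)) for (i in seq_len(nrow(rows))) {
    lo <- max(rows$start[i], from)
    hi <- min(rows$end[i], to)
    if (hi > lo) v[(lo - from + 1):(hi - from)] <- rows$value[i]
  }
  v
}

# dense mean over a region (missing coverage = 0)
oracle_region_mean <- function(track, chrom, start, end) {
  mean(dense_values(track, chrom, start, end))
}

# per-base boolean-scan peak caller with the same cutoff/gap/length rules
oracle_peaks <- function(track, cutoff, min_length, max_gap) {
  layout <- attr(track, "layout")
  out <- list()
  for (ch in unique(track$chrom)) {
    L <- unname(layout$chrom_lengths[ch])
    v <- dense_values(track, ch, 0, L)
    above <- v >= cutoff
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] <= max_gap)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    merged <- merged[merged$end - merged$start >= min_length, , drop = FALSE]
    if (nrow(merged)) {
      merged$summit <- vapply(seq_len(nrow(merged)), function(i)
        max(v[(merged$start[i] + 1):merged$end[i]]), 0)
      merged$chrom <- ch
      out[[ch]] <- merged
    }
  }
  if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
  else data.frame(start = numeric(), end = numeric(), summit = numeric(),
                  chrom = character())
}

# random piecewise-constant track on a small single-chromosome layout
random_track <- function(layout, n_intervals = 30, max_value = 10,
                         units = "rpkm") {
  ch <- layout$chrom_names[1]
  L <- unname(layout$chrom_lengths[ch])
  bounds <- sort(sample(0:L, 2 * n_intervals))
  start <- bounds[seq(1, length(bounds), 2)]
  end <- bounds[seq(2, length(bounds), 2)]
  keep <- end > start
  coverage_track(rep(ch, sum(keep)), start[keep], end[keep],
                 round(stats::runif(sum(keep), 0, max_value), 2),
                 layout, units = units)
}

# cached small synthetic datasets shared across test files
synthetic_cache <- local({
  cache <- list()
  function(key, maker) {
    if (is.null(cache[[key]])) cache[[key]] <<- maker()
    cache[[key]]
  }
})

small_noisy_dataset <- function() {
  synthetic_cache("small_noisy", function()
    generate_dataset(synthetic_config(seed = 3, preset = "small")))
}

small_noisefree_dataset <- function() {
  synthetic_cache("small_clean", function()
    generate_dataset(synthetic_config(seed = 5, preset = "small",
                                      noise_sigma = 0)))
}

# rpkm-normalised merged track for one mark/day of a synthetic dataset
merged_rpkm <- function(ds, mark, day) {
  nms <- grep(paste0("^", mark, "_", day, "_rep"), names(ds$tracks),
              value = TRUE)
  norm <- lapply(nms, function(nm) {
    d <- ds$depths[ds$depths$track == nm, ]
    rpkm_normalize(ds$tracks[[nm]], d$total_reads, ds$config$read_bin)
  })
  if (length(norm) > 1) merge_replicates(norm) else norm[[1]]
}
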