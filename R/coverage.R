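#' Coverage tracks
#'
#' A genome-wide piecewise-constant signal: per chromosome, sorted
#' non-overlapping intervals (0-based half-open) with a non-negative value.
#' Gaps carry an implicit value of 0. Tracks are canonicalised on
#' construction: zero-value and zero-width intervals are dropped and adjacent
#' intervals with equal value are merged, so equal signals have equal
#' representations.
#'
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param value Non-negative signal value per interval.
#' @param layout A [genome_layout()].
#' @param units `"raw_count"` (unnormalised) or `"rpkm"`.
#' @return An object of class `coverage_track` (a data frame with columns
#'   `chrom`, `start`, `end`, `value` and attributes `layout`, `units`).
#' @export
coverage_track <- function(chrom, start, end, value, layout,
                           units = c("rpkm", "raw_count")) {
  units <- match.arg(units)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$value)) || any(df$value < 0))
    stop("track values must be finite and >= 0")
  if (any(df$start < 0) || any(df$start > df$end))
    stop("track intervals must satisfy 0 <= start <= end")
  if (any(df$end > chrom_length(layout, df$chrom)))
    stop("track interval extends past chromosome end")
  df <- df[df$end > df$start & df$value != 0, , drop = FALSE]
  df <- df[order(match(df$chrom, layout$chrom_names), df$start), ,
           drop = FALSE]
  # overlap check + merge of adjacent equal-value runs, per chromosome
  parts <- split(df, factor(df$chrom, levels = unique(df$chrom)))
  parts <- lapply(parts, function(p) {
    if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)]))
      stop("overlapping intervals in coverage track on ", p$chrom[1])
    run <- cumsum(c(TRUE, !(p$value[-1] == p$value[-nrow(p)] &
                              p$start[-1] == p$end[-nrow(p)])))
    run <- factor(run, levels = unique(run))
    data.frame(chrom = p$chrom[match(levels(run), run)],
               start = as.numeric(tapply(p$start, run, min)),
               end = as.numeric(tapply(p$end, run, max)),
               value = p$value[match(levels(run), run)],
               stringsAsFactors = FALSE)
  })
  out <- if (length(parts))
    do.call(rbind, c(parts, list(make.row.names = FALSE))) else df
  rownames(out) <- NULL
  attr(out, "layout") <- layout
  attr(out, "units") <- units
  class(out) <- c("coverage_track", "data.frame")
  out
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track [", attr(x, "units"), "]: ", nrow(x),
      " intervals on ", length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

track_units <- function(track) attr(track, "units")
track_layout <- function(track) attr(track, "layout")

#' Read a 4-column bedGraph file
#'
#' @param path bedGraph path (tab-separated chrom, start, end, value).
#' @param layout A [genome_layout()].
#' @param units Signal units of the file, `"rpkm"` or `"raw_count"`.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, layout, units = c("rpkm", "raw_count")) {
  units <- match.arg(units)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stop("failed to parse bedGraph ", path,
                                          ": ", conditionMessage(e)))
  coverage_track(as.character(GenomeInfoDb::seqnames(gr)),
                 BiocGenerics::start(gr) - 1, BiocGenerics::end(gr),
                 gr$score, layout, units = units)
}

#' Write a coverage track as bedGraph
#'
#' Written in canonical form (sorted, adjacent equal values merged), so
#' `read_bedgraph(write_bedgraph(t))` reproduces `t` exactly.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  df <- data.frame(track$chrom, format_bp(track$start), format_bp(track$end),
                   format_signal(track$value))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_signal <- function(x) formatC(x, digits = 10, format = "g")

#' RPKM normalisation of a raw coverage track
#'
#' Applies the deepTools bamCoverage convention: every value is scaled by
#' `1e9 / (read_bin * total_reads)`, i.e. reads per `read_bin`-bp bin per
#' kilobase per million mapped reads.
#'
#' @param track A raw-count [coverage_track()].
#' @param total_reads Library size (mapped reads), > 0.
#' @param read_bin Bin width in bp used when the track was built (default 50).
#' @return A [coverage_track()] in `"rpkm"` units.
#' @export
rpkm_normalize <- function(track, total_reads, read_bin = 50) {
  stopifnot(inherits(track, "coverage_track"))
  if (track_units(track) != "raw_count")
    stop("rpkm_normalize expects a raw_count track")
  if (!is.finite(total_reads) || total_reads <= 0)
    stop("total_reads must be > 0")
  scale <- 1e9 / (read_bin * total_reads)
  coverage_track(track$chrom, track$start, track$end, track$value * scale,
                 track_layout(track), units = "rpkm")
}

#' Merge replicate coverage tracks
#'
#' Computes the per-base mean (default) or sum of two or more tracks sharing
#' a layout and units. The mean keeps merged tracks on the same scale as a
#' single replicate.
#'
#' @param tracks List of at least two [coverage_track()] objects.
#' @param method `"mean"` or `"sum"`.
#' @return A merged [coverage_track()] in the common units.
#' @export
merge_replicates <- function(tracks, method = c("mean", "sum")) {
  method <- match.arg(method)
  if (length(tracks) < 2) stop("need at least two tracks to merge")
  units <- unique(vapply(tracks, track_units, ""))
  if (length(units) != 1) stop("cannot merge tracks with mixed units")
  layout <- track_layout(tracks[[1]])
  pieces <- lapply(layout$chrom_names, function(ch) {
    subs <- lapply(tracks, function(t) t[t$chrom == ch, , drop = FALSE])
    bp <- sort(unique(unlist(lapply(subs, function(s) c(s$start, s$end)))))
    if (length(bp) < 2) return(NULL)
    lo <- bp[-length(bp)]
    vals <- rowSums(matrix(vapply(subs, function(s) value_at(s, lo),
                                  numeric(length(lo))), nrow = length(lo)))
    if (method == "mean") vals <- vals / length(tracks)
    data.frame(chrom = ch, start = lo, end = bp[-1], value = vals,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  if (is.null(df))
    return(coverage_track(character(), numeric(), numeric(), numeric(),
                          layout, units = units))
  coverage_track(df$chrom, df$start, df$end, df$value, layout, units = units)
}

# piecewise-constant lookup: value of single-chromosome track rows at
# positions `pos` (0-based base index); gaps are 0
value_at <- function(rows, pos) {
  if (nrow(rows) == 0) return(numeric(length(pos)))
  idx <- findInterval(pos, rows$start)
  val <- numeric(length(pos))
  hit <- idx > 0
  hit[hit] <- pos[hit] < rows$end[idx[hit]]
  val[hit] <- rows$value[idx[hit]]
  val
}

# integral of a single-chromosome track over [0, x): vectorised in x
track_integral_fun <- function(rows) {
  if (nrow(rows) == 0) return(function(x) numeric(length(x)))
  w <- rows$end - rows$start
  cum0 <- c(0, cumsum(rows$value * w))
  starts <- rows$start; ends <- rows$end; vals <- rows$value
  function(x) {
    idx <- findInterval(x, starts)
    out <- numeric(length(x))
    pos <- idx > 0
    i <- idx[pos]
    out[pos] <- cum0[i] + vals[i] * pmin(pmax(x[pos] - starts[i], 0), w[i])
    out
  }
}

# sum of value*bp over arbitrary (chrom,start,end) triples of a track
region_area <- function(track, chrom, start, end) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    f <- track_integral_fun(track[track$chrom == ch, , drop = FALSE])
    out[sel] <- f(end[sel]) - f(start[sel])
  }
  out
}

#' Mean signal over labelled regions
#'
#' Scores each region group as `sum(value * covered bp) / total group length`
#' (signal units per bp). Intervals sharing a `group` (merged exons) are
#' pooled, with the summed merged-exon length as the denominator. Missing
#' coverage counts as 0 signal.
#'
#' @param track A [coverage_track()].
#' @param regions A [region_set()].
#' @return A named numeric vector of class `region_scores` (one score per
#'   region group, in input group order) with attribute `kind`.
#' @export
score_regions <- function(track, regions) {
  stopifnot(inherits(track, "coverage_track"), inherits(regions, "region_set"))
  if (nrow(regions) == 0)
    return(region_scores(numeric(), character(), attr(regions, "kind")))
  area <- region_area(track, regions$chrom, regions$start, regions$end)
  len <- regions$end - regions$start
  groups <- unique(regions$group)
  num <- tapply(area, factor(regions$group, levels = groups), sum)
  den <- tapply(len, factor(regions$group, levels = groups), sum)
  region_scores(as.numeric(num / den), groups, attr(regions, "kind"))
}

#' Region scores container
#'
#' @param scores Numeric scores (signal units per bp).
#' @param labels Region (group) labels, unique.
#' @param kind Region kind the scores were computed over.
#' @return Named numeric vector of class `region_scores`.
#' @export
region_scores <- function(scores, labels, kind = "generic") {
  if (length(scores) != length(labels)) stop("one label per score required")
  if (anyDuplicated(labels)) stop("score labels must be unique")
  x <- as.numeric(scores)
  names(x) <- as.character(labels)
  attr(x, "kind") <- kind
  class(x) <- "region_scores"
  x
}

#' @export
print.region_scores <- function(x, ...) {
  cat("region_scores (", attr(x, "kind"), "): ", length(x), " regions, mean ",
      format(mean(unclass(x)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write region scores as TSV
#'
#' @param scores A [region_scores()] vector.
#' @param path Output path.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(
    data.frame(label = names(scores), score = format_signal(as.numeric(scores))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Metagene score matrix
#'
#' Builds a genes-by-bins matrix of mean signal. With
#' `anchor = "scale_regions"` each gene body is divided into `body_bins`
#' equal-width bins (integer boundaries) flanked by fixed-width bins covering
#' `flank` bp on each side; with `anchor = "center_tss"` the window is
#' `TSS +/- flank` in `2 * flank_bins` fixed-width bins. Rows of minus-strand
#' genes are flipped so column 1 is always the 5' end. Genes with a body
#' shorter than `body_bins` bp are dropped with a warning. Positions outside
#' the chromosome contribute 0 signal.
#'
#' @param track A [coverage_track()].
#' @param genes A [gene_models()] table.
#' @param body_bins Number of gene-body bins (scale_regions; default 100).
#' @param flank Flank length in bp (default 2000).
#' @param flank_bins Number of bins per flank (default 40, i.e. 50-bp bins).
#' @param anchor `"scale_regions"` or `"center_tss"`.
#' @return A numeric matrix of class `score_matrix`; rows named by gene id,
#'   attribute `anchor` records the mode.
#' @export
metagene_matrix <- function(track, genes, body_bins = 100, flank = 2000,
                            flank_bins = 40,
                            anchor = c("scale_regions", "center_tss")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(track, "coverage_track"), inherits(genes, "gene_models"),
            body_bins >= 1, flank_bins >= 1, flank >= 0)
  if (flank %% flank_bins != 0)
    stop("flank must be a multiple of flank_bins")
  fw <- flank / flank_bins
  if (anchor == "scale_regions") {
    short <- (genes$end - genes$start) < body_bins
    if (any(short)) {
      warning("dropped ", sum(short), " gene(s) shorter than body_bins bp")
      genes <- genes[!short, , drop = FALSE]
    }
  }
  ncol_out <- if (anchor == "scale_regions") body_bins + 2 * flank_bins
              else 2 * flank_bins
  mat <- matrix(0, nrow(genes), ncol_out,
                dimnames = list(genes$gene_id, NULL))
  ints <- lapply(split(seq_len(nrow(track)), track$chrom),
                 function(i) track_integral_fun(track[i, , drop = FALSE]))
  zero_fun <- function(x) numeric(length(x))
  for (i in seq_len(nrow(mat))) {
    f <- ints[[genes$chrom[i]]]
    if (is.null(f)) f <- zero_fun
    if (anchor == "scale_regions") {
      body <- floor(seq(genes$start[i], genes$end[i],
                        length.out = body_bins + 1))
      up <- genes$start[i] - flank + fw * (0:flank_bins)
      down <- genes$end[i] + fw * (0:flank_bins)
      bounds <- c(up[-length(up)], body, down[-1])
    } else {
      bounds <- genes$tss[i] - flank + fw * (0:(2 * flank_bins))
    }
    area <- diff(f(pmax(bounds, 0)))
    row <- area / diff(bounds)
    if (genes$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  attr(mat, "anchor") <- anchor
  class(mat) <- c("score_matrix", class(mat))
  mat
}

#' Decile assignment from ranked scores
#'
#' Ranks scores ascending (ties broken deterministically by label) and splits
#' them into 10 groups whose sizes differ by at most one. Decile 1 holds the
#' lowest scores, decile 10 the highest.
#'
#' @param scores A [region_scores()] vector with at least 10 entries.
#' @return Named integer vector (1-10) of class `decile_assignment`, in the
#'   input label order, with attribute `sort_key = "score,label"`.
#' @export
assign_deciles <- function(scores) {
  n <- length(scores)
  if (n < 10) stop("need at least 10 regions to form deciles")
  ord <- order(as.numeric(scores), names(scores))
  dec <- integer(n)
  dec[ord] <- ceiling(seq_len(n) * 10 / n)
  names(dec) <- names(scores)
  attr(dec, "sort_key") <- "score,label"
  class(dec) <- "decile_assignment"
  dec
}

#' Pairwise Pearson correlation of region score sets
#'
#' Correlates each pair of score sets over the labels present in both; with
#' `positive_filter` each pair is restricted to labels where both scores are
#' strictly positive (the convention used for signal-vs-signal density
#' plots). Pairs with fewer than 3 usable labels are reported as `NA`.
#'
#' @param score_sets Named list of [region_scores()] vectors.
#' @param positive_filter Restrict each pair to labels with both scores > 0.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_correlation_matrix <- function(score_sets, positive_filter = FALSE) {
  if (length(score_sets) < 2) stop("need at least two score sets")
  if (is.null(names(score_sets)) || anyDuplicated(names(score_sets)))
    stop("score_sets must have unique names")
  k <- length(score_sets)
  m <- diag(1, k)
  dimnames(m) <- list(names(score_sets), names(score_sets))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- score_sets[[i]]; b <- score_sets[[j]]
    shared <- intersect(names(a), names(b))
    x <- as.numeric(a[shared]); y <- as.numeric(b[shared])
    if (positive_filter) {
      keep <- x > 0 & y > 0
      x <- x[keep]; y <- y[keep]
    }
    m[i, j] <- m[j, i] <-
      if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
      else stats::cor(x, y)
  }
  m
}
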