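#' Count features from raw coverage tracks
#'
#' Builds an integer feature-by-sample count matrix from unnormalised
#' coverage: the count for a feature is the rounded sum of `value * bp` over
#' its region (fragment-count semantics; grouped regions such as merged
#' exons are pooled). Supplying a normalised track is an error, since counts
#' must be on the raw library scale for size-factor normalisation.
#'
#' @param raw_tracks Named list of raw-count [coverage_track()] objects, one
#'   per sample.
#' @param regions A [region_set()] of features.
#' @return Integer matrix (features x samples) with dimnames.
#' @export
count_features <- function(raw_tracks, regions) {
  if (is.null(names(raw_tracks)) || anyDuplicated(names(raw_tracks)))
    stop("raw_tracks must be a uniquely named list")
  bad <- !vapply(raw_tracks, function(t) track_units(t) == "raw_count", TRUE)
  if (any(bad))
    stop("count_features requires raw_count tracks; normalized units in: ",
         paste(names(raw_tracks)[bad], collapse = ", "))
  groups <- unique(regions$group)
  gf <- factor(regions$group, levels = groups)
  len_ok <- regions$end > regions$start
  stopifnot(all(len_ok))
  counts <- vapply(raw_tracks, function(t) {
    area <- region_area(t, regions$chrom, regions$start, regions$end)
    as.numeric(tapply(area, gf, sum))
  }, numeric(length(groups)))
  counts <- round(matrix(counts, nrow = length(groups),
                         dimnames = list(groups, names(raw_tracks))))
  storage.mode(counts) <- "integer"
  counts
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across features of the
#' ratio of that sample's count to the feature's geometric mean, computed
#' over features with positive counts in every sample.
#'
#' @param counts Integer count matrix (features x samples).
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has positive counts in all samples; ",
         "cannot form a median-of-ratios reference")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(exp(lg - ref), 2, stats::median)
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  sf
}

#' Per-feature NB dispersion estimation
#'
#' Method-of-moments estimate of the NB dispersion `alpha` in
#' `Var = mu + alpha * mu^2`, computed on size-factor-normalised counts and
#' pooled across the two conditions, then moderated toward a mean-dispersion
#' trend (the mean raw dispersion within deciles of log base mean). The
#' moderation is information-weighted, `(df * raw + prior_df * trend) /
#' (df + prior_df)` with `df = n_samples - 2`: with few replicates the
#' gene-wise moment estimate is nearly uninformative and the fitted trend
#' dominates, which keeps the downstream Wald test calibrated. Estimates
#' are floored at `1e-8`. Features with zero counts in every sample have no
#' defined dispersion and are returned as `NA` (they are excluded from
#' testing).
#'
#' @param counts Integer count matrix (features x samples).
#' @param size_factors Per-sample size factors.
#' @param condition Factor (two levels) assigning samples to conditions.
#' @param prior_df Weight of the trend in moderation units of residual
#'   degrees of freedom (default 20).
#' @return Numeric vector of dispersions per feature (`NA` for all-zero
#'   features).
#' @export
estimate_dispersion <- function(counts, size_factors, condition,
                                prior_df = 20) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("condition must have exactly two levels")
  if (any(table(condition) < 2))
    stop("need at least 2 replicates per condition")
  norm <- sweep(counts, 2, size_factors, "/")
  lev <- levels(condition)
  mom <- matrix(NA_real_, nrow(counts), 2)
  wts <- matrix(0, nrow(counts), 2)
  for (k in 1:2) {
    x <- norm[, condition == lev[k], drop = FALSE]
    m <- rowMeans(x)
    v <- apply(x, 1, stats::var)
    mom[, k] <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    wts[, k] <- ifelse(m > 0, ncol(x) - 1, 0)
  }
  raw <- rowSums(ifelse(is.na(mom), 0, mom) * wts) / pmax(rowSums(wts), 1)
  raw[rowSums(wts) == 0] <- NA_real_
  base_mean <- rowMeans(norm)
  defined <- !is.na(raw)
  raw_pos <- pmax(raw, 0)
  # trend: mean raw dispersion within log-mean decile bins (arithmetic
  # means; a log-scale regression would be biased low by near-zero moment
  # estimates). Falls back to the global mean for small panels.
  trend <- rep(mean(raw_pos[defined]), nrow(counts))
  if (sum(defined) >= 50) {
    lb <- log(pmax(base_mean[defined], 1e-8))
    br <- unique(stats::quantile(lb, seq(0, 1, 0.1)))
    if (length(br) > 2) {
      bin <- cut(lb, br, include.lowest = TRUE)
      tv <- tapply(raw_pos[defined], bin, mean)
      trend[defined] <- as.numeric(tv[as.integer(bin)])
    }
  }
  df <- ncol(counts) - 2
  alpha <- pmax((df * raw_pos + prior_df * trend) / (df + prior_df), 1e-8)
  alpha[!defined] <- NA_real_
  alpha
}

# vectorised per-group NB GLM fit with log link and offsets log(sf):
# maximises the NB log-likelihood in the group intercept b by Newton steps,
# simultaneously for all features. Returns b and the Fisher information.
nb_group_fit <- function(y, sf, alpha, max_iter = 50, tol = 1e-10) {
  n <- ncol(y)
  b <- log(pmax(rowMeans(sweep(y, 2, sf, "/")), 1e-8))
  for (it in seq_len(max_iter)) {
    mu <- exp(b) %o% sf
    w <- mu / (1 + alpha * mu)
    score <- rowSums((y - mu) / (1 + alpha * mu))
    info <- rowSums(w)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    b <- pmax(b + step, log(1e-12))
    if (max(abs(step)) < tol) break
  }
  mu <- exp(b) %o% sf
  list(b = b, info = rowSums(mu / (1 + alpha * mu)),
       converged = max(abs(step)) < 1e-6)
}

#' Negative-binomial Wald test for two-group differential occupancy
#'
#' Fits, per feature, an NB generalised linear model with log link, known
#' per-feature dispersion and log size-factor offsets (equivalent to one
#' mean parameter per condition, fitted by Newton iterations), and tests the
#' log2 fold change (second condition vs first) with a Wald statistic
#' `log2FC / SE` against the standard normal.
#'
#' @param counts Integer count matrix (features x samples).
#' @param size_factors Per-sample size factors.
#' @param dispersions Per-feature dispersions from [estimate_dispersion()]
#'   (`NA` features are skipped).
#' @param condition Two-level factor; the fold change is
#'   `levels(condition)[2]` vs `levels(condition)[1]`.
#' @return Data frame of class `differential_result` with columns `feature`,
#'   `base_mean`, `log2_fold_change`, `se`, `wald_stat`, `wald_p` (`NA` for
#'   skipped features).
#' @export
nb_wald_test <- function(counts, size_factors, dispersions, condition) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("condition must have exactly two levels")
  if (any(table(condition) < 2))
    stop("need at least 2 replicates per condition")
  lev <- levels(condition)
  norm <- sweep(counts, 2, size_factors, "/")
  base_mean <- rowMeans(norm)
  ok <- !is.na(dispersions)
  lfc <- se <- stat <- p <- rep(NA_real_, nrow(counts))
  if (any(ok)) {
    a <- dispersions[ok]
    fa <- nb_group_fit(counts[ok, condition == lev[1], drop = FALSE],
                       size_factors[condition == lev[1]], a)
    fb <- nb_group_fit(counts[ok, condition == lev[2], drop = FALSE],
                       size_factors[condition == lev[2]], a)
    beta <- fb$b - fa$b
    se_ln <- sqrt(1 / pmax(fa$info, 1e-12) + 1 / pmax(fb$info, 1e-12))
    lfc[ok] <- beta / log(2)
    se[ok] <- se_ln / log(2)
    stat[ok] <- beta / se_ln
    p[ok] <- 2 * stats::pnorm(-abs(stat[ok]))
  }
  out <- data.frame(feature = rownames(counts), base_mean = base_mean,
                    log2_fold_change = lfc, se = se, wald_stat = stat,
                    wald_p = p, stringsAsFactors = FALSE)
  attr(out, "contrast") <- paste(lev[2], "vs", lev[1])
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' mapped back to input positions (`NA` p values stay `NA`).
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Classify differential features by fold change and adjusted significance
#'
#' Optionally restricts the testing set to features whose day-7 RNA signal
#' exceeds `min_expression` (features below it, or with no RNA record, are
#' marked `excluded` and take no part in the BH adjustment), applies
#' [bh_adjust()] to the Wald p values of the testing set, and calls each
#' tested feature `increased` (`log2FC >= lfc_threshold` and
#' `padj < alpha`), `decreased` (symmetric) or `unchanged`.
#'
#' @param result A [nb_wald_test()] result.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1.5).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param rna_day7 Optional [region_scores()] of day-7 RNA (RPKM) keyed by
#'   feature label, used as the expression gate.
#' @param min_expression Expression gate in RPKM (default 25); only applied
#'   when `rna_day7` is given.
#' @return The input with columns `adjusted_p` and `call` added (`call` is
#'   one of `increased`, `decreased`, `unchanged`, `excluded`).
#' @export
classify_differential <- function(result, lfc_threshold = 1.5, alpha = 0.05,
                                  rna_day7 = NULL, min_expression = 25) {
  stopifnot(inherits(result, "differential_result"))
  tested <- !is.na(result$wald_p)
  if (!is.null(rna_day7)) {
    rna <- as.numeric(rna_day7)[match(result$feature, names(rna_day7))]
    tested <- tested & !is.na(rna) & rna > min_expression
  }
  result$adjusted_p <- rep(NA_real_, nrow(result))
  result$adjusted_p[tested] <- bh_adjust(result$wald_p[tested])
  call <- rep("excluded", nrow(result))
  call[tested] <- "unchanged"
  call[tested & result$adjusted_p < alpha &
         result$log2_fold_change >= lfc_threshold] <- "increased"
  call[tested & result$adjusted_p < alpha &
         result$log2_fold_change <= -lfc_threshold] <- "decreased"
  result$call <- call
  attr(result, "lfc_threshold") <- lfc_threshold
  attr(result, "alpha") <- alpha
  result
}

#' Write a differential result table as TSV
#'
#' @param result A (classified) `differential_result`.
#' @param path Output path.
#' @export
write_differential_tsv <- function(result, path) {
  df <- as.data.frame(result)
  for (col in c("base_mean", "log2_fold_change", "se", "wald_stat",
                "wald_p", "adjusted_p"))
    if (col %in% names(df)) df[[col]] <- format_signal(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
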