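#' Pausing index per gene
#'
#' Computes the pausing-index proxy `PI = promoter score / body score` from
#' Ser5 Pol II signal averaged over the promoter (TSS +/- flank) and the gene
#' body (TSS to TES). Genes with `body_score <= 0` get an undefined PI and
#' are excluded from downstream paused/non-paused splits; genes with
#' `promoter_score = 0` but positive body signal get a valid `PI = 0`.
#' No pseudocount is applied.
#'
#' @param ser5_promoter [region_scores()] of promoter Ser5 Pol II signal.
#' @param ser5_body [region_scores()] of gene-body Ser5 Pol II signal.
#' @param pi_threshold PI above which a gene is classed as paused (default 4).
#' @return Data frame of class `pausing_records` with columns `gene_id`,
#'   `promoter_score`, `body_score`, `pi`, `pi_class` (one of `paused_gt4`,
#'   `nonpaused_lt4`, `undefined`).
#' @export
pausing_index <- function(ser5_promoter, ser5_body, pi_threshold = 4) {
  shared <- intersect(names(ser5_promoter), names(ser5_body))
  if (length(shared) == 0)
    stop("promoter and body scores share no gene labels")
  if (length(shared) < length(ser5_promoter) ||
      length(shared) < length(ser5_body))
    warning("restricting pausing index to ", length(shared),
            " shared gene labels")
  p <- as.numeric(ser5_promoter[shared])
  b <- as.numeric(ser5_body[shared])
  pi <- ifelse(b > 0, p / b, NA_real_)
  cls <- ifelse(is.na(pi), "undefined",
                ifelse(pi > pi_threshold, "paused_gt4", "nonpaused_lt4"))
  out <- data.frame(gene_id = shared, promoter_score = p, body_score = b,
                    pi = pi, pi_class = cls, stringsAsFactors = FALSE)
  attr(out, "pi_threshold") <- pi_threshold
  class(out) <- c("pausing_records", "data.frame")
  out
}

#' Split genes by pausing index among expressed genes
#'
#' Expressed genes are those with RNA signal (merged-exon RPKM) strictly
#' above `expr_threshold`. Among expressed genes with a defined PI, genes
#' with `PI > pi_threshold` are paused and the rest (including `PI` exactly
#' equal to the threshold) non-paused, following the strict "PI > 4"
#' convention.
#'
#' @param records A [pausing_index()] table.
#' @param rna [region_scores()] of RNA over merged exons (RPKM).
#' @param expr_threshold Expression cutoff in RPKM (default 100).
#' @param pi_threshold PI cutoff (default 4).
#' @return List with character vectors `expressed`, `paused_gt4`,
#'   `nonpaused_lt4`.
#' @export
split_by_pi <- function(records, rna, expr_threshold = 100, pi_threshold = 4) {
  stopifnot(inherits(records, "pausing_records"))
  expressed <- names(rna)[as.numeric(rna) > expr_threshold]
  r <- records[records$gene_id %in% expressed & !is.na(records$pi), ,
               drop = FALSE]
  list(expressed = expressed,
       paused_gt4 = r$gene_id[r$pi > pi_threshold],
       nonpaused_lt4 = r$gene_id[r$pi <= pi_threshold])
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sided t test with Welch-Satterthwaite degrees of
#' freedom. When both groups are constant with equal means the test is
#' degenerate and reported as `t = 0`, `p = 1`.
#'
#' @param group_a,group_b Numeric score vectors, each of length >= 2.
#' @return List of class `welch_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
welch_t_test <- function(group_a, group_b) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations")
  res <- if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      list(statistic = 0, parameter = length(group_a) + length(group_b) - 2,
           p.value = 1)
    else list(statistic = sign(mean(group_a) - mean(group_b)) * Inf,
              parameter = length(group_a) + length(group_b) - 2, p.value = 0)
  } else {
    t <- stats::t.test(group_a, group_b, var.equal = FALSE)
    list(statistic = unname(t$statistic), parameter = unname(t$parameter),
         p.value = t$p.value)
  }
  structure(list(t_statistic = res$statistic,
                 degrees_of_freedom = res$parameter,
                 p_value = res$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 n_a = length(group_a), n_b = length(group_b)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.3g, p = %.4g (means %.4g vs %.4g)\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              x$mean_a, x$mean_b))
  invisible(x)
}

#' Compare score distributions between gene groups
#'
#' Summarises a score set within each named gene group (n, mean, median,
#' quartiles) and runs pairwise Welch tests between groups, recording the
#' direction of each comparison (whether the first group's mean is increased
#' or decreased relative to the second). Empty groups are skipped with a
#' warning; groups of size 1 are summarised but not tested.
#'
#' @param scores A [region_scores()] vector.
#' @param groups Named list of gene-label character vectors.
#' @return List of class `group_comparison` with `summary` (data frame) and
#'   `tests` (data frame of pairwise Welch results with a `direction`
#'   column).
#' @export
compare_groups <- function(scores, groups) {
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must have unique names")
  vals <- lapply(groups, function(g) as.numeric(scores[intersect(g, names(scores))]))
  empty <- vapply(vals, length, 0L) == 0
  if (any(empty)) {
    warning("skipping empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    vals <- vals[!empty]
  }
  sm <- do.call(rbind, lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = nm, n = length(v), mean = mean(v), q25 = q[1],
               median = q[2], q75 = q[3], stringsAsFactors = FALSE)
  }))
  tests <- list()
  nms <- names(vals)
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      a <- vals[[i]]; b <- vals[[j]]
      if (length(a) < 2 || length(b) < 2) next
      w <- welch_t_test(a, b)
      tests[[length(tests) + 1]] <- data.frame(
        group_a = nms[i], group_b = nms[j],
        t_statistic = w$t_statistic, df = w$degrees_of_freedom,
        p_value = w$p_value,
        direction = if (w$mean_a > w$mean_b) "increased"
                    else if (w$mean_a < w$mean_b) "decreased" else "equal",
        stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests)
           else data.frame(group_a = character(), group_b = character(),
                           t_statistic = numeric(), df = numeric(),
                           p_value = numeric(), direction = character())
  structure(list(summary = sm, tests = tests), class = "group_comparison")
}

#' Write a per-gene pausing table as TSV
#'
#' @param records A [pausing_index()] table.
#' @param path Output path.
#' @export
write_pausing_tsv <- function(records, path) {
  df <- records
  df$promoter_score <- format_signal(df$promoter_score)
  df$body_score <- format_signal(df$body_score)
  df$pi <- format_signal(df$pi)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
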