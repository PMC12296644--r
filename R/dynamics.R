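#' TSS- vs body-localisation classes for one mark
#'
#' Classifies each gene by where a mark's signal sits: `tss_enriched` when
#' the TSS (promoter) score exceeds `margin` times the body score and the
#' signal floor, `body_enriched` symmetrically, `neither` otherwise (in
#' particular when both scores are below the floor).
#'
#' @param mark_tss [region_scores()] of the mark over promoters.
#' @param mark_body [region_scores()] of the same mark over gene bodies.
#' @param margin Ratio a score must exceed the other by (default 1.0, i.e.
#'   strictly greater).
#' @param floor Minimum signal for an enriched call; default is the 25th
#'   percentile of all supplied scores.
#' @return Data frame of class `localization_classes` with columns
#'   `gene_id`, `tss_score`, `body_score`, `class`.
#' @export
localization_classes <- function(mark_tss, mark_body, margin = 1.0,
                                 floor = NULL) {
  shared <- intersect(names(mark_tss), names(mark_body))
  if (length(shared) == 0) stop("no shared gene labels")
  tss <- as.numeric(mark_tss[shared])
  body <- as.numeric(mark_body[shared])
  if (is.null(floor))
    floor <- stats::quantile(c(tss, body), 0.25, names = FALSE)
  cls <- ifelse(tss > body * margin & tss > floor, "tss_enriched",
                ifelse(body > tss * margin & body > floor, "body_enriched",
                       "neither"))
  out <- data.frame(gene_id = shared, tss_score = tss, body_score = body,
                    class = cls, stringsAsFactors = FALSE)
  attr(out, "margin") <- margin
  attr(out, "floor") <- floor
  class(out) <- c("localization_classes", "data.frame")
  out
}

#' Fate map between two marks' differential results
#'
#' Builds gene-level sets of H4K20me1/H4K20me3 gain and loss from two
#' classified differential results and intersects them: genes losing the
#' first mark while gaining the second (progressive-methylation candidates)
#' and the reverse. Differential features are mapped to genes through
#' optional assignment vectors (e.g. from [peak_gene_assignment()]);
#' features mapping to `NA` (intergenic) are excluded. Without an
#' assignment, feature labels are taken to be gene ids.
#'
#' @param me1_diff,me3_diff Classified [classify_differential()] results for
#'   the two marks.
#' @param me1_genes,me3_genes Optional named character vectors mapping
#'   feature labels to gene ids (`NA` drops the feature).
#' @return List of class `fate_map` with gene-id sets `me1_increased`,
#'   `me1_decreased`, `me3_increased`, `me3_decreased`,
#'   `me1_loss_me3_gain`, `me3_loss_me1_gain`, and a `counts` vector.
#' @export
fate_map <- function(me1_diff, me3_diff, me1_genes = NULL, me3_genes = NULL) {
  sets <- function(diff, map) {
    if (is.null(diff$call)) stop("differential result must be classified")
    to_gene <- function(features) {
      g <- if (is.null(map)) features else unname(map[features])
      sort(unique(g[!is.na(g)]))
    }
    list(increased = to_gene(diff$feature[diff$call == "increased"]),
         decreased = to_gene(diff$feature[diff$call == "decreased"]))
  }
  s1 <- sets(me1_diff, me1_genes)
  s3 <- sets(me3_diff, me3_genes)
  fm <- list(me1_increased = s1$increased, me1_decreased = s1$decreased,
             me3_increased = s3$increased, me3_decreased = s3$decreased,
             me1_loss_me3_gain = intersect(s1$decreased, s3$increased),
             me3_loss_me1_gain = intersect(s3$decreased, s1$increased))
  fm$counts <- vapply(fm, length, 0L)
  class(fm) <- "fate_map"
  fm
}

#' @export
print.fate_map <- function(x, ...) {
  cat("fate_map counts:\n")
  print(x$counts)
  invisible(x)
}

#' Percent of differential features by direction
#'
#' Of the features called `increased` or `decreased`, the whole-number
#' percentage in each direction, truncated toward zero (so 7128 decreased of
#' 8236 differential reports 86). Accepts either a classified
#' `differential_result` or explicit counts.
#'
#' @param diff A classified `differential_result`, or `NULL` when counts are
#'   given directly.
#' @param increased,decreased Optional explicit counts of differential
#'   features in each direction.
#' @return Named numeric vector `c(percent_decreased, percent_increased)`;
#'   both `NA` (with a message) when there are no differential features.
#' @export
percent_by_direction <- function(diff = NULL, increased = NULL,
                                 decreased = NULL) {
  if (is.null(increased) || is.null(decreased)) {
    stopifnot(inherits(diff, "differential_result"))
    increased <- sum(diff$call == "increased")
    decreased <- sum(diff$call == "decreased")
  }
  total <- increased + decreased
  if (total == 0) {
    message("no differential features; percentages undefined")
    return(c(percent_decreased = NA_real_, percent_increased = NA_real_))
  }
  c(percent_decreased = trunc(100 * decreased / total),
    percent_increased = trunc(100 * increased / total))
}

#' Log2 fold-change quantile groups
#'
#' Ranks genes above a minimum expression by log2 fold change (ties broken
#' by label) and splits them into `k` near-equal groups; group 1 holds the
#' most decreased genes, group `k` the most increased.
#'
#' @param rna_lfc Named numeric vector of per-gene log2 fold changes.
#' @param rna_day7 [region_scores()] of day-7 RNA (RPKM) for the expression
#'   gate.
#' @param min_expr Minimum RPKM (default 1, strictly greater).
#' @param k Number of groups (default 5).
#' @return Named integer vector of group indices (1..k) over eligible genes.
#' @export
l2fc_quantiles <- function(rna_lfc, rna_day7, min_expr = 1, k = 5) {
  if (k < 2) stop("k must be at least 2")
  eligible <- intersect(names(rna_lfc),
                        names(rna_day7)[as.numeric(rna_day7) > min_expr])
  n <- length(eligible)
  if (n < k) stop("fewer than k eligible genes above the expression threshold")
  lfc <- as.numeric(rna_lfc[eligible])
  ord <- order(lfc, eligible)
  grp <- integer(n)
  grp[ord] <- ceiling(seq_len(n) * k / n)
  names(grp) <- eligible
  grp
}

#' Write a fate map as TSV
#'
#' One row per (set, gene id) pair.
#'
#' @param fm A [fate_map()].
#' @param path Output path.
#' @export
write_fatemap_tsv <- function(fm, path) {
  set_names <- setdiff(names(fm), "counts")
  rows <- do.call(rbind, lapply(set_names, function(s) {
    if (length(fm[[s]]) == 0) return(NULL)
    data.frame(set = s, gene_id = fm[[s]], stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(set = character(),
                                        gene_id = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
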