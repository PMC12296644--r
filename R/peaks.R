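#' Threshold peak calling from a coverage track
#'
#' Calls peaks as maximal runs of bases whose signal is at least `cutoff`
#' (the bdgpeakcall model: a fixed signal threshold on a bedGraph track).
#' Runs separated by at most `max_gap` bp are merged into one peak spanning
#' the gap, and merged peaks shorter than `min_length` bp are discarded. The
#' peak's `summit_value` is the maximum signal inside it.
#'
#' @param track A [coverage_track()].
#' @param cutoff Signal threshold (> 0), in the track's units.
#' @param min_length Minimum peak length in bp (default 200, the bdgpeakcall
#'   default).
#' @param max_gap Maximum below-threshold gap to bridge in bp (default 30).
#' @param prefix Label prefix for peak names.
#' @return A data frame of class `peak_set` (also a valid `region_set`) with
#'   columns `chrom`, `start`, `end`, `strand`, `label`, `group`,
#'   `summit_value`.
#' @export
call_peaks_threshold <- function(track, cutoff, min_length = 200,
                                 max_gap = 30, prefix = "peak") {
  stopifnot(inherits(track, "coverage_track"))
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  stopifnot(min_length >= 1, max_gap >= 0)
  out <- list()
  for (ch in unique(track$chrom)) {
    p <- track[track$chrom == ch & track$value >= cutoff, , drop = FALSE]
    if (nrow(p) == 0) next
    # merge runs whose separation is <= max_gap (adjacent = separation 0)
    new_run <- c(TRUE, p$start[-1] - p$end[-nrow(p)] > max_gap)
    run <- factor(cumsum(new_run), levels = unique(cumsum(new_run)))
    start <- as.numeric(tapply(p$start, run, min))
    end <- as.numeric(tapply(p$end, run, max))
    summit <- as.numeric(tapply(p$value, run, max))
    keep <- (end - start) >= min_length
    if (!any(keep)) next
    out[[ch]] <- data.frame(chrom = ch, start = start[keep], end = end[keep],
                            summit_value = summit[keep],
                            stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
        else data.frame(chrom = character(), start = numeric(),
                        end = numeric(), summit_value = numeric())
  rs <- region_set(df$chrom, df$start, df$end,
                   label = if (nrow(df)) paste0(prefix, "_", seq_len(nrow(df)))
                           else character(),
                   name = prefix, kind = "peak", layout = NULL)
  rs$summit_value <- df$summit_value
  class(rs) <- c("peak_set", class(rs))
  attr(rs, "cutoff") <- cutoff
  attr(rs, "min_length") <- min_length
  attr(rs, "max_gap") <- max_gap
  rs
}

#' Convert a peak set to a plain region set
#'
#' @param peaks A `peak_set`.
#' @param name Name for the resulting set.
#' @return A `region_set` of kind `"peak"`.
#' @export
peaks_as_regions <- function(peaks, name = "peaks") {
  region_set(peaks$chrom, peaks$start, peaks$end, peaks$label,
             name = name, kind = "peak")
}

#' Write peaks as narrowPeak-style BED6+
#'
#' Columns: chrom, start, end, label, `round(summit_value * 10)` as score,
#' strand ".".
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, format_bp(peaks$start), format_bp(peaks$end),
                   peaks$label, round(peaks$summit_value * 10), ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

annotation_levels <- c("promoter_tss", "tts", "exon", "intron", "intergenic")

# strand-aware promoter/TTS windows, 0-based half-open.
# window = c(upstream, downstream) relative to transcription direction.
anchor_windows <- function(pos, strand, window) {
  up <- window[1]; down <- window[2]
  start <- ifelse(strand == "+", pos - up, pos - down)
  end <- ifelse(strand == "+", pos + down, pos + up)
  cbind(start = start, end = end)
}

# GRanges of category windows for a gene_models table
category_ranges <- function(genes, promoter_window = c(1000, 100),
                            tts_window = c(100, 1000)) {
  prom <- anchor_windows(genes$tss, genes$strand, promoter_window)
  tts <- anchor_windows(genes$tes, genes$strand, tts_window)
  mk <- function(m) GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(m[, 1], 0) + 1, pmax(m[, 2], 0)))
  ex <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    cbind(i, genes$exons[[i]])))
  list(
    promoter_tss = mk(prom),
    tts = mk(tts),
    exon = GenomicRanges::GRanges(genes$chrom[ex[, 1]],
                                  IRanges::IRanges(ex[, 2] + 1, ex[, 3])),
    body = GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start + 1, genes$end))
  )
}

#' Annotate peaks with genomic categories
#'
#' Assigns each peak, by the category of its midpoint, to exactly one of
#' `promoter_tss`, `tts`, `exon`, `intron` or `intergenic`, with precedence
#' promoter_tss > tts > exon > intron > intergenic (the annotatePeaks
#' convention). Windows are strand-aware: `promoter_window = c(1000, 100)`
#' means TSS -1000 bp upstream to +100 bp downstream of transcription.
#'
#' @param peaks A `peak_set` or `region_set`.
#' @param genes A [gene_models()] table.
#' @param promoter_window `c(upstream, downstream)` bp around the TSS.
#' @param tts_window `c(upstream, downstream)` bp around the TES.
#' @return Factor of categories (levels promoter_tss, tts, exon, intron,
#'   intergenic), one per peak, named by peak label.
#' @export
annotate_peaks <- function(peaks, genes, promoter_window = c(1000, 100),
                           tts_window = c(100, 1000)) {
  stopifnot(inherits(genes, "gene_models"))
  mid <- floor((peaks$start + peaks$end) / 2)
  pts <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1, mid + 1))
  cr <- category_ranges(genes, promoter_window, tts_window)
  cat <- rep("intergenic", nrow(peaks))
  in_body <- IRanges::overlapsAny(pts, cr$body)
  cat[in_body] <- "intron"
  cat[IRanges::overlapsAny(pts, cr$exon)] <- "exon"
  cat[IRanges::overlapsAny(pts, cr$tts)] <- "tts"
  cat[IRanges::overlapsAny(pts, cr$promoter_tss)] <- "promoter_tss"
  out <- factor(cat, levels = annotation_levels)
  names(out) <- peaks$label
  out
}

#' Map peaks to genes via their annotation category
#'
#' Returns, for each peak, the gene whose feature (promoter, TTS, exon or
#' body, in the annotation precedence order) contains the peak midpoint;
#' intergenic peaks map to `NA`. When several genes qualify at the same
#' precedence level the first in `genes` order is taken.
#'
#' @inheritParams annotate_peaks
#' @return Named character vector (peak label -> gene id, `NA` for
#'   intergenic peaks).
#' @export
peak_gene_assignment <- function(peaks, genes, promoter_window = c(1000, 100),
                                 tts_window = c(100, 1000)) {
  mid <- floor((peaks$start + peaks$end) / 2)
  pts <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1, mid + 1))
  cr <- category_ranges(genes, promoter_window, tts_window)
  ex_gene <- {
    ex <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
      cbind(i, genes$exons[[i]])))
    ex[, 1]
  }
  gene_of <- rep(NA_character_, nrow(peaks))
  assign_from <- function(gr, idx_map) {
    hits <- GenomicRanges::findOverlaps(pts, gr, select = "first")
    found <- !is.na(hits) & is.na(gene_of)
    gene_of[found] <<- genes$gene_id[idx_map[hits[found]]]
  }
  assign_from(cr$promoter_tss, seq_len(nrow(genes)))
  assign_from(cr$tts, seq_len(nrow(genes)))
  assign_from(cr$exon, ex_gene)
  assign_from(cr$body, seq_len(nrow(genes)))
  names(gene_of) <- peaks$label
  gene_of
}

#' Observed/expected annotation enrichment
#'
#' Compares the fraction of peaks assigned to each genomic category with the
#' fraction of the genome occupied by that category (computed with the same
#' windows and precedence as [annotate_peaks()]), reporting
#' `log2(observed / genome)` per category. Categories with no observed peaks
#' give `-Inf`; a category with observed peaks but zero genome fraction gives
#' `+Inf` with a warning.
#'
#' @param categories Factor of peak categories from [annotate_peaks()].
#' @param layout A [genome_layout()].
#' @param genes A [gene_models()] table.
#' @inheritParams annotate_peaks
#' @return Data frame of class `annotation_enrichment` with columns
#'   `category`, `observed_fraction`, `genome_fraction`, `log2_ratio`.
#' @export
annotation_enrichment <- function(categories, layout, genes,
                                  promoter_window = c(1000, 100),
                                  tts_window = c(100, 1000)) {
  if (length(categories) == 0) stop("need at least one annotated peak")
  obs <- table(factor(categories, levels = annotation_levels))
  observed_fraction <- as.numeric(obs) / sum(obs)
  genome_fraction <- genome_category_fractions(layout, genes,
                                               promoter_window, tts_window)
  log2_ratio <- log2(observed_fraction / genome_fraction)
  if (any(observed_fraction > 0 & genome_fraction == 0))
    warning("category with zero genome fraction but observed peaks")
  out <- data.frame(category = annotation_levels,
                    observed_fraction = observed_fraction,
                    genome_fraction = genome_fraction,
                    log2_ratio = log2_ratio,
                    stringsAsFactors = FALSE)
  class(out) <- c("annotation_enrichment", "data.frame")
  out
}

#' Genome-wide category fractions
#'
#' Fraction of genomic bases per annotation category under the
#' [annotate_peaks()] precedence (promoter_tss > tts > exon > intron >
#' intergenic). Fractions sum to 1 exactly.
#'
#' @inheritParams annotation_enrichment
#' @return Named numeric vector over the five categories.
#' @export
genome_category_fractions <- function(layout, genes,
                                      promoter_window = c(1000, 100),
                                      tts_window = c(100, 1000)) {
  total <- sum(layout$chrom_lengths)
  genome <- GenomicRanges::GRanges(
    layout$chrom_names, IRanges::IRanges(1, layout$chrom_lengths))
  cr <- category_ranges(genes, promoter_window, tts_window)
  clip <- function(gr) GenomicRanges::intersect(GenomicRanges::reduce(gr),
                                                genome)
  prom <- clip(cr$promoter_tss)
  tts <- GenomicRanges::setdiff(clip(cr$tts), prom)
  upper <- GenomicRanges::union(prom, tts)
  exon <- GenomicRanges::setdiff(clip(cr$exon), upper)
  upper <- GenomicRanges::union(upper, exon)
  intron <- GenomicRanges::setdiff(clip(cr$body), upper)
  widths <- c(promoter_tss = sum(BiocGenerics::width(prom)),
              tts = sum(BiocGenerics::width(tts)),
              exon = sum(BiocGenerics::width(exon)),
              intron = sum(BiocGenerics::width(intron)))
  widths <- c(widths, intergenic = total - sum(widths))
  widths / total
}

#' Write an annotation enrichment table as TSV
#'
#' @param enr An `annotation_enrichment` data frame.
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(enr, path) {
  df <- enr
  df$observed_fraction <- format_signal(df$observed_fraction)
  df$genome_fraction <- format_signal(df$genome_fraction)
  df$log2_ratio <- format_signal(df$log2_ratio)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
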