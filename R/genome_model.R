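#' Genome layout
#'
#' A minimal description of the reference genome: ordered chromosome names and
#' their lengths in base pairs. All coordinates in the package are 0-based,
#' half-open (BED convention) and validated against a layout.
#'
#' @param chrom_names Character vector of unique chromosome identifiers.
#' @param chrom_lengths Numeric vector of chromosome lengths (bp), same length
#'   as `chrom_names`, all positive.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  names(chrom_lengths) <- chrom_names
  structure(list(chrom_names = chrom_names, chrom_lengths = chrom_lengths),
            class = "genome_layout")
}

#' Read a UCSC chrom.sizes file into a genome layout
#'
#' @param path Two-column tab-separated file: chromosome name, length.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(df$chrom, df$length)
}

#' Write a genome layout as a chrom.sizes file
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  utils::write.table(
    data.frame(layout$chrom_names, format_bp(layout$chrom_lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_names), "chromosomes,",
      format_bp(sum(x$chrom_lengths)), "bp total\n")
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  len <- layout$chrom_lengths[chrom]
  if (any(is.na(len))) stop("unknown chromosome: ",
                            paste(chrom[is.na(len)], collapse = ", "))
  unname(len)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Gene models
#'
#' A table of strand-aware gene models. Coordinates are 0-based half-open;
#' `start`/`end` give the genomic span, and the biological transcription start
#' and end sites are derived from strand (`tss = start` on `+`, `tss = end` on
#' `-`). Exons are stored as a list column of two-column matrices
#' (start, end), sorted and within the gene span.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param start,end Genomic span per gene (0-based half-open), `start < end`.
#' @param exons List of two-column matrices of exon intervals per gene.
#' @param layout Optional [genome_layout()] used to validate coordinates.
#' @return A data frame of class `gene_models` with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `tss`, `tes` and list column `exons`.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end, exons,
                        layout = NULL) {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene/transcript id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("gene span must have start < end")
  if (!is.null(layout)) {
    if (any(start < 0) || any(end > chrom_length(layout, chrom)))
      stop("gene span outside chromosome bounds")
  }
  if (length(exons) != n) stop("one exon matrix required per gene")
  exons <- lapply(seq_len(n), function(i) {
    ex <- exons[[i]]
    ex <- matrix(as.numeric(ex), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    if (nrow(ex) == 0) stop("gene ", gene_id[i], " has no exons")
    ex <- ex[order(ex[, 1], ex[, 2]), , drop = FALSE]
    if (any(ex[, 1] >= ex[, 2]))
      stop("gene ", gene_id[i], " has a zero/negative-length exon")
    if (ex[1, 1] < start[i] || ex[nrow(ex), 2] > end[i])
      stop("gene ", gene_id[i], " has exons outside its span")
    ex
  })
  df <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                   strand = strand, start = start, end = end,
                   tss = ifelse(strand == "+", start, end),
                   tes = ifelse(strand == "+", end, start),
                   stringsAsFactors = FALSE)
  df$exons <- exons
  class(df) <- c("gene_models", "data.frame")
  df
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x), "genes on",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read gene models from a BED12 or GTF file
#'
#' One gene model is produced per transcript record. When a GTF gene has
#' several transcripts, the longest-spanning transcript is kept as the
#' representative model. Records on chromosomes absent from `layout` are
#' dropped with a warning. BED12 files are read in their native 0-based
#' half-open coordinates; GTF (1-based closed) is converted on read.
#'
#' @param path Path to a BED12 or GTF file.
#' @param layout A [genome_layout()].
#' @param format `"auto"` (from extension), `"bed12"` or `"gtf"`.
#' @return A [gene_models()] table.
#' @export
read_gene_models <- function(path, layout, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed12", bed12 = "bed12",
                     gtf = "gtf", gff = "gtf",
                     stop("cannot infer gene model format from extension '",
                          ext, "'"))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed12") "bed" else "gtf"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (format == "bed12") {
    ids <- as.character(gr$name)
    keep <- drop_unknown_chroms(as.character(GenomeInfoDb::seqnames(gr)),
                                layout, ids)
    gr <- gr[keep]
    bl <- rtracklayer::blocks(gr)
    exons <- lapply(seq_along(bl), function(i) {
      cbind(start = BiocGenerics::start(bl[[i]]) - 1,
            end = BiocGenerics::end(bl[[i]]))
    })
    gene_models(as.character(gr$name),
                as.character(GenomeInfoDb::seqnames(gr)),
                as.character(BiocGenerics::strand(gr)),
                BiocGenerics::start(gr) - 1, BiocGenerics::end(gr),
                exons, layout = layout)
  } else {
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0) stop("no exon records in ", path)
    tx <- as.character(gr$transcript_id)
    gene <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else tx
    keep <- drop_unknown_chroms(as.character(GenomeInfoDb::seqnames(gr)),
                                layout, tx)
    gr <- gr[keep]; tx <- tx[keep]; gene <- gene[keep]
    parts <- split(seq_along(gr), tx)
    # a transcript id spanning several chromosomes/strands means a duplicate id
    rec <- lapply(names(parts), function(t) {
      i <- parts[[t]]
      ch <- unique(as.character(GenomeInfoDb::seqnames(gr[i])))
      st <- unique(as.character(BiocGenerics::strand(gr[i])))
      if (length(ch) > 1 || length(st) > 1)
        stop("duplicate transcript id across chromosomes/strands: ", t)
      list(id = t, gene = gene[i[1]], chrom = ch, strand = st,
           start = min(BiocGenerics::start(gr[i])) - 1,
           end = max(BiocGenerics::end(gr[i])),
           exons = cbind(start = BiocGenerics::start(gr[i]) - 1,
                         end = BiocGenerics::end(gr[i])))
    })
    # one representative transcript per gene: the longest span
    by_gene <- split(rec, vapply(rec, `[[`, "", "gene"))
    rec <- lapply(by_gene, function(rs) {
      spans <- vapply(rs, function(r) r$end - r$start, 0)
      rs[[which.max(spans)]]
    })
    gene_models(vapply(rec, `[[`, "", "gene"),
                vapply(rec, `[[`, "", "chrom"),
                vapply(rec, `[[`, "", "strand"),
                vapply(rec, `[[`, 0, "start"),
                vapply(rec, `[[`, 0, "end"),
                lapply(rec, `[[`, "exons"), layout = layout)
  }
}

drop_unknown_chroms <- function(chroms, layout, ids) {
  keep <- chroms %in% layout$chrom_names
  if (!all(keep))
    warning("dropped ", sum(!keep), " record(s) on unknown chromosome(s): ",
            paste(unique(chroms[!keep]), collapse = ", "))
  keep
}

#' Region sets
#'
#' A labelled set of genomic intervals (0-based half-open). Labels are unique
#' within a set; an optional `group` column lets several intervals share one
#' scoring unit (used for merged exons, where the score denominator is the
#' summed exon length of the gene).
#'
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param label Unique interval labels.
#' @param strand Optional strand (`"+"`, `"-"` or `"*"`).
#' @param group Optional grouping identifier (defaults to `label`).
#' @param name Name of the set.
#' @param kind Region kind: `"promoter"`, `"body"`, `"merged_exons"`,
#'   `"peak"` or `"generic"`.
#' @param layout Optional [genome_layout()] for validation.
#' @return A data frame of class `region_set`.
#' @export
region_set <- function(chrom, start, end, label, strand = NULL, group = NULL,
                       name = "regions",
                       kind = c("generic", "promoter", "body", "merged_exons",
                                "peak"),
                       layout = NULL) {
  kind <- match.arg(kind)
  start <- as.numeric(start); end <- as.numeric(end)
  label <- as.character(label)
  if (anyDuplicated(label)) stop("region labels must be unique within a set")
  if (any(start < 0) || any(start >= end))
    stop("regions must satisfy 0 <= start < end")
  if (!is.null(layout) && any(end > chrom_length(layout, as.character(chrom))))
    stop("region extends past chromosome end")
  n <- length(label)
  df <- data.frame(chrom = rep_len(as.character(chrom), n), start = start,
                   end = end,
                   strand = if (is.null(strand)) rep_len("*", n)
                            else rep_len(as.character(strand), n),
                   label = label,
                   group = if (is.null(group)) label else as.character(group),
                   stringsAsFactors = FALSE)
  attr(df, "name") <- name
  attr(df, "kind") <- kind
  class(df) <- c("region_set", "data.frame")
  df
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set '", attr(x, "name"), "' (", attr(x, "kind"), "): ",
      nrow(x), " regions, ", length(unique(x$group)), " groups\n", sep = "")
  invisible(x)
}

as_granges <- function(rs) {
  GenomicRanges::GRanges(rs$chrom,
                         IRanges::IRanges(rs$start + 1, rs$end),
                         strand = rs$strand)
}

#' Promoter window of a gene
#'
#' The promoter is the unstranded window `TSS +/- flank` around the biological
#' (strand-aware) transcription start site, clipped to the chromosome. Clipped
#' windows are flagged in the `clipped` attribute of the returned set.
#'
#' @param genes A [gene_models()] table.
#' @param flank Half-width of the window in bp (default 500).
#' @param layout A [genome_layout()] used to clip at chromosome edges.
#' @return A `region_set` of kind `"promoter"`, one region per gene, labelled
#'   by `gene_id`.
#' @export
promoters_of <- function(genes, flank = 500, layout) {
  stopifnot(inherits(genes, "gene_models"), flank >= 0)
  start <- genes$tss - flank
  end <- genes$tss + flank
  lens <- chrom_length(layout, genes$chrom)
  clipped <- start < 0 | end > lens
  start <- pmax(start, 0)
  end <- pmin(end, lens)
  rs <- region_set(genes$chrom, start, end, genes$gene_id,
                   strand = genes$strand, name = "promoters",
                   kind = "promoter", layout = layout)
  attr(rs, "clipped") <- genes$gene_id[clipped]
  rs
}

#' Gene-body regions (TSS to TES)
#'
#' @param genes A [gene_models()] table.
#' @param layout Optional [genome_layout()] for validation.
#' @return A `region_set` of kind `"body"`, one region per gene spanning
#'   `min(tss, tes)` to `max(tss, tes)` (half-open), labelled by `gene_id`.
#' @export
bodies_of <- function(genes, layout = NULL) {
  stopifnot(inherits(genes, "gene_models"))
  if (any(genes$start >= genes$end)) stop("zero-length gene span")
  region_set(genes$chrom, genes$start, genes$end, genes$gene_id,
             strand = genes$strand, name = "gene_bodies", kind = "body",
             layout = layout)
}

#' Merged exon regions
#'
#' Unions each gene's exon intervals (overlaps merged) into a region set in
#' which all intervals of a gene share one scoring group, so that region
#' scores use the summed merged-exon length as denominator (the metagene
#' convention for RNA).
#'
#' @param genes A [gene_models()] table.
#' @param layout Optional [genome_layout()] for validation.
#' @return A `region_set` of kind `"merged_exons"`; interval labels are
#'   `<gene_id>.e<k>` and `group` is the gene id.
#' @export
merged_exons_of <- function(genes, layout = NULL) {
  stopifnot(inherits(genes, "gene_models"))
  per_gene <- lapply(seq_len(nrow(genes)), function(i) {
    ex <- merge_intervals(genes$exons[[i]])
    data.frame(chrom = genes$chrom[i], start = ex[, 1], end = ex[, 2],
               strand = genes$strand[i],
               label = paste0(genes$gene_id[i], ".e", seq_len(nrow(ex))),
               group = genes$gene_id[i], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, per_gene)
  region_set(df$chrom, df$start, df$end, df$label, strand = df$strand,
             group = df$group, name = "merged_exons", kind = "merged_exons",
             layout = layout)
}

# union of possibly-overlapping intervals; input/output 2-col matrix, 0-based
merge_intervals <- function(m) {
  ir <- IRanges::reduce(IRanges::IRanges(m[, 1] + 1, m[, 2]))
  cbind(start = BiocGenerics::start(ir) - 1, end = BiocGenerics::end(ir))
}

#' Two-set overlap (Venn) counts for region sets
#'
#' A region counts as shared ("both") when it overlaps at least one region of
#' the other set by at least `min_overlap` bp; counts partition each input
#' set, as in a two-set Venn diagram of peak overlap.
#'
#' @param a,b `region_set` objects on the same layout.
#' @param min_overlap Minimum overlap in bp to count as shared (default 1,
#'   i.e. any direct overlap).
#' @return A list with `only_a`, `only_b`, `both_a`, `both_b` (counts of
#'   regions of each set that are shared), `both` (= `both_a`), and
#'   `shared_regions`, the `region_set` of `a`-regions that are shared.
#' @export
venn_overlap <- function(a, b, min_overlap = 1) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"),
            min_overlap >= 1)
  gra <- as_granges(a); grb <- as_granges(b)
  hit_a <- IRanges::overlapsAny(gra, grb, minoverlap = min_overlap,
                                ignore.strand = TRUE)
  hit_b <- IRanges::overlapsAny(grb, gra, minoverlap = min_overlap,
                                ignore.strand = TRUE)
  shared <- a[hit_a, , drop = FALSE]
  attr(shared, "name") <- "shared"
  list(only_a = sum(!hit_a), only_b = sum(!hit_b),
       both_a = sum(hit_a), both_b = sum(hit_b), both = sum(hit_a),
       shared_regions = shared)
}

#' Write a region set as BED6
#'
#' @param rs A `region_set`.
#' @param path Output path.
#' @param score Optional numeric score column (default 0).
#' @export
write_bed <- function(rs, path, score = NULL) {
  stopifnot(inherits(rs, "region_set"))
  sc <- if (is.null(score)) rep(0, nrow(rs)) else score
  df <- data.frame(rs$chrom, format_bp(rs$start), format_bp(rs$end),
                   rs$label, sc, rs$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as BED12
#'
#' @param genes A [gene_models()] table.
#' @param path Output path.
#' @export
write_bed12 <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    paste(genes$chrom[i], format_bp(genes$start[i]), format_bp(genes$end[i]),
          genes$gene_id[i], 0, genes$strand[i],
          format_bp(genes$start[i]), format_bp(genes$end[i]), 0, nrow(ex),
          paste0(paste(format_bp(ex[, 2] - ex[, 1]), collapse = ","), ","),
          paste0(paste(format_bp(ex[, 1] - genes$start[i]), collapse = ","),
                 ","),
          sep = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}
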