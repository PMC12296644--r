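#' Configuration for the synthetic two-timepoint dataset
#'
#' Defines the study conditions the generator emulates: a multi-mark
#' (H4K20me1, H4K20me3, Ser5/Ser2 Pol II, ATAC, RNA), two-timepoint
#' (day7/day10), replicated coverage dataset over a synthetic gene
#' annotation, with planted gene classes: active genes with gene-body
#' H4K20me1 covarying with Pol II and RNA; paused genes with a promoter
#' Ser5 spike, promoter H4K20me3 and TSS-restricted H4K20me1; silent genes
#' with TSS-restricted H4K20me1; dynamic H4K20me1 gain/loss classes;
#' "globin-like" genes losing gene-body H4K20me1 while gaining promoter
#' H4K20me3; and background genes. Intergenic H4K20me3 blocks are planted in
#' gene-free space. Every output is a pure function of the configuration.
#'
#' @param seed Integer seed controlling all randomness.
#' @param preset `"small"` (5 Mb, 200 genes; unit-test scale) or `"medium"`
#'   (50 Mb, 2000 genes; full-analysis scale). `NULL` keeps explicit values.
#' @param n_chrom,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Number of genes.
#' @param class_fractions Named fractions over the seven gene classes
#'   (must sum to 1).
#' @param intergenic_me3_block_density Intergenic H4K20me3 blocks per Mb.
#' @param block_width,block_value Width (bp) and signal level of intergenic
#'   H4K20me3 blocks.
#' @param ser5_pi_ratio Promoter:body Ser5 score ratio planted at paused
#'   genes (default 8).
#' @param dynamic_lfc Planted |log2 fold change| of the dynamic H4K20me1
#'   classes (default 2).
#' @param noise_sigma Lognormal sigma of multiplicative replicate noise
#'   (default 0.2); 0 gives identical replicates.
#' @param nb_dispersion NB dispersion used by [simulate_counts()]
#'   (default 0.1).
#' @param replicates Replicates per condition (default 3).
#' @param read_bin Nominal bin width (bp) tying raw track values to library
#'   size (default 50).
#' @param gene_length_range Log-uniform gene length range in bp.
#' @param min_gap Minimum intergenic gap in bp (default 2000).
#' @param peak_cutoffs Named RPKM cutoffs used by the pipeline's peak calls.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, preset = NULL,
                             n_chrom = 2, chrom_length = 2.5e6,
                             n_genes = 200,
                             class_fractions = c(active_body_me1 = 0.25,
                                                 paused_tss_me3 = 0.30,
                                                 repressed_tss_me1 = 0.10,
                                                 dynamic_gain_me1 = 0.10,
                                                 dynamic_loss_me1 = 0.10,
                                                 me1loss_me3gain_globinlike = 0.05,
                                                 background = 0.10),
                             intergenic_me3_block_density = 2,
                             block_width = 5000, block_value = 20,
                             ser5_pi_ratio = 8, dynamic_lfc = 2,
                             noise_sigma = 0.2, nb_dispersion = 0.1,
                             replicates = 3, read_bin = 50,
                             gene_length_range = c(2000, 50000),
                             min_gap = 2000,
                             peak_cutoffs = c(me1 = 5, me3 = 5)) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("small", "medium"))
    if (preset == "small") {
      n_chrom <- 2; chrom_length <- 2.5e6; n_genes <- 200
    } else {
      n_chrom <- 5; chrom_length <- 1e7; n_genes <- 2000
    }
  }
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  if (any(class_fractions < 0)) stop("class fractions must be >= 0")
  stopifnot(replicates >= 2, noise_sigma >= 0, nb_dispersion >= 0,
            ser5_pi_ratio > 0, dynamic_lfc > 0)
  structure(list(seed = as.integer(seed), n_chrom = n_chrom,
                 chrom_length = chrom_length, n_genes = n_genes,
                 class_fractions = class_fractions,
                 intergenic_me3_block_density = intergenic_me3_block_density,
                 block_width = block_width, block_value = block_value,
                 ser5_pi_ratio = ser5_pi_ratio, dynamic_lfc = dynamic_lfc,
                 noise_sigma = noise_sigma, nb_dispersion = nb_dispersion,
                 replicates = replicates, read_bin = read_bin,
                 gene_length_range = gene_length_range, min_gap = min_gap,
                 peak_cutoffs = peak_cutoffs),
            class = "synthetic_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

synthetic_marks <- c("me1", "me3", "ser5", "ser2", "atac", "rna")
synthetic_days <- c("day7", "day10")
mark_baseline <- c(me1 = 0.4, me3 = 0.3, ser5 = 0.3, ser2 = 0.3,
                   atac = 0.5, rna = 0.05)

#' Generate the synthetic genome: layout and gene models
#'
#' Places non-overlapping genes (random strand, 1-10 exons, lengths
#' log-uniform over `gene_length_range`) on equal-length chromosomes,
#' separated by at least `min_gap` bp. Deterministic under the
#' configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `layout` ([genome_layout()]) and `genes`
#'   ([gene_models()]).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    layout <- genome_layout(paste0("chr", seq_len(config$n_chrom)),
                            rep(config$chrom_length, config$n_chrom))
    n_per <- diff(round(seq(0, config$n_genes,
                            length.out = config$n_chrom + 1)))
    rows <- list()
    gi <- 0
    for (ci in seq_len(config$n_chrom)) {
      n <- n_per[ci]
      if (n == 0) next
      lr <- log(config$gene_length_range)
      lens <- round(exp(stats::runif(n, lr[1], lr[2])))
      free <- config$chrom_length - sum(lens) - (n + 1) * config$min_gap
      if (free < 0)
        stop("infeasible gene packing; increase chrom_length or reduce ",
             "n_genes")
      extra <- stats::runif(n + 1)
      extra <- floor(extra / sum(extra) * free)
      gaps <- config$min_gap + extra
      starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, lens[-n]))
      for (k in seq_len(n)) {
        gi <- gi + 1
        glen <- lens[k]
        n_ex <- sample.int(10, 1)
        ex <- if (n_ex == 1) cbind(0, glen) else {
          cuts <- sort(sample(seq_len(glen - 1), 2 * n_ex - 2))
          bounds <- c(0, cuts, glen)
          seg <- cbind(bounds[-length(bounds)], bounds[-1])
          seg[seq(1, nrow(seg), by = 2), , drop = FALSE]
        }
        rows[[gi]] <- list(gene_id = sprintf("g%04d", gi),
                           chrom = layout$chrom_names[ci],
                           strand = sample(c("+", "-"), 1),
                           start = starts[k], end = starts[k] + glen,
                           exons = ex + starts[k])
      }
    }
    genes <- if (gi == 0)
      gene_models(character(), character(), character(), numeric(),
                  numeric(), list(), layout = layout)
    else
      gene_models(vapply(rows, `[[`, "", "gene_id"),
                  vapply(rows, `[[`, "", "chrom"),
                  vapply(rows, `[[`, "", "strand"),
                  vapply(rows, `[[`, 0, "start"),
                  vapply(rows, `[[`, 0, "end"),
                  lapply(rows, `[[`, "exons"), layout = layout)
    list(layout = layout, genes = genes)
  })
}

# per-class generative mean levels (RPKM-like units), day7 / day10
class_levels <- function(config) {
  r <- config$ser5_pi_ratio
  fc <- 2^config$dynamic_lfc
  lv <- list(
    background = list(me1_body = c(0.5, 0.5), me1_tss = 0,
                      me3_prom = c(0, 0), ser5_body = c(0.5, 0.5),
                      ser5_ratio = 1, ser2_body = c(0.5, 0.5),
                      atac_prom = 1, rna = c(2, 2)),
    active_body_me1 = list(me1_body = c(20, 20), me1_tss = 0,
                           me3_prom = c(0, 0), ser5_body = c(10, 10),
                           ser5_ratio = 2, ser2_body = c(15, 15),
                           atac_prom = 20, rna = c(200, 200)),
    paused_tss_me3 = list(me1_body = c(2, 2), me1_tss = 15,
                          me3_prom = c(20, 20), ser5_body = c(5, 5),
                          ser5_ratio = r, ser2_body = c(2, 2),
                          atac_prom = 25, rna = c(150, 150)),
    repressed_tss_me1 = list(me1_body = c(1, 1), me1_tss = 15,
                             me3_prom = c(0, 0), ser5_body = c(0.5, 0.5),
                             ser5_ratio = 1, ser2_body = c(0.5, 0.5),
                             atac_prom = 2, rna = c(0.2, 0.2)),
    dynamic_gain_me1 = list(me1_body = c(6, 6 * fc), me1_tss = 0,
                            me3_prom = c(0, 0), ser5_body = c(5, 20),
                            ser5_ratio = 2, ser2_body = c(5, 10),
                            atac_prom = 10, rna = c(50, 200)),
    dynamic_loss_me1 = list(me1_body = c(6 * fc, 6), me1_tss = 0,
                            me3_prom = c(0, 0), ser5_body = c(5, 1.25),
                            ser5_ratio = 2, ser2_body = c(5, 1.25),
                            atac_prom = 10, rna = c(50, 12.5)),
    me1loss_me3gain_globinlike = list(me1_body = c(30, 0.8), me1_tss = 0,
                                      me3_prom = c(1, 20),
                                      ser5_body = c(12, 24), ser5_ratio = 2,
                                      ser2_body = c(12, 24), atac_prom = 20,
                                      rna = c(300, 600))
  )
  lv
}

#' Plant the ground truth: class labels, generative levels, me3 blocks
#'
#' Assigns each gene to a class according to the configured fractions and
#' records per-gene, per-mark, per-timepoint generative mean levels and true
#' log2 fold changes; places intergenic H4K20me3 blocks in gene-free space.
#'
#' @param config A [synthetic_config()].
#' @param genome Result of [make_genome()].
#' @return List of class `synthetic_truth` with `genes` (per-gene truth
#'   table) and `blocks` (intergenic block coordinates).
#' @export
plant_truth <- function(config, genome) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- genome$genes
  n <- nrow(genes)
  with_seed(config$seed + 1L, {
    fr <- config$class_fractions
    counts <- floor(fr * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      ord <- order(fr * n - counts, decreasing = TRUE)
      counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
    }
    cls <- sample(rep(names(fr), counts))
    lv <- class_levels(config)
    g <- function(field, day) vapply(cls, function(c) {
      v <- lv[[c]][[field]]
      if (length(v) == 2) v[day] else v
    }, 0)
    truth_genes <- data.frame(
      gene_id = genes$gene_id, class = cls,
      me1_body_d7 = g("me1_body", 1), me1_body_d10 = g("me1_body", 2),
      me1_tss = g("me1_tss", 1),
      me3_prom_d7 = g("me3_prom", 1), me3_prom_d10 = g("me3_prom", 2),
      ser5_body_d7 = g("ser5_body", 1), ser5_body_d10 = g("ser5_body", 2),
      ser5_ratio = g("ser5_ratio", 1),
      ser2_body_d7 = g("ser2_body", 1), ser2_body_d10 = g("ser2_body", 2),
      atac_prom = g("atac_prom", 1),
      rna_d7 = g("rna", 1), rna_d10 = g("rna", 2),
      stringsAsFactors = FALSE, row.names = NULL)
    truth_genes$true_lfc_me1_body <-
      log2(truth_genes$me1_body_d10 / truth_genes$me1_body_d7)
    bg <- mark_baseline["me3"]
    truth_genes$true_lfc_me3_prom <-
      log2(pmax(truth_genes$me3_prom_d10, bg) /
             pmax(truth_genes$me3_prom_d7, bg))
    blocks <- place_me3_blocks(config, genome)
    structure(list(genes = truth_genes, blocks = blocks),
              class = "synthetic_truth")
  })
}

place_me3_blocks <- function(config, genome) {
  n_blocks <- round(config$intergenic_me3_block_density *
                      config$n_chrom * config$chrom_length / 1e6)
  margin <- config$min_gap / 2
  gaps <- list()
  for (ch in genome$layout$chrom_names) {
    g <- genome$genes[genome$genes$chrom == ch, , drop = FALSE]
    edges <- c(0, as.vector(rbind(g$start, g$end)), config$chrom_length)
    free <- matrix(edges, ncol = 2, byrow = TRUE)  # gap intervals
    lo <- free[, 1] + margin
    hi <- free[, 2] - margin - config$block_width
    ok <- hi > lo
    if (any(ok))
      gaps[[ch]] <- data.frame(chrom = ch, lo = lo[ok], hi = hi[ok])
  }
  gaps <- do.call(rbind, gaps)
  if (is.null(gaps) || nrow(gaps) == 0 || n_blocks == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  space <- gaps$hi - gaps$lo
  pick <- sample.int(nrow(gaps), n_blocks, replace = TRUE,
                     prob = space / sum(space))
  start <- floor(gaps$lo[pick] + stats::runif(n_blocks) * space[pick])
  df <- data.frame(chrom = gaps$chrom[pick], start = start,
                   end = start + config$block_width,
                   value = config$block_value, stringsAsFactors = FALSE)
  # keep blocks disjoint: drop later blocks that collide with earlier ones
  keep <- rep(TRUE, nrow(df))
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    i <- i[order(df$start[i])]
    if (length(i) > 1)
      keep[i[-1]][df$start[i][-1] < df$end[i][-length(i)]] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# patch table for one mark: non-overlapping intervals with per-day levels.
# kinds get independent replicate noise. Upstream Ser5 spikes are placed on
# the strand-aware 500 bp upstream of the TSS with amplitude (2r-1)*body so
# the promoter-window mean is r*body for any gene length.
mark_patches <- function(mark, genome, truth, flank = 500) {
  g <- genome$genes
  t <- truth$genes
  up_start <- ifelse(g$strand == "+", g$tss - flank, g$tss)
  up_end <- ifelse(g$strand == "+", g$tss, g$tss + flank)
  body_inner_start <- ifelse(g$strand == "+", g$start + flank, g$start)
  body_inner_end <- ifelse(g$strand == "+", g$end, g$end - flank)
  rows <- list()
  add <- function(chrom, start, end, d7, d10, gene, kind) {
    keep <- end > start & (d7 > 0 | d10 > 0)
    if (!any(keep)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      chrom = chrom[keep], start = start[keep], end = end[keep],
      d7 = d7[keep], d10 = d10[keep], gene = gene[keep], kind = kind,
      stringsAsFactors = FALSE)
  }
  if (mark == "me1") {
    tssw <- t$me1_tss > 0
    add(g$chrom[!tssw], g$start[!tssw], g$end[!tssw],
        t$me1_body_d7[!tssw], t$me1_body_d10[!tssw], g$gene_id[!tssw],
        "body")
    # TSS-restricted genes: window at the TSS level, remaining body lower
    add(g$chrom[tssw], g$tss[tssw] - flank, g$tss[tssw] + flank,
        t$me1_tss[tssw], t$me1_tss[tssw], g$gene_id[tssw], "tss_window")
    add(g$chrom[tssw], body_inner_start[tssw], body_inner_end[tssw],
        t$me1_body_d7[tssw], t$me1_body_d10[tssw], g$gene_id[tssw], "body")
  } else if (mark == "me3") {
    add(g$chrom, g$tss - flank, g$tss + flank, t$me3_prom_d7,
        t$me3_prom_d10, g$gene_id, "promoter")
    b <- truth$blocks
    if (nrow(b))
      add(b$chrom, b$start, b$end, b$value, b$value,
          paste0("block_", seq_len(nrow(b))), "block")
  } else if (mark == "ser5") {
    spike7 <- (2 * t$ser5_ratio - 1) * t$ser5_body_d7
    spike10 <- (2 * t$ser5_ratio - 1) * t$ser5_body_d10
    add(g$chrom, up_start, up_end, spike7, spike10, g$gene_id, "spike")
    add(g$chrom, g$start, g$end, t$ser5_body_d7, t$ser5_body_d10,
        g$gene_id, "body")
  } else if (mark == "ser2") {
    add(g$chrom, g$start, g$end, t$ser2_body_d7, t$ser2_body_d10,
        g$gene_id, "body")
  } else if (mark == "atac") {
    add(g$chrom, g$tss - flank, g$tss + flank, t$atac_prom, t$atac_prom,
        g$gene_id, "promoter")
  } else if (mark == "rna") {
    ex <- merged_exons_of(genome$genes)
    lev7 <- t$rna_d7[match(ex$group, t$gene_id)]
    lev10 <- t$rna_d10[match(ex$group, t$gene_id)]
    add(ex$chrom, ex$start, ex$end, lev7, lev10, ex$group, "exons")
  }
  if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(chrom = character(), start = numeric(), end = numeric(),
                  d7 = numeric(), d10 = numeric(), gene = character(),
                  kind = character())
}

# complement of patch intervals within each chromosome (baseline regions)
baseline_rows <- function(patches, layout) {
  out <- list()
  for (ch in layout$chrom_names) {
    p <- patches[patches$chrom == ch, , drop = FALSE]
    L <- unname(layout$chrom_lengths[ch])
    if (nrow(p) == 0) {
      out[[ch]] <- data.frame(chrom = ch, start = 0, end = L)
      next
    }
    p <- p[order(p$start), , drop = FALSE]
    starts <- c(0, p$end)
    ends <- c(p$start, L)
    keep <- ends > starts
    out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                            end = ends[keep])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate per-mark, per-timepoint, per-replicate coverage tracks
#'
#' Builds raw-count coverage tracks from the planted truth: class-dependent
#' piecewise-constant means with independent multiplicative lognormal noise
#' per (gene, patch kind, timepoint, replicate), a genome-wide per-mark
#' baseline, and a per-track depth factor tying the track to a nominal
#' library size (`total_reads = depth * 1e9 / read_bin`). With
#' `noise_sigma = 0` replicates are identical and depth factors are 1.
#'
#' @param config A [synthetic_config()].
#' @param genome Result of [make_genome()].
#' @param truth Result of [plant_truth()].
#' @return List of class `synthetic_tracks`: `tracks` (named list of
#'   raw-count [coverage_track()]s, names `<mark>_<day>_rep<k>`) and
#'   `depths` (data frame of per-track depth factors and `total_reads`).
#' @export
simulate_tracks <- function(config, genome, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_truth"))
  layout <- genome$layout
  sigma <- config$noise_sigma
  with_seed(config$seed + 2L, {
    tracks <- list()
    depths <- list()
    for (mark in synthetic_marks) {
      patches <- mark_patches(mark, genome, truth)
      base <- baseline_rows(patches, layout)
      for (day in synthetic_days) {
        lev <- if (day == "day7") patches$d7 else patches$d10
        for (rep_k in seq_len(config$replicates)) {
          noise <- if (nrow(patches) && sigma > 0) {
            key <- paste(patches$gene, patches$kind)
            uk <- unique(key)
            stats::rlnorm(length(uk), 0, sigma)[match(key, uk)]
          } else rep(1, nrow(patches))
          depth <- if (sigma > 0) stats::rlnorm(1, 0, sigma / 2) else 1
          nm <- paste0(mark, "_", day, "_rep", rep_k)
          vals <- c(lev * noise * depth,
                    rep(mark_baseline[mark] * depth, nrow(base)))
          df <- data.frame(chrom = c(patches$chrom, base$chrom),
                           start = c(patches$start, base$start),
                           end = c(patches$end, base$end),
                           value = vals, stringsAsFactors = FALSE)
          tracks[[nm]] <- coverage_track(df$chrom, df$start, df$end,
                                         df$value, layout,
                                         units = "raw_count")
          depths[[nm]] <- data.frame(
            track = nm, mark = mark, day = day, rep = rep_k, depth = depth,
            total_reads = round(depth * 1e9 / config$read_bin),
            stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(tracks = tracks,
                   depths = do.call(rbind, c(depths,
                                             list(make.row.names = FALSE)))),
              class = "synthetic_tracks")
  })
}

#' Simulate an NB count matrix with planted fold changes
#'
#' Draws a generic negative-binomial feature-by-sample count matrix for two
#' conditions with known per-sample depth multipliers, planting `frac_up`
#' and `frac_down` of the features at `+lfc` / `-lfc` true log2 fold change
#' (day10 vs day7) and the rest at 0.
#'
#' @param n_features,n_per_group Panel dimensions.
#' @param base_mean_range Log-uniform range of generative base means.
#' @param dispersion NB dispersion alpha (`Var = mu + alpha mu^2`); 0 gives
#'   Poisson draws.
#' @param frac_up,frac_down Fractions of features planted up/down.
#' @param lfc Planted |log2 fold change|.
#' @param depth_range Per-sample depth multipliers are drawn log-uniformly
#'   from this range.
#' @param seed Integer seed.
#' @return List: `counts` (integer matrix), `condition` (factor
#'   day7/day10), `true_lfc`, `depth_factors`, `base_mean`.
#' @export
simulate_nb_counts <- function(n_features = 2000, n_per_group = 3,
                               base_mean_range = c(50, 2000),
                               dispersion = 0.1, frac_up = 0.1,
                               frac_down = 0.1, lfc = 2,
                               depth_range = c(0.8, 1.25), seed = 1) {
  with_seed(seed, {
    base <- exp(stats::runif(n_features, log(base_mean_range[1]),
                             log(base_mean_range[2])))
    n_up <- round(frac_up * n_features)
    n_dn <- round(frac_down * n_features)
    true_lfc <- rep(0, n_features)
    planted <- sample.int(n_features, n_up + n_dn)
    true_lfc[planted[seq_len(n_up)]] <- lfc
    if (n_dn > 0) true_lfc[planted[n_up + seq_len(n_dn)]] <- -lfc
    condition <- factor(rep(c("day7", "day10"), each = n_per_group),
                        levels = c("day7", "day10"))
    depth <- exp(stats::runif(2 * n_per_group, log(depth_range[1]),
                              log(depth_range[2])))
    mu <- outer(base, ifelse(condition == "day10", 1, 0), function(b, d) b) *
      2^outer(true_lfc, as.numeric(condition == "day10"))
    mu <- sweep(mu, 2, depth, "*")
    counts <- matrix(
      if (dispersion > 0)
        stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion)
      else stats::rpois(length(mu), as.vector(mu)),
      nrow = n_features)
    dimnames(counts) <- list(sprintf("f%05d", seq_len(n_features)),
                             paste0(condition, "_rep",
                                    c(seq_len(n_per_group),
                                      seq_len(n_per_group))))
    names(true_lfc) <- rownames(counts)
    list(counts = counts, condition = condition, true_lfc = true_lfc,
         depth_factors = depth, base_mean = base)
  })
}

#' Simulate NB counts over the planted gene features
#'
#' Draws NB counts for the H4K20me1 gene-body features of the planted truth
#' (mean = generative level x body length / read_bin x per-sample depth),
#' giving a count matrix whose true log2 fold changes are the planted
#' `true_lfc_me1_body`.
#'
#' @param config A [synthetic_config()].
#' @param genome Result of [make_genome()].
#' @param truth Result of [plant_truth()].
#' @return List: `counts`, `condition`, `true_lfc`, `depth_factors`.
#' @export
simulate_counts <- function(config, genome, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_truth"))
  with_seed(config$seed + 3L, {
    t <- truth$genes
    width <- genome$genes$end - genome$genes$start
    n_rep <- config$replicates
    condition <- factor(rep(synthetic_days, each = n_rep),
                        levels = synthetic_days)
    depth <- if (config$noise_sigma > 0)
      stats::rlnorm(2 * n_rep, 0, config$noise_sigma / 2)
    else rep(1, 2 * n_rep)
    mu_day <- cbind(t$me1_body_d7, t$me1_body_d10)[, as.integer(condition)]
    mu <- mu_day * width / config$read_bin
    mu <- sweep(mu, 2, depth, "*")
    counts <- matrix(
      if (config$nb_dispersion > 0)
        stats::rnbinom(length(mu), mu = as.vector(mu),
                       size = 1 / config$nb_dispersion)
      else stats::rpois(length(mu), as.vector(mu)),
      nrow = nrow(t),
      dimnames = list(t$gene_id, paste0(condition, "_rep",
                                        rep(seq_len(n_rep), 2))))
    true_lfc <- t$true_lfc_me1_body
    names(true_lfc) <- t$gene_id
    list(counts = counts, condition = condition, true_lfc = true_lfc,
         depth_factors = depth)
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs [make_genome()], [plant_truth()] and [simulate_tracks()] under one
#' configuration.
#'
#' @param config A [synthetic_config()].
#' @param tracks Whether to simulate coverage tracks (default TRUE).
#' @return List of class `synthetic_dataset`: `config`, `layout`, `genes`,
#'   `truth`, and (optionally) `tracks`, `depths`.
#' @export
generate_dataset <- function(config, tracks = TRUE) {
  genome <- make_genome(config)
  truth <- plant_truth(config, genome)
  out <- list(config = config, layout = genome$layout, genes = genome$genes,
              truth = truth)
  if (tracks) {
    tr <- simulate_tracks(config, genome, truth)
    out$tracks <- tr$tracks
    out$depths <- tr$depths
  }
  structure(out, class = "synthetic_dataset")
}

#' Write a synthetic dataset as a self-contained fixture directory
#'
#' Layout: `tracks/<mark>_<day>_rep<k>.bedGraph`, `annotation.bed12`,
#' `chrom.sizes`, `truth.tsv`, `truth_blocks.tsv`, `config.yaml`,
#' `manifest.json` (per-track library sizes and the file inventory).
#'
#' @param dataset A [generate_dataset()] result with tracks.
#' @param dir Output directory (created; must be creatable).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            !is.null(dataset$tracks))
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create fixture directory ", dir)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  write_chrom_sizes(dataset$layout, file.path(dir, "chrom.sizes"))
  write_bed12(dataset$genes, file.path(dir, "annotation.bed12"))
  tg <- dataset$truth$genes
  num <- vapply(tg, is.numeric, TRUE)
  tg[num] <- lapply(tg[num], format_signal)
  utils::write.table(tg, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$blocks, file.path(dir, "truth_blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(dataset$tracks))
    write_bedgraph(dataset$tracks[[nm]],
                   file.path(dir, "tracks", paste0(nm, ".bedGraph")))
  cfg <- unclass(dataset$config)
  cfg$class_fractions <- as.list(cfg$class_fractions)
  cfg$peak_cutoffs <- as.list(cfg$peak_cutoffs)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  manifest <- list(
    read_bin = dataset$config$read_bin,
    tracks = lapply(seq_len(nrow(dataset$depths)), function(i) {
      d <- dataset$depths[i, ]
      list(file = file.path("tracks", paste0(d$track, ".bedGraph")),
           mark = d$mark, day = d$day, rep = d$rep,
           total_reads = d$total_reads)
    }),
    files = c("chrom.sizes", "annotation.bed12", "truth.tsv",
              "truth_blocks.tsv", "config.yaml"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Reload a fixture directory
#'
#' @param dir A directory written by [write_fixture()].
#' @return List: `layout`, `genes`, `tracks` (raw-count tracks), `manifest`,
#'   `truth` (gene truth table), `blocks`, `config`.
#' @export
read_fixture <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  layout <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  genes <- read_gene_models(file.path(dir, "annotation.bed12"), layout,
                            format = "bed12")
  tracks <- list()
  meta <- list()
  for (tr in manifest$tracks) {
    nm <- sub("\\.bedGraph$", "", basename(tr$file))
    tracks[[nm]] <- read_bedgraph(file.path(dir, tr$file), layout,
                                  units = "raw_count")
    meta[[nm]] <- data.frame(track = nm, mark = tr$mark, day = tr$day,
                             rep = tr$rep, total_reads = tr$total_reads,
                             stringsAsFactors = FALSE)
  }
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  blocks <- utils::read.table(file.path(dir, "truth_blocks.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  config <- yaml::read_yaml(file.path(dir, "config.yaml"))
  list(layout = layout, genes = genes, tracks = tracks,
       track_meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       manifest = manifest, truth = truth, blocks = blocks, config = config)
}
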