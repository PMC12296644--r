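#' Pipeline run configuration
#'
#' Bundles every input path and threshold of the two-timepoint analysis.
#' The configuration is serialised verbatim into the output directory for
#' provenance; outputs are a pure function of (configuration, input files).
#'
#' @param fixture_dir Input directory in [write_fixture()] layout (tracks/,
#'   annotation.bed12, chrom.sizes, manifest.json).
#' @param out_dir Output directory.
#' @param peak_cutoffs Named RPKM cutoffs for threshold peak calling per
#'   mark (default `c(me1 = 5, me3 = 5)`; on real data these correspond to
#'   the bdgpeakcall `-c` values and must match the track scale).
#' @param peak_min_length,peak_max_gap Peak-call length/gap parameters (bp).
#' @param pi_threshold Pausing-index cutoff (default 4).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1.5).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param expr_high RPKM cutoff defining expressed genes for the PI split
#'   (default 100).
#' @param expr_min RPKM gate for differential testing (default 25).
#' @param expr_floor RPKM gate for L2FC quantiles (default 1).
#' @param promoter_flank Promoter half-width in bp (default 500).
#' @param merge_method Replicate merge, `"mean"` or `"sum"`.
#' @param seed Seed recorded for provenance (the analysis itself is
#'   deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(fixture_dir, out_dir,
                       peak_cutoffs = c(me1 = 5, me3 = 5),
                       peak_min_length = 200, peak_max_gap = 30,
                       pi_threshold = 4, lfc_threshold = 1.5, alpha = 0.05,
                       expr_high = 100, expr_min = 25, expr_floor = 1,
                       promoter_flank = 500, merge_method = "mean",
                       seed = 1) {
  for (f in c("manifest.json", "chrom.sizes", "annotation.bed12"))
    if (!file.exists(file.path(fixture_dir, f)))
      stop("missing input file: ", file.path(fixture_dir, f))
  stopifnot(all(peak_cutoffs > 0), pi_threshold > 0, lfc_threshold > 0,
            alpha > 0, alpha < 1, expr_high > 0, expr_min > 0,
            expr_floor > 0, promoter_flank >= 0)
  structure(list(fixture_dir = fixture_dir, out_dir = out_dir,
                 peak_cutoffs = peak_cutoffs,
                 peak_min_length = peak_min_length,
                 peak_max_gap = peak_max_gap,
                 pi_threshold = pi_threshold,
                 lfc_threshold = lfc_threshold, alpha = alpha,
                 expr_high = expr_high, expr_min = expr_min,
                 expr_floor = expr_floor, promoter_flank = promoter_flank,
                 merge_method = merge_method, seed = seed),
            class = "run_config")
}

pipeline_stages <- c("normalize", "score", "peaks", "pausing", "deciles",
                     "differential", "fatemap", "report")

load_inputs <- function(cfg) {
  dir <- cfg$fixture_dir
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  layout <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  genes <- read_gene_models(file.path(dir, "annotation.bed12"), layout,
                            format = "bed12")
  meta <- do.call(rbind, lapply(manifest$tracks, function(tr)
    data.frame(file = tr$file, mark = tr$mark, day = tr$day, rep = tr$rep,
               total_reads = tr$total_reads, stringsAsFactors = FALSE)))
  missing <- !file.exists(file.path(dir, meta$file))
  if (any(missing))
    stop("missing replicate file(s): ",
         paste(file.path(dir, meta$file[missing]), collapse = ", "))
  list(manifest = manifest, layout = layout, genes = genes, meta = meta,
       read_bin = manifest$read_bin)
}

merged_path <- function(cfg, mark, day)
  file.path(cfg$out_dir, "merged", paste0(mark, "_", day, ".bedGraph"))

score_path <- function(cfg, mark, day, kind)
  file.path(cfg$out_dir, "scores", paste0(mark, "_", day, "_", kind, ".tsv"))

read_scores_tsv <- function(path, kind = "generic") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  region_scores(df$score, df$label, kind)
}

raw_replicates <- function(cfg, inp, mark, day) {
  m <- inp$meta[inp$meta$mark == mark & inp$meta$day == day, , drop = FALSE]
  m <- m[order(m$rep), , drop = FALSE]
  tracks <- lapply(file.path(cfg$fixture_dir, m$file), read_bedgraph,
                   layout = inp$layout, units = "raw_count")
  names(tracks) <- paste0(mark, "_", day, "_rep", m$rep)
  list(tracks = tracks, total_reads = m$total_reads)
}

stage_normalize <- function(cfg, inp) {
  dir.create(file.path(cfg$out_dir, "merged"), recursive = TRUE,
             showWarnings = FALSE)
  for (mark in unique(inp$meta$mark)) for (day in unique(inp$meta$day)) {
    rr <- raw_replicates(cfg, inp, mark, day)
    if (length(rr$tracks) == 0) next
    norm <- lapply(seq_along(rr$tracks), function(i)
      rpkm_normalize(rr$tracks[[i]], rr$total_reads[i],
                     read_bin = inp$read_bin))
    merged <- if (length(norm) > 1)
      merge_replicates(norm, method = cfg$merge_method) else norm[[1]]
    write_bedgraph(merged, merged_path(cfg, mark, day))
  }
}

stage_score <- function(cfg, inp) {
  dir.create(file.path(cfg$out_dir, "scores"), recursive = TRUE,
             showWarnings = FALSE)
  prom <- promoters_of(inp$genes, flank = cfg$promoter_flank,
                       layout = inp$layout)
  body <- bodies_of(inp$genes, layout = inp$layout)
  exons <- merged_exons_of(inp$genes, layout = inp$layout)
  for (mark in unique(inp$meta$mark)) for (day in unique(inp$meta$day)) {
    mp <- merged_path(cfg, mark, day)
    if (!file.exists(mp)) next
    tr <- read_bedgraph(mp, inp$layout, units = "rpkm")
    write_scores_tsv(score_regions(tr, prom),
                     score_path(cfg, mark, day, "promoter"))
    write_scores_tsv(score_regions(tr, body),
                     score_path(cfg, mark, day, "body"))
    if (mark == "rna")
      write_scores_tsv(score_regions(tr, exons),
                       score_path(cfg, mark, day, "exons"))
  }
}

stage_peaks <- function(cfg, inp) {
  dir.create(file.path(cfg$out_dir, "peaks"), recursive = TRUE,
             showWarnings = FALSE)
  called <- list()
  for (mark in names(cfg$peak_cutoffs)) for (day in unique(inp$meta$day)) {
    mp <- merged_path(cfg, mark, day)
    if (!file.exists(mp)) next
    tr <- read_bedgraph(mp, inp$layout, units = "rpkm")
    pk <- call_peaks_threshold(tr, cfg$peak_cutoffs[[mark]],
                               min_length = cfg$peak_min_length,
                               max_gap = cfg$peak_max_gap,
                               prefix = paste0(mark, "_", day))
    called[[paste0(mark, "_", day)]] <- pk
    write_peaks_bed(pk, file.path(cfg$out_dir, "peaks",
                                  paste0(mark, "_", day, ".bed")))
    cats <- annotate_peaks(pk, inp$genes)
    if (length(cats))
      write_enrichment_tsv(
        annotation_enrichment(cats, inp$layout, inp$genes),
        file.path(cfg$out_dir, "peaks",
                  paste0(mark, "_", day, "_enrichment.tsv")))
  }
  venn <- if (!is.null(called$me1_day7) && !is.null(called$me3_day7))
    venn_overlap(peaks_as_regions(called$me1_day7),
                 peaks_as_regions(called$me3_day7))
  else NULL
  out <- list(peak_counts = lapply(called, nrow),
              venn_me1_me3_day7 = if (is.null(venn)) NULL else
                list(only_me1 = venn$only_a, only_me3 = venn$only_b,
                     both_me1 = venn$both_a, both_me3 = venn$both_b))
  jsonlite::write_json(out, file.path(cfg$out_dir, "peaks", "peaks.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

stage_pausing <- function(cfg, inp) {
  dir.create(file.path(cfg$out_dir, "pausing"), recursive = TRUE,
             showWarnings = FALSE)
  ser5_prom <- read_scores_tsv(score_path(cfg, "ser5", "day7", "promoter"),
                               "promoter")
  ser5_body <- read_scores_tsv(score_path(cfg, "ser5", "day7", "body"),
                               "body")
  rna <- read_scores_tsv(score_path(cfg, "rna", "day7", "exons"),
                         "merged_exons")
  rec <- pausing_index(ser5_prom, ser5_body, pi_threshold = cfg$pi_threshold)
  write_pausing_tsv(rec, file.path(cfg$out_dir, "pausing", "pausing.tsv"))
  split <- split_by_pi(rec, rna, expr_threshold = cfg$expr_high,
                       pi_threshold = cfg$pi_threshold)
  jsonlite::write_json(
    list(n_expressed = length(split$expressed),
         n_paused_gt4 = length(split$paused_gt4),
         n_nonpaused_lt4 = length(split$nonpaused_lt4),
         paused_gt4 = sort(split$paused_gt4)),
    file.path(cfg$out_dir, "pausing", "pi_split.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  # mark levels at promoters/bodies across the PI classes (Welch comparisons)
  groups <- list(paused_gt4 = split$paused_gt4,
                 nonpaused_lt4 = split$nonpaused_lt4)
  rows <- list()
  for (mark in c("me1", "me3")) for (kind in c("promoter", "body")) {
    sp <- score_path(cfg, mark, "day7", kind)
    if (!file.exists(sp)) next
    cmp <- compare_groups(read_scores_tsv(sp, kind), groups)
    if (nrow(cmp$tests)) {
      cmp$tests$mark <- mark; cmp$tests$region <- kind
      rows[[paste(mark, kind)]] <- cmp$tests
    }
  }
  tests <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  if (!is.null(tests)) {
    for (col in c("t_statistic", "df", "p_value"))
      tests[[col]] <- format_signal(tests[[col]])
    utils::write.table(tests,
                       file.path(cfg$out_dir, "pausing",
                                 "pi_group_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

stage_deciles <- function(cfg, inp) {
  dir.create(file.path(cfg$out_dir, "deciles"), recursive = TRUE,
             showWarnings = FALSE)
  me1_body <- read_scores_tsv(score_path(cfg, "me1", "day7", "body"), "body")
  rna <- read_scores_tsv(score_path(cfg, "rna", "day7", "exons"),
                         "merged_exons")
  for (nm in c("me1_body", "rna")) {
    sc <- if (nm == "me1_body") me1_body else rna
    dec <- assign_deciles(sc)
    utils::write.table(
      data.frame(label = names(dec), decile = as.integer(dec)),
      file.path(cfg$out_dir, "deciles", paste0(nm, "_deciles.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sets <- list()
  for (mark in unique(inp$meta$mark)) {
    kind <- if (mark == "rna") "exons" else
      if (mark %in% c("atac", "me3")) "promoter" else "body"
    sp <- score_path(cfg, mark, "day7", kind)
    if (file.exists(sp))
      sets[[paste0(mark, "_", kind)]] <- read_scores_tsv(sp)
  }
  if (length(sets) >= 2) {
    m <- pearson_correlation_matrix(sets, positive_filter = TRUE)
    utils::write.table(
      cbind(data.frame(set = rownames(m)),
            as.data.frame(apply(m, 2, format_signal))),
      file.path(cfg$out_dir, "deciles", "correlations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

run_differential <- function(cfg, inp, mark, regions, rna_gate) {
  rr7 <- raw_replicates(cfg, inp, mark, "day7")
  rr10 <- raw_replicates(cfg, inp, mark, "day10")
  tracks <- c(rr7$tracks, rr10$tracks)
  condition <- factor(rep(c("day7", "day10"),
                          c(length(rr7$tracks), length(rr10$tracks))),
                      levels = c("day7", "day10"))
  counts <- count_features(tracks, regions)
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, condition)
  res <- nb_wald_test(counts, sf, disp, condition)
  classify_differential(res, lfc_threshold = cfg$lfc_threshold,
                        alpha = cfg$alpha, rna_day7 = rna_gate,
                        min_expression = cfg$expr_min)
}

stage_differential <- function(cfg, inp) {
  dir.create(file.path(cfg$out_dir, "differential"), recursive = TRUE,
             showWarnings = FALSE)
  rna <- read_scores_tsv(score_path(cfg, "rna", "day7", "exons"),
                         "merged_exons")
  body <- bodies_of(inp$genes, layout = inp$layout)
  prom <- promoters_of(inp$genes, flank = cfg$promoter_flank,
                       layout = inp$layout)
  for (job in list(list(mark = "me1", regions = body, tag = "me1_body"),
                    list(mark = "me3", regions = prom,
                         tag = "me3_promoter"))) {
    res <- run_differential(cfg, inp, job$mark, job$regions, rna)
    write_differential_tsv(res, file.path(cfg$out_dir, "differential",
                                          paste0(job$tag, ".tsv")))
    for (dir_call in c("increased", "decreased")) {
      sel <- res$feature[res$call == dir_call]
      rs <- job$regions[job$regions$group %in% sel, , drop = FALSE]
      if (nrow(rs))
        write_bed(rs, file.path(cfg$out_dir, "differential",
                                paste0(job$tag, "_", dir_call, ".bed")))
    }
  }
}

read_differential_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("differential_result", "data.frame")
  df
}

stage_fatemap <- function(cfg, inp) {
  dir.create(file.path(cfg$out_dir, "fatemap"), recursive = TRUE,
             showWarnings = FALSE)
  me1 <- read_differential_tsv(file.path(cfg$out_dir, "differential",
                                         "me1_body.tsv"))
  me3 <- read_differential_tsv(file.path(cfg$out_dir, "differential",
                                         "me3_promoter.tsv"))
  fm <- fate_map(me1, me3)
  write_fatemap_tsv(fm, file.path(cfg$out_dir, "fatemap", "fatemap.tsv"))
  pct1 <- percent_by_direction(me1)
  pct3 <- percent_by_direction(me3)
  rna7 <- read_scores_tsv(score_path(cfg, "rna", "day7", "exons"),
                          "merged_exons")
  rna10 <- read_scores_tsv(score_path(cfg, "rna", "day10", "exons"),
                           "merged_exons")
  shared <- intersect(names(rna7), names(rna10))
  rna_lfc <- log2((as.numeric(rna10[shared]) + 0.1) /
                    (as.numeric(rna7[shared]) + 0.1))
  names(rna_lfc) <- shared
  lq <- l2fc_quantiles(rna_lfc, rna7, min_expr = cfg$expr_floor, k = 5)
  utils::write.table(
    data.frame(label = names(lq), quantile_group = as.integer(lq),
               rna_log2fc = format_signal(rna_lfc[names(lq)])),
    file.path(cfg$out_dir, "fatemap", "rna_l2fc_quantiles.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(counts = as.list(fm$counts),
         me1_loss_me3_gain = fm$me1_loss_me3_gain,
         me3_loss_me1_gain = fm$me3_loss_me1_gain,
         me1_percent = as.list(pct1), me3_percent = as.list(pct3)),
    file.path(cfg$out_dir, "fatemap", "fatemap.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

stage_report <- function(cfg, inp) {
  read_json_if <- function(p) if (file.exists(p)) jsonlite::read_json(p)
  cfg_echo <- unclass(cfg)
  cfg_echo$fixture_dir <- cfg_echo$out_dir <- NULL
  summary <- list(
    config = cfg_echo,
    config_hash = config_hash(cfg),
    n_genes = nrow(inp$genes),
    peaks = read_json_if(file.path(cfg$out_dir, "peaks", "peaks.json")),
    pausing = read_json_if(file.path(cfg$out_dir, "pausing",
                                     "pi_split.json")),
    fatemap = read_json_if(file.path(cfg$out_dir, "fatemap",
                                     "fatemap.json")))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$out_dir <- x$fixture_dir <- NULL
  # position-stable serialisation of the remaining fields
  s <- paste(names(x), vapply(x, function(v)
    paste(format(v, digits = 15), collapse = ","), ""), collapse = ";")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 997)) %% 1e9
}

#' Run one pipeline stage
#'
#' Stages communicate through files under the output directory, so a chain
#' of single-stage runs is identical to [run_full_analysis()].
#'
#' @param cfg A [run_config()].
#' @param stage One of `"normalize"`, `"score"`, `"peaks"`, `"pausing"`,
#'   `"deciles"`, `"differential"`, `"fatemap"`, `"report"`.
#' @return Invisibly, the stage name.
#' @export
run_stage <- function(cfg, stage) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- match.arg(stage, pipeline_stages)
  inp <- load_inputs(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  fn <- switch(stage, normalize = stage_normalize, score = stage_score,
               peaks = stage_peaks, pausing = stage_pausing,
               deciles = stage_deciles, differential = stage_differential,
               fatemap = stage_fatemap, report = stage_report)
  tryCatch(fn(cfg, inp), error = function(e) {
    file.create(file.path(cfg$out_dir, paste0("FAILED_", stage)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(stage)
}

#' Run the full two-timepoint analysis
#'
#' Executes, in order: replicate normalisation and merging; region scoring
#' over promoters, gene bodies and merged exons; threshold peak calling
#' with annotation enrichment and the me1/me3 overlap Venn; the
#' pausing-index split with Welch group comparisons; deciles and
#' correlation matrices; NB differential occupancy over gene bodies
#' (H4K20me1) and promoters (H4K20me3); the methylation fate map with
#' percent-by-direction summaries and RNA L2FC quantiles; and a summary
#' report. Also writes `run.log` with per-stage timings (the log is the
#' only non-deterministic output).
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the path to `summary.json`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_out <- unclass(cfg)
  yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "config_used.yaml"))
  log <- file.path(cfg$out_dir, "run.log")
  cat("run started ", format(Sys.time()), "\n", file = log, sep = "")
  for (stage in pipeline_stages) {
    t0 <- proc.time()[["elapsed"]]
    run_stage(cfg, stage)
    cat(sprintf("stage %-12s %.2fs\n", stage,
                proc.time()[["elapsed"]] - t0),
        file = log, append = TRUE)
  }
  cat("config hash ", config_hash(cfg), "\n", file = log, append = TRUE,
      sep = "")
  invisible(file.path(cfg$out_dir, "summary.json"))
}
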