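# File-in/file-out pipeline drivers. Each mirrors one analysis entry
# point (simulate / classify / shift / coexpress / retention): read the
# package's TSV formats, run the corresponding operations, write TSV/JSON
# results. All randomness is controlled by explicit seeds, so a rerun
# with identical inputs is byte-identical.

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Pipeline: simulate a replicate-level expression study
#'
#' Writes `expression.tsv`, `meta.tsv`, `map.tsv`, `lengths.tsv`,
#' `truth.json` to `out_dir`.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
run_simulate <- function(config, out_dir) {
  save_simulation(simulate_expression(config), out_dir)
}

#' Pipeline: triad bias classification
#'
#' Reads a replicate-level count or TPM table, converts counts to TPM if
#' gene lengths are given, filters expressed genes, averages replicates
#' and classifies every triad per tissue. Writes `triads.tsv` (per-triad
#' ternary coordinates, category, distance), `percent.tsv` (per-tissue
#' category percentages) and `abundance.tsv` (relative subgenome
#' abundance) to `out_dir`.
#'
#' @param expr_path,meta_path expression and metadata TSVs
#'   (see [read_expression()]).
#' @param map_path homoeolog map TSV (see [read_homoeolog_map()]).
#' @param lengths_path gene-length TSV (`gene_id`, `length_bp`); required
#'   when the expression unit is counts.
#' @param tissues tissues to classify (default: all).
#' @param min_tpm,min_samples expressed-gene filter, see
#'   [filter_expressed()].
#' @param expressed_min_sum triad expression threshold.
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
run_classify <- function(expr_path, meta_path, map_path,
                         lengths_path = NULL, tissues = NULL,
                         min_tpm = 1, min_samples = 2,
                         expressed_min_sum = 0.5, out_dir) {
  m <- read_expression(expr_path, meta_path)
  if (m$unit == "counts") {
    if (is.null(lengths_path))
      stop_fmt("expression is in counts; lengths_path is required")
    len <- utils::read.delim(lengths_path, comment.char = "#")
    m <- counts_to_tpm(m, stats::setNames(len$length_bp, len$gene_id))
  }
  m <- filter_expressed(m, min_tpm = min_tpm, min_samples = min_samples)
  map <- read_homoeolog_map(map_path, ratio_class = "triad")
  avg <- average_replicates(m)
  res <- categorize_species(avg, map, tissues = tissues,
                            expressed_min_sum = expressed_min_sum)
  ab <- relative_subgenome_abundance(m, map)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("triads.tsv", "percent.tsv", "abundance.tsv"))
  write_tsv(res$triads, paths[1])
  write_tsv(data.frame(tissue = rownames(res$percent), res$percent,
                       check.names = FALSE), paths[2])
  write_tsv(data.frame(subgenome = names(ab), percent = as.numeric(ab)),
            paths[3])
  invisible(paths)
}

#' Pipeline: expression-shift clustering
#'
#' Builds homoeolog tissue profiles, clusters them into `k` groups,
#' computes the shifted fraction and (optionally) the ploidy-matched
#' subsampling distribution. Writes `assignments.tsv` and
#' `shift_summary.json` to `out_dir`.
#'
#' @inheritParams run_classify
#' @param k number of expression-pattern groups (default 10).
#' @param n_target,n_reps subsampling design; `n_target = NULL` skips
#'   subsampling.
#' @param seed integer seed for the subsampling.
#' @param ratio_class of the map.
#' @return invisibly, the written paths.
#' @export
run_shift <- function(expr_path, meta_path, map_path, lengths_path = NULL,
                      tissues = NULL, k = 10, n_target = NULL,
                      n_reps = 100, seed = 1, ratio_class = "triad",
                      min_tpm = 1, min_samples = 2, out_dir) {
  m <- read_expression(expr_path, meta_path)
  if (m$unit == "counts") {
    if (is.null(lengths_path))
      stop_fmt("expression is in counts; lengths_path is required")
    len <- utils::read.delim(lengths_path, comment.char = "#")
    m <- counts_to_tpm(m, stats::setNames(len$length_bp, len$gene_id))
  }
  m <- filter_expressed(m, min_tpm = min_tpm, min_samples = min_samples)
  map <- read_homoeolog_map(map_path, ratio_class = ratio_class)
  pr <- build_profiles(average_replicates(m), map, tissues = tissues)
  cl <- cluster_profiles(pr$profiles, k = k)
  sf <- shifted_fraction(cl, pr$key)
  summary <- list(k = k, n_groups = sf$n_groups,
                  shifted_fraction = sf$fraction)
  if (!is.null(n_target)) {
    ss <- subsample_comparison(pr$profiles, pr$key, n_target = n_target,
                               n_reps = n_reps, k = k, seed = seed)
    summary$subsample <- list(n_target = n_target, n_reps = n_reps,
                              seed = seed, mean = ss$mean,
                              ci_2.5 = unname(ss$ci[1]),
                              ci_97.5 = unname(ss$ci[2]),
                              fractions = ss$fractions)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("assignments.tsv", "shift_summary.json"))
  write_tsv(cbind(pr$key, cluster = unname(cl[pr$key$gene_id]),
                  shifted = sf$per_group$shifted[
                    match(pr$key$group_id, sf$per_group$group_id)]),
            paths[1])
  write_json_out(summary, paths[2])
  invisible(paths)
}

#' Pipeline: lightweight co-expression network
#'
#' Runs [build_network()] on a log2(TPM+1) matrix and writes
#' `modules.tsv` (gene, module, KME, hub), `hubs_by_subgenome.tsv`,
#' `neighbor_composition.tsv`, `composition_summary.tsv` and
#' `power.json` (chosen power and fit table) to `out_dir`.
#'
#' @inheritParams run_classify
#' @param labels_path TSV mapping `gene_id` to `subgenome`.
#' @param power soft power; `NULL` scans.
#' @param kme_threshold,k_neighbors,min_size,merge_height see
#'   [build_network()].
#' @return invisibly, the written paths.
#' @export
run_coexpress <- function(expr_path, meta_path, labels_path,
                          lengths_path = NULL, power = NULL,
                          kme_threshold = 0.9, k_neighbors = 100,
                          min_size = 30, merge_height = 0.15,
                          min_tpm = 1, min_samples = 2, out_dir) {
  m <- read_expression(expr_path, meta_path)
  if (m$unit == "counts") {
    if (is.null(lengths_path))
      stop_fmt("expression is in counts; lengths_path is required")
    len <- utils::read.delim(lengths_path, comment.char = "#")
    m <- counts_to_tpm(m, stats::setNames(len$length_bp, len$gene_id))
  }
  if (m$unit == "TPM") m <- log_transform(filter_expressed(
    m, min_tpm = min_tpm, min_samples = min_samples))
  lab <- utils::read.delim(labels_path, comment.char = "#")
  subgenomes <- stats::setNames(lab$subgenome, lab$gene_id)
  net <- build_network(m, subgenomes, power = power,
                       kme_threshold = kme_threshold,
                       k_neighbors = k_neighbors, min_size = min_size,
                       merge_height = merge_height)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("modules.tsv", "hubs_by_subgenome.tsv",
                                "neighbor_composition.tsv",
                                "composition_summary.tsv", "power.json"))
  write_tsv(net$kme, paths[1])
  write_tsv(hub_subgenome_counts(net$kme, subgenomes), paths[2])
  write_tsv(net$neighbor_composition, paths[3])
  write_tsv(neighbor_composition_summary(net$neighbor_composition), paths[4])
  pj <- list(power = net$power)
  if (!is.null(net$fit_table)) pj$fit_table <- net$fit_table
  write_json_out(pj, paths[5])
  invisible(paths)
}

#' Pipeline: fractionation-bias retention windows
#'
#' Reads a retention track, computes sliding-window retention per
#' subgenome, compares subgenomes by Wilcoxon rank-sum test and censuses
#' group copy-count ratios. Writes `windows.tsv`, `comparison.json` and
#' `ratio_census.tsv` to `out_dir`. Window coordinates are 0-based,
#' half-open.
#'
#' @param track_path retention TSV (see [read_retention_track()]).
#' @param window,step see [windowed_retention()].
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
run_retention <- function(track_path, window = 100, step = 10, out_dir) {
  track <- read_retention_track(track_path)
  w <- windowed_retention(track, window = window, step = step)
  cmp <- compare_retention(w)
  census <- group_ratio_census(track_to_copy_counts(track))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("windows.tsv", "comparison.json",
                                "ratio_census.tsv"))
  write_tsv(w, paths[1])
  write_json_out(list(window = window, step = step, comparisons = cmp),
                 paths[2])
  write_tsv(census, paths[3])
  invisible(paths)
}
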