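#' Pair homoeolog log-ratio
#'
#' `log2((TPM_x + pseudocount) / (TPM_y + pseudocount))` for an ordered
#' label pair, vectorized over tissues/groups.
#'
#' @param tpm_x,tpm_y nonnegative TPM values of the two homoeologs.
#' @param pseudocount added to numerator and denominator (default 0.01).
#' @return numeric log2 ratio(s).
#' @export
pair_log_ratio <- function(tpm_x, tpm_y, pseudocount = 0.01) {
  if (any(tpm_x < 0) || any(tpm_y < 0)) stop_fmt("TPM values must be nonnegative")
  log2((tpm_x + pseudocount) / (tpm_y + pseudocount))
}

#' Pair log-ratio table over a homoeolog map
#'
#' Computes the ordered-pair log ratio for every group of a pair map in
#' every sample/tissue column of a TPM matrix. Groups with a member absent
#' from the matrix are skipped with a message.
#'
#' @param m an [expression_matrix()] with unit `"TPM"` (typically
#'   replicate-averaged).
#' @param map a pair [homoeolog_map()].
#' @param numerator,denominator subgenome labels forming the ordered pair.
#' @param pseudocount see [pair_log_ratio()].
#' @return data.frame `group_id` plus one log-ratio column per sample.
#' @export
pair_log_ratio_table <- function(m, map, numerator, denominator,
                                 pseudocount = 0.01) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(map, "HomoeologMap"))
  wide <- map_wide(map)
  if (!all(c(numerator, denominator) %in% colnames(wide)))
    stop_fmt("labels %s/%s not both present in map", numerator, denominator)
  keep <- wide[, numerator] %in% rownames(m$values) &
    wide[, denominator] %in% rownames(m$values)
  if (any(!keep))
    message(sum(!keep), " group(s) skipped: member gene(s) not in matrix")
  wide <- wide[keep, , drop = FALSE]
  lr <- pair_log_ratio(m$values[wide[, numerator], , drop = FALSE],
                       m$values[wide[, denominator], , drop = FALSE],
                       pseudocount)
  data.frame(group_id = rownames(wide), lr, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Triad relative expression
#'
#' Standardizes each triad's homoeolog TPMs to fractions of the triad sum.
#' A triad is expressed in a tissue only when the sum of its three
#' homoeolog TPMs exceeds `expressed_min_sum`; non-expressed triads get NA
#' fractions and are excluded from classification.
#'
#' @param tpm numeric vector of 3 TPMs, or a triads x 3 matrix.
#' @param expressed_min_sum exclusive lower bound on the triad TPM sum
#'   (default 0.5).
#' @return list with `rel` (fractions summing to 1 per expressed triad,
#'   NA otherwise) and `expressed` (logical).
#' @export
triad_relative_expression <- function(tpm, expressed_min_sum = 0.5) {
  v <- if (is.matrix(tpm)) tpm else matrix(tpm, nrow = 1)
  if (any(v < 0, na.rm = TRUE)) stop_fmt("TPM values must be nonnegative")
  s <- rowSums(v)
  expressed <- !is.na(s) & s > expressed_min_sum
  rel <- v / s
  rel[!expressed, ] <- NA_real_
  list(rel = if (is.matrix(tpm)) rel else drop(rel), expressed = expressed)
}

#' Hexaploid log deviation from equal thirds
#'
#' Per subgenome `i`: `log2(((TPM_i + pc) / (sum(TPM) + pc)) / expectation)`,
#' the log fold deviation of a homoeolog's share of the triad from the
#' equal-thirds expectation (0.33 by convention).
#'
#' @param tpm numeric vector of 3 TPMs, or a triads x 3 matrix.
#' @param pseudocount added to numerator and to the triad sum (default 0.01).
#' @param expectation reference share (default 0.33).
#' @return deviations, same shape as `tpm`.
#' @export
hexaploid_log_deviation <- function(tpm, pseudocount = 0.01,
                                    expectation = 0.33) {
  v <- if (is.matrix(tpm)) tpm else matrix(tpm, nrow = 1)
  if (any(v < 0, na.rm = TRUE)) stop_fmt("TPM values must be nonnegative")
  out <- log2(((v + pseudocount) / (rowSums(v) + pseudocount)) / expectation)
  if (is.matrix(tpm)) out else drop(out)
}

#' Ideal category points on the relative-expression simplex
#'
#' The wheat-style scheme: balanced = equal shares; `X_dominant` = all
#' expression on X; `X_suppressed` = X silent, the rest equal. With three
#' subgenomes this gives 7 points (or 6 biased points when
#' `include_balanced = FALSE`).
#'
#' @param labels subgenome labels (sorted internally).
#' @param include_balanced include the balanced point (default TRUE).
#' @return matrix categories x labels; rows sum to 1 and are ordered
#'   balanced, dominants, suppresseds (the tie-break order).
#' @export
ideal_points <- function(labels, include_balanced = TRUE) {
  labels <- sort(labels)
  k <- length(labels)
  rows <- list()
  if (include_balanced) rows$balanced <- rep(1 / k, k)
  for (l in labels) rows[[paste0(l, "_dominant")]] <- as.numeric(labels == l)
  for (l in labels)
    rows[[paste0(l, "_suppressed")]] <-
      ifelse(labels == l, 0, 1 / (k - 1))
  out <- do.call(rbind, rows)
  colnames(out) <- labels
  out
}

#' Classify triads by nearest ideal point
#'
#' Euclidean distance from each relative-expression vector to every ideal
#' point; the shortest distance assigns the category. Distances equal
#' within 1e-12 of the minimum are ties, resolved by the fixed row order
#' of [ideal_points()] (balanced first, then dominants, then suppresseds)
#' and flagged.
#'
#' @param rel numeric vector summing to 1, or a triads x labels matrix.
#' @param ideal matrix from [ideal_points()] (default: 7-point scheme over
#'   the column names of `rel`, or A/B/C for an unnamed vector).
#' @return data.frame `category`, `distance`, `tie`.
#' @export
classify_triad <- function(rel, ideal = NULL) {
  v <- if (is.matrix(rel)) rel else matrix(rel, nrow = 1,
                                           dimnames = list(NULL, names(rel)))
  if (is.null(ideal)) {
    labs <- colnames(v) %||% c("A", "B", "C")[seq_len(ncol(v))]
    if (is.null(colnames(v))) colnames(v) <- labs
    ideal <- ideal_points(labs)
  }
  if (!is.null(colnames(v))) v <- v[, colnames(ideal), drop = FALSE]
  bad <- abs(rowSums(v) - 1) > 1e-6
  if (any(bad, na.rm = TRUE))
    stop_fmt("relative vector %d sums to %.8f, not 1", which(bad)[1],
             rowSums(v)[which(bad)[1]])
  # squared distances to each ideal point: ||v||^2 - 2 v.p + ||p||^2
  cross <- v %*% t(ideal)
  d2 <- outer(rowSums(v^2), rowSums(ideal^2), "+") - 2 * cross
  d2[d2 < 0] <- 0
  dmin <- apply(d2, 1, min)
  tol <- 1e-12
  near <- sqrt(d2) <= sqrt(dmin) + tol   # candidates within tie tolerance
  best <- apply(near, 1, which.max)      # first candidate wins: fixed tie order
  tie <- rowSums(near) > 1
  data.frame(category = rownames(ideal)[best], distance = sqrt(dmin),
             tie = tie, row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify every triad of a species across tissues
#'
#' Runs [triad_relative_expression()] and [classify_triad()] per tissue on
#' a replicate-averaged TPM matrix, and tabulates category percentages
#' over expressed triads per tissue plus an `all_tissues` aggregate (mean
#' of per-tissue percentages).
#'
#' @param m an [expression_matrix()] with unit `"TPM"`, one column per
#'   tissue (see [average_replicates()]).
#' @param map a triad [homoeolog_map()].
#' @param tissues tissue columns to use (default: all columns of `m`).
#' @param expressed_min_sum see [triad_relative_expression()].
#' @param include_balanced see [ideal_points()].
#' @return list with `triads` (per-triad per-tissue data.frame: group_id,
#'   tissue, one `rel_<label>` column per subgenome, expressed, category,
#'   distance, tie) and `percent` (tissues x categories percentage matrix;
#'   rows sum to 100; a tissue with no expressed triads is all NA).
#' @export
categorize_species <- function(m, map, tissues = NULL,
                               expressed_min_sum = 0.5,
                               include_balanced = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(map, "HomoeologMap"))
  if (attr(map, "ratio_class") != "triad")
    stop_fmt("categorize_species needs a triad map")
  if (m$unit != "TPM") stop_fmt("categorize_species needs unit 'TPM'")
  tissues <- tissues %||% colnames(m$values)
  miss <- setdiff(tissues, colnames(m$values))
  if (length(miss)) stop_fmt("tissue(s) not in matrix: %s",
                             paste(miss, collapse = ", "))
  wide <- map_wide(map)
  keep <- rowSums(matrix(wide %in% rownames(m$values), nrow(wide))) ==
    ncol(wide)
  wide <- wide[keep, , drop = FALSE]
  labs <- colnames(wide)
  ideal <- ideal_points(labs, include_balanced)
  res <- list()
  for (tt in tissues) {
    tpm <- matrix(m$values[as.vector(wide), tt], nrow(wide), ncol(wide),
                  dimnames = dimnames(wide))
    rr <- triad_relative_expression(tpm, expressed_min_sum)
    cls <- data.frame(category = NA_character_, distance = NA_real_,
                      tie = NA, stringsAsFactors = FALSE)[rep(1, nrow(wide)), ]
    if (any(rr$expressed))
      cls[rr$expressed, ] <- classify_triad(
        rr$rel[rr$expressed, , drop = FALSE], ideal)
    rel_df <- as.data.frame(rr$rel)
    names(rel_df) <- paste0("rel_", labs)
    res[[tt]] <- cbind(data.frame(group_id = rownames(wide), tissue = tt,
                                  stringsAsFactors = FALSE),
                       rel_df,
                       data.frame(expressed = rr$expressed, cls,
                                  stringsAsFactors = FALSE))
  }
  triads <- do.call(rbind, res)
  rownames(triads) <- NULL
  cats <- rownames(ideal)
  percent <- matrix(NA_real_, length(tissues), length(cats),
                    dimnames = list(tissues, cats))
  for (tt in tissues) {
    sub <- triads[triads$tissue == tt & triads$expressed, ]
    if (nrow(sub) == 0) next                     # flagged undefined (NA row)
    percent[tt, ] <- 100 * as.vector(table(factor(sub$category, cats))) /
      nrow(sub)
  }
  if (all(!is.na(percent))) {
    percent <- rbind(percent, all_tissues = colMeans(percent))
  } else {
    ok <- !apply(is.na(percent), 1, any)
    percent <- rbind(percent,
                     all_tissues = if (any(ok))
                       colMeans(percent[ok, , drop = FALSE])
                     else rep(NA_real_, ncol(percent)))
  }
  list(triads = triads, percent = percent)
}

#' Relative transcript abundance per subgenome
#'
#' Summed TPM of each subgenome's triad members divided by the total over
#' all triad members, as a percentage (sums to 100).
#'
#' @param m an [expression_matrix()] with unit `"TPM"`.
#' @param map a [homoeolog_map()].
#' @return named percentage vector over subgenomes.
#' @export
relative_subgenome_abundance <- function(m, map) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(map, "HomoeologMap"))
  if (m$unit != "TPM") stop_fmt("relative_subgenome_abundance needs unit 'TPM'")
  if (nrow(map) == 0) stop_fmt("empty homoeolog map")
  present <- map[map$gene_id %in% rownames(m$values), ]
  tot <- vapply(split(present$gene_id, present$subgenome),
                function(g) sum(m$values[g, , drop = FALSE]), numeric(1))
  100 * tot / sum(tot)
}

#' Count up-regulated homoeologs per ordered subgenome pair
#'
#' For each homoeolog pair within each group (all three unordered pairs of
#' a triad), a two-sided Welch t-test on the log2(TPM+1) replicate values
#' of one tissue, Benjamini-Hochberg adjusted across all groups tested for
#' that tissue and label pair. A homoeolog counts as up-regulated over its
#' partner when the adjusted p-value is below `alpha` and the absolute
#' log2 fold change of replicate-mean TPMs (with `pseudocount`) is at
#' least `min_abs_log2fc`.
#'
#' @param m replicate-level [expression_matrix()] with unit `"TPM"`.
#' @param map a [homoeolog_map()].
#' @param tissue tissue to test; needs >= 2 replicates.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param min_abs_log2fc fold-change threshold (default 1).
#' @param pseudocount used in the fold change of means (default 0.01).
#' @param test_fun function(x, y) returning a p-value; defaults to the
#'   two-sided Welch t-test on log2(TPM+1) values.
#' @return list with `counts` (data.frame `up`, `over`, `n_up`: number of
#'   groups where subgenome `up` is up-regulated over subgenome `over`)
#'   and `detail` (per group x pair test results).
#' @export
upregulated_counts <- function(m, map, tissue, alpha = 0.05,
                               min_abs_log2fc = 1, pseudocount = 0.01,
                               test_fun = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(map, "HomoeologMap"))
  if (m$unit != "TPM") stop_fmt("upregulated_counts needs unit 'TPM'")
  cols <- which(m$meta$tissue == tissue)
  if (length(cols) < 2)
    stop_fmt(paste("tissue '%s' has %d replicate(s); need >= 2 for the",
                   "replicate test - use log-ratio summaries instead"),
             tissue, length(cols))
  if (is.null(test_fun))
    test_fun <- function(x, y) {
      if (stats::sd(c(x, y)) == 0) return(1)
      stats::t.test(log2(x + 1), log2(y + 1))$p.value
    }
  wide <- map_wide(map)
  keep <- rowSums(matrix(wide %in% rownames(m$values), nrow(wide))) ==
    ncol(wide)
  wide <- wide[keep, , drop = FALSE]
  labs <- colnames(wide)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  detail <- list()
  for (pr in pairs) {
    x <- m$values[wide[, pr[1]], cols, drop = FALSE]
    y <- m$values[wide[, pr[2]], cols, drop = FALSE]
    p <- vapply(seq_len(nrow(wide)),
                function(i) test_fun(x[i, ], y[i, ]), numeric(1))
    padj <- stats::p.adjust(p, method = "BH")
    lfc <- log2((rowMeans(x) + pseudocount) / (rowMeans(y) + pseudocount))
    detail[[paste(pr, collapse = "_vs_")]] <-
      data.frame(group_id = rownames(wide), sub_x = pr[1], sub_y = pr[2],
                 p = p, padj = padj, log2fc = lfc,
                 row.names = NULL, stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, detail)
  rownames(detail) <- NULL
  sig <- detail$padj < alpha & abs(detail$log2fc) >= min_abs_log2fc
  up_x <- sig & detail$log2fc > 0
  up_y <- sig & detail$log2fc < 0
  counts <- rbind(
    stats::aggregate(up_x, by = list(up = detail$sub_x, over = detail$sub_y),
                     FUN = sum),
    stats::aggregate(up_y, by = list(up = detail$sub_y, over = detail$sub_x),
                     FUN = sum))
  names(counts)[3] <- "n_up"
  counts <- counts[order(counts$up, counts$over), ]
  rownames(counts) <- NULL
  list(counts = counts, detail = detail)
}
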