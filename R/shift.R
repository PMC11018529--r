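#' Build per-homoeolog tissue profiles
#'
#' One log2(TPM+1) profile per homoeolog gene of every group whose members
#' are all present in the replicate-averaged matrix, over a fixed tissue
#' order. Profiles are ordered by (group, subgenome).
#'
#' @param m replicate-averaged [expression_matrix()] with unit `"TPM"`
#'   (one column per tissue).
#' @param map a [homoeolog_map()].
#' @param tissues tissue columns, in the order profiles should use
#'   (default: all columns of `m`).
#' @return list with `profiles` (genes x tissues matrix of log2(TPM+1))
#'   and `key` (data.frame `gene_id`, `group_id`, `subgenome`).
#' @export
build_profiles <- function(m, map, tissues = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(map, "HomoeologMap"))
  if (m$unit != "TPM") stop_fmt("build_profiles needs unit 'TPM'")
  tissues <- tissues %||% colnames(m$values)
  miss <- setdiff(tissues, colnames(m$values))
  if (length(miss)) stop_fmt("missing tissue(s): %s", paste(miss, collapse = ", "))
  in_mat <- map$gene_id %in% rownames(m$values)
  bad_groups <- unique(map$group_id[!in_mat])
  if (length(bad_groups))
    message(length(bad_groups), " group(s) skipped: member gene(s) not in matrix")
  key <- as.data.frame(map[!map$group_id %in% bad_groups, ])
  key <- key[order(key$group_id, key$subgenome),
             c("gene_id", "group_id", "subgenome")]
  rownames(key) <- NULL
  profiles <- log2(m$values[key$gene_id, tissues, drop = FALSE] + 1)
  list(profiles = profiles, key = key)
}

# correlation distance robust to constant profiles: identical rows get 0,
# a constant row gets distance 1 to every non-identical row
cor_dist <- function(x) {
  sds <- apply(x, 1, stats::sd)
  d <- matrix(1, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  ok <- sds > 0
  if (sum(ok) >= 2)
    d[ok, ok] <- 1 - stats::cor(t(x[ok, , drop = FALSE]))
  diag(d) <- 0
  if (any(!ok)) {                       # identical constant rows merge at 0
    same <- as.matrix(stats::dist(x)) == 0
    d[same] <- 0
  }
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Cluster homoeolog profiles into expression-pattern groups
#'
#' Average-linkage agglomerative clustering of profiles, cut to exactly
#' `k` groups. The default dissimilarity is 1 - Pearson correlation
#' between profiles (pattern clustering); `"euclidean"` on the log scale
#' is available as an alternative. Rows are sorted by id before
#' clustering, so the result is invariant to input order.
#'
#' @param profiles genes x tissues numeric matrix with unique rownames.
#' @param k number of groups (default 10; >= 2).
#' @param method `"correlation"` (default) or `"euclidean"`.
#' @return named integer vector gene -> group in 1..k, in the input row
#'   order.
#' @export
cluster_profiles <- function(profiles, k = 10,
                             method = c("correlation", "euclidean")) {
  method <- match.arg(method)
  if (k < 2) stop_fmt("k must be >= 2")
  if (nrow(profiles) < k)
    stop_fmt("need >= k profiles (%d < %d)", nrow(profiles), k)
  ord <- order(rownames(profiles))
  x <- profiles[ord, , drop = FALSE]
  d <- if (method == "correlation") cor_dist(x) else stats::dist(x)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = k)
  cl[rownames(profiles)]
}

#' Shifted fraction of homoeolog groups
#'
#' A pair/triad is shifted when its members do not all fall in the same
#' expression-pattern group.
#'
#' @param assignments named vector gene -> cluster (from
#'   [cluster_profiles()]).
#' @param key data.frame `gene_id`, `group_id` (from [build_profiles()]).
#' @return list with `per_group` (data.frame `group_id`, `shifted`),
#'   `fraction` (shifted groups / groups) and `n_groups`.
#' @export
shifted_fraction <- function(assignments, key) {
  miss <- setdiff(key$gene_id, names(assignments))
  if (length(miss)) stop_fmt("unassigned gene(s): %s",
                             paste(utils::head(miss, 5), collapse = ", "))
  cl <- split(assignments[key$gene_id], key$group_id)
  shifted <- vapply(cl, function(v) length(unique(v)) > 1, logical(1))
  list(per_group = data.frame(group_id = names(shifted), shifted = shifted,
                              row.names = NULL, stringsAsFactors = FALSE),
       fraction = mean(shifted), n_groups = length(shifted))
}

#' Ploidy-matched subsampling of the shifted fraction
#'
#' Repeatedly samples `n_target` groups without replacement, reclusters
#' their profiles with [cluster_profiles()] and records the shifted
#' fraction; used to compare pair cohorts against a smaller triad cohort
#' on equal footing.
#'
#' @param profiles,key as produced by [build_profiles()].
#' @param n_target number of groups per draw; at most the available count.
#' @param n_reps number of draws.
#' @param k clusters per draw (default 10).
#' @param method dissimilarity, see [cluster_profiles()].
#' @param seed integer seed.
#' @return list with `fractions` (length `n_reps`), `mean` and `ci`
#'   (2.5/97.5 percentiles).
#' @export
subsample_comparison <- function(profiles, key, n_target, n_reps = 100,
                                 k = 10, method = "correlation", seed = 1) {
  groups <- unique(key$group_id)
  if (n_target > length(groups))
    stop_fmt("n_target = %d exceeds available groups (%d)", n_target,
             length(groups))
  with_seed(seed, {
    fr <- vapply(seq_len(n_reps), function(i) {
      g <- sample(groups, n_target)
      kk <- key[key$group_id %in% g, ]
      cl <- cluster_profiles(profiles[kk$gene_id, , drop = FALSE], k = k,
                             method = method)
      shifted_fraction(cl, kk)$fraction
    }, numeric(1))
    list(fractions = fr, mean = mean(fr),
         ci = stats::quantile(fr, c(0.025, 0.975)))
  })
}
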