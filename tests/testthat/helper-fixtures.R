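# Shared fixtures, built in code.

# tiny expression matrix: genes x samples with tissue/replicate metadata
tiny_matrix <- function(values, unit = "TPM", tissues = NULL) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(tissues)) tissues <- colnames(values)
  meta <- data.frame(sample_id = colnames(values), species = "sp",
                     tissue = tissues,
                     replicate = stats::ave(seq_along(tissues), tissues,
                                            FUN = seq_along))
  expression_matrix(values, meta, unit = unit)
}

# one-triad map over labels A/B/C
triad_map <- function(n = 1, labels = c("A", "B", "C")) {
  groups <- sprintf("t%03d", seq_len(n))
  homoeolog_map(data.frame(
    group_id = rep(groups, each = length(labels)),
    subgenome = rep(labels, n),
    gene_id = paste0(rep(groups, each = length(labels)), "_", labels)),
    ratio_class = if (length(labels) == 2) "pair" else "triad")
}

# uniform random points on the 2-simplex (rows sum to 1)
random_simplex <- function(n, k = 3) {
  e <- matrix(stats::rexp(n * k), n, k)
  e / rowSums(e)
}

# independent scalar-loop nearest-ideal-point classifier (oracle)
brute_force_classify <- function(rel, ideal) {
  t(vapply(seq_len(nrow(rel)), function(i) {
    d <- numeric(nrow(ideal))
    for (j in seq_len(nrow(ideal))) {
      s <- 0
      for (c in seq_len(ncol(ideal))) s <- s + (rel[i, c] - ideal[j, c])^2
      d[j] <- sqrt(s)
    }
    c(best = which.min(d), dist = min(d))
  }, c(best = 0, dist = 0)))
}

# naive scalar-loop biweight midcorrelation (oracle, no outlier cap)
naive_bicor <- function(x, y) {
  tr <- function(v) {
    u <- (v - median(v)) / (9 * mad(v, constant = 1))
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    vt <- (v - median(v)) * w
    vt / sqrt(sum(vt^2))
  }
  sum(tr(x) * tr(y))
}

# naive triple-loop unsigned TOM (oracle)
naive_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
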