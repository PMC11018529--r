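#' Biweight midcorrelation
#'
#' Robust correlation based on median/MAD weights: with
#' `u_i = (x_i - median(x)) / (9 * MAD(x))` (unscaled MAD), observation
#' weights are `w_i = (1 - u_i^2)^2` for `|u_i| < 1` and 0 otherwise.
#' `max_p_outliers` caps the fraction of observations per side that can
#' receive zero weight: if the `max_p_outliers` (or `1 - max_p_outliers`)
#' quantile of `u` lies beyond -1 (or +1), that side of `u` is rescaled so
#' the quantile sits at the boundary.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param max_p_outliers per-side cap on zero-weight observations
#'   (default 0.05).
#' @param fallback_pearson if TRUE, constant or zero-MAD vectors fall back
#'   to Pearson correlation instead of erroring.
#' @return correlation in \[-1, 1\].
#' @export
bicor <- function(x, y, max_p_outliers = 0.05, fallback_pearson = FALSE) {
  if (length(x) != length(y)) stop_fmt("x and y must have equal length")
  if (length(x) < 3) stop_fmt("need >= 3 observations")
  tx <- bicor_transform(x, max_p_outliers)
  ty <- bicor_transform(y, max_p_outliers)
  if (is.null(tx) || is.null(ty)) {
    if (fallback_pearson) return(stats::cor(x, y))
    stop_fmt("constant (zero-MAD) vector; set fallback_pearson = TRUE")
  }
  sum(tx * ty)
}

# robust standardization of one vector; NULL when MAD or spread degenerate
bicor_transform <- function(x, max_p_outliers = 0.05) {
  med <- stats::median(x)
  madx <- stats::mad(x, constant = 1)
  if (madx == 0) return(NULL)
  u <- (x - med) / (9 * madx)
  if (max_p_outliers < 0.5) {
    qlo <- stats::quantile(u, max_p_outliers, names = FALSE)
    qhi <- stats::quantile(u, 1 - max_p_outliers, names = FALSE)
    if (qlo < -1) u[u < 0] <- u[u < 0] / (-qlo)
    if (qhi > 1) u[u > 0] <- u[u > 0] / qhi
  }
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- (x - med) * w
  nrm <- sqrt(sum(xt^2))
  if (nrm == 0) return(NULL)
  xt / nrm
}

#' Biweight midcorrelation matrix over genes
#'
#' Correlates every pair of rows (genes) of an expression matrix.
#'
#' @param x genes x samples numeric matrix (or an [expression_matrix()],
#'   whose values are taken as-is).
#' @param max_p_outliers see [bicor()].
#' @param robust if FALSE, plain Pearson correlation of rows is returned.
#' @param fallback_pearson per-gene Pearson fallback for zero-MAD rows.
#' @return symmetric genes x genes correlation matrix, unit diagonal.
#' @export
bicor_matrix <- function(x, max_p_outliers = 0.05, robust = TRUE,
                         fallback_pearson = TRUE) {
  if (inherits(x, "ExpressionMatrix")) x <- x$values
  if (!robust) {
    r <- stats::cor(t(x))
  } else {
    tx <- t(apply(x, 1, function(row) {
      v <- bicor_transform(row, max_p_outliers)
      if (is.null(v)) {
        if (!fallback_pearson)
          stop_fmt("constant (zero-MAD) gene row; set robust = FALSE or fallback_pearson = TRUE")
        s <- row - mean(row)
        n <- sqrt(sum(s^2))
        if (n == 0) rep(0, length(row)) else s / n
      } else v
    }))
    r <- tcrossprod(tx)
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rownames(x), rownames(x))
  r
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities, regresses log10(frequency) on log10(mean
#' connectivity) over occupied bins, and signs the R-squared by the slope
#' (negative slope required for a scale-free decay).
#'
#' @param k nonnegative connectivity vector.
#' @param n_bins histogram bins (default 10).
#' @return list `fit` (signed R-squared, NA when degenerate) and `slope`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins || stats::sd(k) == 0)
    return(list(fit = NA_real_, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  kmean <- vapply(split(k, bin), function(v) mean(v), numeric(1))
  occ <- freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(occ) < 3) return(list(fit = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[occ]) ~ log10(kmean[occ]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(fit = -sign(slope) * r2, slope = slope)
}

#' Pick the soft-thresholding power by scale-free fit
#'
#' For each candidate power, builds the signed-hybrid adjacency, computes
#' connectivities and the signed scale-free fit index, and returns the
#' smallest power whose fit reaches `target_fit`. If none qualifies the
#' power with the maximal fit is returned with a warning.
#'
#' @param cor_mat gene correlation matrix (e.g. [bicor_matrix()]).
#' @param powers candidate powers (default 1:30).
#' @param target_fit required fit index (default 0.9).
#' @param n_bins see [scale_free_fit()].
#' @return chosen power (integer), with the per-power fit table as
#'   attribute `"fit_table"`.
#' @export
pick_soft_power <- function(cor_mat, powers = 1:30, target_fit = 0.9,
                            n_bins = 10) {
  tab <- data.frame(power = powers, fit = NA_real_, slope = NA_real_)
  for (i in seq_along(powers)) {
    a <- adjacency_signed_hybrid(cor_mat, powers[i])
    sf <- scale_free_fit(rowSums(a), n_bins)
    if (is.na(sf$fit)) {
      warning("degenerate connectivity at power ", powers[i], "; skipped")
      next
    }
    tab$fit[i] <- sf$fit
    tab$slope[i] <- sf$slope
  }
  ok <- which(!is.na(tab$fit) & tab$fit >= target_fit)
  if (length(ok)) {
    power <- powers[ok[1]]
  } else {
    if (all(is.na(tab$fit))) stop_fmt("no power yields a defined fit index")
    power <- powers[which.max(tab$fit)]
    warning(sprintf("no power reached fit %.2f; using power %d (fit %.3f)",
                    target_fit, power, max(tab$fit, na.rm = TRUE)))
  }
  structure(as.integer(power), fit_table = tab)
}

#' Signed-hybrid adjacency
#'
#' `a_ij = cor_ij ^ power` for positive correlations, 0 otherwise;
#' the diagonal is set to 0 (self-adjacency excluded from connectivity).
#'
#' @param cor_mat correlation matrix in \[-1, 1\].
#' @param power soft-thresholding exponent (positive).
#' @return adjacency matrix in \[0, 1\].
#' @export
adjacency_signed_hybrid <- function(cor_mat, power) {
  if (power <= 0) stop_fmt("power must be positive")
  a <- ifelse(cor_mat > 0, cor_mat^power, 0)
  diag(a) <- 0
  a
}

#' Unsigned topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; rewards shared neighbors in addition to direct
#' adjacency.
#'
#' @param adj adjacency in \[0, 1\], symmetric, zero diagonal.
#' @return symmetric TOM in \[0, 1\].
#' @export
tom_unsigned <- function(adj) {
  if (any(adj < 0 | adj > 1)) stop_fmt("adjacency entries must lie in [0, 1]")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom <- (tom + t(tom)) / 2               # enforce exact symmetry
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage clustering on 1 - TOM, cut at `cut_height`; clusters
#' smaller than `min_size` become unassigned (module 0). When an
#' expression matrix is supplied, modules whose eigengenes correlate
#' above `1 - merge_height` are merged iteratively until stable. Final
#' labels are 1, 2, ... by decreasing module size (0 = unassigned).
#'
#' @param tom TOM from [tom_unsigned()], with gene dimnames.
#' @param expr genes x samples matrix for eigengene merging (NULL skips
#'   the merge step).
#' @param min_size minimum module size (default 30).
#' @param merge_height eigengene dissimilarity below which modules merge
#'   (default 0.15).
#' @param cut_height static cut height on 1 - TOM (default 0.99).
#' @return named integer vector gene -> module label.
#' @export
detect_modules <- function(tom, expr = NULL, min_size = 30,
                           merge_height = 0.15, cut_height = 0.99) {
  genes <- rownames(tom) %||% as.character(seq_len(nrow(tom)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  labels <- relabel_by_size(cl, min_size)
  if (!is.null(labels) && max(labels) == 0)
    warning("no cluster reached min_size = ", min_size,
            "; all genes unassigned")
  if (!is.null(expr) && max(labels) >= 2) {
    if (inherits(expr, "ExpressionMatrix")) expr <- expr$values
    repeat {
      mods <- sort(unique(labels[labels > 0]))
      mes <- vapply(mods, function(mm)
        module_eigengene(expr, genes[labels == mm]), numeric(ncol(expr)))
      if (length(mods) < 2) break
      cc <- stats::cor(mes)
      diag(cc) <- -Inf
      best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (max(cc) <= 1 - merge_height) break
      a <- mods[min(best)]; b <- mods[max(best)]
      labels[labels == b] <- a
    }
    labels <- relabel_by_size(labels, min_size = 1)
  }
  stats::setNames(labels, genes)
}

# drop clusters below min_size to 0 and relabel 1.. by decreasing size
# (ties broken by smallest original label); label 0 stays unassigned
relabel_by_size <- function(cl, min_size) {
  sizes <- table(cl[cl != 0])
  keep <- names(sizes)[sizes >= min_size]
  out <- integer(length(cl))
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  for (i in seq_along(keep)) out[cl == as.integer(keep[i])] <- i
  out
}

#' Module eigengene
#'
#' First principal component of the standardized module submatrix over
#' samples, oriented so its mean correlation with member genes is
#' nonnegative, and scaled to unit variance. A one-gene module returns
#' that gene's standardized profile.
#'
#' @param expr genes x samples matrix (log scale recommended).
#' @param genes member gene ids (rownames of `expr`).
#' @return numeric vector over samples (unit variance).
#' @export
module_eigengene <- function(expr, genes) {
  if (inherits(expr, "ExpressionMatrix")) expr <- expr$values
  sub <- expr[genes, , drop = FALSE]
  z <- t(scale(t(sub)))                   # standardize each gene
  z[is.na(z)] <- 0                        # constant genes carry no signal
  if (nrow(sub) == 1) {
    me <- z[1, ]
  } else {
    sv <- svd(t(z), nu = 1, nv = 0)
    me <- sv$u[, 1]
  }
  cors <- suppressWarnings(stats::cor(me, t(sub)))
  if (mean(cors, na.rm = TRUE) < 0) me <- -me
  s <- stats::sd(me)
  if (s > 0) me <- me / s
  stats::setNames(me, colnames(expr))
}

#' Module membership (KME) and hub genes
#'
#' KME of a gene is the Pearson correlation between its profile and its
#' own module's eigengene; genes with KME above `kme_threshold` are hubs.
#' Unassigned genes (module 0) have NA KME and are never hubs.
#'
#' @param expr genes x samples matrix (log scale recommended).
#' @param labels named module labels from [detect_modules()].
#' @param kme_threshold hub threshold (default 0.9, exclusive).
#' @return data.frame `gene_id`, `module`, `kme`, `hub`.
#' @export
hub_genes <- function(expr, labels, kme_threshold = 0.9) {
  if (inherits(expr, "ExpressionMatrix")) expr <- expr$values
  genes <- names(labels)
  kme <- rep(NA_real_, length(labels))
  for (mm in sort(unique(labels[labels > 0]))) {
    members <- genes[labels == mm]
    me <- module_eigengene(expr, members)
    kme[labels == mm] <- suppressWarnings(
      as.vector(stats::cor(t(expr[members, , drop = FALSE]), me)))
  }
  data.frame(gene_id = genes, module = as.integer(labels), kme = kme,
             hub = !is.na(kme) & kme > kme_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hub counts per module and subgenome
#'
#' @param hubs data.frame from [hub_genes()].
#' @param subgenomes named character vector gene -> subgenome label.
#' @return data.frame `module`, `subgenome`, `n_hubs`.
#' @export
hub_subgenome_counts <- function(hubs, subgenomes) {
  h <- hubs[hubs$hub, ]
  h$subgenome <- subgenomes[h$gene_id]
  out <- as.data.frame(table(module = h$module, subgenome = h$subgenome),
                       stringsAsFactors = FALSE)
  names(out)[3] <- "n_hubs"
  out$module <- as.integer(out$module)
  out[order(out$module, out$subgenome), ]
}

#' Top-k neighbor subgenome composition
#'
#' For every gene, ranks all other genes by edge weight (descending;
#' ties by ascending gene id) and counts how many of the top `k`
#' neighbors share the gene's subgenome (intra) versus not (inter), with
#' a per-subgenome breakdown.
#'
#' @param weights symmetric edge-weight matrix (TOM by default in the
#'   pipeline) with gene dimnames.
#' @param subgenomes named character vector gene -> subgenome label.
#' @param k neighbors per gene (default 100); capped at n - 1 with a
#'   note column when the network is smaller.
#' @return data.frame `gene_id`, `subgenome`, `k_used`, `intra`, `inter`,
#'   plus one `n_<label>` count column per subgenome label.
#' @export
neighbor_composition <- function(weights, subgenomes, k = 100) {
  genes <- rownames(weights)
  if (is.null(genes)) stop_fmt("weight matrix needs gene dimnames")
  miss <- setdiff(genes, names(subgenomes))
  if (length(miss)) stop_fmt("no subgenome label for gene(s): %s",
                             paste(utils::head(miss, 5), collapse = ", "))
  labs <- sort(unique(subgenomes[genes]))
  k_used <- min(k, length(genes) - 1)
  if (k_used < k)
    message("k reduced to ", k_used, " (network has ", length(genes),
            " genes)")
  rows <- lapply(seq_along(genes), function(i) {
    w <- weights[i, -i]
    ids <- genes[-i]
    ord <- order(-w, ids)
    top <- subgenomes[ids[ord[seq_len(k_used)]]]
    cnt <- table(factor(top, labs))
    own <- subgenomes[[genes[i]]]
    data.frame(gene_id = genes[i], subgenome = own, k_used = k_used,
               intra = sum(top == own), inter = sum(top != own),
               t(as.matrix(cnt)), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[-(1:5)] <- paste0("n_", labs)
  out
}

#' Aggregate neighbor composition per subgenome
#'
#' Mean percentage of intra-subgenome neighbors per focal-gene subgenome.
#'
#' @param comp data.frame from [neighbor_composition()].
#' @return data.frame `subgenome`, `n_genes`, `pct_intra`.
#' @export
neighbor_composition_summary <- function(comp) {
  sp <- split(comp, comp$subgenome)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(subgenome = d$subgenome[1], n_genes = nrow(d),
               pct_intra = 100 * mean(d$intra / d$k_used),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Full lightweight co-expression pipeline
#'
#' bicor correlation, soft-power selection, signed-hybrid adjacency,
#' unsigned TOM, static-cut module detection with eigengene merging, KME
#' hubs and neighbor composition, in one call.
#'
#' @param expr an [expression_matrix()] or genes x samples matrix
#'   (log2(TPM+1) recommended).
#' @param subgenomes named character vector gene -> subgenome label.
#' @param power soft power; `NULL` (default) scans via
#'   [pick_soft_power()].
#' @param powers,target_fit passed to [pick_soft_power()].
#' @param min_size,merge_height,cut_height passed to [detect_modules()].
#' @param kme_threshold passed to [hub_genes()].
#' @param k_neighbors passed to [neighbor_composition()].
#' @param robust use bicor (TRUE) or Pearson (FALSE) correlation.
#' @return object of class `CoexpressionNetwork`: list with `genes`,
#'   `cor`, `power`, `fit_table`, `adjacency`, `tom`, `labels`,
#'   `eigengenes`, `kme` (the [hub_genes()] table), `hubs`,
#'   `neighbor_composition`.
#' @export
build_network <- function(expr, subgenomes, power = NULL, powers = 1:30,
                          target_fit = 0.9, min_size = 30,
                          merge_height = 0.15, cut_height = 0.99,
                          kme_threshold = 0.9, k_neighbors = 100,
                          robust = TRUE) {
  x <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  cc <- bicor_matrix(x, robust = robust)
  fit_table <- NULL
  if (is.null(power)) {
    power <- pick_soft_power(cc, powers = powers, target_fit = target_fit)
    fit_table <- attr(power, "fit_table")
  }
  adj <- adjacency_signed_hybrid(cc, as.integer(power))
  tom <- tom_unsigned(adj)
  labels <- detect_modules(tom, expr = x, min_size = min_size,
                           merge_height = merge_height,
                           cut_height = cut_height)
  kme <- hub_genes(x, labels, kme_threshold)
  mods <- sort(unique(labels[labels > 0]))
  mes <- if (length(mods))
    vapply(mods, function(mm) module_eigengene(x, names(labels)[labels == mm]),
           numeric(ncol(x)))
  else matrix(numeric(0), ncol(x), 0)
  if (length(mods)) colnames(mes) <- paste0("ME", mods)
  comp <- neighbor_composition(tom, subgenomes, k = k_neighbors)
  structure(list(genes = rownames(x), cor = cc, power = as.integer(power),
                 fit_table = fit_table, adjacency = adj, tom = tom,
                 labels = labels, eigengenes = mes, kme = kme,
                 hubs = kme[kme$hub, ], neighbor_composition = comp),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf("CoexpressionNetwork: %d genes, power %d, %d modules (%d unassigned), %d hubs\n",
              length(x$genes), x$power, length(unique(x$labels[x$labels > 0])),
              sum(x$labels == 0), nrow(x$hubs)))
  invisible(x)
}
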