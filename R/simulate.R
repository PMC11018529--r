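#' Simulation configuration for replicate-level homoeolog expression
#'
#' Defaults describe the sampling design the analysis assumes: five
#' tissues with three biological replicates each, hexaploid triads over
#' subgenomes A/B/C, negative-binomial count noise and log-normal
#' library-size variation. Category proportions default to a
#' predominantly balanced mixture (78% balanced, 2% each dominant, 16/3%
#' each suppressed).
#'
#' @param n_groups number of homoeolog groups.
#' @param ratio_class `"triad"` (3 subgenomes) or `"pair"` (2).
#' @param subgenome_labels ordered subgenome labels; length must match
#'   `ratio_class`.
#' @param tissues tissue names.
#' @param replicates_per_tissue biological replicates per tissue (>= 1).
#' @param category_proportions named fractions over the categories
#'   `balanced`, `<label>_dominant`, `<label>_suppressed`; nonnegative,
#'   summing to 1.
#' @param dominance_fold linear fold applied to the favored (dominant) or
#'   disfavored (suppressed) homoeolog; > 1.
#' @param base_mean mean TPM-scale expression of a gene.
#' @param nb_dispersion negative-binomial dispersion phi in
#'   `var = mu + phi * mu^2`; 0 gives Poisson noise.
#' @param library_size_cv coefficient of variation of per-sample library
#'   size; 0 disables library variation.
#' @param gene_length_range min/max gene length in bp (shared within a
#'   group, so homoeologs are length-matched).
#' @param seed integer master seed.
#' @return validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_groups = 1157,
                              ratio_class = c("triad", "pair"),
                              subgenome_labels = NULL,
                              tissues = c("leaf_blade", "leaf_sheath",
                                          "shoot", "root", "rhizome"),
                              replicates_per_tissue = 3,
                              category_proportions = NULL,
                              dominance_fold = 8,
                              base_mean = 50,
                              nb_dispersion = 0.05,
                              library_size_cv = 0.1,
                              gene_length_range = c(500, 5000),
                              seed = 1) {
  ratio_class <- match.arg(ratio_class)
  if (is.null(subgenome_labels))
    subgenome_labels <- if (ratio_class == "triad") c("A", "B", "C") else c("C", "D")
  need <- if (ratio_class == "pair") 2L else 3L
  if (length(subgenome_labels) != need)
    stop_fmt("ratio_class '%s' needs %d subgenome labels, got %d",
             ratio_class, need, length(subgenome_labels))
  cats <- category_names(subgenome_labels)
  if (is.null(category_proportions)) {
    k <- length(subgenome_labels)
    category_proportions <- c(0.78, rep(0.06 / k, k), rep(0.16 / k, k))
    names(category_proportions) <- cats
  }
  bad <- setdiff(names(category_proportions), cats)
  if (length(bad))
    stop_fmt("unknown category '%s'; valid: %s", bad[1],
             paste(cats, collapse = ", "))
  if (any(category_proportions < 0))
    stop_fmt("category proportions must be nonnegative")
  if (abs(sum(category_proportions) - 1) > 1e-9)
    stop_fmt("category proportions sum to %.12f, not 1",
             sum(category_proportions))
  if (replicates_per_tissue < 1) stop_fmt("replicates_per_tissue must be >= 1")
  if (dominance_fold <= 1) stop_fmt("dominance_fold must be > 1")
  if (nb_dispersion < 0) stop_fmt("nb_dispersion must be >= 0")
  if (library_size_cv < 0) stop_fmt("library_size_cv must be >= 0")
  stopifnot(length(gene_length_range) == 2, gene_length_range[1] > 0,
            gene_length_range[2] >= gene_length_range[1])
  structure(list(n_groups = as.integer(n_groups), ratio_class = ratio_class,
                 subgenome_labels = subgenome_labels, tissues = tissues,
                 replicates_per_tissue = as.integer(replicates_per_tissue),
                 category_proportions = category_proportions,
                 dominance_fold = dominance_fold, base_mean = base_mean,
                 nb_dispersion = nb_dispersion,
                 library_size_cv = library_size_cv,
                 gene_length_range = gene_length_range,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Bias category names for a label set
#' @param labels subgenome labels.
#' @return `balanced`, then `<label>_dominant`, then `<label>_suppressed`.
#' @export
category_names <- function(labels) {
  c("balanced", paste0(sort(labels), "_dominant"),
    paste0(sort(labels), "_suppressed"))
}

# exact largest-remainder allocation of n items to proportions p
allocate_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate replicate-level homoeolog expression counts
#'
#' Each group gets a shared gene length and a per-tissue baseline mean;
#' the planted category scales one homoeolog's mean by `dominance_fold`
#' (dominant) or its inverse (suppressed). Counts are drawn
#' negative-binomially with expected count
#' `mu * (length/1000) * library_factor`, so TPM computed downstream
#' recovers the planted TPM-scale means. Category counts follow the
#' configured proportions exactly (largest-remainder allocation), with the
#' assignment order randomised.
#'
#' @param config a [simulation_config()].
#' @return list with elements `counts` (an [expression_matrix()] of unit
#'   `"counts"`), `mu` (matrix of expected counts), `lengths` (named bp
#'   vector), `map` (a [homoeolog_map()]), `truth` (data.frame `group_id`,
#'   `tissue`, `category`) and `config`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, {
    labs <- config$subgenome_labels
    n <- config$n_groups
    groups <- sprintf("g%05d", seq_len(n))
    gene_ids <- as.vector(t(outer(groups, labs, paste, sep = "_")))
    gene_group <- rep(groups, each = length(labs))
    gene_sub <- rep(labs, times = n)

    lengths_grp <- round(stats::runif(n, config$gene_length_range[1],
                                      config$gene_length_range[2]))
    lengths <- stats::setNames(rep(lengths_grp, each = length(labs)), gene_ids)

    cats <- category_names(labs)
    prop <- stats::setNames(numeric(length(cats)), cats)
    prop[names(config$category_proportions)] <- config$category_proportions
    planted <- rep(cats, allocate_counts(n, prop))
    planted <- sample(planted)                       # random order, exact counts

    tissues <- config$tissues
    reps <- config$replicates_per_tissue
    sample_ids <- as.vector(t(outer(tissues, seq_len(reps),
                                    function(t, r) sprintf("%s_r%d", t, r))))
    sample_tissue <- rep(tissues, each = reps)

    # per-group per-tissue baseline TPM-scale mean (gene effect x tissue effect)
    gene_effect <- stats::rlnorm(n, meanlog = log(config$base_mean) - 0.125,
                                 sdlog = 0.5)
    tissue_effect <- matrix(stats::rlnorm(n * length(tissues), 0, 0.4),
                            n, length(tissues))
    base_mu <- gene_effect * tissue_effect           # groups x tissues

    # category fold per member: dominant label x fold, suppressed label / fold
    fold <- matrix(1, n, length(labs), dimnames = list(groups, labs))
    dom <- sub("_dominant$", "", planted[grepl("_dominant$", planted)])
    fold[cbind(which(grepl("_dominant$", planted)), match(dom, labs))] <-
      config$dominance_fold
    sup <- sub("_suppressed$", "", planted[grepl("_suppressed$", planted)])
    fold[cbind(which(grepl("_suppressed$", planted)), match(sup, labs))] <-
      1 / config$dominance_fold

    lib <- rlnorm_cv(length(sample_ids), config$library_size_cv)

    n_genes <- length(gene_ids)
    mu <- matrix(0, n_genes, length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
    g_idx <- match(gene_group, groups)
    s_idx <- match(gene_sub, labs)
    for (j in seq_along(sample_ids)) {
      t_idx <- match(sample_tissue[j], tissues)
      tpm_mean <- base_mu[cbind(g_idx, t_idx)] * fold[cbind(g_idx, s_idx)]
      mu[, j] <- tpm_mean * (lengths / 1000) * lib[j]
    }
    counts <- matrix(0, n_genes, length(sample_ids),
                     dimnames = dimnames(mu))
    if (config$nb_dispersion > 0) {
      counts[] <- stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$nb_dispersion)
    } else {
      counts[] <- stats::rpois(length(mu), mu)
    }

    meta <- data.frame(sample_id = sample_ids, species = "synthetic",
                       tissue = sample_tissue,
                       replicate = rep(seq_len(reps), times = length(tissues)),
                       stringsAsFactors = FALSE)
    map <- homoeolog_map(data.frame(group_id = gene_group,
                                    subgenome = gene_sub, gene_id = gene_ids,
                                    stringsAsFactors = FALSE),
                         ratio_class = config$ratio_class)
    truth <- data.frame(group_id = rep(groups, each = length(tissues)),
                        tissue = rep(tissues, times = n),
                        category = rep(planted, each = length(tissues)),
                        stringsAsFactors = FALSE)
    list(counts = expression_matrix(counts, meta, unit = "counts"),
         mu = mu, lengths = lengths, map = map, truth = truth,
         config = config)
  })
}

#' Simulate co-expression modules with planted subgenome-weighted hubs
#'
#' Each module is one latent sample profile; member genes are
#' `loading * latent + N(0, noise_sd)`. Genes whose loading is at or above
#' the within-module `hub_quantile` are planted hubs; hub subgenome labels
#' are drawn with probability proportional to `hub_subgenome_weights`,
#' non-hub labels uniformly.
#'
#' @param n_genes total genes; must be at least
#'   `n_modules * min_module_size`.
#' @param n_modules number of modules (>= 1).
#' @param hub_subgenome_weights named nonnegative weights over subgenome
#'   labels.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n_samples number of samples (default 15: five tissues, three
#'   replicates).
#' @param hub_quantile loading quantile above which a gene is a planted hub.
#' @param min_module_size smallest admissible module.
#' @param seed integer seed.
#' @return list with `expr` (an [expression_matrix()], unit `"log"`) and
#'   `truth` (data.frame `gene_id`, `module`, `subgenome`, `loading`,
#'   `hub`).
#' @export
simulate_modules <- function(n_genes = 200, n_modules = 2,
                             hub_subgenome_weights = c(A = 1, B = 1, C = 1),
                             noise_sd = 0.1, n_samples = 15,
                             hub_quantile = 0.9, min_module_size = 30,
                             seed = 1) {
  if (n_modules < 1) stop_fmt("n_modules must be >= 1")
  if (any(hub_subgenome_weights < 0)) stop_fmt("weights must be nonnegative")
  if (n_genes < n_modules * min_module_size)
    stop_fmt("n_genes = %d cannot host %d modules of minimum size %d",
             n_genes, n_modules, min_module_size)
  with_seed(seed + 1000003L, {
    labs <- names(hub_subgenome_weights)
    sizes <- allocate_counts(n_genes, rep(1 / n_modules, n_modules))
    module <- rep(seq_len(n_modules), sizes)
    gene_ids <- sprintf("mg%05d", seq_len(n_genes))
    latent <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
    loading <- stats::runif(n_genes, 0.4, 1)
    expr <- latent[module, , drop = FALSE] * loading +
      matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
             n_genes, n_samples)
    dimnames(expr) <- list(gene_ids, sprintf("s%02d", seq_len(n_samples)))

    hub <- logical(n_genes)
    for (mmod in seq_len(n_modules)) {
      idx <- which(module == mmod)
      thr <- stats::quantile(loading[idx], hub_quantile)
      hub[idx] <- loading[idx] >= thr
    }
    w <- hub_subgenome_weights / sum(hub_subgenome_weights)
    subgenome <- character(n_genes)
    subgenome[hub] <- sample(labs, sum(hub), replace = TRUE, prob = w)
    subgenome[!hub] <- sample(labs, sum(!hub), replace = TRUE)

    meta <- data.frame(sample_id = colnames(expr), species = "synthetic",
                       tissue = colnames(expr), replicate = 1L,
                       stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = gene_ids, module = module,
                        subgenome = subgenome, loading = loading, hub = hub,
                        stringsAsFactors = FALSE)
    list(expr = expression_matrix(expr, meta, unit = "log"), truth = truth)
  })
}

#' Simulate a gene-retention track with subgenome-biased loss
#'
#' Every reference gene is retained in subgenome `s` independently with
#' probability `1 - loss_prob[s]`.
#'
#' @param n_reference_genes ordered reference genes per chromosome.
#' @param loss_prob named loss probabilities in \[0, 1\] per subgenome.
#' @param n_chromosomes reference chromosomes (genes split evenly).
#' @param seed integer seed.
#' @return list with `track` (a [retention_track()]) and `truth`
#'   (data.frame of planted loss events: `ref_chrom`, `ref_index`,
#'   `subgenome`, `lost`).
#' @export
simulate_retention <- function(n_reference_genes = 10000,
                               loss_prob = c(A = 0.1, B = 0.3, C = 0.2),
                               n_chromosomes = 1, seed = 1) {
  if (any(loss_prob < 0 | loss_prob > 1))
    stop_fmt("loss probabilities must lie in [0, 1]")
  with_seed(seed + 2000003L, {
    labs <- names(loss_prob)
    per_chr <- allocate_counts(n_reference_genes,
                               rep(1 / n_chromosomes, n_chromosomes))
    rows <- list()
    for (ch in seq_len(n_chromosomes)) {
      nch <- per_chr[ch]
      chrom <- sprintf("ref%d", ch)
      for (s in labs) {
        present <- stats::rbinom(nch, 1, 1 - loss_prob[[s]])
        rows[[length(rows) + 1]] <- data.frame(
          ref_chrom = chrom, ref_index = seq_len(nch) - 1L,
          ref_gene_id = sprintf("%s_gene%05d", chrom, seq_len(nch)),
          subgenome = s, present = present, stringsAsFactors = FALSE)
      }
    }
    track <- retention_track(do.call(rbind, rows))
    truth <- data.frame(ref_chrom = track$ref_chrom,
                        ref_index = track$ref_index,
                        subgenome = track$subgenome,
                        lost = track$present == 0L,
                        stringsAsFactors = FALSE)
    list(track = track, truth = truth)
  })
}

#' Write a full expression simulation to a directory
#'
#' Emits `expression.tsv`, `meta.tsv`, `map.tsv`, `lengths.tsv` and
#' `truth.json` in the package's TSV dialects.
#'
#' @param sim result of [simulate_expression()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
save_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("expression.tsv", "meta.tsv", "map.tsv",
                            "lengths.tsv", "truth.json"))
  write_expression(sim$counts, paths[1], paths[2])
  write_homoeolog_map(sim$map, paths[3])
  utils::write.table(data.frame(gene_id = names(sim$lengths),
                                length_bp = as.integer(sim$lengths)),
                     paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[5], dataframe = "columns",
                       digits = NA)
  invisible(paths)
}

#' Simulate homoeolog pair profiles with a planted shifted fraction
#'
#' Draws a bank of base tissue patterns; a non-shifted pair gives both
#' members the same pattern, a shifted pair two different patterns, each
#' plus Gaussian noise. Clustering the profiles into expression-pattern
#' groups should recover the planted shifted fraction.
#'
#' @param n_pairs number of homoeolog pairs.
#' @param shifted_fraction planted fraction of shifted pairs in \[0, 1\]
#'   (realised exactly up to rounding).
#' @param n_tissues profile length (default 5).
#' @param n_patterns distinct base patterns (default 10, matching the
#'   10-group clustering).
#' @param noise_sd Gaussian noise on profiles (default 0.05).
#' @param subgenome_labels the two member labels.
#' @param seed integer seed.
#' @return list with `profiles` (2*n_pairs x n_tissues matrix), `key`
#'   (data.frame `gene_id`, `group_id`, `subgenome`) and `truth`
#'   (data.frame `group_id`, `shifted`).
#' @export
simulate_shift_profiles <- function(n_pairs = 400, shifted_fraction = 0.5,
                                    n_tissues = 5, n_patterns = 10,
                                    noise_sd = 0.05,
                                    subgenome_labels = c("C", "D"),
                                    seed = 1) {
  if (shifted_fraction < 0 || shifted_fraction > 1)
    stop_fmt("shifted_fraction must lie in [0, 1]")
  with_seed(seed + 3000003L, {
    pats <- matrix(stats::rnorm(n_patterns * n_tissues), n_patterns)
    n_sh <- round(n_pairs * shifted_fraction)
    shifted <- sample(rep(c(TRUE, FALSE), c(n_sh, n_pairs - n_sh)))
    p1 <- sample(n_patterns, n_pairs, replace = TRUE)
    jump <- sample(n_patterns - 1, n_pairs, replace = TRUE)
    p2 <- ifelse(shifted, (p1 + jump - 1) %% n_patterns + 1, p1)
    groups <- sprintf("p%05d", seq_len(n_pairs))
    prof <- rbind(pats[p1, , drop = FALSE], pats[p2, , drop = FALSE]) +
      stats::rnorm(2 * n_pairs * n_tissues, sd = noise_sd)
    rownames(prof) <- c(paste0(groups, "_", subgenome_labels[1]),
                        paste0(groups, "_", subgenome_labels[2]))
    colnames(prof) <- sprintf("tissue%d", seq_len(n_tissues))
    key <- data.frame(gene_id = rownames(prof), group_id = rep(groups, 2),
                      subgenome = rep(subgenome_labels, each = n_pairs),
                      stringsAsFactors = FALSE)
    key <- key[order(key$group_id, key$subgenome), ]
    rownames(key) <- NULL
    list(profiles = prof, key = key,
         truth = data.frame(group_id = groups, shifted = shifted,
                            stringsAsFactors = FALSE))
  })
}
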