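#' Gene-retention track
#'
#' Long-format record of per-subgenome presence of ordered reference
#' genes: one row per reference gene x subgenome, with a 0/1 presence
#' flag. Indices are 0-based and contiguous within each reference
#' chromosome.
#'
#' @param df data.frame with columns `ref_chrom`, `ref_index` (0-based),
#'   `ref_gene_id`, `subgenome`, `present` (0/1).
#' @return validated data.frame of class `RetentionTrack`, sorted by
#'   (subgenome, ref_chrom, ref_index).
#' @export
retention_track <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("ref_chrom", "ref_index", "ref_gene_id", "subgenome", "present")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_fmt("retention track lacks column(s): %s", paste(miss, collapse = ", "))
  df <- df[, req]
  df$ref_index <- as.integer(df$ref_index)
  df$present <- as.integer(df$present)
  if (!all(df$present %in% c(0L, 1L)))
    stop_fmt("presence flags must be 0/1")
  df <- df[order(df$subgenome, df$ref_chrom, df$ref_index), ]
  for (key in split(df$ref_index,
                    interaction(df$subgenome, df$ref_chrom, drop = TRUE))) {
    if (!identical(sort(key), seq_along(key) - 1L))
      stop_fmt("ref_index not contiguous from 0 within a chromosome")
  }
  rownames(df) <- NULL
  structure(df, class = c("RetentionTrack", "data.frame"))
}

#' Read/write retention tracks
#'
#' TSV with columns `ref_chrom`, `ref_index` (0-based within chromosome),
#' `ref_gene_id`, `subgenome`, `present` (0/1); `#` lines ignored.
#'
#' @param path file path.
#' @return a [retention_track()].
#' @export
read_retention_track <- function(path) {
  retention_track(utils::read.delim(path, header = TRUE, sep = "\t",
                                    comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' @rdname read_retention_track
#' @param track a [retention_track()].
#' @export
write_retention_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# window coordinates downstream are 0-based, half-open", con)
  utils::write.table(as.data.frame(track), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(track)
}

#' Sliding-window retention fractions
#'
#' Per subgenome and reference chromosome, windows `[i, i + window)` at
#' stride `step` over the ordered reference genes; each window's fraction
#' is retained genes / window size. Windows never span chromosome
#' boundaries; trailing partial windows are dropped.
#'
#' @param track a [retention_track()].
#' @param window window size in genes (default 100).
#' @param step stride in genes (default 10).
#' @return data.frame `subgenome`, `ref_chrom`, `start` (0-based),
#'   `end` (exclusive), `retained`, `fraction`.
#' @export
windowed_retention <- function(track, window = 100, step = 10) {
  stopifnot(inherits(track, "RetentionTrack"))
  if (window < 1 || step < 1) stop_fmt("window and step must be >= 1")
  parts <- split(as.data.frame(track),
                 interaction(track$subgenome, track$ref_chrom, drop = TRUE))
  out <- lapply(parts, function(d) {
    d <- d[order(d$ref_index), ]
    n <- nrow(d)
    if (window > n)
      stop_fmt("window (%d) exceeds track length (%d) on %s/%s", window, n,
               d$subgenome[1], d$ref_chrom[1])
    starts <- seq(0L, n - window, by = step)
    csum <- c(0L, cumsum(d$present))
    retained <- csum[starts + window + 1L] - csum[starts + 1L]
    data.frame(subgenome = d$subgenome[1], ref_chrom = d$ref_chrom[1],
               start = starts, end = starts + window, retained = retained,
               fraction = retained / window, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$subgenome, out$ref_chrom, out$start), ]
}

#' Compare windowed retention between subgenomes
#'
#' Two-sided Wilcoxon rank-sum test on window retention fractions for
#' every subgenome pair, with sample sizes, medians and direction. When
#' both samples are identical constants the comparison is degenerate and
#' reported with p = 1 and a note.
#'
#' @param windows data.frame from [windowed_retention()].
#' @return data.frame `sub_a`, `sub_b`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `direction` (`"a>b"`, `"b>a"` or `"a=b"` by median),
#'   `statistic`, `p_value`, `note`.
#' @export
compare_retention <- function(windows) {
  subs <- sort(unique(windows$subgenome))
  if (length(subs) < 2) stop_fmt("need >= 2 subgenomes to compare")
  pairs <- utils::combn(subs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    fa <- windows$fraction[windows$subgenome == pr[1]]
    fb <- windows$fraction[windows$subgenome == pr[2]]
    if (length(fa) < 2 || length(fb) < 2)
      stop_fmt("subgenome pair %s/%s needs >= 2 windows each", pr[1], pr[2])
    ma <- stats::median(fa); mb <- stats::median(fb)
    degenerate <- length(unique(c(fa, fb))) == 1
    if (degenerate) {
      w <- list(statistic = c(W = length(fa) * length(fb) / 2), p.value = 1)
      note <- "degenerate: identical constant samples"
    } else {
      w <- suppressWarnings(stats::wilcox.test(fa, fb, exact = FALSE))
      note <- ""
    }
    data.frame(sub_a = pr[1], sub_b = pr[2], n_a = length(fa),
               n_b = length(fb), median_a = ma, median_b = mb,
               direction = if (ma > mb) "a>b" else if (mb > ma) "b>a" else "a=b",
               statistic = unname(w$statistic), p_value = w$p.value,
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Copy-count table from a retention track
#'
#' Treats each reference gene as a homoeologous group and its per-
#' subgenome presence flags as copy counts (0/1).
#'
#' @param track a [retention_track()].
#' @return groups x subgenomes integer matrix of copy counts.
#' @export
track_to_copy_counts <- function(track) {
  stopifnot(inherits(track, "RetentionTrack"))
  key <- paste(track$ref_chrom, track$ref_index, sep = ":")
  subs <- sort(unique(track$subgenome))
  groups <- unique(key)
  out <- matrix(0L, length(groups), length(subs),
                dimnames = list(groups, subs))
  out[cbind(match(key, groups), match(track$subgenome, subs))] <-
    track$present
  out
}

#' Homoeologous-group ratio census
#'
#' Classifies each group by its copy-count signature sorted in decreasing
#' order (e.g. `1:1:1`, `1:1:0`, `2:1`) and reports the percentage of
#' groups per signature (sums to 100).
#'
#' @param counts groups x subgenomes matrix/data.frame of nonnegative
#'   copy counts.
#' @return data.frame `signature`, `n_groups`, `percent`, ordered by
#'   decreasing frequency.
#' @export
group_ratio_census <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0) stop_fmt("empty copy-count table")
  if (any(counts < 0)) stop_fmt("copy counts must be nonnegative")
  sig <- apply(counts, 1, function(v)
    paste(sort(as.integer(v), decreasing = TRUE), collapse = ":"))
  tab <- table(sig)
  tab <- tab[order(-as.integer(tab), names(tab))]  # count desc, then name
  data.frame(signature = names(tab), n_groups = as.integer(tab),
             percent = 100 * as.integer(tab) / nrow(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
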