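#' Homoeolog group map
#'
#' Maps homoeologous groups to their member genes: each group has at most
#' one gene per subgenome, a pair exactly 2 members, a triad exactly 3.
#' No gene may occur in two groups.
#'
#' @param groups data.frame with columns `group_id`, `subgenome`, `gene_id`.
#' @param ratio_class `"pair"` or `"triad"`.
#' @return an object of class `HomoeologMap`: the validated data.frame with
#'   attributes `ratio_class` and `subgenomes` (sorted label set).
#' @export
homoeolog_map <- function(groups, ratio_class = c("triad", "pair")) {
  ratio_class <- match.arg(ratio_class)
  need <- if (ratio_class == "pair") 2L else 3L
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  req <- c("group_id", "subgenome", "gene_id")
  miss <- setdiff(req, names(groups))
  if (length(miss))
    stop_fmt("homoeolog map lacks column(s): %s", paste(miss, collapse = ", "))
  groups <- groups[, req]
  if (anyDuplicated(groups$gene_id))
    stop_fmt("gene '%s' occurs in more than one group",
             groups$gene_id[duplicated(groups$gene_id)][1])
  dup <- duplicated(groups[, c("group_id", "subgenome")])
  if (any(dup))
    stop_fmt("group '%s' has two genes on subgenome '%s'",
             groups$group_id[dup][1], groups$subgenome[dup][1])
  sizes <- table(groups$group_id)
  if (length(sizes) && any(sizes != need))
    stop_fmt("group '%s' has %d member(s); a %s needs exactly %d",
             names(sizes)[sizes != need][1], sizes[sizes != need][1],
             ratio_class, need)
  groups <- groups[order(groups$group_id, groups$subgenome), ]
  rownames(groups) <- NULL
  structure(groups, class = c("HomoeologMap", "data.frame"),
            ratio_class = ratio_class,
            subgenomes = sort(unique(groups$subgenome)))
}

#' @export
print.HomoeologMap <- function(x, ...) {
  cat(sprintf("HomoeologMap: %d %ss over subgenomes %s\n",
              length(unique(x$group_id)), attr(x, "ratio_class"),
              paste(attr(x, "subgenomes"), collapse = ",")))
  invisible(x)
}

#' Read a homoeolog map from TSV
#'
#' Expects tab-separated columns `group_id`, `subgenome`, `gene_id`; `#`
#' lines are ignored. Groups whose member count does not match
#' `ratio_class` raise an error when `strict = TRUE` (default) and are
#' dropped with a warning otherwise. An empty file yields an empty map with
#' a warning.
#'
#' @param path input TSV path.
#' @param ratio_class `"pair"` or `"triad"`.
#' @param strict reject (TRUE) or drop (FALSE) malformed groups.
#' @return a [homoeolog_map()].
#' @export
read_homoeolog_map <- function(path, ratio_class = c("triad", "pair"),
                               strict = TRUE) {
  ratio_class <- match.arg(ratio_class)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    warning("homoeolog map '", path, "' is empty")
    empty <- data.frame(group_id = character(), subgenome = character(),
                        gene_id = character(), stringsAsFactors = FALSE)
    return(homoeolog_map(empty, ratio_class))
  }
  if (!strict) {
    need <- if (ratio_class == "pair") 2L else 3L
    sizes <- table(tab$group_id)
    bad <- names(sizes)[sizes != need]
    if (length(bad)) {
      warning(length(bad), " group(s) with wrong member count dropped")
      tab <- tab[!tab$group_id %in% bad, ]
    }
  }
  homoeolog_map(tab, ratio_class)
}

#' Write a homoeolog map to TSV
#' @param map a [homoeolog_map()].
#' @param path output path.
#' @return invisibly, `map`.
#' @export
write_homoeolog_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(map)
}

# genes of one group as named vector subgenome -> gene_id
map_group_genes <- function(map, group) {
  rows <- map[map$group_id == group, ]
  stats::setNames(rows$gene_id, rows$subgenome)
}

# wide gene-id matrix: groups x subgenomes (NA if absent)
map_wide <- function(map) {
  groups <- unique(map$group_id)
  subs <- attr(map, "subgenomes")
  out <- matrix(NA_character_, length(groups), length(subs),
                dimnames = list(groups, subs))
  out[cbind(match(map$group_id, groups), match(map$subgenome, subs))] <-
    map$gene_id
  out
}
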