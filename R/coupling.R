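#' Mask a correlation matrix for display
#'
#' Reproduces the display convention of the correlation contour maps:
#' entries below the floor are masked out (set to `NA`), entries at or above
#' it are kept, and the unit diagonal is always masked.
#'
#' @param corr A `cmca_cor` object.
#' @param floor Display floor; entries `< floor` are masked. Default 0.5.
#' @return A numeric L x L matrix with masked cells as `NA`.
#' @export
filter_display <- function(corr, floor = 0.5) {
  stopifnot(inherits(corr, "cmca_cor"))
  m <- corr$values
  m[m < floor] <- NA_real_
  diag(m) <- NA_real_
  m
}

#' Extract strongly coupled position pairs
#'
#' Scans the lower triangle of a correlation matrix for entries strictly
#' above the pair threshold (default 0.80). Each hit is reported once as an
#' ordered pair `i > j` in reduced-alignment numbering.
#'
#' @param corr A `cmca_cor` object.
#' @param threshold Strict lower bound on the coefficient. Default 0.80.
#' @return A `cmca_pairs` data frame with columns `i`, `j` (1-based reduced
#'   positions, `i > j`) and `r`, sorted by `(j, i)`; zero rows when nothing
#'   exceeds the threshold. The threshold is kept as attribute `threshold`.
#' @export
extract_pairs <- function(corr, threshold = 0.80) {
  stopifnot(inherits(corr, "cmca_cor"))
  m <- corr$values
  hit <- which(lower.tri(m) & m > threshold, arr.ind = TRUE)
  pairs <- data.frame(i = as.integer(hit[, 1L]), j = as.integer(hit[, 2L]),
                      r = m[hit])
  pairs <- pairs[order(pairs$j, pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "threshold") <- threshold
  class(pairs) <- c("cmca_pairs", "data.frame")
  pairs
}

#' Cluster coupled pairs into contiguous matrix regions
#'
#' Groups pair cells `(i, j)` that are close in the correlation matrix into
#' labelled regions, mirroring the visually contiguous blobs of a contour
#' map. Two cells belong to the same region when a chain of cells connects
#' them with consecutive Chebyshev distance at most `radius`
#' (single linkage).
#'
#' @param pairs A `cmca_pairs` data frame.
#' @param radius Chebyshev linkage radius in matrix cells. Default 5.
#' @return The pairs data frame with a `region` column (labels `R1`, `R2`,
#'   ... ordered by each region's smallest member under `(j, i)` order), plus
#'   attribute `regions`: a data frame of per-region bounding boxes.
#' @export
cluster_regions <- function(pairs, radius = 5L) {
  stopifnot(inherits(pairs, "data.frame"))
  stopifnot(radius >= 0)
  np <- nrow(pairs)
  if (np == 0L) {
    pairs$region <- character(0)
    attr(pairs, "regions") <- data.frame(region = character(0),
                                         n_pairs = integer(0),
                                         i_min = integer(0), i_max = integer(0),
                                         j_min = integer(0), j_max = integer(0))
    return(pairs)
  }
  cheb <- outer(pairs$i, pairs$i, function(a, b) abs(a - b))
  cheb <- pmax(cheb, outer(pairs$j, pairs$j, function(a, b) abs(a - b)))
  adj <- cheb <= radius
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # order components by smallest member cell under (j, i)
  ord <- order(pairs$j, pairs$i)
  labels <- integer(max(comp))
  nxt <- 1L
  for (p in ord) {
    if (labels[comp[p]] == 0L) {
      labels[comp[p]] <- nxt
      nxt <- nxt + 1L
    }
  }
  pairs$region <- paste0("R", labels[comp])
  boxes <- do.call(rbind, lapply(seq_len(nxt - 1L), function(k) {
    sel <- labels[comp] == k
    data.frame(region = paste0("R", k), n_pairs = sum(sel),
               i_min = min(pairs$i[sel]), i_max = max(pairs$i[sel]),
               j_min = min(pairs$j[sel]), j_max = max(pairs$j[sel]))
  }))
  attr(pairs, "regions") <- boxes
  pairs
}

#' Assemble mutually mutative position groups
#'
#' Treats coupled pairs as edges of an undirected graph on positions and
#' returns its connected components: sets of positions linked directly or
#' transitively by strong mutation coupling, interpreted as mutually
#' constraining evolutionary units.
#'
#' @param pairs A `cmca_pairs` data frame.
#' @param min_size Smallest component size to report. Default 2 (every
#'   coupled component); 3 restricts to multi-position networks.
#' @return A list of `cmca_group` lists, each with `members` (sorted reduced
#'   positions), `pairs` (supporting pair rows), and `size`. Ordered by
#'   smallest member.
#' @export
build_groups <- function(pairs, min_size = 2L) {
  stopifnot(inherits(pairs, "data.frame"))
  stopifnot(min_size >= 2L)
  if (nrow(pairs) == 0L) return(list())
  verts <- sort(unique(c(pairs$i, pairs$j)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs$i), to = as.character(pairs$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(verts))
  )
  comp <- igraph::components(g)$membership
  groups <- lapply(split(as.integer(names(comp)), comp), sort)
  groups <- Filter(function(m) length(m) >= min_size, groups)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  lapply(groups, function(m) {
    sel <- pairs$i %in% m & pairs$j %in% m
    structure(list(members = m, pairs = pairs[sel, , drop = FALSE],
                   size = length(m)),
              class = "cmca_group")
  })
}

#' @export
print.cmca_group <- function(x, ...) {
  cat("cmca_group: (", paste(x$members, collapse = ", "), "), ",
      nrow(x$pairs), " supporting pair(s)\n", sep = "")
  invisible(x)
}

.ref_label <- function(position_map, reduced_pos) {
  # reference residue number of a reduced position, or "-" for a reference gap
  if (is.null(position_map$reference)) return(rep(NA_character_,
                                                  length(reduced_pos)))
  num <- position_map$reference$numbering[reduced_pos]
  ifelse(is.na(num), "-", as.character(num))
}

#' Build the coupling report
#'
#' Collects pairs, regions and groups into one machine-readable report with
#' both numbering systems: reduced-alignment positions and, when a reference
#' sequence was mapped, its residue numbering ("-" where the reference is
#' gapped).
#'
#' @param pairs A `cmca_pairs` data frame, optionally with a `region` column
#'   from [cluster_regions()].
#' @param groups Output of [build_groups()].
#' @param position_map A `cmca_posmap`, used for reference numbering.
#' @param undefined Integer positions with undefined correlations.
#' @param parameters Named list of run parameters, stored verbatim.
#' @return A `cmca_report` list with `pairs` (data frame: region, i, j, r,
#'   ref_i, ref_j), `regions`, `groups`, `undefined_positions`, and
#'   `parameters`.
#' @export
coupling_report <- function(pairs, groups, position_map,
                            undefined = integer(0), parameters = list()) {
  stopifnot(inherits(position_map, "cmca_posmap"))
  L <- length(position_map$kept)
  if (nrow(pairs) > 0L && (max(pairs$i) > L || min(pairs$j) < 1L)) {
    stop("pair positions outside 1..", L, ": inconsistent inputs")
  }
  tab <- data.frame(
    region = if ("region" %in% names(pairs)) pairs$region
             else rep(NA_character_, nrow(pairs)),
    i = pairs$i, j = pairs$j,
    r = pairs$r,
    ref_i = .ref_label(position_map, pairs$i),
    ref_j = .ref_label(position_map, pairs$j),
    stringsAsFactors = FALSE
  )
  if ("region" %in% names(pairs) && nrow(tab) > 0L) {
    rnum <- as.integer(sub("^R", "", tab$region))
    tab <- tab[order(rnum, tab$i, tab$j), , drop = FALSE]
    rownames(tab) <- NULL
  }
  grp <- lapply(groups, function(g) {
    list(members = g$members,
         members_reference = .ref_label(position_map, g$members),
         n_pairs = nrow(g$pairs))
  })
  structure(
    list(pairs = tab,
         regions = attr(pairs, "regions"),
         groups = grp,
         undefined_positions = as.integer(undefined),
         parameters = parameters),
    class = "cmca_report"
  )
}

#' @export
print.cmca_report <- function(x, ...) {
  cat("cmca_report:", nrow(x$pairs), "pair(s),",
      if (is.null(x$regions)) 0L else nrow(x$regions), "region(s),",
      length(x$groups), "group(s)\n")
  invisible(x)
}

#' Write a coupling report as TSV and JSON
#'
#' `write_pairs_tsv()` renders the pair table in the conventional layout
#' (region, pair in reduced numbering, coefficient at 6 decimals, pair in
#' reference numbering, "-" for reference gaps). `write_report_json()`
#' serializes the full report.
#'
#' @param report A `cmca_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pairs_tsv <- function(report, path) {
  stopifnot(inherits(report, "cmca_report"))
  tab <- report$pairs
  lines <- c(paste(c("region", "i", "j", "r", "ref_i", "ref_j"),
                   collapse = "\t"))
  if (nrow(tab) > 0L) {
    lines <- c(lines, vapply(seq_len(nrow(tab)), function(k) {
      paste(c(ifelse(is.na(tab$region[k]), "-", tab$region[k]),
              tab$i[k], tab$j[k],
              formatC(tab$r[k], format = "f", digits = 6),
              ifelse(is.na(tab$ref_i[k]), "-", tab$ref_i[k]),
              ifelse(is.na(tab$ref_j[k]), "-", tab$ref_j[k])),
            collapse = "\t")
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pairs_tsv
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cmca_report"))
  obj <- list(
    pairs = report$pairs,
    regions = report$regions,
    groups = report$groups,
    undefined_positions = report$undefined_positions,
    parameters = report$parameters
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")
  invisible(path)
}
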