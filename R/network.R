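# Partition of strong pairs into common / normal-specific / disease-specific
# networks, edge thicknesses, Pajek export, degree report.

#' Linear edge-thickness transform
#'
#' Maps coexpression levels in `[C_star, C_max]` linearly onto display
#' thicknesses in `[1, 6]`: the threshold level draws at 1 point, the maximum
#' level at 6. If the network is degenerate (`C_max == C_star`, a single
#' level), every thickness is 1 and a message is emitted.
#'
#' @param C Numeric vector of coexpression levels, each in
#'   `[C_star, C_max]`.
#' @param C_star Threshold level (lower endpoint).
#' @param C_max Maximum level within the network being drawn.
#' @return Numeric vector of thicknesses in `[1, 6]`.
#' @examples
#' edge_thickness(c(0.4, 0.7, 1), C_star = 0.4, C_max = 1)
#' @export
edge_thickness <- function(C, C_star, C_max) {
  if (C_max < C_star) stop("`C_max` must be at least `C_star`")
  if (length(C) == 0L) return(numeric(0))
  if (any(C < C_star - 1e-9 | C > C_max + 1e-9))
    stop("all levels must lie in [C_star, C_max]")
  if (C_max == C_star) {
    message("degenerate single-level network: all thicknesses set to 1")
    return(rep(1, length(C)))
  }
  pmin(pmax(1 + 5 * (C - C_star) / (C_max - C_star), 1), 6)
}

#' Partition strong pairs into common and group-specific networks
#'
#' Pairs strongly coexpressed (level `>= C_star`) in both groups form the
#' common network; pairs strong in only the disease or only the normal group
#' form the disease-specific and normal-specific networks. Pairs weak in
#' both groups appear nowhere. The three edge sets are disjoint and satisfy
#' `|common| + |disease_specific| =` number of disease-strong pairs (and the
#' normal analogue).
#'
#' Each edge carries a display level `C_used` -- the group's own level for
#' the specific networks, `max(C_d, C_n)` for common edges -- and a thickness
#' computed by [edge_thickness()] within its own network, using that
#' network's maximum level as `C_max`.
#'
#' @param table A [coexpression_table()].
#' @param C_star Threshold in `[0, 1]`, typically from
#'   [optimal_threshold()].
#' @return An object of class `"network_partition"`: list with data.frames
#'   `common`, `normal_specific`, `disease_specific` (columns `gene_a`,
#'   `gene_b`, `r_d`, `r_n`, `C_used`, `thickness`) and the `C_star` used.
#' @export
partition_network <- function(table, C_star) {
  if (!is.numeric(C_star) || length(C_star) != 1L || C_star < 0 || C_star > 1)
    stop("`C_star` must be a single value in [0, 1]")
  ok <- stats::complete.cases(table[c("C_d", "C_n")])
  tab <- as.data.frame(table)[ok, , drop = FALSE]
  strong_d <- tab$C_d >= C_star
  strong_n <- tab$C_n >= C_star

  build <- function(rows, C_used) {
    edges <- data.frame(tab[rows, c("gene_a", "gene_b", "r_d", "r_n")],
                        C_used = C_used[rows], stringsAsFactors = FALSE)
    edges <- sort_edges(edges)
    edges$thickness <- if (nrow(edges))
      suppressMessages(edge_thickness(edges$C_used, C_star,
                                      max(edges$C_used)))
    else numeric(0)
    edges
  }
  structure(list(
    common = build(strong_d & strong_n, pmax(tab$C_d, tab$C_n)),
    normal_specific = build(strong_n & !strong_d, tab$C_n),
    disease_specific = build(strong_d & !strong_n, tab$C_d),
    C_star = C_star),
    class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat("Coexpression network partition at C* =",
      format(x$C_star, digits = 4), "\n")
  cat("  common:           ", nrow(x$common), "edges\n")
  cat("  normal-specific:  ", nrow(x$normal_specific), "edges\n")
  cat("  disease-specific: ", nrow(x$disease_specific), "edges\n")
  invisible(x)
}

#' Write an edge set as a Pajek .net file
#'
#' Produces a plain-text Pajek network file: a `*Vertices N` section listing
#' each gene once (1-based contiguous ids, quoted labels, stable
#' alphabetical order) followed by a `*Edges` section (undirected) with one
#' `i j w` line per edge, `w` being the value of `weight_col` (by default
#' the display thickness).
#'
#' @param edges Data.frame with columns `gene_a`, `gene_b` and the weight
#'   column.
#' @param path Output path.
#' @param vertices Optional character vector of additional vertex labels to
#'   include even when isolated (e.g. the full gene panel).
#' @param allow_empty Permit writing a network with no edges (default
#'   `FALSE`).
#' @param weight_col Name of the edge-weight column (default
#'   `"thickness"`; a missing column writes weight 1).
#' @return `path`, invisibly.
#' @seealso [read_pajek()] for the inverse.
#' @export
write_pajek <- function(edges, path, vertices = NULL, allow_empty = FALSE,
                        weight_col = "thickness") {
  if (nrow(edges) == 0L && !allow_empty)
    stop("refusing to write an empty network (set allow_empty = TRUE)")
  labels <- sort(unique(c(as.character(vertices),
                          edges$gene_a, edges$gene_b)))
  if (!length(labels))
    stop("no vertices: supply `vertices` when writing an empty network")
  id <- stats::setNames(seq_along(labels), labels)
  w <- if (weight_col %in% names(edges)) edges[[weight_col]]
       else rep(1, nrow(edges))
  lines <- c(sprintf("*Vertices %d", length(labels)),
             sprintf('%d "%s"', seq_along(labels), labels),
             "*Edges",
             if (nrow(edges))
               sprintf("%d %d %s", id[edges$gene_a], id[edges$gene_b],
                       format(w, digits = 6, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Pajek .net file back into an edge set
#'
#' Parses the `*Vertices` and `*Edges` (or `*Arcs`) sections written by
#' [write_pajek()].
#'
#' @param path Path to a `.net` file.
#' @return Data.frame with `gene_a`, `gene_b` (canonical order) and
#'   `weight`; the vertex labels are in the `"vertices"` attribute.
#' @export
read_pajek <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  v_at <- grep("^\\*[Vv]ertices", lines)
  e_at <- grep("^\\*([Ee]dges|[Aa]rcs)", lines)
  if (length(v_at) != 1L || length(e_at) != 1L)
    stop("not a recognisable Pajek file: ", path)
  n_vert <- as.integer(sub("^\\*[Vv]ertices\\s+", "", lines[v_at]))
  vlines <- lines[(v_at + 1L):(v_at + n_vert)]
  ids <- as.integer(sub("^(\\d+)\\s.*$", "\\1", vlines))
  labels <- sub('^\\d+\\s+"(.*)".*$', "\\1", vlines)
  labels <- labels[order(ids)]

  elines <- if (e_at < length(lines)) lines[(e_at + 1L):length(lines)]
            else character(0)
  if (!length(elines)) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(elines, "\\s+")
    i <- vapply(parts, function(p) as.integer(p[1L]), integer(1L))
    j <- vapply(parts, function(p) as.integer(p[2L]), integer(1L))
    w <- vapply(parts,
                function(p) if (length(p) > 2L) as.numeric(p[3L]) else 1,
                numeric(1L))
    out <- data.frame(canonical_pairs(labels[i], labels[j]), weight = w,
                      stringsAsFactors = FALSE)
    out <- sort_edges(out)
  }
  attr(out, "vertices") <- labels
  out
}

#' Per-gene connection counts of a network
#'
#' Counts the edges incident to each gene, for hub identification.
#'
#' @param edges Data.frame with columns `gene_a`, `gene_b`.
#' @param vertices Optional labels to report with degree 0 when isolated.
#' @return Data.frame (`gene`, `degree`) sorted by decreasing degree, ties
#'   alphabetical.
#' @export
degree_report <- function(edges, vertices = NULL) {
  genes <- sort(unique(c(as.character(vertices), edges$gene_a,
                         edges$gene_b)))
  counts <- table(factor(c(edges$gene_a, edges$gene_b), levels = genes))
  out <- data.frame(gene = genes, degree = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flatten a network partition to a single edge list
#'
#' @param partition A [partition_network()] result.
#' @return Data.frame with the three edge sets stacked and a `class` column
#'   (`common`, `normal_specific`, `disease_specific`).
#' @export
partition_edges <- function(partition) {
  stopifnot(inherits(partition, "network_partition"))
  pieces <- lapply(c("common", "normal_specific", "disease_specific"),
                   function(cl) {
                     e <- partition[[cl]]
                     if (nrow(e)) e$class <- cl
                     else e$class <- character(0)
                     e
                   })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
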