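# miRNA / transcription-factor regulatory signatures over a strong-pair
# network: per-regulator covered pairs, the >=4-pair selection rule,
# merging on shared genes, and the MRS/TRS composite (CRS).

#' Read a regulator-to-target annotation table
#'
#' Tab-delimited, one target per line: `regulator_id`, `class` (`miRNA` or
#' `TF`), `target_symbol`. A header line is tolerated and dropped.
#'
#' @param path File path.
#' @return Data.frame with columns `regulator`, `class`, `target`.
#' @export
read_regulator_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("annotation file must have 3 tab-delimited columns: ",
         "regulator, class, target")
  df <- data.frame(regulator = vapply(fields, `[`, character(1L), 1L),
                   class = vapply(fields, `[`, character(1L), 2L),
                   target = vapply(fields, `[`, character(1L), 3L),
                   stringsAsFactors = FALSE)
  if (nrow(df) && !(df$class[1L] %in% c("miRNA", "TF")))
    df <- df[-1L, , drop = FALSE]  # header line
  bad <- setdiff(unique(df$class), c("miRNA", "TF"))
  if (length(bad))
    stop("regulator class must be 'miRNA' or 'TF'; found: ",
         paste(bad, collapse = ", "))
  rownames(df) <- NULL
  df
}

#' @noRd
new_signature <- function(regulators, targets, pairs, merged = FALSE) {
  pairs <- sort_edges(pairs)
  regulators <- regulators[order(regulators$regulator), , drop = FALSE]
  rownames(regulators) <- NULL
  structure(list(
    regulators = regulators,
    targets = targets[order(names(targets))],
    pairs = pairs,
    genes = sort(unique(c(pairs$gene_a, pairs$gene_b))),
    merged = merged),
    class = "regulatory_signature")
}

#' @export
print.regulatory_signature <- function(x, ...) {
  cat("Regulatory signature",
      if (x$merged) "(merged)" else "", "\n")
  cat("  regulators:",
      paste(sprintf("%s [%s]", x$regulators$regulator, x$regulators$class),
            collapse = ", "), "\n")
  cat("  covered pairs:", nrow(x$pairs),
      " covered genes:", length(x$genes), "\n")
  invisible(x)
}

#' Network pairs covered by one regulator
#'
#' A strongly coexpressed pair is covered when both endpoint genes are
#' putative targets of the regulator (`rule = "both"`, the default); the
#' permissive alternative `rule = "any"` requires only one endpoint.
#'
#' @param edges Data.frame of network edges (`gene_a`, `gene_b`, ...).
#' @param targets Character vector of the regulator's target gene symbols.
#' @param rule Endpoint rule, `"both"` or `"any"`.
#' @return The subset of `edges` covered (always a subset of the input).
#' @export
covered_pairs <- function(edges, targets, rule = c("both", "any")) {
  rule <- match.arg(rule)
  a_in <- edges$gene_a %in% targets
  b_in <- edges$gene_b %in% targets
  keep <- if (rule == "both") a_in & b_in else a_in | b_in
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select regulatory signatures covering enough gene pairs
#'
#' For every annotated regulator, collects the network pairs it covers and
#' keeps the regulator as a signature when the covered-pair count is at
#' least `min_pairs` ("no less than" is inclusive: exactly `min_pairs`
#' covered pairs selects). All regulators, selected or not, are listed with
#' their pair and gene counts in the `"report"` attribute.
#'
#' @param edges Data.frame of network edges (`gene_a`, `gene_b`, ...).
#' @param annotations Data.frame as returned by
#'   [read_regulator_annotations()].
#' @param min_pairs Minimum covered-pair count (default 4).
#' @param rule Endpoint rule passed to [covered_pairs()].
#' @return List of `"regulatory_signature"` objects (one per selected
#'   regulator) with attribute `"report"`: a data.frame `regulator`,
#'   `class`, `n_pairs`, `n_genes`, `selected`.
#' @export
select_signatures <- function(edges, annotations, min_pairs = 4,
                              rule = c("both", "any")) {
  rule <- match.arg(rule)
  if (min_pairs < 1) stop("`min_pairs` must be at least 1")
  stopifnot(all(c("regulator", "class", "target") %in% names(annotations)))
  cls <- tapply(annotations$class, annotations$regulator,
                function(x) unique(x))
  if (any(lengths(cls) > 1L))
    stop("regulator annotated with more than one class: ",
         paste(names(cls)[lengths(cls) > 1L], collapse = ", "))
  targets_of <- tapply(annotations$target, annotations$regulator,
                       function(x) unique(as.character(x)), simplify = FALSE)

  regs <- sort(names(targets_of))
  sigs <- list()
  report <- data.frame(regulator = regs,
                       class = vapply(cls[regs], `[`, character(1L), 1L),
                       n_pairs = 0L, n_genes = 0L, selected = FALSE,
                       stringsAsFactors = FALSE)
  for (k in seq_along(regs)) {
    cp <- covered_pairs(edges, targets_of[[regs[k]]], rule = rule)
    report$n_pairs[k] <- nrow(cp)
    report$n_genes[k] <- length(unique(c(cp$gene_a, cp$gene_b)))
    if (nrow(cp) >= min_pairs) {
      report$selected[k] <- TRUE
      sigs[[regs[k]]] <- new_signature(
        regulators = data.frame(regulator = regs[k],
                                class = report$class[k],
                                stringsAsFactors = FALSE),
        targets = stats::setNames(list(targets_of[[regs[k]]]), regs[k]),
        pairs = cp)
    }
  }
  structure(unname(sigs), report = report)
}

#' Merge signatures that share covered genes
#'
#' Signatures of one class whose covered gene sets overlap are combined:
#' connected components of the gene-overlap relation are each emitted as one
#' merged signature (union of regulators, targets and covered pairs). The
#' result is independent of the input order.
#'
#' @param signatures List of `"regulatory_signature"` objects (typically one
#'   class, miRNA or TF).
#' @return List of merged `"regulatory_signature"` objects, one per
#'   component, ordered by their first gene; components combining more than
#'   one signature carry `merged = TRUE`.
#' @export
merge_signatures <- function(signatures) {
  if (!length(signatures)) return(list())
  for (s in signatures)
    if (!inherits(s, "regulatory_signature"))
      stop("`signatures` must be a list of regulatory_signature objects")

  # union-find over shared covered genes
  comp <- seq_along(signatures)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_along(signatures))
    for (j in seq_len(i - 1L))
      if (length(intersect(signatures[[i]]$genes, signatures[[j]]$genes)))
        comp[find(i)] <- find(j)
  roots <- vapply(seq_along(signatures), find, integer(1L))

  merged <- lapply(unique(roots), function(r) {
    members <- signatures[roots == r]
    pairs <- unique(do.call(rbind, lapply(members, `[[`, "pairs")))
    new_signature(
      regulators = unique(do.call(rbind,
                                  lapply(members, `[[`, "regulators"))),
      targets = do.call(c, lapply(members, `[[`, "targets")),
      pairs = pairs,
      merged = length(members) > 1L)
  })
  merged[order(vapply(merged,
                      function(s) if (length(s$genes)) s$genes[1L] else "",
                      character(1L)))]
}

#' Composite regulatory signature (CRS)
#'
#' Intersects the covered pairs of a miRNA signature network (MRS) and a TF
#' signature network (TRS). The composite's regulators are the regulators of
#' either input, of both classes, whose target sets contain every gene of
#' the intersection. An empty intersection yields a valid empty composite
#' (reported via a message).
#'
#' @param mrs,trs `"regulatory_signature"` objects (possibly merged).
#' @return A `"regulatory_signature"` whose pair set is the intersection;
#'   always a subset of both inputs.
#' @export
composite_signature <- function(mrs, trs) {
  stopifnot(inherits(mrs, "regulatory_signature"),
            inherits(trs, "regulatory_signature"))
  keys_trs <- pair_key(trs$pairs$gene_a, trs$pairs$gene_b)
  keep <- pair_key(mrs$pairs$gene_a, mrs$pairs$gene_b) %in% keys_trs
  pairs <- mrs$pairs[keep, , drop = FALSE]
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  if (!nrow(pairs))
    message("MRS and TRS pair sets are disjoint: empty composite signature")

  all_regs <- unique(rbind(mrs$regulators, trs$regulators))
  all_targets <- c(mrs$targets, trs$targets)
  all_targets <- all_targets[!duplicated(names(all_targets))]
  covers <- vapply(all_regs$regulator, function(rg) {
    length(genes) > 0L && all(genes %in% all_targets[[rg]])
  }, logical(1L))
  new_signature(regulators = all_regs[covers, , drop = FALSE],
                targets = all_targets[all_regs$regulator[covers]],
                pairs = pairs)
}
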