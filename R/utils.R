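# Internal helpers shared across modules.

# Canonical (lexicographically sorted) unordered pair representation.
# Returns a data.frame with gene_a < gene_b row-wise.
#' @noRd
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (any(a == b)) stop("a gene cannot be paired with itself")
  swap <- a > b
  ga <- ifelse(swap, b, a)
  gb <- ifelse(swap, a, b)
  data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
}

# Collision-free key for an already-canonical pair.
#' @noRd
pair_key <- function(gene_a, gene_b) {
  paste(gene_a, gene_b, sep = "\r")
}

#' @noRd
group_levels <- function() c("disease", "normal")

# Sort edge rows canonically (gene_a, then gene_b) for deterministic output.
#' @noRd
sort_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  out <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
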