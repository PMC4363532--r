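# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk except the shipped
# synthetic demo annotation files.

# Small random dataset with no planted structure.
random_dataset <- function(n_genes = 5, n_disease = 6, n_normal = 6,
                           seed = 1) {
  set.seed(seed)
  values <- matrix(rnorm(n_genes * (n_disease + n_normal)), n_genes,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("s%02d",
                                           seq_len(n_disease + n_normal))))
  expression_dataset(values, rep(c("disease", "normal"),
                                 c(n_disease, n_normal)))
}

# Random coexpression table (valid pair universe over a synthetic panel).
random_pair_table <- function(n_genes = 10, seed = 1) {
  set.seed(seed)
  ij <- t(combn(n_genes, 2))
  genes <- sprintf("g%02d", seq_len(n_genes))
  r_d <- runif(nrow(ij), -1, 1)
  r_n <- runif(nrow(ij), -1, 1)
  structure(
    data.frame(gene_a = genes[ij[, 1]], gene_b = genes[ij[, 2]],
               r_d = r_d, r_n = r_n, C_d = abs(r_d), C_n = abs(r_n),
               stringsAsFactors = FALSE),
    class = c("coexpression_table", "data.frame"),
    n_genes = n_genes, n_undefined = 0L)
}

# A coexpression table with prescribed strong/weak counts per group:
# `n_strong_d` of the disease levels sit at `strong`, the rest at `weak`,
# and likewise for normal; membership overlap is controlled by `n_common`.
counted_pair_table <- function(n_pairs, n_strong_d, n_strong_n,
                               n_common = min(n_strong_d, n_strong_n),
                               strong = 0.9, weak = 0.1) {
  stopifnot(n_common <= n_strong_d, n_common <= n_strong_n,
            n_strong_d + n_strong_n - n_common <= n_pairs)
  # enough genes for n_pairs pairs
  n_genes <- ceiling((1 + sqrt(1 + 8 * n_pairs)) / 2)
  ij <- t(combn(n_genes, 2))[seq_len(n_pairs), , drop = FALSE]
  genes <- sprintf("g%03d", seq_len(n_genes))
  C_d <- rep(weak, n_pairs)
  C_n <- rep(weak, n_pairs)
  C_d[seq_len(n_strong_d)] <- strong
  # common pairs first, then normal-only strong pairs after the disease ones
  n_only <- n_strong_n - n_common
  C_n[seq_len(n_common)] <- strong
  if (n_only > 0)
    C_n[n_strong_d + seq_len(n_only)] <- strong
  structure(
    data.frame(gene_a = genes[ij[, 1]], gene_b = genes[ij[, 2]],
               r_d = C_d, r_n = C_n, C_d = C_d, C_n = C_n,
               stringsAsFactors = FALSE),
    class = c("coexpression_table", "data.frame"),
    n_genes = n_genes, n_undefined = 0L)
}

demo_path <- function(f) system.file("extdata", f, package = "dcnet")

demo_edges <- function() {
  read.delim(demo_path("synthetic_demo_edges.tsv"),
             stringsAsFactors = FALSE)
}

demo_annotations <- function() {
  read_regulator_annotations(demo_path("synthetic_demo_regulators.tsv"))
}
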