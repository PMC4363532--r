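# Synthetic two-group expression data with planted correlation blocks.

#' Specify a planted correlation block
#'
#' A block is a set of genes whose pairwise population Pearson correlation is
#' forced to a common target value in one or both sample groups. Blocks are
#' the planting mechanism of [simulate_expression()].
#'
#' A block of `k` genes with uniform correlation `r` has a positive
#' semi-definite correlation matrix only for `r >= -1/(k-1)`, so strongly
#' negative blocks are restricted to gene pairs (`k = 2`).
#'
#' @param genes Integer indices (distinct, >= 2) into the simulated gene
#'   panel.
#' @param r Target signed correlation in `[-1, 1]`.
#' @param groups Which groups the block applies to: a subset of
#'   `c("disease", "normal")` (default both).
#' @return An object of class `"correlation_block"`.
#' @examples
#' correlation_block(1:3, 0.9, "normal")
#' @export
correlation_block <- function(genes, r, groups = c("disease", "normal")) {
  genes <- as.integer(genes)
  if (length(genes) < 2L || anyDuplicated(genes) || any(genes < 1L))
    stop("`genes` must be at least two distinct positive indices")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) > 1)
    stop("`r` must be a single correlation in [-1, 1]")
  groups <- match.arg(groups, several.ok = TRUE)
  if (r < -1 / (length(genes) - 1L))
    stop(sprintf(paste0("block on genes {%s}: uniform correlation %.3f is ",
                        "not positive semi-definite for %d genes ",
                        "(needs r >= %.3f)"),
                 paste(genes, collapse = ", "), r, length(genes),
                 -1 / (length(genes) - 1L)))
  structure(list(genes = genes, r = r, groups = groups),
            class = "correlation_block")
}

#' @noRd
build_group_correlation <- function(n_genes, blocks, group) {
  R <- diag(n_genes)
  used <- integer(0)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    if (!(group %in% b$groups)) next
    if (max(b$genes) > n_genes)
      stop("block ", k, " references gene index ", max(b$genes),
           " beyond the ", n_genes, "-gene panel")
    clash <- intersect(used, b$genes)
    if (length(clash))
      stop("blocks overlap on gene index ", paste(clash, collapse = ", "),
           " within the ", group,
           " group; overlapping blocks are rejected, not merged")
    R[b$genes, b$genes] <- b$r
    diag(R)[b$genes] <- 1
    used <- c(used, b$genes)
  }
  # blocks are disjoint, so per-block PSD (checked in correlation_block())
  # implies global PSD; assert anyway against numerical surprises
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("implied ", group, " correlation matrix is not positive ",
         "semi-definite (min eigenvalue ", format(min(ev)), ")")
  R
}

#' Simulate two-group expression data with planted correlations
#'
#' Draws, independently for the disease and the normal group, samples from a
#' multivariate normal with unit variances and block-structured correlation:
#' within each [correlation_block()] that applies to the group, every gene
#' pair has the block's target population correlation; all other pairs are
#' independent. Optional iid measurement noise with standard deviation
#' `noise_sd` is added on top; it attenuates the planted correlations by the
#' factor `1/(1 + noise_sd^2)` (the default `0` leaves them exact).
#'
#' A constant `baseline` is added to every value to mimic log-scale array
#' intensities; it has no effect on any correlation. Runs are bit-reproducible
#' for a fixed `seed`.
#'
#' @param n_genes Number of genes (default 20, the analysis panel size).
#' @param n_disease,n_normal Samples per group (defaults 16 and 8, the study
#'   design this generator emulates). Each must be at least 3.
#' @param blocks List of [correlation_block()] objects. Blocks may not share
#'   genes within a group.
#' @param noise_sd Standard deviation of additional iid noise (default 0).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param baseline Constant added to all values (default 8).
#' @param gene_names Optional character vector of row names (default
#'   `g01, g02, ...`).
#' @return An [expression_dataset()] with samples `CML_01..` (disease) and
#'   `NOR_01..` (normal).
#' @examples
#' ds <- simulate_expression(
#'   blocks = list(correlation_block(1:2, 0.95)), seed = 1)
#' cor(ds$values["g01", ], ds$values["g02", ])
#' @export
simulate_expression <- function(n_genes = 20, n_disease = 16, n_normal = 8,
                                blocks = list(), noise_sd = 0, seed = NULL,
                                baseline = 8, gene_names = NULL) {
  if (n_genes < 2L) stop("need at least 2 genes")
  if (n_disease < 3L || n_normal < 3L)
    stop("each group needs at least 3 samples; Pearson correlation is ",
         "degenerate below that")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be a non-negative number")
  if (is.null(gene_names)) gene_names <- sprintf("g%02d", seq_len(n_genes))
  stopifnot(length(gene_names) == n_genes, !anyDuplicated(gene_names))
  for (b in blocks)
    if (!inherits(b, "correlation_block"))
      stop("`blocks` must be a list of correlation_block objects")

  R_d <- build_group_correlation(n_genes, blocks, "disease")
  R_n <- build_group_correlation(n_genes, blocks, "normal")

  if (!is.null(seed)) set.seed(as.integer(seed))
  draw <- function(R, n) {
    x <- t(MASS::mvrnorm(n, mu = rep(0, n_genes), Sigma = R, tol = 1e-8))
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow(x))
    x
  }
  values <- baseline + cbind(draw(R_d, n_disease), draw(R_n, n_normal))
  dimnames(values) <- list(
    gene_names,
    c(sprintf("CML_%02d", seq_len(n_disease)),
      sprintf("NOR_%02d", seq_len(n_normal))))
  expression_dataset(values, rep(group_levels(), c(n_disease, n_normal)))
}

#' Study-like fixture with known planted pair categories
#'
#' Generates a 20-gene two-group dataset whose planted correlation structure
#' spans the three strong-pair categories the downstream partition should
#' recover, plus independent control pairs:
#'
#' * genes `g01..g12`: pairwise `r = 0.9` in the normal group only
#'   (66 `normal_specific` pairs);
#' * genes `g13..g15`: pairwise `r = 0.95` in both groups (3 `common` pairs);
#' * genes `g16, g17`: `r = -0.95` in the disease group only (1
#'   `disease_specific` pair; negative, so the sign-erasing coexpression
#'   measure is exercised);
#' * genes `g18..g20`: fully independent; their 3 mutual pairs are labelled
#'   `absent` as controls.
#'
#' Only planted block pairs and the designated control pairs are labelled:
#' the classification of unplanted background cross pairs at a finite sample
#' size is boundary noise at the fitted threshold, not planted truth.
#'
#' @param seed Integer seed (required; the fixture is meant to be
#'   reproducible).
#' @param n_disease,n_normal Samples per group; defaults mirror the
#'   emulated study (16 disease, 8 normal). Use 200/200 for
#'   parameter-recovery checks.
#' @param noise_sd Passed to [simulate_expression()].
#' @return A list with `dataset` (an [expression_dataset()]) and `planted`,
#'   a data.frame of labelled pairs (`gene_a`, `gene_b`, `category`).
#' @examples
#' fx <- simulate_planted_fixture(seed = 1)
#' table(fx$planted$category)
#' @export
simulate_planted_fixture <- function(seed, n_disease = 16, n_normal = 8,
                                     noise_sd = 0) {
  blocks <- list(
    correlation_block(1:12, 0.9, "normal"),
    correlation_block(13:15, 0.95, c("disease", "normal")),
    correlation_block(16:17, -0.95, "disease"))
  dataset <- simulate_expression(
    n_genes = 20, n_disease = n_disease, n_normal = n_normal,
    blocks = blocks, noise_sd = noise_sd, seed = seed)

  genes <- rownames(dataset$values)
  label_block <- function(idx, category) {
    combos <- utils::combn(genes[idx], 2L)
    cbind(canonical_pairs(combos[1L, ], combos[2L, ]),
          category = category)
  }
  planted <- rbind(
    label_block(1:12, "normal_specific"),
    label_block(13:15, "common"),
    label_block(16:17, "disease_specific"),
    label_block(18:20, "absent"))
  rownames(planted) <- NULL
  list(dataset = dataset, planted = planted)
}
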