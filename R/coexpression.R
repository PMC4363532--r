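# Per-group signed correlation and absolute coexpression level per gene pair.

#' Pearson correlation with explicit degeneracy handling
#'
#' Standard sample Pearson correlation, but a zero-variance input yields
#' `NA` with a warning instead of silently returning anything: a constant
#' profile has no defined coexpression.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Signed correlation in `[-1, 1]`, or `NA` if either input has zero
#'   variance or contains missing values.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) {
    warning("missing values: correlation undefined")
    return(NA_real_)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero-variance input: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Coexpression table of all unordered gene pairs
#'
#' For every unordered gene pair, computes the signed Pearson correlation
#' separately across the disease samples (`r_d`) and the normal samples
#' (`r_n`), and the coexpression levels `C_d = |r_d|`, `C_n = |r_n|` in
#' `[0, 1]`. The absolute value erases the correlation sign so that both
#' activating and inhibiting relationships count as strong coexpression.
#'
#' Pairs whose correlation is undefined in either group (a constant profile,
#' or a missing value within that group's samples) keep their row with `NA`
#' entries; they are flagged here (message plus the `"n_undefined"`
#' attribute) and excluded from all downstream statistics.
#'
#' @param dataset An [expression_dataset()] with unique gene symbols
#'   (collapse probes first, see [select_panel()]).
#' @return A data.frame of class `"coexpression_table"` with columns
#'   `gene_a`, `gene_b` (lexicographically ordered within each row), `r_d`,
#'   `r_n`, `C_d`, `C_n`; one row per pair, `G*(G-1)/2` rows for `G` genes.
#'   Attributes: `"n_genes"`, `"n_undefined"`.
#' @examples
#' fx <- simulate_planted_fixture(seed = 1)
#' tab <- coexpression_table(fx$dataset)
#' nrow(tab) # 190 pairs for 20 genes
#' @export
coexpression_table <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  if (nrow(v) < 2L) stop("need at least 2 genes")
  dup <- unique(rownames(v)[duplicated(rownames(v))])
  if (length(dup))
    stop("duplicated gene symbols (collapse probes with select_panel() ",
         "first): ", paste(dup, collapse = ", "))

  group_cor <- function(group) {
    sub <- v[, dataset$groups == group, drop = FALSE]
    # a gene with any missing value in this group has undefined correlations
    # here; cor() with use = "everything" propagates exactly that as NA
    suppressWarnings(stats::cor(t(sub)))
  }
  cm_d <- group_cor("disease")
  cm_n <- group_cor("normal")

  ij <- t(utils::combn(nrow(v), 2L))
  pairs <- canonical_pairs(rownames(v)[ij[, 1L]], rownames(v)[ij[, 2L]])
  tab <- data.frame(pairs,
                    r_d = cm_d[ij], r_n = cm_n[ij],
                    stringsAsFactors = FALSE)
  tab$C_d <- abs(tab$r_d)
  tab$C_n <- abs(tab$r_n)

  n_undefined <- sum(!stats::complete.cases(tab))
  if (n_undefined > 0L)
    message(n_undefined, " pair(s) with undefined correlation flagged; ",
            "they are excluded from downstream statistics")
  structure(tab,
            class = c("coexpression_table", "data.frame"),
            n_genes = nrow(v), n_undefined = n_undefined)
}

#' Write or read a coexpression table as tab-delimited text
#'
#' @param table A [coexpression_table()].
#' @param path File path.
#' @return `write_coexpression_table()` returns `path` invisibly;
#'   `read_coexpression_table()` returns the table (class restored).
#' @export
write_coexpression_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coexpression_table
#' @export
read_coexpression_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "r_d", "r_n", "C_d", "C_n")
  if (!all(need %in% names(tab)))
    stop("coexpression table needs columns: ", paste(need, collapse = ", "))
  structure(tab, class = c("coexpression_table", "data.frame"),
            n_undefined = sum(!stats::complete.cases(tab)))
}
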