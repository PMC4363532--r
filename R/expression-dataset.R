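# Two-group expression container and tab-delimited IO.

#' Construct a two-group expression dataset
#'
#' Bundles a gene-by-sample expression matrix with a disease/normal sample
#' assignment and validates the two jointly. Values are used as provided
#' (typically normalized, log-scale intensities); no transform is applied
#' here. Pearson correlation needs at least three points, so each group must
#' contain at least three samples.
#'
#' @param values Numeric matrix with one row per gene (rownames are gene or
#'   probe symbols) and one column per sample (colnames are sample ids).
#'   `NA` entries are allowed -- a gene with a missing value inside a group is
#'   treated as having an undefined correlation in that group downstream --
#'   but infinite values are rejected. Duplicate row symbols are allowed and
#'   interpreted as multiple probes of one gene; collapse them with
#'   [select_panel()] before computing coexpression.
#' @param groups Character or factor with one entry per sample, each
#'   `"disease"` or `"normal"`. If named, names are matched against
#'   `colnames(values)`; otherwise column order is assumed.
#'
#' @return An object of class `"expression_dataset"`: a list with elements
#'   `values` (the matrix) and `groups` (factor aligned with the columns,
#'   levels `disease`, `normal`).
#' @examples
#' m <- matrix(rnorm(30), 5, 6,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
#' expression_dataset(m, rep(c("disease", "normal"), each = 3))
#' @export
expression_dataset <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene symbols as rownames and sample ids as colnames")
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop("duplicated sample ids: ", paste(dup, collapse = ", "))
  if (any(is.nan(values) | is.infinite(values)))
    stop("expression matrix contains NaN or infinite values")

  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("samples without a group assignment: ",
           paste(missing, collapse = ", "))
    groups <- groups[colnames(values)]
  } else if (length(groups) != ncol(values)) {
    stop("`groups` must have one entry per sample (got ", length(groups),
         " for ", ncol(values), " samples)")
  }
  bad <- setdiff(unique(as.character(groups)), group_levels())
  if (length(bad))
    stop("group labels must be 'disease' or 'normal'; found: ",
         paste(bad, collapse = ", "))
  groups <- factor(as.character(groups), levels = group_levels())
  names(groups) <- colnames(values)

  n_by_group <- table(groups)
  if (any(n_by_group < 3L))
    stop("each group needs at least 3 samples (disease: ",
         n_by_group[["disease"]], ", normal: ", n_by_group[["normal"]], ")")

  structure(list(values = values, groups = groups),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  n <- table(x$groups)
  cat("Two-group expression dataset\n")
  cat("  genes:  ", nrow(x$values), "\n", sep = "")
  cat("  samples:", ncol(x$values),
      sprintf(" (%d disease, %d normal)\n", n[["disease"]], n[["normal"]]),
      sep = "")
  if (anyDuplicated(rownames(x$values)))
    cat("  note: duplicated gene symbols present (probe-level rows);",
        "collapse with select_panel()\n")
  invisible(x)
}

#' Read an expression matrix and its sample-group file
#'
#' Reads a tab-delimited expression matrix (header row of sample ids, first
#' column gene/probe symbols) together with a two-column tab-delimited
#' sample-to-group file (`sample_id<TAB>group`, group being `disease` or
#' `normal`). Lines starting with `!` in the matrix file are skipped, so a
#' GEO series-matrix text layout can be read directly. A header line in the
#' groups file is tolerated and dropped.
#'
#' @param matrix_path Path to the tab-delimited expression matrix.
#' @param groups_path Path to the sample-group file.
#' @return An [expression_dataset()].
#' @seealso [write_expression()] for the inverse operation.
#' @export
read_expression <- function(matrix_path, groups_path) {
  if (!file.exists(matrix_path))
    stop("expression matrix not found: ", matrix_path)
  if (!file.exists(groups_path))
    stop("groups file not found: ", groups_path)
  lines <- readLines(matrix_path)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("expression matrix needs a header line and at least one gene row")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  sample_ids <- fields[[1L]][-1L]
  if (!length(sample_ids)) stop("no sample columns found in header")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicated sample ids in matrix header: ",
         paste(dup, collapse = ", "))

  body <- fields[-1L]
  n_fields <- lengths(body)
  if (any(n_fields != length(sample_ids) + 1L))
    stop("row ", which(n_fields != length(sample_ids) + 1L)[1L] + 1L,
         " has ", n_fields[n_fields != length(sample_ids) + 1L][1L],
         " fields; expected ", length(sample_ids) + 1L)
  genes <- vapply(body, `[`, character(1L), 1L)
  raw <- t(vapply(body, function(f) f[-1L], character(length(sample_ids))))
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(values) & !(trimws(raw) %in% c("", "NA", "na", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at gene row %d, sample column '%s'",
                 raw[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 sample_ids[bad[1L, 2L]]))
  dimnames(values) <- list(genes, sample_ids)

  grp <- read_group_file(groups_path)
  missing <- setdiff(sample_ids, names(grp))
  if (length(missing))
    stop("samples in matrix missing from groups file: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(grp), sample_ids)
  if (length(extra))
    warning("groups file lists samples absent from the matrix (ignored): ",
            paste(extra, collapse = ", "))

  expression_dataset(values, grp[sample_ids])
}

#' @noRd
read_group_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("groups file must be two tab-delimited columns: sample_id, group")
  ids <- vapply(fields, `[`, character(1L), 1L)
  grp <- vapply(fields, `[`, character(1L), 2L)
  # tolerate a header line
  if (length(grp) && !(grp[1L] %in% group_levels()) &&
      tolower(grp[1L]) %in% c("group", "label", "condition")) {
    ids <- ids[-1L]
    grp <- grp[-1L]
  }
  bad <- setdiff(unique(grp), group_levels())
  if (length(bad))
    stop("group labels must be 'disease' or 'normal'; found: ",
         paste(bad, collapse = ", "))
  stats::setNames(grp, ids)
}

#' Write an expression dataset as tab-delimited files
#'
#' Inverse of [read_expression()]: writes the matrix (first column `gene`,
#' then one column per sample) and the two-column sample-group file.
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,groups_path Output paths.
#' @return Invisibly, a character vector with the two paths.
#' @export
write_expression <- function(dataset, matrix_path, groups_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  header <- paste(c("gene", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], format(v[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), matrix_path)
  writeLines(paste(names(dataset$groups), as.character(dataset$groups),
                   sep = "\t"), groups_path)
  invisible(c(matrix_path, groups_path))
}

#' Restrict a dataset to a gene panel, collapsing probes to genes
#'
#' Keeps exactly one row per panel symbol found in the dataset, in panel
#' order. Symbols represented by several probe rows are collapsed with the
#' chosen rule; panel symbols absent from the dataset are reported via a
#' message and the `"missing_symbols"` attribute, never silently dropped.
#'
#' @param dataset An [expression_dataset()].
#' @param panel Character vector of unique gene symbols (at least 2).
#' @param collapse Probe-collapse rule: `"max_mean"` (default) keeps the probe
#'   row with the highest mean expression; `"mean"` averages the rows
#'   per sample.
#' @return An [expression_dataset()] restricted to the panel, with attribute
#'   `"missing_symbols"` listing panel symbols not found. The operation is
#'   idempotent and never changes samples or group labels.
#' @examples
#' fx <- simulate_planted_fixture(seed = 1)
#' sub <- select_panel(fx$dataset, c("g01", "g02", "g03"))
#' rownames(sub$values)
#' @export
select_panel <- function(dataset, panel,
                         collapse = c("max_mean", "mean")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  collapse <- match.arg(collapse)
  panel <- as.character(panel)
  if (anyDuplicated(panel)) stop("panel symbols must be unique")
  if (length(panel) < 2L) stop("panel needs at least 2 symbols")

  present <- panel[panel %in% rownames(dataset$values)]
  missing <- setdiff(panel, present)
  if (length(present) < 2L)
    stop("fewer than 2 panel symbols found in the dataset (found: ",
         length(present), ")")
  if (length(missing))
    message("panel symbols not found in the dataset: ",
            paste(missing, collapse = ", "))

  v <- dataset$values
  collapsed <- vapply(present, function(sym) {
    rows <- which(rownames(v) == sym)
    if (length(rows) == 1L) return(v[rows, ])
    if (collapse == "mean") {
      colMeans(v[rows, , drop = FALSE])
    } else {
      means <- rowMeans(v[rows, , drop = FALSE], na.rm = TRUE)
      v[rows[which.max(means)], ]
    }
  }, numeric(ncol(v)))
  out <- expression_dataset(t(collapsed), dataset$groups)
  attr(out, "missing_symbols") <- missing
  out
}
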