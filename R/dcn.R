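# The central fit: differential coexpression network estimation.

#' Fit a differential gene-coexpression network
#'
#' Runs the whole estimator on a two-group expression dataset: per-group
#' absolute Pearson coexpression for all gene pairs, selection of the
#' disease-associated threshold `C*` by maximizing the deviation `D` between
#' the groups' inverted empirical CDFs (two-sample Kolmogorov-Smirnov),
#' chi-square verification of the strong/weak dichotomy, and partition of the
#' strong pairs into common, normal-specific and disease-specific networks
#' with display thicknesses. If regulator annotations are supplied, miRNA and
#' TF regulatory signatures are enumerated on the two group-specific
#' networks, merged on shared genes, and intersected into composite
#' signatures.
#'
#' @param dataset An [expression_dataset()].
#' @param panel Optional character vector of gene symbols to restrict the
#'   analysis to (passed to [select_panel()], which also collapses probe
#'   rows).
#' @param collapse Probe-collapse rule for `panel`, see [select_panel()].
#' @param grid,step Threshold grid, see [survival_curves()].
#' @param annotations Optional regulator annotation data.frame
#'   ([read_regulator_annotations()]); `NULL` skips the signature stage.
#' @param min_pairs Minimum covered-pair count for signature selection
#'   (default 4).
#' @param rule Endpoint rule for pair coverage, see [covered_pairs()].
#' @return An object of class `"dcn"`: list with `pairs` (the
#'   [coexpression_table()]), `curve`, `C_star`, `D`, `ks_p`, `contingency`
#'   (2x2 strong/weak x disease/normal counts), `chi2`, `chi2_p`,
#'   `partition` (a [partition_network()] result), `signatures` (`NULL` or a
#'   list with per-network signature sets, merged networks and composites)
#'   and the matched `call`.
#' @examples
#' fx <- simulate_planted_fixture(seed = 1)
#' fit <- dcn(fx$dataset)
#' fit
#' coef(fit)
#' @export
dcn <- function(dataset, panel = NULL, collapse = c("max_mean", "mean"),
                grid = c("observed", "uniform"), step = 1e-4,
                annotations = NULL, min_pairs = 4,
                rule = c("both", "any")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  rule <- match.arg(rule)
  if (!is.null(panel))
    dataset <- select_panel(dataset, panel, collapse = match.arg(collapse))

  pairs <- coexpression_table(dataset)
  curve <- survival_curves(pairs, grid = match.arg(grid), step = step)
  opt <- optimal_threshold(curve)
  ks_p <- ks_pvalue(opt$D, curve$n_pairs, curve$n_pairs)
  contingency <- dichotomize(pairs, opt$C_star)
  chi <- chi_square(contingency)
  partition <- partition_network(pairs, opt$C_star)

  signatures <- NULL
  if (!is.null(annotations)) {
    run_class <- function(edges) {
      sigs <- select_signatures(edges, annotations, min_pairs = min_pairs,
                                rule = rule)
      report <- attr(sigs, "report")
      cls <- vapply(sigs, function(s) s$regulators$class[1L], character(1L))
      list(report = report,
           mrs = merge_signatures(sigs[cls == "miRNA"]),
           trs = merge_signatures(sigs[cls == "TF"]))
    }
    per_network <- lapply(
      list(normal_specific = partition$normal_specific,
           disease_specific = partition$disease_specific),
      function(edges) {
        res <- run_class(edges)
        res$crs <- if (length(res$mrs) && length(res$trs))
          mapply(composite_signature,
                 rep(res$mrs, each = length(res$trs)),
                 rep(res$trs, times = length(res$mrs)),
                 SIMPLIFY = FALSE)
        else list()
        res
      })
    signatures <- per_network
  }

  structure(list(pairs = pairs, curve = curve,
                 C_star = opt$C_star, D = opt$D, ks_p = ks_p,
                 contingency = contingency,
                 chi2 = chi$chi2, chi2_p = chi$p,
                 partition = partition, signatures = signatures,
                 n_genes = nrow(dataset$values),
                 n_samples = table(dataset$groups),
                 call = match.call()),
            class = "dcn")
}

#' @export
print.dcn <- function(x, ...) {
  cat("Differential coexpression network fit\n")
  cat(sprintf("  %d genes, %d pairs (%d disease / %d normal samples)\n",
              x$n_genes, x$curve$n_pairs,
              x$n_samples[["disease"]], x$n_samples[["normal"]]))
  cat(sprintf("  C* = %.4f   D = %.4f   KS p = %.3g\n",
              x$C_star, x$D, x$ks_p))
  cat(sprintf("  chi-square = %.4f (p = %.3g), no continuity correction\n",
              x$chi2, x$chi2_p))
  cat(sprintf("  edges: %d common, %d normal-specific, %d disease-specific\n",
              nrow(x$partition$common), nrow(x$partition$normal_specific),
              nrow(x$partition$disease_specific)))
  invisible(x)
}

#' @export
coef.dcn <- function(object, ...) {
  c(C_star = object$C_star, D = object$D)
}

#' @export
summary.dcn <- function(object, ...) {
  hubs <- lapply(object$partition[c("common", "normal_specific",
                                    "disease_specific")],
                 function(e) utils::head(degree_report(e), 5L))
  structure(list(fit = object, hubs = hubs), class = "summary.dcn")
}

#' @export
print.summary.dcn <- function(x, ...) {
  print(x$fit)
  cat("\nContingency table (pairs at C*):\n")
  print(x$fit$contingency)
  for (nm in names(x$hubs)) {
    if (!nrow(x$hubs[[nm]])) next
    cat("\nTop hubs,", gsub("_", "-", nm), "network:\n")
    print(x$hubs[[nm]], row.names = FALSE)
  }
  if (!is.null(x$fit$signatures)) {
    for (nm in names(x$fit$signatures)) {
      rep <- x$fit$signatures[[nm]]$report
      cat("\nRegulators on the", gsub("_", "-", nm), "network",
          "(selected cover >= min_pairs pairs):\n")
      print(rep, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Plot the inverted CDFs of a fit
#'
#' Draws `F_d(t) = Prob(C_d >= t)` and `F_n(t) = Prob(C_n >= t)` as step
#' curves with the fitted threshold `C*` marked; the vertical gap at `C*` is
#' the KS deviation `D`.
#'
#' @param x A [dcn()] fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dcn <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$thresholds, cv$F_d, type = "s", col = "firebrick",
                 lwd = 2, xlab = "coexpression threshold C",
                 ylab = "fraction of pairs with level >= C",
                 main = "Inverted empirical CDFs", ylim = c(0, 1), ...)
  graphics::lines(cv$thresholds, cv$F_n, type = "s", col = "navy", lwd = 2)
  graphics::abline(v = x$C_star, lty = 2)
  graphics::legend("topright",
                   legend = c("disease", "normal",
                              sprintf("C* = %.4f (D = %.4f)",
                                      x$C_star, x$D)),
                   col = c("firebrick", "navy", "black"),
                   lty = c(1, 1, 2), lwd = c(2, 2, 1), bty = "n")
  invisible(x)
}
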