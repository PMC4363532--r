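# End-to-end pipeline: config-driven orchestration with reproducible
# file outputs.

#' Write the threshold report
#'
#' Plain-text report (full precision plus 4-decimal display) and a
#' machine-readable YAML twin with the fitted threshold, KS statistics,
#' contingency counts and chi-square verification.
#'
#' @param fit A [dcn()] fit.
#' @param txt_path,yaml_path Output paths (`NULL` skips either).
#' @return Invisibly, the written paths.
#' @export
write_threshold_report <- function(fit, txt_path = NULL, yaml_path = NULL) {
  stopifnot(inherits(fit, "dcn"))
  ct <- fit$contingency
  if (!is.null(txt_path)) {
    lines <- c(
      "Differential coexpression threshold report",
      sprintf("gene pairs per group: %d", fit$curve$n_pairs),
      sprintf("optimal threshold C*: %.4f (%.15g)", fit$C_star, fit$C_star),
      sprintf("maximum deviation D:  %.4f (%.15g)", fit$D, fit$D),
      sprintf("asymptotic KS p:      %.4g", fit$ks_p),
      "",
      "contingency (pairs at C*):",
      sprintf("  strong coexpression  disease %4d  normal %4d",
              ct["strong", "disease"], ct["strong", "normal"]),
      sprintf("  weak coexpression    disease %4d  normal %4d",
              ct["weak", "disease"], ct["weak", "normal"]),
      sprintf("chi-square (no continuity correction): %.4f (%.15g)",
              fit$chi2, fit$chi2),
      sprintf("chi-square p: %.4g", fit$chi2_p))
    writeLines(lines, txt_path)
  }
  if (!is.null(yaml_path)) {
    yaml::write_yaml(list(
      n_pairs = fit$curve$n_pairs,
      C_star = fit$C_star, D = fit$D, ks_p = fit$ks_p,
      contingency = list(
        strong = list(disease = unname(ct["strong", "disease"]),
                      normal = unname(ct["strong", "normal"])),
        weak = list(disease = unname(ct["weak", "disease"]),
                    normal = unname(ct["weak", "normal"]))),
      chi2 = fit$chi2, chi2_p = fit$chi2_p), yaml_path, precision = 15)
  }
  invisible(c(txt_path, yaml_path))
}

#' Write a regulatory signature as a bipartite-style Pajek file
#'
#' Vertices are the covered genes plus the regulators (labelled
#' `miRNA:<id>` / `TF:<id>` so regulator vertices are recognisable); edges
#' are the covered gene pairs plus one regulator-to-gene link for each
#' covered gene targeted by the regulator.
#'
#' @param signature A `"regulatory_signature"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_pajek <- function(signature, path) {
  stopifnot(inherits(signature, "regulatory_signature"))
  reg_label <- sprintf("%s:%s", signature$regulators$class,
                       signature$regulators$regulator)
  gene_edges <- signature$pairs[, c("gene_a", "gene_b"), drop = FALSE]
  reg_edges <- do.call(rbind, lapply(seq_along(reg_label), function(k) {
    covered <- intersect(signature$genes,
                         signature$targets[[
                           signature$regulators$regulator[k]]])
    if (!length(covered)) return(NULL)
    data.frame(gene_a = reg_label[k], gene_b = covered,
               stringsAsFactors = FALSE)
  }))
  edges <- rbind(gene_edges, reg_edges)
  write_pajek(edges, path, vertices = c(signature$genes, reg_label),
              allow_empty = TRUE, weight_col = "none")
}

#' Run the full analysis from a configuration
#'
#' Orchestrates read, panel selection, coexpression, threshold fitting,
#' network partition, Pajek export and (optionally) regulatory-signature
#' identification, writing every artifact plus a run log under
#' `output_dir`. Identical config and inputs give byte-identical tabular
#' outputs. Any stage error aborts with the stage name and cause.
#'
#' @param config Path to a YAML file or an equivalent named list with
#'   fields: `expression_path`, `groups_path`, `output_dir` (required);
#'   `panel` (character vector or path to a one-symbol-per-line file),
#'   `collapse` (`"max_mean"`/`"mean"`), `log2` (apply `log2(x + 1)` to
#'   raw-scale inputs; default `FALSE`), `grid` (`"observed"`/`"uniform"`),
#'   `step`, `annotation_path`, `min_pairs` (default 4), `rule`
#'   (`"both"`/`"any"`), `include_isolated` (list all panel genes as Pajek
#'   vertices; default `FALSE`), `seed` (echoed into the log for simulated
#'   inputs).
#' @return Invisibly, a list with the fitted [dcn()] object and the paths of
#'   all written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (f in c("expression_path", "groups_path", "output_dir"))
    if (is.null(config[[f]])) stop("config field '", f, "' is required")
  cfg <- utils::modifyList(
    list(panel = NULL, collapse = "max_mean", log2 = FALSE,
         grid = "observed", step = 1e-4, annotation_path = NULL,
         min_pairs = 4, rule = "both", include_isolated = FALSE,
         seed = NULL),
    config)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("dcnet %s on R %s",
                         as.character(utils::packageVersion("dcnet")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("run at %s", format(Sys.time(), usetz = TRUE)),
                 "config:",
                 paste0("  ", strsplit(yaml::as.yaml(cfg), "\n")[[1L]]))

  ds <- run_stage("read_expression",
                  read_expression(cfg$expression_path, cfg$groups_path))
  if (isTRUE(cfg$log2))
    ds <- run_stage("log2_transform",
                    expression_dataset(log2(ds$values + 1), ds$groups))
  panel <- cfg$panel
  if (!is.null(panel) && length(panel) == 1L && file.exists(panel))
    panel <- trimws(readLines(panel))
  annotations <- if (!is.null(cfg$annotation_path))
    run_stage("read_annotations",
              read_regulator_annotations(cfg$annotation_path))
  else NULL

  fit <- run_stage("fit", dcn(
    ds, panel = panel, collapse = cfg$collapse, grid = cfg$grid,
    step = cfg$step, annotations = annotations,
    min_pairs = cfg$min_pairs, rule = cfg$rule))

  paths <- list()
  p <- function(f) file.path(out_dir, f)
  run_stage("write_outputs", {
    paths$pair_table <- write_coexpression_table(fit$pairs,
                                                 p("pair_table.tsv"))
    utils::write.table(
      data.frame(threshold = fit$curve$thresholds,
                 F_d = fit$curve$F_d, F_n = fit$curve$F_n),
      p("survival_curves.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    paths$survival_curves <- p("survival_curves.tsv")
    write_threshold_report(fit, p("threshold_report.txt"),
                           p("threshold_report.yaml"))
    paths$threshold_report <- p("threshold_report.txt")
    paths$threshold_yaml <- p("threshold_report.yaml")

    all_genes <- if (isTRUE(cfg$include_isolated))
      rownames(ds$values) else NULL
    for (cl in c("common", "normal_specific", "disease_specific")) {
      f <- p(paste0(cl, ".net"))
      suppressMessages(write_pajek(fit$partition[[cl]], f,
                                   vertices = all_genes,
                                   allow_empty = TRUE))
      paths[[paste0(cl, "_net")]] <- f
    }
    edges <- partition_edges(fit$partition)
    utils::write.table(edges, p("edges.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$edges <- p("edges.tsv")
    degrees <- do.call(rbind, lapply(
      c("common", "normal_specific", "disease_specific"), function(cl) {
        d <- degree_report(fit$partition[[cl]])
        if (nrow(d)) d$class <- cl else d$class <- character(0)
        d
      }))
    utils::write.table(degrees, p("degrees.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$degrees <- p("degrees.tsv")
  })

  if (is.null(annotations)) {
    log_lines <- c(log_lines, "signature stage skipped: no annotation_path")
  } else {
    run_stage("write_signatures", {
      for (nw in names(fit$signatures)) {
        sg <- fit$signatures[[nw]]
        utils::write.table(sg$report,
                           p(sprintf("signature_report_%s.tsv", nw)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        paths[[paste0("signature_report_", nw)]] <-
          p(sprintf("signature_report_%s.tsv", nw))
        write_nets <- function(lst, tag) {
          for (k in seq_along(lst))
            write_signature_pajek(
              lst[[k]], p(sprintf("%s_%s_%d.net", tag, nw, k)))
        }
        write_nets(sg$mrs, "mrs")
        write_nets(sg$trs, "trs")
        write_nets(Filter(function(s) nrow(s$pairs) > 0, sg$crs), "crs")
      }
    })
  }

  log_lines <- c(log_lines, sprintf(
    "fit: C*=%.6f D=%.6f ks_p=%.4g chi2=%.6f (%d/%d/%d edges)",
    fit$C_star, fit$D, fit$ks_p, fit$chi2,
    nrow(fit$partition$common), nrow(fit$partition$normal_specific),
    nrow(fit$partition$disease_specific)))
  writeLines(log_lines, p("run_log.txt"))
  paths$run_log <- p("run_log.txt")

  invisible(list(fit = fit, paths = paths))
}
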