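test_that("covered_pairs applies the both-endpoint rule", {
  edges <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "D"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(covered_pairs(edges, c("A", "B", "C"))), 1)
  expect_equal(covered_pairs(edges, c("A", "B", "C"))$gene_b, "B")
  expect_equal(nrow(covered_pairs(edges, "Q")), 0)
  expect_equal(nrow(covered_pairs(edges, c("A", "B", "D"))), 2)
  # permissive single-endpoint alternative
  expect_equal(nrow(covered_pairs(edges, "A", rule = "any")), 2)
  expect_equal(nrow(covered_pairs(edges, "D", rule = "any")), 1)
})

test_that("covered pairs are always a subset of the network (property)", {
  set.seed(20)
  genes <- LETTERS[1:10]
  for (i in 1:25) {
    ij <- t(combn(genes, 2))
    edges <- as.data.frame(ij[sample(nrow(ij), 12), ])
    names(edges) <- c("gene_a", "gene_b")
    targets <- sample(genes, sample(0:8, 1))
    cp <- covered_pairs(edges, targets)
    expect_true(all(paste(cp$gene_a, cp$gene_b) %in%
                      paste(edges$gene_a, edges$gene_b)))
    expect_true(all(cp$gene_a %in% targets) || nrow(cp) == 0)
  }
})

test_that("signature selection applies the inclusive >= 4 pair rule", {
  sigs <- select_signatures(demo_edges(), demo_annotations())
  report <- attr(sigs, "report")
  expect_setequal(report$regulator[report$selected],
                  c("hsa-miR-504", "hsa-miR-125a", "AP-4", "E2F"))
  # exactly 4 covered pairs selects; 1-3 do not
  expect_true(all(report$n_pairs[report$selected] >= 4))
  expect_equal(report$n_pairs[report$regulator == "VDR"], 2)
  expect_false(report$selected[report$regulator == "VDR"])
  expect_equal(report$n_pairs[report$regulator == "hsa-miR-15a"], 1)

  # permissive threshold keeps every regulator covering at least one pair
  all_sel <- attr(select_signatures(demo_edges(), demo_annotations(),
                                    min_pairs = 1), "report")
  expect_setequal(all_sel$regulator[all_sel$selected],
                  all_sel$regulator[all_sel$n_pairs >= 1])
  expect_error(select_signatures(demo_edges(), demo_annotations(),
                                 min_pairs = 0), "at least 1")
})

test_that("signatures sharing genes merge into one network", {
  sigs <- select_signatures(demo_edges(), demo_annotations())
  cls <- vapply(sigs, function(s) s$regulators$class[1], character(1))

  mrs <- merge_signatures(sigs[cls == "miRNA"])
  expect_length(mrs, 1)  # BAK1 and BCL2 are shared
  expect_true(mrs[[1]]$merged)
  expect_setequal(mrs[[1]]$regulators$regulator,
                  c("hsa-miR-504", "hsa-miR-125a"))
  expect_equal(nrow(mrs[[1]]$pairs), 7)  # union, shared pair once

  trs <- merge_signatures(sigs[cls == "TF"])
  expect_length(trs, 1)  # E2F2 is shared
  expect_setequal(trs[[1]]$regulators$regulator, c("AP-4", "E2F"))

  # disjoint signatures stay separate; a single signature is unchanged
  e1 <- data.frame(gene_a = c("A", "A", "B", "A"),
                   gene_b = c("B", "C", "C", "D"), stringsAsFactors = FALSE)
  e2 <- data.frame(gene_a = c("W", "X", "X", "Y"),
                   gene_b = c("X", "Y", "Z", "Z"), stringsAsFactors = FALSE)
  ann <- data.frame(
    regulator = rep(c("m1", "m2"), each = 4),
    class = "miRNA",
    target = c("A", "B", "C", "D", "X", "Y", "Z", "W"),
    stringsAsFactors = FALSE)
  two <- select_signatures(rbind(e1, e2), ann)
  kept <- merge_signatures(two)
  expect_length(kept, 2)
  expect_false(any(vapply(kept, `[[`, logical(1), "merged")))

  # merging is order-independent
  rev_merged <- merge_signatures(rev(sigs[cls == "miRNA"]))
  expect_equal(rev_merged[[1]]$pairs, mrs[[1]]$pairs)
  expect_equal(rev_merged[[1]]$regulators, mrs[[1]]$regulators)
})

test_that("the composite signature is the MRS/TRS pair intersection", {
  sigs <- select_signatures(demo_edges(), demo_annotations())
  cls <- vapply(sigs, function(s) s$regulators$class[1], character(1))
  mrs <- merge_signatures(sigs[cls == "miRNA"])[[1]]
  trs <- merge_signatures(sigs[cls == "TF"])[[1]]

  crs <- composite_signature(mrs, trs)
  expect_setequal(crs$genes, c("BAK1", "E2F2", "PIK3R5"))  # the triangle
  expect_equal(nrow(crs$pairs), 3)
  expect_setequal(crs$regulators$regulator, c("AP-4", "hsa-miR-125a"))

  # CRS pairs are contained in both inputs
  key <- function(s) paste(s$pairs$gene_a, s$pairs$gene_b)
  expect_true(all(key(crs) %in% key(mrs)))
  expect_true(all(key(crs) %in% key(trs)))

  # disjoint pair sets give a valid empty composite
  expect_message(none <- composite_signature(sigs[cls == "miRNA"][[1]],
                                             trs0 <- local({
                                               s <- trs
                                               s$pairs <- s$pairs[0, ]
                                               s$genes <- character(0)
                                               s
                                             })), "disjoint")
  expect_equal(nrow(none$pairs), 0)

  # identical pair sets are a fixed point
  self <- composite_signature(mrs, mrs)
  expect_equal(self$pairs[c("gene_a", "gene_b")],
               mrs$pairs[c("gene_a", "gene_b")])
})
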