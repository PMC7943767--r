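mk_ogc <- function(...) {
  rows <- list(...)
  ogc_table(do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(cluster_id = r$id, species = r$sp,
               gene_id = paste0(r$id, "_", seq_along(r$sp)),
               stringsAsFactors = FALSE)
  })))
}

test_that("cluster classification follows the species-composition rules", {
  ogc <- mk_ogc(list(id = "c1", sp = c("cactus1", "cactus1", "cactus2")),
                list(id = "c2", sp = c("cactus1", "noncactus1")),
                list(id = "c3", sp = c("cactus1", "cactus1", "cactus1")),
                list(id = "c4", sp = c("noncactus1", "noncactus2")),
                list(id = "c5", sp = c("noncactus1")))
  cls <- classify_ogcs(ogc, c("cactus1", "cactus2"),
                       c("noncactus1", "noncactus2"))
  lab <- stats::setNames(cls$label, cls$cluster_id)
  expect_equal(unname(lab["c1"]), "specific_to_A")  # two A species, no B
  expect_equal(unname(lab["c2"]), "shared")         # one of each
  expect_equal(unname(lab["c3"]), "unclassified")   # single species
  expect_equal(unname(lab["c4"]), "specific_to_B")
  expect_equal(unname(lab["c5"]), "unclassified")
  # conservation: labels partition the clusters
  expect_equal(nrow(cls), length(unique(ogc$cluster_id)))

  expect_error(classify_ogcs(ogc, "cactus1", "noncactus1"),
               "without group label")
  expect_error(classify_ogcs(ogc, c("cactus1", "x"), c("x", "y")), "disjoint")
})

test_that("cluster term sets are deduplicated unions of member annotations", {
  ann <- annotation_table(data.frame(
    gene_id = c("c1_1", "c1_2", "c1_2"),
    term = c("GO:1", "GO:1", "GO:2")))
  expect_setequal(ogc_terms(c("c1_1", "c1_2"), ann), c("GO:1", "GO:2"))
  expect_length(ogc_terms("unannotated", ann), 0)
  expect_equal(ogc_terms("c1_1", ann), "GO:1")
})

test_that("exact binomial tails match full enumeration for all n <= 12", {
  for (n in 1:12) {
    for (p in c(0.05, 0.1, 0.25, 0.5)) {
      for (k in 0:n) {
        oracle <- sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
        expect_equal(binom_tail(k, n, p), oracle, tolerance = 1e-12)
      }
    }
  }
  expect_equal(binom_tail(4, 10, 0.1), 0.0127952, tolerance = 1e-5)
  expect_equal(binom_tail(0, 10, 0.1), 1)
  expect_equal(binom_tail(7, 10, 1), 1)
})

test_that("binomial enrichment counts, smooths and adjusts correctly", {
  # 10 foreground clusters (4 carry the term), 20 background (2 carry it)
  fg_sp <- lapply(1:10, function(i)
    list(id = paste0("f", i), sp = c("a1", "a2")))
  bg_sp <- lapply(1:20, function(i)
    list(id = paste0("b", i), sp = c("a1", "b1")))
  ogc <- do.call(mk_ogc, c(fg_sp, bg_sp))
  ann <- annotation_table(data.frame(
    gene_id = c(paste0("f", 1:4, "_1"), paste0("b", 1:2, "_1"),
                paste0("f", 1:10, "_2"), paste0("b", 1:20, "_2")),
    term = c(rep("GO:X", 6), rep("GO:base", 30))))
  out <- binomial_enrich(paste0("f", 1:10), paste0("b", 1:20), ogc, ann,
                         alpha = 0.05, min_fg = 3)
  row <- out[out$term == "GO:X", ]
  expect_equal(row$k_fg, 4)
  expect_equal(row$n_fg, 10)
  expect_equal(row$k_bg, 2)
  expect_equal(row$p_bg, 0.1)
  expect_equal(row$p_value, binom_tail(4, 10, 0.1))
  expect_true(all(out$p_adj >= out$p_value - 1e-12))
  expect_true(all(diff(out$p_adj[order(out$p_value)]) >= -1e-12))

  # a term absent from the background gets add-one smoothing
  ann2 <- annotation_table(data.frame(
    gene_id = c(paste0("f", 1:5, "_1"), paste0("b", 1:20, "_2")),
    term = c(rep("GO:new", 5), rep("GO:base", 20))))
  out2 <- binomial_enrich(paste0("f", 1:10), paste0("b", 1:20), ogc, ann2,
                          min_fg = 3)
  r2 <- out2[out2$term == "GO:new", ]
  expect_equal(r2$k_bg, 0)
  expect_equal(r2$p_bg, 1 / 21)

  # rare foreground terms are skipped; degenerate inputs error
  expect_false("GO:X" %in% binomial_enrich(paste0("f", 1:10),
                                           paste0("b", 1:20), ogc, ann,
                                           min_fg = 5)$term)
  expect_error(binomial_enrich(paste0("f", 1:10), character(0), ogc, ann),
               "empty background")
  expect_error(binomial_enrich(c("f1", "b1"), c("b1", "b2"), ogc, ann),
               "disjoint")
})

test_that("expanded-set enrichment uses the conserved core as background", {
  ogc <- mk_ogc(list(id = "e1", sp = c("s1", "s2", "s3")),
                list(id = "k1", sp = c("s1", "s2", "s3")),
                list(id = "k2", sp = c("s1", "s2")),
                list(id = "k3", sp = c("s1", "s2", "s3")))
  clades <- c(s1 = "clade1", s2 = "clade2", s3 = "clade3")
  ann <- annotation_table(data.frame(
    gene_id = c("e1_1", "e1_2", "e1_3", "k1_1", "k2_1", "k3_1"),
    term = c("GO:A", "GO:A", "GO:A", "GO:A", "GO:A", "GO:B")))
  out <- expanded_set_enrich("e1", ogc, clades, ann, min_fg = 1)
  # background is k1 and k3 (all three clades), never k2 or the expanded set
  expect_equal(unique(out$n_bg), 2)
  expect_error(expanded_set_enrich("missing", ogc, clades, ann), "missing")
  expect_error(expanded_set_enrich("e1", ogc, clades[1:2], ann),
               "without clade")
})

test_that("planted enrichment is recovered and null replicates control error", {
  sim <- simulate_cluster_annotations(250, 750,
                                      planted = list(list(term_index = 5,
                                                          fold = 3)),
                                      seed = 99)
  er <- binomial_enrich(sim$foreground, sim$background, sim$ogc,
                        sim$annotations, alpha = 0.01)
  expect_lt(er$p_adj[er$term == sim$planted_terms], 0.01)

  fp <- vapply(1:10, function(r) {
    s <- simulate_cluster_annotations(200, 600, seed = 5000 + r)
    e <- binomial_enrich(s$foreground, s$background, s$ogc, s$annotations)
    if (nrow(e) == 0) 0 else mean(e$p_adj < 0.05)
  }, numeric(1))
  expect_lte(mean(fp), 0.10)
})
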