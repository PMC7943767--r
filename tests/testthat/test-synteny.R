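test_that("perfect diagonals chain into single blocks with orientation", {
  anc <- data.frame(a = paste0("a", 0:5), b = paste0("b", 0:5),
                    chrom1 = "c1", rank1 = 0:5, chrom2 = "c2", rank2 = 0:5)
  ch <- chain_blocks(anc, max_gap = 25, min_block = 5)
  expect_equal(nrow(ch$blocks), 1)
  expect_equal(ch$blocks$n_anchors, 6)
  expect_equal(ch$blocks$orientation, "same")

  anc$rank2 <- 5:0
  ch2 <- chain_blocks(anc, max_gap = 25, min_block = 5)
  expect_equal(ch2$blocks$orientation, "inverted")
  expect_equal(ch2$blocks$n_anchors, 6)
})

test_that("chained blocks equal brute-force monotone chain enumeration", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- 12
    anc <- data.frame(a = paste0("a", seq_len(n)), b = paste0("b", seq_len(n)),
                      chrom1 = "c1",
                      rank1 = sample.int(30, n),
                      chrom2 = "c2",
                      rank2 = sample.int(30, n))
    anc <- anc[!duplicated(anc[, c("rank1", "rank2")]), ]
    anc <- anc[order(anc$chrom1, anc$rank1, anc$chrom2, anc$rank2), ]
    rownames(anc) <- NULL
    max_gap <- sample(c(5L, 10L, 30L), 1)
    min_block <- 3L
    got <- chain_blocks(anc, max_gap = max_gap, min_block = min_block)
    want <- oracle_blocks(anc, max_gap, min_block)
    got_sets <- lapply(split(seq_len(nrow(got$anchors)),
                             got$anchors$block_id), sort)
    got_sets <- unname(got_sets[order(vapply(got_sets, min, numeric(1)))])
    want <- unname(want[order(vapply(want, min, numeric(1)))])
    expect_equal(lapply(got_sets, as.integer), lapply(want, as.integer),
                 info = paste("seed", seed))
  }
})

test_that("emitted blocks are strictly monotone on both axes", {
  set.seed(4)
  anc <- data.frame(a = paste0("a", 1:60), b = paste0("b", 1:60),
                    chrom1 = sample(c("c1", "c2"), 60, TRUE),
                    rank1 = sample.int(80, 60),
                    chrom2 = sample(c("d1", "d2"), 60, TRUE),
                    rank2 = sample.int(80, 60))
  ch <- chain_blocks(anc, max_gap = 20, min_block = 3)
  for (bid in unique(stats::na.omit(ch$anchors$block_id))) {
    d <- ch$anchors[!is.na(ch$anchors$block_id) & ch$anchors$block_id == bid, ]
    d <- d[order(d$rank1), ]
    expect_true(all(diff(d$rank1) > 0))
    expect_true(all(diff(d$rank2) > 0) || all(diff(d$rank2) < 0))
  }
})

test_that("tandem classification applies an inclusive same-chromosome window", {
  g <- make_genome(list(c1 = 15, c2 = 5))
  ids <- g$genes$gene_id
  on_c1 <- ids[g$genes$chrom == "c1"][order(g$genes$rank[g$genes$chrom == "c1"])]
  on_c2 <- ids[g$genes$chrom == "c2"]
  pairs <- data.frame(a = c(on_c1[6], on_c1[1], on_c1[1], on_c1[1]),
                      b = c(on_c1[13], on_c1[11], on_c1[12], on_c2[1]))
  out <- classify_tandem(pairs, g, window = 10)
  expect_equal(out$class, c("tandem", "tandem", "dispersed", "dispersed"))
  expect_equal(out$rank_distance[1:3], c(7L, 10L, 11L))
  expect_true(all(out$class %in% c("tandem", "dispersed")))  # total partition
})

test_that("block restriction returns an exact subset keyed by pair", {
  div <- data.frame(a = c("a1", "a2", "a3"), b = c("b1", "b2", "b3"),
                    ks = c(0.1, 0.2, 0.3))
  anc <- data.frame(a = c("a1", "a2"), b = c("b1", "b2"),
                    chrom1 = "c", rank1 = 1:2, chrom2 = "d", rank2 = 1:2,
                    block_id = c("B1", NA))
  chained <- list(blocks = data.frame(), anchors = anc)
  out <- restrict_to_blocks(div, chained)
  expect_equal(out$a, "a1")
  expect_true(all(pair_key(out$a, out$b) %in% pair_key(div$a, div$b)))

  none <- list(blocks = data.frame(),
               anchors = transform(anc, block_id = NA_character_))
  expect_equal(nrow(restrict_to_blocks(div, none)), 0)
  all_in <- list(blocks = data.frame(),
                 anchors = data.frame(a = div$a, b = div$b, block_id = "B1"))
  expect_equal(restrict_to_blocks(div, all_in), div)
})

test_that("synteny depth counts covering block intervals per target gene", {
  g <- make_genome(list(t1 = 20))
  blocks <- data.frame(block_id = c("B1", "B2"),
                       chrom1 = "q1", chrom2 = "t1",
                       orientation = "same", n_anchors = 5L,
                       rank1_min = 0L, rank1_max = 9L,
                       rank2_min = c(0L, 0L), rank2_max = c(9L, 9L))
  d1 <- synteny_depth(list(blocks = blocks[1, ], anchors = NULL), g)
  expect_equal(sum(d1$genes$depth == 1), 10)
  expect_equal(d1$modal_depth, 1)
  expect_equal(d1$coverage, 0.5)
  d2 <- synteny_depth(list(blocks = blocks, anchors = NULL), g)
  expect_equal(sum(d2$genes$depth == 2), 10)
  expect_equal(d2$modal_depth, 2)
})

test_that("co-localization spans are per chromosome with a primary flag", {
  genes <- data.frame(gene_id = paste0("g", 1:5),
                      chrom = c("chrX", "chrX", "chrA", "chrA", "chrB"),
                      start = c(100, 1100, 10, 50, 5),
                      end = c(200, 1200, 20, 60, 8),
                      strand = "+")
  g <- new_genome("sp", genes)
  out <- colocalization_span(c("g1", "g2"), g)
  expect_equal(out$span_bp, 1101)
  expect_equal(out$n_genes, 2)

  single <- colocalization_span("g5", g)
  expect_equal(single$span_bp, 4)

  multi <- colocalization_span(c("g1", "g2", "g3", "g5"), g)
  expect_equal(multi$chromosome[multi$primary], "chrX")
  expect_equal(nrow(multi), 3)

  expect_error(colocalization_span("nope", g), "nope")
})

test_that("dot-plot tables project anchors deterministically", {
  expect_equal(nrow(dotplot_table(data.frame(chrom1 = character(0),
                                             rank1 = integer(0),
                                             chrom2 = character(0),
                                             rank2 = integer(0)))), 0)
  anc <- data.frame(chrom1 = "c1", rank1 = c(3L, 1L), chrom2 = "c2",
                    rank2 = c(4L, 2L), block_id = c("B1", NA))
  dp <- dotplot_table(anc)
  expect_equal(dp$rank1, c(1L, 3L))
  expect_equal(dp$block_id, c("none", "B1"))
})

test_that("anchors from pairs use rank coordinates and drop tandem neighbours", {
  g <- make_genome(list(c1 = 30))
  pairs <- data.frame(a = c("g1", "g1", "g2"), b = c("g5", "g25", "g2"))
  anc <- anchors_from_pairs(pairs, g, exclude_tandem_window = 10)
  expect_equal(nrow(anc), 1)  # self pair and near-diagonal pair removed
  expect_equal(anc$a, "g1")
  anc2 <- anchors_from_pairs(pairs, g, exclude_tandem_window = 0)
  expect_equal(nrow(anc2), 2)
  expect_error(anchors_from_pairs(data.frame(a = "g1", b = "zz"), g), "zz")
})
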