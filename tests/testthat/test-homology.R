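test_that("alignment scores match hand-summed BLOSUM62 self-scores", {
  r <- align_score("MKV", "MKV")
  expect_equal(r$score, 5 + 5 + 4)  # BLOSUM62 diagonal M, K, V
  expect_equal(r$identity, 1)
  expect_error(align_score("", "MKV"), "empty")
})

test_that("alignment is symmetric and self-alignment is maximal", {
  set.seed(1)
  aas <- setdiff(rownames(paleodup:::blosum62x()), "*")
  rp <- function(n) paste(sample(aas, n, TRUE), collapse = "")
  for (i in 1:8) {
    s1 <- rp(sample(15:60, 1)); s2 <- rp(sample(15:60, 1))
    expect_equal(align_score(s1, s2)$score, align_score(s2, s1)$score)
    expect_gte(align_score(s1, s1)$score, align_score(s1, s2)$score)
  }
})

test_that("compiled score kernel agrees with the reference aligner", {
  set.seed(2)
  aas <- setdiff(rownames(paleodup:::blosum62x()), "*")
  rp <- function(n) paste(sample(aas, n, TRUE), collapse = "")
  m <- paleodup:::blosum62x()
  for (i in 1:30) {
    s1 <- rp(sample(10:120, 1)); s2 <- rp(sample(10:120, 1))
    expect_equal(
      paleodup:::sw_score_batch(s1, s2, m, paste(colnames(m), collapse = ""),
                                11, 1),
      align_score(s1, s2)$score)
  }
})

test_that("reciprocity is required for RBH pairs", {
  hits <- data.frame(query = c("a1", "b1"), subject = c("b1", "a1"),
                     score = c(100, 100), identity = c(0.9, 0.9))
  ga <- make_genome(list(c1 = 1)); ga$genes$gene_id <- "a1"
  gb <- make_genome(list(c1 = 1)); gb$genes$gene_id <- "b1"
  out <- rbh_orthologs(ga, gb, hits = hits)
  expect_equal(nrow(out), 1)
  expect_equal(out$kind, "ortholog")

  # a's best is b, but b's best is c: no pair for a
  hits2 <- data.frame(query = c("a1", "b1", "b1", "c1"),
                      subject = c("b1", "c1", "a1", "b1"),
                      score = c(100, 90, 80, 90),
                      identity = rep(0.9, 4))
  ga2 <- make_genome(list(c1 = 2)); ga2$genes$gene_id <- c("a1", "c1")
  out2 <- rbh_orthologs(ga2, gb, hits = hits2)
  expect_equal(nrow(out2), 1)
  expect_setequal(c(out2$a, out2$b), c("b1", "c1"))
})

test_that("paralog RBH handles identical genes and reciprocity", {
  cds <- c(g1 = "ATGGGTAAAGTTCATCATCATCAT", g2 = "ATGGGTAAAGTTCATCATCATCAT")
  g <- make_genome(list(c1 = 2), cds = cds)
  out <- rbh_paralogs(g, kmer = 0)
  expect_equal(nrow(out), 1)
  expect_setequal(c(out$a, out$b), c("g1", "g2"))

  hits <- data.frame(query = c("g1", "g2", "g3", "g2", "g1", "g3"),
                     subject = c("g2", "g1", "g1", "g3", "g3", "g2"),
                     score = c(100, 100, 90, 70, 70, 60),
                     identity = rep(0.9, 6))
  g3 <- make_genome(list(c1 = 3))
  out3 <- rbh_paralogs(g3, hits = hits)
  expect_equal(nrow(out3), 1)
  expect_setequal(c(out3$a, out3$b), c("g1", "g2"))

  g1only <- make_genome(list(c1 = 1))
  expect_equal(nrow(rbh_paralogs(g1only)), 0)
})

test_that("RBH equals brute-force mutual argmax on random score matrices", {
  brute_rbh <- function(m) {
    # unique argmax with ties broken by smaller column/row index (identity is
    # constant in these fixtures, so the lexicographic rule applies)
    pairs <- list()
    for (i in seq_len(nrow(m))) {
      j <- which(m[i, ] == max(m[i, ]))[1]
      i2 <- which(m[, j] == max(m[, j]))[1]
      if (i2 == i) pairs[[length(pairs) + 1L]] <- c(i, j)
    }
    do.call(rbind, pairs)
  }
  for (seed in 1:100) {
    set.seed(seed)
    m <- matrix(round(stats::runif(64, 51, 500)), 8, 8)
    qn <- sprintf("a%02d", 1:8); sn <- sprintf("b%02d", 1:8)
    hits <- data.frame(query = c(rep(qn, each = 8), rep(sn, each = 8)),
                       subject = c(rep(sn, 8), rep(qn, 8)),
                       score = c(as.vector(t(m)), as.vector(m)),
                       identity = 0.9)
    ga <- make_genome(list(c1 = 8)); ga$genes$gene_id <- qn
    gb <- make_genome(list(c1 = 8)); gb$genes$gene_id <- sn
    got <- rbh_orthologs(ga, gb, hits = hits)
    want <- brute_rbh(m)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(pair_key(got$a, got$b),
                    pair_key(qn[want[, 1]], sn[want[, 2]]))
  }
})

test_that("RBH output is invariant to hit ordering and bounded in size", {
  set.seed(33)
  n <- 10
  ids <- sprintf("g%02d", 1:n)
  hits <- expand.grid(query = ids, subject = ids, stringsAsFactors = FALSE)
  hits <- hits[hits$query != hits$subject, ]
  hits$score <- round(stats::runif(nrow(hits), 51, 300))
  hits$identity <- round(stats::runif(nrow(hits), 0.3, 1), 3)
  g <- make_genome(list(c1 = n))
  ref <- rbh_paralogs(g, hits = hits)
  for (i in 1:5) {
    shuffled <- hits[sample.int(nrow(hits)), ]
    expect_identical(rbh_paralogs(g, hits = shuffled), ref)
  }
  expect_lte(nrow(ref), n %/% 2)
})

test_that("cluster construction equals an independent union-find oracle", {
  union_find <- function(ids, edges) {
    parent <- stats::setNames(ids, ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges$a[r]); rb <- find(edges$b[r])
      if (ra != rb) parent[[ra]] <- rb
    }
    split(ids, vapply(ids, find, character(1)))
  }
  g <- make_genome(list(c1 = 12))
  ids <- g$genes$gene_id
  # worked examples: transitivity and disjoint pairs
  p <- data.frame(a = c("g1", "g2"), b = c("g2", "g3"))
  ogc <- build_ogcs(list(g), p)
  expect_equal(length(unique(ogc$cluster_id)), 1)
  expect_setequal(ogc$gene_id, c("g1", "g2", "g3"))
  p2 <- data.frame(a = c("g1", "g3"), b = c("g2", "g4"))
  expect_equal(length(unique(build_ogcs(list(g), p2)$cluster_id)), 2)

  for (seed in 1:20) {
    set.seed(seed)
    edges <- data.frame(a = sample(ids, 8, TRUE), b = sample(ids, 8, TRUE))
    edges <- edges[edges$a != edges$b, ]
    got <- build_ogcs(list(g), edges)
    want <- union_find(unique(c(edges$a, edges$b)), edges)
    want <- lapply(want, sort)
    got_sets <- lapply(split(got$gene_id, got$cluster_id), sort)
    expect_setequal(unname(vapply(got_sets, paste, character(1),
                                  collapse = ",")),
                    unname(vapply(want, paste, character(1),
                                  collapse = ",")))
  }
})

test_that("top hit pairs keep k best subjects per query", {
  hits <- data.frame(query = c("q", "q", "q"), subject = c("s1", "s2", "s3"),
                     score = c(300, 200, 100), identity = c(0.9, 0.8, 0.7))
  tp <- top_hit_pairs(hits, k = 2)
  expect_equal(nrow(tp), 2)
  expect_setequal(tp$b, c("s1", "s2"))
})
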