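test_that("back-translation maps aligned residues to codons and drops bad columns", {
  ca <- backtranslate("G", "G", "GGT", "GGC")
  expect_equal(ca$codon1, "GGT")
  expect_equal(ca$codon2, "GGC")

  ca2 <- backtranslate("G-", "GA", "GGT", "GGTGCA")
  expect_equal(ca2$n_codons, 1)
  expect_equal(ca2$n_dropped, 1)

  ca3 <- backtranslate("GX", "GG", "GGTGGN", "GGTGGA")
  expect_equal(ca3$n_codons, 1)  # ambiguous GGN column dropped
  expect_equal(ca3$n_dropped, 1)

  expect_error(backtranslate("GG", "GG", "GGT", "GGTGGT", a = "geneX"),
               "geneX")
})

test_that("NG86 reproduces the hand-derived toy case and conserves sites", {
  ca <- make_ca(rep("GGT", 4), c("GGC", "GGT", "GGT", "GGT"))
  r <- ng86(ca)
  expect_equal(r$S, 4)
  expect_equal(r$N, 8)
  expect_equal(r$sd, 1)
  expect_equal(r$pS, 0.25)
  expect_equal(r$ks, -0.75 * log(2 / 3), tolerance = 1e-9)
  expect_false(r$saturated)

  # identity gives zero everywhere
  r0 <- ng86(make_ca(rep("GGT", 4), rep("GGT", 4)))
  expect_equal(r0$sd, 0)
  expect_equal(r0$ks, 0)

  # pS = 1 is beyond the correction domain
  rs <- ng86(make_ca(rep("GGT", 4), rep("GGA", 4)))
  expect_true(rs$saturated)
  expect_true(is.na(rs$ks))

  expect_error(ng86(make_ca(character(0), character(0))), "empty")
})

test_that("multi-hit codons average over stop-free minimal pathways", {
  # TTA -> CTG (Leu -> Leu): both orders are synonymous at every step
  r <- ng86(make_ca("TTA", "CTG"))
  expect_equal(r$sd, 2)
  expect_equal(r$nd, 0)
  # ATG -> ACA: pathways give (1 syn, 1 nonsyn) and (0 syn, 2 nonsyn)
  r2 <- ng86(make_ca("ATG", "ACA"))
  expect_equal(r2$sd, 0.5)
  expect_equal(r2$nd, 1.5)
})

test_that("S + N = 3 n_codons and self-distance is zero on random sequences", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    c1 <- sample(sense_codons(), n, TRUE)
    c2 <- sample(sense_codons(), n, TRUE)
    r <- ng86(make_ca(c1, c2))
    expect_equal(r$S + r$N, 3 * n, tolerance = 1e-9)
    expect_gte(r$sd, 0)
    # sd can locally exceed S for non-homologous codons (synonymous steps on
    # multi-hit pathways are counted per change, sites per opportunity), but
    # never the total change count
    expect_lte(r$sd + r$nd, 3 * n + 1e-9)
    self <- ng86(make_ca(c1, c1))
    expect_equal(self$ks, 0)
    fself <- fourdtv(make_ca(c1, c1))
    if (!fself$undefined) expect_equal(fself$fourdtv, 0)
  }
})

test_that("4dTv counts transversions at matched fourfold sites only", {
  # third-position T->C in a GGN (Gly) family codon is a transition
  ca <- make_ca(rep("GGT", 4), c("GGC", "GGT", "GGT", "GGT"))
  f <- fourdtv(ca)
  expect_equal(f$n_4d, 4)
  expect_equal(f$fourdtv, 0)
  # T->A is a transversion
  f2 <- fourdtv(make_ca(rep("GGT", 4), c("GGA", "GGT", "GGT", "GGT")))
  expect_equal(f2$fourdtv, 0.25)
  # ATG is not fourfold degenerate: undefined
  f3 <- fourdtv(make_ca("ATG", "ATG"))
  expect_true(f3$undefined)
  expect_true(is.na(f3$fourdtv))
  # corrected variant exists and exceeds the raw proportion
  f4 <- fourdtv(make_ca(rep("GGT", 10), c(rep("GGA", 3), rep("GGT", 7))),
                correct = TRUE)
  expect_gt(f4$fourdtv_corrected, f4$fourdtv)
})

test_that("4dTv site counting matches per-codon brute-force enumeration", {
  code <- Biostrings::GENETIC_CODE
  brute <- function(c1, c2) {
    n4 <- 0L; tv <- 0L
    for (i in seq_along(c1)) {
      p1 <- substr(c1[i], 1, 2); p2 <- substr(c2[i], 1, 2)
      if (p1 != p2) next
      fam <- unname(code[paste0(p1, c("A", "C", "G", "T"))])
      if (any(fam == "*") || length(unique(fam)) != 1) next
      n4 <- n4 + 1L
      b1 <- substr(c1[i], 3, 3); b2 <- substr(c2[i], 3, 3)
      if ((b1 %in% c("A", "G")) != (b2 %in% c("A", "G"))) tv <- tv + 1L
    }
    c(n4, tv)
  }
  set.seed(6)
  c1 <- sample(sense_codons(), 1000, TRUE)
  c2 <- c1
  flip <- sample(1000, 500)
  c2[flip] <- sample(sense_codons(), 500, TRUE)
  got <- fourdtv(make_ca(c1, c2))
  want <- brute(c1, c2)
  expect_equal(got$n_4d, want[1])
  expect_equal(got$tv_4d, want[2])
})

test_that("median ks and 4dTv increase with true divergence and ks is consistent", {
  set.seed(77)
  base <- vapply(1:200, function(i) random_cds(100), character(1))
  med <- function(d) {
    ev <- evolve_genes(base, d, kappa = 2)
    vals <- vapply(seq_along(base), function(i) {
      ca <- make_ca(substring(base[i], seq(1, 300, 3), seq(3, 300, 3)),
                    substring(ev$cds[i], seq(1, 300, 3), seq(3, 300, 3)))
      c(ng86(ca)$ks, fourdtv(ca)$fourdtv)
    }, numeric(2))
    apply(vals, 1, stats::median, na.rm = TRUE)
  }
  m1 <- med(0.1); m3 <- med(0.3); m6 <- med(0.6)
  expect_lt(m1[1], m3[1]); expect_lt(m3[1], m6[1])
  expect_lt(m1[2], m3[2]); expect_lt(m3[2], m6[2])

  set.seed(78)
  base300 <- vapply(1:200, function(i) random_cds(300), character(1))
  ev <- evolve_genes(base300, 0.3, kappa = 2)
  ks <- vapply(seq_along(base300), function(i) {
    ng86(make_ca(substring(base300[i], seq(1, 900, 3), seq(3, 900, 3)),
                 substring(ev$cds[i], seq(1, 900, 3), seq(3, 900, 3))))$ks
  }, numeric(1))
  expect_gte(stats::median(ks), 0.24)
  expect_lte(stats::median(ks), 0.36)
})

test_that("divergence_table is a per-pair batch of the single-pair operations", {
  cds <- c(g1 = "ATGGGTAAAGTTCATGGCGAT", g2 = "ATGGGCAAAGTTCATGGCGAT")
  g <- make_genome(list(c1 = 2), cds = cds)
  d <- divergence_table(data.frame(a = "g1", b = "g2", kind = "paralog"),
                        list(g))
  expect_equal(nrow(d), 1)
  ca <- codon_align(g$protein[["g1"]], g$protein[["g2"]],
                    cds[["g1"]], cds[["g2"]])
  expect_equal(d$ks, ng86(ca)$ks)
  expect_equal(d$fourdtv, fourdtv(ca)$fourdtv)

  expect_equal(nrow(divergence_table(data.frame(a = character(0),
                                                b = character(0)), list(g))),
               0)
  expect_error(divergence_table(data.frame(a = "g1", b = "nope"), list(g)),
               "nope")
})

test_that("peak detection recovers planted unimodal and bimodal structure", {
  set.seed(9)
  p1 <- detect_peaks(stats::rnorm(500, 0.5, 0.05), "ks")
  expect_equal(nrow(p1), 1)
  expect_equal(p1$mean, 0.5, tolerance = 0.03 / 0.5)

  x <- c(stats::rnorm(500, 0.2, 0.04), stats::rnorm(500, 0.8, 0.08))
  p2 <- detect_peaks(x, "fourdtv", cap = 2)  # raw-scale fit
  expect_equal(nrow(p2), 2)
  expect_equal(p2$mean[1], 0.2, tolerance = 0.25)
  expect_equal(p2$mean[2], 0.8, tolerance = 0.15)
  expect_equal(sum(p2$weight), 1, tolerance = 1e-6)
  expect_setequal(p2$label, c("alpha", "beta"))

  expect_error(detect_peaks(stats::rnorm(10, 0.5, 0.1), "ks"), "kde")
  expect_warning(p3 <- detect_peaks(rep(0.4, 50), "ks"), "constant")
  expect_equal(p3$sigma, 0)
  # kde fallback works on small samples
  p4 <- detect_peaks(stats::rnorm(25, 0.5, 0.05), "ks", method = "kde")
  expect_gte(nrow(p4), 1)
})

test_that("molecular-clock dating is exact and linear in the peak location", {
  expect_equal(date_peak(0.9, rate = 1.5e-8), 30)
  expect_equal(date_peak(0), 0)
  # inverting the dating formula at 25.7 MY gives back the same ks
  expect_equal(date_peak(0.771, rate = 1.5e-8), 25.7)
  expect_equal(date_peak(0.4), 2 * date_peak(0.2))
  expect_error(date_peak(0.5, rate = -1), "positive")
  pk <- detect_peaks(stats::rnorm(100, 0.5, 0.02), "ks")
  dated <- date_peak(pk, rate = 1.5e-8)
  expect_equal(dated$time_mya, dated$mean / (2 * 1.5e-8) / 1e6)
  expect_error(date_peak(detect_peaks(stats::rnorm(100, .2, .02), "fourdtv")),
               "ks")
})
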