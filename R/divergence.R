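# Codon-aware divergence estimation for homolog pairs: back-translation of a
# protein alignment onto the two coding sequences, Nei-Gojobori (NG86)
# synonymous rates with Jukes-Cantor correction, and the transversion rate at
# fourfold-degenerate third positions (4dTv).

#' Back-translate an aligned protein pair onto its coding sequences
#'
#' Each aligned amino-acid column is mapped to the corresponding codon pair.
#' Columns with a gap on either side, any non-ACGT base, or a stop codon are
#' dropped and counted in `n_dropped`.
#'
#' @param aln1,aln2 aligned (gapped, equal-length) amino-acid strings.
#' @param cds1,cds2 ungapped coding sequences; after trimming of incomplete
#'   terminal codons and a terminal stop their length must be 3x the ungapped
#'   protein length.
#' @param a,b gene identifiers carried through for reporting.
#' @return object of class `codon_alignment`: list with `a`, `b`, `codon1`,
#'   `codon2` (character vectors of kept codons), `n_codons`, `n_dropped`.
#' @export
backtranslate <- function(aln1, aln2, cds1, cds2, a = "seq1", b = "seq2") {
  if (nchar(aln1) != nchar(aln2)) stop("aligned strings differ in length")
  cds1 <- trim_cds(cds1); cds2 <- trim_cds(cds2)
  c1 <- strsplit(aln1, "")[[1]]
  c2 <- strsplit(aln2, "")[[1]]
  n1 <- sum(c1 != "-"); n2 <- sum(c2 != "-")
  if (nchar(cds1) != 3L * n1) {
    stop("CDS length of ", a, " (", nchar(cds1),
         ") does not match 3 x ungapped protein length (", 3L * n1, ")")
  }
  if (nchar(cds2) != 3L * n2) {
    stop("CDS length of ", b, " (", nchar(cds2),
         ") does not match 3 x ungapped protein length (", 3L * n2, ")")
  }
  pos1 <- cumsum(c1 != "-")
  pos2 <- cumsum(c2 != "-")
  keep <- c1 != "-" & c2 != "-"
  cod1 <- substring(cds1, (pos1 - 1L) * 3L + 1L, pos1 * 3L)[keep]
  cod2 <- substring(cds2, (pos2 - 1L) * 3L + 1L, pos2 * 3L)[keep]
  tb <- codon_tables()
  i1 <- codon_index(cod1)
  i2 <- codon_index(cod2)
  ok <- !is.na(i1) & !is.na(i2) & !tb$is_stop[i1] & !tb$is_stop[i2]
  structure(list(a = a, b = b,
                 codon1 = cod1[ok], codon2 = cod2[ok],
                 n_codons = sum(ok),
                 n_dropped = length(c1) - sum(ok)),
            class = "codon_alignment")
}

#' Codon alignment of two unaligned coding genes
#'
#' Globally aligns the two proteins (Needleman-Wunsch, BLOSUM62, affine gaps)
#' and back-translates the alignment.
#'
#' @param protein1,protein2 amino-acid strings.
#' @param cds1,cds2 coding sequences.
#' @param a,b identifiers.
#' @param params scoring configuration, see [align_params()].
#' @return a `codon_alignment`.
#' @export
codon_align <- function(protein1, protein2, cds1, cds2,
                        a = "seq1", b = "seq2", params = align_params()) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein1), Biostrings::AAString(protein2),
    type = "global", substitutionMatrix = blosum62x(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  backtranslate(as.character(Biostrings::alignedPattern(al)),
                as.character(Biostrings::alignedSubject(al)),
                cds1, cds2, a = a, b = b)
}

#' Nei-Gojobori (NG86) synonymous and nonsynonymous rates
#'
#' Synonymous sites per codon are the per-position fractions of one-step
#' changes that are synonymous (changes to stops count as nonsynonymous, so
#' S + N = 3 x n_codons exactly), averaged between the two sequences.
#' Differences in multi-hit codons are averaged over all minimal mutational
#' pathways, excluding pathways through stop codons. Distances are
#' Jukes-Cantor corrected: ks = -3/4 log(1 - 4/3 pS); when the log argument is
#' non-positive (pS >= 3/4) the estimate is flagged `saturated` and `ks` is NA.
#'
#' @param ca a `codon_alignment`.
#' @return list with `n_codons`, `S`, `N`, `sd`, `nd`, `pS`, `pN`, `ks`, `ka`,
#'   `saturated` (logical, for ks).
#' @export
ng86 <- function(ca) {
  if (ca$n_codons == 0) stop("empty alignment")
  tb <- codon_tables()
  ng <- ng86_tables()
  i1 <- codon_index(ca$codon1)
  i2 <- codon_index(ca$codon2)
  S <- (sum(tb$syn_sites[i1]) + sum(tb$syn_sites[i2])) / 2
  N <- 3 * ca$n_codons - S
  sd <- sum(ng$SD[cbind(i1, i2)])
  nd <- sum(ng$ND[cbind(i1, i2)])
  pS <- sd / S
  pN <- nd / N
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) NA_real_ else -0.75 * log(arg)
  }
  ks <- jc(pS)
  ka <- jc(pN)
  list(n_codons = ca$n_codons, S = S, N = N, sd = sd, nd = nd,
       pS = pS, pN = pN, ks = ks, ka = ka, saturated = is.na(ks))
}

#' Transversion rate at fourfold-degenerate sites (4dTv)
#'
#' A third-codon position is counted iff both codons belong to a
#' fourfold-degenerate family AND their first two bases are identical (the
#' common convention; sites whose degeneracy class cannot be matched between
#' the sequences are excluded). `fourdtv` is the fraction of counted sites
#' whose third bases differ by a transversion (purine vs pyrimidine). The raw
#' proportion is the default; `correct = TRUE` additionally reports the
#' K80-style transversion distance -1/2 log(1 - 2q), which corrects for
#' multiple hits.
#'
#' @param ca a `codon_alignment`.
#' @param correct also compute the corrected value.
#' @return list with `n_4d` (counted sites), `tv_4d` (transversion
#'   differences), `fourdtv` (raw proportion; NA with `undefined = TRUE` when
#'   `n_4d` is 0), and `fourdtv_corrected` when requested.
#' @export
fourdtv <- function(ca, correct = FALSE) {
  if (ca$n_codons == 0) stop("empty alignment")
  tb <- codon_tables()
  i1 <- codon_index(ca$codon1)
  i2 <- codon_index(ca$codon2)
  pre1 <- (i1 - 1L) %/% 4L   # first-two-base prefix, 0..15
  pre2 <- (i2 - 1L) %/% 4L
  site <- pre1 == pre2 & tb$fourfold2[pre1 + 1L]
  b1 <- substr(ca$codon1, 3L, 3L)
  b2 <- substr(ca$codon2, 3L, 3L)
  tv <- site & ((b1 %in% pd_purines) != (b2 %in% pd_purines))
  n_4d <- sum(site)
  tv_4d <- sum(tv)
  out <- list(n_4d = n_4d, tv_4d = tv_4d,
              fourdtv = if (n_4d > 0) tv_4d / n_4d else NA_real_,
              undefined = n_4d == 0)
  if (correct) {
    q <- out$fourdtv
    out$fourdtv_corrected <-
      if (!is.na(q) && q < 0.5) -0.5 * log(1 - 2 * q) else NA_real_
  }
  out
}

#' Per-pair divergence table
#'
#' Batch driver: codon-aligns every homolog pair and reports NG86 and 4dTv
#' statistics, one row per pair.
#'
#' @param pairs data.frame of homolog pairs (`a`, `b`, optional `kind`).
#' @param genomes list of `genome` objects covering all pair members.
#' @param correct_4dtv also report the multiple-hit corrected 4dTv.
#' @param params alignment scoring configuration.
#' @return data.frame with columns `a`, `b`, `kind`, `n_codons`, `S`, `sd`,
#'   `pS`, `ks`, `ka`, `saturated`, `n_4d`, `tv_4d`, `fourdtv` (and
#'   `fourdtv_corrected` when requested).
#' @export
divergence_table <- function(pairs, genomes, correct_4dtv = FALSE,
                             params = align_params()) {
  cds <- do.call(c, unname(lapply(genomes, function(g) g$cds)))
  prot <- do.call(c, unname(lapply(genomes, function(g) g$protein)))
  cols <- c("a", "b", "kind", "n_codons", "S", "sd", "pS", "ks", "ka",
            "saturated", "n_4d", "tv_4d", "fourdtv",
            if (correct_4dtv) "fourdtv_corrected")
  if (nrow(pairs) == 0) {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), logical(0), simplify = FALSE), cols))
    return(out)
  }
  miss <- setdiff(unique(c(pairs$a, pairs$b)), names(cds))
  if (length(miss)) {
    stop("pair gene(s) without CDS in supplied genomes: ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  kind <- if ("kind" %in% names(pairs)) pairs$kind else NA_character_
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$a[i]; b <- pairs$b[i]
    ca <- codon_align(prot[[a]], prot[[b]], cds[[a]], cds[[b]],
                      a = a, b = b, params = params)
    ngr <- ng86(ca)
    fd <- fourdtv(ca, correct = correct_4dtv)
    data.frame(a = a, b = b,
               kind = if (length(kind) > 1) kind[i] else kind,
               n_codons = ngr$n_codons, S = ngr$S, sd = ngr$sd, pS = ngr$pS,
               ks = ngr$ks, ka = ngr$ka, saturated = ngr$saturated,
               n_4d = fd$n_4d, tv_4d = fd$tv_4d, fourdtv = fd$fourdtv,
               stringsAsFactors = FALSE) -> r
    if (correct_4dtv) r$fourdtv_corrected <- fd$fourdtv_corrected
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histogram table of a divergence statistic
#'
#' @param values numeric vector (NA dropped).
#' @param width bin width.
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
divergence_histogram <- function(values, width = 0.01) {
  v <- values[is.finite(values)]
  if (length(v) == 0) {
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0)))
  }
  bin <- floor(v / width)
  t <- table(bin)
  data.frame(bin_start = as.numeric(names(t)) * width,
             bin_end = (as.numeric(names(t)) + 1) * width,
             count = as.integer(t))
}
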