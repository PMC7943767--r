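# Collinearity analysis: homolog anchors on gene rank coordinates, block
# chaining by dynamic programming, tandem-duplicate classification,
# block-restricted divergence subsets, synteny depth, and bp co-localization
# spans. All within/between-gene distances use rank (gene-order) coordinates;
# only co-localization spans use base pairs.

#' Build synteny anchors from homolog pairs
#'
#' Each pair becomes one anchor at (chromosome, rank) of its two genes. For
#' intragenome anchors (one genome supplied), self pairs are excluded and, by
#' default, same-chromosome pairs within the tandem window are removed as
#' well: tandem arrays otherwise chain into spurious near-diagonal "blocks",
#' which collinearity tools conventionally filter out.
#'
#' @param pairs data.frame with columns `a`, `b`.
#' @param genome1 `genome` for the first axis.
#' @param genome2 `genome` for the second axis; NULL for intragenome anchors.
#' @param exclude_tandem_window same-chromosome rank distance below which
#'   intragenome anchors are dropped (0 disables; ignored between genomes).
#' @return data.frame `a`, `b`, `chrom1`, `rank1`, `chrom2`, `rank2`.
#' @export
anchors_from_pairs <- function(pairs, genome1, genome2 = NULL,
                               exclude_tandem_window = 10L) {
  intra <- is.null(genome2)
  if (intra) genome2 <- genome1
  g1 <- genome1$genes; g2 <- genome2$genes
  a <- pairs$a; b <- pairs$b
  if (!intra) {
    # canonical pair order is lexicographic, not by genome: put the genome1
    # member on the first axis
    swap <- !(a %in% g1$gene_id) & (b %in% g1$gene_id)
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  pairs$a <- a; pairs$b <- b
  i1 <- match(pairs$a, g1$gene_id)
  i2 <- match(pairs$b, g2$gene_id)
  if (anyNA(i1) || anyNA(i2)) {
    bad <- unique(c(pairs$a[is.na(i1)], pairs$b[is.na(i2)]))
    stop("pair gene(s) not present in the supplied genome(s): ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  anc <- data.frame(a = pairs$a, b = pairs$b,
                    chrom1 = g1$chrom[i1], rank1 = g1$rank[i1],
                    chrom2 = g2$chrom[i2], rank2 = g2$rank[i2],
                    stringsAsFactors = FALSE)
  if (intra) {
    anc <- anc[anc$a != anc$b, , drop = FALSE]
    if (exclude_tandem_window > 0) {
      near <- anc$chrom1 == anc$chrom2 &
        abs(anc$rank1 - anc$rank2) <= exclude_tandem_window
      anc <- anc[!near, , drop = FALSE]
    }
  }
  anc <- anc[order(anc$chrom1, anc$rank1, anc$chrom2, anc$rank2), ,
             drop = FALSE]
  rownames(anc) <- NULL
  anc
}

# Best chain among anchors (r1, r2 integer vectors) for one orientation.
# Chains are strictly monotone on both axes (increasing; for inverted pass
# negated r2), with per-step rank gaps <= max_gap on both axes. Quality order:
# longer, then smaller total gap, then lexicographically smallest index
# sequence. Returns list(idx, len, gap).
chain_dp <- function(r1, r2, max_gap) {
  n <- length(r1)
  o <- order(r1, r2)
  r1 <- r1[o]; r2 <- r2[o]
  len <- rep(1L, n); gap <- rep(0, n); nxt <- rep(NA_integer_, n)
  for (i in seq(n - 1L, 1L)) {
    if (n < 2L) break
    for (j in seq(i + 1L, n)) {
      g1 <- r1[j] - r1[i] - 1L
      if (g1 > max_gap) break  # r1 sorted ascending: no later j can qualify
      if (g1 < 0L) next
      g2 <- r2[j] - r2[i] - 1L
      if (g2 < 0L || g2 > max_gap) next
      cl <- len[j] + 1L
      cg <- gap[j] + g1 + g2
      if (cl > len[i] || (cl == len[i] && (cg < gap[i] ||
          (cg == gap[i] && (is.na(nxt[i]) || j < nxt[i]))))) {
        len[i] <- cl; gap[i] <- cg; nxt[i] <- j
      }
    }
  }
  best <- 1L
  if (n > 1L) {
    for (i in 2:n) {
      if (len[i] > len[best] || (len[i] == len[best] && (gap[i] < gap[best] ||
          (gap[i] == gap[best] && i < best)))) best <- i
    }
  }
  idx <- integer(0); i <- best
  while (!is.na(i)) { idx <- c(idx, i); i <- nxt[i] }
  list(idx = o[idx], len = len[best], gap = gap[best])
}

#' Chain homolog anchors into collinearity blocks
#'
#' Within each chromosome pair, repeatedly extracts the best remaining chain
#' of anchors that is strictly monotone on both rank axes (increasing =
#' `same` orientation, decreasing on the second axis = `inverted`) with
#' per-step rank gaps at most `max_gap`; chains are scored by anchor count,
#' ties broken by smaller total gap (then deterministically). Chains shorter
#' than `min_block` are discarded, and each anchor belongs to at most one
#' block.
#'
#' @param anchors anchor table from [anchors_from_pairs()].
#' @param max_gap maximum rank gap between consecutive anchors (both axes).
#' @param min_block minimum number of anchors per block.
#' @return list with `blocks` (block_id, chrom1, chrom2, orientation,
#'   n_anchors, span columns) and `anchors` (the input with a `block_id`
#'   column, NA for unassigned anchors).
#' @export
chain_blocks <- function(anchors, max_gap = 25L, min_block = 5L) {
  anchors$block_id <- NA_character_
  blocks <- list()
  bi <- 0L
  groups <- split(seq_len(nrow(anchors)),
                  paste(anchors$chrom1, anchors$chrom2, sep = "\r"))
  for (key in sort(names(groups))) {
    rows <- groups[[key]]
    repeat {
      free <- rows[is.na(anchors$block_id[rows])]
      if (length(free) < min_block) break
      r1 <- anchors$rank1[free]; r2 <- anchors$rank2[free]
      fwd <- chain_dp(r1, r2, max_gap)
      rev <- chain_dp(r1, -r2, max_gap)
      use_fwd <- fwd$len > rev$len ||
        (fwd$len == rev$len && fwd$gap <= rev$gap)
      ch <- if (use_fwd) fwd else rev
      if (ch$len < min_block) break
      bi <- bi + 1L
      bid <- sprintf("B%04d", bi)
      sel <- free[ch$idx]
      anchors$block_id[sel] <- bid
      blocks[[bi]] <- data.frame(
        block_id = bid,
        chrom1 = anchors$chrom1[sel[1]], chrom2 = anchors$chrom2[sel[1]],
        orientation = if (use_fwd) "same" else "inverted",
        n_anchors = ch$len,
        rank1_min = min(anchors$rank1[sel]), rank1_max = max(anchors$rank1[sel]),
        rank2_min = min(anchors$rank2[sel]), rank2_max = max(anchors$rank2[sel]),
        stringsAsFactors = FALSE)
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = character(0), chrom1 = character(0),
               chrom2 = character(0), orientation = character(0),
               n_anchors = integer(0), rank1_min = integer(0),
               rank1_max = integer(0), rank2_min = integer(0),
               rank2_max = integer(0))
  list(blocks = blocks, anchors = anchors)
}

#' Classify paralog pairs as tandem or dispersed
#'
#' A pair is tandem iff both genes lie on the same chromosome within `window`
#' gene positions of each other (boundary inclusive); otherwise dispersed.
#'
#' @param pairs data.frame with columns `a`, `b`.
#' @param genome the `genome` holding both genes of every pair.
#' @param window rank-distance window (default 10 genes).
#' @return the input with `rank_distance` (NA across chromosomes) and `class`
#'   (`"tandem"`/`"dispersed"`) columns.
#' @export
classify_tandem <- function(pairs, genome, window = 10L) {
  stopifnot(window >= 1L)
  g <- genome$genes
  i1 <- match(pairs$a, g$gene_id)
  i2 <- match(pairs$b, g$gene_id)
  if (anyNA(i1) || anyNA(i2)) stop("pair gene(s) missing from genome")
  same <- g$chrom[i1] == g$chrom[i2]
  dist <- ifelse(same, abs(g$rank[i1] - g$rank[i2]), NA_integer_)
  pairs$rank_distance <- dist
  pairs$class <- ifelse(same & dist <= window, "tandem", "dispersed")
  pairs
}

#' Restrict a divergence table to pairs anchored in synteny blocks
#'
#' @param div_table output of [divergence_table()].
#' @param chained output of [chain_blocks()].
#' @return the subset of rows whose (a, b) pair is an anchor of some block.
#' @export
restrict_to_blocks <- function(div_table, chained) {
  anc <- chained$anchors
  anc <- anc[!is.na(anc$block_id), , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  keep <- key(div_table$a, div_table$b) %in% key(anc$a, anc$b)
  out <- div_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synteny depth along the second-axis genome
#'
#' For each gene of the target genome, the depth is the number of blocks whose
#' second-axis rank interval covers the gene's rank on its chromosome. A
#' one-to-one genome relationship gives modal depth 1 over covered genes; a
#' genome comparison across one whole-genome duplication gives modal depth 2.
#'
#' @param chained output of [chain_blocks()] computed genomeA vs genomeB.
#' @param target_genome genomeB.
#' @return list with `genes` (gene_id, chrom, rank, depth), `histogram`
#'   (depth, n_genes), `modal_depth` (most common depth among covered genes;
#'   NA when nothing is covered) and `coverage` (fraction of genes with
#'   depth >= 1).
#' @export
synteny_depth <- function(chained, target_genome) {
  g <- target_genome$genes
  depth <- integer(nrow(g))
  b <- chained$blocks
  for (i in seq_len(nrow(b))) {
    hit <- g$chrom == b$chrom2[i] &
      g$rank >= b$rank2_min[i] & g$rank <= b$rank2_max[i]
    depth[hit] <- depth[hit] + 1L
  }
  hist <- as.data.frame(table(depth = depth), stringsAsFactors = FALSE)
  names(hist) <- c("depth", "n_genes")
  hist$depth <- as.integer(hist$depth)
  covered <- depth[depth >= 1L]
  modal <- if (length(covered)) {
    t <- table(covered)
    as.integer(names(t)[which.max(t)])
  } else NA_integer_
  list(genes = data.frame(gene_id = g$gene_id, chrom = g$chrom,
                          rank = g$rank, depth = depth,
                          stringsAsFactors = FALSE),
       histogram = hist, modal_depth = modal,
       coverage = mean(depth >= 1L))
}

#' Base-pair span of a gene set per chromosome
#'
#' For each chromosome holding at least one of the listed genes, reports how
#' many of them it carries and the bp span max(end) - min(start) + 1. The
#' chromosome with the most listed genes is flagged primary.
#'
#' @param gene_ids character vector of gene ids.
#' @param genome a `genome` object.
#' @return data.frame `chromosome`, `n_genes`, `span_bp`, `primary`.
#' @export
colocalization_span <- function(gene_ids, genome) {
  g <- genome$genes
  i <- match(gene_ids, g$gene_id)
  if (anyNA(i)) stop("unknown gene id ", gene_ids[is.na(i)][1])
  d <- g[i, , drop = FALSE]
  out <- do.call(rbind, lapply(split(d, d$chrom), function(x) {
    data.frame(chromosome = x$chrom[1], n_genes = nrow(x),
               span_bp = max(x$end) - min(x$start) + 1,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_genes, out$chromosome), , drop = FALSE]
  out$primary <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  out
}

#' Dot-plot table of anchors
#'
#' @param chained output of [chain_blocks()], or a plain anchor table.
#' @return data.frame `chrom1`, `rank1`, `chrom2`, `rank2`, `block_id`
#'   (`"none"` for unassigned anchors), deterministically ordered.
#' @export
dotplot_table <- function(chained) {
  anc <- if (is.list(chained) && !is.data.frame(chained)) chained$anchors
         else chained
  if (is.null(anc$block_id)) anc$block_id <- rep(NA_character_, nrow(anc))
  out <- data.frame(chrom1 = anc$chrom1, rank1 = anc$rank1,
                    chrom2 = anc$chrom2, rank2 = anc$rank2,
                    block_id = ifelse(is.na(anc$block_id), "none",
                                      anc$block_id),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom1, out$rank1, out$chrom2, out$rank2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
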