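# Exhaustive chain oracle: enumerates every strictly monotone chain (both
# orientations) under the same gap constraint and quality order (length desc,
# total gap asc, lexicographically smallest index sequence, 'same' orientation
# preferred), then applies the same greedy decomposition as chain_blocks.
oracle_chain_one <- function(r1, y, max_gap) {
  n <- length(r1)
  best <- NULL
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$len != b$len) return(a$len > b$len)
    if (a$gap != b$gap) return(a$gap < b$gap)
    for (i in seq_len(min(length(a$idx), length(b$idx)))) {
      if (a$idx[i] != b$idx[i]) return(a$idx[i] < b$idx[i])
    }
    FALSE
  }
  extend <- function(idx, gap) {
    cand <- list(len = length(idx), gap = gap, idx = idx)
    if (better(cand, best)) best <<- cand
    last <- idx[length(idx)]
    for (j in seq_len(n)) {
      g1 <- r1[j] - r1[last] - 1L
      g2 <- y[j] - y[last] - 1L
      if (g1 >= 0 && g1 <= max_gap && g2 >= 0 && g2 <= max_gap) {
        extend(c(idx, j), gap + g1 + g2)
      }
    }
  }
  for (s in seq_len(n)) extend(s, 0)
  best
}

oracle_best_chain <- function(r1, r2, max_gap) {
  fwd <- oracle_chain_one(r1, r2, max_gap)
  rev <- oracle_chain_one(r1, -r2, max_gap)
  if (fwd$len > rev$len || (fwd$len == rev$len && fwd$gap <= rev$gap)) fwd
  else rev
}

oracle_blocks <- function(anchors, max_gap, min_block) {
  free <- seq_len(nrow(anchors))
  out <- list()
  repeat {
    if (length(free) < min_block) break
    b <- oracle_best_chain(anchors$rank1[free], anchors$rank2[free], max_gap)
    if (is.null(b) || b$len < min_block) break
    out[[length(out) + 1L]] <- sort(free[b$idx])
    free <- setdiff(free, free[b$idx])
  }
  out
}
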