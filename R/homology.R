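# Protein similarity and reciprocal-best-hit (RBH) homolog calling.
#
# At desk scale, hits are computed by exact Smith-Waterman local alignment
# under BLOSUM62 with affine gaps (the role BlastP plays on full proteomes);
# precomputed tabular hit lists can be supplied instead for large inputs.
# Candidate pairs for internal alignment are prefiltered by shared amino-acid
# k-mers, a seed heuristic in the spirit of word-based search tools.

#' Default scoring configuration for protein alignment
#' @param gap_open gap opening penalty.
#' @param gap_extend gap extension penalty.
#' @param matrix substitution matrix name (only `"BLOSUM62"` is bundled).
#' @return list of scoring parameters.
#' @export
align_params <- function(gap_open = 11, gap_extend = 1, matrix = "BLOSUM62") {
  list(gap_open = gap_open, gap_extend = gap_extend, matrix = matrix)
}

# BLOSUM62 with the ambiguity code X scored 0 against everything
blosum62x <- function() {
  if (!is.null(.pd$blosum62x)) return(.pd$blosum62x)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0
  m[, "X"] <- 0
  .pd$blosum62x <- m
  m
}

#' Smith-Waterman local alignment score and identity of two proteins
#'
#' @param seq1,seq2 amino-acid strings (X allowed, scored 0).
#' @param params scoring configuration, see [align_params()].
#' @return list with `score` (local alignment score) and `identity`
#'   (identical positions / aligned length, in [0, 1]).
#' @export
align_score <- function(seq1, seq2, params = align_params()) {
  if (!nzchar(seq1) || !nzchar(seq2)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    type = "local", substitutionMatrix = blosum62x(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  list(score = Biostrings::score(al), identity = Biostrings::pid(al) / 100)
}

# Align one query against many subjects in a single vectorized call.
align_scores_many <- function(query, subjects, params = align_params()) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep(query, length(subjects))),
    Biostrings::AAStringSet(subjects),
    type = "local", substitutionMatrix = blosum62x(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  data.frame(score = Biostrings::score(al),
             identity = Biostrings::pid(al) / 100)
}

# Candidate pairs for alignment: pairs sharing at least `min_shared` exact
# amino-acid k-mers, plus each gene's `top_n` partners by shared-k-mer count
# (>= 2) so that diverged homologs with few exact word matches still surface.
# Returns a two-column matrix of (index into a, index into b).
kmer_candidates <- function(seqs_a, seqs_b, k = 4L, min_shared = 5L,
                            top_n = 3L, max_kmer_freq = 50L) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  ka <- lapply(seqs_a, kmers_of)
  kb <- lapply(seqs_b, kmers_of)
  A <- data.frame(kmer = unlist(ka, use.names = FALSE),
                  i = rep(seq_along(ka), lengths(ka)))
  B <- data.frame(kmer = unlist(kb, use.names = FALSE),
                  j = rep(seq_along(kb), lengths(kb)))
  # drop promiscuous (low-complexity) kmers
  fa <- table(A$kmer); fb <- table(B$kmer)
  A <- A[fa[A$kmer] <= max_kmer_freq, , drop = FALSE]
  B <- B[fb[B$kmer] <= max_kmer_freq, , drop = FALSE]
  m <- merge(A, B, by = "kmer")
  if (nrow(m) == 0) return(matrix(integer(0), ncol = 2))
  key <- paste(m$i, m$j)
  cnt <- table(key)
  ij <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
  df <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                   n = as.integer(cnt))
  df <- df[df$n >= 2L, , drop = FALSE]
  if (nrow(df) == 0) return(matrix(integer(0), ncol = 2))
  rank_i <- stats::ave(-df$n, df$i, FUN = rank)
  rank_j <- stats::ave(-df$n, df$j, FUN = rank)
  keep <- df$n >= min_shared | rank_i <= top_n | rank_j <= top_n
  cbind(df$i[keep], df$j[keep])
}

#' All-vs-all protein hits by local alignment
#'
#' Computes Smith-Waterman hits between two protein sets (or within one set
#' when `proteins_b` is NULL; self-hits are excluded). Scores come from a
#' compiled score-only Gotoh kernel; the identity of score-passing pairs is
#' then computed from full alignments. When the number of pairs exceeds
#' `exhaustive_pairs`, candidates are prefiltered by shared amino-acid k-mers
#' (keeping every pair with at least two shared words plus each gene's top
#' partners by word count); like any word-seeded search this can miss
#' extremely diverged pairs. Hits below the reporting thresholds are dropped.
#' Both hit directions are emitted (scores are symmetric).
#'
#' @param proteins_a named character vector of proteins.
#' @param proteins_b optional second set; NULL for intra-set hits.
#' @param params scoring configuration.
#' @param min_score,min_identity reporting thresholds.
#' @param kmer word size of the prefilter (`0` forces exhaustive alignment).
#' @param exhaustive_pairs align all pairs when there are at most this many.
#' @return data.frame with `query`, `subject`, `score`, `identity`.
#' @export
all_vs_all_hits <- function(proteins_a, proteins_b = NULL,
                            params = align_params(),
                            min_score = 50, min_identity = 0.3,
                            kmer = 4L, exhaustive_pairs = 1e6) {
  intra <- is.null(proteins_b)
  pb <- if (intra) proteins_a else proteins_b
  na <- length(proteins_a); nb <- length(pb)
  if (na == 0 || nb == 0) {
    return(data.frame(query = character(0), subject = character(0),
                      score = numeric(0), identity = numeric(0)))
  }
  n_pairs <- if (intra) as.double(na) * (na - 1) / 2 else as.double(na) * nb
  if (kmer == 0L || n_pairs <= exhaustive_pairs) {
    cand <- cbind(rep(seq_len(na), each = nb), rep(seq_len(nb), na))
  } else {
    cand <- kmer_candidates(proteins_a, pb, k = kmer)
  }
  if (intra && nrow(cand)) {
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    return(data.frame(query = character(0), subject = character(0),
                      score = numeric(0), identity = numeric(0)))
  }
  ord <- order(cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  m <- blosum62x()
  scores <- sw_score_batch(unname(proteins_a[cand[, 1]]),
                           unname(pb[cand[, 2]]),
                           m, paste(colnames(m), collapse = ""),
                           params$gap_open, params$gap_extend)
  keep <- scores >= min_score
  cand <- cand[keep, , drop = FALSE]
  scores <- scores[keep]
  if (nrow(cand) == 0) {
    return(data.frame(query = character(0), subject = character(0),
                      score = numeric(0), identity = numeric(0)))
  }
  chunks <- split(seq_len(nrow(cand)), ceiling(seq_len(nrow(cand)) / 5000))
  identity <- do.call(c, lapply(chunks, function(rows) {
    Biostrings::pid(Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(unname(proteins_a[cand[rows, 1]])),
      Biostrings::AAStringSet(unname(pb[cand[rows, 2]])),
      type = "local", substitutionMatrix = blosum62x(),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)) / 100
  }))
  hits <- data.frame(query = names(proteins_a)[cand[, 1]],
                     subject = names(pb)[cand[, 2]],
                     score = scores, identity = identity,
                     stringsAsFactors = FALSE)
  hits <- hits[hits$identity >= min_identity, , drop = FALSE]
  if (intra && nrow(hits)) {
    rev <- hits
    rev$query <- hits$subject
    rev$subject <- hits$query
    hits <- rbind(hits, rev)
  }
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Best subject per query: highest score, ties by higher identity then
# lexicographically smaller subject id (tie events reported via message).
best_hits <- function(hits, quiet = TRUE) {
  if (nrow(hits) == 0) return(hits[0, ])
  o <- order(hits$query, -hits$score, -hits$identity, hits$subject)
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$query)
  if (!quiet) {
    # a tie: the top two rows of a query share score and identity
    second <- which(first) + 1L
    second <- second[second <= nrow(h)]
    tied <- h$query[second][!first[second] &
                              h$score[second] == h$score[second - 1L] &
                              h$identity[second] == h$identity[second - 1L]]
    if (length(tied)) {
      message("RBH tie broken lexicographically for ", length(tied),
              " quer", if (length(tied) == 1) "y" else "ies")
    }
  }
  h[first, , drop = FALSE]
}

canonical_pairs <- function(a, b) {
  swap <- a > b
  data.frame(a = ifelse(swap, b, a), b = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

rbh_from_hits <- function(hits, kind, source, quiet = TRUE) {
  empty <- data.frame(a = character(0), b = character(0),
                      kind = character(0), source = character(0),
                      score = numeric(0), identity = numeric(0))
  if (nrow(hits) == 0) return(empty)
  bh <- best_hits(hits, quiet = quiet)
  fwd <- paste(bh$query, bh$subject, sep = "\r")
  rev <- paste(bh$subject, bh$query, sep = "\r")
  mutual <- bh[fwd %in% rev, , drop = FALSE]
  if (nrow(mutual) == 0) return(empty)
  cp <- canonical_pairs(mutual$query, mutual$subject)
  keep <- !duplicated(paste(cp$a, cp$b, sep = "\r"))
  out <- data.frame(a = cp$a[keep], b = cp$b[keep], kind = kind,
                    source = source, score = mutual$score[keep],
                    identity = mutual$identity[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal-best-hit orthologs between two genomes
#'
#' A pair (a, b) is emitted iff b is the unique top-scoring subject of a among
#' genome B's genes and a is the unique top-scoring subject of b among genome
#' A's genes. Score ties are broken by higher identity, then lexicographic
#' subject id (logged).
#'
#' @param genome_a,genome_b `genome` objects.
#' @param hits optional precomputed hit table (`query`, `subject`, `score`,
#'   `identity`), e.g. from [read_hits_table()]; computed internally by
#'   [all_vs_all_hits()] when NULL.
#' @param ... passed to [all_vs_all_hits()].
#' @param quiet suppress tie messages.
#' @return data.frame of homolog pairs: `a`, `b` (canonical order a < b),
#'   `kind`, `source`, `score`, `identity`.
#' @export
rbh_orthologs <- function(genome_a, genome_b, hits = NULL, quiet = TRUE, ...) {
  src <- if (is.null(hits)) "rbh" else "table"
  ids_a <- genome_a$genes$gene_id
  ids_b <- genome_b$genes$gene_id
  if (is.null(hits)) {
    hits <- all_vs_all_hits(genome_a$protein[names(genome_a$protein) %in% ids_a],
                            genome_b$protein[names(genome_b$protein) %in% ids_b],
                            ...)
    hits <- rbind(hits,
                  data.frame(query = hits$subject, subject = hits$query,
                             score = hits$score, identity = hits$identity))
  }
  hits <- hits[(hits$query %in% ids_a & hits$subject %in% ids_b) |
                 (hits$query %in% ids_b & hits$subject %in% ids_a), ,
               drop = FALSE]
  rbh_from_hits(hits, kind = "ortholog", source = src, quiet = quiet)
}

#' Reciprocal-best-hit paralogs within one genome
#'
#' Self-hits are excluded before ranking; each gene contributes to at most one
#' pair. A genome with fewer than two genes yields an empty table.
#'
#' @param genome a `genome` object.
#' @param hits optional precomputed hit table; computed internally when NULL.
#' @param quiet suppress tie messages.
#' @param ... passed to [all_vs_all_hits()].
#' @return data.frame of paralog pairs (see [rbh_orthologs()]).
#' @export
rbh_paralogs <- function(genome, hits = NULL, quiet = TRUE, ...) {
  src <- if (is.null(hits)) "rbh" else "table"
  ids <- genome$genes$gene_id
  if (length(ids) < 2) {
    return(data.frame(a = character(0), b = character(0), kind = character(0),
                      source = character(0), score = numeric(0),
                      identity = numeric(0)))
  }
  if (is.null(hits)) {
    hits <- all_vs_all_hits(genome$protein[names(genome$protein) %in% ids], ...)
  }
  hits <- hits[hits$query != hits$subject &
                 hits$query %in% ids & hits$subject %in% ids, , drop = FALSE]
  rbh_from_hits(hits, kind = "paralog", source = src, quiet = quiet)
}

#' Top-k hit pairs (non-reciprocal) for synteny anchoring
#'
#' Collinearity chaining benefits from more than one homolog per gene (a gene
#' retained in two duplicated regions should anchor both). This keeps the
#' top `k` subjects per query and returns deduplicated canonical pairs.
#'
#' @param hits hit table.
#' @param k hits kept per query.
#' @return data.frame `a`, `b`, `score`, `identity`.
#' @export
top_hit_pairs <- function(hits, k = 3L) {
  if (nrow(hits) == 0) {
    return(data.frame(a = character(0), b = character(0),
                      score = numeric(0), identity = numeric(0)))
  }
  o <- order(hits$query, -hits$score, -hits$identity, hits$subject)
  h <- hits[o, , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(h)), h$query, FUN = seq_along) <= k
  h <- h[keep, , drop = FALSE]
  cp <- canonical_pairs(h$query, h$subject)
  cp$score <- h$score
  cp$identity <- h$identity
  cp <- cp[!duplicated(paste(cp$a, cp$b, sep = "\r")), , drop = FALSE]
  cp <- cp[order(cp$a, cp$b), , drop = FALSE]
  rownames(cp) <- NULL
  cp
}

#' Build orthologous gene clusters as connected components
#'
#' Single-linkage clustering of the homolog-pair graph: connected components
#' over all supplied ortholog and paralog pairs. Singleton genes are not
#' reported. Cluster ids are assigned deterministically by the
#' lexicographically smallest member gene id.
#'
#' @param genomes list of `genome` objects (provides species membership).
#' @param pairs data.frame of homolog pairs with columns `a`, `b`.
#' @return an `ogc_table`.
#' @export
build_ogcs <- function(genomes, pairs) {
  sp_of <- do.call(c, unname(lapply(genomes, function(g)
    structure(rep(g$species, n_genes(g)), names = g$genes$gene_id))))
  if (nrow(pairs) == 0) {
    return(ogc_table(data.frame(cluster_id = character(0),
                                species = character(0),
                                gene_id = character(0))))
  }
  gr <- igraph::graph_from_data_frame(pairs[, c("a", "b")], directed = FALSE)
  cmp <- igraph::components(gr)
  members <- split(names(cmp$membership), cmp$membership)
  members <- members[order(vapply(members, min, character(1)))]
  df <- do.call(rbind, lapply(seq_along(members), function(i) {
    g <- sort(members[[i]])
    data.frame(cluster_id = sprintf("OGC%05d", i),
               species = unname(sp_of[g]),
               gene_id = g, stringsAsFactors = FALSE)
  }))
  if (any(is.na(df$species))) {
    stop("pair gene(s) not found in any genome: ",
         paste(utils::head(df$gene_id[is.na(df$species)], 3), collapse = ", "))
  }
  ogc_table(df)
}

#' Construct an OGC table
#'
#' @param df data.frame with columns `cluster_id`, `species`, `gene_id` (one
#'   row per member gene).
#' @return object of class `ogc_table` (a data.frame).
#' @export
ogc_table <- function(df) {
  stopifnot(all(c("cluster_id", "species", "gene_id") %in% names(df)))
  if (anyDuplicated(df$gene_id)) {
    stop("gene ", df$gene_id[duplicated(df$gene_id)][1],
         " assigned to more than one cluster")
  }
  rownames(df) <- NULL
  structure(df, class = c("ogc_table", "data.frame"))
}
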