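# Orthologous-gene-cluster (OGC) classification by species composition and
# cluster-level binomial functional enrichment.
#
# Clusters are labelled by which species groups contribute members: a cluster
# is specific to group A when at least two distinct A species (and no B
# species) are present, shared when both groups contribute, and unclassified
# otherwise. Enrichment of a term in a foreground cluster set against a
# background set uses a one-sided exact binomial tail with the background
# term frequency as the success probability, with Benjamini-Hochberg
# adjustment across terms; a term's duplicated occurrences within a cluster
# count once.

#' Classify clusters by species-group composition
#'
#' @param ogc an `ogc_table`.
#' @param group_a,group_b disjoint character vectors of species names.
#' @return data.frame `cluster_id`, `n_species_a`, `n_species_b`, `label` with
#'   labels in `specific_to_A`, `specific_to_B`, `shared`, `unclassified`.
#' @export
classify_ogcs <- function(ogc, group_a, group_b) {
  if (length(intersect(group_a, group_b))) {
    stop("species groups must be disjoint")
  }
  df <- as.data.frame(ogc)
  unknown <- setdiff(unique(df$species), c(group_a, group_b))
  if (length(unknown)) {
    stop("species without group label: ", paste(unknown, collapse = ", "))
  }
  sp <- split(df$species, df$cluster_id)
  na <- vapply(sp, function(s) length(unique(s[s %in% group_a])), integer(1))
  nb <- vapply(sp, function(s) length(unique(s[s %in% group_b])), integer(1))
  label <- rep("unclassified", length(sp))
  label[na >= 2 & nb == 0] <- "specific_to_A"
  label[nb >= 2 & na == 0] <- "specific_to_B"
  label[na >= 1 & nb >= 1] <- "shared"
  out <- data.frame(cluster_id = names(sp), n_species_a = na,
                    n_species_b = nb, label = label,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$cluster_id), , drop = FALSE]
}

#' Term set of a cluster
#'
#' Union of the member genes' term sets; duplicated terms count once.
#'
#' @param gene_ids member gene ids.
#' @param annotations an `annotation_table`.
#' @return character vector of distinct terms (possibly empty).
#' @export
ogc_terms <- function(gene_ids, annotations) {
  sort(unique(annotations$term[annotations$gene_id %in% gene_ids]))
}

# terms per cluster as a named list
cluster_term_sets <- function(ogc, annotations) {
  df <- as.data.frame(ogc)
  i <- match(annotations$gene_id, df$gene_id)
  keep <- !is.na(i)
  lst <- split(annotations$term[keep], df$cluster_id[i[keep]])
  lst <- lapply(lst, function(t) sort(unique(t)))
  # clusters without any annotated gene
  missing <- setdiff(unique(df$cluster_id), names(lst))
  c(lst, stats::setNames(rep(list(character(0)), length(missing)), missing))
}

#' One-sided exact binomial tail probability
#'
#' P(X >= k) for X ~ Binomial(n, p); the enrichment p-value.
#'
#' @param k observed count.
#' @param n trials.
#' @param p success probability.
#' @return upper tail probability (1 when k = 0).
#' @export
binom_tail <- function(k, n, p) {
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Cluster-level binomial term enrichment
#'
#' For each term, counts the foreground clusters carrying it (`k_fg`) and
#' tests against the background frequency `p_bg = k_bg / n_bg` with a
#' one-sided exact binomial tail P(X >= k_fg | n_fg, p_bg). By default the
#' denominators count annotated clusters only (clusters with no annotated
#' member cannot contribute to any term and would dilute both frequencies).
#' Add-one smoothing is applied to `p_bg` when `k_bg = 0`. Terms present in
#' fewer than `min_fg` foreground clusters are skipped. P-values are
#' Benjamini-Hochberg adjusted across all tested terms.
#'
#' @param foreground,background disjoint character vectors of cluster ids.
#' @param ogc an `ogc_table` covering both sets.
#' @param annotations an `annotation_table`.
#' @param alpha significance level on the adjusted p-value.
#' @param min_fg minimum foreground occurrence for a term to be tested.
#' @param annotated_only count only annotated clusters in `n_fg` / `n_bg`.
#' @return data.frame `term`, `k_fg`, `n_fg`, `k_bg`, `n_bg`, `p_bg`,
#'   `p_value`, `p_adj`, `significant`, ordered by p-value.
#' @export
binomial_enrich <- function(foreground, background, ogc, annotations,
                            alpha = 0.01, min_fg = 3L, annotated_only = TRUE) {
  if (length(background) == 0) stop("empty background")
  if (length(intersect(foreground, background))) {
    stop("foreground and background cluster sets must be disjoint")
  }
  sets <- cluster_term_sets(ogc, annotations)
  miss <- setdiff(c(foreground, background), names(sets))
  if (length(miss)) {
    stop("cluster id(s) not in table: ", paste(utils::head(miss, 3),
                                               collapse = ", "))
  }
  fg <- sets[foreground]
  bg <- sets[background]
  n_fg <- if (annotated_only) sum(lengths(fg) > 0) else length(fg)
  n_bg <- if (annotated_only) sum(lengths(bg) > 0) else length(bg)
  if (n_bg == 0) stop("no annotated background cluster")
  k_fg_t <- table(unlist(fg, use.names = FALSE))
  k_bg_t <- table(unlist(bg, use.names = FALSE))
  terms <- names(k_fg_t)[k_fg_t >= min_fg]
  if (length(terms) == 0) {
    return(data.frame(term = character(0), k_fg = integer(0),
                      n_fg = integer(0), k_bg = integer(0), n_bg = integer(0),
                      p_bg = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  }
  k_fg <- as.integer(k_fg_t[terms])
  k_bg <- as.integer(k_bg_t[terms])
  k_bg[is.na(k_bg)] <- 0L
  p_bg <- ifelse(k_bg == 0, (k_bg + 1) / (n_bg + 1), k_bg / n_bg)
  p_value <- binom_tail(k_fg, n_fg, p_bg)
  p_adj <- stats::p.adjust(p_value, method = "BH")
  out <- data.frame(term = terms, k_fg = k_fg, n_fg = n_fg,
                    k_bg = k_bg, n_bg = n_bg, p_bg = p_bg,
                    p_value = p_value, p_adj = p_adj,
                    significant = p_adj < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment of an externally supplied expanded cluster set
#'
#' The foreground is a supplied set of expanded clusters (their detection,
#' e.g. by gene-family birth-death modelling, is an upstream input). The
#' background is the conserved core: clusters containing at least one species
#' from every clade, minus the expanded set (so the two are disjoint).
#'
#' @param expanded character vector of expanded cluster ids.
#' @param ogc an `ogc_table`.
#' @param clade_map named character vector: species -> clade.
#' @param annotations an `annotation_table`.
#' @param ... passed to [binomial_enrich()].
#' @return enrichment table, see [binomial_enrich()].
#' @export
expanded_set_enrich <- function(expanded, ogc, clade_map, annotations, ...) {
  df <- as.data.frame(ogc)
  miss <- setdiff(expanded, df$cluster_id)
  if (length(miss)) {
    stop("expanded cluster id(s) not in table: ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  unknown <- setdiff(unique(df$species), names(clade_map))
  if (length(unknown)) {
    stop("species without clade: ", paste(unknown, collapse = ", "))
  }
  clades <- sort(unique(clade_map))
  per_cluster <- split(clade_map[df$species], df$cluster_id)
  conserved <- names(per_cluster)[vapply(per_cluster, function(cl)
    all(clades %in% cl), logical(1))]
  background <- setdiff(conserved, expanded)
  binomial_enrich(expanded, background, ogc, annotations, ...)
}
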