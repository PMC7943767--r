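# Genome-evolution simulator with ground truth.
#
# An ancestral gene set of random sense codons evolves along a ladder of
# speciation events; the focal lineage can additionally undergo whole-genome
# duplications (every gene duplicated onto a mirrored chromosome set, each
# copy retained with a configurable probability), recent tandem duplications,
# and rearrangements (inversions, translocations). Substitution follows the
# K80 model applied per nucleotide site with stop-codon proposals rejected:
# per branch the proposal intensity per site equals the nominal synonymous
# divergence of the branch, so neutrally evolving (fourfold) sites realise
# exactly the configured distance, while nonsynonymous divergence is emergent.
# GO terms are drawn per ancestral family from a power-law vocabulary, with
# planted terms oversampled in families destined for a target species group.
# Every duplicate/ortholog pair carries a truth row with its origin and true
# synonymous divergence.

#' Simulation configuration
#'
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @param n_genes ancestral gene count.
#' @param n_chromosomes ancestral chromosome count.
#' @param codons_per_gene codons per gene.
#' @param synonymous_rate synonymous substitutions per site per year.
#' @param kappa transition/transversion rate ratio of the K80 model.
#' @param wgd_events list of `list(time_mya=, retention_prob=)`, focal lineage
#'   only.
#' @param speciation_times_mya named numeric vector: sister species name ->
#'   split time from the focal lineage (million years).
#' @param species focal species name.
#' @param species_groups optional named character vector species -> group
#'   label (e.g. cactus / noncactus); enables family-presence sampling and
#'   planted enrichment.
#' @param group_fractions when groups are set: fractions of ancestral families
#'   destined to be specific to group A, specific to group B, or shared.
#' @param tandem_rate per-gene probability of one recent tandem copy (focal).
#' @param tandem_depth synonymous divergence of a tandem pair.
#' @param n_inversions,n_translocations rearrangement counts (focal).
#' @param go_vocab_size GO vocabulary size; term i has base frequency
#'   proportional to i^-1.5 (scaled so the most common term has frequency
#'   `go_base_p1`).
#' @param go_base_p1 frequency of the most common term.
#' @param planted_terms list of `list(term=, target_group=, fold=)`:
#'   term frequency multiplied by `fold` in families destined to be specific
#'   to `target_group`.
#' @param intergenic_bp gap between consecutive genes.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 500L, n_chromosomes = 4L,
                       codons_per_gene = 300L,
                       synonymous_rate = 1.5e-8, kappa = 2,
                       wgd_events = list(list(time_mya = 25.7,
                                              retention_prob = 0.75)),
                       speciation_times_mya = c(),
                       species = "focal",
                       species_groups = NULL,
                       group_fractions = c(specific_a = 0.25,
                                           specific_b = 0.15, shared = 0.6),
                       tandem_rate = 0.1, tandem_depth = 0.05,
                       n_inversions = 2L, n_translocations = 1L,
                       go_vocab_size = 200L, go_base_p1 = 0.8,
                       planted_terms = list(),
                       intergenic_bp = 2000L) {
  stopifnot(synonymous_rate >= 0, kappa > 0, tandem_rate >= 0,
            tandem_depth >= 0, n_genes >= 1, n_chromosomes >= 1,
            codons_per_gene >= 2)
  for (w in wgd_events) {
    if (is.null(w$time_mya) || w$time_mya < 0) stop("WGD time must be >= 0")
    if (is.null(w$retention_prob) || w$retention_prob <= 0 ||
        w$retention_prob > 1) {
      stop("retention_prob must be in (0, 1]")
    }
  }
  if (length(speciation_times_mya) && is.null(names(speciation_times_mya))) {
    stop("speciation_times_mya must be a named vector")
  }
  if (any(speciation_times_mya < 0)) stop("speciation times must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

# One evolved branch for one gene. `cod` is an integer vector of codon
# indices; `d` is the branch's per-site substitution intensity. Proposals that
# would create a stop codon are rejected.
evolve_cds_idx <- function(cod, d, kappa, tb) {
  L <- 3L * length(cod)
  n_prop <- stats::rpois(1L, d * L)
  n_events <- 0L; n_syn <- 0L
  if (n_prop > 0L) {
    sites <- sample.int(L, n_prop, replace = TRUE)
    u <- stats::runif(n_prop)
    p_ts <- kappa / (kappa + 2)
    p_ts1 <- p_ts + (1 - p_ts) / 2
    aa <- tb$aa; is_stop <- tb$is_stop
    for (m in seq_len(n_prop)) {
      s <- sites[m]
      ci <- (s - 1L) %/% 3L + 1L
      p <- s - (ci - 1L) * 3L
      cur <- cod[ci]
      i0 <- cur - 1L
      dcur <- switch(p, i0 %/% 16L, (i0 %/% 4L) %% 4L, i0 %% 4L)
      b <- if (u[m] < p_ts) {
        (dcur + 2L) %% 4L            # transition partner
      } else if (dcur %% 2L == 0L) { # purine: transversions to C/T
        if (u[m] < p_ts1) 1L else 3L
      } else {                       # pyrimidine: transversions to A/G
        if (u[m] < p_ts1) 0L else 2L
      }
      nc <- cur + (b - dcur) * c(16L, 4L, 1L)[p]
      if (is_stop[nc]) next
      if (aa[nc] == aa[cur]) n_syn <- n_syn + 1L
      n_events <- n_events + 1L
      cod[ci] <- nc
    }
  }
  list(cod = cod, n_prop = n_prop, n_events = n_events, n_syn = n_syn)
}

#' Evolve coding sequences along one branch
#'
#' Exposed mainly for calibration checks: evolves each CDS under K80 with
#' stop rejection at per-site proposal intensity `d`.
#'
#' @param cds character vector of coding sequences (whole codons, no stops).
#' @param d branch length: substitution proposals per site.
#' @param kappa transition/transversion rate ratio.
#' @return list with `cds` (evolved sequences), `n_proposals`, `n_events`,
#'   `n_syn_events` per gene.
#' @export
evolve_genes <- function(cds, d, kappa = 2) {
  tb <- codon_tables()
  idx <- lapply(cds, function(s) {
    i <- codon_index(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)))
    if (anyNA(i) || any(tb$is_stop[i])) stop("CDS must be stop-free ACGT codons")
    i
  })
  res <- lapply(idx, evolve_cds_idx, d = d, kappa = kappa, tb = tb)
  list(cds = vapply(res, function(r) paste(codon_string(r$cod), collapse = ""),
                    character(1)),
       n_proposals = vapply(res, `[[`, integer(1), "n_prop"),
       n_events = vapply(res, `[[`, integer(1), "n_events"),
       n_syn_events = vapply(res, `[[`, integer(1), "n_syn"))
}

# --- internal lineage state -------------------------------------------------
# seqs: list of codon-index vectors, indexed by gene uid
# fam:  ancestral family per uid; tokens: list of (label, time_mya) per uid
# strand: "+"/"-" per uid; chrom: list of uid vectors in chromosomal order

evolve_state <- function(state, d, kappa, tb) {
  if (d <= 0) return(state)
  uids <- unlist(state$chrom, use.names = FALSE)
  for (u in uids) {
    r <- evolve_cds_idx(state$seqs[[u]], d, kappa, tb)
    state$seqs[[u]] <- r$cod
  }
  state
}

apply_wgd <- function(state, retention, label, time_mya) {
  n_old <- length(state$chrom)
  for (k in seq_len(n_old)) {
    new_uids <- integer(0)
    for (u in state$chrom[[k]]) {
      if (stats::runif(1) > retention) next
      v <- length(state$seqs) + 1L
      state$seqs[[v]] <- state$seqs[[u]]
      state$fam[v] <- state$fam[u]
      state$strand[v] <- state$strand[u]
      state$tokens[[v]] <- list(labels = c(state$tokens[[u]]$labels, label),
                                times = c(state$tokens[[u]]$times, time_mya))
      new_uids <- c(new_uids, v)
    }
    state$chrom[[n_old + k]] <- new_uids
  }
  state
}

apply_tandems <- function(state, rate, depth, kappa, tb, rate_my) {
  if (rate <= 0) return(state)
  t_mya <- depth / (2 * rate_my)
  for (k in seq_along(state$chrom)) {
    uids <- state$chrom[[k]]
    out <- integer(0)
    for (u in uids) {
      out <- c(out, u)
      if (stats::runif(1) < rate) {
        v <- length(state$seqs) + 1L
        r <- evolve_cds_idx(state$seqs[[u]], depth, kappa, tb)
        state$seqs[[v]] <- r$cod
        state$fam[v] <- state$fam[u]
        state$strand[v] <- state$strand[u]
        state$tokens[[v]] <- list(labels = c(state$tokens[[u]]$labels, "t"),
                                  times = c(state$tokens[[u]]$times, t_mya))
        out <- c(out, v)
      }
    }
    state$chrom[[k]] <- out
  }
  state
}

apply_inversion <- function(state) {
  sizes <- lengths(state$chrom)
  elig <- which(sizes >= 6L)
  if (!length(elig)) return(state)
  k <- elig[sample.int(length(elig), 1L)]
  n <- sizes[k]
  len <- sample(3:max(3L, n %/% 3L), 1L)
  i <- sample.int(n - len + 1L, 1L)
  seg <- i:(i + len - 1L)
  uids <- state$chrom[[k]]
  uids[seg] <- rev(uids[seg])
  flip <- uids[seg]
  state$strand[flip] <- ifelse(state$strand[flip] == "+", "-", "+")
  state$chrom[[k]] <- uids
  state
}

apply_translocation <- function(state) {
  sizes <- lengths(state$chrom)
  if (length(sizes) < 2L) return(state)
  elig <- which(sizes >= 6L)
  if (!length(elig)) return(state)
  k <- elig[sample.int(length(elig), 1L)]
  n <- sizes[k]
  len <- sample(3:max(3L, n %/% 4L), 1L)
  i <- sample.int(n - len + 1L, 1L)
  seg <- i:(i + len - 1L)
  moved <- state$chrom[[k]][seg]
  state$chrom[[k]] <- state$chrom[[k]][-seg]
  dest <- sample(setdiff(seq_along(state$chrom), k), 1L)
  m <- length(state$chrom[[dest]])
  at <- sample.int(m + 1L, 1L) - 1L
  state$chrom[[dest]] <- append(state$chrom[[dest]], moved, after = at)
  state
}

# split time (mya) of two copies from their duplication-token paths; floor is
# the speciation time separating the carrying lineages (0 within a genome)
pair_split <- function(tok_u, tok_v, floor_time = 0) {
  lu <- tok_u$labels; lv <- tok_v$labels
  n <- max(length(lu), length(lv))
  t_diff <- -Inf; lab <- NA_character_
  for (i in seq_len(n)) {
    a <- if (i <= length(lu)) lu[i] else NA
    b <- if (i <= length(lv)) lv[i] else NA
    if (identical(a, b)) next
    ta <- if (i <= length(tok_u$times)) tok_u$times[i] else -Inf
    tb <- if (i <= length(tok_v$times)) tok_v$times[i] else -Inf
    t_diff <- max(ta, tb, na.rm = TRUE)
    lab <- if (is.finite(ta) && ta >= tb) a else b
    break
  }
  if (t_diff > floor_time) {
    list(time = t_diff, origin = if (identical(substr(lab, 1, 1), "t"))
      "tandem" else "wgd")
  } else {
    list(time = floor_time, origin = "speciation")
  }
}

state_gene_ids <- function(state, species) {
  tags <- vapply(state$tokens, function(t) paste(t$labels, collapse = ""),
                 character(1))
  sprintf("%s_g%04d%s", species, state$fam, tags)
}

assemble_genome <- function(state, species, group, present_fams, config) {
  tb <- codon_tables()
  ids <- state_gene_ids(state, species)
  gene_len <- 3L * config$codons_per_gene
  rows <- list(); cds <- character(0)
  for (k in seq_along(state$chrom)) {
    uids <- state$chrom[[k]]
    uids <- uids[state$fam[uids] %in% present_fams]
    if (!length(uids)) next
    pos <- seq_along(uids)
    start <- (pos - 1L) * (gene_len + config$intergenic_bp) + 1L
    rows[[k]] <- data.frame(gene_id = ids[uids],
                            chrom = sprintf("chr%02d", k),
                            start = start, end = start + gene_len - 1L,
                            strand = state$strand[uids],
                            stringsAsFactors = FALSE)
    cds <- c(cds, stats::setNames(vapply(state$seqs[uids], function(s)
      paste(codon_string(s), collapse = ""), character(1)), ids[uids]))
  }
  genes <- do.call(rbind, rows)
  new_genome(species, genes, cds = cds, group = group)
}

#' Run the genome-evolution simulation
#'
#' @param config a [sim_config()].
#' @return list of class `sim_result` with `genomes` (focal genome first),
#'   `annotations` (an `annotation_table`), `truth` (class `sim_truth`: list
#'   with `pairs` - per-pair origin and true synonymous divergence -,
#'   `anchors` - the planted focal duplicate anchor map -, `group_truth`,
#'   `enriched_terms`, `families`), and the `config`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tb <- codon_tables()
  sense <- which(!tb$is_stop)
  rate_my <- config$synonymous_rate * 1e6   # per site per MY
  n <- config$n_genes

  # destined family labels and term sampling
  groups <- config$species_groups
  fam_label <- rep("shared", n)
  if (!is.null(groups)) {
    fr <- config$group_fractions
    fam_label <- sample(c("specific_to_A", "specific_to_B", "shared"), n,
                        replace = TRUE,
                        prob = c(fr[["specific_a"]], fr[["specific_b"]],
                                 fr[["shared"]]))
  }
  vocab <- sprintf("GO:%07d", seq_len(config$go_vocab_size))
  base_p <- config$go_base_p1 * seq_len(config$go_vocab_size)^(-1.5)
  planted <- config$planted_terms
  fam_terms <- vector("list", n)
  for (f in seq_len(n)) {
    p <- base_p
    for (pl in planted) {
      j <- match(pl$term, vocab)
      if (is.na(j)) stop("planted term not in vocabulary: ", pl$term)
      target_label <- if (identical(pl$target_group, "A")) "specific_to_A"
                      else "specific_to_B"
      if (fam_label[f] == target_label) p[j] <- min(1, p[j] * pl$fold)
    }
    fam_terms[[f]] <- vocab[stats::runif(length(p)) < p]
  }

  # ancestral state
  state <- list(
    seqs = lapply(seq_len(n), function(i)
      sample(sense, config$codons_per_gene, replace = TRUE)),
    fam = seq_len(n),
    strand = rep("+", n),
    tokens = rep(list(list(labels = character(0), times = numeric(0))), n),
    chrom = split(seq_len(n),
                  cut(seq_len(n), config$n_chromosomes, labels = FALSE))
  )

  # event timeline on the focal lineage (descending time)
  spec_t <- config$speciation_times_mya
  ev <- rbind(
    if (length(spec_t)) data.frame(time = as.numeric(spec_t), type = "spec",
                                   who = names(spec_t)),
    if (length(config$wgd_events)) data.frame(
      time = vapply(config$wgd_events, `[[`, numeric(1), "time_mya"),
      type = "wgd",
      who = paste0("w", seq_along(config$wgd_events)))
  )
  sisters <- list()
  now <- if (!is.null(ev) && nrow(ev)) max(ev$time) else 0
  if (!is.null(ev) && nrow(ev)) {
    ev <- ev[order(-ev$time, ev$type), , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      state <- evolve_state(state, rate_my * (now - ev$time[r]),
                            config$kappa, tb)
      now <- ev$time[r]
      if (ev$type[r] == "spec") {
        sister <- evolve_state(state, rate_my * ev$time[r], config$kappa, tb)
        sisters[[ev$who[r]]] <- list(state = sister, split = ev$time[r])
      } else {
        w <- config$wgd_events[[as.integer(sub("w", "", ev$who[r]))]]
        state <- apply_wgd(state, w$retention_prob, ev$who[r], ev$time[r])
      }
    }
  }
  state <- evolve_state(state, rate_my * now, config$kappa, tb)
  state <- apply_tandems(state, config$tandem_rate, config$tandem_depth,
                         config$kappa, tb, rate_my)
  for (i in seq_len(config$n_inversions)) state <- apply_inversion(state)
  for (i in seq_len(config$n_translocations)) state <- apply_translocation(state)

  # species presence of families
  focal_group <- if (!is.null(groups)) groups[[config$species]] else NA
  group_letter <- function(sp) {
    if (is.null(groups)) return(NA_character_)
    g <- groups[[sp]]
    if (is.na(g)) NA_character_ else if (g == groups[[config$species]]) "A"
    else "B"
  }
  present_for <- function(sp) {
    if (is.null(groups)) return(seq_len(n))
    gl <- group_letter(sp)
    keep <- switch(gl,
                   A = fam_label != "specific_to_B",
                   B = fam_label != "specific_to_A",
                   rep(TRUE, n))
    which(keep)
  }

  focal <- assemble_genome(state, config$species,
                           if (!is.null(groups)) groups[[config$species]] else "",
                           present_for(config$species), config)
  genomes <- list(focal)
  names(genomes) <- config$species
  for (s in names(sisters)) {
    genomes[[s]] <- assemble_genome(sisters[[s]]$state, s,
                                    if (!is.null(groups)) groups[[s]] else "",
                                    present_for(s), config)
  }

  # truth pairs (focal-centric)
  focal_ids <- state_gene_ids(state, config$species)
  focal_present <- focal$genes$gene_id
  pairs <- list()
  by_fam <- split(seq_along(state$fam), state$fam)
  for (f in names(by_fam)) {
    uids <- by_fam[[f]]
    uids <- uids[focal_ids[uids] %in% focal_present]
    if (length(uids) >= 2) {
      cmb <- utils::combn(uids, 2)
      for (c2 in seq_len(ncol(cmb))) {
        u <- cmb[1, c2]; v <- cmb[2, c2]
        sp <- pair_split(state$tokens[[u]], state$tokens[[v]], 0)
        cp <- canonical_pairs(focal_ids[u], focal_ids[v])
        pairs[[length(pairs) + 1L]] <- data.frame(
          a = cp$a, b = cp$b, origin = sp$origin,
          d_true = 2 * rate_my * sp$time, stringsAsFactors = FALSE)
      }
    }
    for (s in names(sisters)) {
      st <- sisters[[s]]$state
      sids <- state_gene_ids(st, s)
      spres <- genomes[[s]]$genes$gene_id
      vids <- which(st$fam == as.integer(f))
      vids <- vids[sids[vids] %in% spres]
      for (u in uids) for (v in vids) {
        sp <- pair_split(state$tokens[[u]], st$tokens[[v]],
                         sisters[[s]]$split)
        cp <- canonical_pairs(focal_ids[u], sids[v])
        pairs[[length(pairs) + 1L]] <- data.frame(
          a = cp$a, b = cp$b, origin = sp$origin,
          d_true = 2 * rate_my * sp$time, stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a = character(0), b = character(0), origin = character(0),
               d_true = numeric(0))

  # planted anchor map of focal duplicates (the collinear structure a perfect
  # synteny detector should recover)
  wgd_pairs <- pairs[pairs$origin == "wgd" &
                       pairs$a %in% focal_present &
                       pairs$b %in% focal_present, , drop = FALSE]
  anchors <- if (nrow(wgd_pairs)) {
    anchors_from_pairs(wgd_pairs, focal, exclude_tandem_window = 0L)
  } else NULL

  # annotations for every emitted gene
  ann_rows <- list()
  for (g in genomes) {
    fams <- as.integer(sub("^.*_g([0-9]+).*$", "\\1", g$genes$gene_id))
    terms <- fam_terms[fams]
    keep <- lengths(terms) > 0
    if (any(keep)) {
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        gene_id = rep(g$genes$gene_id[keep], lengths(terms[keep])),
        term = unlist(terms[keep]), stringsAsFactors = FALSE)
    }
  }
  ann <- annotation_table(if (length(ann_rows)) do.call(rbind, ann_rows) else
    data.frame(gene_id = character(0), term = character(0)))

  truth <- structure(list(
    pairs = pairs,
    anchors = anchors,
    group_truth = data.frame(family = seq_len(n), label = fam_label,
                             stringsAsFactors = FALSE),
    enriched_terms = if (length(planted)) data.frame(
      term = vapply(planted, `[[`, character(1), "term"),
      target_group = vapply(planted, `[[`, character(1), "target_group"),
      fold = vapply(planted, `[[`, numeric(1), "fold")) else
        data.frame(term = character(0), target_group = character(0),
                   fold = numeric(0)),
    families = fam_terms), class = "sim_truth")

  structure(list(genomes = genomes, annotations = ann, truth = truth,
                 config = config), class = "sim_result")
}

#' Fast cluster/annotation simulator for enrichment testing
#'
#' Generates foreground and background cluster sets with term annotations
#' drawn from a power-law vocabulary; planted terms are oversampled in the
#' foreground by their fold factor. No sequences are involved, so large
#' replicate studies of the enrichment statistics are cheap.
#'
#' @param n_fg,n_bg numbers of foreground / background clusters.
#' @param go_vocab_size,go_base_p1 vocabulary settings (term i has base
#'   frequency `go_base_p1 * i^-1.5`).
#' @param planted list of `list(term_index=, fold=)`.
#' @param seed RNG seed.
#' @return list with `ogc` (an `ogc_table`), `annotations`, `foreground`,
#'   `background` (cluster id vectors), `planted_terms`.
#' @export
simulate_cluster_annotations <- function(n_fg, n_bg, go_vocab_size = 200L,
                                         go_base_p1 = 0.8,
                                         planted = list(), seed = 1L) {
  set.seed(seed)
  vocab <- sprintf("GO:%07d", seq_len(go_vocab_size))
  base_p <- go_base_p1 * seq_len(go_vocab_size)^(-1.5)
  fg_p <- base_p
  for (pl in planted) fg_p[pl$term_index] <- min(1, base_p[pl$term_index] * pl$fold)
  draw <- function(prefix, m, p) {
    ids <- sprintf("%s%05d", prefix, seq_len(m))
    rows <- lapply(seq_len(m), function(i) {
      terms <- vocab[stats::runif(length(p)) < p]
      gene <- sprintf("%s_gene", ids[i])
      list(ogc = data.frame(cluster_id = ids[i],
                            species = c("spA1", "spA2"),
                            gene_id = paste0(gene, c(".1", ".2")),
                            stringsAsFactors = FALSE),
           ann = if (length(terms)) data.frame(gene_id = paste0(gene, ".1"),
                                               term = terms,
                                               stringsAsFactors = FALSE))
    })
    list(ids = ids,
         ogc = do.call(rbind, lapply(rows, `[[`, "ogc")),
         ann = do.call(rbind, lapply(rows, `[[`, "ann")))
  }
  fg <- draw("FG", n_fg, fg_p)
  bg <- draw("BG", n_bg, base_p)
  ann <- rbind(fg$ann, bg$ann)
  if (is.null(ann)) ann <- data.frame(gene_id = character(0),
                                      term = character(0))
  list(ogc = ogc_table(rbind(fg$ogc, bg$ogc)),
       annotations = annotation_table(ann),
       foreground = fg$ids, background = bg$ids,
       planted_terms = vapply(planted, function(pl) vocab[pl$term_index],
                              character(1)))
}

#' Recovery metrics of estimates against simulation truth
#'
#' @param truth a `sim_truth`.
#' @param estimates a divergence table (from [divergence_table()]) keyed by
#'   the same gene pairs.
#' @param chained optional [chain_blocks()] output on the focal genome, scored
#'   against the planted anchor map.
#' @param enrichment optional [binomial_enrich()] output, scored against the
#'   planted terms.
#' @return list with `divergence` (per-origin n, median bias and RMSE of ks
#'   against true divergence), `blocks` (anchor precision/recall) and
#'   `enrichment` (planted-term recall), the latter two NULL when not
#'   supplied.
#' @export
truth_report <- function(truth, estimates, chained = NULL, enrichment = NULL) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  tr <- truth$pairs
  m <- match(key(estimates$a, estimates$b), key(tr$a, tr$b))
  est <- estimates[!is.na(m), , drop = FALSE]
  tru <- tr[m[!is.na(m)], , drop = FALSE]
  div <- if (nrow(est)) {
    do.call(rbind, lapply(split(seq_len(nrow(est)), tru$origin), function(i) {
      err <- est$ks[i] - tru$d_true[i]
      data.frame(origin = tru$origin[i][1], n = length(i),
                 median_bias = stats::median(err, na.rm = TRUE),
                 rmse = sqrt(mean(err^2, na.rm = TRUE)),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(origin = character(0), n = integer(0),
                    median_bias = numeric(0), rmse = numeric(0))
  rownames(div) <- NULL
  blocks <- NULL
  if (!is.null(chained) && !is.null(truth$anchors)) {
    anc <- chained$anchors
    anc <- anc[!is.na(anc$block_id), , drop = FALSE]
    got <- key(anc$a, anc$b)
    want <- key(truth$anchors$a, truth$anchors$b)
    blocks <- data.frame(precision = if (length(got)) mean(got %in% want)
                         else NA_real_,
                         recall = if (length(want)) mean(want %in% got)
                         else NA_real_)
  }
  enr <- NULL
  if (!is.null(enrichment) && nrow(truth$enriched_terms)) {
    sig <- enrichment$term[enrichment$significant]
    enr <- data.frame(planted = nrow(truth$enriched_terms),
                      recovered = sum(truth$enriched_terms$term %in% sig),
                      recall = mean(truth$enriched_terms$term %in% sig))
  }
  list(divergence = div, blocks = blocks, enrichment = enr)
}
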