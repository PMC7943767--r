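# Pipeline driver: simulate -> homology -> divergence -> synteny ->
# enrichment, exchanging plain TSV between stages and recording a JSON
# manifest (config snapshot, seeds, per-stage parameters, output digests).
# Deterministic stages reproduce byte-identical outputs given the same
# configuration and seed.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the simulated inputs.
#' @param homology list: `min_score`, `min_identity` (hit reporting
#'   thresholds), `anchor_k` (top hits per gene kept for synteny anchoring).
#' @param divergence list: `rate` (synonymous substitutions/site/year for
#'   dating), `max_components`, `correct_4dtv`, `peak_seed`.
#' @param synteny list: `max_gap`, `min_block`, `tandem_window`.
#' @param enrichment list: `alpha`, `min_fg`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            homology = list(),
                            divergence = list(),
                            synteny = list(),
                            enrichment = list()) {
  merge_defaults <- function(x, d) { d[names(x)] <- x; d }
  structure(list(
    sim = sim,
    homology = merge_defaults(homology, list(min_score = 50,
                                             min_identity = 0.3,
                                             anchor_k = 2L)),
    divergence = merge_defaults(divergence, list(rate = 1.5e-8,
                                                 max_components = 4L,
                                                 correct_4dtv = FALSE,
                                                 peak_seed = 1729L)),
    synteny = merge_defaults(synteny, list(max_gap = 25L, min_block = 5L,
                                           tandem_window = 10L)),
    enrichment = merge_defaults(enrichment, list(alpha = 0.01, min_fg = 3L))
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `sim` block
#' mirrors [sim_config()] fields.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simargs <- y$sim
  if (!is.null(simargs$speciation_times_mya)) {
    simargs$speciation_times_mya <- unlist(simargs$speciation_times_mya)
  }
  if (!is.null(simargs$species_groups)) {
    simargs$species_groups <- unlist(simargs$species_groups)
  }
  pipeline_config(sim = do.call(sim_config, simargs),
                  homology = y$homology %||% list(),
                  divergence = y$divergence %||% list(),
                  synteny = y$synteny %||% list(),
                  enrichment = y$enrichment %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_msg <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing every intermediate as TSV
#' under `outdir` and a `manifest.json` with the configuration snapshot, seed,
#' per-stage parameters and md5 digests of all outputs. Log lines report
#' counts (genes, pairs, blocks, terms tested), never timings.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @param outdir output directory, created if needed.
#' @param stages subset of
#'   `c("simulate","homology","divergence","synteny","enrichment")`; earlier
#'   stages not run are loaded from their files in `outdir` (a missing file is
#'   an error naming the stage and path).
#' @param quiet suppress progress messages.
#' @return the manifest (list), invisibly. All results are also returned in
#'   the `results` element.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "homology", "divergence",
                                    "synteny", "enrichment"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outdir, ...)
  need <- function(stage, path) {
    if (!file.exists(path)) {
      stop("stage '", stage, "': missing input ", path)
    }
    path
  }
  res <- list()

  # --- simulate --------------------------------------------------------------
  if ("simulate" %in% stages) {
    sim <- simulate_genomes(config$sim)
    for (g in sim$genomes) {
      write_genome(g, pth(paste0(g$species, ".gff3")),
                   fna = pth(paste0(g$species, ".fna")),
                   faa = pth(paste0(g$species, ".faa")))
    }
    write_annotation_table(sim$annotations, pth("go.tsv"))
    write_tsv(sim$truth$pairs, pth("truth_pairs.tsv"))
    if (!quiet) stage_msg("simulate", length(sim$genomes), " genome(s), ",
                          sum(vapply(sim$genomes, n_genes, integer(1))),
                          " genes")
    res$sim <- sim
    genomes <- sim$genomes
  } else {
    species <- c(config$sim$species, names(config$sim$speciation_times_mya))
    genomes <- lapply(species, function(s) {
      read_gff3(need("homology", pth(paste0(s, ".gff3"))),
                cds = read_fasta(need("homology", pth(paste0(s, ".fna"))),
                                 type = "nt"),
                species = s,
                group = if (!is.null(config$sim$species_groups))
                  config$sim$species_groups[[s]] else "")
    })
    names(genomes) <- species
  }
  focal <- genomes[[1]]

  # --- homology --------------------------------------------------------------
  hp <- config$homology
  if ("homology" %in% stages) {
    intra_hits <- all_vs_all_hits(focal$protein, min_score = hp$min_score,
                                  min_identity = hp$min_identity)
    paralogs <- rbh_paralogs(focal, hits = intra_hits)
    paralogs$source <- "rbh"
    pairs <- paralogs
    anchor_pairs <- top_hit_pairs(intra_hits, k = hp$anchor_k)
    inter_anchors <- list()
    for (s in names(genomes)[-1]) {
      ih <- all_vs_all_hits(focal$protein, genomes[[s]]$protein,
                            min_score = hp$min_score,
                            min_identity = hp$min_identity)
      ih2 <- rbind(ih, data.frame(query = ih$subject, subject = ih$query,
                                  score = ih$score, identity = ih$identity))
      orth <- rbh_orthologs(focal, genomes[[s]], hits = ih2)
      orth$source <- "rbh"
      pairs <- rbind(pairs, orth)
      inter_anchors[[s]] <- top_hit_pairs(ih, k = hp$anchor_k)
    }
    write_tsv(pairs, pth("pairs.tsv"))
    write_tsv(anchor_pairs, pth("anchor_pairs.tsv"))
    for (s in names(inter_anchors)) {
      write_tsv(inter_anchors[[s]], pth(paste0("anchor_pairs_", s, ".tsv")))
    }
    if (!quiet) stage_msg("homology", nrow(pairs), " RBH pairs (",
                          sum(pairs$kind == "paralog"), " paralog)")
  } else {
    pairs <- read_tsv(need("divergence", pth("pairs.tsv")))
    anchor_pairs <- read_tsv(need("synteny", pth("anchor_pairs.tsv")))
    inter_anchors <- list()
    for (s in names(genomes)[-1]) {
      f <- pth(paste0("anchor_pairs_", s, ".tsv"))
      if (file.exists(f)) inter_anchors[[s]] <- read_tsv(f)
    }
  }
  res$pairs <- pairs

  # --- divergence ------------------------------------------------------------
  dv <- config$divergence
  if ("divergence" %in% stages) {
    div <- divergence_table(pairs, genomes, correct_4dtv = dv$correct_4dtv)
    write_tsv(div, pth("ks4dtv.tsv"))
    par_ks <- div$ks[div$kind == "paralog" & !div$saturated]
    peaks <- tryCatch(
      date_peak(detect_peaks(par_ks, "ks",
                             max_components = dv$max_components,
                             seed = dv$peak_seed), rate = dv$rate),
      error = function(e) {
        if (!quiet) stage_msg("divergence", "peak detection skipped: ",
                              conditionMessage(e))
        NULL
      })
    if (!is.null(peaks)) write_tsv(peaks, pth("peaks.tsv"))
    if (!quiet) stage_msg("divergence", nrow(div), " pairs, ",
                          if (is.null(peaks)) 0 else nrow(peaks), " ks peaks")
  } else {
    div <- read_tsv(need("synteny", pth("ks4dtv.tsv")))
    peaks <- if (file.exists(pth("peaks.tsv"))) read_tsv(pth("peaks.tsv"))
  }
  res$divergence <- div
  res$peaks <- peaks

  # --- synteny ---------------------------------------------------------------
  sy <- config$synteny
  if ("synteny" %in% stages) {
    anc <- anchors_from_pairs(anchor_pairs, focal,
                              exclude_tandem_window = sy$tandem_window)
    chained <- chain_blocks(anc, max_gap = sy$max_gap,
                            min_block = sy$min_block)
    write_tsv(chained$blocks, pth("blocks.tsv"))
    write_tsv(dotplot_table(chained), pth("dotplot.tsv"))
    div_blocks <- restrict_to_blocks(div, chained)
    write_tsv(div_blocks, pth("ks4dtv_in_blocks.tsv"))
    par_pairs <- pairs[pairs$kind == "paralog", , drop = FALSE]
    tandem <- classify_tandem(par_pairs, focal, window = sy$tandem_window)
    write_tsv(tandem, pth("tandem.tsv"))
    depth <- NULL
    if (length(genomes) > 1 && length(inter_anchors)) {
      s <- names(genomes)[2]
      ianc <- anchors_from_pairs(inter_anchors[[s]], focal, genomes[[s]])
      ichained <- chain_blocks(ianc, max_gap = sy$max_gap,
                               min_block = sy$min_block)
      depth <- synteny_depth(ichained, genomes[[s]])
      write_tsv(depth$histogram, pth(paste0("depth_", s, ".tsv")))
      res$inter_blocks <- ichained
    }
    if (!quiet) stage_msg("synteny", nrow(chained$blocks), " blocks, ",
                          sum(tandem$class == "tandem"), " tandem pairs")
    res$blocks <- chained
    res$div_blocks <- div_blocks
    res$tandem <- tandem
    res$depth <- depth
  }

  # --- enrichment ------------------------------------------------------------
  en <- config$enrichment
  if ("enrichment" %in% stages) {
    ogc <- build_ogcs(genomes, pairs)
    write_cluster_table(ogc, pth("ogcs.tsv"))
    ann <- if ("simulate" %in% stages) res$sim$annotations else
      read_annotation_table(need("enrichment", pth("go.tsv")))
    groups <- config$sim$species_groups
    enrich <- NULL
    if (!is.null(groups) && length(unique(groups)) >= 2) {
      ga <- names(groups)[groups == groups[[config$sim$species]]]
      gb <- setdiff(names(groups), ga)
      cls <- classify_ogcs(ogc, ga, gb)
      write_tsv(cls, pth("ogc_classes.tsv"))
      fg <- cls$cluster_id[cls$label == "specific_to_A"]
      bg <- cls$cluster_id[cls$label == "shared"]
      if (length(fg) && length(bg)) {
        enrich <- binomial_enrich(fg, bg, ogc, ann, alpha = en$alpha,
                                  min_fg = en$min_fg)
        write_tsv(enrich, pth("enrichment.tsv"))
      }
      res$ogc_classes <- cls
    }
    if (!quiet) stage_msg("enrichment", length(unique(ogc$cluster_id)),
                          " clusters, ",
                          if (is.null(enrich)) 0 else nrow(enrich),
                          " terms tested")
    res$ogc <- ogc
    res$enrichment <- enrich
  }

  files <- sort(list.files(outdir, pattern = "\\.(tsv|gff3|fna|faa)$",
                           full.names = TRUE))
  manifest <- list(
    tool = "paleodup",
    version = as.character(utils::packageVersion("paleodup")),
    seed = config$sim$seed,
    stages = stages,
    parameters = config[c("homology", "divergence", "synteny", "enrichment")],
    sim = config$sim[setdiff(names(config$sim), c("wgd_events",
                                                  "planted_terms"))],
    wgd_events = config$sim$wgd_events,
    planted_terms = config$sim$planted_terms,
    digests = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest$results <- res
  invisible(manifest)
}
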