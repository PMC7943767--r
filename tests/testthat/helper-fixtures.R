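# Shared test helpers: tiny deterministic fixtures built in code, plus a
# lazy cache so expensive simulations are built once per test run.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

sense_codons <- function() {
  tb <- paleodup:::codon_tables()
  paleodup:::codon_string(which(!tb$is_stop))
}

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# codon alignment object straight from two codon vectors (no indels)
make_ca <- function(codon1, codon2, a = "x", b = "y") {
  structure(list(a = a, b = b, codon1 = codon1, codon2 = codon2,
                 n_codons = length(codon1), n_dropped = 0L),
            class = "codon_alignment")
}

# a small genome laid out on one or more chromosomes; genes named g1..gn
make_genome <- function(chroms, species = "sp", cds = character()) {
  rows <- list()
  gi <- 0
  for (ch in names(chroms)) {
    n <- chroms[[ch]]
    for (i in seq_len(n)) {
      gi <- gi + 1
      rows[[gi]] <- data.frame(gene_id = paste0("g", gi), chrom = ch,
                               start = i * 1000L, end = i * 1000L + 500L,
                               strand = "+", stringsAsFactors = FALSE)
    }
  }
  new_genome(species, do.call(rbind, rows), cds = cds)
}

# lazily-built expensive fixtures shared between tests
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# WGD + recent tandem simulation with its downstream homology/divergence
# artifacts (shared by the bimodality and tandem-classification tests)
wgd_tandem_fixture <- function() {
  fixture("wgd_tandem", function() {
    cfg <- sim_config(seed = 42, n_genes = 400, codons_per_gene = 200,
                      wgd_events = list(list(time_mya = 16.667,
                                             retention_prob = 0.75)),
                      tandem_rate = 0.1, tandem_depth = 0.05,
                      n_inversions = 2, n_translocations = 1)
    sim <- simulate_genomes(cfg)
    genome <- sim$genomes[[1]]
    paralogs <- rbh_paralogs(genome)
    div <- divergence_table(paralogs, sim$genomes)
    chained <- chain_blocks(anchors_from_pairs(paralogs, genome))
    list(sim = sim, genome = genome, paralogs = paralogs, div = div,
         chained = chained)
  })
}
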