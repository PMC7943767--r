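# Canonical in-memory genome model and readers/writers for the external
# formats the pipeline consumes: FASTA (protein + CDS), GFF3 gene coordinates,
# 12-column tabular hit lists, orthologous-cluster tables, and gene->term
# annotation tables.

#' Construct a genome object
#'
#' A genome is a per-species container holding gene coordinates (1-based,
#' inclusive), the 0-based rank order of genes along each chromosome, and the
#' CDS / protein sequence of each gene. Genes are sorted by
#' (chromosome, start, end, gene_id) and ranks are assigned per chromosome
#' after sorting, so rank distances ("within 10 genes") are always consistent
#' with coordinate order.
#'
#' @param species species label.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`).
#' @param cds named character vector of coding sequences (names = gene ids).
#' @param protein named character vector of protein sequences; translated from
#'   `cds` when missing.
#' @param group free-form group label (e.g. `"cactus"`), used by the
#'   cluster-classification stage.
#' @return object of class `genome`: list with `species`, `group`, `genes`
#'   (with `rank` and `has_cds` columns added), `cds`, `protein`.
#' @export
new_genome <- function(species, genes, cds = character(), protein = NULL,
                       group = "") {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id ", genes$gene_id[duplicated(genes$gene_id)][1])
  }
  bad <- genes$start > genes$end
  if (any(bad)) {
    warning(sum(bad), " record(s) with start > end dropped")
    genes <- genes[!bad, , drop = FALSE]
  }
  ok_strand <- genes$strand %in% c("+", "-")
  if (!all(ok_strand)) {
    warning(sum(!ok_strand), " record(s) with unknown strand treated as '+'")
    genes$strand[!ok_strand] <- "+"
  }
  o <- order(genes$chrom, genes$start, genes$end, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  genes$rank <- NA_integer_
  for (ch in unique(genes$chrom)) {
    i <- which(genes$chrom == ch)
    genes$rank[i] <- seq_along(i) - 1L
  }
  rownames(genes) <- NULL
  cds <- toupper(cds)
  if (length(cds)) cds <- vapply(cds, trim_cds, character(1))
  genes$has_cds <- genes$gene_id %in% names(cds)
  if (is.null(protein)) {
    protein <- structure(translate_cds(cds), names = names(cds))
  }
  structure(list(species = species, group = group, genes = genes,
                 cds = cds, protein = protein),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$species,
      if (nzchar(x$group)) paste0("(", x$group, ")") else "",
      "-", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Number of genes in a genome
#' @param genome a `genome` object.
#' @return integer count.
#' @export
n_genes <- function(genome) nrow(genome$genes)

#' Read a FASTA file into a named character vector
#'
#' Identifiers are the first whitespace-delimited token of each header.
#' Sequences are uppercased; in nucleotide mode, `U` is converted to `T`.
#' Record order is preserved. A duplicated identifier is an error.
#'
#' @param path file path.
#' @param type `"aa"`, `"nt"`, or `"auto"` (nucleotide iff the alphabet is a
#'   subset of ACGTUN-).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("auto", "nt", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(structure(character(0), names = character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate id ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (type == "auto") {
    chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    type <- if (length(chars) == 0 || all(chars %in% c("A", "C", "G", "T", "U", "N", "-"))) "nt" else "aa"
  }
  if (type == "nt") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  seqs
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Read gene models from GFF3 into a genome
#'
#' Uses `gene` features when present, otherwise `mRNA`. Coordinates are
#' 1-based inclusive. Records with start > end are dropped with a warning;
#' unknown strand symbols are coerced to `+` with a warning. Genes without a
#' CDS sequence are retained and flagged via the `has_cds` column.
#'
#' @param path GFF3 file.
#' @param cds named character vector of CDS sequences (e.g. from
#'   [read_fasta()]).
#' @param protein optional named character vector of proteins.
#' @param species species label (defaults to the file stem).
#' @param group group label.
#' @return a `genome` object.
#' @export
read_gff3 <- function(path, cds = character(), protein = NULL,
                      species = sub("\\.gff3?$", "", basename(path)),
                      group = "") {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  keep_type <- if (any(g$type == "gene")) "gene" else "mRNA"
  g <- g[g$type == keep_type, , drop = FALSE]
  id <- as.character(g$ID)
  if (all(is.na(id)) && !is.null(g$Name)) id <- as.character(g$Name)
  genes <- data.frame(gene_id = id,
                      chrom = as.character(g$seqid),
                      start = as.integer(g$start),
                      end = as.integer(g$end),
                      strand = as.character(g$strand),
                      stringsAsFactors = FALSE)
  new_genome(species, genes, cds = cds, protein = protein, group = group)
}

#' Write a genome as GFF3 (+ optional FASTA)
#'
#' @param genome a `genome` object.
#' @param gff3 output GFF3 path.
#' @param fna optional CDS FASTA path.
#' @param faa optional protein FASTA path.
#' @return `gff3`, invisibly.
#' @export
write_genome <- function(genome, gff3, fna = NULL, faa = NULL) {
  g <- genome$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tpaleodup\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, g$start, g$end, g$strand, g$gene_id))
  writeLines(lines, gff3)
  if (!is.null(fna)) write_fasta(genome$cds, fna)
  if (!is.null(faa)) write_fasta(genome$protein, faa)
  invisible(gff3)
}

#' Read a 12-column tabular hit list
#'
#' Accepts the common tabular alignment dialect with columns qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore. The returned `score` is the bitscore and `identity` is pident
#' rescaled to [0, 1].
#'
#' @param path file path.
#' @return data.frame with columns `query`, `subject`, `score`, `identity`.
#' @export
read_hits_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(query = character(0), subject = character(0),
                      score = numeric(0), identity = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    stop("line ", i, ": expected 12 columns, found ", nf[i])
  }
  m <- do.call(rbind, parts)
  data.frame(query = m[, 1], subject = m[, 2],
             score = as.numeric(m[, 12]),
             identity = as.numeric(m[, 3]) / 100,
             stringsAsFactors = FALSE)
}

#' Write pairs/hits/divergence tables as TSV
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}

#' Read an orthologous-cluster table
#'
#' Tab-separated dialect: first field is the cluster id (a trailing `:` is
#' tolerated), each further field is `species:gene1,gene2,...`. A gene
#' assigned to two clusters is an error.
#'
#' @param path file path.
#' @return an `ogc_table` (see [ogc_table()]).
#' @export
read_cluster_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    cid <- sub(":$", "", f[1])
    for (fld in f[-1]) {
      sp <- sub(":.*$", "", fld)
      genes <- strsplit(sub("^[^:]*:", "", fld), ",", fixed = TRUE)[[1]]
      genes <- genes[nzchar(genes)]
      if (length(genes)) {
        rows[[length(rows) + 1L]] <- data.frame(cluster_id = cid, species = sp,
                                                gene_id = genes,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), species = character(0),
               gene_id = character(0))
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) stop("gene ", dup[1], " assigned to more than one cluster")
  ogc_table(df)
}

#' Write an ogc_table in the cluster-table dialect
#' @param ogc an `ogc_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(ogc, path) {
  df <- as.data.frame(ogc)
  con <- file(path, "w")
  on.exit(close(con))
  for (cid in unique(df$cluster_id)) {
    d <- df[df$cluster_id == cid, , drop = FALSE]
    flds <- vapply(split(d$gene_id, d$species), function(g)
      paste(sort(g), collapse = ","), character(1))
    writeLines(paste(c(cid, paste0(names(flds), ":", flds)), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' One row per gene: `gene_id <TAB> term` or `gene_id <TAB> term1,term2,...`.
#' Term sets are deduplicated per gene; empty term identifiers are an error.
#'
#' @param path file path.
#' @param namespace `"GO"` or `"KEGG"`.
#' @return an `annotation_table`: data.frame (`gene_id`, `term`) with a
#'   `namespace` attribute.
#' @export
read_annotation_table <- function(path, namespace = c("GO", "KEGG")) {
  namespace <- match.arg(namespace)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    terms <- unique(unlist(strsplit(f[-1], ",", fixed = TRUE)))
    terms <- terms[nzchar(terms)]
    if (length(f) > 1 && length(terms) == 0 && any(!nzchar(f[-1]))) {
      stop("empty term for gene ", f[1])
    }
    if (length(terms) == 0) return(NULL)
    data.frame(gene_id = f[1], term = terms, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(gene_id = character(0), term = character(0))
  df <- unique(df)
  annotation_table(df, namespace)
}

#' Construct an annotation table
#' @param df data.frame with columns `gene_id`, `term`.
#' @param namespace `"GO"` or `"KEGG"`.
#' @return `annotation_table` object.
#' @export
annotation_table <- function(df, namespace = "GO") {
  df <- unique(df[, c("gene_id", "term")])
  if (any(!nzchar(df$term))) stop("empty term identifier")
  rownames(df) <- NULL
  structure(df, namespace = namespace,
            class = c("annotation_table", "data.frame"))
}

#' Write an annotation table as TSV (one gene per row, comma-joined terms)
#' @param ann an `annotation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  sp <- split(ann$term, ann$gene_id)
  writeLines(paste0(names(sp), "\t",
                    vapply(sp, function(t) paste(sort(t), collapse = ","),
                           character(1))), path)
  invisible(path)
}
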