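# Internal codon machinery shared by the NG86 / 4dTv estimators and the
# genome simulator. Everything is driven by small lookup tables computed once
# per session from the standard genetic code and cached in a package
# environment: per-codon synonymous site fractions, one-step synonymous-change
# indicators, fourfold-degenerate family flags, and the pairwise NG86
# synonymous/nonsynonymous difference matrices (pathway-averaged).

.pd <- new.env(parent = emptyenv())

pd_bases <- c("A", "C", "G", "T")
pd_purines <- c("A", "G")

#' @noRd
codon_index <- function(codons) {
  m1 <- match(substr(codons, 1L, 1L), pd_bases)
  m2 <- match(substr(codons, 2L, 2L), pd_bases)
  m3 <- match(substr(codons, 3L, 3L), pd_bases)
  idx <- (m1 - 1L) * 16L + (m2 - 1L) * 4L + m3
  idx[nchar(codons) != 3L] <- NA_integer_
  idx
}

#' @noRd
codon_string <- function(idx) {
  i <- idx - 1L
  paste0(pd_bases[i %/% 16L + 1L],
         pd_bases[(i %/% 4L) %% 4L + 1L],
         pd_bases[i %% 4L + 1L])
}

# digit (0..3) of codon idx at position p
codon_digit <- function(idx, p) {
  i <- idx - 1L
  switch(p, i %/% 16L, (i %/% 4L) %% 4L, i %% 4L)
}

# codon index after setting position p of codon idx to base digit b (0..3)
codon_set <- function(idx, p, b) {
  mult <- c(16L, 4L, 1L)[p]
  idx + (b - codon_digit(idx, p)) * mult
}

#' Core codon lookup tables (cached).
#'
#' @return list with elements:
#'   `aa` amino acid per codon index (1..64, `*` = stop);
#'   `is_stop` logical(64);
#'   `syn_change` 64 x 3 x 4 logical array: changing codon c at position p to
#'     base digit b+1 is a synonymous (sense-to-sense, same amino acid) change;
#'   `is_stop_target` same shape, TRUE when the mutated codon is a stop;
#'   `syn_sites` NG86 synonymous site count per codon (sum over positions of
#'     synonymous one-step changes / 3); NA for stops;
#'   `fourfold2` logical(16): the 16 first-two-base prefixes whose third
#'     position is fourfold degenerate.
#' @noRd
codon_tables <- function() {
  if (!is.null(.pd$tables)) return(.pd$tables)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codon_string(1:64)])
  is_stop <- aa == "*"

  syn_change <- array(FALSE, dim = c(64, 3, 4))
  stop_target <- array(FALSE, dim = c(64, 3, 4))
  for (c in 1:64) {
    if (is_stop[c]) next
    for (p in 1:3) {
      dp <- codon_digit(c, p)
      for (b in 0:3) {
        if (b == dp) next
        nc <- codon_set(c, p, b)
        if (is_stop[nc]) {
          stop_target[c, p, b + 1L] <- TRUE
        } else if (aa[nc] == aa[c]) {
          syn_change[c, p, b + 1L] <- TRUE
        }
      }
    }
  }
  # NG86 site counting: per position, the fraction of the three possible
  # nucleotide changes that are synonymous; changes to stop codons count as
  # nonsynonymous, so S + N = 3 per codon exactly.
  syn_sites <- rep(NA_real_, 64)
  syn_sites[!is_stop] <- vapply(which(!is_stop), function(c) {
    sum(syn_change[c, , ]) / 3
  }, numeric(1))

  fourfold2 <- vapply(0:15, function(pre) {
    idx <- pre * 4L + 1:4
    !any(is_stop[idx]) && length(unique(aa[idx])) == 1L
  }, logical(1))

  .pd$tables <- list(aa = aa, is_stop = is_stop, syn_change = syn_change,
                     is_stop_target = stop_target, syn_sites = syn_sites,
                     fourfold2 = fourfold2)
  .pd$tables
}

#' Pairwise NG86 difference matrices (cached).
#'
#' For every ordered pair of sense codons, the expected number of synonymous
#' (`SD`) and nonsynonymous (`ND`) differences, averaging over all minimal
#' mutational pathways between the two codons. Pathways passing through a stop
#' codon are excluded; in the (rare) event that every pathway is blocked, all
#' pathways are used with steps into/out of stops counted as nonsynonymous.
#' Entries involving stop codons are NA.
#' @noRd
ng86_tables <- function() {
  if (!is.null(.pd$ng86)) return(.pd$ng86)
  tb <- codon_tables()
  SD <- matrix(NA_real_, 64, 64)
  ND <- matrix(NA_real_, 64, 64)
  sense <- which(!tb$is_stop)
  perms <- list(matrix(1L, 1, 1),
                rbind(c(1L, 2L), c(2L, 1L)),
                do.call(rbind, lapply(seq_len(6), function(i) {
                  p <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                             c(3,1,2), c(3,2,1))
                  p[i, ]
                })))
  for (i in sense) {
    di <- c(codon_digit(i, 1L), codon_digit(i, 2L), codon_digit(i, 3L))
    for (j in sense) {
      if (i == j) { SD[i, j] <- 0; ND[i, j] <- 0; next }
      dj <- c(codon_digit(j, 1L), codon_digit(j, 2L), codon_digit(j, 3L))
      pos <- which(di != dj)
      k <- length(pos)
      ords <- perms[[k]]
      path_sd <- numeric(0); path_nd <- numeric(0)
      path_sd_all <- numeric(0); path_nd_all <- numeric(0)
      for (r in seq_len(nrow(ords))) {
        cur <- i; sd <- 0; nd <- 0; blocked <- FALSE
        for (p in pos[ords[r, seq_len(k)]]) {
          nxt <- codon_set(cur, p, dj[match(p, c(1, 2, 3))])
          if (tb$is_stop[nxt] || tb$is_stop[cur]) {
            blocked <- TRUE
            nd <- nd + 1   # fallback accounting: stop-crossing step = nonsyn
          } else if (tb$aa[nxt] == tb$aa[cur]) {
            sd <- sd + 1
          } else {
            nd <- nd + 1
          }
          cur <- nxt
        }
        path_sd_all <- c(path_sd_all, sd); path_nd_all <- c(path_nd_all, nd)
        if (!blocked) { path_sd <- c(path_sd, sd); path_nd <- c(path_nd, nd) }
      }
      if (length(path_sd) > 0) {
        SD[i, j] <- mean(path_sd); ND[i, j] <- mean(path_nd)
      } else {
        SD[i, j] <- mean(path_sd_all); ND[i, j] <- mean(path_nd_all)
      }
    }
  }
  .pd$ng86 <- list(SD = SD, ND = ND)
  .pd$ng86
}

#' Translate coding sequences with the standard genetic code.
#'
#' Stops are rendered as `*`; a single trailing `*` is removed. Incomplete
#' terminal codons are ignored. Codons containing non-ACGT characters
#' translate to `X`.
#'
#' @param cds character vector of nucleotide coding sequences.
#' @return character vector of amino-acid sequences.
#' @export
translate_cds <- function(cds) {
  tb <- codon_tables()
  vapply(cds, function(s) {
    s <- toupper(s)
    n <- nchar(s) - nchar(s) %% 3L
    if (n == 0L) return("")
    cods <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    idx <- codon_index(cods)
    aa <- ifelse(is.na(idx), "X", tb$aa[idx])
    p <- paste(aa, collapse = "")
    sub("\\*$", "", p)
  }, character(1), USE.NAMES = FALSE)
}

#' Trim a CDS to whole codons and drop a terminal stop codon.
#'
#' @param cds character vector of nucleotide sequences.
#' @return character vector; length is a multiple of 3 and the final codon is
#'   not a stop.
#' @export
trim_cds <- function(cds) {
  tb <- codon_tables()
  vapply(cds, function(s) {
    s <- toupper(s)
    n <- nchar(s) - nchar(s) %% 3L
    s <- substr(s, 1L, n)
    if (n >= 3L) {
      last <- codon_index(substr(s, n - 2L, n))
      if (!is.na(last) && tb$is_stop[last]) s <- substr(s, 1L, n - 3L)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}
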