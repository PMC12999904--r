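# Codon-level machinery shared by the synthetic generator and the
# Nei-Gojobori estimator. The genetic code is the standard one from
# Biostrings::GENETIC_CODE; everything downstream (site fractions, pathwise
# difference counting) is computed here once and cached.

BASES <- c("A", "C", "G", "T")

codon_universe <- function() {
  if (!is.null(the$codons)) return(the$codons)
  cods <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  aa <- Biostrings::GENETIC_CODE[cods]
  the$codons <- list(codons = cods, aa = aa, stops = cods[aa == "*"])
  the$codons
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Translate an in-frame CDS to protein
#'
#' @param cds A CDS string (length divisible by 3, standard genetic code).
#' @return Amino-acid string; stop codons translate to `*`.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) abort("CDS length must be divisible by 3.")
  paste0(translate_codons(split_codons(cds)), collapse = "")
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0) return(character(0))
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

# Per-codon synonymous site count: each position contributes the fraction of
# its valid (non-stop) one-step changes that are synonymous; positions whose
# valid changes are exhausted by stops contribute zero synonymous weight.
syn_site_table <- function() {
  if (!is.null(the$syn_sites)) return(the$syn_sites)
  cu <- codon_universe()
  out <- stats::setNames(numeric(length(cu$codons)), cu$codons)
  for (cod in cu$codons) {
    if (cu$aa[[cod]] == "*") { out[[cod]] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      alts <- alt_codons(cod, pos)
      valid <- alts[translate_codons(alts) != "*"]
      if (length(valid) > 0) {
        s <- s + sum(translate_codons(valid) == cu$aa[[cod]]) / length(valid)
      }
    }
    out[[cod]] <- s
  }
  the$syn_sites <- out
  out
}

alt_codons <- function(codon, pos) {
  base <- substr(codon, pos, pos)
  vapply(setdiff(BASES, base), function(b) {
    `substr<-`(codon, pos, pos, b)
  }, "")
}

# Pathwise synonymous/nonsynonymous difference counts between two codons:
# average over all orderings of the single-base steps, discarding paths that
# pass through a stop codon (falling back to all paths if every ordering is
# blocked). Cached as 64x64 matrices.
pair_diff_tables <- function() {
  if (!is.null(the$sd_mat)) return(list(sd = the$sd_mat, nd = the$nd_mat))
  cu <- codon_universe()
  k <- length(cu$codons)
  sd_mat <- matrix(0, k, k, dimnames = list(cu$codons, cu$codons))
  nd_mat <- sd_mat
  perms <- list(
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      a <- cu$codons[[i]]; b <- cu$codons[[j]]
      if (cu$aa[[a]] == "*" || cu$aa[[b]] == "*") { sd_mat[i, j] <- NA; nd_mat[i, j] <- NA; next }
      pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      d <- length(pos)
      paths <- perms[[d]]
      tally <- matrix(NA_real_, length(paths), 2)
      for (p in seq_along(paths)) {
        cur <- a; syn <- 0; non <- 0; ok <- TRUE
        for (step in pos[paths[[p]]]) {
          nxt <- `substr<-`(cur, step, step, substr(b, step, step))
          if (translate_codons(nxt) == "*") { ok <- FALSE; break }
          if (translate_codons(nxt) == translate_codons(cur)) syn <- syn + 1 else non <- non + 1
          cur <- nxt
        }
        if (ok) tally[p, ] <- c(syn, non)
      }
      if (all(is.na(tally[, 1]))) {
        # every ordering passes through a stop: average over all orderings
        for (p in seq_along(paths)) {
          cur <- a; syn <- 0; non <- 0
          for (step in pos[paths[[p]]]) {
            nxt <- `substr<-`(cur, step, step, substr(b, step, step))
            if (translate_codons(nxt) == translate_codons(cur)) syn <- syn + 1 else non <- non + 1
            cur <- nxt
          }
          tally[p, ] <- c(syn, non)
        }
      }
      sd_mat[i, j] <- mean(tally[, 1], na.rm = TRUE)
      nd_mat[i, j] <- mean(tally[, 2], na.rm = TRUE)
    }
  }
  the$sd_mat <- sd_mat
  the$nd_mat <- nd_mat
  list(sd = sd_mat, nd = nd_mat)
}

# reverse complement for plain character DNA
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}
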