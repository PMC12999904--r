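# Synthetic multi-species genome generator with planted ground truth.
#
# The generator emulates the study design the pipeline targets: a panel of
# plant genomes carrying one gene family organised into orthogroups (OGGs)
# with a planted conserved/variable/rare mix, subfamily/cluster sequence
# structure for tree-based classification, duplication events of five modes
# with the collinear-block context needed to call them, promoters with
# planted cis-element instances on motif-free backgrounds, and
# treatment-vs-control expression with planted fold changes. Every planted
# fact is returned (and written) as a truth table so downstream stages can
# be scored exactly.

#' Synthetic dataset configuration
#'
#' Defaults are the study conditions used throughout the package's
#' validation: 10 species, 5 chromosomes of 40 gene slots, 50 orthogroups
#' with a 0.30/0.50/0.20 conserved/variable/rare mix, 12-anchor collinear
#' blocks, and duplication events of all five modes.
#'
#' @param n_species Number of species (>= 2).
#' @param chromosomes_per_species Chromosomes per species (>= 1).
#' @param genes_per_chromosome Gene slots per chromosome (>= 20).
#' @param n_oggs Number of orthogroups (>= 1).
#' @param category_mix Fractions (conserved, variable, rare) summing to 1.
#' @param planted_omegas Target Ka/Ks values in (0, 2] cycled over
#'   orthogroups.
#' @param dup_events Named counts of planted duplication events per mode
#'   (WGD, TD, PD, TRD, DSD).
#' @param block_length Anchors per planted collinear block (>= 10).
#' @param n_cross_blocks Planted cross-species collinear blocks.
#' @param motif_plan Named integer vector: element name -> insertions per
#'   family promoter (names must exist in [default_motif_library()]).
#' @param promoter_window Promoter length in bp (default 2000).
#' @param de_frac Fraction of expression genes planted as responsive.
#' @param seed Integer seed; fully determines all outputs.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_species = 10,
                         chromosomes_per_species = 5,
                         genes_per_chromosome = 40,
                         n_oggs = 50,
                         category_mix = c(conserved = 0.3, variable = 0.5, rare = 0.2),
                         planted_omegas = c(0.1, 0.2, 0.35, 0.5, 1.0),
                         dup_events = c(WGD = 2, TD = 3, PD = 2, TRD = 2, DSD = 3),
                         block_length = 12,
                         n_cross_blocks = 2,
                         motif_plan = c("ABRE" = 2, "G-box" = 1, "MYB" = 1,
                                        "MYC" = 1, "ARE" = 1, "STRE" = 1),
                         promoter_window = 2000,
                         de_frac = 0.25,
                         seed = 1) {
  if (n_species < 2) abort("`n_species` must be >= 2.")
  if (chromosomes_per_species < 1) abort("`chromosomes_per_species` must be >= 1.")
  if (genes_per_chromosome < 20) abort("`genes_per_chromosome` must be >= 20.")
  if (n_oggs < 1) abort("`n_oggs` must be >= 1.")
  if (abs(sum(category_mix) - 1) > 1e-9) abort("`category_mix` must sum to 1.")
  if (any(category_mix < 0)) abort("`category_mix` fractions must be non-negative.")
  if (block_length < 10) abort("`block_length` must be >= 10.")
  if (any(planted_omegas <= 0) || any(planted_omegas > 2)) {
    abort("`planted_omegas` must lie in (0, 2].")
  }
  modes <- c("WGD", "TD", "PD", "TRD", "DSD")
  ev <- stats::setNames(rep(0L, 5), modes)
  if (length(dup_events) > 0) {
    bad <- setdiff(names(dup_events), modes)
    if (length(bad) > 0) abort(sprintf("Unknown duplication mode(s): %s",
                                       paste(bad, collapse = ", ")))
    ev[names(dup_events)] <- as.integer(dup_events)
  }
  if (length(motif_plan) > 0) {
    lib <- default_motif_library()
    bad <- setdiff(names(motif_plan), lib$element)
    if (length(bad) > 0) abort(sprintf("motif_plan element(s) not in library: %s",
                                       paste(bad, collapse = ", ")))
  }
  structure(list(
    n_species = as.integer(n_species),
    chromosomes_per_species = as.integer(chromosomes_per_species),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    n_oggs = as.integer(n_oggs),
    category_mix = category_mix,
    planted_omegas = planted_omegas,
    dup_events = ev,
    block_length = as.integer(block_length),
    n_cross_blocks = as.integer(n_cross_blocks),
    motif_plan = motif_plan,
    promoter_window = as.integer(promoter_window),
    de_frac = de_frac,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# ---- codon mutation helpers ---------------------------------------------

codon_neighbors <- function() {
  if (!is.null(the$neighbors)) return(the$neighbors)
  cu <- codon_universe()
  nb <- lapply(stats::setNames(cu$codons, cu$codons), function(cod) {
    if (cu$aa[[cod]] == "*") return(list(syn = character(0), nonsyn = character(0)))
    alts <- unlist(lapply(1:3, function(p) alt_codons(cod, p)))
    alts <- alts[translate_codons(alts) != "*"]
    list(
      syn = alts[translate_codons(alts) == cu$aa[[cod]]],
      nonsyn = alts[translate_codons(alts) != cu$aa[[cod]]]
    )
  })
  the$neighbors <- nb
  nb
}

random_codons <- function(n, first_atg = TRUE) {
  cu <- codon_universe()
  pool <- setdiff(cu$codons, cu$stops)
  out <- sample(pool, n, replace = TRUE)
  if (first_atg && n >= 1) out[1] <- "ATG"
  out
}

mutate_codon <- function(codon, type = c("any", "syn", "nonsyn")) {
  type <- match.arg(type)
  nb <- codon_neighbors()[[codon]]
  cand <- switch(type, any = c(nb$syn, nb$nonsyn), syn = nb$syn, nonsyn = nb$nonsyn)
  if (length(cand) == 0) return(NULL)
  cand[sample.int(length(cand), 1)]
}

#' Evolve a codon-sequence pair with exact planted substitution counts
#'
#' Generates a random stop-free ancestor CDS and a derived copy differing at
#' exactly `syn_subs` synonymous and `nonsyn_subs` nonsynonymous codon
#' positions, with at most one single-base substitution per codon (so the
#' planted counts are unambiguous ground truth for Ka/Ks recovery). No
#' substitution creates a stop codon.
#'
#' @param ancestor_len_codons Ancestor length in codons.
#' @param syn_subs,nonsyn_subs Planted substitution counts;
#'   `syn_subs + nonsyn_subs <= ancestor_len_codons`.
#' @param seed Integer seed.
#' @return List: cds_a, cds_b (in-frame stop-free strings of equal length),
#'   syn_positions, nonsyn_positions (codon indices).
#' @export
evolve_codon_pair <- function(ancestor_len_codons, syn_subs, nonsyn_subs, seed) {
  if (syn_subs + nonsyn_subs > ancestor_len_codons) {
    abort("syn_subs + nonsyn_subs must be <= ancestor_len_codons.")
  }
  with_seed(seed, {
    anc <- random_codons(ancestor_len_codons)
    der <- anc
    # position 1 is the start codon and is never substituted
    free <- setdiff(seq_len(ancestor_len_codons), 1L)
    syn_pos <- integer(0); nonsyn_pos <- integer(0)
    place <- function(count, type, free) {
      pos <- integer(0)
      attempts <- 0
      while (length(pos) < count) {
        attempts <- attempts + 1
        if (attempts > 1000) {
          abort("Could not place substitutions without stop codons within 1000 attempts.")
        }
        if (length(free) == 0) abort("Ran out of codon positions for substitutions.")
        p <- free[sample.int(length(free), 1)]
        alt <- mutate_codon(anc[[p]], type)
        if (!is.null(alt)) {
          der[[p]] <<- alt
          pos <- c(pos, p)
          free <- setdiff(free, p)
        } else {
          free <- setdiff(free, p) # codon admits no such change (e.g. ATG/TGG for syn)
        }
      }
      list(pos = pos, free = free)
    }
    s <- place(syn_subs, "syn", free)
    n <- place(nonsyn_subs, "nonsyn", s$free)
    list(
      cds_a = paste0(anc, collapse = ""),
      cds_b = paste0(der, collapse = ""),
      syn_positions = sort(s$pos),
      nonsyn_positions = sort(n$pos)
    )
  })
}

#' Synthetic anchor sets with planted collinear chains
#'
#' Emits an anchor table holding planted strictly monotone chains (one per
#' designated chromosome pair) plus sparse noise anchors, for validating
#' block recovery. Noise anchors are kept outside the gap-reach corridor of
#' every planted chain so a noise anchor cannot legitimately extend a
#' planted chain, keeping the exact-recovery oracle well-posed.
#'
#' @param n_blocks Planted chains (each on its own chromosome pair).
#' @param block_lengths Integer vector (recycled) of chain lengths.
#' @param n_noise Total noise anchors spread over the chromosome pairs.
#' @param rank_space Rank range per chromosome side.
#' @param max_rank_gap Corridor width used to shield planted chains.
#' @param inverted Logical vector (recycled): plant the chain inverted?
#' @param seed Integer seed.
#' @return List: anchors tibble (gene_a, chr_a, rank_a, gene_b, chr_b,
#'   rank_b), truth tibble (chain_id, chr_a, chr_b, gene_a, gene_b, ...).
#' @export
synth_anchor_set <- function(n_blocks = 5, block_lengths = c(10, 15, 20, 25, 30),
                             n_noise = 200, rank_space = 1500,
                             max_rank_gap = 25, inverted = FALSE, seed = 1) {
  lens <- rep_len(block_lengths, n_blocks)
  inv <- rep_len(inverted, n_blocks)
  with_seed(seed, {
    anchors <- list(); truth <- list()
    for (b in seq_len(n_blocks)) {
      chr_a <- sprintf("A%02d", b); chr_b <- sprintf("B%02d", b)
      len <- lens[[b]]
      start_a <- sample.int(rank_space - 3 * len - 100, 1) + 50
      start_b <- sample.int(rank_space - 3 * len - 100, 1) + 50
      step_a <- sample(1:2, len, replace = TRUE)
      step_b <- sample(1:2, len, replace = TRUE)
      ra <- start_a + cumsum(step_a)
      rb_up <- start_b + cumsum(step_b)
      rb <- if (inv[[b]]) max(rb_up) + min(rb_up) - rb_up else rb_up
      chain <- tibble(
        chain_id = sprintf("chain%02d", b),
        gene_a = sprintf("a%02d_%03d", b, seq_len(len)),
        chr_a = chr_a, rank_a = ra,
        gene_b = sprintf("b%02d_%03d", b, seq_len(len)),
        chr_b = chr_b, rank_b = rb
      )
      truth[[b]] <- chain
      # noise for this chromosome pair, shielded from the chain corridor
      n_here <- n_noise %/% n_blocks
      pts <- matrix(NA_integer_, 0, 2)
      guard <- max_rank_gap + 2
      while (nrow(pts) < n_here) {
        cand <- cbind(sample.int(rank_space, n_here), sample.int(rank_space, n_here))
        near <- vapply(seq_len(nrow(cand)), function(i) {
          any(abs(cand[i, 1] - ra) <= guard & abs(cand[i, 2] - rb) <= guard)
        }, logical(1))
        pts <- rbind(pts, cand[!near, , drop = FALSE])
      }
      pts <- pts[seq_len(n_here), , drop = FALSE]
      anchors[[b]] <- bind_rows(
        select(chain, "gene_a", "chr_a", "rank_a", "gene_b", "chr_b", "rank_b"),
        tibble(
          gene_a = sprintf("na%02d_%03d", b, seq_len(n_here)),
          chr_a = chr_a, rank_a = pts[, 1],
          gene_b = sprintf("nb%02d_%03d", b, seq_len(n_here)),
          chr_b = chr_b, rank_b = pts[, 2]
        )
      )
    }
    list(anchors = bind_rows(anchors), truth = bind_rows(truth))
  })
}
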