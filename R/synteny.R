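# Collinear-block detection by longest-monotone-chain dynamic programming,
# duplication-mode classification with the WGD > TD > PD > TRD > DSD
# priority, and the synteny-vs-conservation cross-tabulation.

#' Chain anchor pairs into collinear blocks
#'
#' Within each chromosome pair (and species pair, when species columns are
#' present), finds longest strictly monotone chains in both orientations
#' (side-A ranks strictly increasing; side-B ranks strictly increasing for
#' `same`, strictly decreasing for `inverted`), with the rank gap between
#' consecutive anchors bounded by `max_rank_gap` on both sides. Blocks are
#' extracted greedily by chain length (ties: `same` orientation first, then
#' leftmost start); each anchor joins at most one block, and chains shorter
#' than `min_block_size` anchors are discarded.
#'
#' @param anchors Tibble with columns gene_a, chr_a, rank_a, gene_b, chr_b,
#'   rank_b and optionally species_a, species_b.
#' @param min_block_size Minimum anchors per block (default 10).
#' @param max_rank_gap Maximum rank gap between consecutive anchors on either
#'   side (default 25).
#' @return Tibble with one row per block: block_id, species_a, species_b,
#'   chr_a, chr_b, orientation, n_anchors, and a list-column `anchors`
#'   holding the chain (gene_a, rank_a, gene_b, rank_b) in order.
#' @export
chain_anchors <- function(anchors, min_block_size = 10, max_rank_gap = 25) {
  stopifnot_cols(anchors, c("gene_a", "chr_a", "rank_a", "gene_b", "chr_b", "rank_b"))
  if (!"species_a" %in% names(anchors)) anchors$species_a <- ""
  if (!"species_b" %in% names(anchors)) anchors$species_b <- ""
  if (nrow(anchors) == 0) return(empty_blocks())
  groups <- anchors |>
    mutate(.grp = paste(.data$species_a, .data$species_b, .data$chr_a, .data$chr_b,
                        sep = "\r")) |>
    group_by(.data$.grp)
  blocks <- groups |>
    dplyr::group_split() |>
    purrr::map(~ chain_one_group(.x, min_block_size, max_rank_gap)) |>
    bind_rows()
  if (nrow(blocks) == 0) return(empty_blocks())
  blocks <- blocks[c_order(blocks$species_a, blocks$species_b, blocks$chr_a,
                           blocks$chr_b, blocks$start_rank_a), , drop = FALSE]
  blocks$block_id <- sprintf("B%03d", seq_len(nrow(blocks)))
  select(blocks, "block_id", "species_a", "species_b", "chr_a", "chr_b",
         "orientation", "n_anchors", "anchors")
}

empty_blocks <- function() {
  tibble(block_id = character(0), species_a = character(0), species_b = character(0),
         chr_a = character(0), chr_b = character(0), orientation = character(0),
         n_anchors = integer(0), anchors = list())
}

# Longest chain DP over one chromosome pair, greedy extraction of disjoint
# blocks. `flip = TRUE` negates side-B ranks to find inverted chains.
best_chain <- function(ra, rb, avail, max_rank_gap, flip) {
  idx <- which(avail)
  if (length(idx) == 0) return(integer(0))
  rb_eff <- if (flip) -rb else rb
  ord <- idx[c_order(ra[idx], rb_eff[idx])]
  k <- length(ord)
  len <- rep(1L, k); prev <- rep(0L, k)
  for (ii in seq_len(k)) {
    for (jj in seq_len(ii - 1L)) {
      da <- ra[ord[ii]] - ra[ord[jj]]
      db <- rb_eff[ord[ii]] - rb_eff[ord[jj]]
      if (da > 0 && db > 0 && da <= max_rank_gap && db <= max_rank_gap &&
          len[jj] + 1L > len[ii]) {
        len[ii] <- len[jj] + 1L
        prev[ii] <- jj
      }
    }
  }
  best <- which(len == max(len))
  # leftmost chain start among maxima: reconstruct each candidate, compare heads
  chains <- lapply(best, function(e) {
    ch <- integer(0)
    while (e != 0L) { ch <- c(e, ch); e <- prev[e] }
    ord[ch]
  })
  heads <- vapply(chains, function(ch) ra[ch[1]] * 1e9 + rb[ch[1]], numeric(1))
  chains[[which.min(heads)]]
}

chain_one_group <- function(g, min_block_size, max_rank_gap) {
  avail <- rep(TRUE, nrow(g))
  out <- list()
  repeat {
    ch_same <- best_chain(g$rank_a, g$rank_b, avail, max_rank_gap, flip = FALSE)
    ch_inv <- best_chain(g$rank_a, g$rank_b, avail, max_rank_gap, flip = TRUE)
    pick_same <- length(ch_same) >= length(ch_inv)
    ch <- if (pick_same) ch_same else ch_inv
    if (length(ch) < min_block_size) break
    avail[ch] <- FALSE
    out[[length(out) + 1]] <- tibble(
      species_a = g$species_a[[1]], species_b = g$species_b[[1]],
      chr_a = g$chr_a[[1]], chr_b = g$chr_b[[1]],
      orientation = if (pick_same) "same" else "inverted",
      n_anchors = length(ch),
      start_rank_a = g$rank_a[ch[1]],
      anchors = list(tibble(
        gene_a = g$gene_a[ch], rank_a = g$rank_a[ch],
        gene_b = g$gene_b[ch], rank_b = g$rank_b[ch]
      ))
    )
  }
  bind_rows(out)
}

block_anchor_genes <- function(blocks) {
  if (is.null(blocks) || nrow(blocks) == 0) return(character(0))
  unique(unlist(lapply(blocks$anchors, function(a) c(a$gene_a, a$gene_b))))
}

#' Classify duplication modes for one species' family genes
#'
#' Priority assignment per gene: WGD when the gene is an anchor of an
#' intra-species collinear block; TD when it has a homolog on the same
#' chromosome at rank distance 1; PD at rank distance 2..`proximal_max_gap`;
#' TRD when it belongs to a homolog pair in which only the partner lies in a
#' collinear block with the outgroup (the non-syntenic copy is the
#' transposed one); DSD for any remaining gene with at least one homolog;
#' singleton otherwise.
#'
#' @param roster Tibble (gene_id, chromosome, rank) for one species.
#' @param homolog_pairs Tibble (gene_a, gene_b) of within-species homolog
#'   pairs among the roster genes.
#' @param intra_blocks Blocks tibble from [chain_anchors()] run on
#'   intra-species anchors (or NULL).
#' @param outgroup_blocks Blocks tibble from [chain_anchors()] run on
#'   species-vs-outgroup anchors (or NULL).
#' @param proximal_max_gap Maximum rank distance for proximal duplicates
#'   (default 10).
#' @return Tibble: gene_id, mode (WGD/TD/PD/TRD/DSD/singleton), evidence
#'   (partner gene or block anchor note).
#' @export
classify_duplications <- function(roster, homolog_pairs,
                                  intra_blocks = NULL, outgroup_blocks = NULL,
                                  proximal_max_gap = 10) {
  stopifnot_cols(roster, c("gene_id", "chromosome", "rank"))
  if (nrow(homolog_pairs) > 0) {
    stopifnot_cols(homolog_pairs, c("gene_a", "gene_b"))
    bad <- setdiff(unique(c(homolog_pairs$gene_a, homolog_pairs$gene_b)), roster$gene_id)
    if (length(bad) > 0) {
      abort(sprintf("Homolog gene(s) absent from annotation: %s",
                    paste(c_sort(bad), collapse = ", ")))
    }
  }
  chr <- stats::setNames(roster$chromosome, roster$gene_id)
  rnk <- stats::setNames(roster$rank, roster$gene_id)
  wgd_set <- intersect(block_anchor_genes(intra_blocks), roster$gene_id)
  og_set <- intersect(block_anchor_genes(outgroup_blocks), roster$gene_id)
  partners <- function(g) {
    c(homolog_pairs$gene_b[homolog_pairs$gene_a == g],
      homolog_pairs$gene_a[homolog_pairs$gene_b == g]) |> unique() |> setdiff(g)
  }
  call_one <- function(g) {
    hs <- partners(g)
    if (g %in% wgd_set) {
      return(tibble(gene_id = g, mode = "WGD", evidence = "intra-species block anchor"))
    }
    if (length(hs) > 0) {
      same_chr <- hs[chr[hs] == chr[[g]]]
      dist <- abs(rnk[same_chr] - rnk[[g]])
      td <- same_chr[dist == 1]
      if (length(td) > 0) {
        return(tibble(gene_id = g, mode = "TD", evidence = c_sort(td)[1]))
      }
      pd <- same_chr[dist >= 2 & dist <= proximal_max_gap]
      if (length(pd) > 0) {
        return(tibble(gene_id = g, mode = "PD", evidence = c_sort(pd)[1]))
      }
      anc <- hs[hs %in% og_set]
      if (!(g %in% og_set) && length(anc) > 0) {
        return(tibble(gene_id = g, mode = "TRD",
                      evidence = paste0("ancestral:", c_sort(anc)[1])))
      }
      return(tibble(gene_id = g, mode = "DSD", evidence = c_sort(hs)[1]))
    }
    tibble(gene_id = g, mode = "singleton", evidence = NA_character_)
  }
  purrr::map(roster$gene_id, call_one) |> bind_rows()
}

#' Conservation categories among syntenic gene pairs
#'
#' Each anchored pair contributes its two genes' categories (genes without a
#' category — e.g. non-family anchors — are skipped); percentages are over
#' all contributing genes per species pair, rounded half-up to 2 decimals.
#'
#' @param blocks Blocks tibble from [chain_anchors()] on cross-species
#'   anchors.
#' @param categories Tibble (gene_id, category) with category in
#'   conserved/variable/rare.
#' @return Tibble: species_a, species_b, n_genes, pct_conserved,
#'   pct_variable, pct_rare. Empty blocks give an empty table.
#' @export
synteny_conservation_table <- function(blocks, categories) {
  stopifnot_cols(categories, c("gene_id", "category"))
  if (is.null(blocks) || nrow(blocks) == 0) {
    return(tibble(species_a = character(0), species_b = character(0),
                  n_genes = integer(0), pct_conserved = numeric(0),
                  pct_variable = numeric(0), pct_rare = numeric(0)))
  }
  cat_of <- stats::setNames(categories$category, categories$gene_id)
  rows <- purrr::pmap(list(blocks$species_a, blocks$species_b, blocks$anchors),
    function(sa, sb, a) {
      g <- c(a$gene_a, a$gene_b)
      tibble(species_a = sa, species_b = sb, gene_id = g,
             category = unname(cat_of[g]))
    }) |> bind_rows() |>
    filter(!is.na(.data$category))
  rows |>
    group_by(.data$species_a, .data$species_b) |>
    summarise(
      n_genes = dplyr::n(),
      pct_conserved = round_half_up(100 * mean(.data$category == "conserved"), 2),
      pct_variable = round_half_up(100 * mean(.data$category == "variable"), 2),
      pct_rare = round_half_up(100 * mean(.data$category == "rare"), 2),
      .groups = "drop"
    )
}
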