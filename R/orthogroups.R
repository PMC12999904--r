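# Orthogroup (OGG) construction by reciprocal best hits + connected
# components, presence/copy-number matrices, and the conserved / variable /
# rare classification.

#' Build orthogroups from a homology table
#'
#' For each gene and each other species, the top-scoring cross-species
#' partner is its best hit (score ties broken by the smallest partner id);
#' an edge is kept iff the best-hit relation is mutual. Connected components
#' of the resulting graph are the orthogroups; genes with no mutual edge
#' become singleton orthogroups.
#'
#' @param homology Tibble (gene_a, gene_b, score), score >= 0; treated as
#'   undirected. Self-pairs are ignored with a warning.
#' @param genes Roster tibble (gene_id, species) spanning >= 2 species;
#'   homology rows involving genes outside the roster are dropped.
#' @return Tibble (gene_id, species, ogg_id); ogg ids are assigned in
#'   C-locale order of each component's smallest member id.
#' @export
build_oggs <- function(homology, genes) {
  stopifnot_cols(homology, c("gene_a", "gene_b", "score"))
  stopifnot_cols(genes, c("gene_id", "species"))
  if (length(unique(genes$species)) < 2) abort("Roster must span at least 2 species.")
  if (any(homology$gene_a == homology$gene_b)) {
    warn("Ignoring self-pair(s) in homology table.")
    homology <- filter(homology, .data$gene_a != .data$gene_b)
  }
  sp <- stats::setNames(genes$species, genes$gene_id)
  h <- homology |>
    filter(.data$gene_a %in% genes$gene_id, .data$gene_b %in% genes$gene_id)
  # undirected input -> both directions, cross-species only
  dir <- bind_rows(
    select(h, from = "gene_a", to = "gene_b", "score"),
    select(h, from = "gene_b", to = "gene_a", "score")
  ) |>
    distinct() |>
    filter(sp[.data$from] != sp[.data$to]) |>
    mutate(to_species = unname(sp[.data$to]))
  best <- dir[c_order(dir$from, dir$to_species, -dir$score, dir$to), , drop = FALSE] |>
    distinct(.data$from, .data$to_species, .keep_all = TRUE) |>
    select("from", "to")
  mutual <- inner_join(best, select(best, from = "to", to = "from"),
                       by = c("from", "to"))
  g <- igraph::graph_from_data_frame(mutual, directed = FALSE,
                                     vertices = genes$gene_id)
  comp <- igraph::components(g)$membership
  comp_min <- tapply(names(comp), comp, function(v) c_sort(v)[1])
  ord <- c_order(unname(comp_min))
  ogg_index <- match(as.character(comp), names(comp_min)[ord])
  width <- max(3, nchar(as.character(max(ogg_index))))
  tibble(
    gene_id = names(comp),
    species = unname(sp[names(comp)]),
    ogg_id = paste0("OGG", formatC(ogg_index, width = width, flag = "0"))
  ) |>
    arrange(.data$ogg_id, .data$gene_id)
}

#' Per-orthogroup, per-species copy-number matrix
#'
#' @param membership Tibble (gene_id, species, ogg_id) as from [build_oggs()].
#' @return Wide tibble: ogg_id, then one copy-number column per species.
#' @export
presence_matrix <- function(membership) {
  stopifnot_cols(membership, c("gene_id", "species", "ogg_id"))
  membership |>
    count(.data$ogg_id, .data$species) |>
    tidyr::pivot_wider(names_from = "species", values_from = "n", values_fill = 0L) |>
    arrange(.data$ogg_id)
}

#' Classify one orthogroup from its presence vector
#'
#' Conserved: present (copy number > 0) in all `n_species`; variable:
#' present in exactly `n_species - 1`; rare: present in 1 to `n_species - 2`.
#'
#' @param presence Numeric per-species copy-number vector of length
#'   `n_species`.
#' @param n_species Number of species in the panel.
#' @return `"conserved"`, `"variable"` or `"rare"`.
#' @export
classify_ogg <- function(presence, n_species) {
  if (length(presence) != n_species) {
    abort("`presence` length must equal `n_species`.")
  }
  k <- sum(presence > 0)
  if (k == 0) abort("Empty presence vector: orthogroup present in no species.")
  if (k == n_species) "conserved" else if (k == n_species - 1) "variable" else "rare"
}

#' Classify all orthogroups of a membership table
#'
#' @param membership Tibble (gene_id, species, ogg_id).
#' @param n_species Total species in the panel (defaults to the number of
#'   distinct species observed).
#' @return Tibble: ogg_id, n_present, n_genes, category.
#' @export
classify_oggs <- function(membership, n_species = dplyr::n_distinct(membership$species)) {
  pm <- presence_matrix(membership)
  cols <- setdiff(names(pm), "ogg_id")
  tibble(
    ogg_id = pm$ogg_id,
    n_present = apply(pm[cols], 1, function(v) sum(v > 0)),
    n_genes = as.integer(rowSums(pm[cols])),
    category = apply(pm[cols], 1, function(v) {
      classify_ogg(c(v, numeric(n_species - length(cols))), n_species)
    })
  )
}

#' Percentage of genes per category
#'
#' `100 * count / total`, rounded half-up to 2 decimals (the convention used
#' for reported category shares).
#'
#' @param counts Named or unnamed numeric vector of per-category gene counts.
#' @param total Total gene count; `sum(counts) <= total`.
#' @return Numeric vector of percentages (2 decimals, half-up).
#' @export
category_proportions <- function(counts, total) {
  if (sum(counts) > total) abort("Category counts exceed the total.")
  round_half_up(100 * counts / total, 2)
}
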