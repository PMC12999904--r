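# Family identification: apply the domain-hit filters (E-value, domain
# completeness, minimum protein length), keep one isoform per locus, and
# rename family members by chromosomal position.

#' Filter candidate family members from domain hits
#'
#' A protein is accepted when at least one of its hits passes all three
#' filters: full-sequence E-value at or below the cutoff, model coverage
#' (`(model_to - model_from + 1) / model_len`) at or above the completeness
#' fraction, and protein length at or above the minimum.
#'
#' @param hits Tibble of domain hits: protein_id, model_id, evalue,
#'   model_len, model_from, model_to (see [read_domain_hits()]).
#' @param proteins Tibble (protein_id, length) with one row per protein;
#'   every hit's protein must be present.
#' @param evalue_cutoff Full-sequence E-value cutoff (default `1e-10`).
#' @param min_protein_length Minimum protein length in amino acids
#'   (default 100).
#' @param domain_completeness_fraction Minimum fraction of the domain model
#'   covered by the alignment (default 0.8); the operational stand-in for
#'   requiring a complete domain.
#' @return Tibble of accepted proteins (protein_id, best_evalue,
#'   best_coverage, length), sorted by protein_id (C locale).
#' @export
filter_candidates <- function(hits, proteins,
                              evalue_cutoff = 1e-10,
                              min_protein_length = 100,
                              domain_completeness_fraction = 0.8) {
  stopifnot_cols(hits, c("protein_id", "evalue", "model_len", "model_from", "model_to"))
  stopifnot_cols(proteins, c("protein_id", "length"))
  if (evalue_cutoff <= 0) abort("`evalue_cutoff` must be > 0.")
  unknown <- setdiff(hits$protein_id, proteins$protein_id)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown protein id(s) in hits: %s",
                  paste(c_sort(unknown), collapse = ", ")))
  }
  hits |>
    mutate(coverage = (.data$model_to - .data$model_from + 1) / .data$model_len) |>
    left_join(proteins, by = "protein_id") |>
    mutate(pass = .data$evalue <= evalue_cutoff &
             .data$coverage >= domain_completeness_fraction &
             .data$length >= min_protein_length) |>
    filter(.data$pass) |>
    group_by(.data$protein_id) |>
    summarise(
      best_evalue = min(.data$evalue),
      best_coverage = max(.data$coverage),
      length = first(.data$length),
      .groups = "drop"
    ) |>
    arrange(.data$protein_id) # tibble arrange uses C locale for character
}

#' Keep the longest isoform per gene
#'
#' For each gene, retains exactly one transcript: the one with the greatest
#' summed CDS length, ties broken by the lexicographically smallest
#' transcript id (C locale, so `"t10" < "t2"`).
#'
#' @param features Tibble (gene_id, transcript_id, type, start, end) with at
#'   least one `"cds"` row per transcript.
#' @return The `features` rows of the retained transcripts only.
#' @export
longest_isoform <- function(features) {
  stopifnot_cols(features, c("gene_id", "transcript_id", "type", "start", "end"))
  cds <- features |> filter(.data$type == "cds")
  no_tx <- setdiff(unique(features$gene_id), unique(cds$gene_id))
  if (length(no_tx) > 0) {
    abort(sprintf("Gene(s) without any CDS-bearing transcript: %s",
                  paste(c_sort(no_tx), collapse = ", ")))
  }
  retained <- cds |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(cds_length = sum(.data$end - .data$start + 1L), .groups = "drop")
  retained <- retained[c_order(retained$gene_id, -retained$cds_length,
                               retained$transcript_id), , drop = FALSE]
  retained <- retained |> distinct(.data$gene_id, .keep_all = TRUE)
  features |> inner_join(select(retained, "gene_id", "transcript_id"),
                         by = c("gene_id", "transcript_id"))
}

#' Rename family members by chromosomal position
#'
#' Orders one species' genes by chromosome (natural numeric order, so chr2
#' precedes chr10), then start coordinate, then gene id, and assigns
#' `prefix` + zero-padded index. Padding width is the digit count of the
#' family size, so names sort lexicographically.
#'
#' @param genes Tibble (gene_id, chromosome, start) for a single species.
#' @param prefix Name prefix, e.g. `"Hann_MAPKKK"`.
#' @return `genes` with a `family_name` column, in naming order.
#' @export
rename_by_position <- function(genes, prefix) {
  stopifnot_cols(genes, c("gene_id", "chromosome", "start"))
  if (nrow(genes) == 0) return(mutate(genes, family_name = character(0)))
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("Duplicate gene id(s): %s",
                  paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")))
  }
  chr_levels <- unique(genes$chromosome)[natural_order(unique(genes$chromosome))]
  ord <- c_order(match(genes$chromosome, chr_levels), genes$start, genes$gene_id)
  out <- genes[ord, , drop = FALSE]
  width <- nchar(as.character(nrow(out)))
  out$family_name <- paste0(prefix, formatC(seq_len(nrow(out)), width = width, flag = "0"))
  out
}
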