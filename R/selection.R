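# Selection-pressure estimation: codon-aware back-translation, Nei-Gojobori
# (1986) Ka/Ks with Jukes-Cantor correction, and the two-level aggregation
# (pair -> orthogroup mean -> cluster mean).

#' Back-translate a pairwise protein alignment to a codon alignment
#'
#' Each aligned amino acid is replaced by its source codon and each gap by
#' `---`, so gap runs stay on codon boundaries and removing gaps recovers the
#' original CDS.
#'
#' @param prot_a,prot_b Gapped protein rows of equal length (`-` for gaps).
#' @param cds_a,cds_b Ungapped in-frame CDS for the two rows; each must
#'   translate exactly to its ungapped protein under the standard code.
#' @return Named character vector `c(a =, b =)` of gapped CDS rows.
#' @examples
#' backtranslate("M-F", "MKF", "ATGTTT", "ATGAAATTC")
#' @export
backtranslate <- function(prot_a, prot_b, cds_a, cds_b) {
  if (nchar(prot_a) != nchar(prot_b)) {
    abort("Protein alignment rows must have equal length.")
  }
  row_bt <- function(prot, cds, label) {
    if (nchar(cds) %% 3 != 0) abort(sprintf("CDS of %s is not a multiple of 3.", label))
    codons <- split_codons(cds)
    aas <- strsplit(prot, "")[[1]]
    res <- character(length(aas))
    k <- 0
    for (i in seq_along(aas)) {
      if (aas[[i]] == "-") { res[[i]] <- "---"; next }
      k <- k + 1
      if (k > length(codons)) {
        abort(sprintf("CDS of %s is shorter than its aligned protein.", label))
      }
      if (translate_codons(codons[[k]]) != aas[[i]]) {
        abort(sprintf(
          "Translation mismatch for %s at alignment column %d: codon %s is %s, protein says %s.",
          label, i, codons[[k]], translate_codons(codons[[k]]), aas[[i]]
        ))
      }
      res[[i]] <- codons[[k]]
    }
    if (k != length(codons)) {
      abort(sprintf("CDS of %s has %d unaligned trailing codon(s).", label, length(codons) - k))
    }
    paste0(res, collapse = "")
  }
  c(a = row_bt(prot_a, cds_a, "sequence a"), b = row_bt(prot_b, cds_b, "sequence b"))
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - (4/3) p)`; undefined (NA) when `p >= 3/4`.
#'
#' @param p Proportion of differing sites.
#' @return Corrected distance, or NA where undefined.
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori (1986) Ka/Ks for one codon alignment
#'
#' Synonymous site fractions per codon come from one-step mutations with
#' paths through stop codons excluded and sites renormalised over valid
#' changes; S and N are averaged over the two sequences. Differences at
#' multi-position codons are averaged over all orderings of single steps,
#' discarding orderings that pass through a stop. `ps = Sd/S` and `pd = Nd/N`
#' are Jukes-Cantor corrected to Ks and Ka; `omega = Ka/Ks` is NA when
#' `Ks = 0` or a correction is undefined (`p >= 3/4`).
#'
#' @param aln Named character vector of two gapped CDS rows (as from
#'   [backtranslate()]); gap runs must sit on codon boundaries. Columns with a
#'   gap in either row are excluded from counting.
#' @param gene_a,gene_b Identifiers carried into the result.
#' @return One-row tibble: gene_a, gene_b, n_codons, S, N, Sd, Nd, ps, pd,
#'   ka, ks, omega.
#' @export
ng86 <- function(aln, gene_a = "a", gene_b = "b") {
  if (length(aln) != 2) abort("`aln` must hold exactly two rows.")
  if (nchar(aln[[1]]) != nchar(aln[[2]])) abort("Alignment rows differ in length.")
  if (nchar(aln[[1]]) %% 3 != 0) abort("Alignment length must be divisible by 3.")
  ca <- split_codons(aln[[1]])
  cb <- split_codons(aln[[2]])
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  if (!any(keep)) abort("All codon columns are gapped; nothing to compare.")
  ca <- ca[keep]; cb <- cb[keep]
  if (any(translate_codons(ca) == "*") || any(translate_codons(cb) == "*")) {
    abort("Stop codon in a compared column.")
  }
  sites <- syn_site_table()
  s_a <- sum(sites[ca]); s_b <- sum(sites[cb])
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  tabs <- pair_diff_tables()
  idx <- cbind(ca, cb)
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  ps <- Sd / S
  pd <- Nd / N
  ks <- jc_correct(ps)
  ka <- jc_correct(pd)
  omega <- if (is.na(ks) || is.na(ka) || ks == 0) NA_real_ else ka / ks
  tibble(
    gene_a = gene_a, gene_b = gene_b, n_codons = sum(keep),
    S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pd = pd,
    ka = ka, ks = ks, omega = omega
  )
}

#' Aggregate pairwise Ka/Ks to orthogroup and cluster means
#'
#' The orthogroup value is the arithmetic mean of all defined pairwise values
#' within the group; the cluster value is the unweighted mean of its
#' orthogroups' means.
#'
#' @param pairs Tibble of pairwise results (as from [ng86()]): gene_a,
#'   gene_b, ka, ks, omega.
#' @param membership Tibble (gene_id, ogg_id) mapping genes to orthogroups;
#'   both genes of a pair must map to the same orthogroup.
#' @param clusters Optional tibble (ogg_id, cluster) for the second level.
#' @return List of tibbles `ogg` (ogg_id, mean_ka, mean_ks, mean_omega,
#'   n_pairs) and `cluster` (cluster, mean_ka, mean_ks, mean_omega, n_oggs);
#'   `cluster` is NULL when `clusters` is not given. Orthogroups whose
#'   pairwise omegas are all undefined are omitted with a warning.
#' @export
aggregate_kaks <- function(pairs, membership, clusters = NULL) {
  stopifnot_cols(pairs, c("gene_a", "gene_b", "ka", "ks", "omega"))
  stopifnot_cols(membership, c("gene_id", "ogg_id"))
  ogg_of <- stats::setNames(membership$ogg_id, membership$gene_id)
  oa <- ogg_of[pairs$gene_a]; ob <- ogg_of[pairs$gene_b]
  if (any(is.na(oa)) || any(is.na(ob))) {
    abort("Every paired gene must appear in `membership`.")
  }
  if (any(oa != ob)) abort("Pair spans two orthogroups; pairs must be within-OGG.")
  df <- mutate(pairs, ogg_id = unname(oa))
  dropped <- df |>
    group_by(.data$ogg_id) |>
    summarise(all_na = all(is.na(.data$omega)), .groups = "drop") |>
    filter(.data$all_na)
  if (nrow(dropped) > 0) {
    warn(sprintf(
      "Omitting %d orthogroup(s) with no defined omega: %s",
      nrow(dropped), paste(dropped$ogg_id, collapse = ", ")
    ))
  }
  ogg <- df |>
    filter(!is.na(.data$omega)) |>
    group_by(.data$ogg_id) |>
    summarise(
      mean_ka = mean(.data$ka), mean_ks = mean(.data$ks),
      mean_omega = mean(.data$omega), n_pairs = dplyr::n(), .groups = "drop"
    )
  cluster <- NULL
  if (!is.null(clusters)) {
    stopifnot_cols(clusters, c("ogg_id", "cluster"))
    cluster <- ogg |>
      inner_join(clusters, by = "ogg_id") |>
      group_by(.data$cluster) |>
      summarise(
        mean_ka = mean(.data$mean_ka), mean_ks = mean(.data$mean_ks),
        mean_omega = mean(.data$mean_omega), n_oggs = dplyr::n(), .groups = "drop"
      )
  }
  list(ogg = ogg, cluster = cluster)
}
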