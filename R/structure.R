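# Gene-structure metrics on the retained transcript, and the unpaired
# two-group comparison used for the boxplot panels.

#' Structural metrics per gene
#'
#' Computes, for each gene's retained transcript: total gene length
#' (`end - start + 1`), CDS segment count, intron count (`exons - 1`), total
#' intron length (transcript span minus summed exon length), and amino-acid
#' length (summed CDS length / 3, minus one when the CDS ends in a stop
#' codon).
#'
#' @param genes Tibble (gene_id, start, end, ...) of gene records.
#' @param features Tibble (gene_id, transcript_id, type, start, end) holding
#'   exactly one retained transcript per gene (see [longest_isoform()]).
#' @param cds_seqs Optional named character vector of CDS sequences used to
#'   detect a terminal stop codon; without it the stop is assumed absent.
#' @return Tibble: gene_id, gene_length, cds_count, intron_count,
#'   total_intron_length, aa_length.
#' @export
structure_metrics <- function(genes, features, cds_seqs = NULL) {
  stopifnot_cols(genes, c("gene_id", "start", "end"))
  stopifnot_cols(features, c("gene_id", "transcript_id", "type", "start", "end"))
  per_gene <- function(gid, gstart, gend) {
    fx <- features[features$gene_id == gid, , drop = FALSE]
    if (length(unique(fx$transcript_id)) != 1) {
      abort(sprintf("Gene %s must have exactly one retained transcript.", gid))
    }
    ex <- fx[fx$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      abort(sprintf("Overlapping exons in gene %s.", gid))
    }
    cds <- fx[fx$type == "cds", , drop = FALSE]
    exon_len <- sum(ex$end - ex$start + 1L)
    span <- max(ex$end) - min(ex$start) + 1L
    cds_sum <- sum(cds$end - cds$start + 1L)
    aa <- cds_sum %/% 3
    if (!is.null(cds_seqs) && gid %in% names(cds_seqs) && cds_sum %% 3 == 0 && cds_sum >= 3) {
      s <- cds_seqs[[gid]]
      last <- substr(s, nchar(s) - 2, nchar(s))
      if (translate_codons(last) == "*") aa <- aa - 1L
    }
    tibble(
      gene_id = gid,
      gene_length = as.integer(gend - gstart + 1L),
      cds_count = nrow(cds),
      intron_count = nrow(ex) - 1L,
      total_intron_length = as.integer(span - exon_len),
      aa_length = as.integer(aa)
    )
  }
  purrr::pmap(list(genes$gene_id, genes$start, genes$end), per_gene) |> bind_rows()
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Exact enumeration of all group assignments (midranks for ties) when both
#' groups have at most 8 observations; otherwise the normal approximation
#' with the tie-corrected variance. The two-sided exact p-value is
#' `min(1, 2 * min(lower tail, upper tail))`.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return One-row tibble: statistic (rank sum of group a, midranks),
#'   p_value, method.
#' @export
group_compare <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("Both groups must be non-empty.")
  }
  n1 <- length(values_a); n2 <- length(values_b)
  pooled <- c(values_a, values_b)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(n1)])
  if (n1 <= 8 && n2 <= 8) {
    combos <- utils::combn(n1 + n2, n1)
    w_all <- apply(combos, 2, function(idx) sum(rk[idx]))
    eps <- 1e-9
    p_lo <- mean(w_all <= w_obs + eps)
    p_hi <- mean(w_all >= w_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    mu <- n1 * (n + 1) / 2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w_obs - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  tibble(statistic = w_obs, p_value = p, method = method)
}
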