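# Expression analysis: FPKM normalisation, the |log2FC| > 1 responsiveness
# screen, row-scaled heatmap matrices, and 2^-ddCt qPCR analysis with
# replicate statistics and compact letter display.

#' Fragments per kilobase of transcript per million mapped reads
#'
#' `count * 1e9 / (transcript_length_bp * total_mapped)`; vectorised.
#'
#' @param count Fragment count(s) (>= 0).
#' @param transcript_length_bp Transcript length(s) in bp (> 0).
#' @param total_mapped Total mapped fragments in the library (> 0).
#' @return FPKM value(s).
#' @examples
#' fpkm(10, 1000, 1e6) # 10
#' @export
fpkm <- function(count, transcript_length_bp, total_mapped) {
  if (any(count < 0) || any(transcript_length_bp <= 0) || any(total_mapped <= 0)) {
    abort("count must be >= 0; length and library size must be > 0.")
  }
  count * 1e9 / (transcript_length_bp * total_mapped)
}

#' Screen genes for stress responsiveness by fold change
#'
#' `log2fc = log2((treated + pseudocount) / (control + pseudocount))`; a
#' gene is responsive iff `|log2fc| > 1` (strict).
#'
#' @param expr Tibble (gene_id, treated, control) of non-negative expression
#'   values (e.g. mean FPKM per condition).
#' @param pseudocount Added to both sides before the ratio (default 1).
#' @return Tibble: gene_id, log2fc, responsive.
#' @export
de_screen <- function(expr, pseudocount = 1.0) {
  stopifnot_cols(expr, c("gene_id", "treated", "control"))
  if (any(expr$treated < 0) || any(expr$control < 0)) {
    abort("Expression values must be >= 0.")
  }
  expr |>
    mutate(
      log2fc = log2((.data$treated + pseudocount) / (.data$control + pseudocount)),
      responsive = abs(.data$log2fc) > 1
    ) |>
    select("gene_id", "log2fc", "responsive")
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = ct_target - ct_reference`; `ddCt` subtracts the
#' mean control `dCt` (the 0 h samples); `fold = 2^-ddCt`. The mean and sd
#' of the replicate folds are reported per gene/condition/timepoint.
#'
#' @param records Tibble (gene_id, condition, timepoint, replicate,
#'   ct_target, ct_reference).
#' @param control_timepoint Timepoint serving as the control (default 0).
#' @return Tibble: gene_id, condition, timepoint, fold_mean, fold_sd (sample
#'   sd over replicate folds; 0 for a single replicate), n_reps.
#' @export
ddct <- function(records, control_timepoint = 0) {
  stopifnot_cols(records, c("gene_id", "condition", "timepoint", "replicate",
                            "ct_target", "ct_reference"))
  if (any(records$ct_target <= 0 | records$ct_target >= 45) ||
      any(records$ct_reference <= 0 | records$ct_reference >= 45)) {
    abort("Ct values must lie in (0, 45).")
  }
  rec <- mutate(records, dct = .data$ct_target - .data$ct_reference)
  ctrl <- rec |>
    filter(.data$timepoint == control_timepoint) |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(ctrl_dct = mean(.data$dct), .groups = "drop")
  missing <- rec |>
    distinct(.data$gene_id, .data$condition) |>
    anti_join(ctrl, by = c("gene_id", "condition"))
  if (nrow(missing) > 0) {
    abort(sprintf("Missing control timepoint %s for: %s", control_timepoint,
                  paste(paste(missing$gene_id, missing$condition, sep = "/"),
                        collapse = ", ")))
  }
  rec |>
    inner_join(ctrl, by = c("gene_id", "condition")) |>
    mutate(fold = 2^(-(.data$dct - .data$ctrl_dct))) |>
    group_by(.data$gene_id, .data$condition, .data$timepoint) |>
    summarise(
      fold_mean = mean(.data$fold),
      fold_sd = if (dplyr::n() > 1) stats::sd(.data$fold) else 0,
      n_reps = dplyr::n(),
      .groups = "drop"
    )
}

#' Compact letter display for timepoint fold changes
#'
#' One-way ANOVA on log2(fold) followed by Tukey HSD at `alpha`; letters are
#' assigned greedily from the highest group mean downward, groups not
#' significantly different from a letter's anchor sharing that letter.
#'
#' @param folds Tibble (timepoint, fold) of replicate folds; >= 2 groups
#'   with >= 2 replicates each.
#' @param alpha Significance level (default 0.05).
#' @return Tibble: timepoint, mean_fold, letters.
#' @export
letter_groups <- function(folds, alpha = 0.05) {
  stopifnot_cols(folds, c("timepoint", "fold"))
  folds <- mutate(folds, grp = factor(.data$timepoint))
  sizes <- table(folds$grp)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Need >= 2 groups with >= 2 replicates each.")
  }
  folds <- mutate(folds, y = log2(.data$fold))
  if (stats::var(folds$y) == 0) {
    # all observations identical: one shared letter
    means <- folds |> group_by(.data$grp) |> summarise(m = mean(.data$fold), .groups = "drop")
    return(tibble(timepoint = as.character(means$grp), mean_fold = means$m,
                  letters = "a"))
  }
  fit <- stats::aov(y ~ grp, data = folds)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
  padj <- tk[, "p adj"]
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  differs <- function(a, b) {
    hit <- (pairs[, 1] == a & pairs[, 2] == b) | (pairs[, 1] == b & pairs[, 2] == a)
    any(padj[hit] < alpha)
  }
  means <- folds |>
    group_by(.data$grp) |>
    summarise(m = mean(.data$y), mf = mean(.data$fold), .groups = "drop") |>
    arrange(desc(.data$m))
  grps <- as.character(means$grp)
  letter_sets <- stats::setNames(vector("list", length(grps)), grps)
  next_letter <- 1
  for (g in grps) {
    if (length(letter_sets[[g]]) > 0) next
    lett <- letters[next_letter]; next_letter <- next_letter + 1
    for (h in grps) {
      if (!differs(g, h)) letter_sets[[h]] <- c(letter_sets[[h]], lett)
    }
  }
  tibble(
    timepoint = grps,
    mean_fold = means$mf,
    letters = vapply(letter_sets[grps], paste0, "", collapse = "")
  )
}

#' Row z-scores of an expression matrix
#'
#' Per gene (row), `(x - mean) / sd` with the population sd; constant rows
#' become zeros. Requires at least 2 samples.
#'
#' @param mat Numeric genes x samples matrix, or a tibble whose first column
#'   is the gene id.
#' @return Same shape, rows scaled.
#' @export
row_scale <- function(mat) {
  is_df <- is.data.frame(mat)
  if (is_df) {
    label <- mat[, 1, drop = FALSE]
    m <- as.matrix(mat[, -1, drop = FALSE])
  } else {
    m <- as.matrix(mat)
  }
  if (ncol(m) < 2) abort("Need at least 2 samples to row-scale.")
  scaled <- t(apply(m, 1, function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  if (is_df) bind_cols(label, as_tibble(scaled)) else {
    dimnames(scaled) <- dimnames(m)
    scaled
  }
}
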