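#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages in this
#' package use conventional half-up rounding so that e.g. `0.125 -> 0.13`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(29.335, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Natural (version-style) ordering of identifiers
#'
#' Splits each string into alternating non-digit and digit runs and compares
#' digit runs numerically, so `"chr2"` sorts before `"chr10"`.
#'
#' @param x Character vector.
#' @return Integer permutation that sorts `x` naturally.
#' @examples
#' natural_order(c("chr10", "chr2", "chr1"))
#' @export
natural_order <- function(x) {
  if (length(x) == 0) return(integer(0))
  pieces <- stringr::str_extract_all(x, "\\d+|\\D+")
  width <- max(lengths(pieces))
  keymat <- vapply(seq_len(width), function(i) {
    tok <- vapply(pieces, function(p) if (i <= length(p)) p[[i]] else "", "")
    isnum <- grepl("^\\d+$", tok)
    # numeric runs sort before/among themselves numerically; pad to fixed width
    num <- suppressWarnings(as.numeric(tok))
    ifelse(isnum,
      sprintf("0%030.10f", num),
      sprintf("1%s", tok)
    )
  }, character(length(x)))
  if (length(x) == 1) keymat <- matrix(keymat, nrow = 1)
  key <- apply(keymat, 1, paste0, collapse = "\r")
  order(key, method = "radix")
}

# C-locale (radix) sort of a character vector; used for deterministic
# lexicographic tie-breaks such as "t10" < "t2".
c_sort <- function(x) sort(x, method = "radix")

c_order <- function(...) order(..., method = "radix")

# stable sub-seed derivation: one RNG stream per file kind / section
sub_seed <- function(seed, k) {
  (as.double(seed) * 1009 + 7919 * k) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# log-uniform integer draw on [lo, hi]
rlogunif_int <- function(n, lo, hi) {
  as.integer(round(exp(stats::runif(n, log(lo), log(hi)))))
}

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
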