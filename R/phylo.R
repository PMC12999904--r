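# Alignment trimming, p-distances, neighbor joining, and reference-anchored
# subfamily/cluster label propagation.

#' Trim alignment columns by gap occupancy
#'
#' Keeps exactly the columns whose non-gap fraction is at or above the gap
#' threshold (inclusive boundary); row order is preserved.
#'
#' @param alignment Named character vector of equal-length aligned rows
#'   (`-` for gaps).
#' @param gap_threshold Minimum fraction of non-gap residues for a column to
#'   be kept; in (0, 1], default 0.2.
#' @return Named character vector of trimmed rows.
#' @export
trim_alignment <- function(alignment, gap_threshold = 0.2) {
  if (gap_threshold <= 0 || gap_threshold > 1) {
    abort("`gap_threshold` must be in (0, 1].")
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) > 1) abort("Ragged alignment: rows differ in length.")
  if (lens[[1]] == 0) return(alignment)
  m <- do.call(rbind, strsplit(unname(alignment), ""))
  nongap <- colMeans(m != "-")
  keep <- nongap >= gap_threshold
  stats::setNames(apply(m[, keep, drop = FALSE], 1, paste0, collapse = ""),
                  names(alignment))
}

#' Pairwise p-distances from an alignment
#'
#' `d(i, j)` is the fraction of mismatching positions among columns where
#' neither row has a gap; pairs with zero comparable columns get distance 1
#' with a warning.
#'
#' @param alignment Named character vector of equal-length aligned rows.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = row names.
#' @export
pairwise_distance <- function(alignment) {
  if (length(alignment) < 2) abort("Need at least 2 rows.")
  if (length(unique(nchar(alignment))) > 1) abort("Ragged alignment.")
  m <- do.call(rbind, strsplit(unname(alignment), ""))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  gap <- m == "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !gap[i, ] & !gap[j, ]
      if (!any(comp)) {
        warn(sprintf("No comparable columns between %s and %s; distance set to 1.",
                     names(alignment)[i], names(alignment)[j]))
        d[i, j] <- d[j, i] <- 1
      } else {
        d[i, j] <- d[j, i] <- mean(m[i, comp] != m[j, comp])
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Negative branch lengths are clamped to
#' zero with the deficit transferred to the sister branch; ties in the
#' Q-matrix are broken by the lexicographically smallest pair of cluster
#' representative labels (the smallest original leaf label in each cluster).
#'
#' @param d Symmetric distance matrix with dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  if (is.null(dimnames(d)) || is.null(rownames(d))) abort("`d` needs dimnames.")
  n <- nrow(d)
  if (n < 3) abort("Neighbor joining needs at least 3 taxa.")
  if (max(abs(d - t(d))) > 1e-12) abort("`d` must be symmetric.")
  labs <- rownames(d)
  nwk <- labs            # newick fragment per active cluster
  rep_lab <- labs        # smallest original leaf label per cluster
  clamp2 <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      pr <- c_sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[c_order(key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    b <- clamp2(bi, bj)
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(b[1]), nwk[j], fmt(b[2]))
    new_rep <- c_sort(c(rep_lab[i], rep_lab[j]))[1]
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
    rn <- c(rownames(d)[keep], new_rep)
    dimnames(d2) <- list(rn, rn)
    d <- d2
  }
  # three-point closed form for the final star
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[1], fmt(b[1]), nwk[2], fmt(b[2]), nwk[3], fmt(b[3]))
  ape::read.tree(text = txt)
}

#' Propagate subfamily/cluster labels from reference leaves
#'
#' Every non-reference leaf receives the labels of its nearest reference
#' leaf by patristic distance; ties are broken by the smallest reference id.
#' Reference leaves keep their own panel labels.
#'
#' @param tree An `ape::phylo` tree whose tips include the references.
#' @param panel Tibble (ref_id, subfamily, cluster) — the reference panel;
#'   all three subfamilies (RAF, MEKK, ZIK) must be represented among the
#'   references present in the tree.
#' @return Tibble: gene_id, subfamily, cluster (one row per tree tip).
#' @export
assign_labels <- function(tree, panel) {
  stopifnot_cols(panel, c("ref_id", "subfamily"))
  if (!"cluster" %in% names(panel)) panel$cluster <- NA
  refs <- panel |> filter(.data$ref_id %in% tree$tip.label)
  missing_sf <- setdiff(c("RAF", "MEKK", "ZIK"), unique(refs$subfamily))
  if (length(missing_sf) > 0) {
    abort(sprintf("Reference panel lacks subfamily: %s",
                  paste(missing_sf, collapse = ", ")))
  }
  pd <- stats::cophenetic(tree)
  refs <- refs[c_order(refs$ref_id), , drop = FALSE]
  lab_of <- function(tip) {
    if (tip %in% refs$ref_id) {
      r <- refs[refs$ref_id == tip, ]
      return(tibble(gene_id = tip, subfamily = r$subfamily[[1]], cluster = r$cluster[[1]]))
    }
    dd <- pd[tip, refs$ref_id]
    hit <- which(dd <= min(dd) + 1e-9)[1] # refs pre-sorted: first = smallest id
    tibble(gene_id = tip, subfamily = refs$subfamily[[hit]], cluster = refs$cluster[[hit]])
  }
  purrr::map(tree$tip.label, lab_of) |> bind_rows()
}
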