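# Promoter extraction (2 kb upstream of the translation start), IUPAC
# consensus scanning on both strands, and the proportion / z-score matrices
# behind the element heatmaps.

IUPAC_SETS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

iupac_regex <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) {
    abort(sprintf("Non-IUPAC character(s) in consensus %s: %s",
                  consensus, paste(bad, collapse = ", ")))
  }
  paste0(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (nchar(s) == 1) s else paste0("[", s, "]")
  }, ""), collapse = "")
}

#' Packaged cis-element motif library
#'
#' The 14 high-frequency plant promoter elements with IUPAC consensi and
#' their functional class (stress / light / hormone / development). The
#' consensus strings are editable stand-ins maintained with the package;
#' users can extend or replace the table (columns: element, consensus,
#' class).
#'
#' @return Tibble: element, consensus, class.
#' @export
default_motif_library <- function() {
  tibble::tribble(
    ~element,       ~consensus,  ~class,
    "MYC",          "CATGTG",    "stress",
    "MYB",          "CAACAG",    "stress",
    "ARE",          "AAACCA",    "stress",
    "STRE",         "AGGGG",     "stress",
    "MYB-like",     "TAACCA",    "stress",
    "Box-4",        "ATTAAT",    "light",
    "G-box",        "CACGTG",    "light",
    "GT1-motif",    "GGTTAA",    "light",
    "ABRE",         "ACGTGGC",   "hormone",
    "ERE",          "ATTTCAAA",  "hormone",
    "CGTCA-motif",  "CGTCA",     "hormone",
    "TGACG-motif",  "TGACG",     "hormone",
    "as-1",         "TGACGTCA",  "hormone",
    "AAGAA-motif",  "GAAAGAA",   "development"
  )
}

#' Extract promoter sequences upstream of the translation start
#'
#' For a plus-strand gene the promoter is the `window` bases immediately 5'
#' of the first CDS base (`[cds_start - window, cds_start - 1]`); for a
#' minus-strand gene, the reverse complement of
#' `[cds_end + 1, cds_end + window]`. Windows are truncated at chromosome
#' boundaries and flagged.
#'
#' @param genes Tibble (gene_id, chromosome, strand).
#' @param features Tibble (gene_id, transcript_id, type, start, end) of the
#'   retained transcripts; each gene needs at least one `"cds"` row.
#' @param genome Named character vector chromosome -> sequence.
#' @param window Upstream window in bp (default 2000).
#' @return Tibble: gene_id, sequence, actual_length, truncated.
#' @export
extract_promoter <- function(genes, features, genome, window = 2000) {
  stopifnot_cols(genes, c("gene_id", "chromosome", "strand"))
  cds <- features |> filter(.data$type == "cds")
  one <- function(gid, chrom, strand) {
    cx <- cds[cds$gene_id == gid, , drop = FALSE]
    if (nrow(cx) == 0) abort(sprintf("Gene %s has no CDS segment.", gid))
    if (!chrom %in% names(genome)) abort(sprintf("Chromosome %s not in genome.", chrom))
    chr_seq <- genome[[chrom]]
    chr_len <- nchar(chr_seq)
    if (strand == "+") {
      cds_start <- min(cx$start)
      from <- max(1, cds_start - window)
      to <- cds_start - 1
      seq <- if (to < from) "" else substr(chr_seq, from, to)
      truncated <- (cds_start - window) < 1
    } else {
      cds_end <- max(cx$end)
      from <- cds_end + 1
      to <- min(chr_len, cds_end + window)
      seq <- if (to < from) "" else revcomp(substr(chr_seq, from, to))
      truncated <- (cds_end + window) > chr_len
    }
    tibble(gene_id = gid, sequence = toupper(seq),
           actual_length = nchar(seq), truncated = truncated)
  }
  purrr::pmap(list(genes$gene_id, genes$chromosome, genes$strand), one) |> bind_rows()
}

# all (overlapping) match starts of an IUPAC consensus in one sequence
iupac_match_starts <- function(sequence, consensus) {
  if (nchar(sequence) < nchar(consensus) || nchar(sequence) == 0) return(integer(0))
  rx <- paste0("(?=", iupac_regex(consensus), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Scan promoters for cis-element matches
#'
#' Exact IUPAC-consensus scanning on both strands; overlapping matches are
#' all reported. Minus-strand hits are reported at the plus-strand start of
#' the matched window; for palindromic consensi the duplicate
#' (element, start) hit is collapsed to a single plus-strand hit. `N` in the
#' promoter never matches.
#'
#' @param promoters Tibble (gene_id, sequence) as from [extract_promoter()].
#' @param library Motif library tibble (element, consensus, class);
#'   default [default_motif_library()].
#' @return Tibble: gene_id, element, class, start (1-based), strand.
#' @export
scan_motifs <- function(promoters, library = default_motif_library()) {
  stopifnot_cols(promoters, c("gene_id", "sequence"))
  stopifnot_cols(library, c("element", "consensus", "class"))
  if (anyDuplicated(library$element)) abort("Element names must be unique.")
  seqs <- toupper(promoters$sequence)
  starts_all <- function(consensus) {
    # vectorised overlapping-match starts across all promoters
    rx <- paste0("(?=", iupac_regex(consensus), ")")
    ok <- nchar(seqs) >= nchar(consensus) & nchar(seqs) > 0
    out <- vector("list", length(seqs))
    if (any(ok)) {
      m <- gregexpr(rx, seqs[ok], perl = TRUE)
      out[ok] <- lapply(m, function(v) if (v[1] == -1) integer(0) else as.integer(v))
    }
    out[!ok] <- list(integer(0))
    out
  }
  rows <- list()
  for (j in seq_len(nrow(library))) {
    cons <- library$consensus[[j]]
    plus <- starts_all(cons)
    minus <- starts_all(revcomp(cons))
    np <- lengths(plus); nm <- lengths(minus)
    if (sum(np) + sum(nm) == 0) next
    hits <- tibble(
      gene_id = c(rep(promoters$gene_id, np), rep(promoters$gene_id, nm)),
      element = library$element[[j]],
      class = library$class[[j]],
      start = c(unlist(plus), unlist(minus)),
      strand = c(rep("+", sum(np)), rep("-", sum(nm)))
    )
    # palindromic dedup: identical (element, start, end) on both strands
    hits <- hits[c_order(hits$gene_id, hits$start, hits$strand), , drop = FALSE] |>
      distinct(.data$gene_id, .data$element, .data$start, .keep_all = TRUE)
    rows[[j]] <- hits
  }
  if (length(rows) == 0) {
    return(tibble(gene_id = character(0), element = character(0),
                  class = character(0), start = integer(0), strand = character(0)))
  }
  bind_rows(rows) |> arrange(.data$gene_id, .data$start, .data$element)
}

#' Element proportions per group
#'
#' For each group (species, subfamily or orthogroup), the proportion of each
#' element relative to the total number of element hits in that group; rows
#' sum to 1 and groups with zero hits are omitted.
#'
#' @param hits Tibble from [scan_motifs()].
#' @param grouping Tibble (gene_id, group) mapping every hit gene to a group.
#' @return Wide tibble: group, then one proportion column per element.
#' @export
element_proportions <- function(hits, grouping) {
  stopifnot_cols(hits, c("gene_id", "element"))
  stopifnot_cols(grouping, c("gene_id", "group"))
  unmapped <- setdiff(unique(hits$gene_id), grouping$gene_id)
  if (length(unmapped) > 0) {
    abort(sprintf("Hit gene(s) missing from grouping: %s",
                  paste(c_sort(unmapped), collapse = ", ")))
  }
  hits |>
    inner_join(grouping, by = "gene_id") |>
    count(.data$group, .data$element) |>
    group_by(.data$group) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup() |>
    select("group", "element", "prop") |>
    tidyr::pivot_wider(names_from = "element", values_from = "prop",
                       values_fill = 0) |>
    arrange(.data$group)
}

#' Column z-scores of a matrix
#'
#' Per column, `(x - mean) / sd` with the population standard deviation;
#' constant columns become all zeros. Used for column-scaled element
#' heatmaps.
#'
#' @param mat Numeric matrix or a wide tibble whose first column is a group
#'   label (preserved) with numeric columns after it.
#' @return Object of the same shape with scaled columns.
#' @export
zscore_columns <- function(mat) {
  is_df <- is.data.frame(mat)
  if (is_df) {
    label <- mat[, 1, drop = FALSE]
    m <- as.matrix(mat[, -1, drop = FALSE])
  } else {
    m <- as.matrix(mat)
  }
  if (nrow(m) < 2) abort("Need at least 2 rows to scale columns.")
  scaled <- apply(m, 2, function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  if (is_df) bind_cols(label, as_tibble(scaled)) else {
    dimnames(scaled) <- dimnames(m)
    scaled
  }
}
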