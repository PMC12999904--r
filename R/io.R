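#' Read a FASTA file as a named character vector
#'
#' @param path Path to a FASTA file (DNA or protein).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "wb") # binary mode: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    body <- if (nchar(s) == 0) character(0) else {
      starts <- seq(1, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1, nchar(s)))
    }
    writeLines(c(paste0(">", names(seqs)[i]), body), con, sep = "\n")
  }
  invisible(path)
}

#' Read gene models from a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS features into two tidy tables: one row per gene
#' and one row per exon/CDS segment. Gene `rank` is the 1-based position of
#' the gene along its chromosome ordered by start coordinate.
#'
#' @param path Path to a GFF3 file (1-based, inclusive coordinates).
#' @param species Optional species label attached to every gene.
#' @return A list with tibbles `genes` (gene_id, species, chromosome, start,
#'   end, strand, rank) and `features` (gene_id, transcript_id, type
#'   `"exon"`/`"cds"`, start, end).
#' @export
read_gff_models <- function(path, species = NA_character_) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  first_parent <- function(p) vapply(p, function(v) if (length(v)) v[[1]] else NA_character_, "")
  genes <- g[g$type == "gene", , drop = FALSE]
  genes_tb <- tibble(
    gene_id = as.character(genes$ID),
    species = species,
    chromosome = as.character(genes$seqid),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = as.character(genes$strand)
  ) |>
    group_by(.data$chromosome) |>
    mutate(rank = rank(.data$start, ties.method = "first")) |>
    ungroup()
  mrna <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx2gene <- stats::setNames(first_parent(mrna$Parent), as.character(mrna$ID))
  feats <- g[g$type %in% c("exon", "CDS"), , drop = FALSE]
  tx <- first_parent(feats$Parent)
  features_tb <- tibble(
    gene_id = unname(tx2gene[tx]),
    transcript_id = tx,
    type = tolower(as.character(feats$type)),
    start = as.integer(feats$start),
    end = as.integer(feats$end)
  ) |>
    arrange(.data$gene_id, .data$transcript_id, .data$type, .data$start)
  list(genes = genes_tb, features = features_tb)
}

# Write simple gene/mRNA/exon/CDS models as GFF3. `models` is a list as
# returned by read_gff_models() plus a features table carrying both exon and
# cds rows per transcript.
write_gff3 <- function(genes, features, path, source = "famscape") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- genes[natural_order(genes$chromosome), , drop = FALSE]
  genes <- genes[c_order(genes$chromosome, genes$start), , drop = FALSE]
  fmt <- function(seqid, src, type, start, end, strand, phase, attr) {
    paste(seqid, src, type, start, end, ".", strand, phase, attr, sep = "\t")
  }
  for (i in seq_len(nrow(genes))) {
    gn <- genes[i, ]
    writeLines(fmt(gn$chromosome, source, "gene", gn$start, gn$end, gn$strand,
                   ".", paste0("ID=", gn$gene_id)), con)
    fx <- features[features$gene_id == gn$gene_id, , drop = FALSE]
    for (txid in unique(fx$transcript_id)) {
      txf <- fx[fx$transcript_id == txid, , drop = FALSE]
      writeLines(fmt(gn$chromosome, source, "mRNA", min(txf$start), max(txf$end),
                     gn$strand, ".",
                     paste0("ID=", txid, ";Parent=", gn$gene_id)), con)
      txf <- txf[order(txf$start), , drop = FALSE]
      for (j in seq_len(nrow(txf))) {
        ft <- txf[j, ]
        writeLines(fmt(gn$chromosome, source, ifelse(ft$type == "cds", "CDS", "exon"),
                       ft$start, ft$end, gn$strand,
                       ifelse(ft$type == "cds", "0", "."),
                       paste0("Parent=", txid)), con)
      }
    }
  }
  invisible(path)
}

#' Read an HMMER3-style domain-hit table
#'
#' Tab-separated with columns: protein_id, model_id, evalue, model_len,
#' model_from, model_to, ali_from, ali_to (the domtblout column convention
#' reduced to the fields the identification filters use).
#'
#' @param path Path to the TSV.
#' @return Tibble of domain hits.
#' @export
read_domain_hits <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    protein_id = "c", model_id = "c", evalue = "d",
                    model_len = "i", model_from = "i", model_to = "i",
                    ali_from = "i", ali_to = "i"))
}

write_tsv_file <- function(df, path) {
  readr::write_tsv(df, path, eol = "\n")
  invisible(path)
}

#' Read a homology/similarity table
#'
#' @param path TSV with columns gene_a, gene_b, score.
#' @return Tibble.
#' @export
read_homology <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene_a = "c", gene_b = "c", score = "d"))
}
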