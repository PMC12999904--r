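# Shared fixtures: synthetic datasets are expensive to build, so they are
# generated once per test run and cached here.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(seed = 7) {
  synth_config(
    n_species = 4, n_oggs = 20, chromosomes_per_species = 3,
    genes_per_chromosome = 30,
    dup_events = c(WGD = 1, TD = 1, PD = 1, TRD = 1, DSD = 1),
    n_cross_blocks = 1, seed = seed
  )
}

small_dataset <- function() {
  if (is.null(.fixtures$small)) {
    dir <- file.path(tempdir(), "famscape_small")
    .fixtures$small <- generate_dataset(small_config(), dir)
  }
  .fixtures$small
}

small_run <- function() {
  if (is.null(.fixtures$small_run)) {
    ds <- small_dataset()
    .fixtures$small_run <- suppressWarnings(
      run_pipeline(ds$dir, file.path(tempdir(), "famscape_small_out"))
    )
  }
  .fixtures$small_run
}

# the study-condition panel: 10 species, 50 OGGs, 0.3/0.5/0.2 mix
default_dataset <- function() {
  if (is.null(.fixtures$default)) {
    dir <- file.path(tempdir(), "famscape_default")
    .fixtures$default <- generate_dataset(synth_config(seed = 101), dir)
  }
  .fixtures$default
}

default_run <- function() {
  if (is.null(.fixtures$default_run)) {
    ds <- default_dataset()
    .fixtures$default_run <- suppressWarnings(
      run_pipeline(ds$dir, file.path(tempdir(), "famscape_default_out"))
    )
  }
  .fixtures$default_run
}

# canonical form of a gene partition, for id-scheme-independent comparison
partition_canon <- function(df, gene = "gene_id", group = "ogg_id") {
  unname(sort(vapply(split(df[[gene]], df[[group]]),
                     function(v) paste(sort(v), collapse = ","), "")))
}

# independent codon-difference oracle used against evolve_codon_pair/ng86
recount_codon_diffs <- function(cds_a, cds_b) {
  code <- Biostrings::GENETIC_CODE
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  diff <- which(ca != cb)
  n_pos_diff <- vapply(diff, function(i) {
    sum(strsplit(ca[[i]], "")[[1]] != strsplit(cb[[i]], "")[[1]])
  }, numeric(1))
  list(
    n_diff = length(diff),
    single_step = all(n_pos_diff == 1),
    syn = sum(code[ca[diff]] == code[cb[diff]]),
    nonsyn = sum(code[ca[diff]] != code[cb[diff]])
  )
}

motif_hit_set <- function(df) {
  df <- df[order(df$gene_id, df$start, df$element), c("gene_id", "element", "start", "strand")]
  df$start <- as.integer(df$start)
  rownames(df) <- NULL
  as.data.frame(df)
}
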