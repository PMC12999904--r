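# Promoter extraction, IUPAC scanning, proportion and z-score matrices.

toy_models <- function(strand, cds_start, cds_end, chrom_len = 5000) {
  list(
    genes = tibble::tibble(gene_id = "g", chromosome = "chr1", strand = strand),
    features = tibble::tibble(gene_id = "g", transcript_id = "g.t1",
                              type = "cds", start = cds_start, end = cds_end),
    genome = c(chr1 = paste0(sample(c("A", "C", "G", "T"), chrom_len,
                                    replace = TRUE), collapse = ""))
  )
}

test_that("extract_promoter takes the window upstream of the CDS start", {
  set.seed(5)
  m <- toy_models("+", 2500, 2800)
  pr <- extract_promoter(m$genes, m$features, m$genome)
  expect_equal(pr$actual_length, 2000)
  expect_false(pr$truncated)
  expect_identical(pr$sequence, substr(m$genome[["chr1"]], 500, 2499))

  short <- extract_promoter(toy_models("+", 1500, 1700)$genes,
                            tibble::tibble(gene_id = "g", transcript_id = "g.t1",
                                           type = "cds", start = 1500, end = 1700),
                            m$genome)
  expect_equal(short$actual_length, 1499)
  expect_true(short$truncated)

  mm <- toy_models("-", 50, 100)
  pr2 <- extract_promoter(mm$genes, mm$features, mm$genome)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(mm$genome[["chr1"]], 101, 2100))))
  expect_identical(pr2$sequence, rc)
  expect_false(pr2$truncated)
  expect_error(
    extract_promoter(m$genes, m$features[0, ], m$genome),
    "no CDS"
  )
})

mklib <- function(el, cons, cl = "stress") {
  tibble::tibble(element = el, consensus = cons, class = cl)
}

test_that("scanning finds overlapping IUPAC matches on both strands", {
  pr <- tibble::tibble(gene_id = "g", sequence = "AAACGTGAA")
  h <- scan_motifs(pr, mklib("ACGTG-el", "ACGTG"))
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 3)
  expect_equal(h$strand, "+")

  # minus-strand hit reported at plus-strand window start
  h2 <- scan_motifs(tibble::tibble(gene_id = "g", sequence = "AACACGTAA"),
                    mklib("ACGTG-el", "ACGTG"))
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 3)

  # palindromic consensus collapses to one hit
  h3 <- scan_motifs(tibble::tibble(gene_id = "g", sequence = "TCACGTGA"),
                    mklib("G-box", "CACGTG"))
  expect_equal(nrow(h3), 1)
  expect_equal(h3$strand, "+")

  # N in the promoter never matches
  h4 <- scan_motifs(tibble::tibble(gene_id = "g", sequence = "AANCGTGAA"),
                    mklib("ACGTG-el", "ACGTG"))
  expect_equal(nrow(h4), 0)

  # overlapping matches all reported
  h5 <- scan_motifs(tibble::tibble(gene_id = "g", sequence = "AGGGGG"),
                    mklib("STRE", "AGGGG"))
  expect_equal(nrow(h5), 1) # plus strand once; overlapping AGGGG at 1 only
  h6 <- scan_motifs(tibble::tibble(gene_id = "g", sequence = "ATATATA"),
                    mklib("AT", "ATA"))
  expect_equal(sum(h6$strand == "+"), 3)
  expect_equal(nrow(scan_motifs(tibble::tibble(gene_id = "g", sequence = ""),
                                mklib("x", "ACGT"))), 0)
})

test_that("reverse-complementing a promoter mirrors the hit set", {
  ds <- small_dataset()
  pr <- read_fasta(ds$files$promoters)[1]
  lib <- default_motif_library()
  fwd <- scan_motifs(tibble::tibble(gene_id = "g", sequence = unname(pr)), lib)
  rc_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pr[[1]])))
  rev <- scan_motifs(tibble::tibble(gene_id = "g", sequence = rc_seq), lib)
  expect_equal(nrow(fwd), nrow(rev))
  len <- nchar(pr[[1]])
  mirrored <- sort(len - (rev$start + nchar(
    lib$consensus[match(rev$element, lib$element)]) - 1) + 1)
  expect_equal(sort(fwd$start), mirrored)
})

test_that("planted motif instances are recovered with no false positives", {
  ds <- small_dataset()
  pr <- read_fasta(ds$files$promoters)
  hits <- scan_motifs(tibble::tibble(gene_id = names(pr), sequence = unname(pr)))
  expect_identical(motif_hit_set(hits), motif_hit_set(ds$truth$motifs))
})

test_that("element proportions sum to one per group", {
  hits <- tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g2"),
    element = c("A", "A", "A", "B")
  )
  grouping <- tibble::tibble(gene_id = c("g1", "g2"), group = "G")
  m <- element_proportions(hits, grouping)
  expect_equal(m$A, 0.75)
  expect_equal(m$B, 0.25)
  expect_equal(rowSums(m[, -1]), 1, ignore_attr = TRUE)
  expect_error(element_proportions(hits, grouping[1, ]), "missing from grouping")
})

test_that("column z-scores use the population sd and handle constants", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), ncol = 2,
              dimnames = list(NULL, c("v", "const")))
  z <- zscore_columns(m)
  expect_equal(z[, "v"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(unname(z[1, "v"]), -1.2247, tolerance = 1e-4)
  expect_equal(z[, "const"], rep(0, 3), ignore_attr = TRUE)
  expect_equal(zscore_columns(z), z) # idempotent
  expect_error(zscore_columns(m[1, , drop = FALSE]), "at least 2 rows")
})
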