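# Identification filters, isoform selection, and positional renaming.

mk_hits <- function(...) {
  dplyr::bind_rows(...)
}
hit <- function(id, e = 1e-20, from = 1, to = 260, len = 260) {
  tibble::tibble(protein_id = id, model_id = "PF00069", evalue = e,
                 model_len = len, model_from = from, model_to = to,
                 ali_from = 1L, ali_to = to)
}
prot <- function(ids, len) tibble::tibble(protein_id = ids, length = len)

test_that("filter_candidates applies E-value, length and completeness filters", {
  hits <- mk_hits(hit("weak", e = 1e-5), hit("short"), hit("good"),
                  hit("partial", to = 130))
  proteins <- prot(c("weak", "short", "good", "partial"), c(300, 90, 300, 300))
  acc <- filter_candidates(hits, proteins)
  expect_identical(acc$protein_id, "good")
  # relaxing the cutoff admits the weak hit but never drops an accepted id
  acc2 <- filter_candidates(hits, proteins, evalue_cutoff = 1e-4)
  expect_true(all(acc$protein_id %in% acc2$protein_id))
  expect_true("weak" %in% acc2$protein_id)
})

test_that("filter_candidates is monotone in the E-value cutoff", {
  set.seed(42)
  hits <- dplyr::bind_rows(lapply(1:30, function(i) {
    hit(paste0("p", i), e = 10^-runif(1, 2, 30), to = sample(100:260, 1))
  }))
  proteins <- prot(paste0("p", 1:30), sample(80:400, 30, replace = TRUE))
  cuts <- 10^-c(20, 15, 10, 5)
  prev <- character(0)
  for (ct in cuts) {
    cur <- filter_candidates(hits, proteins, evalue_cutoff = ct)$protein_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("filter_candidates names unknown proteins in its error", {
  expect_error(filter_candidates(hit("ghost"), prot("other", 300)), "ghost")
})

test_that("longest_isoform keeps the greatest CDS sum, ties to smallest id", {
  fx <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    transcript_id = c("a1", "a2", "t2", "t10", "solo"),
    type = "cds",
    start = c(1, 1, 1, 101, 1),
    end = c(300, 500, 400, 500, 99)
  )
  kept <- longest_isoform(fx)
  expect_setequal(unique(kept$transcript_id[kept$gene_id == "g1"]), "a2")
  # tie at 400: "t10" < "t2" in C locale
  expect_setequal(unique(kept$transcript_id[kept$gene_id == "g2"]), "t10")
  expect_setequal(unique(kept$transcript_id[kept$gene_id == "g3"]), "solo")
  expect_error(longest_isoform(tibble::tibble(
    gene_id = "gx", transcript_id = "t", type = "exon", start = 1, end = 10
  )), "without any CDS")
})

test_that("rename_by_position orders naturally and is a bijection", {
  g <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    chromosome = c("chr10", "chr2", "chr1", "chr1"),
    start = c(5, 50, 900, 100)
  )
  out <- rename_by_position(g, "Hann_MAPKKK")
  expect_identical(out$gene_id, c("d", "c", "b", "a")) # chr1 < chr2 < chr10
  expect_identical(out$family_name, paste0("Hann_MAPKKK", 1:4))
  expect_equal(anyDuplicated(out$family_name), 0)
  # idempotence: renaming the renamed set reproduces the names
  again <- rename_by_position(out, "Hann_MAPKKK")
  expect_identical(again$family_name, out$family_name)
  expect_identical(rename_by_position(g[0, ], "x")$family_name, character(0))
  expect_error(rename_by_position(dplyr::bind_rows(g, g[1, ]), "x"), "Duplicate")
})

test_that("zero-padding width follows the family size", {
  g <- tibble::tibble(gene_id = paste0("g", 1:12), chromosome = "chr1",
                      start = 1:12 * 100)
  out <- rename_by_position(g, "X")
  expect_identical(out$family_name[1], "X01")
  expect_identical(out$family_name[12], "X12")
})

test_that("identification recovers the planted family roster exactly", {
  ds <- small_dataset()
  run <- small_run()
  roster <- run$results$identification$roster
  expect_setequal(roster$gene_id, ds$truth$roster$gene_id)
  expect_false(any(ds$truth$violators$gene_id %in% roster$gene_id))
  # retained transcripts match the planted longest isoforms
  retained <- run$results$identification$retained |>
    dplyr::distinct(gene_id, transcript_id)
  truth_tx <- ds$truth$retained_tx[
    ds$truth$retained_tx$gene_id %in% roster$gene_id, ]
  merged <- dplyr::inner_join(retained, truth_tx, by = "gene_id",
                              suffix = c("", ".truth"))
  expect_equal(nrow(merged), nrow(truth_tx))
  expect_true(all(merged$transcript_id == merged$transcript_id.truth))
})
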