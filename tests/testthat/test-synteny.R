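# Collinear block chaining, duplication-mode priority, synteny/conservation.

diag_anchors <- function(n, chr_a = "c1", chr_b = "c2", invert = FALSE,
                         offset = 0) {
  rb <- if (invert) rev(seq_len(n)) else seq_len(n)
  tibble::tibble(
    gene_a = paste0("a", seq_len(n) + offset), chr_a = chr_a,
    rank_a = seq_len(n) + offset,
    gene_b = paste0("b", rb + offset), chr_b = chr_b, rank_b = rb + offset
  )
}

test_that("a clean diagonal of 12 anchors yields one same-orientation block", {
  b <- chain_anchors(diag_anchors(12))
  expect_equal(nrow(b), 1)
  expect_equal(b$orientation, "same")
  expect_equal(b$n_anchors, 12)
  expect_identical(b$anchors[[1]]$gene_a, paste0("a", 1:12))
})

test_that("nine anchors are below the minimum block size", {
  expect_equal(nrow(chain_anchors(diag_anchors(9))), 0)
})

test_that("an anti-diagonal of 10 anchors forms an inverted block", {
  b <- chain_anchors(diag_anchors(10, invert = TRUE))
  expect_equal(nrow(b), 1)
  expect_equal(b$orientation, "inverted")
  expect_equal(b$n_anchors, 10)
  # side-B ranks strictly decreasing along the chain
  expect_true(all(diff(b$anchors[[1]]$rank_b) < 0))
})

test_that("rank gaps beyond the bound break chains", {
  a <- diag_anchors(6)
  a2 <- diag_anchors(6, offset = 40) # gap of 35 > 25 between the two runs
  expect_equal(nrow(chain_anchors(dplyr::bind_rows(a, a2), min_block_size = 5)), 2)
  expect_equal(nrow(chain_anchors(dplyr::bind_rows(a, a2), min_block_size = 5,
                                  max_rank_gap = 50)), 1)
})

test_that("anchors join at most one block, greedily by length", {
  # a 15-anchor diagonal sharing its middle anchor with a 10-anchor diagonal
  long <- diag_anchors(15)
  short <- tibble::tibble(
    gene_a = "a8", chr_a = "c1", rank_a = 8,
    gene_b = paste0("x", 1), chr_b = "c2", rank_b = 100
  )
  short <- dplyr::bind_rows(short, tibble::tibble(
    gene_a = paste0("s", 2:10), chr_a = "c1", rank_a = 101:109,
    gene_b = paste0("x", 2:10), chr_b = "c2", rank_b = 101:109
  ))
  b <- chain_anchors(dplyr::bind_rows(long, short), min_block_size = 9)
  expect_equal(max(b$n_anchors), 15)
  all_a <- unlist(lapply(b$anchors, function(x) paste(x$gene_a, x$rank_a)))
  expect_equal(anyDuplicated(all_a), 0)
})

mk_roster <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6", "g7"),
    chromosome = c("c1", "c1", "c1", "c1", "c2", "c2", "c3"),
    rank = c(7, 8, 10, 20, 5, 30, 2)
  )
}

test_that("duplication modes follow the stated priority", {
  roster <- mk_roster()
  # adjacent homologs -> both TD
  calls <- classify_duplications(roster, tibble::tibble(gene_a = "g1", gene_b = "g2"))
  expect_equal(calls$mode[calls$gene_id %in% c("g1", "g2")], c("TD", "TD"))
  expect_equal(calls$mode[calls$gene_id == "g7"], "singleton")

  # rank distance 3 -> proximal
  calls2 <- classify_duplications(roster, tibble::tibble(gene_a = "g1", gene_b = "g3"))
  expect_equal(calls2$mode[calls2$gene_id == "g1"], "PD")

  # block anchors win over adjacency
  blk <- chain_anchors(tibble::tibble(
    gene_a = c("g1", paste0("f", 2:10)), chr_a = "c1",
    rank_a = c(7, 31:39),
    gene_b = c("g2", paste0("h", 2:10)), chr_b = "c1b",
    rank_b = c(1, 11:19)
  ), min_block_size = 10, max_rank_gap = 25)
  roster_blk <- dplyr::bind_rows(
    mk_roster(),
    tibble::tibble(gene_id = c(paste0("f", 2:10), paste0("h", 2:10)),
                   chromosome = "c1", rank = 100 + 1:18)
  )
  calls3 <- classify_duplications(roster_blk,
                                  tibble::tibble(gene_a = "g1", gene_b = "g2"),
                                  intra_blocks = blk)
  expect_equal(calls3$mode[calls3$gene_id == "g1"], "WGD")
  expect_equal(calls3$mode[calls3$gene_id == "g2"], "WGD")

  # transposed: only the partner holds the ancestral (outgroup-syntenic) locus
  og_blk <- chain_anchors(tibble::tibble(
    gene_a = c("g5", paste0("f", 2:10)), chr_a = "c2", rank_a = c(5, 6:14),
    gene_b = paste0("o", 1:10), chr_b = "oc1", rank_b = 1:10
  ), min_block_size = 10)
  calls4 <- classify_duplications(roster, tibble::tibble(gene_a = "g5", gene_b = "g6"),
                                  outgroup_blocks = og_blk)
  expect_equal(calls4$mode[calls4$gene_id == "g6"], "TRD")
  expect_equal(calls4$mode[calls4$gene_id == "g5"], "DSD") # ancestral copy
  # distant homologs with no synteny context -> dispersed
  calls5 <- classify_duplications(roster, tibble::tibble(gene_a = "g1", gene_b = "g5"))
  expect_equal(sort(calls5$mode[calls5$gene_id %in% c("g1", "g5")]), c("DSD", "DSD"))
  expect_error(
    classify_duplications(roster, tibble::tibble(gene_a = "g1", gene_b = "nope")),
    "absent from annotation"
  )
})

test_that("modes partition the roster exhaustively", {
  run <- small_run()
  calls <- run$results$duplication$calls
  roster <- run$results$identification$roster
  expect_setequal(calls$gene_id, roster$gene_id)
  expect_equal(anyDuplicated(calls$gene_id), 0)
})

test_that("planted blocks and duplication modes are recovered exactly", {
  ds <- small_dataset()
  run <- small_run()
  calls <- dplyr::inner_join(run$results$duplication$calls, ds$truth$dup_mode,
                             by = "gene_id", suffix = c(".got", ".true"))
  expect_equal(nrow(calls), nrow(ds$truth$dup_mode))
  expect_true(all(calls$mode.got == calls$mode.true))
  rec <- dplyr::bind_rows(
    tidyr::unnest(run$results$duplication$intra_blocks, "anchors"),
    tidyr::unnest(run$results$duplication$cross_blocks, "anchors"),
    tidyr::unnest(run$results$duplication$outgroup_blocks, "anchors")
  )
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  planted <- ds$truth$blocks
  expect_true(all(key(planted$gene_a, planted$gene_b) %in%
                    key(rec$gene_a, rec$gene_b)))
})

test_that("synteny conservation percentages count anchored genes", {
  blk <- chain_anchors(diag_anchors(10))
  blk$species_a <- "spA"; blk$species_b <- "spB"
  cats_all <- tibble::tibble(gene_id = c(paste0("a", 1:10), paste0("b", 1:10)),
                             category = "conserved")
  t1 <- synteny_conservation_table(blk, cats_all)
  expect_equal(t1$pct_conserved, 100)
  mixed <- tibble::tibble(gene_id = c("a1", "b1", "a2", "b2"),
                          category = c("conserved", "conserved", "rare", "rare"))
  t2 <- synteny_conservation_table(blk, mixed)
  expect_equal(c(t2$pct_conserved, t2$pct_variable, t2$pct_rare), c(50, 0, 50))
  t3 <- synteny_conservation_table(chain_anchors(diag_anchors(3)), mixed)
  expect_equal(nrow(t3), 0)
})
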