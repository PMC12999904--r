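# RBH orthogroup construction and conserved/variable/rare classification.

test_that("mutual best hits across three species form one orthogroup", {
  genes <- tibble::tibble(gene_id = c("a1", "b1", "c1"),
                          species = c("A", "B", "C"))
  hom <- tibble::tibble(gene_a = c("a1", "a1", "b1"),
                        gene_b = c("b1", "c1", "c1"),
                        score = c(95, 94, 93))
  m <- build_oggs(hom, genes)
  expect_equal(dplyr::n_distinct(m$ogg_id), 1)
})

test_that("non-mutual best hits leave genes separate", {
  # a1's best is b1, but b1's best is b-side partner c1 and vice versa
  genes <- tibble::tibble(gene_id = c("a1", "b1", "c1"),
                          species = c("A", "B", "C"))
  hom <- tibble::tibble(gene_a = c("a1", "b1"),
                        gene_b = c("b1", "c1"),
                        score = c(50, 95))
  m <- build_oggs(hom, genes)
  # b1-c1 mutual; a1's edge to b1 is mutual too (it is b1's only A partner)
  expect_equal(dplyr::n_distinct(m$ogg_id), 1)
  hom2 <- tibble::tibble(gene_a = c("a1", "a2", "b1"),
                         gene_b = c("b1", "b1", "c1"),
                         score = c(50, 90, 95))
  genes2 <- dplyr::bind_rows(genes, tibble::tibble(gene_id = "a2", species = "A"))
  m2 <- build_oggs(hom2, genes2)
  # b1's best in A is a2, so a1 has no mutual edge and stays a singleton
  a1_ogg <- m2$ogg_id[m2$gene_id == "a1"]
  expect_equal(sum(m2$ogg_id == a1_ogg), 1)
})

test_that("no cross-species hits gives all singletons; self-pairs warn", {
  genes <- tibble::tibble(gene_id = c("a1", "a2", "b1"),
                          species = c("A", "A", "B"))
  m <- build_oggs(tibble::tibble(gene_a = "a1", gene_b = "a2", score = 99), genes)
  expect_equal(dplyr::n_distinct(m$ogg_id), 3)
  expect_warning(
    build_oggs(tibble::tibble(gene_a = "a1", gene_b = "a1", score = 9), genes),
    "self-pair"
  )
})

test_that("classify_ogg applies the presence-width rules", {
  expect_equal(classify_ogg(rep(1, 10), 10), "conserved")
  expect_equal(classify_ogg(c(rep(1, 9), 0), 10), "variable")
  expect_equal(classify_ogg(c(rep(1, 3), rep(0, 7)), 10), "rare")
  expect_equal(classify_ogg(c(2, 0, 3), 3), "variable") # copy number > presence
  expect_error(classify_ogg(c(1, 1), 3), "length")
  expect_error(classify_ogg(c(0, 0, 0), 3), "no species")
})

test_that("category proportions use half-up rounding to two decimals", {
  expect_equal(category_proportions(296, 1009), 29.34)
  expect_equal(category_proportions(495, 1009), 49.06)
  expect_equal(category_proportions(0, 1009), 0)
  expect_equal(category_proportions(c(1, 1), 16), c(6.25, 6.25))
  expect_error(category_proportions(c(500, 600), 1000), "exceed")
})

test_that("orthogroups partition the roster", {
  run <- small_run()
  m <- run$results$orthogroups$membership
  roster <- run$results$identification$roster
  expect_setequal(m$gene_id, roster$gene_id)
  expect_equal(anyDuplicated(m$gene_id), 0)
  cats <- run$results$orthogroups$categories
  expect_true(all(cats$category %in% c("conserved", "variable", "rare")))
})

test_that("planted orthogroup membership and categories are recovered", {
  ds <- small_dataset()
  run <- small_run()
  got <- run$results$orthogroups$membership
  expect_identical(partition_canon(got), partition_canon(ds$truth$membership))
  map_ogg <- dplyr::inner_join(got, ds$truth$membership, by = "gene_id",
                               suffix = c("", ".t")) |>
    dplyr::distinct(ogg_id, ogg_id.t)
  cmp <- run$results$orthogroups$categories |>
    dplyr::inner_join(map_ogg, by = "ogg_id") |>
    dplyr::inner_join(ds$truth$ogg_info[, c("ogg_id", "category")],
                      by = c("ogg_id.t" = "ogg_id"), suffix = c(".got", ".true"))
  expect_equal(nrow(cmp), nrow(ds$truth$ogg_info))
  expect_true(all(cmp$category.got == cmp$category.true))
})
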