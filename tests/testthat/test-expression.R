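# FPKM, the fold-change screen, ddCt analysis, and row scaling.

test_that("fpkm follows the closed form and is linear in counts", {
  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 1000, 1e6), 0)
  expect_equal(fpkm(3, 1500, 2e6), 1)
  set.seed(2)
  for (i in 1:20) {
    cnt <- runif(1, 1, 1000); len <- runif(1, 200, 5000); tot <- runif(1, 1e6, 5e7)
    expect_equal(fpkm(2 * cnt, len, tot), 2 * fpkm(cnt, len, tot))
    expect_equal(fpkm(cnt, 2 * len, tot), fpkm(cnt, len, tot) / 2)
    expect_equal(fpkm(cnt, len, 2 * tot), fpkm(cnt, len, tot) / 2)
  }
  expect_error(fpkm(-1, 10, 10), ">= 0")
})

test_that("de_screen applies the strict |log2FC| > 1 rule", {
  expr <- tibble::tibble(gene_id = c("up", "flat", "edge"),
                         treated = c(8, 5, 3), control = c(2, 5, 1))
  de <- de_screen(expr)
  expect_equal(de$log2fc[de$gene_id == "up"], log2(9 / 3), tolerance = 1e-12)
  expect_true(de$responsive[de$gene_id == "up"])
  expect_equal(de$log2fc[de$gene_id == "flat"], 0)
  expect_false(de$responsive[de$gene_id == "flat"])
  expect_equal(de$log2fc[de$gene_id == "edge"], 1) # exactly 1 -> not responsive
  expect_false(de$responsive[de$gene_id == "edge"])
})

qrec <- function(gene, tp, reps_dct, ct_ref = 20) {
  tibble::tibble(
    gene_id = gene, condition = "salt", timepoint = tp,
    replicate = seq_along(reps_dct),
    ct_target = ct_ref + reps_dct, ct_reference = ct_ref
  )
}

test_that("ddct computes 2^-ddCt folds against the 0 h control", {
  rec <- dplyr::bind_rows(qrec("g", 0, c(5, 5, 5)), qrec("g", 6, c(3, 3, 3)))
  out <- ddct(rec)
  expect_equal(out$fold_mean[out$timepoint == 6], 4) # ddCt = -2
  expect_equal(out$fold_mean[out$timepoint == 0], 1)
  expect_equal(out$fold_sd[out$timepoint == 6], 0)
  expect_error(ddct(qrec("g", 6, c(3, 3))), "Missing control")
})

test_that("control against itself gives fold one for generated qPCR data", {
  ds <- small_dataset()
  qp <- readr::read_tsv(ds$files$qpcr, show_col_types = FALSE)
  folds <- ddct(qp)
  ctrl <- folds[folds$timepoint == 0, ]
  expect_equal(ctrl$fold_mean, rep(1, nrow(ctrl)), tolerance = 0.02)
})

test_that("letter groups share letters exactly when Tukey finds no difference", {
  same <- dplyr::bind_rows(qrec("g", 0, c(5, 5, 5)), qrec("g", 6, c(5, 5, 5)))
  lf <- ddct(same) |> dplyr::select(timepoint, fold = fold_mean)
  all_same <- letter_groups(tibble::tibble(
    timepoint = rep(c(0, 6), each = 3), fold = rep(1, 6)
  ))
  expect_true(all(all_same$letters == "a"))

  set.seed(9)
  sep <- tibble::tibble(
    timepoint = rep(c(0, 24), each = 4),
    fold = c(rnorm(4, 1, 0.02), rnorm(4, 16, 0.3))
  )
  l2 <- letter_groups(sep)
  expect_setequal(l2$letters, c("a", "b"))
  expect_equal(unname(l2$letters[which.max(l2$mean_fold)]), "a") # top group first

  # middle group separable from neither extreme shares both letters
  spread <- 2^c(-0.5, 0.5, -0.25, 0.25)
  mid <- tibble::tibble(
    timepoint = rep(c(0, 6, 24), each = 4),
    fold = c(spread, spread * 1.6, spread * 2.56)
  )
  l3 <- letter_groups(mid)
  expect_identical(unname(l3$letters[l3$timepoint == "24"]), "a")
  expect_identical(unname(l3$letters[l3$timepoint == "6"]), "ab")
  expect_identical(unname(l3$letters[l3$timepoint == "0"]), "b")
  expect_error(letter_groups(tibble::tibble(timepoint = 1, fold = 1)), ">= 2 groups")
})

test_that("row scaling centres rows with the population sd", {
  m <- matrix(c(2, 4, 6, 3, 3, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  z <- row_scale(m)
  expect_equal(unname(z["g1", ]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  expect_error(row_scale(m[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("the expression screen recovers planted responsive genes exactly", {
  ds <- small_dataset()
  run <- small_run()
  de <- dplyr::inner_join(run$results$expression$de, ds$truth$expression,
                          by = "gene_id", suffix = c(".got", ".true"))
  expect_equal(nrow(de), nrow(ds$truth$expression))
  expect_identical(de$responsive.got, de$responsive.true)
})
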