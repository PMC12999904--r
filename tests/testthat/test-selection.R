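# Back-translation, the Nei-Gojobori estimator, and the two-level
# aggregation of Ka/Ks.

test_that("backtranslate substitutes codons under protein gaps", {
  out <- backtranslate("M-F", "MKF", "ATGTTT", "ATGAAATTC")
  expect_identical(unname(out["a"]), "ATG---TTT")
  expect_identical(unname(out["b"]), "ATGAAATTC")
  ident <- backtranslate("MF", "MF", "ATGTTT", "ATGTTT")
  expect_identical(unname(ident["a"]), "ATGTTT")
  expect_error(backtranslate("MF", "MF", "ATGAAA", "ATGTTT"),
               "Translation mismatch.*column 2")
})

test_that("ng86 matches hand-enumerated site and difference counts", {
  id <- ng86(c(a = "ATGGCTTTTGGG", b = "ATGGCTTTTGGG"))
  expect_equal(id$Sd, 0); expect_equal(id$ka, 0); expect_equal(id$ks, 0)
  expect_true(is.na(id$omega))

  # one synonymous third-position change; site fractions ATG:0 GCT:1 TTT:1/3 GGG:1
  x <- ng86(c(a = "ATGGCTTTTGGG", b = "ATGGCTTTCGGG"))
  expect_equal(x$S, 7 / 3, tolerance = 1e-9)
  expect_equal(x$N, 29 / 3, tolerance = 1e-9)
  expect_equal(x$Sd, 1); expect_equal(x$Nd, 0)
  expect_equal(x$ks, -0.75 * log(1 - 4 / 3 * (3 / 7)), tolerance = 1e-9)
  expect_equal(x$ka, 0); expect_equal(x$omega, 0)

  expect_equal(jc_correct(0.3), -0.75 * log(0.6), tolerance = 1e-12)
  expect_true(is.na(jc_correct(0.8)))
})

test_that("ng86 is symmetric and conserves S + N", {
  p <- evolve_codon_pair(80, 6, 9, seed = 21)
  f <- ng86(c(a = p$cds_a, b = p$cds_b))
  r <- ng86(c(a = p$cds_b, b = p$cds_a))
  expect_equal(f$S, r$S, tolerance = 1e-12)
  expect_equal(f$Sd, r$Sd, tolerance = 1e-12)
  expect_equal(f$ks, r$ks, tolerance = 1e-12)
  expect_equal(f$S + f$N, 3 * f$n_codons, tolerance = 1e-9)
  # gapped columns are excluded; all-gap alignment errors
  g <- ng86(c(a = paste0("---", p$cds_a), b = paste0("---", p$cds_b)))
  expect_equal(g$Sd, f$Sd)
  expect_error(ng86(c(a = "---", b = "---")), "gapped")
})

test_that("planted substitution counts are recovered exactly with closed-form rates", {
  for (s in c(2, 7, 15)) {
    p <- evolve_codon_pair(200, s, 2 * s, seed = 100 + s)
    est <- ng86(c(a = p$cds_a, b = p$cds_b))
    expect_equal(est$Sd, s, tolerance = 1e-12)
    expect_equal(est$Nd, 2 * s, tolerance = 1e-12)
    expect_equal(est$ks, jc_correct(s / est$S), tolerance = 1e-9)
    expect_equal(est$ka, jc_correct(2 * s / est$N), tolerance = 1e-9)
  }
})

test_that("Ks never decreases when a synonymous substitution is added", {
  prev <- -Inf
  for (s in c(0, 3, 6, 12, 24)) {
    p <- evolve_codon_pair(300, s, 5, seed = 77)
    est <- ng86(c(a = p$cds_a, b = p$cds_b))
    ks <- if (is.na(est$ks)) 0 else est$ks
    expect_gte(ks + 1e-12, prev)
    prev <- ks
  }
})

test_that("aggregate_kaks averages pairs within OGGs, then OGGs within clusters", {
  pairs <- tibble::tibble(
    gene_a = c("a", "a", "c", "e"),
    gene_b = c("b", "b2", "d", "f"),
    ka = c(0.01, 0.03, 0.02, 0.05),
    ks = c(0.1, 0.1, 0.1, 0.05),
    omega = c(0.1, 0.3, 0.2, 0.4)
  )
  membership <- tibble::tibble(
    gene_id = c("a", "b", "b2", "c", "d", "e", "f"),
    ogg_id = c("O1", "O1", "O1", "O2", "O2", "O3", "O3")
  )
  clusters <- tibble::tibble(ogg_id = c("O1", "O2", "O3"), cluster = c(1, 1, 2))
  agg <- aggregate_kaks(pairs, membership, clusters)
  expect_equal(agg$ogg$mean_omega[agg$ogg$ogg_id == "O1"], 0.2)
  # cluster 1 mean is unweighted over OGG means (0.2, 0.2), not over pairs
  expect_equal(agg$cluster$mean_omega[agg$cluster$cluster == 1], 0.2)
  expect_equal(agg$cluster$mean_omega[agg$cluster$cluster == 2], 0.4)

  und <- dplyr::mutate(pairs[3, ], omega = NA_real_)
  expect_warning(
    agg2 <- aggregate_kaks(dplyr::bind_rows(pairs[c(1, 2, 4), ], und),
                           membership, clusters),
    "no defined omega"
  )
  expect_false("O2" %in% agg2$ogg$ogg_id)
  expect_error(aggregate_kaks(pairs, membership[-1, ]), "must appear")
})
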