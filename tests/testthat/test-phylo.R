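# Alignment trimming, p-distances, neighbor joining, label propagation.

test_that("trim_alignment keeps columns at or above the gap threshold", {
  aln <- c(r1 = "A-A-A", r2 = "A-A--", r3 = "A-AA-", r4 = "A-AA-",
           r5 = "A-A--", r6 = "A-A--", r7 = "A-A--", r8 = "A-A--",
           r9 = "A-A--", r10 = "A-A--")
  # col2 all gaps -> dropped; col5 has 1/10 non-gap (< 0.2) -> dropped;
  # col4 has 2/10 (>= 0.2, boundary) -> kept
  out <- trim_alignment(aln, 0.2)
  expect_equal(nchar(out[[1]]), 3)
  expect_identical(out[["r1"]], "AA-")
  expect_identical(out[["r3"]], "AAA")
  expect_identical(out[["r4"]], "AAA")
  # idempotence
  expect_identical(trim_alignment(out, 0.2), out)
  expect_error(trim_alignment(c(a = "AA", b = "AAA")), "Ragged")
  expect_error(trim_alignment(aln, 0), "gap_threshold")
})

test_that("pairwise_distance excludes gapped columns", {
  expect_equal(pairwise_distance(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(pairwise_distance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  expect_equal(pairwise_distance(c(a = "AA--", b = "AATT"))["a", "b"], 0)
  expect_warning(
    d <- pairwise_distance(c(a = "AA--", b = "--TT", c = "AATT")),
    "distance set to 1"
  )
  expect_equal(d["a", "b"], 1)
})

test_that("neighbor joining recovers a 4-taxon additive tree exactly", {
  # unrooted tree: X-(A:1), X-(B:2), X-Y:1, Y-(C:3), Y-(D:4)
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  pd <- stats::cophenetic(tr)[rownames(d), colnames(d)]
  expect_equal(pd, d, tolerance = 1e-9)
  # A and B are sisters
  mrca_ab <- ape::getMRCA(ape::unroot(tr), c("A", "B"))
  expect_equal(length(ape::extract.clade(ape::root(tr, "D"),
                                         ape::getMRCA(ape::root(tr, "D"), c("A","B")))$tip.label), 2)
})

test_that("three taxa resolve by the closed-form star formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  pd <- stats::cophenetic(tr)[rownames(d), colnames(d)]
  expect_equal(pd, d, tolerance = 1e-12) # branches 1, 2, 3
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ reproduces additive matrices and agrees with ape::nj", {
  set.seed(11)
  for (i in 1:10) {
    tr0 <- ape::rtree(8, br = function(n) runif(n, 0.05, 1))
    d <- stats::cophenetic(tr0)
    tr <- neighbor_joining(d)
    pd <- stats::cophenetic(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(pd - d)), 1e-9)
    ref <- ape::nj(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("assign_labels propagates nearest-reference labels with id ties", {
  txt <- "((L1:0.1,R_MEKK:0.1):0.5,(L2:0.3,R_ZIK:0.1):0.2,R_RAF:0.9);"
  tr <- ape::read.tree(text = txt)
  panel <- tibble::tibble(ref_id = c("R_MEKK", "R_ZIK", "R_RAF"),
                          subfamily = c("MEKK", "ZIK", "RAF"),
                          cluster = c(1, 6, 8))
  lab <- assign_labels(tr, panel)
  expect_equal(lab$subfamily[lab$gene_id == "L1"], "MEKK")
  expect_equal(lab$subfamily[lab$gene_id == "L2"], "ZIK")
  expect_equal(lab$subfamily[lab$gene_id == "R_RAF"], "RAF") # own label
  # exact tie: leaf equidistant to two references -> smaller ref id wins
  txt2 <- "((X:1,AT1:1):1,(AT2:1,AT3:4):1);"
  tr2 <- ape::read.tree(text = txt2)
  panel2 <- tibble::tibble(ref_id = c("AT1", "AT2", "AT3"),
                           subfamily = c("MEKK", "ZIK", "RAF"),
                           cluster = c(2, 6, 9))
  # d(X, AT1) = 2; d(X, AT2) = 1+1+1 = 3; make them tie by using AT2 at 0 length
  tr2$edge.length[which(tr2$edge[, 2] == which(tr2$tip.label == "AT2"))] <- 0
  lab2 <- assign_labels(tr2, panel2)
  expect_equal(lab2$subfamily[lab2$gene_id == "X"], "MEKK") # AT1 < AT2
  expect_error(assign_labels(tr2, panel2[1:2, ]), "lacks subfamily")
})

test_that("planted subfamily and cluster labels are recovered on synthetic data", {
  ds <- small_dataset()
  run <- small_run()
  lab <- run$results$classification$labels |>
    dplyr::inner_join(ds$truth$roster[, c("gene_id", "subfamily", "cluster")],
                      by = "gene_id", suffix = c(".got", ".true"))
  expect_gte(mean(lab$subfamily.got == lab$subfamily.true), 0.95)
  expect_gte(mean(lab$cluster.got == lab$cluster.true), 0.95)
})
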