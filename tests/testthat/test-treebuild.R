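test_that("three-taxon NJ solves the three-point equations exactly", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  x <- ape::cophenetic.phylo(tr)
  expect_equal(x[rownames(d), colnames(d)], d, tolerance = 1e-10)
  el <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("a", "b", "c")]), c(1, 2, 3), tolerance = 1e-10)
})

test_that("NJ is consistent on additive matrices", {
  for (i in 1:50) {
    n <- sample(4:8, 1)
    tr <- random_tree(n, seed = 1000 + i)
    d <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(d)
    expect_equal(robinson_foulds(est, tr), 0)
  }
})

test_that("non-symmetric matrices are rejected and negatives clamped", {
  d <- matrix(runif(16), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(neighbor_joining(d), "symmetric")
  # near-degenerate matrices must still give non-negative branch lengths
  for (i in 1:20) {
    tr <- random_tree(6, seed = 2000 + i)
    d <- ape::cophenetic.phylo(tr)
    noisy <- d + matrix(runif(36, 0, 0.02), 6, 6)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    est <- neighbor_joining(noisy)
    expect_true(all(est$edge.length >= 0))
  }
})

test_that("bootstrap support annotates point-tree edges in [0, 100]", {
  sim <- small_sim(seed = 21)
  bs <- bootstrap_support(sim$sm, n_reps = 30, seed = 2)
  sup <- suppressWarnings(as.numeric(bs$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # strong simulated signal: the true clades should be near-unanimous
  expect_gt(mean(sup), 90)
  # point tree topology equals the plain backend tree
  expect_equal(robinson_foulds(bs, nj_backend(sim$sm)), 0)
  # determinism
  bs2 <- bootstrap_support(sim$sm, n_reps = 30, seed = 2)
  expect_identical(ape::write.tree(bs2), ape::write.tree(bs))
})

test_that("a single self-replicate gives unanimous support", {
  sim <- small_sim(seed = 22)
  # n_reps = 1 on strong data: the replicate recovers the point topology
  bs <- bootstrap_support(sim$sm, n_reps = 1, seed = 3)
  sup <- suppressWarnings(as.numeric(bs$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
})

test_that("the generic backend path honours the backend contract", {
  sim <- small_sim(seed = 23, n_taxa = 6, gene_length = 150)
  backend <- function(sm) nj_backend(sm, model = "p")
  bs <- bootstrap_support(sim$sm, n_reps = 10, backend = backend, seed = 4)
  expect_s3_class(bs, "phylo")
  expect_setequal(bs$tip.label, sim$sm$taxa)
  sup <- suppressWarnings(as.numeric(bs$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
})

test_that("majority-rule consensus counts splits and keeps all compatible groups", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_identical(
    sort(phyloHET:::split_keys(majority_rule_consensus(list(t1, t1, t1)),
                               sort(t1$tip.label))),
    sort(phyloHET:::split_keys(t1, sort(t1$tip.label))))
  cons <- majority_rule_consensus(list(t1, t1, t1))
  sup <- suppressWarnings(as.numeric(cons$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  t2 <- ape::read.tree(text = "((A,B),(D,(C,E)));")
  t3 <- ape::read.tree(text = "((A,C),(E,(B,D)));")
  cons2 <- majority_rule_consensus(list(t1, t2, t3), extended = FALSE)
  ss <- phyloHET:::splits_with_support(cons2, sort(t1$tip.label))
  # {A,B} (= side {C,D,E}) appears in 2 of 3 trees
  expect_equal(ss$support[ss$key == "3,4,5"], 66.7, tolerance = 0.05)
  expect_error(majority_rule_consensus(list(t1, ape::rtree(4))), "leaf sets")
})

test_that("extended consensus equals the brute-force oracle", {
  for (i in 1:30) {
    trees <- lapply(1:7, function(k) random_tree(6, seed = 100 * i + k))
    cons <- majority_rule_consensus(trees, extended = TRUE)
    expect_setequal(oracle_tree_splits(cons),
                    oracle_consensus_splits(trees, extended = TRUE)$split)
  }
})

test_that("Robinson-Foulds distance matches its definition and phangorn", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)
  for (i in 1:25) {
    a <- random_tree(7, seed = 3000 + i)
    b <- random_tree(7, seed = 4000 + i)
    rf <- robinson_foulds(a, b)
    expect_equal(rf, robinson_foulds(b, a))
    expect_equal(rf, as.numeric(phangorn::RF.dist(a, b)))
  }
  expect_error(robinson_foulds(t1, ape::rtree(5)), "leaf sets")
})
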