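test_that("clone collapse keeps unique variants with multiplicities", {
  clone <- strsplit("ACGTACGT", "")[[1]]
  mat12 <- matrix(rep(clone, 12), nrow = 12, byrow = TRUE)
  cc <- collapse_clones(mat12)
  expect_equal(nrow(cc$variants), 1L)
  expect_equal(cc$multiplicity, 12L)

  other <- clone
  other[c(2, 5)] <- c("T", "G")
  mat2 <- rbind(mat12[1:6, ], matrix(rep(other, 6), nrow = 6, byrow = TRUE))
  cc2 <- collapse_clones(mat2)
  expect_equal(nrow(cc2$variants), 2L)
  expect_equal(cc2$multiplicity, c(6L, 6L))

  third <- clone
  third[8] <- "A"
  expect_warning(cc3 <- collapse_clones(rbind(mat2, matrix(third, nrow = 1))),
                 "variants")
  expect_equal(nrow(cc3$variants), 3L)

  # idempotence
  expect_equal(collapse_clones(cc2$variants)$variants, cc2$variants)
})

test_that("a query identical to a reference taxon places as its sister", {
  sim <- small_sim(seed = 71)
  target <- sim$sm$taxa[3]
  q <- lapply(sim$aln[1:2], function(g) g$mat[target, ])
  names(q) <- names(sim$aln)[1:2]
  pl <- place_query(sim$sm, q, names(q), query_id = "Q",
                    config = placement_config(n_boot = 30, seed = 2,
                                              root = sim$sm$taxa[1]))
  expect_identical(pl$lineage, target)
  expect_equal(pl$support, 100)
  expect_true(pl$conclusive)
  expect_error(place_query(sim$sm, stats::setNames(
    list(rep("?", 400)), names(sim$aln)[1]), names(sim$aln)[1]),
    "all-missing")
})

test_that("parent assignment recovers both donors of a synthetic F1", {
  sim <- small_sim(seed = 72)
  tips <- sim$tree$tip.label
  parents <- phyloHET:::choose_f1_parents(sim$tree, 0.05, seed = 1)
  ev <- hybrid_event("HYB", parents[1], parents[2], mode = "F1")
  inj <- inject_hybrid(sim$aln, sim$tree, ev, seed = 2)
  mito <- list()
  for (g in names(inj$alignments)) {
    a <- inj$alignments[[g]]
    if (a$genome == "mito") mito[[g]] <- a$mat["HYB", ]
  }
  cs <- clone_set("HYB", mito = mito,
                  nuclear = list(nuc1 = inj$clones[["nuc1"]]))
  pc <- placement_config(n_boot = 40, seed = 3,
                         root = setdiff(tips, parents)[1])
  pa <- assign_parents(cs, sim$sm, pc)
  expect_identical(pa$maternal$lineage, parents[1])
  expect_identical(pa$paternal$lineage, parents[2])
  expect_equal(nrow(pa$clone_placements), 2L)

  # symmetry: swapping the designated parents swaps the assignment
  ev2 <- hybrid_event("HYB", parents[2], parents[1], mode = "F1")
  inj2 <- inject_hybrid(sim$aln, sim$tree, ev2, seed = 2)
  mito2 <- list()
  for (g in names(inj2$alignments)) {
    a <- inj2$alignments[[g]]
    if (a$genome == "mito") mito2[[g]] <- a$mat["HYB", ]
  }
  cs2 <- clone_set("HYB", mito = mito2,
                   nuclear = list(nuc1 = inj2$clones[["nuc1"]]))
  pa2 <- assign_parents(cs2, sim$sm, pc)
  expect_identical(pa2$maternal$lineage, parents[2])
  expect_identical(pa2$paternal$lineage, parents[1])
})

test_that("a hybrid without mito data has an undetermined mother", {
  sim <- small_sim(seed = 73)
  cs <- clone_set("HYB", mito = list(),
                  nuclear = list(nuc1 = sim$aln[[1]]$mat[1:2, ]))
  pa <- assign_parents(cs, sim$sm,
                       placement_config(n_boot = 10, seed = 1,
                                        root = sim$sm$taxa[1]))
  expect_identical(pa$maternal$lineage, "undetermined")
  expect_false(pa$maternal$conclusive)
})

test_that("the recombination scan flags constructed chimeras only", {
  phyloHET:::with_seed(8, {
    L <- 400
    a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    b <- a
    flip <- sample(L, 60)  # 15% divergence between parents
    b[flip] <- vapply(a[flip], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    sc <- recombination_scan(a, a, b)
    expect_false(sc$mosaic)
    expect_true(all(sc$windows$winner %in% "A" | is.na(sc$windows$winner)))

    chimera <- c(a[1:200], b[201:400])
    sc2 <- recombination_scan(chimera, a, b)
    expect_true(sc2$mosaic)
    first_b <- min(sc2$windows$start[sc2$windows$winner %in% "B"])
    expect_gt(first_b, 100)  # breakpoint region, not the pure-A start
    expect_true(all(sc2$windows$winner[sc2$windows$end <= 200] %in% "A"))

    sc3 <- recombination_scan(a, b, b)
    expect_false(sc3$mosaic)
    expect_true(all(is.na(sc3$windows$winner)))
    expect_error(recombination_scan(a, a, b, window = 1000), "window")
  })
})
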