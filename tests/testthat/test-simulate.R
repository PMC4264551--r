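test_that("pure-birth trees have the right shape and are seeded", {
  tr <- simulate_species_tree(sim_spec(n_taxa = 4, seed = 1))
  expect_equal(length(tr$tip.label), 4L)
  expect_equal(tr$Nnode, 3L)
  expect_true(ape::is.binary(tr) && ape::is.rooted(tr))

  tr41 <- simulate_species_tree(sim_spec(n_taxa = 41, seed = 7))
  expect_equal(length(tr41$tip.label), 41L)
  expect_equal(tr41$Nnode, 40L)
  expect_setequal(tr41$tip.label, sprintf("T%02d", 1:41))

  a <- simulate_species_tree(sim_spec(n_taxa = 10, seed = 3))
  b <- simulate_species_tree(sim_spec(n_taxa = 10, seed = 3))
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_error(sim_spec(n_taxa = 3), "n_taxa")
})

test_that("alignment simulation is deterministic and respects dimensions", {
  spec <- sim_spec(n_taxa = 6, n_nuclear_genes = 7, n_mito_genes = 1,
                   gene_length = 954, seed = 5)
  tree <- simulate_species_tree(spec)
  a1 <- simulate_alignments(tree, spec)
  a2 <- simulate_alignments(tree, spec)
  expect_identical(a1, a2)
  genomes <- vapply(a1, `[[`, character(1), "genome")
  nuc <- concatenate(a1[genomes == "nuclear"])
  # seven genes of 954 bp: a 6,678 bp nuclear supermatrix (study scale)
  expect_equal(ncol(nuc$mat), 6678L)
  expect_equal(sum(genomes == "mito"), 1L)
})

test_that("zero branch lengths give identical sequences", {
  spec <- sim_spec(n_taxa = 5, n_nuclear_genes = 1, n_mito_genes = 0,
                   gene_length = 100, seed = 2)
  tree <- simulate_species_tree(spec)
  tree$edge.length[] <- 0
  aln <- simulate_alignments(tree, spec)[[1]]
  expect_equal(nrow(unique(aln$mat)), 1L)
})

test_that("pairwise divergence follows the JC69 expectation", {
  tree <- ape::read.tree(text = "(x:0.05,y:0.05);")
  spec <- sim_spec(n_taxa = 4, n_nuclear_genes = 1, n_mito_genes = 0,
                   gene_length = 10000, seed = 8)
  aln <- simulate_alignments(tree, spec)[[1]]
  p_obs <- mean(aln$mat["x", ] != aln$mat["y", ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("mosaic hybrids copy the recorded donor at each locus", {
  sim <- small_sim(seed = 31)
  tips <- sim$tree$tip.label
  ev <- hybrid_event("HYB", tips[1], tips[4], maternal_locus_fraction = 0.5,
                     mode = "mosaic", post_hybrid_branch = 0)
  inj <- inject_hybrid(sim$aln, sim$tree, ev, seed = 6)
  for (g in names(inj$alignments)) {
    a <- inj$alignments[[g]]
    expect_equal(nrow(a$mat), nrow(sim$aln[[g]]$mat) + 1L)
    expect_equal(ncol(a$mat), ncol(sim$aln[[g]]$mat))
    donor <- inj$truth$locus_donors$donor[inj$truth$locus_donors$gene == g]
    other <- setdiff(c(tips[1], tips[4]), donor)
    expect_identical(a$mat["HYB", ], a$mat[donor, ])
    expect_gt(sum(a$mat["HYB", ] != a$mat[other, ]), 0)
    if (a$genome == "mito") expect_identical(donor, tips[1])
  }
})

test_that("degenerate mosaic with full maternal fraction copies the mother", {
  sim <- small_sim(seed = 32)
  tips <- sim$tree$tip.label
  ev <- hybrid_event("HYB", tips[2], tips[5], maternal_locus_fraction = 1,
                     mode = "mosaic", post_hybrid_branch = 0)
  inj <- inject_hybrid(sim$aln, sim$tree, ev, seed = 1)
  for (a in inj$alignments) expect_identical(a$mat["HYB", ], a$mat[tips[2], ])
})

test_that("F1 hybrids emit two clones per nuclear locus and maternal mito", {
  sim <- small_sim(seed = 33)
  tips <- sim$tree$tip.label
  ev <- hybrid_event("HYB", tips[3], tips[6], mode = "F1",
                     post_hybrid_branch = 0)
  inj <- inject_hybrid(sim$aln, sim$tree, ev, seed = 2)
  genomes <- vapply(sim$aln, `[[`, character(1), "genome")
  expect_setequal(names(inj$clones), names(sim$aln)[genomes == "nuclear"])
  for (g in names(inj$clones)) {
    expect_equal(nrow(inj$clones[[g]]), 2L)
    expect_identical(inj$clones[[g]][1, ], sim$aln[[g]]$mat[tips[3], ])
    expect_identical(inj$clones[[g]][2, ], sim$aln[[g]]$mat[tips[6], ])
  }
  for (g in names(sim$aln)[genomes == "mito"]) {
    a <- inj$alignments[[g]]
    expect_identical(a$mat["HYB", ], a$mat[tips[3], ])
  }
  expect_error(inject_hybrid(sim$aln, sim$tree,
                             hybrid_event("H", "nope", tips[1])),
               "parent not in tree")
})

test_that("post-hybridisation branch adds divergence at the expected rate", {
  sim <- small_sim(seed = 34, n_nuclear = 1, n_mito = 0, gene_length = 5000)
  tips <- sim$tree$tip.label
  ev <- hybrid_event("HYB", tips[1], tips[2], maternal_locus_fraction = 1,
                     mode = "mosaic", post_hybrid_branch = 0.05)
  inj <- inject_hybrid(sim$aln, sim$tree, ev, seed = 3)
  a <- inj$alignments[[1]]
  p_obs <- mean(a$mat["HYB", ] != a$mat[tips[1], ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.05 / 3))
  expect_lt(abs(p_obs - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / 5000))
})

test_that("cytonuclear transfer regrafts a clade while conserving leaves", {
  tr <- simulate_species_tree(sim_spec(n_taxa = 8, seed = 41))
  # a small clade moved away from its sister group changes the topology
  pick <- phyloHET:::choose_transfer(tr, seed = 2, min_stem = 0)
  cherry <- pick$clade
  away <- pick$attachment
  moved <- inject_cytonuclear_transfer(tr, cherry, away)
  expect_setequal(moved$tip.label, tr$tip.label)
  expect_gt(robinson_foulds(ape::unroot(moved), ape::unroot(tr)), 0)
  expect_true(all(moved$edge.length >= 0))
  # the clade is sister to the attachment afterwards
  expect_setequal(phyloHET:::sister_lineage(moved, away), cherry)

  # regrafting a single leaf back to its current sister keeps the topology
  single <- tr$tip.label[1]
  sib <- phyloHET:::sister_lineage(tr, single)
  if (length(sib) == 1) {
    same <- inject_cytonuclear_transfer(tr, single, sib)
    expect_equal(robinson_foulds(ape::unroot(same), ape::unroot(tr)), 0)
  }
  expect_error(inject_cytonuclear_transfer(tr, c(cherry[1], away), cherry[2]),
               "monophyletic")
})
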