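test_that("the upper-fence outlier rule reproduces the worked example", {
  det <- detect_outliers(61, list(c(50, 52, 55, 57, 60)))
  expect_equal(det$q1, 52)
  expect_equal(det$q3, 57)
  expect_equal(det$fence, 64.5)
  expect_equal(det$whisker, 60)
  expect_true(det$outlier)
  # degenerate spread: IQR 0, whisker at the common value, strict inequality
  d2 <- detect_outliers(c(61, 60), matrix(60, nrow = 5, ncol = 2))
  expect_equal(d2$whisker, c(60, 60))
  expect_identical(d2$outlier, c(TRUE, FALSE))
})

test_that("nodes with too few valid null values are untestable", {
  det <- detect_outliers(c(90, 90), list(c(80, 81, 82, NA, NA, NA),
                                         c(70, 71, 72, 73, 74)))
  expect_equal(det$n_null_valid, c(3L, 5L))
  expect_identical(det$testable, c(FALSE, TRUE))
  expect_identical(det$outlier, c(FALSE, TRUE))
})

test_that("detect_outliers agrees with the sort-and-scan oracle", {
  phyloHET:::with_seed(99, {
    for (i in 1:200) {
      null <- round(runif(sample(5:40, 1), 0, 100))
      obs <- round(runif(1, 0, 100))
      det <- detect_outliers(obs, list(null))
      ora <- oracle_outlier(obs, null)
      expect_equal(det$whisker, ora$whisker)
      expect_identical(det$outlier, ora$outlier)
    }
  })
})

test_that("raising the observed support never unflags an outlier", {
  phyloHET:::with_seed(123, {
    for (i in 1:50) {
      null <- runif(20, 0, 100)
      obs <- sort(runif(2, 0, 100))
      d <- detect_outliers(obs, list(null, null))
      if (d$outlier[1]) expect_true(d$outlier[2])
    }
  })
})

test_that("focal sets are singletons plus small clades of the reference", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),((E,F),(G,H)));")
  cfg <- het_config(max_group_size = 8, n_null = 2)
  sets <- enumerate_focal_sets(tr, cfg)
  sizes <- table(lengths(sets))
  expect_equal(unname(sizes[["1"]]), 8L)   # every leaf
  expect_equal(unname(sizes[["2"]]), 4L)   # the four cherries
  expect_equal(unname(sizes[["4"]]), 2L)   # the two quartets (leave 4 taxa)
  expect_equal(length(sets), 14L)          # the 8-clade would leave too few

  singles <- enumerate_focal_sets(tr, het_config(max_group_size = 1, n_null = 2))
  expect_true(all(lengths(singles) == 1L))

  og <- enumerate_focal_sets(tr, het_config(max_group_size = 8, n_null = 2,
                                            outgroups = c("A", "B")))
  expect_false(any(vapply(og, function(s) any(c("A", "B") %in% s), logical(1))))
})

test_that("support after removal tracks restricted reference nodes", {
  sim <- small_sim(seed = 51)
  cfg <- het_config(n_boot = 30, n_null = 5, seed = 2)
  base <- support_after_removal(sim$sm, character(0), sim$tree, cfg)
  expect_true(all(base$support >= 0 & base$support <= 100, na.rm = TRUE))
  # empty removal is the baseline: strong simulated signal, high support
  expect_gt(mean(base$support), 85)
  base2 <- support_after_removal(sim$sm, character(0), sim$tree, cfg)
  expect_identical(base, base2)

  # removing one side of a cherry leaves that node undefined
  pp <- ape::prop.part(sim$tree)
  labs <- attr(pp, "labels")
  cherry <- NULL
  for (cl in pp) if (length(cl) == 2) cherry <- labs[cl]
  after <- support_after_removal(sim$sm, cherry[1], sim$tree, cfg)
  key <- after$key[grepl(cherry[2], after$clade) &
                     vapply(strsplit(after$clade, "+", fixed = TRUE), length,
                            integer(1)) == 2]
  expect_true(is.na(after$support[after$key == key][1]))
})

test_that("null draws are seeded, reproducible and focal-invariant", {
  sim <- small_sim(seed = 52)
  cfg <- het_config(n_boot = 10, n_null = 4, seed = 5)
  taxa <- sim$sm$taxa
  n1 <- build_null(sim$sm, taxa[1], sim$tree, cfg)
  n1b <- build_null(sim$sm, taxa[1], sim$tree, cfg)
  expect_identical(n1, n1b)
  expect_true(all(n1 >= 0 & n1 <= 100, na.rm = TRUE))

  # the r-th removal draw does not depend on the focal set unless the draw
  # collides with it
  cand <- taxa
  d1 <- phyloHET:::draw_null_removal(cand, 1, focal = taxa[1],
                                     seed = phyloHET:::derive_seed(5, "nullpick.1.1"))
  d2 <- phyloHET:::draw_null_removal(cand, 1, focal = taxa[2],
                                     seed = phyloHET:::derive_seed(5, "nullpick.1.1"))
  if (!(d1 %in% c(taxa[1], taxa[2]))) expect_identical(d1, d2)
  expect_error(phyloHET:::draw_null_removal(taxa[1:2], 2, focal = taxa[1],
                                            seed = 1),
               "disjoint|fewer")
})

test_that("run_het is deterministic and flags exactly the outlier records", {
  sim <- small_sim(seed = 53, n_taxa = 6, n_nuclear = 2, gene_length = 200)
  cfg <- het_config(n_boot = 10, n_null = 6, max_group_size = 2, seed = 4)
  r1 <- run_het(sim$sm, sim$tree, cfg)
  r2 <- run_het(sim$sm, sim$tree, cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$flagged,
                   r1$summary[r1$summary$outlier %in% TRUE, , drop = FALSE])
  expect_true(all(r1$summary$whisker <= r1$summary$fence, na.rm = TRUE))
  # outliers strictly exceed their whisker by definition
  expect_true(all(r1$flagged$observed > r1$flagged$whisker))
})

test_that("shared and fresh null modes agree on non-colliding replicates", {
  sim <- small_sim(seed = 54, n_taxa = 6, n_nuclear = 2, gene_length = 200)
  taxa <- sim$sm$taxa
  cfg_f <- het_config(n_boot = 10, n_null = 5, seed = 7)
  pool <- phyloHET:::shared_null_pool(
    sim$sm, phyloHET:::sm_pattern_stats(sim$sm), 1,
    phyloHET:::reference_side_matrix(sim$tree, taxa), sim$tree, cfg_f)
  fresh <- build_null(sim$sm, taxa[1], sim$tree, cfg_f)
  ok <- !vapply(pool$removals, function(r) taxa[1] %in% r, logical(1))
  expect_equal(fresh[ok, ], pool$supports[ok, ])
})

test_that("removing a mosaic hybrid lifts support at a broken true node", {
  # construct a case where the hybrid drags a parent out of position
  spec <- sim_spec(n_taxa = 10, n_nuclear_genes = 7, n_mito_genes = 0,
                   gene_length = 300, seed = 2)
  tree <- simulate_species_tree(spec)
  aln <- simulate_alignments(tree, spec)
  parents <- phyloHET:::choose_hybrid_parents(tree, 5)
  ev <- hybrid_event("HYB", parents[1], parents[2], 0.5, "mosaic", 0.01)
  sm <- concatenate(inject_hybrid(aln, tree, ev, seed = 3)$alignments)
  cfg <- het_config(n_boot = 40, n_null = 20, max_group_size = 1, seed = 6,
                    shared_null = TRUE)
  res <- run_het(sm, tree, cfg, focal_sets = list("HYB", parents[1]))
  hyb <- res$summary[res$summary$focal == "HYB" & res$summary$testable, ]
  # direction: after removing the hybrid, observed support at the tracked
  # nodes is at least as high as the null median overall
  expect_gt(mean(hyb$observed >= hyb$q3), 0.5)
})
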