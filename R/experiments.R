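# Seeded validation experiments on synthetic data with known truth.  These
# are the package's own power / error-rate studies: HET power and type-I
# behaviour, F1 parent recovery, and cytonuclear-transfer recovery.  The
# problem sizes follow the package's validation design (16-taxon trees,
# seven 950 bp nuclear genes, i.e. a ~6.7 kb nuclear matrix, 100 bootstrap
# and 100 null replicates).

# Seeded choice of a hybrid parent pair: a random non-sister pair of
# closely related species (patristic distance >= 0.05 substitutions/site
# but below the median pairwise distance), the regime in which natural
# hybridisation occurs.
choose_hybrid_parents <- function(tree, seed, min_divergence = 0.05) {
  d <- ape::cophenetic.phylo(tree)
  labs <- rownames(d)
  ceiling_d <- stats::median(d[upper.tri(d)])
  cand <- list()
  for (i in seq_along(labs)) {
    sis <- sister_lineage(tree, labs[i])
    for (j in seq_along(labs)) {
      if (j <= i) next
      if (d[i, j] < min_divergence || d[i, j] > ceiling_d) next
      if (identical(sis, labs[j])) next
      cand[[length(cand) + 1L]] <- sort(c(labs[i], labs[j]))
    }
  }
  if (!length(cand)) return(NULL)
  with_seed(seed, cand[[sample.int(length(cand), 1L)]])
}

# TRUE when some flagged node is ancestral to a parental lineage: the
# flagged reference bipartition corresponds to a clade of the rooted
# reference tree that contains at least one of the parents.
flags_parental_node <- function(flagged, taxa, reference, parents) {
  if (!nrow(flagged)) return(FALSE)
  pp <- ape::prop.part(reference)
  labs <- attr(pp, "labels")
  clades <- vapply(pp, function(cl) paste(sort(labs[cl]), collapse = ";"),
                   character(1))
  ref_tips <- reference$tip.label
  any(vapply(flagged$key, function(k) {
    side <- intersect(taxa[.side_from_key(k)], ref_tips)
    other <- setdiff(ref_tips, side)
    for (s in list(side, other)) {
      id <- paste(sort(s), collapse = ";")
      if (id %in% clades && any(parents %in% s)) return(TRUE)
    }
    FALSE
  }, logical(1)))
}

#' HET power / type-I experiment on synthetic mosaic hybrids
#'
#' For each seed, simulates a 16-taxon pure-birth tree with seven 950 bp
#' nuclear genes; with `with_hybrid`, injects one mosaic hybrid between a
#' random closely related non-sister pair (maternal locus fraction 0.5,
#' post-hybridisation branch 0.01) and runs the homoplasy excess test with
#' 100 bootstrap and 100 null replicates (NJ backend, single-taxon
#' removals, shared null pool), tracking the generating tree's nodes.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param with_hybrid Inject the hybrid (power) or not (type-I control).
#' @param n_boot,n_null Replicate counts.
#' @return List: `per_seed` data frame (per seed: flagged pair counts,
#'   whether the hybrid's removal flagged a parental node), `power`
#'   (fraction of seeds where it did; `NA` without hybrid) and
#'   `flagged_fraction` (flagged / testable records pooled over seeds).
#' @export
het_experiment <- function(seeds = 1:20, with_hybrid = TRUE, n_boot = 100,
                           n_null = 100) {
  rows <- lapply(seeds, function(sd) {
    spec <- sim_spec(n_taxa = 16, n_nuclear_genes = 7, n_mito_genes = 0,
                     gene_length = 950, seed = sd)
    tree <- simulate_species_tree(spec)
    aln <- simulate_alignments(tree, spec)
    parents <- choose_hybrid_parents(tree, derive_seed(sd, "parents"))
    hybrid <- NULL
    if (with_hybrid) {
      hybrid <- "HYB"
      ev <- hybrid_event(hybrid, parents[1], parents[2],
                         maternal_locus_fraction = 0.5, mode = "mosaic",
                         post_hybrid_branch = 0.01)
      aln <- inject_hybrid(aln, tree, ev, seed = derive_seed(sd, "inj"))$alignments
    }
    sm <- concatenate(aln)
    # reference nodes are the generating tree's: known truth, so power and
    # error rates are measured against the nodes the test is meant to guard
    cfg <- het_config(n_boot = n_boot, n_null = n_null, max_group_size = 1,
                      seed = sd, shared_null = TRUE)
    res <- run_het(sm, tree, cfg)
    hyb_flagged <- res$flagged[res$flagged$focal %in% hybrid, , drop = FALSE]
    data.frame(seed = sd,
               n_flagged = nrow(res$flagged),
               n_testable = sum(res$summary$testable),
               hybrid_hit = if (with_hybrid) {
                 flags_parental_node(hyb_flagged, sm$taxa, tree, parents)
               } else NA,
               maternal = parents[1], paternal = parents[2])
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       power = if (with_hybrid) mean(per_seed$hybrid_hit) else NA_real_,
       flagged_fraction = sum(per_seed$n_flagged) / sum(per_seed$n_testable))
}

# Seeded choice of an F1 parent pair: a random non-sister leaf pair with
# patristic distance >= min_divergence.
choose_f1_parents <- function(tree, min_divergence, seed) {
  d <- ape::cophenetic.phylo(tree)
  labs <- rownames(d)
  cand <- list()
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (j <= i || d[i, j] < min_divergence) next
      sis <- sister_lineage(tree, labs[i])
      if (identical(sis, labs[j])) next
      cand[[length(cand) + 1L]] <- c(labs[i], labs[j])
    }
  }
  if (!length(cand)) return(NULL)
  with_seed(seed, cand[[sample.int(length(cand), 1L)]])
}

#' F1 parent-recovery experiment
#'
#' Simulates `n_sims` datasets (16 taxa, seven 950 bp nuclear genes, three
#' mito genes at twice the rate); in each, creates an F1 hybrid between a
#' random non-sister pair at patristic divergence >= `min_divergence` and
#' asks the placement module for its parents from the mitochondrial
#' markers and the gene-1 cloned alleles.
#'
#' @param n_sims Number of simulated hybrids.
#' @param seed Top-level seed.
#' @param min_divergence Minimum inter-parent patristic distance
#'   (substitutions/site).
#' @param n_boot Bootstrap replicates per placement.
#' @return List with `per_sim` data frame and the `maternal_recovery` /
#'   `paternal_recovery` fractions.
#' @export
placement_experiment <- function(n_sims = 50, seed = 1,
                                 min_divergence = 0.05, n_boot = 100) {
  rows <- list()
  for (i in seq_len(n_sims)) {
    sd <- derive_seed(seed, paste0("pl", i))
    spec <- sim_spec(n_taxa = 16, n_nuclear_genes = 7, n_mito_genes = 3,
                     gene_length = 950, seed = sd)
    tree <- simulate_species_tree(spec)
    parents <- choose_f1_parents(tree, min_divergence,
                                 derive_seed(sd, "pick"))
    if (is.null(parents)) next  # tree too shallow; does not count
    aln <- simulate_alignments(tree, spec)
    ev <- hybrid_event("HYB", parents[1], parents[2], mode = "F1",
                       post_hybrid_branch = 0)
    inj <- inject_hybrid(aln, tree, ev, seed = derive_seed(sd, "inj"))
    ref_sm <- concatenate(aln)  # pre-injection reference
    mito <- list()
    for (g in names(inj$alignments)) {
      a <- inj$alignments[[g]]
      if (a$genome == "mito") mito[[g]] <- a$mat["HYB", ]
    }
    cs <- clone_set("HYB", mito = mito,
                    nuclear = list(nuc1 = inj$clones[["nuc1"]]))
    pc <- placement_config(n_boot = n_boot, seed = derive_seed(sd, "place"),
                           root = setdiff(ref_sm$taxa, parents)[1])
    pa <- assign_parents(cs, ref_sm, pc)
    rows[[length(rows) + 1L]] <- data.frame(
      sim = i, maternal_true = parents[1], paternal_true = parents[2],
      maternal_hat = paste(pa$maternal$lineage, collapse = "+"),
      paternal_hat = paste(pa$paternal$lineage, collapse = "+"),
      maternal_support = pa$maternal$support,
      paternal_support = pa$paternal$support,
      maternal_ok = identical(pa$maternal$lineage, parents[1]),
      paternal_ok = identical(pa$paternal$lineage, parents[2]),
      stringsAsFactors = FALSE)
  }
  per_sim <- do.call(rbind, rows)
  list(per_sim = per_sim,
       maternal_recovery = mean(per_sim$maternal_ok),
       paternal_recovery = mean(per_sim$paternal_ok))
}

# Seeded choice of a transferable clade: an internal clade of size 2..4
# on a long stem branch, regrafted next to a non-sister leaf whose
# terminal branch is long enough that the new stem (half of it) is itself
# long — the "ancient transfer across well-separated lineages" scenario,
# where both positions are resolvable with high support.  Returns
# list(clade, attachment, root) or NULL when the tree offers no such
# configuration.
choose_transfer <- function(tree, seed, min_stem = 0.01) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  ntip <- length(tree$tip.label)
  stem_len <- function(tips) {
    mrca <- ape::getMRCA(tree, tips)
    tree$edge.length[tree$edge[, 2L] == mrca]
  }
  clades <- Filter(function(x) {
    length(x) >= 2 && length(x) <= 4 && length(stem_len(x)) &&
      stem_len(x) >= min_stem
  }, lapply(pp, function(cl) sort(labs[cl])))
  if (!length(clades)) return(NULL)
  term_len <- stats::setNames(
    tree$edge.length[match(seq_len(ntip), tree$edge[, 2L])],
    tree$tip.label)
  with_seed(seed, {
    for (k in sample.int(length(clades))) {
      clade <- clades[[k]]
      mrca <- ape::getMRCA(tree, clade)
      parent <- tree$edge[tree$edge[, 2L] == mrca, 1L]
      sister <- setdiff(ape::extract.clade(tree, parent)$tip.label, clade)
      cand <- setdiff(tree$tip.label, c(clade, sister))
      cand <- cand[term_len[cand] >= 2 * min_stem]
      if (length(cand) < 2) next
      attachment <- sample(cand, 1L)
      root <- setdiff(cand, attachment)[1]
      return(list(clade = clade, attachment = attachment, root = root))
    }
    NULL
  })
}

#' Cytonuclear-transfer recovery experiment
#'
#' Simulates `n_sims` datasets; in each, regrafts a small clade elsewhere
#' on the tree for the mitochondrial genealogy (or not, for the control),
#' infers nuclear and mito bootstrap consensus trees, and checks whether
#' the discordance report flags the relocated clade (and, in the control,
#' that no supported conflict is reported).
#'
#' @param n_sims Number of simulations.
#' @param seed Top-level seed.
#' @param with_transfer Inject the transfer (recovery) or not (control).
#' @param n_boot Bootstrap replicates per tree.
#' @param min_support Conflict support threshold.
#' @return List with `per_sim` data frame, `recovery` (fraction of runs
#'   flagging the relocated clade; `NA` in the control) and
#'   `conflict_runs` (runs reporting any supported conflict).
#' @export
cytonuclear_experiment <- function(n_sims = 50, seed = 1,
                                   with_transfer = TRUE, n_boot = 100,
                                   min_support = 95) {
  rows <- list()
  for (i in seq_len(n_sims)) {
    sd <- derive_seed(seed, paste0("cn", i))
    spec <- sim_spec(n_taxa = 16, n_nuclear_genes = 7, n_mito_genes = 3,
                     gene_length = 950, seed = sd)
    tree <- simulate_species_tree(spec)
    tr <- choose_transfer(tree, derive_seed(sd, "pick"))
    if (is.null(tr)) next
    mito_tree <- if (with_transfer) {
      inject_cytonuclear_transfer(tree, tr$clade, tr$attachment)
    } else NULL
    aln <- simulate_alignments(tree, spec, mito_tree = mito_tree)
    genomes <- vapply(aln, `[[`, character(1), "genome")
    nuc_sm <- concatenate(aln[genomes == "nuclear"])
    mit_sm <- concatenate(aln[genomes == "mito"])
    ntree <- bootstrap_consensus(nuc_sm, n_reps = n_boot,
                                 seed = derive_seed(sd, "nuc"))
    mtree <- bootstrap_consensus(mit_sm, n_reps = n_boot,
                                 seed = derive_seed(sd, "mit"))
    rep <- compare_trees(ntree, mtree, min_support = min_support,
                         root = tr$root)
    clade_id <- paste(tr$clade, collapse = "+")
    rows[[length(rows) + 1L]] <- data.frame(
      sim = i, clade = clade_id, attachment = tr$attachment,
      rf = rep$rf, n_conflicts = nrow(rep$conflicts),
      flagged = clade_id %in% rep$relocations$clade,
      stringsAsFactors = FALSE)
  }
  per_sim <- do.call(rbind, rows)
  list(per_sim = per_sim,
       recovery = if (with_transfer) mean(per_sim$flagged) else NA_real_,
       conflict_runs = sum(per_sim$n_conflicts > 0))
}
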