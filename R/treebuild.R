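# Desk-scale tree inference: neighbour joining, nonparametric bootstrap,
# extended majority-rule consensus and Robinson-Foulds distance.  Any
# function mapping a supermatrix to an ape "phylo" on the same leaf set can
# serve as the backend for bootstrap support and the homoplasy excess test;
# the built-in "nj" backend (JC69 distances + neighbour joining) is the
# default and has a pattern-compressed fast path.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration (via [ape::nj()]); negative branch
#' lengths are clamped to zero with the deficit moved onto an adjacent
#' sibling edge so leaf-to-leaf path lengths are approximately preserved.
#'
#' @param d A `"distance_matrix"`, symmetric numeric matrix, or `dist`.
#' @return An unrooted `phylo` with branch lengths.
#' @export
neighbor_joining <- function(d) {
  m <- if (inherits(d, "distance_matrix")) d$d else as.matrix(d)
  if (nrow(m) < 3L) stop("at least 3 taxa required")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(m)
  fix_negative_edges(tr)
}

fix_negative_edges <- function(tr) {
  for (it in seq_len(20L)) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1L]
    node <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == node), e)
    amt <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sib)) tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + amt
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' The built-in NJ backend
#'
#' Maps a supermatrix to a tree: JC69 pairwise distances (pairwise
#' deletion) followed by neighbour joining.  This is the default backend of
#' [bootstrap_support()] and [run_het()]; any function with the same
#' signature and contract can replace it.
#'
#' @param sm A supermatrix.
#' @param model Distance model passed to [pairwise_distances()].
#' @return An unrooted `phylo` on the supermatrix taxa.
#' @export
nj_backend <- function(sm, model = "JC69") {
  neighbor_joining(pairwise_distances(sm, model = model))
}

# Resolve a backend spec: the string "nj" (fast path eligible) or a
# function(sm) -> phylo.
resolve_backend <- function(backend) {
  if (is.function(backend)) return(backend)
  if (identical(backend, "nj")) return(nj_backend)
  stop("unknown backend: ", backend)
}

#' Bootstrap node support
#'
#' Builds the point-estimate tree on the supermatrix, then `n_reps` trees on
#' within-partition bootstrap resamples, and annotates every internal edge
#' of the point tree with the percentage of replicate trees containing its
#' bipartition (as `node.label`).
#'
#' @param sm A supermatrix.
#' @param n_reps Number of bootstrap replicates (conventionally 100).
#' @param backend `"nj"` or a `function(sm) -> phylo`.
#' @param seed Integer seed.
#' @param keep_trees Also return the replicate split sets.
#' @return The point tree (`phylo`) with support node labels in `[0, 100]`;
#'   when `keep_trees`, a list with elements `tree` and `rep_keys`.
#' @export
bootstrap_support <- function(sm, n_reps = 100, backend = "nj", seed = 1,
                              keep_trees = FALSE) {
  stopifnot(n_reps >= 1)
  taxa <- sm$taxa
  if (identical(backend, "nj")) {
    stats <- sm_pattern_stats(sm)
    res <- with_seed(derive_seed(seed, "boot"), {
      point <- kernel_nj_tree(stats, seq_len(stats$n))
      keys <- replicate_split_keys(stats, seq_len(stats$n), n_reps)
      list(point = point, keys = keys)
    })
    point <- res$point
    rep_keys <- res$keys
  } else {
    fn <- resolve_backend(backend)
    point <- fn(sm)
    rep_keys <- lapply(seq_len(n_reps), function(r) {
      bs <- bootstrap_resample(sm, seed = derive_seed(seed, paste0("rep", r)))
      split_keys(fn(bs), taxa)
    })
  }
  tree <- annotate_support(point, rep_keys, taxa, n_reps)
  if (keep_trees) list(tree = tree, rep_keys = rep_keys) else tree
}

# NJ point tree from kernel distances (w = 1) over surviving taxa indices.
kernel_nj_tree <- function(stats, surv, w = NULL) {
  pc <- surviving_pair_cols(stats, surv)
  if (is.null(w)) w <- rep(1, stats$L)
  p <- kernel_pdist(stats, w, pc)
  m <- kernel_dist_matrix(stats, p, surv, pc)
  neighbor_joining(m)
}

# n_reps bootstrap replicate trees' split key sets, drawn from the current
# RNG stream; keys indexed against the *surviving* taxa ordering.  The
# column draws match bootstrap_resample() exactly; all replicate distances
# are computed in one pass as weight x mismatch matrix products.
replicate_split_keys <- function(stats, surv, n_reps, key_taxa = NULL) {
  pc <- surviving_pair_cols(stats, surv)
  surv_taxa <- stats$taxa[surv]
  key_taxa <- key_taxa %||% surv_taxa
  M <- stats$M[, pc, drop = FALSE]
  nvar <- length(stats$var_sites)
  nmiss <- length(stats$miss_sites)
  Wvar <- matrix(0, nvar, n_reps)
  Wmiss <- matrix(0, nmiss, n_reps)
  for (r in seq_len(n_reps)) {
    cols <- draw_bootstrap_columns(stats$partitions, stats$L)
    w <- tabulate(cols, stats$L)
    Wvar[, r] <- w[stats$var_sites]
    if (nmiss) Wmiss[, r] <- w[stats$miss_sites]
  }
  mism <- crossprod(M, Wvar)  # pairs x replicates
  ncomp <- matrix(stats$L, nrow(mism), n_reps)
  if (nmiss) ncomp <- ncomp - crossprod(stats$Miss[, pc, drop = FALSE], Wmiss)
  lapply(seq_len(n_reps), function(r) {
    m <- kernel_dist_matrix(stats, mism[, r] / ncomp[, r], surv, pc)
    split_keys(neighbor_joining(m), key_taxa)
  })
}

# Write bootstrap percentages onto the internal node labels of `tree`.
annotate_support <- function(tree, rep_keys, taxa, n_reps) {
  n <- length(taxa)
  tab <- table(unlist(rep_keys))
  pp <- ape::prop.part(tree)
  idx <- match(attr(pp, "labels"), taxa)
  labs <- character(tree$Nnode)
  for (k in seq_along(pp)) {
    cl <- pp[[k]]
    if (length(cl) < 2L || length(cl) > n - 2L) {
      labs[k] <- ""
      next
    }
    v <- logical(n)
    v[idx[cl]] <- TRUE
    key <- .key_from_logical(v)
    cnt <- tab[key]
    labs[k] <- as.character(round(100 * (if (is.na(cnt)) 0 else cnt) / n_reps, 1))
  }
  tree$node.label <- labs
  tree
}

#' Majority-rule consensus, optionally extended with all compatible groups
#'
#' Includes every bipartition occurring in more than half of the input
#' trees; with `extended = TRUE`, the remaining bipartitions are added
#' greedily in order of decreasing frequency (ties broken lexicographically
#' on the canonical split) whenever they are compatible with everything
#' already accepted.  Each retained edge is annotated with its percentage.
#'
#' @param trees List of `phylo` objects on one common leaf set.
#' @param extended Add all compatible lower-frequency groups (the
#'   "allcompat" consensus).
#' @return A `phylo`; `node.label` holds the split percentages.
#' @export
majority_rule_consensus <- function(trees, extended = TRUE) {
  if (!length(trees)) stop("no trees")
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!setequal(t$tip.label, taxa)) stop("trees have different leaf sets")
  }
  consensus_from_key_sets(lapply(trees, split_keys, taxa = taxa), taxa,
                          extended)
}

# Shared consensus engine: key_sets is a list of per-tree split key sets
# indexed against `taxa`.
consensus_from_key_sets <- function(key_sets, taxa, extended = TRUE) {
  nt <- length(key_sets)
  tab <- table(unlist(key_sets))
  freq <- 100 * as.numeric(tab) / nt
  keys <- names(tab)
  ord <- order(-freq, keys)
  keys <- keys[ord]
  freq <- freq[ord]
  sides <- lapply(keys, .side_from_key)
  maj <- freq > 50
  acc <- which(maj)
  if (extended) {
    for (k in which(!maj)) {
      ok <- all(vapply(acc, function(a) {
        i <- length(intersect(sides[[a]], sides[[k]]))
        i == 0L || i == length(sides[[a]]) || i == length(sides[[k]])
      }, logical(1)))
      if (ok) acc <- c(acc, k)
    }
  }
  build_tree_from_clades(sides[acc], freq[acc], taxa)
}

#' Extended majority-rule consensus of the bootstrap sample
#'
#' Convenience wrapper: draws `n_reps` bootstrap replicate trees from the
#' supermatrix and returns their extended majority-rule consensus, node
#' labels giving the split percentages — the bootstrap analogue of a
#' Bayesian allcompat consensus.
#'
#' @inheritParams bootstrap_support
#' @param extended Include all compatible lower-frequency groups.
#' @return A `phylo` with percentage node labels.
#' @export
bootstrap_consensus <- function(sm, n_reps = 100, backend = "nj", seed = 1,
                                extended = TRUE) {
  bs <- bootstrap_support(sm, n_reps = n_reps, backend = backend,
                          seed = seed, keep_trees = TRUE)
  consensus_from_key_sets(bs$rep_keys, sm$taxa, extended)
}

# Build a phylo from a compatible set of clades (integer index sets over
# `taxa`, all excluding index 1), labelling internal nodes with `freqs`.
build_tree_from_clades <- function(sides, freqs, taxa) {
  n <- length(taxa)
  fmt <- function(x) as.character(round(x, 1))
  rec <- function(tipset, pool) {
    # pool: indices into sides[] that are proper subsets of tipset
    maximal <- pool[!vapply(pool, function(i) {
      any(vapply(pool, function(j) {
        j != i && length(sides[[i]]) < length(sides[[j]]) &&
          all(sides[[i]] %in% sides[[j]])
      }, logical(1)))
    }, logical(1))]
    covered <- integer(0)
    comps <- character(0)
    for (m in maximal) {
      inner_pool <- pool[vapply(pool, function(j) {
        j != m && all(sides[[j]] %in% sides[[m]])
      }, logical(1))]
      inside <- rec(sides[[m]], inner_pool)
      comps <- c(comps, paste0("(", paste(inside, collapse = ","), ")",
                               fmt(freqs[m])))
      covered <- c(covered, sides[[m]])
    }
    c(taxa[setdiff(tipset, covered)], comps)
  }
  all_pool <- seq_along(sides)
  top <- rec(2:n, all_pool)
  nwk <- paste0("(", paste(c(taxa[1], top), collapse = ","), ");")
  ape::read.tree(text = nwk)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of the non-trivial bipartitions.
#'
#' @param a,b `phylo` objects on the same leaf set.
#' @return Non-negative integer count.
#' @export
robinson_foulds <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) stop("trees have different leaf sets")
  taxa <- sort(a$tip.label)
  ka <- split_keys(a, taxa)
  kb <- split_keys(b, taxa)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}
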