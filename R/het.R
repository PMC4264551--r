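# Homoplasy excess test (HET).
#
# A hybrid taxon carries, locus by locus, alleles identical to one of its
# two parents; concatenated into one matrix these conflicting signals
# depress bootstrap support at the nodes containing the parental lineages.
# The test removes each candidate taxon (or monophyletic group) from the
# supermatrix, re-estimates per-node bootstrap support, and compares it to
# a null distribution obtained by removing random non-focal taxa.  A node
# is flagged when the focal-removal support falls above the boxplot upper
# whisker of the null (the highest null value within 1.5 IQR of the upper
# quartile, quartiles as Tukey hinges).  Node identity across taxon subsets
# is maintained by bipartition restriction.

#' HET configuration
#'
#' @param n_boot Bootstrap replicates per tree estimate (default 100).
#' @param n_null Random-removal null replicates (default 100).
#' @param max_group_size Largest monophyletic focal group size (default 8).
#' @param backend `"nj"` or a `function(sm) -> phylo`.
#' @param seed Integer seed governing every random draw.
#' @param outgroups Taxa never removed (focal or null) and never drawn in
#'   null replicates; explicit, not inferred.
#' @param quartile_method `"hinges"` (Tukey hinges, the boxplot convention)
#'   or `"linear"` (type-7 quantiles).
#' @param shared_null Reuse one pool of random removals for all focal sets
#'   of equal size (replicates overlapping a focal set are excluded for
#'   that focal set).  The default draws a fresh null per focal set.
#' @param null_monophyletic Require null group removals (n >= 2) to be
#'   monophyletic in the reference tree; by default null groups are
#'   arbitrary random species sets.
#' @param min_null_valid Minimum defined null values for a node to be
#'   testable.
#' @return Object of class `"het_config"`.
#' @export
het_config <- function(n_boot = 100, n_null = 100, max_group_size = 8,
                       backend = "nj", seed = 1, outgroups = character(),
                       quartile_method = c("hinges", "linear"),
                       shared_null = FALSE, null_monophyletic = FALSE,
                       min_null_valid = 5) {
  quartile_method <- match.arg(quartile_method)
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (n_null < 2) stop("n_null must be >= 2")
  if (max_group_size < 1 || max_group_size > 8) {
    stop("max_group_size must be in [1, 8]")
  }
  structure(list(n_boot = as.integer(n_boot), n_null = as.integer(n_null),
                 max_group_size = as.integer(max_group_size),
                 backend = backend, seed = as.integer(seed),
                 outgroups = outgroups, quartile_method = quartile_method,
                 shared_null = shared_null,
                 null_monophyletic = null_monophyletic,
                 min_null_valid = as.integer(min_null_valid)),
            class = "het_config")
}

#' Enumerate the focal removal sets
#'
#' All single non-outgroup leaves, plus every monophyletic clade of the
#' reference tree of size 2..`max_group_size` that contains no outgroup and
#' leaves at least four taxa after removal.
#'
#' @param reference Reference tree (`phylo`), typically the consensus on
#'   the complete supermatrix.
#' @param config A [het_config()].
#' @param taxa Taxa available for removal (default: the reference leaves;
#'   pass the supermatrix taxa when the reference is built on a subset).
#' @return List of character vectors (taxon sets).
#' @export
enumerate_focal_sets <- function(reference, config,
                                 taxa = reference$tip.label) {
  tips <- taxa
  ingroup <- setdiff(tips, config$outgroups)
  sets <- if (length(tips) - 1L >= 4L) as.list(sort(ingroup)) else list()
  if (config$max_group_size >= 2L) {
    pp <- ape::prop.part(reference)
    labs <- attr(pp, "labels")
    for (cl in pp) {
      members <- sort(labs[cl])
      sz <- length(members)
      if (sz < 2L || sz > config$max_group_size) next
      if (any(members %in% config$outgroups)) next
      if (length(tips) - sz < 4L) next
      sets[[length(sets) + 1L]] <- members
    }
  }
  unique(sets)
}

## ---- support after removal --------------------------------------------

# Restrict reference sides (logical matrix nodes x ntaxa, canonical over
# the full taxa ordering) to the surviving index set; returns canonical
# keys in the surviving index space, NA where the restriction is trivial.
restrict_side_keys <- function(ref_sides, surv) {
  nsurv <- length(surv)
  apply(ref_sides, 1L, function(v) {
    vs <- v[surv]
    cs <- sum(vs)
    if (cs < 2L || cs > nsurv - 2L) return(NA_character_)
    .key_from_logical(vs)
  })
}

# Observed support per reference node after removing `surv`'s complement,
# using the current RNG stream (fast NJ path).  Supports are measured on
# the intersection of the survivors with the reference universe: both the
# reference splits and every replicate tree's splits are restricted to the
# same taxon set before matching, so no node ever compares supports defined
# on different split semantics.
kernel_removal_support <- function(stats, surv, ref_sides, n_boot,
                                   ref_universe = NULL) {
  s0 <- if (is.null(ref_universe)) surv else intersect(surv, ref_universe)
  rk <- restrict_side_keys(ref_sides, s0)
  keys_list <- replicate_split_keys(stats, surv, n_boot,
                                    key_taxa = stats$taxa[s0])
  counts <- numeric(length(rk))
  for (keys in keys_list) counts <- counts + (rk %in% keys)
  ifelse(is.na(rk), NA_real_, 100 * counts / n_boot)
}

# Generic-backend equivalent, materializing supermatrices.
generic_removal_support <- function(sm, removal, ref_sides, config, seed,
                                    ref_universe = NULL) {
  red <- remove_taxa(sm, removal)
  fn <- resolve_backend(config$backend)
  surv <- match(red$taxa, sm$taxa)
  s0 <- if (is.null(ref_universe)) surv else intersect(surv, ref_universe)
  rk <- restrict_side_keys(ref_sides, s0)
  counts <- numeric(length(rk))
  for (r in seq_len(config$n_boot)) {
    bs <- bootstrap_resample(red, seed = derive_seed(seed, paste0("rep", r)))
    keys <- split_keys(fn(bs), sm$taxa[s0])
    counts <- counts + (rk %in% keys)
  }
  ifelse(is.na(rk), NA_real_, 100 * counts / config$n_boot)
}

# Reference sides as a logical matrix over `taxa`, one row per non-trivial
# reference split.
reference_side_matrix <- function(reference, taxa) {
  keys <- split_keys(reference, taxa)
  m <- matrix(FALSE, nrow = length(keys), ncol = length(taxa))
  for (k in seq_along(keys)) m[k, .side_from_key(keys[k])] <- TRUE
  rownames(m) <- keys
  m
}

#' Bootstrap support of reference nodes after a taxon removal
#'
#' Removes the given taxa, infers `n_boot` bootstrap trees on the reduced
#' supermatrix, and reports for every reference bipartition the percentage
#' of bootstrap trees containing its restriction to the surviving taxa
#' (`NA` where the restriction is trivial).
#'
#' @param sm Supermatrix.
#' @param removal Character vector of taxa to remove (may be empty for the
#'   baseline run).
#' @param reference Reference tree whose nodes are tracked.
#' @param config A [het_config()].
#' @return Data frame with `key`, `clade`, `support`.
#' @export
support_after_removal <- function(sm, removal, reference, config = het_config()) {
  taxa <- sm$taxa
  ref_sides <- reference_side_matrix(reference, taxa)
  ref_universe <- which(taxa %in% reference$tip.label)
  seed <- derive_seed(config$seed,
                      paste0("focal.", paste(sort(removal), collapse = "+")))
  if (identical(config$backend, "nj")) {
    stats <- sm_pattern_stats(sm)
    surv <- which(!(taxa %in% removal))
    obs <- with_seed(seed, kernel_removal_support(stats, surv, ref_sides,
                                                  config$n_boot, ref_universe))
  } else {
    obs <- generic_removal_support(sm, removal, ref_sides, config, seed,
                                   ref_universe)
  }
  data.frame(key = rownames(ref_sides),
             clade = vapply(rownames(ref_sides), key_to_label, character(1),
                            taxa = taxa),
             support = obs, row.names = NULL, stringsAsFactors = FALSE)
}

## ---- null distribution -------------------------------------------------

# Draw the r-th null removal of size n: uniform among non-outgroup taxa,
# redrawn until disjoint from the focal set (so the draw stream does not
# depend on the focal identity unless a collision forces a redraw).
draw_null_removal <- function(candidates, n, focal, seed, reference = NULL,
                              monophyletic = FALSE) {
  with_seed(seed, {
    for (i in seq_len(1000L)) {
      rem <- if (monophyletic && n >= 2L) {
        pool <- monophyletic_sets(reference, candidates, n)
        if (!length(pool)) stop("no monophyletic null sets of size ", n)
        pool[[sample.int(length(pool), 1L)]]
      } else {
        sort(sample(candidates, n))
      }
      if (!any(rem %in% focal)) return(rem)
    }
    stop("could not draw a null removal disjoint from the focal set")
  })
}

monophyletic_sets <- function(reference, candidates, n) {
  pp <- ape::prop.part(reference)
  labs <- attr(pp, "labels")
  out <- list()
  for (cl in pp) {
    members <- sort(labs[cl])
    if (length(members) == n && all(members %in% candidates)) {
      out[[length(out) + 1L]] <- members
    }
  }
  out
}

#' Null distribution of node supports from random removals
#'
#' Each of `n_null` replicates removes, uniformly at random without
#' replacement, as many taxa as the focal set (none of which is focal or an
#' outgroup) and measures reference-node support through the same
#' restriction rule as the observed value.  Replicates where a node's
#' restriction is trivial contribute nothing to that node's sample.
#'
#' @inheritParams support_after_removal
#' @param focal Character vector: the focal removal set.
#' @return Matrix `n_null` x nodes of supports (NA = undefined), with the
#'   node keys as column names.
#' @export
build_null <- function(sm, focal, reference, config = het_config()) {
  taxa <- sm$taxa
  ref_sides <- reference_side_matrix(reference, taxa)
  ref_universe <- which(taxa %in% reference$tip.label)
  stats <- if (identical(config$backend, "nj")) sm_pattern_stats(sm) else NULL
  null_support_matrix(sm, stats, focal, ref_sides, reference, config,
                      cache = new.env(parent = emptyenv()),
                      ref_universe = ref_universe)
}

null_support_matrix <- function(sm, stats, focal, ref_sides, reference,
                                config, cache, ref_universe = NULL) {
  taxa <- sm$taxa
  n <- length(focal)
  candidates <- setdiff(taxa, config$outgroups)
  avail <- setdiff(candidates, focal)
  if (length(avail) < n) stop("fewer than ", n, " removable taxa for the null")
  out <- matrix(NA_real_, nrow = config$n_null, ncol = nrow(ref_sides),
                dimnames = list(NULL, rownames(ref_sides)))
  for (r in seq_len(config$n_null)) {
    rem <- draw_null_removal(candidates, n, focal,
                             derive_seed(config$seed, sprintf("nullpick.%d.%d", n, r)),
                             reference = reference,
                             monophyletic = config$null_monophyletic)
    ckey <- paste0(r, ":", paste(rem, collapse = "+"))
    if (!is.null(cache[[ckey]])) {
      out[r, ] <- cache[[ckey]]
      next
    }
    bseed <- derive_seed(config$seed, sprintf("nullboot.%d.%d", n, r))
    obs <- if (!is.null(stats)) {
      surv <- which(!(taxa %in% rem))
      with_seed(bseed, kernel_removal_support(stats, surv, ref_sides,
                                              config$n_boot, ref_universe))
    } else {
      generic_removal_support(sm, rem, ref_sides, config, bseed, ref_universe)
    }
    cache[[ckey]] <- obs
    out[r, ] <- obs
  }
  out
}

# Shared-null economy mode: one pool of removals per size, ignoring focal
# identity; rows overlapping a focal set are masked per focal set.
shared_null_pool <- function(sm, stats, n, ref_sides, reference, config,
                             ref_universe = NULL) {
  taxa <- sm$taxa
  candidates <- setdiff(taxa, config$outgroups)
  removals <- vector("list", config$n_null)
  out <- matrix(NA_real_, nrow = config$n_null, ncol = nrow(ref_sides),
                dimnames = list(NULL, rownames(ref_sides)))
  for (r in seq_len(config$n_null)) {
    rem <- draw_null_removal(candidates, n, character(0),
                             derive_seed(config$seed, sprintf("nullpick.%d.%d", n, r)),
                             reference = reference,
                             monophyletic = config$null_monophyletic)
    removals[[r]] <- rem
    bseed <- derive_seed(config$seed, sprintf("nullboot.%d.%d", n, r))
    out[r, ] <- if (!is.null(stats)) {
      surv <- which(!(taxa %in% rem))
      with_seed(bseed, kernel_removal_support(stats, surv, ref_sides,
                                              config$n_boot, ref_universe))
    } else {
      generic_removal_support(sm, rem, ref_sides, config, bseed, ref_universe)
    }
  }
  list(removals = removals, supports = out)
}

## ---- outlier rule ------------------------------------------------------

tukey_hinges <- function(x) {
  x <- sort(x)
  m <- length(x)
  half <- ceiling(m / 2)
  c(stats::median(x[seq_len(half)]), stats::median(x[(m - half + 1):m]))
}

#' Upper-fence outlier detection against a null support sample
#'
#' For each node: quartiles of the null (Tukey hinges by default), fence =
#' Q3 + 1.5 IQR, whisker = highest null value still at or below the fence;
#' the observed support is an outlier when it exceeds the whisker strictly.
#' Nodes with fewer than `min_null_valid` defined null values are marked
#' untestable.
#'
#' @param observed Numeric vector of observed supports (NA = undefined).
#' @param null Matrix (replicates x nodes) or list of numeric null samples,
#'   aligned with `observed`.
#' @param quartile_method `"hinges"` or `"linear"`.
#' @param min_null_valid Minimum null sample size for testability.
#' @return Data frame with `observed`, `q1`, `q3`, `fence`, `whisker`,
#'   `n_null_valid`, `testable`, `outlier`.
#' @export
detect_outliers <- function(observed, null, quartile_method = "hinges",
                            min_null_valid = 5) {
  if (is.matrix(null)) null <- lapply(seq_len(ncol(null)), function(j) null[, j])
  if (is.numeric(null) && length(observed) == 1L) null <- list(null)
  stopifnot(length(null) == length(observed))
  out <- data.frame(observed = observed, q1 = NA_real_, q3 = NA_real_,
                    fence = NA_real_, whisker = NA_real_,
                    n_null_valid = 0L, testable = FALSE, outlier = FALSE)
  for (j in seq_along(observed)) {
    x <- null[[j]]
    x <- x[!is.na(x)]
    out$n_null_valid[j] <- length(x)
    if (length(x) < min_null_valid || is.na(observed[j])) next
    q <- if (quartile_method == "hinges") tukey_hinges(x) else {
      unname(stats::quantile(x, c(0.25, 0.75), type = 7))
    }
    fence <- q[2] + 1.5 * (q[2] - q[1])
    whisker <- max(x[x <= fence])
    out$q1[j] <- q[1]
    out$q3[j] <- q[2]
    out$fence[j] <- fence
    out$whisker[j] <- whisker
    out$testable[j] <- TRUE
    out$outlier[j] <- observed[j] > whisker
  }
  out
}

## ---- orchestration -----------------------------------------------------

#' Run the homoplasy excess test
#'
#' For every focal removal set: remove it, measure per-reference-node
#' bootstrap support, compare against a null of equal-size random removals,
#' and flag upper-fence outliers.
#'
#' @param sm Supermatrix (normally the concatenated nuclear genes).
#' @param reference Reference tree on the same leaf set (typically the
#'   consensus of the baseline bootstrap).
#' @param config A [het_config()].
#' @param focal_sets Optional list of focal sets; default
#'   [enumerate_focal_sets()].
#' @return Object of class `"het_result"`: `summary` (one row per focal set
#'   x testable node), `flagged` (the outlier rows), `null_samples` (per
#'   focal set the null support matrix, enough to redraw the boxplots),
#'   plus the reference tree and config.
#' @export
run_het <- function(sm, reference, config = het_config(), focal_sets = NULL) {
  taxa <- sm$taxa
  if (!all(reference$tip.label %in% taxa)) {
    stop("reference leaf set must be a subset of the supermatrix taxa")
  }
  ref_sides <- reference_side_matrix(reference, taxa)
  ref_universe <- which(taxa %in% reference$tip.label)
  if (!nrow(ref_sides)) stop("reference tree has no internal splits")
  focal_sets <- focal_sets %||% enumerate_focal_sets(reference, config, taxa)
  focal_sets <- lapply(focal_sets, sort)
  sizes <- unique(lengths(focal_sets))
  stats <- if (identical(config$backend, "nj")) sm_pattern_stats(sm) else NULL
  cache <- new.env(parent = emptyenv())
  pools <- list()
  if (config$shared_null) {
    for (n in sizes) {
      pools[[as.character(n)]] <-
        shared_null_pool(sm, stats, n, ref_sides, reference, config,
                         ref_universe)
    }
  }
  rows <- list()
  null_samples <- list()
  for (f in focal_sets) {
    fid <- paste(f, collapse = "+")
    fseed <- derive_seed(config$seed, paste0("focal.", fid))
    obs <- if (!is.null(stats)) {
      surv <- which(!(taxa %in% f))
      with_seed(fseed, kernel_removal_support(stats, surv, ref_sides,
                                              config$n_boot, ref_universe))
    } else {
      generic_removal_support(sm, f, ref_sides, config, fseed, ref_universe)
    }
    if (config$shared_null) {
      pool <- pools[[as.character(length(f))]]
      usable <- !vapply(pool$removals, function(r) any(r %in% f), logical(1))
      nullm <- pool$supports
      nullm[!usable, ] <- NA_real_
    } else {
      nullm <- null_support_matrix(sm, stats, f, ref_sides, reference,
                                   config, cache, ref_universe)
    }
    det <- detect_outliers(obs, nullm,
                           quartile_method = config$quartile_method,
                           min_null_valid = config$min_null_valid)
    det <- cbind(data.frame(focal = fid,
                            key = rownames(ref_sides),
                            clade = vapply(rownames(ref_sides), key_to_label,
                                           character(1), taxa = taxa),
                            stringsAsFactors = FALSE),
                 det)
    rows[[fid]] <- det
    null_samples[[fid]] <- nullm
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 flagged = summary[summary$outlier %in% TRUE, , drop = FALSE],
                 null_samples = null_samples,
                 reference = reference, taxa = taxa, config = config),
            class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("het_result: %d focal sets, %d reference nodes, %d flagged (focal, node) pairs\n",
              length(x$null_samples),
              length(unique(x$summary$key)), nrow(x$flagged)))
  if (nrow(x$flagged)) {
    cat("flagged:\n")
    print(x$flagged[, c("focal", "clade", "observed", "whisker", "fence")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write HET outputs to a directory
#'
#' Writes the summary TSV, the per-focal-set null samples TSV and a
#' machine-readable JSON result.
#'
#' @param result A [run_het()] result.
#' @param dir Output directory (created if needed).
#' @export
write_het_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$summary, file.path(dir, "het_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nl <- do.call(rbind, lapply(names(result$null_samples), function(f) {
    m <- result$null_samples[[f]]
    data.frame(focal = f, replicate = rep(seq_len(nrow(m)), ncol(m)),
               key = rep(colnames(m), each = nrow(m)),
               support = as.vector(m), stringsAsFactors = FALSE)
  }))
  utils::write.table(nl[!is.na(nl$support), ],
                     file.path(dir, "het_null_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(summary = result$summary,
         flagged = result$flagged,
         config = result$config[c("n_boot", "n_null", "max_group_size",
                                  "seed", "quartile_method", "shared_null")]),
    file.path(dir, "het_result.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
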