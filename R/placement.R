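# Parental assignment of putative hybrids.
#
# The maternal parent is read from the placement of the hybrid's
# mitochondrial sequences (organelles follow the mother); the paternal
# parent from the cloned nuclear allele whose placement falls outside the
# maternal lineage.  Placement is by re-inference with bootstrap: the query
# is added to the reference supermatrix (restricted to the chosen markers),
# the tree is rebuilt, and the query's sister group is reported as the
# nearest lineage, with the bootstrap percentage of that grouping as
# support.  The nearest lineage is the smallest reference clade sister to
# the query, so ambiguous placements honestly come back as multi-taxon
# clades rather than being forced to one taxon.

#' A putative hybrid's sequence set
#'
#' @param hybrid_id Identifier of the individual.
#' @param mito Named list of mitochondrial sequences (character vectors on
#'   the reference gene columns), one per mito gene.
#' @param nuclear Named list; per nuclear gene a character matrix of cloned
#'   allele sequences (>= 1 row).
#' @param locality Free-text locality metadata.
#' @return Object of class `"clone_set"`.
#' @export
clone_set <- function(hybrid_id, mito = list(), nuclear = list(),
                      locality = "") {
  stopifnot(is.list(mito), is.list(nuclear))
  structure(list(hybrid_id = hybrid_id, mito = mito, nuclear = nuclear,
                 locality = locality),
            class = "clone_set")
}

#' Collapse identical clones into unique variants
#'
#' Exact-duplicate collapse per gene, recording multiplicities; warns when
#' more than two variants survive (possible cloning artefacts or
#' polymorphism beyond a simple two-parent model).  Idempotent.
#'
#' @param clones Character matrix of clone sequences (rows = clones), or a
#'   named list of such matrices (one per gene).
#' @return For a matrix: list with `variants` (matrix of unique sequences)
#'   and `multiplicity`; for a list: a named list of such results.
#' @export
collapse_clones <- function(clones) {
  if (is.list(clones) && !is.matrix(clones)) {
    return(lapply(clones, collapse_clones))
  }
  if (is.null(dim(clones))) clones <- matrix(clones, nrow = 1)
  seqs <- apply(clones, 1L, paste, collapse = "")
  uniq <- !duplicated(seqs)
  variants <- clones[uniq, , drop = FALSE]
  mult <- as.integer(table(factor(seqs, levels = seqs[uniq])))
  rownames(variants) <- paste0("variant", seq_len(nrow(variants)))
  if (nrow(variants) > 2L) {
    warning(nrow(variants),
            " distinct variants recovered; more than two parental alleles",
            " suggests cloning artefacts or polymorphism")
  }
  list(variants = variants, multiplicity = mult)
}

#' Placement configuration
#'
#' @param n_boot Bootstrap replicates for placement support.
#' @param min_support Support threshold below which a placement is flagged
#'   inconclusive (default 95).
#' @param backend Tree-building backend (see [bootstrap_support()]).
#' @param root Reference taxon used to root placement trees (default: the
#'   first reference taxon).
#' @param seed Integer seed.
#' @return Object of class `"placement_config"`.
#' @export
placement_config <- function(n_boot = 100, min_support = 95, backend = "nj",
                             root = NULL, seed = 1) {
  structure(list(n_boot = as.integer(n_boot), min_support = min_support,
                 backend = backend, root = root, seed = as.integer(seed)),
            class = "placement_config")
}

#' Place a query sequence on a reference supermatrix
#'
#' Re-infers the tree (with bootstrap) on reference plus query, restricted
#' to the chosen markers, and reports the query's sister group.
#'
#' @param reference_sm Reference supermatrix.
#' @param query Named character vector/list of sequences per marker gene
#'   (aligned to the reference columns), or a single character vector when
#'   one marker is used.
#' @param markers Character vector of gene names to use.
#' @param query_id Tip label for the query.
#' @param config A [placement_config()].
#' @return List with `lineage` (character vector: smallest reference clade
#'   sister to the query), `support` (bootstrap percentage of the grouping
#'   query + lineage), `conclusive` (`support >= min_support`) and `tree`.
#' @export
place_query <- function(reference_sm, query, markers, query_id = "QUERY",
                        config = placement_config()) {
  sub <- lapply(markers, function(g) extract_partition(reference_sm, g))
  if (!is.list(query) && is.null(names(query))) {
    stopifnot(length(markers) == 1L)
    query <- stats::setNames(list(query), markers)
  }
  qrow <- unlist(lapply(markers, function(g) {
    q <- query[[g]]
    if (is.null(q)) stop("query lacks marker ", g)
    q
  }))
  genes <- lapply(sub, function(g) {
    if (ncol(g$mat) == 0) stop("empty marker block")
    g
  })
  sm <- concatenate(genes)
  if (length(qrow) != ncol(sm$mat)) {
    stop("query length ", length(qrow), " does not match the ",
         ncol(sm$mat), " reference columns of the chosen markers")
  }
  if (all(qrow %in% c("-", "?", "N"))) stop("query has all-missing overlap")
  sm$mat <- rbind(sm$mat, matrix(toupper(qrow), nrow = 1,
                                 dimnames = list(query_id, NULL)))
  sm$taxa <- rownames(sm$mat)
  bs <- bootstrap_support(sm, n_reps = config$n_boot,
                          backend = config$backend, seed = config$seed,
                          keep_trees = TRUE)
  root <- config$root %||% setdiff(reference_sm$taxa, query_id)[1]
  rooted <- root_at(bs$tree, root)
  lineage <- sister_lineage(rooted, query_id)
  taxa <- sm$taxa  # the ordering the replicate split keys are indexed on
  key <- .key_from_logical(taxa %in% c(query_id, lineage))
  support <- if (length(lineage) >= length(sm$taxa) - 2L) {
    NA_real_  # sister group spans nearly everything: no internal edge
  } else {
    100 * mean(vapply(bs$rep_keys, function(k) key %in% k, logical(1)))
  }
  list(lineage = sort(lineage), support = support,
       conclusive = !is.na(support) && support >= config$min_support,
       tree = bs$tree)
}

# Tips of the sibling subtree of `tip` in a rooted tree.
sister_lineage <- function(tree, tip) {
  ntip <- length(tree$tip.label)
  nd <- which(tree$tip.label == tip)
  parent <- tree$edge[tree$edge[, 2L] == nd, 1L]
  sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], nd)
  unlist(lapply(sibs, function(s) {
    if (s <= ntip) return(tree$tip.label[s])
    ape::extract.clade(tree, s)$tip.label
  }))
}

#' Assign maternal and paternal parents to a putative hybrid
#'
#' Maternal parent: placement of the concatenated mitochondrial markers.
#' Paternal parent: nearest lineage of the cloned nuclear variant whose
#' placement lies outside the maternal lineage; when every variant places
#' inside the maternal lineage the paternal parent is `"undetermined"`.
#' Placements below `min_support` are reported but flagged inconclusive.
#'
#' @param cs A [clone_set()].
#' @param reference_sm Reference supermatrix (hybrid excluded).
#' @param config A [placement_config()].
#' @return Object of class `"parent_assignment"`: `maternal` and
#'   `paternal` (each with `lineage`, `support`, `conclusive`), and
#'   `clone_placements` (one row per gene x variant).
#' @export
assign_parents <- function(cs, reference_sm, config = placement_config()) {
  stopifnot(inherits(cs, "clone_set"))
  maternal <- list(lineage = "undetermined", support = NA_real_,
                   conclusive = FALSE)
  if (length(cs$mito)) {
    maternal <- place_query(reference_sm, cs$mito, names(cs$mito),
                            query_id = paste0(cs$hybrid_id, "_mt"),
                            config = config)
    maternal$tree <- NULL
  }
  placements <- data.frame(gene = character(0), variant = character(0),
                           lineage = character(0), support = numeric(0),
                           conclusive = logical(0), stringsAsFactors = FALSE)
  paternal <- list(lineage = "undetermined", support = NA_real_,
                   conclusive = FALSE)
  collapsed <- collapse_clones(cs$nuclear)
  for (g in names(collapsed)) {
    v <- collapsed[[g]]$variants
    if (nrow(v) > 2L) {
      warning("gene ", g, ": more than two variants; using all")
    }
    for (i in seq_len(nrow(v))) {
      pl <- place_query(reference_sm, stats::setNames(list(v[i, ]), g), g,
                        query_id = paste0(cs$hybrid_id, "_", g, "_v", i),
                        config = config)
      placements <- rbind(placements, data.frame(
        gene = g, variant = rownames(v)[i],
        lineage = paste(pl$lineage, collapse = "+"),
        support = pl$support, conclusive = pl$conclusive,
        stringsAsFactors = FALSE))
      inside_maternal <- is.character(maternal$lineage) &&
        !identical(maternal$lineage, "undetermined") &&
        all(pl$lineage %in% maternal$lineage)
      if (!inside_maternal &&
          (identical(paternal$lineage, "undetermined") ||
           (!paternal$conclusive && pl$conclusive))) {
        paternal <- list(lineage = pl$lineage, support = pl$support,
                         conclusive = pl$conclusive)
      }
    }
  }
  structure(list(hybrid_id = cs$hybrid_id, maternal = maternal,
                 paternal = paternal, clone_placements = placements),
            class = "parent_assignment")
}

#' @export
print.parent_assignment <- function(x, ...) {
  fmt <- function(p) sprintf("%s (support %s%s)",
                             paste(p$lineage, collapse = "+"),
                             ifelse(is.na(p$support), "NA",
                                    format(p$support)),
                             ifelse(isTRUE(p$conclusive), "", ", inconclusive"))
  cat(sprintf("parent_assignment '%s':\n  maternal: %s\n  paternal: %s\n",
              x$hybrid_id, fmt(x$maternal), fmt(x$paternal)))
  invisible(x)
}

#' Sliding-window recombination scan of a clone against its two parents
#'
#' Per window the clone is assigned to the closer parent at sites where the
#' parents differ (ties unassigned); the mosaic flag is raised when both
#' parents win at least one window each with a margin of at least
#' `min_diff` informative sites — evidence of within-locus recombination.
#'
#' @param clone,parent_a,parent_b Character vectors on shared columns.
#' @param window Window width (bp).
#' @param step Step between window starts (bp).
#' @param min_diff Minimum winning margin (informative-site count) for a
#'   window to count towards the mosaic flag.
#' @return List with `windows` (data frame: `start`, `end`, `d_a`, `d_b`,
#'   `winner`) and the logical `mosaic` flag.
#' @export
recombination_scan <- function(clone, parent_a, parent_b, window = 100,
                               step = 25, min_diff = 3) {
  L <- length(clone)
  if (length(parent_a) != L || length(parent_b) != L) {
    stop("sequences must share columns")
  }
  if (window > L) stop("window (", window, ") larger than alignment (", L, ")")
  ok <- function(x) x %in% c("A", "C", "G", "T")
  informative <- parent_a != parent_b & ok(parent_a) & ok(parent_b) & ok(clone)
  starts <- seq(1L, L - window + 1L, by = step)
  res <- data.frame(start = starts, end = starts + window - 1L,
                    d_a = NA_integer_, d_b = NA_integer_,
                    winner = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window - 1L)
    idx <- idx[informative[idx]]
    da <- sum(clone[idx] != parent_a[idx])
    db <- sum(clone[idx] != parent_b[idx])
    res$d_a[i] <- da
    res$d_b[i] <- db
    res$winner[i] <- if (da < db) "A" else if (db < da) "B" else NA_character_
  }
  margin <- abs(res$d_a - res$d_b)
  strong_a <- any(res$winner %in% "A" & margin >= min_diff)
  strong_b <- any(res$winner %in% "B" & margin >= min_diff)
  list(windows = res, mosaic = strong_a && strong_b)
}

#' Write a parent assignment report
#'
#' @param pa A [assign_parents()] result.
#' @param path Output JSON path (a TSV of clone placements is written next
#'   to it).
#' @export
write_parent_assignment <- function(pa, path) {
  jsonlite::write_json(
    list(hybrid_id = pa$hybrid_id,
         maternal = pa$maternal[c("lineage", "support", "conclusive")],
         paternal = pa$paternal[c("lineage", "support", "conclusive")],
         clone_placements = pa$clone_placements),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.table(pa$clone_placements,
                     sub("\\.json$", "_clones.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
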