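# Bipartition (split) algebra.
#
# A bipartition divides a taxon universe in two.  It is the identity of an
# internal tree edge ("node") that survives across trees built on different
# taxon subsets: after taxa are removed, a reference split is *restricted*
# to the survivors and matched against the splits of the reduced trees.
# Canonical form: the side NOT containing the first taxon of the universe,
# sorted; this makes the representation unique for a given universe.

#' Construct a bipartition
#'
#' A bipartition (split) of a taxon universe, stored in canonical form as
#' the side that does not contain the first taxon of the universe.
#'
#' @param side Character vector of taxon labels on one side of the split.
#' @param universe Character vector of all taxon labels (order fixes the
#'   canonical form).
#' @return An object of class `"bipartition"` with elements `side` and
#'   `universe`.
#' @examples
#' bipartition(c("C", "D"), c("A", "B", "C", "D"))
#' @export
bipartition <- function(side, universe) {
  if (anyDuplicated(universe)) stop("duplicate taxa in universe")
  if (!all(side %in% universe)) {
    stop("side contains taxa outside the universe: ",
         paste(setdiff(side, universe), collapse = ", "))
  }
  if (universe[1] %in% side) side <- setdiff(universe, side)
  side <- sort(unique(side))
  if (length(side) < 1L || length(side) > length(universe) - 1L) {
    stop("degenerate bipartition: one side is empty")
  }
  structure(list(side = side, universe = universe), class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  other <- setdiff(x$universe, x$side)
  cat("{", paste(x$side, collapse = ","), "} | {",
      paste(other, collapse = ","), "}\n", sep = "")
  invisible(x)
}

# Non-trivial means both sides have >= 2 taxa (the split corresponds to an
# internal edge).
is_trivial_bipartition <- function(bp) {
  length(bp$side) < 2L || length(bp$side) > length(bp$universe) - 2L
}

bip_key <- function(bp) paste(bp$side, collapse = ";")

#' Restrict a bipartition to a surviving taxon subset
#'
#' Intersects both sides with the survivors.  This is how a reference-tree
#' node keeps its identity after taxa are removed: the split is restricted,
#' and becomes undefined (`NULL`) when either side is left with fewer than
#' two taxa.
#'
#' @param bp A [bipartition()].
#' @param surviving Character vector of retained taxa (subset of the
#'   universe).
#' @return A `"bipartition"` on the surviving universe, or `NULL` when the
#'   restriction is trivial.
#' @export
restrict_bipartition <- function(bp, surviving) {
  stopifnot(inherits(bp, "bipartition"))
  if (!all(surviving %in% bp$universe)) stop("surviving taxa outside universe")
  s1 <- intersect(surviving, bp$side)
  s2 <- setdiff(surviving, s1)
  if (length(s1) < 2L || length(s2) < 2L) return(NULL)
  bipartition(s1, surviving)
}

#' Test whether two bipartitions are compatible
#'
#' Two splits of the same universe are compatible (can occur in one tree)
#' iff at least one of the four pairwise side intersections is empty; in
#' canonical form this reduces to the sides being nested or disjoint.
#'
#' @param a,b Objects of class `"bipartition"` over the same universe.
#' @return Logical.
#' @export
compatible_bipartitions <- function(a, b) {
  stopifnot(inherits(a, "bipartition"), inherits(b, "bipartition"))
  if (!setequal(a$universe, b$universe)) stop("bipartitions on different universes")
  # canonical sides both exclude universe[1]; compatibility <=> nested or disjoint
  i <- length(intersect(a$side, b$side))
  i == 0L || i == length(a$side) || i == length(b$side)
}

## ---- fast index-space machinery (internal) ----------------------------

# Canonical split key of a logical membership vector over a fixed taxon
# ordering: flip so that position 1 is FALSE, key the TRUE indices.
.key_from_logical <- function(v) {
  if (v[1L]) v <- !v
  paste(which(v), collapse = ",")
}

.side_from_key <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])

# All non-trivial split keys of a tree, indexed against `taxa`.  Tips of
# the tree absent from `taxa` are dropped, i.e. every split is restricted
# to the `taxa` universe before canonicalisation (trivial restrictions are
# discarded); this is what gives a node its identity across trees built on
# different taxon subsets.
split_keys <- function(tree, taxa) {
  n <- length(taxa)
  pp <- ape::prop.part(tree)
  idx <- match(attr(pp, "labels"), taxa)
  keys <- character(0)
  for (cl in pp) {
    members <- idx[cl]
    members <- members[!is.na(members)]
    sz <- length(members)
    if (sz < 2L || sz > n - 2L) next
    v <- logical(n)
    v[members] <- TRUE
    keys <- c(keys, .key_from_logical(v))
  }
  unique(keys)
}

# Split keys of a tree's internal nodes together with the support parsed
# from node labels (NA when absent/trivial).  Returns data.frame.
splits_with_support <- function(tree, taxa = tree$tip.label) {
  n <- length(taxa)
  pp <- ape::prop.part(tree)
  idx <- match(attr(pp, "labels"), taxa)
  labs <- tree$node.label %||% rep(NA_character_, tree$Nnode)
  out <- data.frame(key = character(0), support = numeric(0),
                    stringsAsFactors = FALSE)
  for (k in seq_along(pp)) {
    cl <- pp[[k]]
    sz <- length(cl)
    if (sz < 2L || sz > n - 2L) next
    v <- logical(n)
    v[idx[cl]] <- TRUE
    sup <- suppressWarnings(as.numeric(labs[k]))
    out <- rbind(out, data.frame(key = .key_from_logical(v), support = sup,
                                 stringsAsFactors = FALSE))
  }
  out[!duplicated(out$key), , drop = FALSE]
}

# Convert an index-space key to a bipartition object.
key_to_bipartition <- function(key, taxa) {
  bipartition(taxa[.side_from_key(key)], taxa)
}

# Human-readable clade string for reports.
key_to_label <- function(key, taxa) {
  paste(sort(taxa[.side_from_key(key)]), collapse = "+")
}
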