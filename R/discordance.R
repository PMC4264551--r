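# Cytonuclear discordance between nuclear and mitochondrial consensus
# trees.  Only mutually incompatible bipartitions that are well supported
# in BOTH trees count as conflict; weakly supported incongruence is listed
# separately and never interpreted (absence of resolution is not
# discordance).

#' Compare a nuclear and a mitochondrial tree
#'
#' Detects well-supported topological conflict between the two trees.
#' Conflicts are pairs of incompatible bipartitions, one per tree, both
#' meeting `min_support`; incompatible pairs failing the threshold are
#' reported as `unsupported`.  For clades present (and supported) in both
#' rooted trees, differing sister groups are summarised as relocations.
#'
#' @param nuclear,mito `phylo` objects with bootstrap percentages as
#'   `node.label`, sharing a leaf set (the comparison runs on the shared
#'   subset when the leaf sets differ).
#' @param min_support Support threshold in `[0, 100]` that both sides of a
#'   conflict must meet (default 95).
#' @param root Optional leaf label used to root both trees for the
#'   sister-group (relocation) summary; default: the first shared taxon.
#' @return Object of class `"discordance_report"`: data frames `shared`
#'   (bipartitions in both trees with both supports), `conflicts`,
#'   `unsupported`, `relocations`, and the Robinson-Foulds distance `rf`.
#' @export
compare_trees <- function(nuclear, mito, min_support = 95, root = NULL) {
  shared_taxa <- intersect(nuclear$tip.label, mito$tip.label)
  if (length(shared_taxa) < 4L) stop("fewer than 4 shared taxa")
  if (!setequal(nuclear$tip.label, shared_taxa)) {
    nuclear <- ape::keep.tip(nuclear, shared_taxa)
  }
  if (!setequal(mito$tip.label, shared_taxa)) {
    mito <- ape::keep.tip(mito, shared_taxa)
  }
  taxa <- sort(shared_taxa)
  sn <- splits_with_support(nuclear, taxa)
  sm <- splits_with_support(mito, taxa)
  shared_keys <- intersect(sn$key, sm$key)
  shared <- data.frame(
    clade = vapply(shared_keys, key_to_label, character(1), taxa = taxa),
    key = shared_keys,
    support_nuclear = sn$support[match(shared_keys, sn$key)],
    support_mito = sm$support[match(shared_keys, sm$key)],
    row.names = NULL, stringsAsFactors = FALSE)

  conflicts <- unsupported <- data.frame(
    clade_nuclear = character(0), clade_mito = character(0),
    support_nuclear = numeric(0), support_mito = numeric(0),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sn))) {
    a <- .side_from_key(sn$key[i])
    for (j in seq_len(nrow(sm))) {
      b <- .side_from_key(sm$key[j])
      ov <- length(intersect(a, b))
      compatible <- ov == 0L || ov == length(a) || ov == length(b)
      if (compatible) next
      row <- data.frame(
        clade_nuclear = key_to_label(sn$key[i], taxa),
        clade_mito = key_to_label(sm$key[j], taxa),
        support_nuclear = sn$support[i], support_mito = sm$support[j],
        stringsAsFactors = FALSE)
      strong <- !is.na(sn$support[i]) && !is.na(sm$support[j]) &&
        sn$support[i] >= min_support && sm$support[j] >= min_support
      if (strong) conflicts <- rbind(conflicts, row)
      else unsupported <- rbind(unsupported, row)
    }
  }

  root <- root %||% taxa[1]
  relocations <- relocation_summary(nuclear, mito, root, min_support)
  structure(list(shared = shared, conflicts = conflicts,
                 unsupported = unsupported, relocations = relocations,
                 rf = robinson_foulds(nuclear, mito),
                 min_support = min_support),
            class = "discordance_report")
}

# Clades present and supported in both rooted trees whose sister groups
# differ between the trees.
relocation_summary <- function(nuclear, mito, root, min_support) {
  out <- data.frame(clade = character(0), sister_nuclear = character(0),
                    sister_mito = character(0), support_nuclear = numeric(0),
                    support_mito = numeric(0), stringsAsFactors = FALSE)
  rn <- root_at(nuclear, root)
  rm_ <- root_at(mito, root)
  cn <- rooted_clades(rn)
  cm <- rooted_clades(rm_)
  for (k in names(cn)) {
    if (!(k %in% names(cm))) next
    a <- cn[[k]]
    b <- cm[[k]]
    if (is.na(a$support) || is.na(b$support)) next
    if (a$support < min_support || b$support < min_support) next
    if (setequal(a$sister, b$sister)) next
    out <- rbind(out, data.frame(
      clade = paste(sort(a$tips), collapse = "+"),
      sister_nuclear = paste(sort(a$sister), collapse = "+"),
      sister_mito = paste(sort(b$sister), collapse = "+"),
      support_nuclear = a$support, support_mito = b$support,
      stringsAsFactors = FALSE))
  }
  out
}

root_at <- function(tree, root) {
  if (!(root %in% tree$tip.label)) stop("root taxon not in tree: ", root)
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2) {
    tree <- ape::unroot(tree)
  }
  ape::root(tree, outgroup = root, resolve.root = TRUE, edgelabel = TRUE)
}

# For every internal clade of a rooted tree: member tips, sister tips and
# parsed support.  Named by sorted member string.
rooted_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  labs <- tree$node.label %||% rep(NA_character_, tree$Nnode)
  pp <- ape::prop.part(tree)
  tips_of <- lapply(pp, function(cl) attr(pp, "labels")[cl])
  # map node number -> clade tips
  node_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    tips_of[[node - ntip]]
  }
  out <- list()
  for (nd in (ntip + 2L):(ntip + tree$Nnode)) {  # skip the root itself
    tips <- node_tips(nd)
    if (length(tips) < 2L || length(tips) > ntip - 2L) next
    parent <- tree$edge[tree$edge[, 2L] == nd, 1L]
    sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], nd)
    sister <- unlist(lapply(sibs, node_tips))
    sup <- suppressWarnings(as.numeric(labs[nd - ntip]))
    out[[paste(sort(tips), collapse = ";")]] <-
      list(tips = tips, sister = sister, support = sup)
  }
  out
}

#' @export
print.discordance_report <- function(x, ...) {
  cat(sprintf("discordance_report: RF = %d, %d supported conflict pair(s), %d relocation(s), %d unsupported incongruence pair(s)\n",
              x$rf, nrow(x$conflicts), nrow(x$relocations), nrow(x$unsupported)))
  if (nrow(x$relocations)) print(x$relocations, row.names = FALSE)
  invisible(x)
}

#' Write a discordance report as TSV files
#'
#' @param report A [compare_trees()] result.
#' @param dir Output directory.
#' @export
write_discordance_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("shared", "conflicts", "unsupported", "relocations")) {
    utils::write.table(report[[nm]],
                       file.path(dir, paste0("discordance_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(sprintf("rf\t%d", report$rf), file.path(dir, "discordance_rf.tsv"))
  invisible(dir)
}

#' Leaf orderings for a low-crossing tanglegram
#'
#' Keeps the first tree's ladderised order and reorders the second tree by
#' recursively rotating each internal node so children follow the mean
#' position of their tips in the first ordering (a deterministic barycenter
#' heuristic).
#'
#' @param nuclear,mito `phylo` objects on a shared leaf set.
#' @return List with `left` and `right` leaf orderings and the implied
#'   number of `crossings` (inversions between the two orderings).
#' @export
tanglegram_order <- function(nuclear, mito) {
  if (!setequal(nuclear$tip.label, mito$tip.label)) {
    stop("trees must share a leaf set")
  }
  left <- ladderised_tips(nuclear)
  pos <- stats::setNames(seq_along(left), left)
  right <- barycenter_tips(mito, pos)
  rp <- pos[right]
  inv <- 0L
  for (i in seq_along(rp)) {
    inv <- inv + sum(rp[-seq_len(i)] < rp[i])
  }
  list(left = left, right = right, crossings = inv)
}

ladderised_tips <- function(tree) {
  tr <- ape::ladderize(tree)
  tr$tip.label[tr$edge[tr$edge[, 2L] <= length(tr$tip.label), 2L]]
}

barycenter_tips <- function(tree, pos) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- children[[as.character(node)]]
    sub <- lapply(kids, rec)
    bary <- vapply(sub, function(t) mean(pos[t]), numeric(1))
    unlist(sub[order(bary)])
  }
  rec(ntip + 1L)
}
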