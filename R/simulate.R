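# Synthetic multilocus data with known ground truth.
#
# The generator emulates the shape of a multilocus fish radiation dataset:
# a pure-birth species tree, a nuclear partition of several independently
# simulated genes, a faster-evolving three-gene mitochondrial partition that
# shares a single (possibly regrafted) maternal genealogy, and hybrid taxa
# whose loci are mosaics of two parental lineages (or F1 allele pairs) with
# mitochondria following the maternal parent.

#' Simulation specification
#'
#' Defaults mirror the shape of a clownfish-like adaptive radiation: 41 tips,
#' seven nuclear genes of 954 bp (a ~6.7 kb nuclear supermatrix) and three
#' mitochondrial genes evolving about twice as fast on a shared genealogy.
#' `birth_rate` is in events per unit of expected substitutions/site, so a
#' rate of 12 yields root-to-tip depths of roughly 0.2-0.4.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param n_nuclear_genes Number of nuclear loci.
#' @param n_mito_genes Number of mitochondrial loci (0 allowed).
#' @param gene_length Sites per locus.
#' @param birth_rate Pure-birth speciation rate.
#' @param subst_model `"JC69"`, `"K2P"` or `"HKY"`.
#' @param tstv Transition/transversion rate ratio (K2P, HKY).
#' @param base_freq Base frequencies A,C,G,T (HKY).
#' @param mito_rate_multiplier Branch-length multiplier for mito loci (> 0).
#' @param seed Integer seed; identical spec + seed gives bit-identical data.
#' @return Object of class `"sim_spec"`.
#' @export
sim_spec <- function(n_taxa = 41, n_nuclear_genes = 7, n_mito_genes = 3,
                     gene_length = 954, birth_rate = 12,
                     subst_model = c("JC69", "K2P", "HKY"), tstv = 2,
                     base_freq = rep(0.25, 4), mito_rate_multiplier = 2,
                     seed = 1) {
  subst_model <- match.arg(subst_model)
  if (n_taxa < 4) stop("n_taxa must be >= 4")
  if (gene_length < 1) stop("gene_length must be >= 1")
  if (mito_rate_multiplier <= 0) stop("mito_rate_multiplier must be > 0")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (abs(sum(base_freq) - 1) > 1e-8) stop("base_freq must sum to 1")
  structure(list(n_taxa = as.integer(n_taxa),
                 n_nuclear_genes = as.integer(n_nuclear_genes),
                 n_mito_genes = as.integer(n_mito_genes),
                 gene_length = as.integer(gene_length),
                 birth_rate = birth_rate, subst_model = subst_model,
                 tstv = tstv, base_freq = base_freq,
                 mito_rate_multiplier = mito_rate_multiplier,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a pure-birth species tree
#'
#' @param spec A [sim_spec()].
#' @return A rooted binary `phylo` with `n_taxa` leaves labelled
#'   `T01 ... Tnn`, branch lengths in expected substitutions/site.
#' @export
simulate_species_tree <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  tr <- with_seed(derive_seed(spec$seed, "tree"),
                  ape::rphylo(spec$n_taxa, birth = spec$birth_rate, death = 0))
  ord <- order(as.integer(sub("^t", "", tr$tip.label)))
  new <- sprintf("T%02d", seq_len(spec$n_taxa))
  tr$tip.label[ord] <- new
  tr
}

# phangorn rate parameters for the chosen model (lower-triangle order
# ac, ag, at, cg, ct, gt).
model_Q <- function(spec) {
  switch(spec$subst_model,
         JC69 = rep(1, 6),
         K2P = c(1, spec$tstv, 1, 1, spec$tstv, 1),
         HKY = c(1, spec$tstv, 1, 1, spec$tstv, 1))
}

model_bf <- function(spec) {
  if (spec$subst_model == "HKY") spec$base_freq else rep(0.25, 4)
}

simulate_one_gene <- function(tree, spec, gene_name, genome, gene_seed) {
  aln <- with_seed(gene_seed,
                   phangorn::simSeq(tree, l = spec$gene_length,
                                    Q = model_Q(spec), bf = model_bf(spec),
                                    type = "DNA"))
  mat <- toupper(as.character(aln))
  rownames(mat) <- names(aln)
  gene_alignment(gene_name, mat, genome = genome)
}

#' Simulate per-gene alignments along a species tree
#'
#' Each gene evolves independently under the spec's substitution model.
#' Mitochondrial genes are simulated on `mito_tree` (default: the species
#' tree) with branch lengths scaled by `mito_rate_multiplier`; passing the
#' output of [inject_cytonuclear_transfer()] as `mito_tree` creates ancient
#' cytonuclear discordance with known truth.
#'
#' @param tree Species tree (`phylo`).
#' @param spec A [sim_spec()].
#' @param mito_tree Optional generating topology for the mito partition.
#' @return List of [gene_alignment()] objects (`nuc1..`, then `mit1..`).
#' @export
simulate_alignments <- function(tree, spec, mito_tree = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!length(tree$tip.label)) stop("tree has no leaves")
  genes <- list()
  for (g in seq_len(spec$n_nuclear_genes)) {
    nm <- paste0("nuc", g)
    genes[[nm]] <- simulate_one_gene(tree, spec, nm, "nuclear",
                                     derive_seed(spec$seed, paste0("gene.", nm)))
  }
  if (spec$n_mito_genes > 0) {
    mt <- mito_tree %||% tree
    if (!setequal(mt$tip.label, tree$tip.label)) {
      stop("mito_tree must share the species-tree leaf set")
    }
    mt$edge.length <- mt$edge.length * spec$mito_rate_multiplier
    for (g in seq_len(spec$n_mito_genes)) {
      nm <- paste0("mit", g)
      genes[[nm]] <- simulate_one_gene(mt, spec, nm, "mito",
                                       derive_seed(spec$seed, paste0("gene.", nm)))
    }
  }
  genes
}

#' Describe a hybridisation event
#'
#' @param hybrid_label Name of the hybrid taxon to create.
#' @param maternal_parent,paternal_parent Distinct parental leaf labels.
#' @param maternal_locus_fraction Probability that a nuclear locus copies
#'   the maternal parent (mosaic mode).
#' @param mode `"mosaic"` (each locus fixed for one parental allele) or
#'   `"F1"` (each nuclear locus carries both parental alleles, emitted as
#'   clone records; only the maternal mito enters the alignments).
#' @param post_hybrid_branch Expected substitutions/site accumulated since
#'   hybridisation, applied i.i.d. per site to every hybrid sequence.
#' @return Object of class `"hybrid_event"`.
#' @export
hybrid_event <- function(hybrid_label, maternal_parent, paternal_parent,
                         maternal_locus_fraction = 0.5,
                         mode = c("mosaic", "F1"), post_hybrid_branch = 0) {
  mode <- match.arg(mode)
  if (maternal_parent == paternal_parent) stop("parents must be distinct")
  if (hybrid_label %in% c(maternal_parent, paternal_parent)) {
    stop("hybrid label must differ from the parental labels")
  }
  if (maternal_locus_fraction < 0 || maternal_locus_fraction > 1) {
    stop("maternal_locus_fraction must be in [0, 1]")
  }
  if (post_hybrid_branch < 0) stop("post_hybrid_branch must be >= 0")
  structure(list(hybrid_label = hybrid_label,
                 maternal_parent = maternal_parent,
                 paternal_parent = paternal_parent,
                 maternal_locus_fraction = maternal_locus_fraction,
                 mode = mode, post_hybrid_branch = post_hybrid_branch),
            class = "hybrid_event")
}

# Apply i.i.d. JC-style divergence `b` (expected substitutions/site) to a
# character vector sequence, using the current RNG stream.
mutate_sequence <- function(seq, b) {
  if (b <= 0) return(seq)
  p_change <- 0.75 * (1 - exp(-4 * b / 3))
  hit <- which(stats::runif(length(seq)) < p_change & seq %in% c("A", "C", "G", "T"))
  bases <- c("A", "C", "G", "T")
  for (i in hit) seq[i] <- sample(setdiff(bases, seq[i]), 1L)
  seq
}

#' Add a hybrid taxon to simulated alignments
#'
#' Mosaic mode adds one taxon to every gene: each nuclear locus copies one
#' parent's sequence (the maternal parent with probability
#' `maternal_locus_fraction`); F1 mode emits two allele sequences per
#' nuclear locus as separate clone records instead.  In both modes every
#' mitochondrial locus copies the maternal parent.  Post-hybridisation
#' substitutions are then applied to every hybrid sequence.
#'
#' @param alignments List of [gene_alignment()]s (from
#'   [simulate_alignments()]).
#' @param tree The species tree the alignments were simulated on.
#' @param event A [hybrid_event()].
#' @param seed Integer seed for donor choice and post-hybrid mutation.
#' @return List with `alignments` (augmented), `clones` (F1 mode: per
#'   nuclear gene a 2-row character matrix of alleles, with a `"donors"`
#'   attribute) and `truth` (species tree, the event, and the per-locus
#'   donor table).
#' @export
inject_hybrid <- function(alignments, tree, event, seed = 1) {
  stopifnot(inherits(event, "hybrid_event"))
  parents <- c(event$maternal_parent, event$paternal_parent)
  missing <- setdiff(parents, tree$tip.label)
  if (length(missing)) stop("parent not in tree: ", paste(missing, collapse = ", "))
  hyb <- event$hybrid_label
  clones <- list()
  donors <- character(length(alignments))
  names(donors) <- vapply(alignments, `[[`, character(1), "gene_name")
  with_seed(derive_seed(seed, paste0("hybrid.", hyb)), {
    for (k in seq_along(alignments)) {
      g <- alignments[[k]]
      if (!all(parents %in% rownames(g$mat))) {
        stop("parent missing from gene ", g$gene_name)
      }
      if (g$genome == "mito") {
        donors[k] <- event$maternal_parent
        row <- mutate_sequence(g$mat[event$maternal_parent, ],
                               event$post_hybrid_branch)
        g$mat <- rbind(g$mat, matrix(row, nrow = 1, dimnames = list(hyb, NULL)))
      } else if (event$mode == "mosaic") {
        donors[k] <- if (stats::runif(1) < event$maternal_locus_fraction) {
          event$maternal_parent
        } else {
          event$paternal_parent
        }
        row <- mutate_sequence(g$mat[donors[k], ], event$post_hybrid_branch)
        g$mat <- rbind(g$mat, matrix(row, nrow = 1, dimnames = list(hyb, NULL)))
      } else {  # F1: two alleles per nuclear locus, emitted as clone records
        donors[k] <- "both"
        al <- rbind(mutate_sequence(g$mat[event$maternal_parent, ],
                                    event$post_hybrid_branch),
                    mutate_sequence(g$mat[event$paternal_parent, ],
                                    event$post_hybrid_branch))
        rownames(al) <- paste0(hyb, "_clone", 1:2)
        attr(al, "donors") <- parents
        clones[[g$gene_name]] <- al
      }
      alignments[[k]] <- g
    }
  })
  truth <- list(species_tree = tree, event = event,
                locus_donors = data.frame(
                  gene = names(donors),
                  genome = vapply(alignments, `[[`, character(1), "genome"),
                  donor = unname(donors), stringsAsFactors = FALSE))
  list(alignments = alignments, clones = clones, truth = truth)
}

#' Prune a clade and regraft it as sister to another taxon
#'
#' Models an ancient cytonuclear transfer: the returned copy of the species
#' tree, used as the generating tree for the mitochondrial partition,
#' carries the clade next to `attachment`, creating known-truth discordance
#' with the nuclear genome.
#'
#' @param tree Rooted `phylo`.
#' @param clade Character vector of leaf labels; must be monophyletic.
#' @param attachment Leaf label outside the clade to become its sister.
#' @return A `phylo` with the identical leaf set and the clade relocated.
#' @export
inject_cytonuclear_transfer <- function(tree, clade, attachment) {
  if (!all(clade %in% tree$tip.label)) stop("clade taxa not in tree")
  if (!(attachment %in% tree$tip.label)) stop("attachment not in tree")
  if (attachment %in% clade) stop("attachment must lie outside the clade")
  if (length(clade) > 1L) {
    mrca <- ape::getMRCA(tree, clade)
    below <- ape::extract.clade(tree, mrca)$tip.label
    if (!setequal(below, clade)) {
      stop("clade is not monophyletic (subtends ",
           paste(sort(below), collapse = ", "), ")")
    }
  }
  backbone <- ape::drop.tip(tree, clade)
  at <- which(backbone$tip.label == attachment)
  el <- backbone$edge.length[backbone$edge[, 2L] == at]
  if (length(clade) == 1L) {
    out <- phytools::bind.tip(backbone, clade, edge.length = el / 2,
                              where = at, position = el / 2)
  } else {
    sub <- ape::keep.tip(tree, clade)
    sub$root.edge <- el / 2
    out <- ape::bind.tree(backbone, sub, where = at, position = el / 2)
  }
  out
}

#' Write the ground-truth table of a simulated dataset
#'
#' @param truth Truth list from [inject_hybrid()].
#' @param path Output TSV path.
#' @export
write_truth_table <- function(truth, path) {
  df <- truth$locus_donors
  df$hybrid <- truth$event$hybrid_label
  df$maternal <- truth$event$maternal_parent
  df$paternal <- truth$event$paternal_parent
  df$mode <- truth$event$mode
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
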