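# End-to-end orchestration: simulate -> infer -> discord -> het -> place.
# Every stage consumes and produces plain files under the run directory, so
# stages are independently testable and resumable; a manifest records the
# seed, the configuration and the md5 digest of every output file.  All
# randomness derives from the single top-level seed via named substreams.

#' Pipeline run configuration
#'
#' @param out_dir Run directory (created if needed).
#' @param stages Subset of `c("simulate", "infer", "discord", "het",
#'   "place")`, run in dependency order.
#' @param sim A [sim_spec()] for the synthetic dataset.
#' @param hybrid Optional [hybrid_event()] of mode `"mosaic"`, injected
#'   into the alignments (the ancient-hybrid scenario the homoplasy excess
#'   test targets).
#' @param clone_hybrid Optional [hybrid_event()] of mode `"F1"` providing a
#'   recent-hybrid individual with cloned alleles for the placement stage.
#' @param transfer Optional `list(clade =, attachment =)` cytonuclear
#'   transfer regrafting the mito genealogy.
#' @param het A [het_config()] (its seed is overridden by `seed`).
#' @param placement A [placement_config()] (seed likewise overridden).
#' @param min_support Discordance support threshold.
#' @param root Leaf used to root trees in reports (default: first taxon).
#' @param seed Top-level integer seed.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "infer", "discord", "het",
                                  "place"),
                       sim = sim_spec(n_taxa = 16, gene_length = 500),
                       hybrid = NULL, clone_hybrid = NULL, transfer = NULL,
                       het = het_config(n_boot = 50, n_null = 20,
                                        max_group_size = 1,
                                        shared_null = TRUE),
                       placement = placement_config(n_boot = 50),
                       min_support = 95, root = NULL, seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(hybrid) && hybrid$mode != "mosaic") {
    stop("`hybrid` must be a mosaic event (use `clone_hybrid` for F1)")
  }
  if (!is.null(clone_hybrid) && clone_hybrid$mode != "F1") {
    stop("`clone_hybrid` must be an F1 event")
  }
  structure(list(out_dir = out_dir, stages = stages, sim = sim,
                 hybrid = hybrid, clone_hybrid = clone_hybrid,
                 transfer = transfer, het = het, placement = placement,
                 min_support = min_support, root = root,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Stages run in dependency order, each reading its inputs from and writing
#' its reports to the run directory; `manifest.json` records the seed and
#' the md5 digest of every file written, so two runs with the same
#' configuration and seed are verifiably identical.
#'
#' @param config A [run_config()].
#' @return The manifest (invisibly), as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log <- file.path(out, "pipeline.log")
  cat(sprintf("seed\t%d\nstages\t%s\n", config$seed,
              paste(config$stages, collapse = ",")), file = log)
  note <- function(...) cat(sprintf(...), file = log, append = TRUE)
  add <- function(p) written <<- c(written, p)

  if ("simulate" %in% config$stages) {
    note("stage\tsimulate\tseed\t%d\n", derive_seed(config$seed, "simulate"))
    spec <- config$sim
    spec$seed <- derive_seed(config$seed, "simulate")
    tree <- simulate_species_tree(spec)
    mito_tree <- NULL
    if (!is.null(config$transfer)) {
      mito_tree <- inject_cytonuclear_transfer(tree, config$transfer$clade,
                                               config$transfer$attachment)
      ape::write.tree(mito_tree, file.path(out, "truth_mito_tree.nwk"))
      add(file.path(out, "truth_mito_tree.nwk"))
    }
    aln <- simulate_alignments(tree, spec, mito_tree = mito_tree)
    if (!is.null(config$hybrid)) {
      inj <- inject_hybrid(aln, tree, config$hybrid,
                           seed = derive_seed(config$seed, "hybrid"))
      aln <- inj$alignments
      write_truth_table(inj$truth, file.path(out, "truth_hybrid.tsv"))
      add(file.path(out, "truth_hybrid.tsv"))
    }
    if (!is.null(config$clone_hybrid)) {
      f1 <- inject_hybrid(aln, tree, config$clone_hybrid,
                          seed = derive_seed(config$seed, "clone_hybrid"))
      dir.create(file.path(out, "clones"), showWarnings = FALSE)
      for (g in names(f1$clones)) {
        p <- file.path(out, "clones", paste0(g, ".fasta"))
        write_fasta(f1$clones[[g]], p)
        add(p)
      }
      # the F1 individual's mito sequences (maternal copies)
      hyb <- config$clone_hybrid$hybrid_label
      for (g in names(f1$alignments)) {
        a <- f1$alignments[[g]]
        if (a$genome == "mito" && hyb %in% rownames(a$mat)) {
          p <- file.path(out, "clones", paste0(g, "_mito.fasta"))
          write_fasta(a$mat[hyb, , drop = FALSE], p)
          add(p)
        }
      }
    }
    dir.create(file.path(out, "alignments"), showWarnings = FALSE)
    genomes <- character(0)
    for (g in names(aln)) {
      p <- file.path(out, "alignments", paste0(g, ".fasta"))
      write_fasta(aln[[g]], p)
      add(p)
      genomes[g] <- aln[[g]]$genome
    }
    writeLines(paste(names(genomes), genomes, sep = "\t"),
               file.path(out, "alignments", "genomes.tsv"))
    add(file.path(out, "alignments", "genomes.tsv"))
    ape::write.tree(tree, file.path(out, "truth_species_tree.nwk"))
    add(file.path(out, "truth_species_tree.nwk"))
  }

  read_genes <- function() {
    gtab <- utils::read.table(file.path(out, "alignments", "genomes.tsv"),
                              sep = "\t", stringsAsFactors = FALSE,
                              col.names = c("gene", "genome"))
    lapply(seq_len(nrow(gtab)), function(i) {
      read_gene_alignment(file.path(out, "alignments",
                                    paste0(gtab$gene[i], ".fasta")),
                          format = "fasta", gene_name = gtab$gene[i],
                          genome = gtab$genome[i])
    })
  }

  if ("infer" %in% config$stages) {
    note("stage\tinfer\tseed\t%d\n", derive_seed(config$seed, "infer"))
    genes <- read_genes()
    genomes <- vapply(genes, `[[`, character(1), "genome")
    for (gen in unique(genomes)) {
      sm <- concatenate(genes[genomes == gen])
      write_phylip(sm, file.path(out, paste0(gen, ".phy")))
      write_partition_file(sm$partitions, file.path(out, paste0(gen, ".part")))
      add(file.path(out, paste0(gen, ".phy")))
      add(file.path(out, paste0(gen, ".part")))
      cons <- bootstrap_consensus(sm, n_reps = config$het$n_boot,
                                  backend = config$het$backend,
                                  seed = derive_seed(config$seed,
                                                     paste0("infer.", gen)))
      ape::write.tree(cons, file.path(out, paste0(gen, "_consensus.nwk")))
      add(file.path(out, paste0(gen, "_consensus.nwk")))
    }
  }

  if ("discord" %in% config$stages) {
    nf <- file.path(out, "nuclear_consensus.nwk")
    mf <- file.path(out, "mito_consensus.nwk")
    if (!file.exists(nf) || !file.exists(mf)) {
      stop("discord stage requires the infer stage outputs")
    }
    ntree <- ape::read.tree(nf)
    mtree <- ape::read.tree(mf)
    shared <- intersect(ntree$tip.label, mtree$tip.label)
    rep <- compare_trees(ntree, mtree, min_support = config$min_support,
                         root = config$root %||% sort(shared)[1])
    write_discordance_report(rep, file.path(out, "discordance"))
    add(list.files(file.path(out, "discordance"), full.names = TRUE))
    note("stage\tdiscord\trf\t%d\n", rep$rf)
  }

  if ("het" %in% config$stages) {
    phy <- file.path(out, "nuclear.phy")
    if (!file.exists(phy)) stop("het stage requires the infer stage outputs")
    mat <- ape::read.dna(phy, format = "sequential", as.character = TRUE)
    mat <- toupper(mat)
    parts <- read_partition_file(file.path(out, "nuclear.part"))
    sm <- supermatrix_from_matrix(mat, parts)
    reference <- ape::read.tree(file.path(out, "nuclear_consensus.nwk"))
    hc <- config$het
    hc$seed <- derive_seed(config$seed, "het")
    res <- run_het(sm, reference, hc)
    write_het_result(res, file.path(out, "het"))
    add(list.files(file.path(out, "het"), full.names = TRUE))
    note("stage\thet\tflagged\t%d\n", nrow(res$flagged))
  }

  if ("place" %in% config$stages && !is.null(config$clone_hybrid)) {
    genes <- read_genes()
    hyb <- config$clone_hybrid$hybrid_label
    # reference excludes any injected mosaic hybrid and the F1 individual
    drop <- c(hyb, if (!is.null(config$hybrid)) config$hybrid$hybrid_label)
    genes <- lapply(genes, function(g) {
      g$mat <- g$mat[setdiff(rownames(g$mat), drop), , drop = FALSE]
      g
    })
    ref_sm <- concatenate(genes)
    cdir <- file.path(out, "clones")
    nuc_files <- list.files(cdir, pattern = "^nuc.*\\.fasta$")
    mit_files <- list.files(cdir, pattern = "_mito\\.fasta$")
    nuclear <- list()
    for (f in nuc_files) {
      g <- sub("\\.fasta$", "", f)
      a <- read_gene_alignment(file.path(cdir, f), "fasta", gene_name = g)
      nuclear[[g]] <- a$mat
    }
    mito <- list()
    for (f in mit_files) {
      g <- sub("_mito\\.fasta$", "", f)
      a <- read_gene_alignment(file.path(cdir, f), "fasta", gene_name = g)
      mito[[g]] <- a$mat[1, ]
    }
    cs <- clone_set(hyb, mito = mito, nuclear = nuclear)
    pc <- config$placement
    pc$seed <- derive_seed(config$seed, "place")
    pc$root <- pc$root %||% config$root %||% ref_sm$taxa[1]
    pa <- assign_parents(cs, ref_sm, pc)
    write_parent_assignment(pa, file.path(out, "parent_assignment.json"))
    add(file.path(out, "parent_assignment.json"))
    add(file.path(out, "parent_assignment_clones.tsv"))
    note("stage\tplace\tmaternal\t%s\n",
         paste(pa$maternal$lineage, collapse = "+"))
  }

  written <- sort(unique(unlist(written)))
  manifest <- list(
    package = "phyloHET",
    version = as.character(utils::packageVersion("phyloHET")),
    seed = config$seed,
    stages = config$stages,
    files = as.list(unname(vapply(written, function(p) {
      unname(tools::md5sum(p))
    }, character(1)))),
    paths = as.list(sub(paste0("^", out, "/?"), "", written)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
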