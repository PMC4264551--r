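# Fixtures are built in code: tiny gene alignments with hand-set sequences
# and seeded simulations small enough for fast unit tests.

toy_gene <- function(gene_name = "g1", genome = "nuclear",
                     seqs = c(A = "ACGTACGTAC", B = "ACGTACGTAT",
                              C = "ACGAACGTAC")) {
  mat <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- names(seqs)
  gene_alignment(gene_name, mat, genome = genome)
}

toy_supermatrix <- function() {
  concatenate(list(
    toy_gene("g1"),
    toy_gene("g2", seqs = c(A = "TTTT", B = "TTTA", C = "TATT"))))
}

# A small simulated dataset with strong signal, shared across tests.
small_sim <- function(seed = 11, n_taxa = 8, n_nuclear = 3, n_mito = 2,
                      gene_length = 400) {
  spec <- sim_spec(n_taxa = n_taxa, n_nuclear_genes = n_nuclear,
                   n_mito_genes = n_mito, gene_length = gene_length,
                   seed = seed)
  tree <- simulate_species_tree(spec)
  aln <- simulate_alignments(tree, spec)
  list(spec = spec, tree = tree, aln = aln, sm = concatenate(aln))
}

# Random resolved topology with comfortable branch lengths.
random_tree <- function(n, seed) {
  phyloHET:::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 0.3)
    tr$tip.label <- sprintf("T%02d", seq_len(n))
    tr
  })
}

write_tmp_fasta <- function(seqs, dir = tempdir()) {
  path <- tempfile("aln", tmpdir = dir, fileext = ".fasta")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  path
}
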