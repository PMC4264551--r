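test_that("FASTA reading validates and normalises sequences", {
  p <- write_tmp_fasta(list(t1 = "acgtacgtac", t2 = "ACGUACGUAC"))
  g <- read_gene_alignment(p, "fasta")
  expect_s3_class(g, "gene_alignment")
  expect_equal(dim(g$mat), c(2L, 10L))
  expect_identical(paste(g$mat["t1", ], collapse = ""), "ACGTACGTAC")
  # U mapped to T
  expect_identical(paste(g$mat["t2", ], collapse = ""), "ACGTACGTAC")

  ragged <- write_tmp_fasta(list(t1 = "ACGTACGTAC", t2 = "ACGTACGTA"))
  expect_error(read_gene_alignment(ragged, "fasta"), "t2")

  dup <- write_tmp_fasta(list(t1 = "ACGT", t1 = "ACGT"))
  expect_error(read_gene_alignment(dup, "fasta"), "duplicate")
})

test_that("phylip and fasta writers round-trip through the readers", {
  g <- toy_gene()
  fp <- tempfile(fileext = ".fasta")
  write_fasta(g, fp)
  expect_identical(read_gene_alignment(fp, "fasta", gene_name = "g1")$mat,
                   g$mat)
  pp <- tempfile(fileext = ".phy")
  write_phylip(g, pp)
  expect_identical(read_gene_alignment(pp, "phylip", gene_name = "g1")$mat,
                   g$mat)
})

test_that("concatenation records partitions and pads missing taxa", {
  g1 <- toy_gene("g1", seqs = c(A = "ACG", B = "AGG", C = "ATG"))
  g2 <- toy_gene("g2", seqs = c(A = "TTTT", B = "TGTT"))  # C missing
  sm <- concatenate(list(g1, g2))
  expect_equal(ncol(sm$mat), 7L)
  expect_equal(sm$partitions$start, c(0L, 3L))
  expect_equal(sm$partitions$end, c(3L, 7L))
  expect_identical(paste(sm$mat["C", 4:7], collapse = ""), "????")
  expect_error(concatenate(list()), "empty")

  # round trip: extracting each partition recovers the inputs
  expect_identical(extract_partition(sm, "g1")$mat, g1$mat)
  expect_identical(extract_partition(sm, "g2")$mat, g2$mat)
})

test_that("seven genes at the study's lengths give a 6,679 bp supermatrix", {
  lens <- c(954, 954, 954, 954, 954, 954, 955)
  genes <- lapply(seq_along(lens), function(i) {
    mat <- matrix("A", nrow = 4, ncol = lens[i],
                  dimnames = list(c("a", "b", "c", "d"), NULL))
    gene_alignment(paste0("g", i), mat)
  })
  expect_equal(ncol(concatenate(genes)$mat), 6679L)
})

test_that("taxon removal preserves width and guards the minimum", {
  sim <- small_sim()
  sm <- sim$sm
  expect_identical(remove_taxa(sm, character(0)), sm)
  red <- remove_taxa(sm, sm$taxa[1])
  expect_equal(length(red$taxa), length(sm$taxa) - 1L)
  expect_equal(ncol(red$mat), ncol(sm$mat))
  expect_identical(red$partitions, sm$partitions)
  expect_error(remove_taxa(sm, sm$taxa[1:5]), "at least 4")
  expect_error(remove_taxa(sm, "nope"), "unknown")
})

test_that("bootstrap resampling stays within partitions and is seeded", {
  # distinct symbols per partition: resampled columns must keep provenance
  g1 <- toy_gene("g1", seqs = c(A = "AAAA", B = "AAAA"))
  g2 <- toy_gene("g2", seqs = c(A = "CCC", B = "CCC"))
  g3 <- toy_gene("g3", seqs = c(A = "G", B = "G"))  # single column
  sm <- concatenate(list(g1, g2, g3))
  bs <- bootstrap_resample(sm, seed = 5)
  expect_identical(bs$mat[, 1:4], sm$mat[, 1:4])
  expect_identical(bs$mat[, 5:7], sm$mat[, 5:7])
  expect_identical(bs$mat[, 8], sm$mat[, 8])
  expect_equal(ncol(bs$mat), ncol(sm$mat))
  sim <- small_sim()
  b1 <- bootstrap_resample(sim$sm, seed = 9)
  b2 <- bootstrap_resample(sim$sm, seed = 9)
  expect_identical(b1$mat, b2$mat)
  expect_false(identical(bootstrap_resample(sim$sm, seed = 10)$mat, b1$mat))
})

test_that("partition files round-trip in the RAxML dialect", {
  sim <- small_sim()
  path <- tempfile(fileext = ".part")
  write_partition_file(sim$sm$partitions, path)
  lines <- readLines(path)
  expect_match(lines[1], "^DNA, nuc1 = 1-400$")
  back <- read_partition_file(path, genomes = c(mit1 = "mito", mit2 = "mito"))
  expect_equal(back$start, sim$sm$partitions$start)
  expect_equal(back$end, sim$sm$partitions$end)
  expect_equal(back$genome, sim$sm$partitions$genome)
  sm2 <- supermatrix_from_matrix(sim$sm$mat, back)
  expect_identical(sm2$mat, sim$sm$mat)
  expect_error(supermatrix_from_matrix(sim$sm$mat, back[-1, ]), "tile")
})
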