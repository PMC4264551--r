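# Multilocus alignment containers and I/O.
#
# A gene_alignment is one aligned locus; a supermatrix is the concatenation
# of several loci with a gene -> column partition map.  Internally the
# partition intervals are 0-based half-open; the on-disk partition file uses
# the 1-based inclusive RAxML dialect ("DNA, gene1 = 1-954").  '?' denotes a
# missing gene x taxon cell, '-' an alignment gap.

VALID_SYMBOLS <- c("A", "C", "G", "T", "-", "N", "?")

normalise_seq_matrix <- function(mat) {
  mat[] <- toupper(mat)
  mat[mat == "U"] <- "T"
  bad <- setdiff(unique(as.vector(mat)), VALID_SYMBOLS)
  if (length(bad)) {
    # degenerate IUPAC codes are tolerated as missing information
    mat[mat %in% bad] <- "N"
  }
  mat
}

#' Construct a single-gene alignment
#'
#' @param gene_name Gene identifier.
#' @param mat Character matrix of aligned sequences (rows = taxa, rownames
#'   give the taxon labels; columns = sites).  Symbols are uppercased and
#'   `U` is mapped to `T`.
#' @param genome `"nuclear"` or `"mito"`.
#' @return Object of class `"gene_alignment"`.
#' @export
gene_alignment <- function(gene_name, mat, genome = c("nuclear", "mito")) {
  genome <- match.arg(genome)
  if (is.null(rownames(mat))) stop("sequence matrix must have taxon rownames")
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate taxon name: ",
         rownames(mat)[duplicated(rownames(mat))][1])
  }
  mat <- normalise_seq_matrix(mat)
  structure(list(gene_name = gene_name, genome = genome, mat = mat),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("gene_alignment '%s' (%s): %d taxa x %d bp\n",
              x$gene_name, x$genome, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Read a single-gene alignment from file
#'
#' @param path File path.
#' @param format `"fasta"`, `"phylip"` (relaxed names) or `"nexus"`.
#' @param gene_name Gene identifier (default: file base name).
#' @param genome Genome flag for the partition map.
#' @return A [gene_alignment()].
#' @export
read_gene_alignment <- function(path, format = c("fasta", "phylip", "nexus"),
                                gene_name = NULL, genome = "nuclear") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gene_name <- gene_name %||% sub("\\.[^.]*$", "", basename(path))
  seqs <- switch(format,
    fasta = {
      x <- seqinr::read.fasta(path, seqtype = "DNA",
                              forceDNAtolower = FALSE)
      lapply(x, function(s) toupper(as.character(s)))
    },
    phylip = {
      x <- ape::read.dna(path, format = "sequential", as.character = TRUE)
      stats::setNames(lapply(seq_len(nrow(x)), function(i) toupper(x[i, ])),
                      rownames(x))
    },
    nexus = {
      x <- ape::read.nexus.data(path)
      lapply(x, toupper)
    })
  if (!length(seqs)) stop("no sequences in ", path)
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1L) {
    off <- names(seqs)[which(lens != lens[1])[1]]
    stop("ragged alignment in ", path, ": taxon '", off,
         "' has length ", lens[[off]], " (expected ", lens[1], ")")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate taxon name in ", path, ": ",
         names(seqs)[duplicated(names(seqs))][1])
  }
  mat <- do.call(rbind, seqs)
  rownames(mat) <- names(seqs)
  gene_alignment(gene_name, mat, genome = genome)
}

#' Write an alignment to FASTA
#'
#' @param mat Character matrix (rows = taxa) or a [gene_alignment()].
#' @param path Output path.
#' @export
write_fasta <- function(mat, path) {
  if (inherits(mat, "gene_alignment")) mat <- mat$mat
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(mat))) {
    writeLines(c(paste0(">", rownames(mat)[i]),
                 paste(mat[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Write an alignment in relaxed PHYLIP format
#'
#' @inheritParams write_fasta
#' @export
write_phylip <- function(mat, path) {
  if (inherits(mat, "gene_alignment")) mat <- mat$mat
  if (inherits(mat, "supermatrix")) mat <- mat$mat
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(rownames(mat)[i], paste(mat[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Taxa are the union over genes; a taxon absent from a gene is padded with
#' `'?'` over that gene's columns.  Partition intervals are recorded in the
#' input gene order (0-based half-open internally).
#'
#' @param genes List of [gene_alignment()] objects.
#' @return Object of class `"supermatrix"` with elements `taxa`, `mat`
#'   (character matrix) and `partitions` (data frame with `gene`, `start`,
#'   `end`, `genome`).
#' @export
concatenate <- function(genes) {
  if (!length(genes)) stop("empty gene list")
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_alignment")))
  nm <- vapply(genes, `[[`, character(1), "gene_name")
  if (anyDuplicated(nm)) stop("duplicate gene name: ", nm[duplicated(nm)][1])
  taxa <- Reduce(union, lapply(genes, function(g) rownames(g$mat)))
  lens <- vapply(genes, function(g) ncol(g$mat), integer(1))
  total <- sum(lens)
  mat <- matrix("?", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  start <- cumsum(c(0L, lens[-length(lens)]))
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    cols <- (start[k] + 1L):(start[k] + lens[k])
    mat[rownames(g$mat), cols] <- g$mat
  }
  partitions <- data.frame(
    gene = nm, start = start, end = start + lens,
    genome = vapply(genes, `[[`, character(1), "genome"),
    stringsAsFactors = FALSE)
  structure(list(taxa = taxa, mat = mat, partitions = partitions),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d bp, %d partitions (%s)\n",
              length(x$taxa), ncol(x$mat), nrow(x$partitions),
              paste(x$partitions$gene, collapse = ", ")))
  invisible(x)
}

#' Extract one partition of a supermatrix as a gene alignment
#'
#' @param sm A [concatenate()] supermatrix.
#' @param gene Gene name.
#' @param drop_missing Drop taxa whose block is entirely `'?'` padding.
#' @return A [gene_alignment()].
#' @export
extract_partition <- function(sm, gene, drop_missing = TRUE) {
  p <- sm$partitions[sm$partitions$gene == gene, ]
  if (!nrow(p)) stop("unknown gene: ", gene)
  cols <- (p$start + 1L):p$end
  block <- sm$mat[, cols, drop = FALSE]
  if (drop_missing) {
    keep <- rowSums(block != "?") > 0L
    block <- block[keep, , drop = FALSE]
  }
  gene_alignment(gene, block, genome = p$genome)
}

#' Remove taxa from a supermatrix
#'
#' @param sm A supermatrix.
#' @param removal Character vector of taxa to drop (may be empty).
#' @return A new supermatrix; the input is untouched and the partition map
#'   is unchanged.
#' @export
remove_taxa <- function(sm, removal) {
  stopifnot(inherits(sm, "supermatrix"))
  if (!length(removal)) return(sm)
  unknown <- setdiff(removal, sm$taxa)
  if (length(unknown)) stop("unknown taxon: ", paste(unknown, collapse = ", "))
  keep <- setdiff(sm$taxa, removal)
  if (length(keep) < 4L) {
    stop("removal would leave ", length(keep), " taxa; at least 4 required")
  }
  sm$taxa <- keep
  sm$mat <- sm$mat[keep, , drop = FALSE]
  sm
}

#' Bootstrap-resample the columns of a supermatrix
#'
#' Columns are resampled with replacement independently within each
#' partition, so every gene contributes exactly its own length and the
#' partition structure is preserved.
#'
#' @param sm A supermatrix.
#' @param seed Integer seed (resampling is deterministic given the seed).
#' @param scope `"partition"` (default) resamples within genes;
#'   `"global"` resamples across the whole matrix while keeping the
#'   partition map (columns are drawn from anywhere).
#' @return A resampled supermatrix of identical dimensions.
#' @export
bootstrap_resample <- function(sm, seed, scope = c("partition", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(sm, "supermatrix"))
  cols <- with_seed(seed, draw_bootstrap_columns(sm$partitions, ncol(sm$mat), scope))
  sm$mat <- sm$mat[, cols, drop = FALSE]
  sm
}

# Draw resampled column indices using the current RNG stream.
draw_bootstrap_columns <- function(partitions, total, scope = "partition") {
  if (scope == "global") return(sample.int(total, total, replace = TRUE))
  cols <- integer(total)
  for (k in seq_len(nrow(partitions))) {
    s <- partitions$start[k]
    len <- partitions$end[k] - s
    cols[(s + 1L):(s + len)] <- s + sample.int(len, len, replace = TRUE)
  }
  cols
}

#' Write a partition table in the RAxML text dialect
#'
#' One line per gene: `DNA, <name> = <start>-<end>` with 1-based inclusive
#' coordinates.
#'
#' @param partitions Partition data frame of a supermatrix.
#' @param path Output path.
#' @export
write_partition_file <- function(partitions, path) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$gene,
                     partitions$start + 1L, partitions$end), path)
  invisible(path)
}

#' Read a RAxML-dialect partition table
#'
#' @param path File path.
#' @param genomes Optional named character vector mapping gene names to
#'   `"nuclear"`/`"mito"`; unnamed genes default to nuclear.
#' @return Partition data frame (0-based half-open intervals).
#' @export
read_partition_file <- function(path, genomes = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^DNA,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)$", lines))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) stop("unparseable partition line: '", lines[bad[1]], "'")
  gene <- vapply(m, `[`, character(1), 2)
  start <- as.integer(vapply(m, `[`, character(1), 3)) - 1L
  end <- as.integer(vapply(m, `[`, character(1), 4))
  genome <- rep("nuclear", length(gene))
  if (!is.null(genomes)) {
    hit <- match(gene, names(genomes))
    genome[!is.na(hit)] <- unname(genomes[hit[!is.na(hit)]])
  }
  data.frame(gene = gene, start = start, end = end, genome = genome,
             stringsAsFactors = FALSE)
}

#' Assemble a supermatrix from a sequence matrix and a partition table
#'
#' @param mat Character matrix (rows = taxa).
#' @param partitions Partition data frame (as from [read_partition_file()]).
#' @return A supermatrix.
#' @export
supermatrix_from_matrix <- function(mat, partitions) {
  stopifnot(!is.null(rownames(mat)))
  if (nrow(partitions)) {
    ord <- order(partitions$start)
    partitions <- partitions[ord, , drop = FALSE]
    rownames(partitions) <- NULL
    gaps <- c(partitions$start[1] != 0L,
              partitions$start[-1] != partitions$end[-nrow(partitions)],
              partitions$end[nrow(partitions)] != ncol(mat))
    if (any(gaps)) stop("partitions do not tile the alignment columns")
  }
  mat <- normalise_seq_matrix(mat)
  structure(list(taxa = rownames(mat), mat = mat, partitions = partitions),
            class = "supermatrix")
}
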