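# Pairwise distances and the fast bootstrap kernel.
#
# Public distances go through ape::dist.dna with pairwise deletion.  The
# internal kernel precomputes, for every taxon pair, a per-site mismatch
# indicator restricted to variable sites; a bootstrap replicate (columns
# resampled within partitions) is then just a multinomial weight vector, and
# all pairwise p-distances fall out of one matrix product.  This makes the
# thousands of replicate trees needed by the homoplasy excess test tractable
# at desk scale.

JC69_CAP <- 10  # substitutions/site assigned to saturated pairs (p >= 3/4)

#' Pairwise distances from a supermatrix
#'
#' Computes pairwise distances with pairwise deletion of `-`/`?`/`N` sites.
#' Under JC69 the distance is \eqn{-\frac{3}{4}\ln(1 - \frac{4}{3}p)};
#' saturated pairs (\eqn{p \ge 3/4}) are capped at a large finite value so
#' downstream agglomeration stays well defined.
#'
#' @param sm A supermatrix (or a plain character matrix with rownames).
#' @param model `"JC69"`, `"p"` (raw proportion) or `"K2P"`.
#' @return Object of class `"distance_matrix"`: list with `taxa`, `d`
#'   (symmetric numeric matrix, zero diagonal) and `model`.
#' @export
pairwise_distances <- function(sm, model = c("JC69", "p", "K2P")) {
  model <- match.arg(model)
  mat <- if (inherits(sm, "supermatrix")) sm$mat else sm
  if (nrow(mat) < 2L) stop("at least 2 taxa required")
  # pairwise-deletion overlap check
  present <- matrix(as.numeric(!(mat %in% c("-", "?", "N"))), nrow = nrow(mat))
  ov <- tcrossprod(present)
  diag(ov) <- 1
  if (any(ov == 0)) {
    ij <- which(ov == 0, arr.ind = TRUE)[1, ]
    stop("no comparable sites between '", rownames(mat)[ij[1]], "' and '",
         rownames(mat)[ij[2]], "'")
  }
  dna <- ape::as.DNAbin(tolower(mat))
  mdl <- c(JC69 = "JC69", p = "raw", K2P = "K80")[[model]]
  d <- as.matrix(ape::dist.dna(dna, model = mdl, pairwise.deletion = TRUE))
  if (any(!is.finite(d))) {
    warning("saturated pairs (p >= 3/4); distance capped at ", JC69_CAP)
    d[!is.finite(d)] <- JC69_CAP
  }
  d <- d[rownames(mat), rownames(mat)]
  structure(list(taxa = rownames(mat), d = d, model = model),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s): %d taxa\n", x$model, length(x$taxa)))
  invisible(x)
}

## ---- internal kernel ---------------------------------------------------

# Precompute pair-level site statistics for fast bootstrap distances.
sm_pattern_stats <- function(sm) {
  mat <- sm$mat
  n <- nrow(mat)
  L <- ncol(mat)
  code <- matrix(match(mat, c("A", "C", "G", "T")), nrow = n)
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  # mismatch indicator per pair, restricted to sites where any pair differs
  present <- !is.na(code)
  any_missing <- colSums(present) < n
  # variable sites: >= 2 distinct observed states
  nstates <- apply(code, 2L, function(x) length(unique(x[!is.na(x)])))
  var_sites <- which(nstates >= 2L)
  M <- matrix(0, nrow = length(var_sites), ncol = np)
  for (p in seq_len(np)) {
    xi <- code[pairs[1L, p], var_sites]
    xj <- code[pairs[2L, p], var_sites]
    d <- xi != xj
    d[is.na(d)] <- FALSE
    M[, p] <- as.numeric(d)
  }
  miss_sites <- which(any_missing)
  Miss <- matrix(0, nrow = length(miss_sites), ncol = np)
  if (length(miss_sites)) {
    for (p in seq_len(np)) {
      Miss[, p] <- as.numeric(!(present[pairs[1L, p], miss_sites] &
                                  present[pairs[2L, p], miss_sites]))
    }
  }
  list(taxa = sm$taxa, n = n, L = L, partitions = sm$partitions,
       pairs = pairs, np = np,
       var_sites = var_sites, M = M,
       miss_sites = miss_sites, Miss = Miss)
}

# Pairwise p-distances under column weights `w` (length L); w = 1 gives the
# observed distances.  Returns a vector aligned with stats$pairs columns.
kernel_pdist <- function(stats, w, pair_cols = NULL) {
  M <- stats$M
  Miss <- stats$Miss
  if (!is.null(pair_cols)) {
    M <- M[, pair_cols, drop = FALSE]
    Miss <- Miss[, pair_cols, drop = FALSE]
  }
  mism <- as.vector(crossprod(w[stats$var_sites], M))
  ncomp <- rep(sum(w), ncol(M))
  if (length(stats$miss_sites)) {
    ncomp <- ncomp - as.vector(crossprod(w[stats$miss_sites], Miss))
  }
  if (any(ncomp <= 0)) stop("a pair has no comparable sites in a replicate")
  mism / ncomp
}

p_to_jc69 <- function(p) {
  d <- suppressWarnings(-0.75 * log(1 - 4 * p / 3))
  d[!is.finite(d) | p >= 0.75] <- JC69_CAP
  d
}

# Assemble a full symmetric matrix over the surviving taxa from the pair
# vector.  `surv` is an integer index vector into stats$taxa.
kernel_dist_matrix <- function(stats, pvec, surv, pair_cols, model = "JC69") {
  d <- if (model == "JC69") p_to_jc69(pvec) else pvec
  ns <- length(surv)
  m <- matrix(0, ns, ns, dimnames = list(stats$taxa[surv], stats$taxa[surv]))
  pos <- match(stats$pairs[1L, pair_cols], surv)
  pos2 <- match(stats$pairs[2L, pair_cols], surv)
  m[cbind(pos, pos2)] <- d
  m[cbind(pos2, pos)] <- d
  m
}

# Columns of stats$pairs whose both endpoints are in `surv`.
surviving_pair_cols <- function(stats, surv) {
  keep <- logical(stats$n)
  keep[surv] <- TRUE
  which(keep[stats$pairs[1L, ]] & keep[stats$pairs[2L, ]])
}
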