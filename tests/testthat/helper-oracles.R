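# Independent oracles used by unit and acceptance tests.  Each reimplements
# the checked rule from scratch on a different representation from the
# implementation under test.

# Brute-force extended majority-rule consensus: splits named by sorted
# tip-label strings (canonical side = the side not containing the
# alphabetically first taxon), counted with table(), greedily accepted by a
# label-set compatibility check.  Returns data frame (split, freq).
oracle_consensus_splits <- function(trees, extended = TRUE) {
  taxa <- sort(trees[[1]]$tip.label)
  lab_splits <- function(tree) {
    pp <- ape::prop.part(tree)
    labs <- attr(pp, "labels")
    out <- character(0)
    for (cl in pp) {
      side <- sort(labs[cl])
      if (taxa[1] %in% side) side <- sort(setdiff(taxa, side))
      if (length(side) < 2 || length(side) > length(taxa) - 2) next
      out <- c(out, paste(side, collapse = "|"))
    }
    unique(out)
  }
  tab <- table(unlist(lapply(trees, lab_splits)))
  freq <- 100 * as.numeric(tab) / length(trees)
  df <- data.frame(split = names(tab), freq = freq, stringsAsFactors = FALSE)
  df <- df[order(-df$freq, df$split), ]
  compat <- function(a, b) {
    sa <- strsplit(a, "|", fixed = TRUE)[[1]]
    sb <- strsplit(b, "|", fixed = TRUE)[[1]]
    ov <- length(intersect(sa, sb))
    ov == 0 || ov == length(sa) || ov == length(sb)
  }
  keep <- df$freq > 50
  if (extended) {
    for (k in which(!keep)) {
      if (all(vapply(which(keep), function(a) compat(df$split[a], df$split[k]),
                     logical(1)))) {
        keep[k] <- TRUE
      }
    }
  }
  out <- df[keep, ]
  rownames(out) <- NULL
  out
}

# Split set of a tree in the oracle's label representation.
oracle_tree_splits <- function(tree) {
  oracle_consensus_splits(list(tree))$split
}

# Sort-and-scan upper-fence outlier oracle: quartiles from fivenum()
# (Tukey hinges), fence = Q3 + 1.5 IQR, whisker found by scanning the
# sorted sample from above.
oracle_outlier <- function(observed, null) {
  fn <- stats::fivenum(null)
  fence <- fn[4] + 1.5 * (fn[4] - fn[2])
  x <- sort(null, decreasing = TRUE)
  whisker <- NA_real_
  for (v in x) {
    if (v <= fence) {
      whisker <- v
      break
    }
  }
  list(whisker = whisker, outlier = observed > whisker)
}
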