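#' Neighbor-joining tree from a distance matrix
#'
#' Saitou & Nei's agglomerative algorithm with the standard Q-criterion
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j` (R = row sums, r = current taxon
#' count). At each step the pair minimizing Q is joined; ties are broken
#' deterministically by the lexicographically smallest pair of cluster
#' representative labels, so runs are bit-reproducible. Branch lengths use the
#' standard two-point formulas; negative estimates are clamped to 0 (the
#' pre-clamp values are reported in the `clamped` attribute). The result is an
#' unrooted tree stored, as usual, with a trifurcating root.
#'
#' @param dm symmetric, non-negative labeled distance matrix with at least 3
#'   rows.
#' @return an [ape::read.tree()]-style `phylo` object with an added
#'   `clamped` attribute (numeric vector of pre-clamp negative lengths,
#'   possibly empty).
#' @examples
#' d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' tr <- neighbor_joining(d)
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stopf("neighbor joining needs at least 3 taxa, got %d", n)
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  }
  if (max(abs(dm - t(dm))) > 1e-8) stopf("distance matrix is not symmetric")
  if (any(dm < 0)) stopf("distance matrix has negative entries")
  labs <- rownames(dm)

  # clusters carry a growing newick fragment over placeholder tips and a
  # representative label (lexicographically smallest member) for tie-breaks
  frag <- paste0("t", seq_len(n))
  rep_lab <- labs
  d <- dm
  active <- seq_len(n)
  clamped <- numeric(0)
  fmt <- function(x) sprintf("%.12g", x + 0)  # + 0 normalizes negative zero

  while (length(active) > 3L) {
    r <- length(active)
    dd <- d[active, active]
    R <- rowSums(dd)
    q <- (r - 2) * dd - outer(R, R, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    reps <- cbind(rep_lab[active[cand[, 1]]], rep_lab[active[cand[, 2]]])
    key <- paste(pmin(reps[, 1], reps[, 2]), pmax(reps[, 1], reps[, 2]), sep = "\r")
    pick <- order(key)[1L]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    ai <- active[i]; aj <- active[j]
    li <- dd[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dd[i, j] - li
    if (li < 0) { clamped <- c(clamped, li); lj <- min(lj - li, dd[i, j]); li <- 0 }
    if (lj < 0) { clamped <- c(clamped, lj); li <- min(li - lj, dd[i, j]); lj <- 0 }
    new_frag <- paste0("(", frag[ai], ":", fmt(li), ",", frag[aj], ":", fmt(lj), ")")
    # distances from the new node to the remaining clusters
    rest <- setdiff(active, c(ai, aj))
    dnew <- (d[ai, rest] + d[aj, rest] - d[ai, aj]) / 2
    dnew <- pmax(dnew, 0)
    d[ai, rest] <- dnew; d[rest, ai] <- dnew
    frag[ai] <- new_frag
    rep_lab[ai] <- min(rep_lab[ai], rep_lab[aj])
    active <- setdiff(active, aj)
  }

  a <- active[1]; b <- active[2]; cc <- active[3]
  la <- (d[a, b] + d[a, cc] - d[b, cc]) / 2
  lb <- (d[a, b] + d[b, cc] - d[a, cc]) / 2
  lc <- (d[a, cc] + d[b, cc] - d[a, b]) / 2
  for (v in c(la, lb, lc)) if (v < 0) clamped <- c(clamped, v)
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- paste0("(", frag[a], ":", fmt(la), ",", frag[b], ":", fmt(lb), ",",
                frag[cc], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labs[as.integer(sub("^t", "", tree$tip.label))]
  attr(tree, "clamped") <- clamped
  tree
}

#' Serialize a tree to Newick
#'
#' Standalone serializer with fixed decimal precision for branch lengths and
#' Newick-conventional quoting: labels containing characters outside
#' `[A-Za-z0-9_.+-]` are wrapped in single quotes (internal quotes doubled).
#'
#' @param tree a `phylo` object.
#' @param precision decimal places for branch lengths (default 6).
#' @return a single Newick string terminated by `;`.
#' @export
to_newick <- function(tree, precision = 6) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  elen <- tree$edge.length %||% rep(NA_real_, nrow(tree$edge))
  quote_label <- function(lab) {
    if (grepl("[^A-Za-z0-9_.+-]", lab)) {
      paste0("'", gsub("'", "''", lab), "'")
    } else lab
  }
  render <- function(node, edge_idx) {
    br <- if (is.null(edge_idx) || is.na(elen[edge_idx])) "" else
      paste0(":", formatC(elen[edge_idx] + 0, format = "f", digits = precision))
    if (node <= ntip) return(paste0(quote_label(tree$tip.label[node]), br))
    ch <- kids[[as.character(node)]]
    inner <- paste(vapply(ch, function(e)
      render(tree$edge[e, 2], e), character(1)), collapse = ",")
    paste0("(", inner, ")", br)
  }
  paste0(render(root, NULL), ";")
}

#' Write a tree as a Newick file
#' @param tree a `phylo` object.
#' @param path output file.
#' @param precision decimals for branch lengths.
#' @export
write_newick <- function(tree, path, precision = 6) {
  writeLines(to_newick(tree, precision), path)
  invisible(path)
}

#' Cophenetic (path-length) distances between all leaf pairs
#'
#' Tree-metric oracle: for a tree built from an exactly additive matrix the
#' cophenetic distances reproduce that matrix.
#'
#' @param tree a `phylo` object.
#' @return symmetric labeled matrix, rows/columns in sorted label order.
#' @export
cophenetic_distances <- function(tree) {
  m <- stats::cophenetic(tree)
  ord <- order(rownames(m))
  m[ord, ord]
}

#' Do two label groups occupy disjoint subtrees?
#'
#' Structural check used for the two-subspecies clustering pattern: `TRUE`
#' when some edge of the unrooted tree separates exactly `group` from the
#' remaining leaves.
#'
#' @param tree a `phylo` object.
#' @param group character vector of tip labels (a proper nonempty subset).
#' @return logical.
#' @export
is_monophyletic_split <- function(tree, group) {
  tips <- tree$tip.label
  group <- intersect(group, tips)
  if (!length(group) || length(group) == length(tips)) {
    stopf("group must be a proper nonempty subset of the tip labels")
  }
  if (length(group) %in% c(1L, length(tips) - 1L)) return(TRUE)
  ntip <- length(tips)
  target <- sort(match(group, tips))
  below <- function(node) {
    if (node <= ntip) return(node)
    ch <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(ch, below)))
  }
  for (node in unique(tree$edge[, 1])) {
    for (child in tree$edge[tree$edge[, 1] == node, 2]) {
      tipset <- below(child)
      if (identical(tipset, target) ||
          identical(tipset, sort(setdiff(seq_len(ntip), target)))) {
        return(TRUE)
      }
    }
  }
  FALSE
}
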