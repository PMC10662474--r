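#' BioNJ tree from a distance matrix
#'
#' Variance-weighted neighbor joining (Gascuel's BioNJ): standard NJ
#' agglomeration with the Q-criterion and NJ branch-length estimates, but
#' the reduction of the distance matrix after each join uses the weight
#' lambda that minimizes the variance of the reduced distances, with the
#' per-pair variance taken proportional to the distance. On additive
#' matrices the generating topology and branch lengths are recovered
#' exactly (to floating-point precision).
#'
#' Determinism: Q-criterion ties are broken by the lexicographically
#' smallest (id, id) pair, keys of merged nodes being the smallest leaf id
#' in their subtree. Negative estimated branch lengths are clamped to zero
#' with the deficit transferred to the sister edge (standard NJ practice,
#' keeps path lengths through the new node unchanged).
#'
#' @param m Labelled symmetric distance matrix, N >= 3 taxa.
#' @return An unrooted [ape::read.tree()] `phylo` object.
#' @export
bionj_tree <- function(m) {
  m <- validate_distance_matrix(m)
  n <- nrow(m)
  if (n < 3L) stop("BioNJ needs at least 3 taxa", call. = FALSE)

  ids <- rownames(m)
  d <- m
  v <- m                                # variance proportional to distance
  frag <- ids                           # newick fragment per active node
  key <- ids                            # smallest leaf id in subtree

  fmt <- function(x) sprintf("%.15g", x)

  while (nrow(d) > 3L) {
    r <- nrow(d)
    S <- rowSums(d)
    Q <- (r - 2) * d - outer(S, S, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(pmin(key[cand[, 1]], key[cand[, 2]]),
                 pmax(key[cand[, 1]], key[cand[, 2]]))
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]

    li <- d[i, j] / 2 + (S[i] - S[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }

    others <- setdiff(seq_len(r), c(i, j))
    vij <- v[i, j]
    lambda <- if (vij > 0) {
      0.5 + sum(v[j, others] - v[i, others]) / (2 * (r - 2) * vij)
    } else 0.5
    lambda <- min(max(lambda, 0), 1)

    du <- lambda * (d[i, others] - li) + (1 - lambda) * (d[j, others] - lj)
    vu <- lambda * v[i, others] + (1 - lambda) * v[j, others] -
      lambda * (1 - lambda) * vij

    new_frag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    new_key <- min(key[i], key[j])

    keep <- others
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du),
               c(du, 0))
    v <- rbind(cbind(v[keep, keep, drop = FALSE], vu),
               c(vu, 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }

  # final three nodes: exact three-point formulas around a central node
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb),
                ",", frag[3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' trees. The normalized value divides by the maximum attainable: the
#' total number of non-trivial splits in both trees, which is 2(N-3) when
#' both are fully resolved.
#'
#' @param treeA,treeB `phylo` objects on identical leaf sets.
#' @return List with integer `rf` and `normalized_rf` in `[0, 1]`.
#' @export
rf_distance <- function(treeA, treeB) {
  if (!setequal(treeA$tip.label, treeB$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  ua <- ape::unroot(treeA)
  ub <- ape::unroot(treeB)
  rf <- as.integer(suppressMessages(
    phangorn::RF.dist(ua, ub, normalize = FALSE)))
  n_splits <- function(t) ape::Nedge(t) - ape::Ntip(t)  # internal edges
  denom <- n_splits(ua) + n_splits(ub)
  list(rf = rf, normalized_rf = if (denom > 0) rf / denom else 0)
}

#' Newick read/write helpers
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()].
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
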