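# Distance-based tree stage: p/Poisson distances with pairwise gap deletion,
# neighbor joining with a deterministic tie-break, column-bootstrap branch
# support mapped onto the full-data tree, and a bipartition monophyly test.
# Trees use the ape `phylo` container throughout.

#' Pairwise distances from a multiple alignment
#'
#' For each pair of rows, columns where either row has a gap are excluded
#' (pairwise deletion); `p` is the mismatch fraction over the remaining
#' columns and `poisson` the correction `-ln(1 - p)`. Near-saturated pairs
#' (`p >= cap_p`) are capped at `-ln(1 - cap_p)` and flagged.
#'
#' @param msa A `multi_alignment` with at least 3 rows.
#' @param correction `"p"` or `"poisson"`.
#' @param cap_p Saturation threshold for the Poisson correction.
#' @return A symmetric numeric matrix with zero diagonal, dimnames the taxon
#'   ids, and attribute `saturated_pairs` (two-column matrix of flagged
#'   pairs, possibly empty).
#' @export
distance_matrix <- function(msa, correction = c("p", "poisson"),
                            cap_p = 0.95) {
  correction <- match.arg(correction)
  stopifnot(inherits(msa, "multi_alignment"))
  m <- msa_matrix(msa)
  n <- nrow(m)
  if (n < 3L) stop("distance matrix needs at least 3 rows")
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- NULL
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      ok <- m[a, ] != GAP_CHAR & m[b, ] != GAP_CHAR
      if (!any(ok)) {
        stop("no comparable columns for pair ", ids[a], " / ", ids[b])
      }
      p <- mean(m[a, ok] != m[b, ok])
      if (correction == "poisson") {
        if (p >= cap_p) {
          sat <- rbind(sat, c(ids[a], ids[b]))
          p <- cap_p
        }
        val <- -log(1 - p)
      } else {
        val <- p
      }
      d[a, b] <- d[b, a] <- val
    }
  }
  attr(d, "saturated_pairs") <-
    if (is.null(sat)) matrix(character(0), ncol = 2) else sat
  d
}

.check_dist <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  invisible(d)
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration. Ties in the Q criterion are broken
#' deterministically by the lexicographically smallest pair of cluster
#' labels (a cluster is labeled by the smallest taxon id it contains).
#' Negative branch lengths are clamped to zero and counted in the
#' `clamped_edges` attribute. NJ is exact on additive matrices: it recovers
#' the generating topology and branch lengths.
#'
#' @param d Symmetric distance matrix with taxon ids as dimnames.
#' @return An unrooted `phylo` tree (trifurcating base), with attribute
#'   `clamped_edges`.
#' @export
nj_tree <- function(d) {
  .check_dist(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(d)        # tie-break label per active cluster
  newick <- labels             # partial newick per active cluster
  D <- d
  clamped <- 0L
  fmt <- function(x) sprintf("%.17g", x)

  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    best <- NULL
    for (a in seq_len(r - 1L)) {
      for (b in seq((a + 1L), r)) {
        if (Q[a, b] <= qmin + 1e-12 * max(1, abs(qmin))) {
          key <- sort(c(labels[a], labels[b]))
          if (is.null(best) || key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])) {
            best <- list(a = a, b = b, key = key)
          }
        }
      }
    }
    a <- best$a; b <- best$b
    bi <- D[a, b] / 2 + (R[a] - R[b]) / (2 * (r - 2))
    bj <- D[a, b] - bi
    if (bi < 0) { clamped <- clamped + 1L; bj <- bj + bi; bi <- 0 }
    if (bj < 0) { clamped <- clamped + 1L; bi <- bi + bj; bj <- 0 }
    nk <- sprintf("(%s:%s,%s:%s)", newick[a], fmt(bi), newick[b], fmt(bj))
    dn <- (D[a, ] + D[b, ] - D[a, b]) / 2
    keep <- setdiff(seq_len(r), c(a, b))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    lab2 <- c(labels[keep], min(labels[a], labels[b]))
    rownames(D2) <- colnames(D2) <- lab2
    newick <- c(newick[keep], nk)
    labels <- lab2
    D <- D2
  }

  # three-point closed form for the final trifurcation
  e <- numeric(3)
  e[1] <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  e[2] <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  e[3] <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (any(e < 0)) { clamped <- clamped + sum(e < 0); e[e < 0] <- 0 }
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 newick[1], fmt(e[1]), newick[2], fmt(e[2]),
                 newick[3], fmt(e[3]))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped_edges") <- clamped
  tree
}

# Canonical key for the non-trivial bipartition below each internal edge:
# the sorted leaf labels of the side NOT containing the alphabetically first
# leaf, pasted with ",".
.split_key <- function(side, all_taxa) {
  anchor <- min(all_taxa)
  side <- sort(side)
  if (anchor %in% side) side <- sort(setdiff(all_taxa, side))
  paste(side, collapse = ",")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' @param tree A `phylo` object.
#' @return Character vector of canonical split keys, one per internal edge.
#' @export
tree_bipartitions <- function(tree) {
  taxa <- tree$tip.label
  n <- length(taxa)
  splits <- character(0)
  parts <- ape::prop.part(tree)
  for (p in parts) {
    side <- taxa[p]
    if (length(side) > 1L && length(side) < n - 1L ||
        (length(side) == n - 1L && length(side) > 1L)) {
      # keep only non-trivial splits (both sides >= 2)
      other <- setdiff(taxa, side)
      if (length(side) >= 2L && length(other) >= 2L) {
        splits <- c(splits, .split_key(side, taxa))
      }
    }
  }
  unique(splits)
}

#' Bootstrap branch support for the neighbor-joining tree
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times; the support of each internal edge is the
#' fraction of replicate trees containing the same bipartition. Replicates
#' whose distance matrix is undefined (a pair with no comparable columns) are
#' dropped, counted and warned about. Deterministic given `seed`.
#'
#' @param msa A `multi_alignment` with at least 3 rows.
#' @param n_replicates Positive integer.
#' @param seed Integer seed.
#' @param correction Distance correction, as in [distance_matrix()].
#' @return The full-data NJ `phylo` tree with `node.label` carrying support
#'   values (root label empty), plus attributes `supports` (named numeric
#'   vector keyed by canonical split) and `n_dropped`.
#' @export
bootstrap_support <- function(msa, n_replicates = 100L, seed = 1L,
                              correction = "p") {
  stopifnot(n_replicates >= 1L)
  full <- nj_tree(distance_matrix(msa, correction))
  splits <- tree_bipartitions(full)
  counts <- setNames(numeric(length(splits)), splits)
  m <- msa_matrix(msa)
  used <- 0L
  dropped <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (k in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_msa <- .multi_alignment(rownames(m),
                                apply(m[, cols, drop = FALSE], 1L,
                                      paste, collapse = ""))
    rep_d <- tryCatch(distance_matrix(rep_msa, correction),
                      error = function(e) NULL)
    if (is.null(rep_d)) { dropped <- dropped + 1L; next }
    rep_splits <- tree_bipartitions(nj_tree(rep_d))
    hit <- splits %in% rep_splits
    counts[hit] <- counts[hit] + 1
    used <- used + 1L
  }
  if (dropped > 0L) {
    warning(dropped, " bootstrap replicate(s) dropped (no comparable columns)")
  }
  supports <- if (used > 0L) counts / used else counts * NA_real_
  full <- .attach_supports(full, supports)
  attr(full, "supports") <- supports
  attr(full, "n_dropped") <- dropped
  full
}

# Write supports into node.label: each internal node (other than the base
# trifurcation) subtends one internal edge whose bipartition is the node's
# descendant leaf set.
.attach_supports <- function(tree, supports) {
  taxa <- tree$tip.label
  ntip <- length(taxa)
  labs <- character(tree$Nnode)
  for (node in seq_len(tree$Nnode)) {
    node_id <- ntip + node
    desc <- ape::extract.clade(tree, node_id)$tip.label
    if (length(desc) >= 2L && length(desc) <= ntip - 2L) {
      key <- .split_key(desc, taxa)
      if (key %in% names(supports)) {
        labs[node] <- sprintf("%.3f", supports[[key]])
      }
    }
  }
  tree$node.label <- labs
  tree
}

#' Bootstrap support for a taxon set's bipartition
#'
#' @param tree A tree from [bootstrap_support()].
#' @param taxa Character vector of tip labels.
#' @return The support in `[0, 1]`, or `NA` if the full-data tree does not
#'   contain that bipartition.
#' @export
clade_support <- function(tree, taxa) {
  supports <- attr(tree, "supports")
  if (is.null(supports)) stop("tree carries no bootstrap supports")
  key <- .split_key(taxa, tree$tip.label)
  if (key %in% names(supports)) unname(supports[[key]]) else NA_real_
}

#' Test whether a taxon set is monophyletic
#'
#' On an unrooted tree, a set is monophyletic iff it forms one side of some
#' edge bipartition. When an outgroup id is supplied the tree is rooted on
#' it first and the set must form a clade of the rooted tree.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels (subset of the leaf set).
#' @param outgroup Optional tip label to root on.
#' @return `TRUE` or `FALSE`.
#' @export
is_monophyletic <- function(tree, taxa, outgroup = NULL) {
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) {
    stop("unknown taxon/taxa: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  n <- length(tree$tip.label)
  k <- length(unique(taxa))
  if (k <= 1L || k >= n) return(TRUE)   # trivial bipartitions always exist
  if (is.null(outgroup) && k == n - 1L) return(TRUE)
  key <- .split_key(taxa, tree$tip.label)
  sides <- lapply(ape::prop.part(tree), function(p) tree$tip.label[p])
  keys <- vapply(sides, .split_key, character(1), all_taxa = tree$tip.label)
  if (!is.null(outgroup)) {
    # rooted variant: the set itself must be a clade
    return(any(vapply(sides, function(s) setequal(s, taxa), logical(1))))
  }
  key %in% keys
}

#' Write a tree to Newick
#'
#' Branch lengths and internal-node support labels are preserved.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
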