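# Independent oracles and small fixtures used across test files.

# --- alignment oracles -------------------------------------------------------

# Optimal affine-gap global alignment score by top-down recursion over
# suffixes with memoization. Written independently of the package's forward
# dynamic program (different decomposition, no traceback, no tie-breaks);
# validated against true exhaustive path enumeration below.
oracle_align_score <- function(x, y, scoring) {
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  m <- length(xs); n <- length(ys)
  open <- scoring$gap_open; ext <- scoring$gap_extend
  sub <- scoring$substitution
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, last) {
    if (i > m && j > n) return(0)
    key <- paste(i, j, last)
    if (!is.null(v <- memo[[key]])) return(v)
    best <- -Inf
    if (i <= m && j <= n) {
      best <- max(best, sub[xs[i], ys[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= m) {
      cost <- if (last == "X") ext else open
      best <- max(best, cost + rec(i + 1, j, "X"))
    }
    if (j <= n) {
      cost <- if (last == "Y") ext else open
      best <- max(best, cost + rec(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "none")
}

# True exhaustive enumeration of every global alignment (as a sequence of
# M/X/Y columns), scoring each complete path; feasible only for very short
# strings. Used to validate oracle_align_score.
enumerate_align_score <- function(x, y, scoring) {
  m <- nchar(x); n <- nchar(y)
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  open <- scoring$gap_open; ext <- scoring$gap_extend
  sub <- scoring$substitution
  best <- -Inf
  walk <- function(i, j, last, acc) {
    if (i > m && j > n) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= m && j <= n) walk(i + 1, j + 1, "M", acc + sub[xs[i], ys[j]])
    if (i <= m) walk(i + 1, j, "X", acc + if (last == "X") ext else open)
    if (j <= n) walk(i, j + 1, "Y", acc + if (last == "Y") ext else open)
  }
  walk(1, 1, "none", 0)
  best
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- center-star SP score ----------------------------------------------------

# Sum over row pairs of the induced pairwise affine score (gap-gap columns
# removed per pair).
sp_score <- function(msa, scoring) {
  m <- msa_matrix(msa)
  ids <- rownames(m)
  total <- 0
  score_pair <- function(a, b) {
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    s <- 0; last <- "none"
    for (k in seq_along(a)) {
      if (a[k] != "-" && b[k] != "-") {
        s <- s + scoring$substitution[a[k], b[k]]; last <- "M"
      } else if (b[k] == "-") {
        s <- s + if (last == "X") scoring$gap_extend else scoring$gap_open
        last <- "X"
      } else {
        s <- s + if (last == "Y") scoring$gap_extend else scoring$gap_open
        last <- "Y"
      }
    }
    s
  }
  for (i in seq_len(nrow(m) - 1)) {
    for (j in seq(i + 1, nrow(m))) {
      total <- total + score_pair(m[i, ], m[j, ])
    }
  }
  total
}

# --- phylo fixtures ----------------------------------------------------------

random_additive_tree <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# assemble a multi_alignment directly from pre-aligned rows
msa_from_strings <- function(ids, rows) {
  structure(list(ids = ids, rows = stats::setNames(rows, ids),
                 n_col = nchar(rows[[1]])),
            class = "multi_alignment")
}

# --- feature helpers ---------------------------------------------------------

# Field-wise comparison of a detected feature vector against planted truth.
# For labels without a Dsr-like region the positional anchor fields
# (sb_present, peripheral, additional) read from a non-homologous alignment
# are positional noise that the classifier never consults, so they are only
# compared when the truth plants a siroheme site.
fv_matches_truth <- function(det, truth) {
  ok <- identical(det$siroheme_site, truth$siroheme_site) &&
    identical(det$frh_core, truth$frh_core) &&
    identical(det$ferredoxin_n_count, truth$ferredoxin_n_count) &&
    identical(det$ferredoxin_c_count, truth$ferredoxin_c_count) &&
    identical(det$fusion_order_ok, truth$fusion_order_ok)
  if (isTRUE(truth$siroheme_site)) {
    ok <- ok &&
      identical(det$peripheral_cluster, truth$peripheral_cluster) &&
      identical(det$additional_cluster, truth$additional_cluster) &&
      identical(unname(det$sb_present), unname(truth$sb_present))
  }
  ok
}

test_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_anchor_profile()
    cache
  }
})

test_scoring <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- blosum62_scheme()
    cache
  }
})
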