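# Global alignment, center-star MSA and column trimming: the in-package
# stand-ins for a production aligner plus conserved-block trimmer. They are
# deterministic by construction and make no attempt to reproduce MUSCLE or
# Gblocks output.

.seq_of <- function(x) {
  if (inherits(x, "protein_record")) x$sequence else toupper(as.character(x))
}

.id_of <- function(x, default) {
  if (inherits(x, "protein_record")) x$id else default
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh three-state dynamic programming. The traceback is
#' deterministic: on ties, substitution is preferred over a gap in the query,
#' which is preferred over a gap in the reference.
#'
#' @param ref,query Sequences (strings or [protein_record()] objects).
#' @param scoring A [scoring_scheme()].
#' @return An object of class `pair_alignment`: `ref_id`, `query_id`,
#'   aligned strings `ref_aln`/`query_aln`, the optimal `score`, and
#'   `ref_to_query_map`, an integer vector giving for each 1-based reference
#'   position the 1-based query position aligned to it (`NA` when the
#'   reference position is aligned to a gap).
#' @export
global_align <- function(ref, query, scoring) {
  rs <- .seq_of(ref); qs <- .seq_of(query)
  if (nchar(rs) == 0L || nchar(qs) == 0L) stop("sequences must be non-empty")
  ab <- rownames(scoring$substitution)
  rv <- match(strsplit(rs, "")[[1]], ab)
  qv <- match(strsplit(qs, "")[[1]], ab)
  if (anyNA(rv) || anyNA(qv)) {
    stop("sequence contains residues outside the scoring alphabet")
  }
  res <- align_affine_cpp(rv - 1L, qv - 1L, scoring$substitution,
                          scoring$gap_open, scoring$gap_extend)
  path <- res$path  # 0 = substitution, 1 = gap in query, 2 = gap in ref
  rchars <- qchars <- character(length(path))
  rmap <- integer(nchar(rs))
  i <- 0L; j <- 0L
  for (k in seq_along(path)) {
    st <- path[k]
    if (st == 0L) {
      i <- i + 1L; j <- j + 1L
      rchars[k] <- substr(rs, i, i); qchars[k] <- substr(qs, j, j)
      rmap[i] <- j
    } else if (st == 1L) {
      i <- i + 1L
      rchars[k] <- substr(rs, i, i); qchars[k] <- GAP_CHAR
      rmap[i] <- NA_integer_
    } else {
      j <- j + 1L
      rchars[k] <- GAP_CHAR; qchars[k] <- substr(qs, j, j)
    }
  }
  structure(list(ref_id = .id_of(ref, "ref"),
                 query_id = .id_of(query, "query"),
                 ref_aln = paste(rchars, collapse = ""),
                 query_aln = paste(qchars, collapse = ""),
                 score = res$score,
                 ref_to_query_map = rmap),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("<pair_alignment> %s vs %s, score %.6g, %d columns\n",
              x$ref_id, x$query_id, x$score, nchar(x$ref_aln)))
  invisible(x)
}

.multi_alignment <- function(ids, rows) {
  stopifnot(length(ids) == length(rows),
            length(unique(nchar(rows))) == 1L)
  structure(list(ids = ids, rows = setNames(rows, ids),
                 n_col = nchar(rows[[1]])),
            class = "multi_alignment")
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat(sprintf("<multi_alignment> %d sequences x %d columns\n",
              length(x$ids), x$n_col))
  invisible(x)
}

#' Center-star multiple sequence alignment
#'
#' Aligns every sequence to a center sequence and merges the pairwise gap
#' patterns ("once a gap, always a gap"). The center is the record with the
#' maximal summed pairwise alignment score against all others, unless given
#' explicitly. Degapping any output row reproduces its input sequence.
#'
#' @param records List of two or more [protein_record()] objects.
#' @param scoring A [scoring_scheme()].
#' @param center Optional center override: an index into `records` or a
#'   record id.
#' @return A `multi_alignment` (ordered as `records`).
#' @export
center_star_msa <- function(records, scoring, center = NULL) {
  n <- length(records)
  if (n < 2L) stop("center-star MSA needs at least 2 records")
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate record ids in MSA input")

  if (is.null(center)) {
    scores <- matrix(0, n, n)
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        s <- global_align(records[[a]], records[[b]], scoring)$score
        scores[a, b] <- scores[b, a] <- s
      }
    }
    center <- which.max(rowSums(scores))  # ties: first index
  } else if (is.character(center)) {
    center <- match(center, ids)
    if (is.na(center)) stop("center id not found")
  }
  c_rec <- records[[center]]
  c_len <- nchar(c_rec$sequence)
  others <- setdiff(seq_len(n), center)

  # Each pairwise alignment decomposed relative to center coordinates:
  # per center position p, the query character aligned to it; per slot
  # 0..c_len, the run of query residues inserted after center position p.
  decomp <- lapply(others, function(k) {
    pa <- global_align(c_rec, records[[k]], scoring)
    cc <- strsplit(pa$ref_aln, "")[[1]]
    qc <- strsplit(pa$query_aln, "")[[1]]
    at <- character(c_len)
    ins <- vector("list", c_len + 1L)
    p <- 0L
    for (col in seq_along(cc)) {
      if (cc[col] == GAP_CHAR) {
        ins[[p + 1L]] <- c(ins[[p + 1L]], qc[col])
      } else {
        p <- p + 1L
        at[p] <- qc[col]
      }
    }
    list(at = at, ins = lapply(ins, function(v) if (is.null(v)) character(0) else v))
  })
  ins_len <- vapply(seq_len(c_len + 1L), function(s) {
    if (length(decomp) == 0L) 0L else
      max(vapply(decomp, function(d) length(d$ins[[s]]), integer(1)))
  }, integer(1))

  build_row <- function(at, ins) {
    parts <- character(0)
    for (s in seq_len(c_len + 1L)) {
      run <- ins[[s]]
      pad <- strrep(GAP_CHAR, ins_len[s] - length(run))
      parts <- c(parts, paste0(paste(run, collapse = ""), pad))
      if (s <= c_len) parts <- c(parts, at[s])
    }
    paste(parts, collapse = "")
  }
  center_row <- build_row(strsplit(c_rec$sequence, "")[[1]],
                          rep(list(character(0)), c_len + 1L))
  rows <- character(n)
  rows[center] <- center_row
  for (k in seq_along(others)) {
    rows[others[k]] <- build_row(decomp[[k]]$at, decomp[[k]]$ins)
  }
  .multi_alignment(ids, rows)
}

#' Trim poorly aligned columns by gap fraction
#'
#' Retains exactly the columns whose gap fraction is at most
#' `max_gap_fraction`; a coarse, explicitly configurable proxy for
#' conserved-block selection. Idempotent at a fixed threshold.
#'
#' @param msa A `multi_alignment`.
#' @param max_gap_fraction Fraction in 0..1.
#' @return The trimmed `multi_alignment`, with attribute `kept_columns`
#'   mapping new column indices to the original 1-based columns.
#' @export
trim_columns <- function(msa, max_gap_fraction = 0.5) {
  stopifnot(inherits(msa, "multi_alignment"),
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  m <- msa_matrix(msa)
  gap_frac <- colMeans(m == GAP_CHAR)
  keep <- which(gap_frac <= max_gap_fraction)
  rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (length(keep) == 0L) rows <- rep("", length(msa$ids))
  out <- structure(list(ids = msa$ids, rows = setNames(rows, msa$ids),
                        n_col = length(keep)),
                   class = "multi_alignment")
  attr(out, "kept_columns") <- keep
  out
}

#' Character matrix view of a multiple alignment
#'
#' @param msa A `multi_alignment`.
#' @return A character matrix, rows named by record id.
#' @export
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa$rows), ""))
  rownames(m) <- msa$ids
  m
}

#' Remove gap characters from an aligned row
#' @param x Aligned string.
#' @return The degapped sequence.
#' @export
degap <- function(x) gsub(GAP_CHAR, "", x, fixed = TRUE)

#' Write a multiple alignment as aligned FASTA
#' @param msa A `multi_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  recs <- lapply(msa$ids, function(i) {
    list(id = i, organism = "", sequence = msa$rows[[i]])
  })
  lines <- unlist(lapply(recs, function(r) {
    n <- nchar(r$sequence)
    starts <- seq(1L, max(n, 1L), by = 60L)
    c(paste0(">", r$id), substring(r$sequence, starts, pmin(starts + 59L, n)))
  }))
  writeLines(lines, path)
  invisible(path)
}
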