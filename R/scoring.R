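#' Create a scoring scheme for protein alignment
#'
#' Bundles a symmetric substitution matrix over the residue alphabet with
#' affine gap penalties. A gap run of length L costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param substitution Symmetric numeric matrix with identical row/column
#'   names covering the residues to be aligned.
#' @param gap_open,gap_extend Penalties with `gap_open <= gap_extend <= 0`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution, gap_open, gap_extend) {
  stopifnot(is.matrix(substitution), !is.null(rownames(substitution)),
            identical(rownames(substitution), colnames(substitution)))
  if (max(abs(substitution - t(substitution))) > 1e-9) {
    stop("substitution matrix must be symmetric")
  }
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    stop("need gap_open <= gap_extend <= 0")
  }
  structure(list(substitution = substitution,
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend)),
            class = "scoring_scheme")
}

#' BLOSUM62 scoring scheme
#'
#' The packaged default: the standard BLOSUM62 log-odds matrix (as shipped
#' with Biostrings), restricted to the 20 standard residues plus `X`, with
#' conventional affine penalties.
#'
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A `scoring_scheme`.
#' @export
blosum62_scheme <- function(gap_open = -11, gap_extend = -1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  scoring_scheme(m, gap_open, gap_extend)
}

#' Identity scoring scheme
#'
#' Match/mismatch scoring over the residue alphabet; mainly for tests and
#' worked examples where alignment scores must be easy to verify by hand.
#'
#' @param match,mismatch Diagonal and off-diagonal scores.
#' @param gap_open,gap_extend Affine gap penalties.
#' @param alphabet Letters to cover; defaults to all 26 so arbitrary example
#'   strings can be aligned.
#' @return A `scoring_scheme`.
#' @export
identity_scheme <- function(match = 1, mismatch = 0,
                            gap_open = -2, gap_extend = -1,
                            alphabet = LETTERS) {
  n <- length(alphabet)
  m <- matrix(mismatch, n, n, dimnames = list(alphabet, alphabet))
  diag(m) <- match
  scoring_scheme(m, gap_open, gap_extend)
}
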