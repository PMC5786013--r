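# BLOSUM90 similarity matrix, loaded once from the shipped table
.blosum_env <- new.env(parent = emptyenv())

#' The BLOSUM90 amino-acid substitution matrix
#' @return Integer 20x20 matrix with amino-acid dimnames.
#' @export
blosum90 <- function() {
  if (is.null(.blosum_env$m)) {
    path <- system.file("extdata", "blosum90.tsv", package = "chains4d",
                        mustWork = TRUE)
    m <- as.matrix(utils::read.delim(path, row.names = 1L,
                                     check.names = FALSE))
    storage.mode(m) <- "integer"
    .blosum_env$m <- m
  }
  .blosum_env$m
}

#' Ungapped fitting alignment of a peptide to a sequence
#'
#' Needleman-Wunsch-style dynamic programme fitting the full peptide into
#' the sequence without internal gaps (end gaps in the sequence are free):
#' `S(i, j) = S(i-1, j-1) + sub[pep_i, seq_j]`, optimum `max_j S(L, j)`.
#' The optimal score equals the best ungapped placement score of the
#' peptide under the substitution matrix.
#'
#' @param peptide,sequence Character vectors of one-letter codes (a single
#'   string is also accepted).
#' @param sub Substitution matrix (default [blosum90()]).
#' @return List with `score` (optimal raw similarity score) and `starts`
#'   (all optimal start offsets, 1-based).
#' @export
nw_align <- function(peptide, sequence, sub = blosum90()) {
  peptide <- to_residues(peptide)
  sequence <- to_residues(sequence)
  L <- length(peptide); n <- length(sequence)
  if (L > n) stop("peptide longer than sequence")
  # S[i, j]: peptide[1..i] aligned ending at sequence position j
  S <- matrix(-Inf, nrow = L, ncol = n)
  S[1L, ] <- sub[peptide[1L], sequence]
  if (L > 1L) for (i in 2:L) {
    js <- i:n
    S[i, js] <- S[i - 1L, js - 1L] + sub[peptide[i], sequence[js]]
  }
  sc <- max(S[L, ])
  ends <- which(S[L, ] == sc)
  list(score = sc, starts = ends - L + 1L)
}

#' Align a candidate peptide to the protein sequence
#'
#' Finds every ungapped placement of the peptide that survives alignment
#' with zero mismatches (mismatched placements are discarded) and scores
#' each with the BLOSUM90 similarity sum, normalized to (0, 1] through a
#' logistic transform of the per-position mean score,
#' `s_align = 1 / (1 + exp(-score / L))`, so that it is commensurate with
#' the probability factors it multiplies.
#'
#' @inheritParams nw_align
#' @return Data frame with columns `start` (1-based offset), `score` (raw
#'   BLOSUM90 sum) and `s_align`; zero rows when the peptide does not occur
#'   in the sequence.
#' @export
align_peptide <- function(peptide, sequence, sub = blosum90()) {
  peptide <- to_residues(peptide)
  sequence <- to_residues(sequence)
  L <- length(peptide); n <- length(sequence)
  if (L > n) stop("peptide longer than sequence")
  starts <- integer(0); scores <- numeric(0)
  for (s in seq_len(n - L + 1L)) {
    win <- sequence[s:(s + L - 1L)]
    if (all(win == peptide)) {
      starts <- c(starts, s)
      scores <- c(scores, sum(sub[cbind(peptide, win)]))
    }
  }
  data.frame(start = starts, score = scores,
             s_align = stats::plogis(scores / L))
}

# internal: accept "ACDE" or c("A","C","D","E")
to_residues <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1L]] else x
}
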