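#' Enumerate atom-type combinations for a spin system and amino acid
#'
#' Considers every way of explaining the observed TOCSY 13C-1H pairs as atom
#' types of a candidate amino acid: pairs whose carbon frequencies differ by
#' at most `methylene_tol` (default 0.2 ppm) may be grouped into a methylene
#' moiety, grouping is attempted only for atom types that are methylenes in
#' that amino acid, and the (possibly grouped) units are assigned injectively
#' to the amino acid's atom types.  If the spin system holds more pairs than
#' the amino acid's cross-peak capacity, no combination exists.
#'
#' @param pairs Data frame of TOCSY CH pairs (`c`, `h` columns).
#' @param aa Candidate amino-acid one-letter code.
#' @param methylene_tol Carbon tolerance for methylene grouping (ppm).
#' @param positive Optional logical matrix (pairs x atom types) restricting
#'   each pair to the given slots; used by the max-probability search to
#'   prune assignments whose density underflows to zero, which can never
#'   win.  `NULL` (the default) enumerates everything.
#' @return List of combinations; each combination is a list of units, each
#'   unit a list with `atom_type`, `carbon`, `group` and `idx` (row indices
#'   of the pairs it explains; length 2 for a grouped methylene).
#' @export
enumerate_combinations <- function(pairs, aa, methylene_tol = 0.2,
                                   positive = NULL) {
  n <- nrow(pairs)
  if (n == 0L) return(list())
  if (n > atom_capacity(aa)) return(list())
  top <- aa_topology(aa)
  ch2_slots <- which(top$group == "CH2")
  if (!is.null(positive) && !all(rowSums(positive) > 0L)) return(list())
  # candidate methylene pairings
  edges <- list()
  if (length(ch2_slots) && n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (abs(pairs$c[i] - pairs$c[j]) <= methylene_tol)
        edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  # enumerate all matchings over the candidate edges (including the empty one)
  matchings <- list()
  grow <- function(used, current, from) {
    matchings[[length(matchings) + 1L]] <<- current
    if (from > length(edges)) return()
    for (e in from:length(edges)) {
      ij <- edges[[e]]
      if (!any(ij %in% used))
        grow(c(used, ij), c(current, list(ij)), e + 1L)
    }
  }
  grow(integer(0), list(), 1L)

  combos <- list()
  for (m in matchings) {
    grouped <- unlist(m)
    singles <- setdiff(seq_len(n), grouped)
    units <- c(m, as.list(singles))
    if (length(units) > nrow(top)) next
    # order units canonically by their smallest pair index
    units <- units[order(vapply(units, min, numeric(1)))]
    # allowed slots per unit (CH2-only for groups; positive-density filter)
    allowed <- lapply(units, function(idx) {
      s <- if (length(idx) == 2L) ch2_slots else seq_len(nrow(top))
      if (!is.null(positive)) {
        ok <- positive[idx[1L], s]
        if (length(idx) == 2L) ok <- ok & positive[idx[2L], s]
        s <- s[ok]
      }
      s
    })
    if (any(!vapply(allowed, length, integer(1)))) next
    used <- logical(nrow(top))
    # recursively assign units to topology slots (in topology order)
    assign_rec <- function(u, acc) {
      if (u > length(units)) {
        combos[[length(combos) + 1L]] <<- acc
        return()
      }
      idx <- units[[u]]
      for (s in allowed[[u]]) {
        if (used[s]) next
        used[s] <<- TRUE
        assign_rec(u + 1L,
                   c(acc, list(list(atom_type = top$atom_type[s],
                                    carbon = top$carbon[s],
                                    group = top$group[s], idx = idx))))
        used[s] <<- FALSE
      }
    }
    assign_rec(1L, list())
  }
  combos
}

# internal: densities of every pair under every atom-type map of one amino
# acid; D_all (from density_all_maps) avoids re-evaluating shared pairs
pair_density_matrix <- function(pairs, aa, stats, D_all = NULL) {
  top <- aa_topology(aa)
  if (!is.null(D_all))
    return(D_all[, stats_key(aa, top$atom_type), drop = FALSE])
  matrix(vapply(top$atom_type, function(at)
    density_at(stats_map(stats, aa, at), pairs$h, pairs$c),
    numeric(nrow(pairs))), nrow = nrow(pairs),
    dimnames = list(NULL, top$atom_type))
}

#' Conditional probability of observed shifts given an amino-acid type
#'
#' P(CCS|AA): the maximum, over all atom-type combinations, of the product
#' of per-pair densities under the candidate amino acid's density maps.  A
#' grouped methylene contributes the logarithmic (geometric) mean of its two
#' pair densities.  Zero if the spin system holds more pairs than the amino
#' acid's atom types can explain.  Ties between combinations are broken
#' deterministically in favour of combinations assigning backbone atom
#' types (CA, CB) first.
#'
#' @inheritParams enumerate_combinations
#' @param stats A `stats_library`.
#' @param D_all Optional precomputed density matrix of the pairs under all
#'   library maps (internal batching).
#' @return List with `p` (the probability) and `combo` (the maximizing
#'   combination, `NULL` when `p` is 0).
#' @export
p_ccs_given_aa <- function(pairs, aa, stats, methylene_tol = 0.2,
                           D_all = NULL) {
  n <- nrow(pairs)
  if (n == 0L || n > atom_capacity(aa))
    return(list(p = 0, combo = NULL))
  top <- aa_topology(aa)
  Dmat <- pair_density_matrix(pairs, aa, stats, D_all)
  if (!all(.rowSums(Dmat, n, ncol(Dmat)) > 0))
    return(list(p = 0, combo = NULL))
  S <- nrow(top)
  ch2 <- top$group == "CH2"
  # candidate methylene pairings
  edges <- list()
  if (any(ch2) && n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (abs(pairs$c[i] - pairs$c[j]) <= methylene_tol)
        edges[[length(edges) + 1L]] <- c(i, j)
  }
  best_p <- 0; best_units <- NULL; best_slots <- NULL
  try_matching <- function(m) {
    grouped <- unlist(m)
    singles <- setdiff(seq_len(n), grouped)
    units <- c(m, as.list(singles))
    if (length(units) > S) return()
    units <- units[order(vapply(units, min, numeric(1)))]
    # per-unit slot scores (geometric mean for grouped methylenes)
    U <- t(vapply(units, function(idx) {
      if (length(idx) == 2L) {
        u <- sqrt(Dmat[idx[1L], ] * Dmat[idx[2L], ])
        u[!ch2] <- 0
        u
      } else Dmat[idx, ]
    }, numeric(S)))
    dimnames(U) <- NULL
    if (any(.rowSums(U, length(units), S) == 0)) return()
    used <- logical(S)
    slots <- integer(length(units))
    dfs <- function(u, prod_) {
      if (u > length(units)) {
        if (prod_ > best_p) {
          best_p <<- prod_; best_units <<- units; best_slots <<- slots
        }
        return()
      }
      for (s in seq_len(S)) {
        if (used[s] || U[u, s] == 0) next
        used[s] <<- TRUE; slots[u] <<- s
        dfs(u + 1L, prod_ * U[u, s])
        used[s] <<- FALSE
      }
    }
    dfs(1L, 1)
  }
  # enumerate matchings over candidate methylene edges (incl. the empty one)
  grow <- function(used_pairs, current, from) {
    try_matching(current)
    if (from > length(edges)) return()
    for (e in from:length(edges)) {
      ij <- edges[[e]]
      if (!any(ij %in% used_pairs))
        grow(c(used_pairs, ij), c(current, list(ij)), e + 1L)
    }
  }
  grow(integer(0), list(), 1L)
  if (best_p <= 0) return(list(p = 0, combo = NULL))
  combo <- lapply(seq_along(best_units), function(u) {
    s <- best_slots[u]
    list(atom_type = top$atom_type[s], carbon = top$carbon[s],
         group = top$group[s], idx = best_units[[u]])
  })
  list(p = best_p, combo = combo)
}

# internal: prior over amino-acid types observable in a TOCSY spin system.
# A TOCSY AAIG reports residue i-1 of an amide at i, and prolines carry no
# amide root, so the reference population is residues followed by a
# non-proline.
sequence_prior <- function(sequence) {
  n <- length(sequence)
  pre <- sequence[seq_len(n - 1L)][sequence[2:n] != "P"]
  if (!length(pre)) stop("sequence has no residue preceding a non-proline")
  tab <- table(factor(pre, levels = standard_aa()))
  as.numeric(tab) / length(pre) -> p
  names(p) <- standard_aa()
  p
}

#' Predict amino-acid types for a TOCSY spin system
#'
#' Bayesian posterior over amino-acid types for the residue preceding the
#' AAIG's amide:
#' \deqn{P(AA|CCS) = \frac{P(CCS|AA)\,P(AA)}{\sum_{AA'} P(CCS|AA')\,P(AA')}}
#' with P(CCS|AA) from [p_ccs_given_aa()] and the prior P(AA) taken as the
#' frequency of each type among sequence residues followed by a non-proline.
#' Predictions are ranked by posterior; a Z-score is computed on the natural
#' logs of the nonzero posteriors.
#'
#' @param pairs TOCSY CH-pair data frame of one AAIG.
#' @param sequence Character vector of one-letter residue codes.
#' @param stats A `stats_library`.
#' @param prior Optional prior probabilities named by amino acid (computed
#'   from `sequence` when `NULL`).
#' @param methylene_tol Carbon tolerance for methylene grouping (ppm).
#' @return Data frame with columns `aa`, `p_ccs`, `prior`, `posterior`,
#'   `zscore`, ranked by decreasing posterior.  Zero rows (with a warning)
#'   if no amino acid has nonzero support.
#' @export
predict_aa_types <- function(pairs, sequence, stats, prior = NULL,
                             methylene_tol = 0.2) {
  if (!length(sequence)) stop("sequence must be non-empty")
  if (is.null(prior)) prior <- sequence_prior(sequence)
  cand <- names(prior)[prior > 0]
  D_all <- if (nrow(pairs)) density_all_maps(stats, pairs$h, pairs$c)
  p_ccs <- vapply(cand, function(aa) {
    if (nrow(pairs) == 0L) return(0)
    p_ccs_given_aa(pairs, aa, stats, methylene_tol, D_all = D_all)$p
  }, numeric(1))
  w <- p_ccs * prior[cand]
  out <- data.frame(aa = cand, p_ccs = p_ccs, prior = as.numeric(prior[cand]),
                    posterior = 0, zscore = NA_real_,
                    stringsAsFactors = FALSE)
  nz <- w > 0
  if (!any(nz)) {
    warning("no amino-acid type with nonzero support (abnormal shifts?)")
    return(out[0, ])
  }
  out$posterior[nz] <- w[nz] / sum(w[nz])
  lp <- log(out$posterior[nz])
  out$zscore[nz] <- if (sum(nz) > 1L && stats::sd(lp) > 0)
    (lp - mean(lp)) / stats::sd(lp) else 0
  out <- out[nz, ]
  out <- out[order(-out$posterior, out$aa), ]
  rownames(out) <- NULL
  out
}

#' Filter type predictions by Z-score
#'
#' Keeps predictions with `zscore >= cutoff`; the top-ranked prediction is
#' always retained.
#'
#' @param predictions Data frame from [predict_aa_types()].
#' @param cutoff Z-score cutoff.
#' @param min_posterior Additional absolute floor: predictions below it are
#'   dropped even when their Z-score passes (the top-ranked prediction is
#'   exempt).  A type with negligible posterior is no prediction at all,
#'   however permissive the Z-cutoff.
#' @return Filtered data frame.
#' @export
zscore_filter <- function(predictions, cutoff, min_posterior = 0) {
  if (nrow(predictions) == 0L) return(predictions)
  keep <- predictions$zscore >= cutoff &
    predictions$posterior >= min_posterior
  keep[1L] <- TRUE
  predictions[keep, , drop = FALSE]
}

# internal: predictions for every AAIG of a set
predict_all_aaigs <- function(aaig_set, sequence, stats,
                              methylene_tol = 0.2) {
  prior <- sequence_prior(sequence)
  out <- lapply(aaig_set$aaigs, function(a)
    suppressWarnings(predict_aa_types(a$tocsy, sequence, stats,
                                      prior = prior,
                                      methylene_tol = methylene_tol)))
  names(out) <- names(aaig_set$aaigs)
  out
}
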