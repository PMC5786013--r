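#' Sequential connectivities between spin systems
#'
#' Matches the TOCSY 13C-1H frequencies of every AAIG (which report residue
#' i-1) against the NOESY 13C-1H frequencies of every other AAIG, excluding
#' the AAIG with the same root resonance.  A high occupancy rate — matched
#' TOCSY frequencies over total TOCSY frequencies — identifies the acceptor
#' as the spin system of the donor's preceding residue.
#'
#' @param aaig_set An `aaig_set` from [cluster_peaks()].
#' @param tol A [tolerances()] object.
#' @param min_occupancy Minimum occupancy rate to report a connectivity.
#' @return Data frame with columns `tocsy_aaig` (donor, residue i),
#'   `noesy_aaig` (acceptor, candidate residue i-1), `matched`, `total`,
#'   `occupancy`.
#' @export
compute_connectivities <- function(aaig_set, tol = tolerances(),
                                   min_occupancy = 0) {
  aaigs <- aaig_set$aaigs
  if (length(aaigs) < 2L) stop("need at least 2 AAIGs")
  labels <- names(aaigs)
  out <- vector("list", length(aaigs))
  for (di in seq_along(aaigs)) {
    don <- aaigs[[di]]
    tp <- don$tocsy
    if (nrow(tp) == 0L) next
    rows <- list()
    for (ai in seq_along(aaigs)) {
      if (ai == di) next
      np <- aaigs[[ai]]$noesy
      if (nrow(np) == 0L) next
      hit <- (abs(outer(tp$c, np$c, "-")) <= tol$tol_c) &
             (abs(outer(tp$h, np$h, "-")) <= tol$tol_h)
      matched <- sum(rowSums(hit) > 0L)
      occ <- matched / nrow(tp)
      if (matched > 0L && occ >= min_occupancy)
        rows[[length(rows) + 1L]] <-
          data.frame(tocsy_aaig = labels[di], noesy_aaig = labels[ai],
                     matched = matched, total = nrow(tp), occupancy = occ,
                     stringsAsFactors = FALSE)
    }
    if (length(rows)) out[[di]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(tocsy_aaig = character(), noesy_aaig = character(),
                      matched = integer(), total = integer(),
                      occupancy = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build chains of sequentially connected AAIGs
#'
#' Grows directed rooted trees along the connectivity digraph (edges run
#' from the acceptor, residue i-1, to the donor, residue i, so chains read
#' N- to C-terminal) and returns every simple path of `L_min` to `L_max`
#' spin systems.  Each chain carries a probability of occurrence: the
#' product over its links of the link's occupancy rate.
#'
#' @param connectivities Data frame from [compute_connectivities()].
#' @param L_max Maximum chain length (spin systems); the default 6 trades
#'   specificity against combinatorial growth.
#' @param L_min Minimum chain length (default 2).
#' @return List of chains, each a list with `aaigs` (character vector in
#'   sequence order) and `p_chain`.
#' @export
build_chains <- function(connectivities, L_max = 6, L_min = 2) {
  if (L_max < 2) stop("L_max must be >= 2")
  if (nrow(connectivities) == 0L) return(list())
  edges <- data.frame(from = connectivities$noesy_aaig,
                      to = connectivities$tocsy_aaig,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  occ <- connectivities$occupancy
  names(occ) <- paste(edges$from, edges$to, sep = "\r")
  chains <- list()
  for (v in igraph::V(g)) {
    paths <- igraph::all_simple_paths(g, from = v, mode = "out",
                                      cutoff = L_max - 1L)
    for (p in paths) {
      nm <- names(p)
      if (length(nm) < L_min) next
      p_chain <- prod(occ[paste(nm[-length(nm)], nm[-1L], sep = "\r")])
      chains[[length(chains) + 1L]] <- list(aaigs = nm, p_chain = p_chain)
    }
  }
  chains
}

#' Translate a chain into candidate peptides
#'
#' Expands the Cartesian product of the Z-score-filtered amino-acid-type
#' predictions of each chain member (each member contributes the type of the
#' residue preceding its amide), ranked by the product of posteriors and
#' capped.
#'
#' @param chain Character vector of AAIG labels (or a chain list with an
#'   `aaigs` element).
#' @param predictions Named list of prediction data frames (one per AAIG,
#'   see [predict_aa_types()]).
#' @param zscore_cutoff Z-score cutoff applied per member.
#' @param cap Maximum number of peptides returned (highest posterior product
#'   first).
#' @return List with `peptides` (character vector), `posteriors` (matrix,
#'   one row per peptide, one column per chain position) and `p_pep`
#'   (posterior products).  Empty peptide vector if a member has no retained
#'   prediction.
#' @export
chains_to_peptides <- function(chain, predictions, zscore_cutoff = -Inf,
                               cap = 2000) {
  aaigs <- if (is.list(chain)) chain$aaigs else chain
  kept <- lapply(aaigs, function(a) {
    p <- predictions[[a]]
    if (is.null(p) || nrow(p) == 0L) return(NULL)
    zscore_filter(p, zscore_cutoff)
  })
  if (any(vapply(kept, is.null, logical(1))))
    return(list(peptides = character(0),
                posteriors = matrix(0, 0, length(aaigs)), p_pep = numeric(0)))
  sizes <- vapply(kept, nrow, integer(1))
  # guard against explosion before expansion: keep the top few per member
  while (prod(sizes) > 20 * cap) {
    w <- which.max(sizes)
    kept[[w]] <- kept[[w]][seq_len(max(1L, nrow(kept[[w]]) - 1L)), ,
                           drop = FALSE]
    sizes <- vapply(kept, nrow, integer(1))
  }
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  post <- vapply(seq_along(aaigs), function(k)
    kept[[k]]$posterior[grid[, k]], numeric(nrow(grid)))
  post <- matrix(post, nrow = nrow(grid))
  p_pep <- apply(post, 1L, prod)
  letters_ <- vapply(seq_along(aaigs), function(k)
    kept[[k]]$aa[grid[, k]], character(nrow(grid)))
  letters_ <- matrix(letters_, nrow = nrow(grid))
  peptides <- apply(letters_, 1L, paste, collapse = "")
  ord <- order(-p_pep, peptides)
  ord <- ord[seq_len(min(cap, length(ord)))]
  list(peptides = peptides[ord],
       posteriors = post[ord, , drop = FALSE], p_pep = p_pep[ord])
}

#' Weighted assignment scores for aligned chain positions
#'
#' The weighted probability of assigning an AAIG from a chain to a specific
#' residue: `s_x = posterior * p_chain * s_align` (type posterior of the
#' AAIG at that position, chain probability of occurrence, normalized
#' alignment score).
#'
#' @param alignment Data frame with columns `position`, `aaig`, `posterior`,
#'   `p_chain`, `s_align`.
#' @return The input with an `s_x` column appended.
#' @export
score_assignments <- function(alignment) {
  alignment$s_x <- alignment$posterior * alignment$p_chain *
    alignment$s_align
  alignment
}

#' Confidence scores per (position, AAIG)
#'
#' Sums the weighted assignment scores over all chains proposing a given
#' AAIG at a given sequence position.
#'
#' @param scored Data frame from [score_assignments()].
#' @return Data frame with columns `position`, `aaig`, `cs`.
#' @export
confidence_scores <- function(scored) {
  if (nrow(scored) == 0L)
    return(data.frame(position = integer(), aaig = character(),
                      cs = numeric(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(s_x ~ position + aaig, data = scored, FUN = sum)
  names(agg)[3L] <- "cs"
  agg[order(agg$position, agg$aaig), ]
}

#' Assemble aligned chains into contigs
#'
#' Overlap-layout-consensus step: aligned chains of identical length L are
#' merged into contigs wherever their AAIG series and alignment offsets
#' overlap by exactly L-1.  A contig terminates when no overlap extends it
#' or when extension would re-introduce an AAIG already part of it.  Chains
#' that cannot be merged with any other chain are considered spurious and
#' discarded.
#'
#' @param aligned_chains List of aligned chains, each a list with `aaigs`
#'   (character vector) and `pos1` (sequence position of the first AAIG).
#' @return List of contigs, each a list with `aaigs`, `pos1` and `n_chains`
#'   (number of member chains).
#' @export
assemble_contigs <- function(aligned_chains) {
  if (!length(aligned_chains)) return(list())
  key <- vapply(aligned_chains, function(ch)
    paste(ch$pos1, paste(ch$aaigs, collapse = "\r"), sep = "|"),
    character(1))
  aligned_chains <- aligned_chains[!duplicated(key)]
  L <- unique(vapply(aligned_chains, function(ch) length(ch$aaigs),
                     integer(1)))
  if (length(L) != 1L) stop("all chains must have the same length")
  pre_key <- vapply(aligned_chains, function(ch)
    paste(ch$pos1, paste(ch$aaigs[seq_len(L - 1L)], collapse = "\r"),
          sep = "|"), character(1))
  suf_key <- vapply(aligned_chains, function(ch)
    paste(ch$pos1 + 1L, paste(ch$aaigs[-1L], collapse = "\r"), sep = "|"),
    character(1))
  succ <- lapply(suf_key, function(k) which(pre_key == k))
  has_pred <- pre_key %in% suf_key
  contigs <- list()
  walk <- function(i, aaigs, pos1) {
    ext <- succ[[i]]
    ext <- ext[!vapply(ext, function(j)
      aligned_chains[[j]]$aaigs[L] %in% aaigs, logical(1))]
    if (!length(ext)) {
      if (length(aaigs) > L)   # at least two member chains
        contigs[[length(contigs) + 1L]] <<-
          list(aaigs = aaigs, pos1 = pos1, n_chains = length(aaigs) - L + 1L)
      return()
    }
    for (j in ext)
      walk(j, c(aaigs, aligned_chains[[j]]$aaigs[L]), pos1)
  }
  for (i in seq_along(aligned_chains)) {
    if (!has_pred[i])
      walk(i, aligned_chains[[i]]$aaigs, aligned_chains[[i]]$pos1)
  }
  contigs
}

#' Consensus assignment of AAIGs to sequence positions
#'
#' A position is assigned iff (a) every contig covering it proposes the same
#' AAIG (absolute consensus) and (b) that AAIG holds the strictly highest
#' confidence score among all AAIGs proposed for the position.  Assignments
#' are bidirectionally exclusive: an AAIG claimed by two positions is kept
#' only at the position where its confidence score is strictly higher, and
#' ties leave both positions unassigned.
#'
#' @param contigs List from [assemble_contigs()].
#' @param cs Data frame from [confidence_scores()].
#' @param state Mapping state (list with named character vector `assigned`,
#'   names = positions); already-assigned positions and AAIGs are skipped.
#' @return Data frame of new assignments: `position`, `aaig`, `cs`.
#' @export
consensus_assign <- function(contigs, cs, state = list(assigned = character())) {
  empty <- data.frame(position = integer(), aaig = character(),
                      cs = numeric(), stringsAsFactors = FALSE)
  if (!length(contigs)) return(empty)
  prop <- do.call(rbind, lapply(contigs, function(ct)
    data.frame(position = ct$pos1 + seq_along(ct$aaigs) - 1L,
               aaig = ct$aaigs, stringsAsFactors = FALSE)))
  prop <- unique(prop)
  cand <- list()
  for (p in unique(prop$position)) {
    if (as.character(p) %in% names(state$assigned)) next
    who <- unique(prop$aaig[prop$position == p])
    if (length(who) != 1L) next                    # consensus violated
    if (who %in% state$assigned) next              # AAIG already used
    cs_p <- cs[cs$position == p, ]
    me <- cs_p$cs[cs_p$aaig == who]
    if (!length(me)) next
    others <- cs_p$cs[cs_p$aaig != who]
    if (length(others) && max(others) >= me) next  # not the clear maximum
    # symmetric condition: p must also be this AAIG's best-scoring position
    elsewhere <- cs$cs[cs$aaig == who & cs$position != p]
    if (length(elsewhere) && max(elsewhere) >= me) next
    cand[[length(cand) + 1L]] <-
      data.frame(position = p, aaig = who, cs = me, stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  # bidirectional exclusivity: one position per AAIG, strict-max tie-break
  keep <- logical(nrow(cand))
  for (a in unique(cand$aaig)) {
    rows <- which(cand$aaig == a)
    if (length(rows) == 1L) { keep[rows] <- TRUE; next }
    best <- rows[cand$cs[rows] == max(cand$cs[rows])]
    if (length(best) == 1L) keep[best] <- TRUE
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

#' Default iterative mapping schedule
#'
#' Rounds proceed from long, stringent chains to short, permissive ones:
#' chain length L from 6 down to 3 while the Z-score cutoff and minimum
#' occupancy are loosened; the final round repeats until it adds nothing.
#'
#' @return Data frame with columns `L`, `zcut`, `min_occ`.
#' @export
default_schedule <- function() {
  data.frame(L = c(6L, 5L, 4L, 3L),
             zcut = c(0, -0.5, -1, -1),
             min_occ = c(0.5, 0.4, 0.3, 0.3))
}

# internal: one mapping round; returns list(new, rows) where new is the
# consensus-assignment data frame
map_round <- function(aaig_set, sequence, preds, conns, L, zcut, min_occ,
                      state, sub = blosum90(), min_posterior = 1e-4) {
  n_seq <- length(sequence)
  conn_r <- conns[conns$occupancy >= min_occ, , drop = FALSE]
  chains <- build_chains(conn_r, L_max = L, L_min = L)
  empty <- list(new = consensus_assign(list(),
                                       confidence_scores(
                                         data.frame(position = integer(),
                                                    aaig = character(),
                                                    s_x = numeric()))),
                n_chains = length(chains))
  if (!length(chains) || n_seq - L + 1L < 2L) return(empty)
  pos_of <- structure(as.integer(names(state$assigned)),
                      names = state$assigned)
  rows <- list(); aligned <- list()
  for (ch in chains) {
    members <- ch$aaigs
    kept <- lapply(members, function(a) {
      p <- preds[[a]]
      if (is.null(p) || nrow(p) == 0L) return(NULL)
      zscore_filter(p, zcut, min_posterior = min_posterior)
    })
    if (any(vapply(kept, is.null, logical(1)))) next
    for (pos1 in 2:(n_seq - L + 1L)) {
      pos <- pos1 + seq_len(L) - 1L
      if (any(sequence[pos] == "P")) next
      ok <- TRUE; post <- numeric(L); letters_ <- character(L)
      for (k in seq_len(L)) {
        aa_k <- sequence[pos[k] - 1L]
        r <- match(aa_k, kept[[k]]$aa)
        if (is.na(r)) { ok <- FALSE; break }
        # consistency with the established mapping
        ass <- state$assigned[as.character(pos[k])]
        if (!is.na(ass) && ass != members[k]) { ok <- FALSE; break }
        mp <- pos_of[members[k]]
        if (!is.na(mp) && mp != pos[k]) { ok <- FALSE; break }
        post[k] <- kept[[k]]$posterior[r]
        letters_[k] <- aa_k
      }
      if (!ok) next
      s_align <- stats::plogis(sum(sub[cbind(letters_, letters_)]) / L)
      rows[[length(rows) + 1L]] <-
        data.frame(position = pos, aaig = members, posterior = post,
                   p_chain = ch$p_chain, s_align = s_align,
                   stringsAsFactors = FALSE)
      aligned[[length(aligned) + 1L]] <- list(aaigs = members, pos1 = pos1)
    }
  }
  if (!length(rows)) return(empty)
  scored <- score_assignments(do.call(rbind, rows))
  cs <- confidence_scores(scored)
  contigs <- assemble_contigs(aligned)
  list(new = consensus_assign(contigs, cs, state), n_chains = length(chains))
}

# internal: restrain predictions and connectivities with the current mapping
restrain_state <- function(preds, conns, state, sequence) {
  pos_of <- structure(as.integer(names(state$assigned)),
                      names = state$assigned)
  n <- length(sequence)
  for (a in names(pos_of)) {
    p <- pos_of[[a]]
    aa_prev <- sequence[p - 1L]
    pr <- preds[[a]]
    row <- if (!is.null(pr) && aa_prev %in% pr$aa) {
      r <- pr[pr$aa == aa_prev, , drop = FALSE]; r$zscore <- Inf; r
    } else {
      data.frame(aa = aa_prev, p_ccs = NA_real_, prior = NA_real_,
                 posterior = 1, zscore = Inf, stringsAsFactors = FALSE)
    }
    preds[[a]] <- row
  }
  if (nrow(conns)) {
    pT <- pos_of[conns$tocsy_aaig]
    pN <- pos_of[conns$noesy_aaig]
    assigned_pos <- as.integer(names(state$assigned))
    keep <- rep(TRUE, nrow(conns))
    for (i in seq_len(nrow(conns))) {
      if (!is.na(pT[i]) && !is.na(pN[i])) {
        keep[i] <- (pN[i] == pT[i] - 1L)
      } else if (!is.na(pT[i])) {
        prev <- pT[i] - 1L
        keep[i] <- prev >= 2L && sequence[prev] != "P" &&
          !(prev %in% assigned_pos)
      } else if (!is.na(pN[i])) {
        nxt <- pN[i] + 1L
        keep[i] <- nxt <= n && sequence[nxt] != "P" &&
          !(nxt %in% assigned_pos)
      }
    }
    conns <- conns[keep, , drop = FALSE]
  }
  list(preds = preds, conns = conns)
}

#' Iterative mapping of AAIGs onto the protein sequence
#'
#' Runs the full mapping loop: per round, build chains of the scheduled
#' length from sufficiently occupied connectivities, translate them to
#' peptides through the Z-score-filtered type predictions, align, score,
#' assemble contigs and accept absolute-consensus assignments; then restrain
#' the next round by eliminating type predictions and connectivities that
#' contradict the mapping.  Assignments are never revoked; the final
#' schedule row repeats until it adds nothing.
#'
#' @param aaig_set An `aaig_set`.
#' @param sequence Character vector of residues.
#' @param predictions Named list of per-AAIG prediction frames (default:
#'   computed internally).
#' @param connectivities Connectivity data frame (default: computed with
#'   `min_occupancy` 0.2 and filtered per round).
#' @param stats A `stats_library` (needed only when `predictions` is NULL).
#' @param schedule Data frame of rounds, see [default_schedule()].
#' @param tol A [tolerances()] object.
#' @param verbose Log per-round counts with `message()`.
#' @return A mapping state: list with `assigned` (named character vector,
#'   names = sequence positions, values = AAIG labels), `log` (data frame
#'   of `round`, `position`, `aaig`, `cs`), and the restrained
#'   `predictions` and `connectivities`.
#' @export
iterate_mapping <- function(aaig_set, sequence, predictions = NULL,
                            connectivities = NULL, stats = NULL,
                            schedule = default_schedule(),
                            tol = tolerances(), verbose = FALSE) {
  if (is.null(predictions)) {
    if (is.null(stats)) stop("need either predictions or stats")
    predictions <- predict_all_aaigs(aaig_set, sequence, stats)
  }
  if (is.null(connectivities))
    connectivities <- compute_connectivities(aaig_set, tol,
                                             min_occupancy = 0.2)
  state <- list(assigned = character(0),
                log = data.frame(round = integer(), position = integer(),
                                 aaig = character(), cs = numeric(),
                                 stringsAsFactors = FALSE))
  preds <- predictions; conns <- connectivities
  run_round <- function(rnd, round_id) {
    res <- map_round(aaig_set, sequence, preds, conns,
                     L = rnd$L, zcut = rnd$zcut, min_occ = rnd$min_occ,
                     state, sub = blosum90())
    new <- res$new
    if (nrow(new)) {
      add <- structure(new$aaig, names = as.character(new$position))
      state$assigned <<- c(state$assigned, add)
      state$log <<- rbind(state$log,
                          data.frame(round = round_id, position = new$position,
                                     aaig = new$aaig, cs = new$cs,
                                     stringsAsFactors = FALSE))
      r <- restrain_state(preds, conns, state, sequence)
      preds <<- r$preds; conns <<- r$conns
    }
    if (verbose)
      message(sprintf("round %d (L=%d z>=%.1f occ>=%.2f): %d chains, +%d assigned (total %d)",
                      round_id, rnd$L, rnd$zcut, rnd$min_occ,
                      res$n_chains, nrow(new), length(state$assigned)))
    nrow(new)
  }
  round_id <- 0L
  for (i in seq_len(nrow(schedule))) {
    round_id <- round_id + 1L
    run_round(schedule[i, ], round_id)
  }
  last <- schedule[nrow(schedule), ]
  repeat {
    round_id <- round_id + 1L
    if (run_round(last, round_id) == 0L || round_id > nrow(schedule) + 15L)
      break
  }
  state$predictions <- preds
  state$connectivities <- conns
  state
}
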