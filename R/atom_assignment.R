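nucleus_of <- function(atom) {
  ifelse(startsWith(atom, "C"), "13C",
         ifelse(startsWith(atom, "N"), "15N", "1H"))
}

entry_row <- function(residue, atom, shift, provenance, score = NA_real_) {
  data.frame(residue = as.integer(residue), atom = atom, shift = shift,
             nucleus = nucleus_of(atom), provenance = provenance,
             score = score, stringsAsFactors = FALSE)
}

empty_entries <- function() entry_row(integer(0), character(0), numeric(0),
                                      character(0), numeric(0))

# internal: shift-table rows for one explained unit (carbon + its protons)
unit_entries <- function(unit, pairs, aa, residue, provenance, score) {
  protons <- proton_names(aa, unit$carbon)
  idx <- unit$idx
  rows <- entry_row(residue, unit$carbon, mean(pairs$c[idx]), provenance,
                    score)
  hs <- sort(pairs$h[idx], decreasing = TRUE)
  pn <- protons[seq_along(hs)]
  rbind(rows, entry_row(residue, pn, hs, provenance, score))
}

#' Atom-type assignment of a TOCSY spin system with known residue type
#'
#' With the amino-acid type fixed by the sequence mapping, re-runs the
#' atom-type combination search of [p_ccs_given_aa()] and converts the
#' highest-probability permutation into per-atom assignments: grouped
#' methylene pairs share one carbon shift (the mean of the grouped carbons)
#' and their protons are named in decreasing shift order.
#'
#' @param pairs TOCSY CH-pair data frame of the AAIG.
#' @param aa Residue type (one-letter code) of the preceding residue.
#' @param residue Sequence position of the preceding residue.
#' @param stats A `stats_library`.
#' @param methylene_tol Methylene grouping tolerance (ppm 13C).
#' @return List with `entries` (assignment-table rows, provenance `TOCSY`)
#'   and `peaks` (data frame mapping peak rows to atoms); both empty, with
#'   a warning, when no combination has nonzero probability.
#' @export
assign_tocsy_atoms <- function(pairs, aa, residue, stats,
                               methylene_tol = 0.2) {
  if (nrow(pairs) == 0L)
    return(list(entries = empty_entries(),
                peaks = data.frame(peak_row = integer(), atom_c = character(),
                                   atom_h = character())))
  best <- p_ccs_given_aa(pairs, aa, stats, methylene_tol)
  if (is.null(best$combo)) {
    warning("residue ", residue, " (", aa,
            "): zero-probability atom-type combination; left untyped")
    return(list(entries = empty_entries(),
                peaks = data.frame(peak_row = integer(), atom_c = character(),
                                   atom_h = character())))
  }
  entries <- do.call(rbind, lapply(best$combo, unit_entries, pairs, aa,
                                   residue, "TOCSY", best$p))
  peaks <- do.call(rbind, lapply(best$combo, function(unit) {
    ord <- unit$idx[order(-pairs$h[unit$idx])]
    pn <- proton_names(aa, unit$carbon)[seq_along(ord)]
    data.frame(peak_row = pairs$peak_row[ord], atom_c = unit$carbon,
               atom_h = pn, stringsAsFactors = FALSE)
  }))
  list(entries = entries, peaks = peaks)
}

# internal: TOCSY typing for every mapped AAIG; residue i-1 of each amide
assign_all_tocsy <- function(state, aaig_set, sequence, stats,
                             methylene_tol = 0.2) {
  entries <- list(); annot <- list()
  for (pch in names(state$assigned)) {
    p <- as.integer(pch)
    a <- state$assigned[[pch]]
    aa_prev <- sequence[p - 1L]
    res <- assign_tocsy_atoms(aaig_set$aaigs[[a]]$tocsy, aa_prev, p - 1L,
                              stats, methylene_tol)
    if (nrow(res$entries)) {
      entries[[length(entries) + 1L]] <- res$entries
      annot[[length(annot) + 1L]] <-
        data.frame(aaig = a, peak_row = res$peaks$peak_row,
                   residue = p - 1L, aa = aa_prev,
                   atom_c = res$peaks$atom_c, atom_h = res$peaks$atom_h,
                   stringsAsFactors = FALSE)
    }
  }
  list(entries = if (length(entries)) do.call(rbind, entries)
       else empty_entries(),
       annotations = if (length(annot)) do.call(rbind, annot)
       else data.frame(aaig = character(), peak_row = integer(),
                       residue = integer(), aa = character(),
                       atom_c = character(), atom_h = character(),
                       stringsAsFactors = FALSE))
}

# internal: (carbon, proton) targets of one residue from the shift table
residue_targets <- function(table, residue, aa) {
  t_r <- table[table$residue == residue, ]
  if (!nrow(t_r)) return(NULL)
  top <- aa_topology(aa)
  out <- list()
  for (i in seq_len(nrow(top))) {
    cb <- top$carbon[i]
    crow <- t_r[t_r$atom == cb, ]
    if (!nrow(crow)) next
    for (pn in strsplit(top$protons[i], ",", fixed = TRUE)[[1L]]) {
      prow <- t_r[t_r$atom == pn, ]
      if (nrow(prow))
        out[[length(out) + 1L]] <-
          data.frame(atom_c = cb, atom_h = pn, c = crow$shift[1L],
                     h = prow$shift[1L], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Transfer TOCSY-derived assignments to the NOESY spectrum
#'
#' Walks the mapped sequence from the last residue backwards; for each amide
#' the intraresidue NOE peaks are labelled first, by matching the known
#' shifts of the amide's own residue (assigned from the TOCSY of the
#' successive residue), and then the sequential NOE peaks, by matching the
#' known shifts of the preceding residue.  Each NOESY peak receives at most
#' one label and each target atom at most one peak; the closest match in
#' tolerance-scaled distance wins.
#'
#' @param state Mapping state from [iterate_mapping()].
#' @param aaig_set An `aaig_set`.
#' @param table Assignment table (TOCSY entries).
#' @param sequence Residue vector.
#' @param tol A [tolerances()] object.
#' @return Annotation data frame: `aaig`, `peak_row`, `residue`, `aa`,
#'   `atom_c`, `atom_h`, `kind` (`intra` or `sequential`).
#' @export
transfer_to_noesy <- function(state, aaig_set, table, sequence,
                              tol = tolerances()) {
  out <- list()
  positions <- sort(as.integer(names(state$assigned)), decreasing = TRUE)
  for (p in positions) {
    a <- state$assigned[[as.character(p)]]
    np <- aaig_set$aaigs[[a]]$noesy
    if (is.null(np) || nrow(np) == 0L) next
    used_peak <- rep(FALSE, nrow(np))
    for (kind in c("intra", "sequential")) {
      r <- if (kind == "intra") p else p - 1L
      if (r < 1L) next
      targets <- residue_targets(table, r, sequence[r])
      if (is.null(targets)) next
      dc <- abs(outer(np$c, targets$c, "-")) / tol$tol_c
      dh <- abs(outer(np$h, targets$h, "-")) / tol$tol_h
      dist <- sqrt(dc^2 + dh^2)
      dist[dc > 1 | dh > 1] <- Inf
      dist[used_peak, ] <- Inf   # intra labels take precedence
      repeat {
        if (!any(is.finite(dist))) break
        m <- arrayInd(which.min(dist), dim(dist))
        i <- m[1L]; j <- m[2L]
        out[[length(out) + 1L]] <-
          data.frame(aaig = a, peak_row = np$peak_row[i], residue = r,
                     aa = sequence[r], atom_c = targets$atom_c[j],
                     atom_h = targets$atom_h[j], kind = kind,
                     stringsAsFactors = FALSE)
        used_peak[i] <- TRUE
        dist[i, ] <- Inf; dist[, j] <- Inf
      }
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  } else {
    data.frame(aaig = character(), peak_row = integer(), residue = integer(),
               aa = character(), atom_c = character(), atom_h = character(),
               kind = character(), stringsAsFactors = FALSE)
  }
}

# internal: N / amide-H table rows for every mapped position
root_entries <- function(state, aaig_set) {
  rows <- list()
  for (pch in names(state$assigned)) {
    a <- aaig_set$aaigs[[state$assigned[[pch]]]]
    p <- as.integer(pch)
    rows[[length(rows) + 1L]] <-
      rbind(entry_row(p, "N", a$n15, "root"),
            entry_row(p, "H", a$hn, "root"))
  }
  if (length(rows)) do.call(rbind, rows) else empty_entries()
}

#' Complete missing assignments from common NOEs
#'
#' Scans the sequence backwards.  For a residue i with missing aliphatic
#' atom types, the unassigned NOESY peaks of amide i are matched against the
#' unassigned NOESY peaks of amide i+1: a common NOE reports an aliphatic
#' atom of residue i.  Per amide, NOESY intensities are normalized to the
#' strongest peak of the spin system and peaks below `intensity_threshold`
#' are left out.  Each matched peak is scored per candidate atom type as
#' `density x (100 x intensity^2)`; candidates whose density fails the map's
#' `percentile` cutoff are dropped, and the highest score (the score product
#' for a grouped methylene) yields the assignment.  The quadratic intensity
#' transform favours methyls, whose intraresidue amide NOEs are strong.
#'
#' @param state Mapping state.
#' @param aaig_set An `aaig_set`.
#' @param table Current assignment table.
#' @param sequence Residue vector.
#' @param stats A `stats_library`.
#' @param annotations NOESY annotations from [transfer_to_noesy()] (their
#'   peaks count as already assigned).
#' @param tol A [tolerances()] object.
#' @param intensity_threshold Normalized-intensity cutoff (default 0.1).
#' @param percentile Density-map percentile filter (default 80).
#' @param methylene_tol Methylene grouping tolerance (ppm 13C).
#' @return List with `entries` (new assignment rows, provenance
#'   `NOESY-common`) and `annotations` (peak labels added by this step).
#' @export
extend_from_common_noes <- function(state, aaig_set, table, sequence, stats,
                                    annotations = NULL, tol = tolerances(),
                                    intensity_threshold = 0.1,
                                    percentile = 80, methylene_tol = 0.2) {
  used <- new.env(parent = emptyenv())
  mark <- function(a, pr) assign(paste(a, pr), TRUE, envir = used)
  is_used <- function(a, pr)
    vapply(pr, function(x) exists(paste(a, x), envir = used), logical(1))
  if (!is.null(annotations) && nrow(annotations))
    for (i in seq_len(nrow(annotations)))
      mark(annotations$aaig[i], annotations$peak_row[i])
  pos_of <- structure(state$assigned, names = names(state$assigned))
  label_at <- function(p) {
    k <- as.character(p)
    if (k %in% names(pos_of)) pos_of[[k]] else NULL
  }
  entries <- list(); annot <- list()
  avail <- function(label) {
    np <- aaig_set$aaigs[[label]]$noesy
    if (is.null(np) || nrow(np) == 0L) return(NULL)
    mx <- max(abs(np$intensity))
    np$norm <- if (mx > 0) abs(np$intensity) / mx else 0
    np <- np[!is_used(label, np$peak_row) & np$norm >= intensity_threshold, ]
    if (nrow(np)) np else NULL
  }
  for (r in rev(seq_len(length(sequence) - 1L))) {
    a_i <- label_at(r)
    a_n <- label_at(r + 1L)
    if (is.null(a_i) || is.null(a_n)) next
    aa <- sequence[r]
    top <- aa_topology(aa)
    missing <- setdiff(top$carbon,
                       table$atom[table$residue == r])
    if (!length(missing)) next
    u <- avail(a_i); v <- avail(a_n)
    if (is.null(u) || is.null(v)) next
    hit <- (abs(outer(u$c, v$c, "-")) <= tol$tol_c) &
           (abs(outer(u$h, v$h, "-")) <= tol$tol_h)
    mu <- which(rowSums(hit) > 0L)
    if (!length(mu)) next
    u <- u[mu, ]; hit <- hit[mu, , drop = FALSE]
    # closest counterpart in the next amide, for marking as consumed
    buddy <- vapply(seq_len(nrow(u)), function(i) {
      js <- which(hit[i, ])
      js[which.min((u$c[i] - v$c[js])^2 / tol$tol_c^2 +
                   (u$h[i] - v$h[js])^2 / tol$tol_h^2)]
    }, integer(1))
    # candidates per missing carbon
    cand <- list()
    for (cb in missing) {
      srow <- top[top$carbon == cb, ]
      map <- stats_map(stats, aa, srow$atom_type)
      cutoff <- percentile_cutoff(map, percentile)
      d <- density_at(map, u$h, u$c)
      pass <- which(d >= cutoff)
      if (!length(pass)) next
      sc <- d[pass] * (100 * u$norm[pass]^2)
      if (srow$group == "CH2" && length(pass) > 1L) {
        prs <- utils::combn(seq_along(pass), 2L)
        grp <- FALSE
        for (q in seq_len(ncol(prs))) {
          i1 <- pass[prs[1L, q]]; i2 <- pass[prs[2L, q]]
          if (abs(u$c[i1] - u$c[i2]) <= methylene_tol) {
            grp <- TRUE
            cand[[length(cand) + 1L]] <-
              list(carbon = cb, idx = c(i1, i2),
                   score = sc[prs[1L, q]] * sc[prs[2L, q]])
          }
        }
        if (grp) next   # grouped methylene preferred over a lone proton
      }
      for (q in seq_along(pass))
        cand[[length(cand) + 1L]] <-
          list(carbon = cb, idx = pass[q], score = sc[q])
    }
    if (!length(cand)) next
    ord <- order(-vapply(cand, `[[`, numeric(1), "score"),
                 vapply(cand, `[[`, character(1), "carbon"),
                 vapply(cand, function(x) min(x$idx), numeric(1)))
    done_c <- character(0); done_u <- integer(0)
    for (ci in ord) {
      cc <- cand[[ci]]
      if (cc$carbon %in% done_c || any(cc$idx %in% done_u)) next
      done_c <- c(done_c, cc$carbon); done_u <- c(done_u, cc$idx)
      idx <- cc$idx[order(-u$h[cc$idx])]
      pn <- proton_names(aa, cc$carbon)[seq_along(idx)]
      entries[[length(entries) + 1L]] <-
        rbind(entry_row(r, cc$carbon, mean(u$c[idx]), "NOESY-common",
                        cc$score),
              entry_row(r, pn, u$h[idx], "NOESY-common", cc$score))
      for (k in seq_along(idx)) {
        i <- idx[k]
        mark(a_i, u$peak_row[i]); mark(a_n, v$peak_row[buddy[i]])
        annot[[length(annot) + 1L]] <- rbind(
          data.frame(aaig = a_i, peak_row = u$peak_row[i], residue = r,
                     aa = aa, atom_c = cc$carbon, atom_h = pn[k],
                     kind = "intra", stringsAsFactors = FALSE),
          data.frame(aaig = a_n, peak_row = v$peak_row[buddy[i]],
                     residue = r, aa = aa, atom_c = cc$carbon,
                     atom_h = pn[k], kind = "sequential",
                     stringsAsFactors = FALSE))
      }
      table <- rbind(table, entries[[length(entries)]][, names(table)])
    }
  }
  list(entries = if (length(entries)) do.call(rbind, entries)
       else empty_entries(),
       annotations = if (length(annot)) do.call(rbind, annot)
       else data.frame(aaig = character(), peak_row = integer(),
                       residue = integer(), aa = character(),
                       atom_c = character(), atom_h = character(),
                       kind = character(), stringsAsFactors = FALSE))
}

#' Merge assignment sources into one shift table
#'
#' Binds entry frames and resolves (residue, atom) conflicts by provenance
#' priority `root` > `TOCSY` > `NOESY-intra` > `NOESY-common` (TOCSY-derived
#' shifts carry the lower error rate); discarded conflicting entries are
#' attached as the `"conflicts"` attribute.
#'
#' @param ... Entry data frames.
#' @return A single assignment table ordered by residue and atom.
#' @export
build_shift_table <- function(...) {
  tabs <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (!length(tabs)) return(empty_entries())
  all <- do.call(rbind, tabs)
  prio <- match(all$provenance,
                c("root", "TOCSY", "NOESY-intra", "NOESY-common"))
  prio[is.na(prio)] <- 5L
  ord <- order(all$residue, atom_rank(all$atom), all$atom, prio)
  all <- all[ord, ]
  key <- paste(all$residue, all$atom)
  dup <- duplicated(key)
  conflicts <- all[dup, ]
  out <- all[!dup, ]
  rownames(out) <- NULL
  if (nrow(conflicts))
    message(nrow(conflicts), " conflicting assignment(s) resolved by provenance")
  attr(out, "conflicts") <- conflicts
  out
}

#' Assign all aliphatic atoms from the NOESY spectrum alone
#'
#' The NOESY-only scenario: backbone amide 15N-1H assignments are supplied
#' externally, the sequence mapping step is skipped, and every aliphatic
#' atom is sought through the common-NOE logic of
#' [extend_from_common_noes()] applied with all atom types missing.
#'
#' @param sequence Residue vector.
#' @param nh_table Data frame with columns `position`, `n15`, `hn`: the
#'   fixed amide assignments.
#' @param noesy 4D NOESY peak data frame.
#' @param stats A `stats_library`.
#' @param tol A [tolerances()] object.
#' @inheritParams extend_from_common_noes
#' @return List with `table` (assignment table), `annotations`, `state` and
#'   `aaig_set`.
#' @export
run_noesy_only <- function(sequence, nh_table, noesy, stats,
                           tol = tolerances(), intensity_threshold = 0.1,
                           percentile = 80, methylene_tol = 0.2) {
  n <- length(sequence)
  pos <- as.integer(nh_table$position)
  if (anyNA(pos) || any(pos < 1L | pos > n))
    stop("NH table positions outside the sequence")
  if (any(sequence[pos] == "P"))
    stop("NH table assigns an amide to a proline")
  if (anyDuplicated(pos)) stop("duplicate positions in NH table")
  roots <- data.frame(label = paste0(sequence[pos], pos),
                      n15 = nh_table$n15, hn = nh_table$hn,
                      stringsAsFactors = FALSE)
  aaig_set <- cluster_peaks(NULL, noesy, roots, tol)
  state <- list(assigned = structure(roots$label,
                                     names = as.character(pos)))
  table <- root_entries(state, aaig_set)
  ext <- extend_from_common_noes(state, aaig_set, table, sequence, stats,
                                 annotations = NULL, tol = tol,
                                 intensity_threshold = intensity_threshold,
                                 percentile = percentile,
                                 methylene_tol = methylene_tol)
  list(table = build_shift_table(table, ext$entries),
       annotations = ext$annotations, state = state, aaig_set = aaig_set)
}
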