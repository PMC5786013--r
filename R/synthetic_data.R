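#' Configuration of the synthetic-data generator
#'
#' The generator emulates the statistical structure the assignment
#' algorithm relies on: per-amide TOCSY patterns holding the aliphatic CH
#' resonances of the preceding residue, NOESY spin systems holding
#' intraresidue (presence `p_noe_intra`, default 0.99) and sequential
#' (presence `p_noe_seq`, default 0.89) CH correlations, chemical-shift
#' jitter, missing TOCSY peaks, and spurious NOESY peaks standing in for
#' long-range NOEs and artifacts.  Jitter is decomposed into a
#' resonance-level offset per (atom, spectrum) — shared by the two peaks of
#' a geminal methylene pair, which observe one carbon frequency — plus a
#' small per-peak picking error.
#'
#' @param n_residues Protein length.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param sigma_c,sigma_h Resonance-level jitter SD (ppm) for aliphatic
#'   13C / 1H.
#' @param sigma_pick_c,sigma_pick_h Per-peak picking error SD (ppm).
#' @param sigma_n15,sigma_hn Per-peak amide 15N / 1H jitter SD (ppm).
#' @param p_tocsy_missing Probability a TOCSY peak is absent.
#' @param p_tocsy_noise Spurious-peak rate in the TOCSY list (per real
#'   peak); near zero in practice since TOCSY picking is clean.
#' @param p_noise_peaks Spurious-peak rate in the NOESY list (per real
#'   peak).
#' @param p_noe_intra,p_noe_seq Presence probabilities of intraresidue and
#'   sequential NOE correlations.
#' @param seq_dropout Named list of extra sequential dropout per amino acid
#'   and carbon (`list(K = c(CD = 0.3, CE = 0.4), ...)`).
#' @param amide_n_mean,amide_n_sd,amide_hn_mean,amide_hn_sd Amide shift
#'   distribution (ppm).
#' @param min_root_sep Minimum tolerance-scaled separation enforced between
#'   root resonances (truly overlapped amides are out of scope).
#' @param intensity_sdlog Log-normal intensity spread.
#' @param methyl_boost Intensity multiplier for intraresidue methyl NOEs.
#' @param composition Amino-acid composition to draw sequences from.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_residues = 120L, seed = 1L,
                             sigma_c = 0.1, sigma_h = 0.01,
                             sigma_pick_c = 0.02, sigma_pick_h = 0.002,
                             sigma_n15 = 0.05, sigma_hn = 0.01,
                             p_tocsy_missing = 0.1, p_tocsy_noise = 0,
                             p_noise_peaks = 0.05,
                             p_noe_intra = 0.99, p_noe_seq = 0.89,
                             seq_dropout = list(
                               K = c(CD = 0.3, CE = 0.4),
                               R = c(CD = 0.3),
                               M = c(CE = 0.5),
                               L = c(CG = 0.15),
                               I = c(CG1 = 0.15)),
                             amide_n_mean = 119, amide_n_sd = 4.5,
                             amide_hn_mean = 8.3, amide_hn_sd = 0.55,
                             min_root_sep = 1.0,
                             intensity_sdlog = 0.4, methyl_boost = 3,
                             composition = default_composition()) {
  probs <- c(p_tocsy_missing, p_tocsy_noise, p_noise_peaks, p_noe_intra,
             p_noe_seq, unlist(seq_dropout))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  sig <- c(sigma_c, sigma_h, sigma_pick_c, sigma_pick_h, sigma_n15, sigma_hn)
  if (any(sig < 0)) stop("jitter SDs must be nonnegative")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Default amino-acid composition (typical globular-protein frequencies)
#' @return Named numeric vector over the 20 standard types, summing to 1.
#' @export
default_composition <- function() {
  p <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.4, C = 1.4, Q = 3.9, E = 6.8,
         G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
         P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  p / sum(p)
}

#' Draw a random protein sequence
#' @param n Number of residues (>= 2).
#' @param seed Integer seed.
#' @param composition Named amino-acid frequencies.
#' @return Character vector of one-letter codes.
#' @export
sample_sequence <- function(n, seed = 1L, composition = default_composition()) {
  if (!is.numeric(n) || n < 2) stop("need at least 2 residues")
  with_seed(seed,
            sample(names(composition), n, replace = TRUE, prob = composition))
}

# internal: draw m points from a density map (kernel smoothing of a random
# record)
kde_sample <- function(map, m) {
  idx <- sample.int(map$n, m, replace = TRUE)
  list(c = map$c[idx] + stats::rnorm(m, 0, map$h_C),
       h = map$h[idx] + stats::rnorm(m, 0, map$h_H))
}

#' Sample ground-truth chemical shifts for a sequence
#'
#' Every aliphatic atom's (C, H) is drawn from its own density map (the same
#' maps the classifier uses), amide 15N/1H from configured Gaussians.
#' Prolines and the N-terminal residue carry no observable amide.  Root
#' resonances closer than `min_root_sep` tolerance-scaled units are
#' resampled, since resolving truly overlapped amides is out of scope.
#'
#' @param sequence Residue vector.
#' @param stats A `stats_library`.
#' @param config A [synthetic_config()].
#' @param seed Integer seed (defaults to `config$seed + 1`).
#' @return Ground truth: list with `sequence`, `amide` (position, label,
#'   n15, hn) and `atoms` (one row per proton: residue, aa, carbon, proton,
#'   group, atom_type, c, h).
#' @export
sample_true_shifts <- function(sequence, stats, config = synthetic_config(),
                               seed = config$seed + 1L) {
  n <- length(sequence)
  with_seed(seed, {
    pos <- which(sequence != "P")
    pos <- pos[pos >= 2L]
    n15 <- stats::rnorm(length(pos), config$amide_n_mean, config$amide_n_sd)
    hn <- stats::rnorm(length(pos), config$amide_hn_mean, config$amide_hn_sd)
    ref <- tolerances()
    for (it in seq_len(200L)) {
      d2 <- outer(n15, n15, "-")^2 / ref$tol_n15^2 +
            outer(hn, hn, "-")^2 / ref$tol_hn^2
      clash <- which(d2 < config$min_root_sep^2 & upper.tri(d2),
                     arr.ind = TRUE)
      if (!nrow(clash)) break
      bad <- unique(clash[, 2L])   # resample the later root of each clash
      n15[bad] <- stats::rnorm(length(bad), config$amide_n_mean,
                               config$amide_n_sd)
      hn[bad] <- stats::rnorm(length(bad), config$amide_hn_mean,
                              config$amide_hn_sd)
    }
    amide <- data.frame(position = pos, label = paste0(sequence[pos], pos),
                        n15 = n15, hn = hn, stringsAsFactors = FALSE)
    rows <- list()
    for (r in seq_len(n)) {
      top <- aa_topology(sequence[r])
      for (i in seq_len(nrow(top))) {
        map <- stats_map(stats, sequence[r], top$atom_type[i])
        protons <- strsplit(top$protons[i], ",", fixed = TRUE)[[1L]]
        draw <- kde_sample(map, length(protons))
        hs <- sort(draw$h, decreasing = TRUE)   # proton names by shift order
        rows[[length(rows) + 1L]] <-
          data.frame(residue = r, aa = sequence[r], carbon = top$carbon[i],
                     proton = protons, group = top$group[i],
                     atom_type = top$atom_type[i],
                     c = draw$c[1L], h = hs, stringsAsFactors = FALSE)
      }
    }
    list(sequence = sequence, amide = amide, atoms = do.call(rbind, rows),
         config = config)
  })
}

#' Generate ground-truth-labelled 4D peak lists
#'
#' Emits the root list plus TOCSY and NOESY 4D peak lists implied by the
#' ground truth: for every amide at position i, TOCSY peaks for each
#' aliphatic CH of residue i-1 (dropped with `p_tocsy_missing`) and NOESY
#' peaks for residue i's own CH (kept with `p_noe_intra`) and residue
#' i-1's CH (kept with `p_noe_seq` minus atom-type-specific dropout).
#' Coordinates receive resonance-level and per-peak jitter; spurious peaks
#' are added uniformly over the occupied shift ranges; intensities are
#' log-normal with an intraresidue methyl boost.
#'
#' @param truth Ground truth from [sample_true_shifts()].
#' @param config A [synthetic_config()].
#' @param seed Integer seed (defaults to `config$seed + 2`).
#' @return List with `roots`, `tocsy`, `noesy` peak data frames and
#'   `peak_truth` (per-peak origin labels for `tocsy` and `noesy`).
#' @export
generate_peaklists <- function(truth, config = truth$config,
                               seed = config$seed + 2L) {
  seqv <- truth$sequence
  atoms <- truth$atoms
  amide <- truth$amide
  with_seed(seed, {
    # resonance-level offsets per (residue, carbon/proton, spectrum)
    ckey <- unique(paste(atoms$residue, atoms$carbon))
    off <- list()
    for (sp in c("tocsy", "noesy")) {
      off[[sp]] <- list(
        c = structure(stats::rnorm(length(ckey), 0, config$sigma_c),
                      names = ckey),
        h = structure(stats::rnorm(nrow(atoms), 0, config$sigma_h),
                      names = paste(atoms$residue, atoms$proton)))
    }
    dropout_of <- function(aa, carbon) {
      d <- config$seq_dropout[[aa]]
      if (!is.null(d) && carbon %in% names(d)) d[[carbon]] else 0
    }
    mk_peaks <- function(spec) {
      rows <- list(); lab <- list()
      for (k in seq_len(nrow(amide))) {
        p <- amide$position[k]
        parts <- if (spec == "tocsy") {
          if (p - 1L >= 1L) list(list(res = p - 1L, kind = "tocsy",
                                      keep = 1 - config$p_tocsy_missing))
        } else {
          c(list(list(res = p, kind = "intra", keep = config$p_noe_intra)),
            if (p - 1L >= 1L)
              list(list(res = p - 1L, kind = "sequential",
                        keep = config$p_noe_seq)))
        }
        for (part in parts) {
          at <- atoms[atoms$residue == part$res, ]
          if (!nrow(at)) next
          keep <- part$keep *
            if (part$kind == "sequential")
              1 - vapply(seq_len(nrow(at)), function(i)
                dropout_of(at$aa[i], at$carbon[i]), numeric(1))
            else rep(1, nrow(at))
          sel <- which(stats::runif(nrow(at)) < keep)
          if (!length(sel)) next
          at <- at[sel, ]
          m <- nrow(at)
          inten <- stats::rlnorm(m, 0, config$intensity_sdlog)
          if (spec == "noesy" && part$kind == "intra")
            inten <- inten * ifelse(at$group == "CH3", config$methyl_boost, 1)
          rows[[length(rows) + 1L]] <- data.frame(
            label = "?",
            h = at$h + off[[spec]]$h[paste(at$residue, at$proton)] +
              stats::rnorm(m, 0, config$sigma_pick_h),
            c = at$c + off[[spec]]$c[paste(at$residue, at$carbon)] +
              stats::rnorm(m, 0, config$sigma_pick_c),
            n15 = amide$n15[k] + stats::rnorm(m, 0, config$sigma_n15),
            hn = amide$hn[k] + stats::rnorm(m, 0, config$sigma_hn),
            intensity = inten, stringsAsFactors = FALSE)
          lab[[length(lab) + 1L]] <- data.frame(
            kind = part$kind, aaig_pos = p, residue = at$residue,
            carbon = at$carbon, proton = at$proton, noise = FALSE,
            stringsAsFactors = FALSE)
        }
      }
      peaks <- do.call(rbind, rows)
      labels <- do.call(rbind, lab)
      p_noise <- if (spec == "tocsy") config$p_tocsy_noise
                 else config$p_noise_peaks
      n_noise <- stats::rbinom(1L, nrow(peaks), p_noise)
      if (n_noise > 0L) {
        at_k <- sample.int(nrow(amide), n_noise, replace = TRUE)
        noise <- data.frame(
          label = "?",
          h = stats::runif(n_noise, min(peaks$h), max(peaks$h)),
          c = stats::runif(n_noise, min(peaks$c), max(peaks$c)),
          n15 = amide$n15[at_k] + stats::rnorm(n_noise, 0, config$sigma_n15),
          hn = amide$hn[at_k] + stats::rnorm(n_noise, 0, config$sigma_hn),
          intensity = stats::rlnorm(n_noise, 0, config$intensity_sdlog),
          stringsAsFactors = FALSE)
        peaks <- rbind(peaks, noise)
        labels <- rbind(labels, data.frame(
          kind = "noise", aaig_pos = amide$position[at_k],
          residue = NA_integer_, carbon = NA_character_,
          proton = NA_character_, noise = TRUE, stringsAsFactors = FALSE))
      }
      rownames(peaks) <- rownames(labels) <- NULL
      list(peaks = peaks, labels = labels)
    }
    toc <- mk_peaks("tocsy")
    noe <- mk_peaks("noesy")
    roots <- data.frame(
      label = amide$label,
      n15 = amide$n15 + stats::rnorm(nrow(amide), 0, config$sigma_n15 / 2),
      hn = amide$hn + stats::rnorm(nrow(amide), 0, config$sigma_hn / 2),
      stringsAsFactors = FALSE)
    list(roots = roots, tocsy = toc$peaks, noesy = noe$peaks,
         peak_truth = list(tocsy = toc$labels, noesy = noe$labels))
  })
}

#' Simulate a complete labelled dataset
#'
#' Sequence, ground-truth shifts and peak lists in one call; all randomness
#' derives from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param stats A `stats_library`.
#' @return List of class `synthetic_dataset` with `sequence`, `truth`,
#'   `roots`, `tocsy`, `noesy`, `peak_truth` and `config`.
#' @export
simulate_dataset <- function(config = synthetic_config(),
                             stats = default_stats_library()) {
  seqv <- sample_sequence(config$n_residues, seed = config$seed,
                          composition = config$composition)
  truth <- sample_true_shifts(seqv, stats, config)
  pk <- generate_peaklists(truth, config)
  structure(c(list(sequence = seqv, truth = truth, config = config), pk),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset: %d residues, %d roots, ",
                     "%d TOCSY + %d NOESY peaks, seed %d>\n"),
              length(x$sequence), nrow(x$roots), nrow(x$tocsy),
              nrow(x$noesy), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to Sparky/FASTA files
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "sequence.fasta"),
             roots = file.path(dir, "roots.list"),
             tocsy = file.path(dir, "tocsy.list"),
             noesy = file.path(dir, "noesy.list"),
             truth = file.path(dir, "truth_shifts.tsv"),
             amide = file.path(dir, "truth_amide.tsv"))
  write_fasta_sequence(ds$sequence, paths["fasta"])
  write_sparky_peaks(ds$roots, paths["roots"], axis_order = c("n15", "hn"))
  write_sparky_peaks(ds$tocsy, paths["tocsy"])
  write_sparky_peaks(ds$noesy, paths["noesy"])
  utils::write.table(ds$truth$atoms, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$amide, paths["amide"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

# internal: positions that the OLC mapping can reach in principle —
# members of runs of >= 4 consecutive amide-bearing positions (two
# overlapping minimum-length chains are needed to form a contig)
mappable_positions <- function(truth, min_run = 4L) {
  pos <- sort(truth$amide$position)
  if (!length(pos)) return(integer(0))
  runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
  unlist(runs[vapply(runs, length, integer(1)) >= min_run], use.names = FALSE)
}

#' Evaluate predicted assignments against the ground truth
#'
#' Scores an assignment run against the generator's truth: sequence-mapping
#' coverage and errors, and atom-level correctness of the carbon-type
#' assignments.  A carbon entry is correct when a truth atom of the same
#' residue carries an equivalent carbon label (prochiral methyl pairs of
#' Val/Leu may be swapped, as assignments are not stereo-specific) with a
#' 13C shift within `tol_c`.  Mapping completeness is reported over the
#' mappable positions: runs of at least four consecutive amide-bearing
#' positions, the minimum the contig rule can cover.
#'
#' @param table Assignment table.
#' @param state Mapping state (list with `assigned`); may be `NULL` for
#'   NOESY-only runs with externally fixed amides.
#' @param truth Ground truth.
#' @param tol_c,tol_h Correctness tolerances (ppm).
#' @return List of metric scalars and count tables.
#' @export
evaluate_assignments <- function(table, state, truth,
                                 tol_c = 0.4, tol_h = 0.04) {
  truth_lab <- structure(truth$amide$label,
                         names = as.character(truth$amide$position))
  mappable <- mappable_positions(truth)
  if (!is.null(state) && length(state$assigned)) {
    ap <- names(state$assigned)
    map_errors <- sum(state$assigned != truth_lab[ap], na.rm = TRUE) +
      sum(is.na(truth_lab[ap]))
    completeness <- mean(as.character(mappable) %in% ap)
    n_assigned_pos <- length(ap)
  } else {
    map_errors <- 0L; completeness <- 0; n_assigned_pos <- 0L
  }
  carb <- table[table$nucleus == "13C" &
                  table$provenance %in% c("TOCSY", "NOESY-common"), ,
                drop = FALSE]
  check <- function(rows) {
    if (!nrow(rows)) return(logical(0))
    vapply(seq_len(nrow(rows)), function(i) {
      r <- rows$residue[i]
      aa <- truth$sequence[r]
      eq <- equivalent_carbons(aa, rows$atom[i])
      ta <- truth$atoms[truth$atoms$residue == r &
                          truth$atoms$carbon %in% eq, ]
      nrow(ta) > 0L && any(abs(ta$c - rows$shift[i]) <= tol_c)
    }, logical(1))
  }
  ok <- check(carb)
  is_methyl <- vapply(seq_len(nrow(carb)), function(i) {
    top <- aa_topology(truth$sequence[carb$residue[i]])
    g <- top$group[top$carbon == carb$atom[i]]
    length(g) == 1L && g == "CH3"
  }, logical(1))
  rate <- function(err, tot) if (tot > 0L) err / tot else 0
  # common-NOE recovery bookkeeping: carbons of typed residues absent from
  # the TOCSY-derived table
  typed_res <- if (!is.null(state) && length(state$assigned))
    as.integer(names(state$assigned)) - 1L else integer(0)
  typed_res <- typed_res[typed_res >= 1L]
  deleted <- unique(truth$atoms[truth$atoms$residue %in% typed_res,
                                c("residue", "carbon")])
  has_tocsy <- paste(carb$residue, carb$atom)[carb$provenance == "TOCSY"]
  deleted <- deleted[!(paste(deleted$residue, deleted$carbon) %in%
                         has_tocsy), ]
  noe_key <- paste(carb$residue, carb$atom)[carb$provenance == "NOESY-common"]
  recovered <- paste(deleted$residue, deleted$carbon) %in% noe_key
  noe_rows <- carb$provenance == "NOESY-common"
  list(
    n_mappable = length(mappable),
    n_assigned_positions = n_assigned_pos,
    mapping_completeness = completeness,
    mapping_errors = map_errors,
    atoms_assigned = nrow(carb),
    atoms_correct = sum(ok),
    atom_error_rate = rate(sum(!ok), nrow(carb)),
    tocsy_assigned = sum(carb$provenance == "TOCSY"),
    tocsy_error_rate = rate(sum(!ok[carb$provenance == "TOCSY"]),
                            sum(carb$provenance == "TOCSY")),
    methyl_assigned = sum(is_methyl),
    methyl_error_rate = rate(sum(!ok[is_methyl]), sum(is_methyl)),
    noe_assigned = sum(noe_rows),
    noe_error_rate = rate(sum(!ok[noe_rows]), sum(noe_rows)),
    missing_after_tocsy = nrow(deleted),
    recovered = sum(recovered),
    recovery_rate = rate(sum(recovered), nrow(deleted))
  )
}
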