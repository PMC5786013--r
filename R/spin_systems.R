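#' Chemical-shift matching tolerances
#'
#' Tolerances (ppm) used when matching peaks to amide roots and CH pairs to
#' each other.  Defaults correspond to the digital resolution of typical
#' sparsely sampled 4D spectra.
#'
#' @param tol_hn,tol_n15 Amide 1H / 15N tolerance for root matching.
#' @param tol_h,tol_c Aliphatic 1H / 13C tolerance for CH-pair matching.
#' @return An object of class `tolerances`.
#' @export
tolerances <- function(tol_hn = 0.04, tol_n15 = 0.2,
                       tol_h = 0.04, tol_c = 0.4) {
  vals <- c(tol_hn = tol_hn, tol_n15 = tol_n15, tol_h = tol_h, tol_c = tol_c)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all tolerances must be positive and finite")
  structure(as.list(vals), class = "tolerances")
}

#' Match CH pairs within tolerance
#'
#' Two 13C-1H pairs match iff their carbon shifts differ by at most `tol_c`
#' and their proton shifts by at most `tol_h` (closed boundaries).
#' Vectorized; the shorter arguments are recycled.
#'
#' @param c_a,h_a,c_b,h_b Shift coordinates of the pairs (ppm).
#' @param tol A [tolerances()] object.
#' @return Logical vector.
#' @export
match_ch <- function(c_a, h_a, c_b, h_b, tol = tolerances()) {
  abs(c_a - c_b) <= tol$tol_c & abs(h_a - h_b) <= tol$tol_h
}

# internal: merge near-duplicate CH pairs within one spin system, keeping the
# strongest peak; deterministic and independent of input order
dedup_ch_pairs <- function(df, tol) {
  if (nrow(df) <= 1L) return(df)
  ord <- order(-abs(df$intensity), df$c, df$h, df$peak_row)
  df <- df[ord, ]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ki <- which(keep)
    if (!length(ki) ||
        !any(abs(df$c[ki] - df$c[i]) <= tol$tol_c / 4 &
             abs(df$h[ki] - df$h[i]) <= tol$tol_h / 4))
      keep[i] <- TRUE
  }
  out <- df[keep, ]
  out[order(out$c, out$h), ]
}

#' Cluster 4D peaks into amino-acid index groups (AAIGs)
#'
#' Attaches every TOCSY and NOESY 4D peak to the nearest root amide
#' resonance within tolerance (distance scaled per dimension by the
#' tolerance), producing one AAIG per root: the root 15N-1H coordinates plus
#' the clustered TOCSY CH pairs (aliphatic resonances of the preceding
#' residue) and NOESY CH pairs (spatially proximal CH).  Peaks matching no
#' root are collected as orphans.  Near-duplicate CH pairs inside one AAIG
#' (within a quarter tolerance) are merged keeping the strongest peak, and
#' TOCSY sets are capped at 10 pairs (the largest aliphatic CH count of any
#' residue type).
#'
#' @param tocsy,noesy 4D peak data frames (see [read_sparky_peaks()]);
#'   either may be empty or `NULL`.
#' @param roots Root peak data frame with columns `label`, `n15`, `hn`;
#'   labels must be unique.
#' @param tol A [tolerances()] object.
#' @return An object of class `aaig_set`: list with `aaigs` (named list;
#'   each AAIG has `label`, `n15`, `hn`, `tocsy`, `noesy` data frames with
#'   columns `c`, `h`, `intensity`, `peak_row`), `orphans` (data frame with
#'   `source` and peak row), and `tol`.
#' @export
cluster_peaks <- function(tocsy, noesy, roots, tol = tolerances()) {
  if (is.null(roots) || nrow(roots) == 0L) stop("roots must be non-empty")
  if (anyDuplicated(roots$label))
    stop("root labels must be unique")
  # degenerate-root warning: roots closer than half tolerance in both dims
  if (nrow(roots) > 1L) {
    dn <- abs(outer(roots$n15, roots$n15, "-")) < tol$tol_n15 / 2
    dh <- abs(outer(roots$hn, roots$hn, "-")) < tol$tol_hn / 2
    bad <- which(dn & dh & upper.tri(dn), arr.ind = TRUE)
    if (nrow(bad))
      warning("degenerate roots: ",
              paste(apply(bad, 1L, function(ij)
                paste(roots$label[ij], collapse = "/")), collapse = ", "))
  }
  attach_peaks <- function(peaks) {
    if (is.null(peaks) || nrow(peaks) == 0L)
      return(integer(0))
    dn <- outer(peaks$n15, roots$n15, "-") / tol$tol_n15
    dh <- outer(peaks$hn, roots$hn, "-") / tol$tol_hn
    inside <- abs(dn) <= 1 & abs(dh) <= 1
    d2 <- dn * dn + dh * dh
    d2[!inside] <- Inf
    best <- max.col(-d2, ties.method = "first")
    best[!is.finite(d2[cbind(seq_len(nrow(peaks)), best)])] <- NA_integer_
    best
  }
  t_idx <- attach_peaks(tocsy)
  n_idx <- attach_peaks(noesy)
  aaigs <- vector("list", nrow(roots))
  names(aaigs) <- roots$label
  empty <- data.frame(c = numeric(), h = numeric(), intensity = numeric(),
                      peak_row = integer(), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(roots))) {
    tp <- if (length(t_idx)) which(t_idx == r) else integer(0)
    np <- if (length(n_idx)) which(n_idx == r) else integer(0)
    tdf <- if (length(tp))
      data.frame(c = tocsy$c[tp], h = tocsy$h[tp],
                 intensity = tocsy$intensity[tp], peak_row = tp,
                 stringsAsFactors = FALSE) else empty
    ndf <- if (length(np))
      data.frame(c = noesy$c[np], h = noesy$h[np],
                 intensity = noesy$intensity[np], peak_row = np,
                 stringsAsFactors = FALSE) else empty
    tdf <- dedup_ch_pairs(tdf, tol)
    ndf <- dedup_ch_pairs(ndf, tol)
    if (nrow(tdf) > 10L) {
      warning("AAIG ", roots$label[r], ": TOCSY pairs capped at 10 (had ",
              nrow(tdf), ")")
      keep <- order(-abs(tdf$intensity), tdf$c)[1:10]
      tdf <- tdf[sort(keep), ]
    }
    rownames(tdf) <- rownames(ndf) <- NULL
    aaigs[[r]] <- list(label = roots$label[r], n15 = roots$n15[r],
                       hn = roots$hn[r], tocsy = tdf, noesy = ndf)
  }
  orphans <- rbind(
    if (length(t_idx) && any(is.na(t_idx)))
      data.frame(source = "TOCSY", peak_row = which(is.na(t_idx))),
    if (length(n_idx) && any(is.na(n_idx)))
      data.frame(source = "NOESY", peak_row = which(is.na(n_idx))))
  if (is.null(orphans))
    orphans <- data.frame(source = character(), peak_row = integer())
  structure(list(aaigs = aaigs, orphans = orphans, tol = tol),
            class = "aaig_set")
}

#' @export
print.aaig_set <- function(x, ...) {
  nt <- vapply(x$aaigs, function(a) nrow(a$tocsy), integer(1))
  nn <- vapply(x$aaigs, function(a) nrow(a$noesy), integer(1))
  cat(sprintf(paste0("<aaig_set: %d AAIGs, %d TOCSY + %d NOESY pairs ",
                     "attached, %d orphan peaks>\n"),
              length(x$aaigs), sum(nt), sum(nn), nrow(x$orphans)))
  invisible(x)
}
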