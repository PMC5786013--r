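#' Scott's bandwidth factor
#'
#' Rule-of-thumb kernel bandwidth factor for a two-dimensional Gaussian kernel
#' density estimate, \eqn{h = n^{-1/6}}.  The factor is dimensionless; each
#' dimension's bandwidth is obtained by multiplying it with that dimension's
#' sample standard deviation so that bandwidths carry ppm units.
#'
#' @param n Sample count, `n >= 1`.
#' @return The scale factor `n^(-1/6)`.
#' @examples
#' scott_bandwidth(64)   # 0.5
#' @export
scott_bandwidth <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("invalid sample count n; need n >= 1")
  n^(-1 / 6)
}

#' Read a correlated chemical-shift statistics table
#'
#' Reads a TSV of per-observation correlated 13C-1H chemical shifts with
#' columns `amino_acid`, `atom_type`, `c_shift`, `h_shift` (one record per
#' row), the format of re-referenced BMRB-derived shift compilations.
#'
#' @param path Path to the TSV file.
#' @return Data frame of shift records.
#' @export
read_shift_table <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("amino_acid", "atom_type", "c_shift", "h_shift")
  if (!all(need %in% names(rec)))
    stop("shift table must have columns: ", paste(need, collapse = ", "))
  validate_shift_records(rec)
  rec[need]
}

validate_shift_records <- function(rec) {
  bad_aa <- setdiff(unique(rec$amino_acid), standard_aa())
  if (length(bad_aa))
    stop("non-standard amino acid code(s): ", paste(bad_aa, collapse = ", "))
  for (aa in unique(rec$amino_acid)) {
    valid <- aa_topology(aa)$atom_type
    bad <- setdiff(unique(rec$atom_type[rec$amino_acid == aa]), valid)
    if (length(bad))
      stop("invalid atom type(s) for ", aa, ": ", paste(bad, collapse = ", "))
  }
  if (!all(is.finite(rec$c_shift)) || !all(is.finite(rec$h_shift)))
    stop("non-finite chemical shift in records")
  invisible(rec)
}

#' Build a 2D probability density map of correlated 13C-1H shifts
#'
#' Places a bivariate Gaussian kernel on every (H, C) observation of one
#' amino acid / atom type:
#' \deqn{G(H_0, C_0) = \frac{1}{2\pi n h_H h_C} \sum_{i=1}^{n}
#'   \exp\left(-\tfrac12\left[\frac{(H_i-H_0)^2}{h_H^2} +
#'   \frac{(C_i-C_0)^2}{h_C^2}\right]\right)}
#' Bandwidths default to Scott's factor times the per-dimension sample
#' standard deviation; for a single record (or zero spread) they fall back to
#' the map bin sizes (0.04 ppm 1H, 0.2 ppm 13C).  Evaluation via
#' [density_at()] is always an exact kernel sum; the binned grid
#' ([density_grid()]) serves visualization and normalization checks only.
#'
#' @param records Data frame with columns `h_shift`, `c_shift` (and optionally
#'   `amino_acid`, `atom_type`, which must then be homogeneous).
#' @param amino_acid,atom_type Identity of the map (taken from `records` when
#'   omitted).
#' @param bandwidth_rule `"scott"` (default) or a numeric vector
#'   `c(h_H, h_C)` of fixed bandwidths in ppm.
#' @param bin_h,bin_c Grid bin sizes in ppm (visualization only).
#' @return An object of class `density_map_2d`.
#' @export
build_density_map <- function(records, amino_acid = NULL, atom_type = NULL,
                              bandwidth_rule = "scott",
                              bin_h = 0.04, bin_c = 0.2) {
  if (is.null(records) || nrow(records) == 0L)
    stop("cannot build a density map from an empty record set")
  if (is.null(amino_acid) && "amino_acid" %in% names(records))
    amino_acid <- unique(records$amino_acid)
  if (is.null(atom_type) && "atom_type" %in% names(records))
    atom_type <- unique(records$atom_type)
  if (length(amino_acid) > 1L || length(atom_type) > 1L)
    stop("records must be homogeneous in (amino_acid, atom_type)")
  n <- nrow(records)
  h <- records$h_shift
  c_ <- records$c_shift
  if (is.numeric(bandwidth_rule)) {
    h_H <- bandwidth_rule[1L]
    h_C <- bandwidth_rule[2L]
  } else if (identical(bandwidth_rule, "scott")) {
    f <- scott_bandwidth(n)
    sd_h <- if (n > 1L) stats::sd(h) else 0
    sd_c <- if (n > 1L) stats::sd(c_) else 0
    h_H <- if (sd_h > 0) f * sd_h else bin_h
    h_C <- if (sd_c > 0) f * sd_c else bin_c
  } else stop("unknown bandwidth rule: ", bandwidth_rule)
  map <- structure(
    list(amino_acid = amino_acid, atom_type = atom_type, n = n,
         h = h, c = c_, h_H = h_H, h_C = h_C,
         bin_h = bin_h, bin_c = bin_c),
    class = "density_map_2d")
  # self-densities of the data points, cached for percentile cutoffs
  map$dens_self <- density_at(map, h, c_)
  map
}

#' Evaluate a density map at query points
#'
#' Exact Gaussian kernel summation over all records of the map (no grid
#' interpolation).  Vectorized over query points.
#'
#' @param map A `density_map_2d`.
#' @param h,c Numeric vectors of 1H and 13C query coordinates (ppm),
#'   recycled to a common length.
#' @return Numeric vector of density values (1/ppm^2).
#' @export
density_at <- function(map, h, c) {
  stopifnot(inherits(map, "density_map_2d"))
  m <- max(length(h), length(c))
  h <- rep_len(h, m); c <- rep_len(c, m)
  n <- map$n
  norm <- 1 / (2 * pi * n * map$h_H * map$h_C)
  out <- numeric(m)
  # chunk so the (records x queries) matrix stays modest
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1L, m, by = chunk)) {
    idx <- s:min(m, s + chunk - 1L)
    dh <- outer(map$h, h[idx], "-") / map$h_H
    dc <- outer(map$c, c[idx], "-") / map$h_C
    out[idx] <- norm * .colSums(exp(-0.5 * (dh * dh + dc * dc)), n, length(idx))
  }
  out
}

#' Rank-based percentile cutoff of a density map
#'
#' Density threshold such that the lowest `100 - q` percent of the map's own
#' data points fall below it; a query point with
#' `density_at(map, h, c) >= percentile_cutoff(map, q)` is classified as
#' lying inside the q-th percentile region of the map.  With `q = 80` and 10
#' data points, exactly 8 points pass and 2 fail.
#'
#' @param map A `density_map_2d`.
#' @param q Percentile in (0, 100).
#' @return Density threshold.
#' @export
percentile_cutoff <- function(map, q) {
  stopifnot(inherits(map, "density_map_2d"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 100)
    stop("percentile q must lie strictly between 0 and 100")
  dens <- sort(map$dens_self)
  k <- floor(map$n * (1 - q / 100) + 1e-9)
  dens[min(k + 1L, map$n)]
}

#' Binned density grid of a map
#'
#' Evaluates the kernel sum on a regular grid with the map's bin sizes,
#' extended `pad` bandwidths beyond the data range.  Used for visualization
#' and for checking that the density integrates to one.
#'
#' @param map A `density_map_2d`.
#' @param pad Number of bandwidths of padding around the data range.
#' @return List with `h`, `c` (bin-center vectors) and `density` (matrix,
#'   rows = h, cols = c).
#' @export
density_grid <- function(map, pad = 6) {
  hs <- seq(min(map$h) - pad * map$h_H, max(map$h) + pad * map$h_H,
            by = map$bin_h)
  cs <- seq(min(map$c) - pad * map$h_C, max(map$c) + pad * map$h_C,
            by = map$bin_c)
  g <- expand.grid(h = hs, c = cs)
  d <- density_at(map, g$h, g$c)
  list(h = hs, c = cs, density = matrix(d, nrow = length(hs)))
}

#' @export
print.density_map_2d <- function(x, ...) {
  cat(sprintf("<density_map_2d %s %s: n=%d, h_H=%.4f ppm, h_C=%.4f ppm>\n",
              x$amino_acid, x$atom_type, x$n, x$h_H, x$h_C))
  invisible(x)
}

#' Build a statistics library of density maps from shift records
#'
#' Groups records by (amino acid, atom type) and builds one density map per
#' group.  The library must cover every aliphatic CH atom type of every
#' amino acid exactly once.
#'
#' @param records Data frame as returned by [read_shift_table()].
#' @param complete Require full coverage of all atom types (default `TRUE`).
#' @inheritParams build_density_map
#' @return An object of class `stats_library`: a named list of
#'   `density_map_2d` keyed by `"<aa>|<atom_type>"`.
#' @export
stats_library_from_records <- function(records, bandwidth_rule = "scott",
                                       complete = TRUE) {
  validate_shift_records(records)
  keys <- stats_key(records$amino_acid, records$atom_type)
  maps <- lapply(split(records, keys), function(r)
    build_density_map(r, bandwidth_rule = bandwidth_rule))
  if (complete) {
    want <- unlist(lapply(standard_aa(), function(aa)
      stats_key(aa, aa_topology(aa)$atom_type)))
    missing <- setdiff(want, names(maps))
    if (length(missing))
      stop("statistics library incomplete; missing: ",
           paste(missing, collapse = ", "))
  }
  out <- structure(maps, class = "stats_library")
  attr(out, "stack") <- build_stats_stack(out)
  out
}

# internal: stacked representation of all maps for batch evaluation
build_stats_stack <- function(stats) {
  idx <- rep(seq_along(stats),
             vapply(stats, function(m) as.integer(m$n), integer(1)))
  list(h = unlist(lapply(stats, `[[`, "h"), use.names = FALSE),
       c = unlist(lapply(stats, `[[`, "c"), use.names = FALSE),
       map = idx,
       inv_hH = unlist(lapply(stats, function(m)
         rep(1 / m$h_H, m$n)), use.names = FALSE),
       inv_hC = unlist(lapply(stats, function(m)
         rep(1 / m$h_C, m$n)), use.names = FALSE),
       norm = vapply(stats, function(m)
         1 / (2 * pi * m$n * m$h_H * m$h_C), numeric(1)),
       nmaps = length(stats), keys = names(stats))
}

# internal: densities of query points under every map of the library;
# returns a (queries x maps) matrix with the library's key order
density_all_maps <- function(stats, h, c) {
  st <- attr(stats, "stack")
  if (is.null(st)) st <- build_stats_stack(stats)
  m <- length(h)
  out <- matrix(0, nrow = m, ncol = st$nmaps,
                dimnames = list(NULL, st$keys))
  for (j in seq_len(m)) {
    zh <- (st$h - h[j]) * st$inv_hH
    zc <- (st$c - c[j]) * st$inv_hC
    e <- exp(-0.5 * (zh * zh + zc * zc))
    s <- rowsum(e, st$map, reorder = FALSE)
    out[j, ] <- s * st$norm
  }
  out
}

#' Look up the density map for one amino acid / atom type
#' @param stats A `stats_library`.
#' @param aa One-letter code.
#' @param atom_type Pair label, e.g. `"CB-HB"`.
#' @return A `density_map_2d`.
#' @export
stats_map <- function(stats, aa, atom_type) {
  m <- stats[[stats_key(aa, atom_type)]]
  if (is.null(m)) stop("no density map for ", aa, " ", atom_type)
  m
}

#' @export
print.stats_library <- function(x, ...) {
  cat(sprintf("<stats_library: %d density maps, n per map %d..%d>\n",
              length(x), min(vapply(x, `[[`, 1L, "n")),
              max(vapply(x, `[[`, 1L, "n"))))
  invisible(x)
}

#' Sample synthetic shift records from the shipped parameter table
#'
#' The package ships a parametric table of per-atom-type Gaussian means and
#' standard deviations consistent with published BMRB aliphatic shift ranges
#' (`inst/extdata/shift_gaussians_synthetic.tsv`).  This draws `n_per_type`
#' independent (C, H) observations per atom type from those Gaussians,
#' producing a record set in the same shape a real re-referenced statistics
#' table would provide.
#'
#' @param n_per_type Observations per (amino acid, atom type).
#' @param seed Integer seed for reproducibility.
#' @param param_path Optional alternative parameter TSV.
#' @return Data frame of shift records.
#' @export
synthetic_shift_records <- function(n_per_type = 150, seed = 1234,
                                    param_path = NULL) {
  if (is.null(param_path))
    param_path <- system.file("extdata", "shift_gaussians_synthetic.tsv",
                              package = "chains4d", mustWork = TRUE)
  par <- utils::read.delim(param_path, stringsAsFactors = FALSE)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(par)), function(i) {
      data.frame(
        amino_acid = par$amino_acid[i], atom_type = par$atom_type[i],
        c_shift = stats::rnorm(n_per_type, par$c_mean[i], par$c_sd[i]),
        h_shift = stats::rnorm(n_per_type, par$h_mean[i], par$h_sd[i]),
        stringsAsFactors = FALSE)
    }))
  })
}

#' Default statistics library
#'
#' Convenience wrapper: samples synthetic shift records and builds the full
#' library of density maps.
#'
#' @inheritParams synthetic_shift_records
#' @return A `stats_library`.
#' @export
default_stats_library <- function(n_per_type = 150, seed = 1234) {
  stats_library_from_records(synthetic_shift_records(n_per_type, seed))
}

# internal: evaluate seeded code without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
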