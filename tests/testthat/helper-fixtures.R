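# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# moderately sized statistics library for unit tests
test_stats <- function() memo("stats60",
                              default_stats_library(n_per_type = 60,
                                                    seed = 11))

# full-size library for end-to-end checks
full_stats <- function() memo("stats150", default_stats_library())

# toy density map from explicit records with fixed bandwidths
toy_map <- function(h, c, h_H = 0.1, h_C = 0.5, aa = "A",
                    atom_type = "CA-HA") {
  build_density_map(data.frame(h_shift = h, c_shift = c),
                    amino_acid = aa, atom_type = atom_type,
                    bandwidth_rule = c(h_H, h_C))
}

# brute-force KDE oracle: explicit double loop
kde_oracle <- function(map, h0, c0) {
  vapply(seq_along(h0), function(j) {
    s <- 0
    for (i in seq_len(map$n)) {
      s <- s + exp(-0.5 * ((map$h[i] - h0[j])^2 / map$h_H^2 +
                           (map$c[i] - c0[j])^2 / map$h_C^2))
    }
    s / (2 * pi * map$n * map$h_H * map$h_C)
  }, numeric(1))
}

# an aaig_set built from explicit per-AAIG CH-pair lists, using
# well-separated synthetic roots so clustering is unambiguous
make_aaig_set <- function(tocsy_pairs, noesy_pairs, tol = tolerances()) {
  labels <- union(names(tocsy_pairs), names(noesy_pairs))
  roots <- data.frame(label = labels,
                      n15 = 100 + 5 * seq_along(labels),
                      hn = 8, stringsAsFactors = FALSE)
  mk <- function(lst) {
    rows <- lapply(labels, function(l) {
      p <- lst[[l]]
      if (is.null(p) || !nrow(p)) return(NULL)
      data.frame(label = "?", h = p$h, c = p$c,
                 n15 = roots$n15[roots$label == l], hn = 8,
                 intensity = if ("intensity" %in% names(p)) p$intensity
                             else rep(1, nrow(p)))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows)
    else data.frame(label = character(), h = numeric(), c = numeric(),
                    n15 = numeric(), hn = numeric(), intensity = numeric())
  }
  cluster_peaks(mk(tocsy_pairs), mk(noesy_pairs), roots, tol)
}
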