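# independent oracle: enumerate atom-type configurations by assigning pairs
# one at a time (join an occupied methylene slot or claim a free slot)
combo_count_oracle <- function(pairs, aa, methylene_tol = 0.2) {
  top <- aa_topology(aa)
  n <- nrow(pairs)
  if (n == 0L || n > atom_capacity(aa)) return(0L)
  count <- 0L
  rec <- function(i, slot_of) {
    if (i > n) { count <<- count + 1L; return() }
    for (s in seq_len(nrow(top))) {
      res <- which(slot_of == s)
      if (length(res) == 0L) {
        slot_of[i] <- s; rec(i + 1L, slot_of); slot_of[i] <- NA_integer_
      } else if (length(res) == 1L && top$group[s] == "CH2" &&
                 abs(pairs$c[res] - pairs$c[i]) <= methylene_tol) {
        slot_of[i] <- s; rec(i + 1L, slot_of); slot_of[i] <- NA_integer_
      }
    }
  }
  rec(1L, rep(NA_integer_, n))
  count
}

test_that("methylene grouping is offered only within the carbon tolerance", {
  near <- data.frame(c = c(45.0, 45.15), h = c(3.9, 3.7))
  far <- data.frame(c = c(45.0, 45.5), h = c(3.9, 3.7))
  expect_length(enumerate_combinations(near, "G"), 1L)   # grouped onto CA
  expect_length(enumerate_combinations(far, "G"), 0L)
  grouped <- enumerate_combinations(near, "G")[[1L]]
  expect_equal(grouped[[1L]]$carbon, "CA")
  expect_equal(sort(grouped[[1L]]$idx), c(1L, 2L))
})

test_that("combination enumeration equals the exhaustive oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(1:4, 1)
    pairs <- data.frame(c = runif(n, 20, 60), h = runif(n, 0.5, 4.5))
    # occasionally force near-degenerate carbons to exercise grouping
    if (n >= 2 && runif(1) < 0.5) pairs$c[2] <- pairs$c[1] + runif(1, 0, 0.3)
    for (aa in c("L", "K", "G", "A", "T", "I")) {
      expect_identical(length(enumerate_combinations(pairs, aa)),
                       as.integer(combo_count_oracle(pairs, aa)),
                       info = sprintf("aa=%s rep=%d", aa, rep))
    }
  }
})

test_that("over-capacity spin systems get zero probability", {
  stats <- test_stats()
  pairs <- data.frame(c = runif(8, 20, 60), h = runif(8, 0.5, 4.5))
  expect_identical(p_ccs_given_aa(pairs, "A", stats)$p, 0)
  expect_length(enumerate_combinations(pairs, "A"), 0L)
})

test_that("a single pair scores as its best single-atom density", {
  stats <- test_stats()
  map <- stats_map(stats, "A", "CB-HB")
  pt <- data.frame(c = 19.0, h = 1.35)   # near the Ala CB mode
  best <- p_ccs_given_aa(pt, "A", stats)
  d_cb <- density_at(map, pt$h, pt$c)
  d_ca <- density_at(stats_map(stats, "A", "CA-HA"), pt$h, pt$c)
  expect_equal(best$p, max(d_cb, d_ca))
  expect_equal(best$combo[[1L]]$carbon, "CB")
})

test_that("max-product search matches an exhaustive oracle on toy maps", {
  stats <- test_stats()
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    pairs <- data.frame(c = runif(n, 15, 65), h = runif(n, 0.5, 4.6))
    for (aa in c("K", "L", "I", "R")) {
      combos <- enumerate_combinations(pairs, aa)
      if (!length(combos)) {
        expect_identical(p_ccs_given_aa(pairs, aa, stats)$p, 0)
        next
      }
      oracle <- max(vapply(combos, function(cb) {
        p <- 1
        for (unit in cb) {
          m <- stats_map(stats, aa, unit$atom_type)
          d <- density_at(m, pairs$h[unit$idx], pairs$c[unit$idx])
          p <- p * if (length(unit$idx) == 2L) sqrt(prod(d)) else d
        }
        p
      }, numeric(1)))
      expect_equal(p_ccs_given_aa(pairs, aa, stats)$p, oracle)
    }
  }
})

test_that("posterior follows Bayes' rule and normalizes exactly", {
  stats <- test_stats()
  # single-support sequence: only Ala precedes non-prolines
  pairs <- data.frame(c = c(52.5, 19.2), h = c(4.2, 1.4))
  pred <- predict_aa_types(pairs, rep("A", 4), stats)
  expect_equal(pred$posterior, 1)
  expect_equal(pred$aa, "A")
  # two-type sequence: posterior equals the hand-computed Bayes ratio
  seqv <- c("A", "G", "A", "G", "A")   # prior: A 1/2, G 1/2 (positions 1..4)
  pred2 <- predict_aa_types(pairs, seqv, stats)
  pa <- p_ccs_given_aa(pairs, "A", stats)$p
  pg <- p_ccs_given_aa(pairs, "G", stats)$p
  want <- pa * 0.5 / (pa * 0.5 + pg * 0.5)
  expect_equal(pred2$posterior[pred2$aa == "A"], want, tolerance = 1e-12)
  expect_equal(sum(pred2$posterior), 1, tolerance = 1e-12)
})

test_that("posteriors normalize for random spin systems", {
  stats <- test_stats()
  seqv <- sample_sequence(60, seed = 2)
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    pairs <- data.frame(c = runif(n, 15, 65), h = runif(n, 0.5, 4.6))
    pred <- suppressWarnings(predict_aa_types(pairs, seqv, stats))
    if (nrow(pred))
      expect_equal(sum(pred$posterior), 1, tolerance = 1e-12)
  }
})

test_that("adding a pair never widens the support", {
  stats <- test_stats()
  seqv <- sample_sequence(60, seed = 3)
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(1:5, 1)
    pairs <- data.frame(c = runif(n + 1, 15, 65), h = runif(n + 1, 0.5, 4.6))
    sup <- function(p) sum(vapply(standard_aa(), function(aa)
      p_ccs_given_aa(p, aa, stats)$p > 0, logical(1)))
    expect_lte(sup(pairs), sup(pairs[seq_len(n), , drop = FALSE]))
  }
})

test_that("Z-score filtering keeps the right predictions", {
  pred <- data.frame(aa = c("L", "I", "V", "T"),
                     p_ccs = c(4, 2, 1, 0.1), prior = 0.25,
                     posterior = c(0.5634, 0.2817, 0.1408, 0.0141),
                     zscore = NA)
  lp <- log(pred$posterior)
  pred$zscore <- (lp - mean(lp)) / sd(lp)
  expect_identical(nrow(zscore_filter(pred, -Inf)), 4L)
  expect_identical(nrow(zscore_filter(pred, Inf)), 1L)
  expect_identical(zscore_filter(pred, Inf)$aa, "L")
  # direct standardization oracle
  keep <- pred$zscore >= 0.2; keep[1] <- TRUE
  expect_identical(zscore_filter(pred, 0.2)$aa, pred$aa[keep])
  # posterior floor drops negligible predictions but never rank 1
  expect_identical(zscore_filter(pred, -Inf, min_posterior = 0.1)$aa,
                   c("L", "I", "V"))
})

test_that("abnormal shifts yield an empty prediction with a warning", {
  stats <- test_stats()
  pairs <- data.frame(c = c(250, 300), h = c(20, 25))
  expect_warning(pred <- predict_aa_types(pairs, rep("A", 5), stats),
                 "nonzero support")
  expect_identical(nrow(pred), 0L)
})
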