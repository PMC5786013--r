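test_that("an alanine pattern at the map modes is typed perfectly", {
  stats <- test_stats()
  pairs <- data.frame(c = c(53.1, 19.0), h = c(4.26, 1.35),
                      intensity = 1, peak_row = 1:2)
  res <- assign_tocsy_atoms(pairs, "A", 7L, stats)
  e <- res$entries
  expect_setequal(e$atom, c("CA", "HA", "CB", "HB"))
  expect_equal(e$shift[e$atom == "CA"], 53.1)
  expect_equal(e$shift[e$atom == "HB"], 1.35)
  expect_true(all(e$provenance == "TOCSY"))
  expect_true(all(e$residue == 7L))
})

test_that("glycine methylene protons group onto one carbon", {
  stats <- test_stats()
  pairs <- data.frame(c = c(45.3, 45.4), h = c(3.9, 3.6),
                      intensity = 1, peak_row = 1:2)
  res <- assign_tocsy_atoms(pairs, "G", 3L, stats)
  e <- res$entries
  expect_setequal(e$atom, c("CA", "HA2", "HA3"))
  expect_equal(e$shift[e$atom == "CA"], 45.35)   # mean of grouped carbons
  expect_equal(e$shift[e$atom == "HA2"], 3.9)    # HA2 is the higher shift
  expect_equal(e$shift[e$atom == "HA3"], 3.6)
})

test_that("full synthetic typing matches the generator truth", {
  stats <- test_stats()
  ds <- simulate_dataset(synthetic_config(
    n_residues = 25, seed = 6, p_tocsy_missing = 0, p_noise_peaks = 0,
    p_noe_intra = 1, p_noe_seq = 1, seq_dropout = list()), stats)
  res <- suppressWarnings(
    assign_resonances(ds$sequence, ds$roots, ds$tocsy, ds$noesy, stats))
  m <- evaluate_assignments(res$table, res$state, ds$truth)
  expect_identical(m$mapping_errors, 0L)
  expect_equal(m$tocsy_error_rate, 0)
})

test_that("NOESY transfer labels match a brute-force nearest-match oracle", {
  stats <- test_stats()
  ds <- simulate_dataset(synthetic_config(n_residues = 25, seed = 9), stats)
  res <- suppressWarnings(
    assign_resonances(ds$sequence, ds$roots, ds$tocsy, ds$noesy, stats,
                      extend = FALSE))
  ann <- res$noesy_annotations
  tol <- tolerances()
  # every label is within tolerance of the table shift it names
  for (i in seq_len(nrow(ann))) {
    tr <- res$table[res$table$residue == ann$residue[i], ]
    expect_true(abs(tr$shift[tr$atom == ann$atom_c[i]] -
                      ds$noesy$c[ann$peak_row[i]]) <= tol$tol_c)
    expect_true(abs(tr$shift[tr$atom == ann$atom_h[i]] -
                      ds$noesy$h[ann$peak_row[i]]) <= tol$tol_h)
  }
  # no peak carries two labels
  expect_false(any(duplicated(paste(ann$aaig, ann$peak_row))))
  # an empty NOESY spin system gets no labels
  aaig2 <- res$aaig_set
  aaig2$aaigs[[1L]]$noesy <- aaig2$aaigs[[1L]]$noesy[0L, ]
  ann2 <- transfer_to_noesy(res$state, aaig2, res$table, ds$sequence, tol)
  expect_false(aaig2$aaigs[[1L]]$label %in% ann2$aaig)
})

test_that("the common-NOE score is density times 100 x intensity^2", {
  stats <- test_stats()
  # two residues, A then A; make residue 1 miss its CB assignment
  seqv <- c("A", "A", "A")
  truth_c <- 19.0; truth_h <- 1.35
  mkpk <- function(c, h, n15, hn, int) data.frame(
    label = "?", h = h, c = c, n15 = n15, hn = hn, intensity = int)
  # residue 2's atoms appear intra in the amide-2 spin system and
  # sequentially in the amide-3 spin system: common NOEs of residue 2
  noesy <- rbind(
    mkpk(truth_c, truth_h, 110, 8.0, 5),     # residue2 CB in AAIG2 (intra)
    mkpk(52.9, 4.25, 110, 8.0, 10),          # residue2 CA in AAIG2
    mkpk(truth_c, truth_h, 120, 8.6, 4),     # residue2 CB in AAIG3 (seq)
    mkpk(52.9, 4.25, 120, 8.6, 2))
  nh <- data.frame(position = 2:3, n15 = c(110, 120), hn = c(8.0, 8.6))
  res <- run_noesy_only(seqv, nh, noesy, stats)
  cb <- res$table[res$table$atom == "CB" & res$table$residue == 2L, ]
  expect_identical(nrow(cb), 1L)
  d <- density_at(stats_map(stats, "A", "CB-HB"), truth_h, truth_c)
  norm <- 5 / 10    # normalized to the strongest peak of AAIG2
  expect_equal(cb$score, d * 100 * norm^2)
  expect_identical(cb$provenance, "NOESY-common")
})

test_that("low-intensity peaks are excluded from the common-NOE step", {
  stats <- test_stats()
  seqv <- c("A", "A", "A")
  mkpk <- function(c, h, n15, hn, int) data.frame(
    label = "?", h = h, c = c, n15 = n15, hn = hn, intensity = int)
  noesy <- rbind(
    mkpk(19.0, 1.35, 110, 8.0, 0.5),   # below 0.1 after normalization
    mkpk(52.9, 4.25, 110, 8.0, 10),
    mkpk(19.0, 1.35, 120, 8.6, 4),
    mkpk(52.9, 4.25, 120, 8.6, 2))
  nh <- data.frame(position = 2:3, n15 = c(110, 120), hn = c(8.0, 8.6))
  res <- run_noesy_only(seqv, nh, noesy, stats)
  expect_false(any(res$table$atom == "CB" & res$table$residue == 2L))
})

test_that("shift tables merge with TOCSY priority and round-trip", {
  a <- data.frame(residue = 1L, atom = c("CA", "HA"), shift = c(52.1, 4.2),
                  nucleus = c("13C", "1H"), provenance = "TOCSY",
                  score = NA_real_)
  b <- data.frame(residue = c(1L, 2L), atom = c("CA", "CB"),
                  shift = c(50.0, 30.2), nucleus = "13C",
                  provenance = "NOESY-common", score = 1)
  expect_message(tab <- build_shift_table(a, b), "conflict")
  expect_equal(tab$shift[tab$residue == 1L & tab$atom == "CA"], 52.1)
  expect_identical(nrow(tab), 3L)
  expect_identical(nrow(attr(tab, "conflicts")), 1L)
  path <- withr::local_tempfile()
  write_xeasy_shifts(tab, path)
  back <- read_xeasy_shifts(path)
  expect_equal(back$shift, tab$shift[order(tab$residue,
                                           chains4d:::atom_rank(tab$atom))],
               tolerance = 1e-3)
})

test_that("the NOESY-only scenario assigns accurately on clean data", {
  stats <- test_stats()
  ds <- simulate_dataset(synthetic_config(
    n_residues = 30, seed = 4, p_tocsy_missing = 0, p_noise_peaks = 0,
    p_noe_intra = 1, p_noe_seq = 1, sigma_c = 0, sigma_h = 0,
    sigma_pick_c = 0, sigma_pick_h = 0, sigma_n15 = 0, sigma_hn = 0,
    seq_dropout = list()), stats)
  nh <- ds$truth$amide[, c("position", "n15", "hn")]
  res <- run_noesy_only(ds$sequence, nh, ds$noesy, stats)
  res2 <- run_noesy_only(ds$sequence, nh, ds$noesy, stats)
  expect_identical(res$table, res2$table)   # deterministic
  carb <- res$table[res$table$nucleus == "13C", ]
  ok <- vapply(seq_len(nrow(carb)), function(i) {
    r <- carb$residue[i]
    eq <- chains4d:::equivalent_carbons(ds$sequence[r], carb$atom[i])
    ta <- ds$truth$atoms[ds$truth$atoms$residue == r &
                           ds$truth$atoms$carbon %in% eq, ]
    nrow(ta) > 0L && any(abs(ta$c - carb$shift[i]) <= 0.4)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # empty NOESY: only the fixed amides come back
  empty <- run_noesy_only(ds$sequence, nh, ds$noesy[0L, ], stats)
  expect_true(all(empty$table$provenance == "root"))
  # NH table inconsistent with the sequence errors out
  bad <- nh; bad$position[1L] <- length(ds$sequence) + 5L
  expect_error(run_noesy_only(ds$sequence, bad, ds$noesy, stats),
               "outside")
})
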