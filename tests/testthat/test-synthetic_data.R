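test_that("sequence sampling is seeded and validates its input", {
  expect_identical(sample_sequence(50, seed = 4), sample_sequence(50, seed = 4))
  expect_false(identical(sample_sequence(50, seed = 4),
                         sample_sequence(50, seed = 5)))
  expect_error(sample_sequence(0), "at least 2")
  # composition within multinomial error over 10^4 draws
  comp <- default_composition()
  s <- sample_sequence(1e4, seed = 1)
  freq <- table(factor(s, levels = names(comp))) / 1e4
  sigma <- sqrt(comp * (1 - comp) / 1e4)
  expect_true(all(abs(freq - comp) < 4 * sigma + 1e-4))
})

test_that("ground-truth shifts respect topology and stay in-distribution", {
  stats <- test_stats()
  seqv <- c("M", "A", "G", "V", "K")
  truth <- sample_true_shifts(seqv, stats, synthetic_config(seed = 2))
  ala <- truth$atoms[truth$atoms$residue == 2L, ]
  expect_setequal(ala$proton, c("HA", "HB"))
  expect_setequal(ala$carbon, c("CA", "CB"))
  gly <- truth$atoms[truth$atoms$residue == 3L, ]
  expect_setequal(gly$proton, c("HA2", "HA3"))
  expect_identical(unique(gly$carbon), "CA")
  expect_equal(length(unique(gly$c)), 1L)   # geminal protons share a carbon
  # draws stay within the overwhelming mass of their maps
  for (i in seq_len(nrow(truth$atoms))) {
    a <- truth$atoms[i, ]
    map <- stats_map(stats, a$aa, a$atom_type)
    expect_lt(abs(a$c - mean(map$c)), 6 * (sd(map$c) + map$h_C))
    expect_lt(abs(a$h - mean(map$h)), 6 * (sd(map$h) + map$h_H))
  }
  # no amide for prolines or the N-terminal residue
  truth_p <- sample_true_shifts(c("M", "P", "A"), stats,
                                synthetic_config(seed = 2))
  expect_identical(truth_p$amide$position, 3L)
  # deterministic per seed
  expect_identical(truth$atoms,
                   sample_true_shifts(seqv, stats,
                                      synthetic_config(seed = 2))$atoms)
})

test_that("peak counts match the closed-form presence expectations", {
  stats <- test_stats()
  seqv <- sample_sequence(60, seed = 31)
  cfg <- synthetic_config(n_residues = 60, p_tocsy_missing = 0.1,
                          p_noise_peaks = 0, p_noe_intra = 0.99,
                          p_noe_seq = 0.89, seq_dropout = list())
  truth <- sample_true_shifts(seqv, stats, cfg, seed = 5)
  amide <- truth$amide$position
  n_atoms <- function(r) sum(truth$atoms$residue %in% r)
  exp_tocsy <- 0.9 * n_atoms(amide - 1L)
  exp_noesy <- 0.99 * n_atoms(amide) + 0.89 * n_atoms(amide - 1L)
  tocsy_n <- noesy_n <- numeric(30)
  for (k in 1:30) {
    pk <- generate_peaklists(truth, cfg, seed = 1000 + k)
    tocsy_n[k] <- nrow(pk$tocsy); noesy_n[k] <- nrow(pk$noesy)
  }
  # binomial standard error of the mean over the replicates
  se_t <- sd(tocsy_n) / sqrt(30); se_n <- sd(noesy_n) / sqrt(30)
  expect_lt(abs(mean(tocsy_n) - exp_tocsy), 4 * se_t + 1)
  expect_lt(abs(mean(noesy_n) - exp_noesy), 4 * se_n + 1)
})

test_that("datasets are fully deterministic per seed", {
  stats <- test_stats()
  d1 <- simulate_dataset(synthetic_config(n_residues = 20, seed = 3), stats)
  d2 <- simulate_dataset(synthetic_config(n_residues = 20, seed = 3), stats)
  expect_identical(d1$tocsy, d2$tocsy)
  expect_identical(d1$noesy, d2$noesy)
  expect_identical(d1$roots, d2$roots)
  expect_identical(d1$truth$atoms, d2$truth$atoms)
})

test_that("the evaluator is exact on perfect and planted-error tables", {
  stats <- test_stats()
  seqv <- c("M", "A", "V")
  truth <- sample_true_shifts(seqv, stats, synthetic_config(seed = 13))
  carb <- unique(truth$atoms[, c("residue", "carbon", "c")])
  perfect <- data.frame(residue = carb$residue, atom = carb$carbon,
                        shift = carb$c, nucleus = "13C",
                        provenance = "TOCSY", score = NA_real_)
  m <- evaluate_assignments(perfect, NULL, truth)
  expect_identical(m$atoms_correct, nrow(perfect))
  expect_equal(m$atom_error_rate, 0)
  # empty prediction: zero coverage, zero errors
  m0 <- evaluate_assignments(perfect[0L, ], NULL, truth)
  expect_identical(m0$atoms_assigned, 0L)
  # one planted error -> error rate exactly 1/N
  planted <- perfect
  planted$shift[1L] <- planted$shift[1L] + 5
  m1 <- evaluate_assignments(planted, NULL, truth)
  expect_equal(m1$atom_error_rate, 1 / nrow(planted))
})

test_that("prochiral methyl swaps are not counted as errors", {
  stats <- test_stats()
  truth <- sample_true_shifts(c("M", "V", "A"), stats,
                              synthetic_config(seed = 23))
  va <- truth$atoms[truth$atoms$residue == 2L, ]
  cg1 <- unique(va$c[va$carbon == "CG1"]); cg2 <- unique(va$c[va$carbon == "CG2"])
  swapped <- data.frame(residue = 2L, atom = c("CG1", "CG2"),
                        shift = c(cg2, cg1), nucleus = "13C",
                        provenance = "TOCSY", score = NA_real_)
  m <- evaluate_assignments(swapped, NULL, truth)
  expect_equal(m$atom_error_rate, 0)
})

test_that("synthetic datasets write to text formats and read back", {
  stats <- test_stats()
  ds <- simulate_dataset(synthetic_config(n_residues = 12, seed = 2), stats)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  expect_identical(as.character(read_fasta_sequence(paths["fasta"])),
                   ds$sequence)
  back <- read_sparky_peaks(paths["tocsy"])
  expect_equal(nrow(back), nrow(ds$tocsy))
  expect_equal(back$c, ds$tocsy$c, tolerance = 1e-3)
})
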