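test_that("occupancy is the matched-over-total ratio", {
  tol <- tolerances()
  donor <- data.frame(c = c(30, 40, 50, 60), h = c(1, 2, 3, 4))
  acceptor_full <- donor
  acceptor_half <- data.frame(c = c(30, 40, 100, 110), h = c(1, 2, 9, 9))
  aset <- make_aaig_set(
    tocsy_pairs = list(D = donor),
    noesy_pairs = list(A = acceptor_full, B = acceptor_half, D = donor))
  conn <- compute_connectivities(aset, tol)
  conn_d <- conn[conn$tocsy_aaig == "D", ]
  expect_equal(conn_d$occupancy[conn_d$noesy_aaig == "A"], 1.0)
  expect_equal(conn_d$occupancy[conn_d$noesy_aaig == "B"], 0.5)
  # the donor's own root is never a partner of itself
  expect_false(any(conn$tocsy_aaig == conn$noesy_aaig))
})

test_that("true sequential neighbours are recovered on synthetic data", {
  stats <- test_stats()
  ds <- simulate_dataset(synthetic_config(n_residues = 40, seed = 13), stats)
  aset <- cluster_peaks(ds$tocsy, ds$noesy, ds$roots, tolerances())
  conn <- compute_connectivities(aset, tolerances(), min_occupancy = 0.5)
  lab <- structure(ds$truth$amide$label,
                   names = as.character(ds$truth$amide$position))
  for (p in ds$truth$amide$position) {
    if (!(p + 1L) %in% ds$truth$amide$position) next
    hit <- conn[conn$noesy_aaig == lab[as.character(p)] &
                  conn$tocsy_aaig == lab[as.character(p + 1L)], ]
    expect_identical(nrow(hit), 1L,
                     info = sprintf("edge %d -> %d", p, p + 1L))
  }
})

test_that("chain enumeration matches the exhaustive path oracle", {
  conn <- rbind(conn_df("A", "B"), conn_df("B", "C"))
  chains <- build_chains(conn, L_max = 6)
  keys <- sort(vapply(chains, function(ch)
    paste(ch$aaigs, collapse = ">"), character(1)))
  expect_identical(keys, c("A>B", "A>B>C", "B>C"))
  expect_true(all(vapply(chains, `[[`, numeric(1), "p_chain") == 1))
  # single-link chain probability is the link occupancy
  c2 <- build_chains(conn_df("X", "Y", occ = 0.37), L_max = 6)
  expect_equal(c2[[1L]]$p_chain, 0.37)
  # random digraphs
  set.seed(77)
  for (rep in 1:20) {
    nv <- sample(4:8, 1)
    verts <- LETTERS[seq_len(nv)]
    ne <- sample(3:12, 1)
    e <- unique(data.frame(from = sample(verts, ne, TRUE),
                           to = sample(verts, ne, TRUE)))
    e <- e[e$from != e$to, ]
    if (!nrow(e)) next
    conn <- conn_df(e$from, e$to, occ = runif(nrow(e), 0.3, 1))
    for (L_max in c(3, 6)) {
      chains <- build_chains(conn, L_max = L_max)
      keys <- sort(vapply(chains, function(ch)
        paste(ch$aaigs, collapse = ">"), character(1)))
      expect_identical(keys, path_oracle(conn, 2, L_max))
      # chain probability is the product of link occupancies
      occ <- structure(conn$occupancy,
                       names = paste(conn$noesy_aaig, conn$tocsy_aaig))
      for (ch in chains) {
        a <- ch$aaigs
        expect_equal(ch$p_chain,
                     prod(occ[paste(a[-length(a)], a[-1L])]))
      }
    }
  }
})

test_that("peptide expansion respects filters and the cap", {
  preds <- list(
    X = data.frame(aa = c("A", "G"), posterior = c(0.7, 0.3),
                   zscore = c(1, -1)),
    Y = data.frame(aa = c("L", "V"), posterior = c(0.6, 0.4),
                   zscore = c(1, -1)))
  one <- chains_to_peptides(c("X", "Y"), lapply(preds, function(p)
    p[1L, , drop = FALSE]), zscore_cutoff = -Inf)
  expect_identical(one$peptides, "AL")
  four <- chains_to_peptides(c("X", "Y"), preds, zscore_cutoff = -Inf)
  expect_identical(sort(four$peptides), c("AL", "AV", "GL", "GV"))
  expect_equal(four$p_pep[1L], 0.42)     # ranked by posterior product
  # cap: keeps the top peptides of the full sorted expansion
  capped <- chains_to_peptides(c("X", "Y"), preds, zscore_cutoff = -Inf,
                               cap = 2)
  expect_identical(capped$peptides, four$peptides[1:2])
  # z-filter: only rank-1 predictions survive a high cutoff
  strict <- chains_to_peptides(c("X", "Y"), preds, zscore_cutoff = 0.5)
  expect_identical(strict$peptides, "AL")
})

test_that("assignment scores multiply and confidence scores add", {
  al <- data.frame(position = 5L, aaig = "X", posterior = 0.5,
                   p_chain = 0.4, s_align = 0.8)
  expect_equal(score_assignments(al)$s_x, 0.16)
  al$posterior <- 1; al$p_chain <- 1; al$s_align <- 1
  expect_equal(score_assignments(al)$s_x, 1)
  al$p_chain <- 0
  expect_equal(score_assignments(al)$s_x, 0)
  # additivity: duplicated chain doubles the confidence score
  sc1 <- score_assignments(data.frame(position = 5L, aaig = "X",
                                      posterior = 0.5, p_chain = 0.4,
                                      s_align = 0.8))
  expect_equal(confidence_scores(sc1)$cs, 0.16)
  expect_equal(confidence_scores(rbind(sc1, sc1))$cs, 0.32)
  # random summation oracle
  set.seed(9)
  sc <- score_assignments(data.frame(
    position = sample(1:5, 40, TRUE),
    aaig = sample(c("A", "B", "C"), 40, TRUE),
    posterior = runif(40), p_chain = runif(40), s_align = runif(40)))
  cs <- confidence_scores(sc)
  for (i in seq_len(nrow(cs))) {
    rows <- sc$position == cs$position[i] & sc$aaig == cs$aaig[i]
    expect_equal(cs$cs[i], sum(sc$s_x[rows]))
  }
})

test_that("contigs merge on L-1 overlaps and drop lone chains", {
  ch <- function(aaigs, pos1) list(aaigs = aaigs, pos1 = pos1)
  contigs <- assemble_contigs(list(ch(c("A", "B", "C"), 1L),
                                   ch(c("B", "C", "D"), 2L)))
  expect_length(contigs, 1L)
  expect_identical(contigs[[1L]]$aaigs, c("A", "B", "C", "D"))
  expect_identical(contigs[[1L]]$pos1, 1L)
  # a lone chain with no L-1 partner is spurious and discarded
  expect_length(assemble_contigs(list(ch(c("A", "B", "C"), 1L))), 0L)
  expect_length(assemble_contigs(list(ch(c("A", "B", "C"), 1L),
                                      ch(c("X", "Y", "Z"), 7L))), 0L)
  # random toy chain sets vs the merge-closure oracle
  set.seed(41)
  for (rep in 1:25) {
    L <- sample(2:4, 1)
    chains <- lapply(seq_len(sample(3:8, 1)), function(i) {
      pos1 <- sample(1:5, 1)
      ch(sample(LETTERS[1:6], L), pos1)
    })
    got <- sort(vapply(assemble_contigs(chains), function(ct)
      paste(ct$pos1, paste(ct$aaigs, collapse = ","), sep = "|"),
      character(1)))
    expect_identical(got, contig_oracle(chains, L))
  }
})

test_that("consensus requires agreement and a strict confidence maximum", {
  ct <- function(aaigs, pos1) list(aaigs = aaigs, pos1 = pos1,
                                   n_chains = 2L)
  cs <- data.frame(position = c(1L, 2L, 3L, 2L),
                   aaig = c("A", "B", "C", "Z"),
                   cs = c(1, 1, 1, 0.5))
  got <- consensus_assign(list(ct(c("A", "B", "C"), 1L)), cs)
  expect_identical(got$position, 1:3)
  expect_identical(got$aaig, c("A", "B", "C"))
  # a disagreeing second contig blocks only the conflicted position
  got2 <- consensus_assign(list(ct(c("A", "B", "C"), 1L),
                                ct(c("Z", "C", "D"), 2L)),
                           rbind(cs, data.frame(position = 4L, aaig = "D",
                                                cs = 1)))
  expect_false(2L %in% got2$position)   # B vs Z disagree at position 2
  expect_true(all(c(1L, 4L) %in% got2$position))
  # equal confidence elsewhere blocks acceptance (no strict maximum)
  cs_tie <- rbind(cs, data.frame(position = 9L, aaig = "A", cs = 1))
  got3 <- consensus_assign(list(ct(c("A", "B", "C"), 1L)), cs_tie)
  expect_false("A" %in% got3$aaig)
})

test_that("overlap-consensus fixture: agreeing shapes map, clashing do not", {
  # two contig sets covering 2..7; all agree except position 4 (X vs Y)
  ct1 <- list(aaigs = c("S2", "S3", "X", "S5", "S6", "S7"), pos1 = 2L,
              n_chains = 3L)
  ct2 <- list(aaigs = c("S2", "S3", "Y", "S5", "S6", "S7"), pos1 = 2L,
              n_chains = 2L)
  cs <- data.frame(position = rep(2:7, 2),
                   aaig = c(ct1$aaigs, ct2$aaigs),
                   cs = c(rep(1, 6), 0.9, 0.9, 0.4, 0.9, 0.9, 0.9))
  cs <- unique(cs[order(-cs$cs), ])
  got <- consensus_assign(list(ct1, ct2), cs)
  expect_identical(sort(got$position), c(2L, 3L, 5L, 6L, 7L))
  expect_false(any(c("X", "Y") %in% got$aaig))
})

test_that("mapping is monotone, deterministic, and never revokes", {
  stats <- test_stats()
  ds <- simulate_dataset(synthetic_config(n_residues = 40, seed = 19), stats)
  run <- function() suppressWarnings(
    assign_resonances(ds$sequence, ds$roots, ds$tocsy, ds$noesy, stats))
  r1 <- run(); r2 <- run()
  expect_identical(r1$state$assigned, r2$state$assigned)
  expect_identical(r1$table, r2$table)
  log <- r1$state$log
  expect_false(any(duplicated(log$position)))   # assignments never revoked
  expect_false(any(duplicated(log$aaig)))
  expect_true(all(diff(log$round) >= 0))        # monotone growth by round
})
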