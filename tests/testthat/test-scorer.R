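test_that("score configs are validated and score0/score8 are pinned", {
  cfgs <- score_configs()
  expect_equal(nrow(cfgs), 15)
  expect_equal(cfgs$name, paste0("score", 0:14))
  s0 <- score_config("score0")
  expect_equal(s0$P, c(0, 0, 0))
  s8 <- score_config("score8")
  expect_equal(s8$P, c(0, 1, 0))
  expect_equal(s8$Q[2], 1)
  expect_error(score_config("score99"), "unknown score config")
  expect_error(score_config("custom", P = c(2, 0, 0), Q = c(0, 0, 0)), "in \\[0, 1\\]")
})

test_that("S* reduces to the position-specific score when all P are zero", {
  withr::local_seed(8)
  m <- bundled_matrix("degenerate_synthetic")
  x <- replicate(50, paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = ""))
  expect_identical(score_star(x, m, NULL, score_config("score0")),
                   position_score(x, m))
})

test_that("score8 subtracts BE(X/X_6) weighted by the branch-site frequency", {
  m <- bundled_matrix("tna_synthetic") # f(6, A) = 1
  tab <- nn_table()
  x <- c("TACTAAC", "CTCTAAT", "TTTTAAT")
  s0 <- score_star(x, m, tab, score_config("score0"))
  s8 <- score_star(x, m, tab, score_config("score8"))
  expect_equal(s8, s0 - binding_energy(x, 6, tab))
  # stable duplexes have BE <= 0, so score8 >= score0
  expect_true(all(s8 >= s0))
  # -Inf propagates through the energy term
  expect_equal(score_star("TACCAAC", m, tab, score_config("score8")), -Inf)
})

test_that("the energy term averages over active k with Q exponents applied", {
  m <- bundled_matrix("degenerate_synthetic")
  tab <- nn_table()
  f <- unclass(m)
  x <- "TACTAAC"
  cfg <- score_config("custom", P = c(1, 1, 0.5), Q = c(1, 0, 0.5))
  want <- position_score(x, m) -
    (1 * binding_energy(x, 5, tab) * f["A", 5]^1 +
     1 * binding_energy(x, 6, tab) * f["A", 6]^0 +
     0.5 * binding_energy(x, 7, tab) * f["C", 7]^0.5) / 2.5
  expect_equal(score_star(x, m, tab, cfg), want)
  # uniform matrix + zero-energy table: any config gives -14
  u <- bps_matrix(matrix(0.25, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL)))
  zero <- tab
  zero$energy[] <- 0
  expect_equal(score_star(x, u, zero, cfg), -14)
})

test_that("candidate enumeration respects zone, intron bounds and N", {
  s <- paste0(strrep("C", 30), "AG") # n = 32
  cand <- enumerate_candidates(s, -10L, -10L)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$branch_pos, -10L)
  expect_equal(cand$heptamer, substr(s, 32 - 15 + 1, 32 - 9 + 1))
  # heptamer position 7 may not leave the intron: p = -1 impossible
  cand_all <- enumerate_candidates(s, -32L, -1L)
  expect_equal(max(cand_all$branch_pos), -2L)
  # heptamer needs 5 nt of room on the 5' side
  expect_equal(min(cand_all$branch_pos), -27L)
  # N anywhere in the heptamer removes the candidate
  sN <- paste0(strrep("C", 10), "N", strrep("C", 19), "AG")
  candN <- enumerate_candidates(sN, -32L, -1L)
  expect_false(any(candN$branch_pos %in% -23:-17))
  expect_true(all(!grepl("N", candN$heptamer)))
})

test_that("predict matches a first-principles rescan on random fixtures", {
  withr::local_seed(17)
  m <- bundled_matrix("degenerate_synthetic")
  tab <- nn_table()
  cfg <- score_config("score8")
  lens <- sample(c(80L, 120L, 160L), 100, TRUE)
  bps <- sample(seq(-40L, -21L), 100, TRUE)
  introns <- simulate_introns(100, seed = 18, intron_length = lens,
                              branch_pos = bps, bps_heptamer = "sample",
                              matrix = m, n_decoy_ag = 3L)
  preds <- predict_branch_points(introns, m, tab, cfg)
  for (i in seq_len(nrow(introns))) {
    want <- oracle_predict(introns$seq[i], unclass(m), tab$energy,
                           P = cfg$P, Q = cfg$Q, L = 9)
    expect_false(is.null(want))
    expect_equal(preds$branch_pos[i], want$branch_pos, info = introns$id[i])
    expect_equal(preds$heptamer[i], want$heptamer, info = introns$id[i])
    expect_equal(preds$score[i], want$score, info = introns$id[i])
  }
})

test_that("ties break toward the 3'ss and all-excluded falls back on BE", {
  m <- bundled_matrix("tna_synthetic")
  tab <- nn_table()
  # two identical planted heptamers in-zone: the 3'-most must win.
  # layout: ...AG | TACTAAC | CC | TACTAAC | pyrimidine tail | AG
  s <- paste0(
    strrep("T", 40), "AG", "TACTAAC", "CC", "TACTAAC",
    strrep("C", 6), strrep("T", 12), "AG"
  )
  introns <- tibble::tibble(id = "tie", seq = s)
  p <- predict_branch_points(introns, m, tab, score_config("score0"))
  n <- nchar(s)
  # branch positions of the two copies (heptamer position 6)
  p1 <- (42 + 6) - n - 1 # 5' copy
  p2 <- (51 + 6) - n - 1 # 3' copy
  expect_equal(p$branch_pos, as.integer(p2))
  expect_gt(p2, p1)

  # all candidates -Inf under the TNA matrix: flagged BE fallback
  s2 <- paste0(strrep("C", 28), "AG", strrep("C", 20), strrep("T", 10), "AG")
  p2r <- predict_branch_points(tibble::tibble(id = "x", seq = s2), m, tab,
                               score_config("score8"))
  expect_true(p2r$all_excluded)
  expect_equal(p2r$score, -Inf)
  expect_false(is.na(p2r$branch_pos))
})

test_that("with the TNA-fixed matrix every finite candidate is T4/A6", {
  m <- bundled_matrix("tna_synthetic")
  introns <- simulate_introns(20, seed = 41)
  tab <- nn_table()
  for (i in seq_len(nrow(introns))) {
    s <- introns$seq[i]
    z <- find_agez(s)
    core_start <- if (is.na(z$defining_ag)) -nchar(s) else z$defining_ag
    ppt <- find_ppt(s, core_start)
    short <- shorten_agez(z, ppt, s)
    cand <- enumerate_candidates(s, short$start, short$end)
    sc <- score_star(cand$heptamer, m, tab, score_config("score8"))
    fin <- is.finite(sc)
    expect_true(all(substr(cand$heptamer[fin], 4, 4) == "T"))
    expect_true(all(substr(cand$heptamer[fin], 6, 6) == "A"))
  }
})
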