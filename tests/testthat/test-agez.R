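# Build an intron whose defining AG sits at a known position: background C's,
# an AG with its A at `a`, pyrimidines downstream, terminal AG.
intron_with_ag_at <- function(a, n = 60L) {
  ch <- rep("C", n)
  ch[n + a + 1] <- "A"
  ch[n + a + 2] <- "G"
  ch[n - 1] <- "A"
  ch[n] <- "G"
  paste(ch, collapse = "")
}

test_that("AGEZ extends L nucleotides past the defining AG", {
  s <- intron_with_ag_at(-31L)
  z <- find_agez(s, agez_params(L = 9))
  expect_equal(z$defining_ag, -31L)
  expect_equal(z$start, -40L)
  expect_equal(z$end, -1L)
  z12 <- find_agez(s, agez_params(L = 12))
  expect_equal(z12$start, -43L)
})

test_that("no internal AG means the whole intron is the AGEZ", {
  s <- paste0(strrep("C", 58), "AG")
  z <- find_agez(s)
  expect_true(is.na(z$defining_ag))
  expect_equal(z$start, -60L)
})

test_that("the ignore zone hides 3'-terminal AGs; an A at -13 is not hidden", {
  # AG with A at -5 (inside the ignore zone) must be skipped
  n <- 60L
  ch <- strsplit(intron_with_ag_at(-31L, n), "")[[1]]
  ch[n - 4] <- "A"
  ch[n - 3] <- "G"
  z <- find_agez(paste(ch, collapse = ""))
  expect_equal(z$defining_ag, -31L)
  # an AG straddling the boundary (A at -13, G at -12) defines the zone
  s <- intron_with_ag_at(-13L)
  expect_equal(find_agez(s)$defining_ag, -13L)
  # AGEZ clamps at the intron start
  s <- intron_with_ag_at(-14L, n = 20L)
  expect_equal(find_agez(s)$start, -20L)
  expect_error(find_agez(paste0(strrep("C", 10), "AG")), "region error")
})

test_that("the AGEZ core carries no AG dinucleotide, on many fixtures", {
  withr::local_seed(13)
  introns <- simulate_introns(60, seed = 202,
                              intron_length = sample(c(90L, 120L, 200L), 60, TRUE),
                              branch_pos = sample(seq(-40L, -22L), 60, TRUE))
  for (i in seq_len(nrow(introns))) {
    s <- introns$seq[i]
    n <- nchar(s)
    z <- find_agez(s)
    expect_false(is.na(z$defining_ag))
    core <- substr(s, pos_idx(z$defining_ag + 2L, n), pos_idx(-13L, n))
    expect_false(grepl("AG", core, fixed = TRUE))
    # and the zone contains the planted branch site
    expect_true(introns$branch_sites[[i]] >= z$start)
  }
})

test_that("shorten_agez removes the PPT's all-pyrimidine suffix", {
  agez <- list(start = -40L, end = -1L)
  # no PPT: unchanged
  expect_equal(shorten_agez(agez, NULL)$end, -1L)

  # PPT "CTTTTAGTTTTC" ending at -5: suffix run TTTTC starts at -9
  s <- paste0(strrep("A", 43), "CTTTTAGTTTTC", "CCAG")
  n <- nchar(s)
  ppt <- c(start = -16L, end = -5L)
  expect_equal(substr(s, pos_idx(-16L, n), pos_idx(-5L, n)), "CTTTTAGTTTTC")
  short <- shorten_agez(agez, ppt, s)
  expect_equal(short$end, -10L)
  expect_equal(short$start, -40L)

  # pure-pyrimidine PPT: boundary just 5' of the whole tract
  s2 <- paste0(strrep("A", 40), strrep("T", 11), strrep("A", 7), "AG")
  short2 <- shorten_agez(agez, c(start = -20L, end = -10L), s2)
  expect_equal(short2$end, -21L)

  # empty searchable space is a region error
  expect_error(
    shorten_agez(list(start = -20L, end = -1L), c(start = -20L, end = -10L), s2),
    "region error"
  )
})

test_that("locate_regions nests SHORT_AGEZ inside AGEZ with sane bounds", {
  introns <- simulate_introns(8, seed = 31)
  reg <- locate_regions(introns)
  expect_true(all(reg$start <= reg$end))
  expect_true(all(reg$end <= -1))
  wide <- tidyr::pivot_wider(reg, names_from = "label",
                             values_from = c("start", "end"))
  expect_true(all(wide$start_SHORT_AGEZ == wide$start_AGEZ))
  expect_true(all(wide$end_SHORT_AGEZ <= wide$end_AGEZ))
  # the PPT ends in a pyrimidine, so its suffix run is non-empty
  expect_true(all(wide$end_SHORT_AGEZ < wide$end_PPT))
})
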