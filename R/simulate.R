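#' Generate synthetic introns with a planted branch point
#'
#' Deterministic generator emulating the canonical intron architecture
#' around the 3' splice site: a planted BPS heptamer (branch site at
#' heptamer position 6), a rule-valid T-rich polypyrimidine tract between
#' the branch point and the terminal AG, an AGEZ-defining AG placed just
#' upstream of the heptamer, an AG-free AGEZ core, and decoy AG
#' dinucleotides in the upstream background. The T-at-4/A-at-6 pattern is
#' actively broken at every other in-zone position, so with a TNA-fixed
#' frequency matrix the planted heptamer is the only finite-score candidate
#' and must be recovered.
#'
#' @param n Number of introns.
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param intron_length Intron length in nucleotides (recycled over introns).
#' @param branch_pos 3'ss-relative branch-site position (negative; recycled).
#' @param bps_heptamer Planted heptamer, or `"sample"` to draw one from
#'   `matrix` (must then be AG-free; resampled up to 50 times).
#' @param matrix Optional `bps_matrix` used when `bps_heptamer = "sample"`.
#' @param ppt_length Length of the planted polypyrimidine tract.
#' @param n_decoy_ag Number of decoy AG dinucleotides planted in the
#'   background upstream of the AGEZ-defining AG.
#' @param gc_background Background GC fraction (default 0.4, intron-like).
#' @return An annotated intron tibble (as from [read_bps_fasta()]).
#' @examples
#' simulate_introns(2, seed = 7)
#' @export
simulate_introns <- function(n = 50L, seed = NULL, intron_length = 120L,
                             branch_pos = -25L, bps_heptamer = "TACTAAC",
                             matrix = NULL, ppt_length = 15L,
                             n_decoy_ag = 2L, gc_background = 0.4) {
  gen <- function() {
    len <- rep_len(as.integer(intron_length), n)
    bp <- rep_len(as.integer(branch_pos), n)
    rows <- lapply(seq_len(n), function(i) {
      generate_intron(
        id = sprintf("synth%03d", i), intron_length = len[i], branch_pos = bp[i],
        bps_heptamer = bps_heptamer, matrix = matrix, ppt_length = ppt_length,
        n_decoy_ag = n_decoy_ag, gc_background = gc_background
      )
    })
    bind_rows(rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' @rdname simulate_introns
#' @param id Record id for the single generated intron.
#' @export
generate_intron <- function(id = "synth001", intron_length = 120L,
                            branch_pos = -25L, bps_heptamer = "TACTAAC",
                            matrix = NULL, ppt_length = 15L, n_decoy_ag = 2L,
                            gc_background = 0.4) {
  nlen <- as.integer(intron_length)
  bp <- as.integer(branch_pos)
  ppt_length <- as.integer(ppt_length)

  if (ppt_length < 9L) {
    abort("generation error: ppt_length must be >= 9 (rule-valid tract)")
  }
  if (bp > -(ppt_length + 4L)) {
    abort(sprintf(
      "generation error: branch_pos %d collides with the PPT (needs <= %d so the PPT fits between the BPS and the 3'ss)",
      bp, -(ppt_length + 4L)
    ))
  }
  a <- bp - 8L # A of the AGEZ-defining AG
  if (a - 16L < -nlen + 2L) {
    abort(sprintf(
      "generation error: intron_length %d leaves no background upstream of the defining AG (branch_pos %d)",
      nlen, bp
    ))
  }

  hept <- if (identical(bps_heptamer, "sample")) {
    if (is.null(matrix)) abort("generation error: bps_heptamer = \"sample\" needs `matrix`")
    sample_heptamer(matrix)
  } else {
    toupper(bps_heptamer)
  }
  if (nchar(hept) != 7L || grepl("[^ACGT]", hept)) {
    abort("generation error: bps_heptamer must be a 7-mer over A/C/G/T")
  }
  if (grepl("AG", hept, fixed = TRUE)) {
    abort("generation error: bps_heptamer contains an AG dinucleotide, which would redefine the AGEZ")
  }

  bases <- c("A", "C", "G", "T")
  wts <- c((1 - gc_background) / 2, gc_background / 2,
           gc_background / 2, (1 - gc_background) / 2)
  ch <- sample(bases, nlen, replace = TRUE, prob = wts)
  set <- function(p, value) {
    ch[pos_idx(p, nlen) + seq_along(value) - 1L] <<- value
  }

  # terminal 3'ss AG
  set(-2L, c("A", "G"))
  # T-rich pure-pyrimidine PPT ending 1 nt before the terminal AG
  ppt <- sample(c("T", "C"), ppt_length, replace = TRUE, prob = c(0.7, 0.3))
  if (sum(ppt == "T") < 5L) ppt[sample(ppt_length, 5L)] <- "T"
  set(-(ppt_length + 2L), ppt)
  # pyrimidine gap between heptamer and PPT
  if (bp + 2L <= -(ppt_length + 3L)) {
    gap <- seq.int(bp + 2L, -(ppt_length + 3L))
    set(gap[1], sample(c("T", "C"), length(gap), replace = TRUE))
  }
  # planted heptamer, branch site at heptamer position 6
  set(bp - 5L, strsplit(hept, "", fixed = TRUE)[[1]])
  # AGEZ-defining AG just upstream, separated by a C
  set(a, c("A", "G"))
  set(bp - 6L, "C")

  # break any AG in the core between the defining AG and the ignore zone
  for (p in seq.int(-13L, a + 2L)) {
    if (ch[pos_idx(p, nlen)] == "A" && ch[pos_idx(p + 1L, nlen)] == "G") {
      set(p + 1L, "C")
    }
  }
  # break T..A patterns (pos 4 / pos 6 of a candidate) at in-zone positions
  # other than the planted branch site, for any L up to 12
  for (p in seq.int(a - 13L, a)) {
    if (p == bp || p - 2L < -nlen) next
    if (ch[pos_idx(p, nlen)] == "A" && ch[pos_idx(p - 2L, nlen)] == "T") {
      if (p == a) set(p - 2L, "C") else set(p, "C")
    }
  }
  # decoy AGs well upstream of any possible AGEZ extension
  if (n_decoy_ag > 0L) {
    room <- seq.int(-nlen + 1L, a - 18L)
    if (length(room) < n_decoy_ag) {
      abort("generation error: intron too short to place the requested decoy AGs upstream of the AGEZ")
    }
    decoys <- sort(sample(room, n_decoy_ag))
    # keep decoys non-overlapping
    decoys <- decoys[c(TRUE, diff(decoys) >= 2L)]
    for (d in decoys) set(d, c("A", "G"))
  }

  seq <- paste(ch, collapse = "")
  tibble(
    id = id, seq = seq, length = nlen,
    branch_sites = list(bp), canonical_3ss = TRUE
  )
}

sample_heptamer <- function(m, tries = 50L) {
  f <- unclass(if (inherits(m, "bps_matrix")) m else bps_matrix(m))
  for (t in seq_len(tries)) {
    h <- paste(vapply(1:7, function(i) {
      sample(c("A", "C", "G", "T"), 1L, prob = f[, i])
    }, character(1)), collapse = "")
    if (!grepl("AG", h, fixed = TRUE)) return(h)
  }
  abort("generation error: could not sample an AG-free heptamer from the matrix")
}
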