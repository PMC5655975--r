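#' Hamming-distance baseline over a fixed 3'-terminal window
#'
#' The literature baseline that ranks heptamers by Hamming distance to the
#' strict yeast consensus TACTAAC over a fixed window (100 or 200 nt)
#' measured from the intron 3' end (terminal AG included). The minimal
#' -distance heptamer wins; ties go to the branch site closest to the 3'ss.
#' The window clamps to the intron length; heptamers containing N are
#' skipped.
#'
#' @param introns Intron tibble.
#' @param window Window length in nucleotides (typically 100 or 200).
#' @param consensus Consensus heptamer (default `TACTAAC`).
#' @return A prediction tibble: `intron_id`, `heptamer`, `branch_pos`,
#'   `distance`, `method`.
#' @examples
#' introns <- simulate_introns(3, seed = 1)
#' hamming_baseline(introns, window = 100)
#' @export
hamming_baseline <- function(introns, window = 100L, consensus = "TACTAAC") {
  check_introns(introns)
  window <- as.integer(window)
  if (window < 7L) abort("window must be at least 7 nt")
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    seq <- introns$seq[i]
    n <- nchar(seq)
    cand <- enumerate_candidates(seq, max(-window, -n) + 5L, -2L)
    if (nrow(cand) == 0L) {
      return(tibble(intron_id = introns$id[i], heptamer = NA_character_,
                    branch_pos = NA_integer_, distance = NA_integer_))
    }
    d <- hamming_to(cand$heptamer, cons)
    best <- which(d == min(d))
    best <- best[which.max(cand$branch_pos[best])]
    tibble(intron_id = introns$id[i], heptamer = cand$heptamer[best],
           branch_pos = cand$branch_pos[best], distance = d[best])
  })
  out <- bind_rows(rows)
  out$method <- paste0("hamming", window)
  out
}

hamming_to <- function(x, cons) {
  ch <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
               ncol = length(cons), byrow = TRUE)
  as.integer(rowSums(ch != matrix(cons, nrow = length(x), ncol = length(cons),
                                  byrow = TRUE)))
}

#' PWM-over-AGEZ baseline
#'
#' Approximate stand-in for the PWM methods that score candidates over the
#' full (un-shortened) AGEZ with the position-specific score alone: the
#' argmax of `S` over candidates whose branch site lies in the AGEZ, ties
#' toward the 3'ss. Equivalent to [predict_branch_points()] with all
#' `P_j = 0` whenever the shortened AGEZ equals the AGEZ.
#'
#' @param introns Intron tibble.
#' @param m A `bps_matrix`.
#' @param params An [agez_params()] object.
#' @return A prediction tibble: `intron_id`, `heptamer`, `branch_pos`,
#'   `score`, `method`.
#' @export
pwm_agez_baseline <- function(introns, m, params = agez_params()) {
  check_introns(introns)
  if (!inherits(m, "bps_matrix")) m <- bps_matrix(m)
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    seq <- introns$seq[i]
    agez <- find_agez(seq, params)
    cand <- enumerate_candidates(seq, agez$start, agez$end)
    if (nrow(cand) == 0L) {
      return(tibble(intron_id = introns$id[i], heptamer = NA_character_,
                    branch_pos = NA_integer_, score = NA_real_))
    }
    sc <- position_score(cand$heptamer, m)
    best <- which(sc == max(sc))
    best <- best[which.max(cand$branch_pos[best])]
    tibble(intron_id = introns$id[i], heptamer = cand$heptamer[best],
           branch_pos = cand$branch_pos[best], score = sc[best])
  })
  out <- bind_rows(rows)
  out$method <- "pwm_agez"
  out
}
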