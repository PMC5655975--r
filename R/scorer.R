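#' S* splicing-strength score of candidate heptamers
#'
#' Combines the position-specific score with the BPS/U2 binding energy and
#' the branch-site nucleotide preference:
#' `S* = S - sum_j P_j * BE(X/X_{j+4}) * f(j+4, X_{j+4})^{Q_j} / sum_j P_j`.
#' Binding energies are negative for stable duplexes, so an active energy
#' term raises the score of heptamers that pair well with GUAGUA. When all
#' `P_j = 0`, `S* = S` exactly. `-Inf` from a zero frequency propagates.
#'
#' @param x Character vector of 7-mers over A/C/G/T.
#' @param m A `bps_matrix`.
#' @param energy A `bps_energy_table` (may be `NULL` when all `P_j = 0`).
#' @param config A [score_config()].
#' @return Numeric vector of scores (bits + energy term; may be `-Inf`).
#' @examples
#' m <- bundled_matrix("degenerate_synthetic")
#' tab <- build_energy_table("nn")
#' score_star("TACTAAC", m, tab, score_config("score8"))
#' @export
score_star <- function(x, m, energy = NULL, config = score_config("score8")) {
  if (!inherits(config, "score_config")) abort("`config` must be a score_config")
  s <- position_score(x, m)
  if (sum(config$P) == 0) return(s)
  if (is.null(energy)) abort("an energy table is required when any P_j > 0")
  f <- unclass(if (inherits(m, "bps_matrix")) m else bps_matrix(m))
  term <- 0
  for (j in 1:3) {
    if (config$P[j] == 0) next
    k <- j + 4L
    xk <- substr(x, k, k)
    fk <- f[cbind(match(xk, c("A", "C", "G", "T")), k)]
    term <- term + config$P[j] * binding_energy(x, k, energy) * fk^config$Q[j]
  }
  s - term / sum(config$P)
}

#' Enumerate candidate branch-point heptamers in the shortened AGEZ
#'
#' One candidate per position `p` in the region such that the heptamer
#' spanning `[p - 5, p + 1]` (branch site at heptamer position 6) lies
#' wholly inside the intron; heptamers containing N are skipped.
#'
#' @param seq Intron sequence.
#' @param start,end 3'ss-relative bounds of the search region.
#' @return A tibble with columns `branch_pos` and `heptamer` (possibly with
#'   zero rows).
#' @export
enumerate_candidates <- function(seq, start, end) {
  n <- nchar(seq)
  lo <- max(start, -n + 5L)
  hi <- min(end, -2L)
  if (lo > hi) return(tibble(branch_pos = integer(0), heptamer = character(0)))
  p <- seq.int(lo, hi)
  hept <- substring(seq, pos_idx(p - 5L, n), pos_idx(p + 1L, n))
  keep <- !grepl("N", hept, fixed = TRUE)
  tibble(branch_pos = as.integer(p[keep]), heptamer = hept[keep])
}

#' Predict branch points for a table of introns
#'
#' The full pipeline per intron: AGEZ from the defining AG, PPT within the
#' AGEZ core, shortened AGEZ, candidate enumeration, S* scoring, and
#' argmax selection. Ties are broken toward the branch site closest to the
#' 3' splice site. If every candidate scores `-Inf` (all excluded by zero
#' frequencies), the candidate with the most negative branch-site binding
#' energy `BE(X/X_6)` is returned and flagged.
#'
#' @param introns Intron tibble (see [read_bps_fasta()]).
#' @param m A `bps_matrix`.
#' @param energy A `bps_energy_table`; defaults to the co-fold table when
#'   the configuration has an active energy term.
#' @param config A [score_config()] (default `score8`).
#' @param params An [agez_params()] object (default L = 9).
#' @param rules A [ppt_rules()] object.
#' @return A tibble, one row per intron: `intron_id`, `status` (`"ok"` or a
#'   reason for no prediction), `heptamer`, `branch_pos`, `score`,
#'   `all_excluded` (flag for the all-`-Inf` fallback), `n_candidates`, the
#'   regions used (`ppt_start`, `ppt_end`, `agez_start`, `short_agez_start`,
#'   `short_agez_end`), `score_name`, `matrix_source`.
#' @examples
#' introns <- simulate_introns(3, seed = 1)
#' m <- bundled_matrix("tna_synthetic")
#' predict_branch_points(introns, m, build_energy_table("nn"))
#' @export
predict_branch_points <- function(introns, m, energy = NULL,
                                  config = score_config("score8"),
                                  params = agez_params(),
                                  rules = ppt_rules()) {
  check_introns(introns)
  if (!inherits(m, "bps_matrix")) m <- bps_matrix(m)
  if (is.null(energy) && sum(config$P) > 0) energy <- build_energy_table("cofold")

  rows <- lapply(seq_len(nrow(introns)), function(i) {
    res <- predict_one(introns$seq[i], m, energy, config, params, rules)
    tibble(
      intron_id = introns$id[i], status = res$status,
      heptamer = res$heptamer, branch_pos = res$branch_pos, score = res$score,
      all_excluded = res$all_excluded, n_candidates = res$n_candidates,
      ppt_start = res$ppt[1], ppt_end = res$ppt[2],
      agez_start = res$agez[1],
      short_agez_start = res$short[1], short_agez_end = res$short[2]
    )
  })
  out <- bind_rows(rows)
  out$score_name <- config$name
  out$matrix_source <- attr(m, "source") %||% "custom"
  out
}

predict_one <- function(seq, m, energy, config, params, rules) {
  none <- list(
    status = "ok", heptamer = NA_character_, branch_pos = NA_integer_,
    score = NA_real_, all_excluded = FALSE, n_candidates = 0L,
    ppt = c(NA_integer_, NA_integer_),
    agez = c(NA_integer_, NA_integer_), short = c(NA_integer_, NA_integer_)
  )
  n <- nchar(seq)
  agez <- tryCatch(find_agez(seq, params), error = function(e) NULL)
  if (is.null(agez)) {
    none$status <- "intron_too_short"
    return(none)
  }
  none$agez <- c(agez$start, agez$end)
  core_start <- if (is.na(agez$defining_ag)) -n else agez$defining_ag
  ppt <- find_ppt(seq, core_start, -1L, rules)
  if (!is.null(ppt)) none$ppt <- c(ppt[["start"]], ppt[["end"]])
  short <- tryCatch(shorten_agez(agez, ppt, seq), error = function(e) NULL)
  if (is.null(short)) {
    none$status <- "empty_shortened_agez"
    return(none)
  }
  none$short <- c(short$start, short$end)
  cand <- enumerate_candidates(seq, short$start, short$end)
  none$n_candidates <- nrow(cand)
  if (nrow(cand) == 0L) {
    none$status <- "no_candidates"
    return(none)
  }
  sc <- score_star(cand$heptamer, m, energy, config)
  if (all(sc == -Inf)) {
    if (is.null(energy)) energy <- build_energy_table("cofold")
    be6 <- binding_energy(cand$heptamer, 6L, energy)
    best <- which(be6 == min(be6))
    best <- best[which.max(cand$branch_pos[best])]
    none$all_excluded <- TRUE
  } else {
    best <- which(sc == max(sc))
    best <- best[which.max(cand$branch_pos[best])]
  }
  none$heptamer <- cand$heptamer[best]
  none$branch_pos <- cand$branch_pos[best]
  none$score <- sc[best]
  none
}
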