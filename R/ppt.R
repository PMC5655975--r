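#' Polypyrimidine-tract validity rules
#'
#' The rule set under which a pyrimidine tract counts as a PPT:
#' both ends must be pyrimidines; no purine run longer than
#' `max_purine_run`; every (non-exempt) purine segment of length l must be
#' flanked on each side by at least l pyrimidines totalling at least
#' `flank_total_factor * l`; T(GT)n stretches are allowed (their G's are
#' exempt from the flanking requirement); and the tract must be at least
#' `min_length` long or contain at least `min_uridines` T's.
#'
#' @param max_purine_run Longest allowed run of consecutive purines.
#' @param flank_total_factor Combined flanking pyrimidine requirement, as a
#'   multiple of the purine-segment length.
#' @param min_length Minimum tract length (disjunct with `min_uridines`).
#' @param min_uridines Minimum T count (disjunct with `min_length`).
#' @return An object of class `ppt_rules`.
#' @export
ppt_rules <- function(max_purine_run = 2L, flank_total_factor = 4L,
                      min_length = 9L, min_uridines = 5L) {
  r <- list(
    max_purine_run = as.integer(max_purine_run),
    flank_total_factor = as.integer(flank_total_factor),
    min_length = as.integer(min_length),
    min_uridines = as.integer(min_uridines)
  )
  if (any(vapply(r, function(x) x < 1L, logical(1)))) {
    abort("all PPT rule thresholds must be positive integers")
  }
  structure(r, class = "ppt_rules")
}

#' Test whether a sequence is a valid polypyrimidine tract
#'
#' Applies the five PPT rules (see [ppt_rules()]) to each string. G's lying
#' inside a T(GT)n stretch are exempt from the flanking-pyrimidine rule;
#' purine runs longer than the maximum invalidate the tract outright.
#'
#' @param s Character vector of A/C/G/T strings.
#' @param rules A [ppt_rules()] object.
#' @return Logical vector.
#' @examples
#' is_valid_ppt(c("TTTTTTTTT", "TTTTAAATTTT", "CTTTTAGTTTTC"))
#' @export
is_valid_ppt <- function(s, rules = ppt_rules()) {
  if (length(s) == 0L) return(logical(0))
  if (any(is.na(s)) || any(nchar(s) == 0L)) abort("input error: empty or NA sequence")
  if (any(grepl("[^ACGT]", s))) abort("input error: PPT sequences must be A/C/G/T only")
  vapply(s, valid_ppt_one, logical(1), rules = rules, USE.NAMES = FALSE)
}

valid_ppt_one <- function(s, rules) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  py <- ch == "C" | ch == "T"

  # rule 1: pyrimidine ends
  if (!py[1] || !py[n]) return(FALSE)

  # rule 5: minimum length or T content
  if (n < rules$min_length && sum(ch == "T") < rules$min_uridines) return(FALSE)

  r <- rle(py)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  # rule 2: cap on purine runs (a run that long cannot sit inside T(GT)n)
  if (any(!r$values & r$lengths > rules$max_purine_run)) return(FALSE)

  # rule 4: G's inside T(GT)n stretches are exempt from rule 3
  exempt <- logical(n)
  m <- gregexpr("T(GT)+", s)[[1]]
  if (m[1] != -1L) {
    for (j in seq_along(m)) {
      len <- attr(m, "match.length")[j]
      exempt[m[j] + seq(1L, len - 2L, by = 2L)] <- TRUE
    }
  }

  # rule 3: flanking pyrimidines around each non-exempt purine segment
  for (k in which(!r$values)) {
    l <- r$lengths[k]
    if (l == 1L && exempt[starts[k]]) next
    left <- if (k > 1L) r$lengths[k - 1L] else 0L
    right <- if (k < length(r$lengths)) r$lengths[k + 1L] else 0L
    if (left < l || right < l || left + right < rules$flank_total_factor * l) {
      return(FALSE)
    }
  }
  TRUE
}

#' Locate the polypyrimidine tract in a search window
#'
#' Finds maximal PPT candidates (valid tracts not extendable by one base on
#' either side within the window) and returns the one whose 3' end is
#' closest to the 3' splice site; overlapping candidates with the same end
#' are resolved toward the 3'-most start. Maximal candidates necessarily
#' begin and end on full pyrimidine runs, so the search enumerates spans of
#' complete pyrimidine segments.
#'
#' @param seq Intron sequence (A/C/G/T/N string).
#' @param search_start,search_end 3'ss-relative bounds of the search window.
#' @param rules A [ppt_rules()] object.
#' @return A named integer vector `c(start, end)` in 3'ss-relative
#'   coordinates, or `NULL` if no valid tract exists.
#' @export
find_ppt <- function(seq, search_start, search_end = -1L, rules = ppt_rules()) {
  n <- nchar(seq)
  if (search_start > search_end || search_end > -1L || search_start < -n) {
    return(NULL)
  }
  w <- substr(seq, pos_idx(search_start, n), pos_idx(search_end, n))
  if (grepl("N", w, fixed = TRUE)) {
    # N cannot belong to a tract; split on N and search each piece,
    # keeping the window-level selection rule.
    best <- NULL
    offset <- 0L
    for (piece in strsplit(w, "N", fixed = TRUE)[[1]]) {
      if (nchar(piece) > 0L) {
        hit <- ppt_in_window(piece, rules)
        if (!is.null(hit)) {
          cand <- hit + offset
          if (is.null(best) || cand[2] > best[2] ||
              (cand[2] == best[2] && cand[1] > best[1])) {
            best <- cand
          }
        }
      }
      offset <- offset + nchar(piece) + 1L
    }
    if (is.null(best)) return(NULL)
    return(c(start = search_start + best[1] - 1L, end = search_start + best[2] - 1L))
  }
  hit <- ppt_in_window(w, rules)
  if (is.null(hit)) return(NULL)
  c(start = search_start + hit[1] - 1L, end = search_start + hit[2] - 1L)
}

# Core search on a plain window string; returns 1-based c(start, end) or NULL.
ppt_in_window <- function(w, rules) {
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  py <- ch == "C" | ch == "T"
  if (!any(py)) return(NULL)
  r <- rle(py)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  ys <- which(r$values)
  # 3'-most end first, then 3'-most start: first valid span wins.
  for (j in rev(seq_along(ys))) {
    for (i in rev(seq_len(j))) {
      a <- seg_start[ys[i]]
      b <- seg_end[ys[j]]
      if (valid_ppt_one(substr(w, a, b), rules)) {
        return(c(a, b))
      }
    }
  }
  NULL
}
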