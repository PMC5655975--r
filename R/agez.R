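#' AGEZ parameters
#'
#' @param L Extension, in nucleotides, added upstream of the AGEZ-defining AG
#'   (valid 7-12; default 9, the operating point at which the scoring
#'   measures peak).
#' @param ignore_zone Number of 3'-terminal intron positions within which AG
#'   dinucleotides are ignored when locating the defining AG (default 12).
#' @return An object of class `agez_params`.
#' @export
agez_params <- function(L = 9L, ignore_zone = 12L) {
  L <- as.integer(L)
  ignore_zone <- as.integer(ignore_zone)
  if (is.na(L) || L < 7L || L > 12L) abort("L must be an integer in [7, 12]")
  if (is.na(ignore_zone) || ignore_zone < 1L) abort("ignore_zone must be positive")
  structure(list(L = L, ignore_zone = ignore_zone), class = "agez_params")
}

#' Locate the AG exclusion zone of an intron
#'
#' Scans 5'-ward from just upstream of the ignore zone for the first AG
#' dinucleotide (the AGEZ-defining AG); the AGEZ runs from `L` nucleotides
#' upstream of that AG to the 3' splice site, clamped to the intron start.
#' If no AG exists upstream, the whole intron is the AGEZ. An AG whose A sits
#' at position -(ignore_zone + 1) is not ignored: only AGs found wholly
#' within the ignore zone are.
#'
#' @param seq Intron sequence (A/C/G/T/N string).
#' @param params An [agez_params()] object.
#' @return A list with `start`, `end` (3'ss-relative) and `defining_ag` (the
#'   position of the A of the defining AG, or `NA` if none).
#' @export
find_agez <- function(seq, params = agez_params()) {
  n <- nchar(seq)
  if (n <= params$ignore_zone + 2L) {
    abort(sprintf(
      "region error: intron of length %d too short for an AGEZ (need > %d)",
      n, params$ignore_zone + 2L
    ))
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  a <- NA_integer_
  for (p in seq(-(params$ignore_zone + 1L), -n, by = -1L)) {
    i <- pos_idx(p, n)
    if (ch[i] == "A" && i < n && ch[i + 1L] == "G") {
      a <- p
      break
    }
  }
  start <- if (is.na(a)) -n else max(a - params$L, -n)
  list(start = as.integer(start), end = -1L, defining_ag = a)
}

#' Shorten the AGEZ by the pyrimidine-rich 3' end of the PPT
#'
#' The branch point is not found inside the pyrimidine-rich 3' end of the
#' PPT, so the BPS search region excludes it: the shortened AGEZ ends
#' immediately 5' of the PPT's maximal all-pyrimidine suffix (the whole PPT,
#' if it is purely pyrimidine). With no PPT the AGEZ is returned unchanged.
#'
#' @param agez A region list from [find_agez()] (or any list with `start`,
#'   `end`).
#' @param ppt `c(start, end)` from [find_ppt()], or `NULL`.
#' @param seq The intron sequence.
#' @return A list with `start` and `end` (3'ss-relative).
#' @export
shorten_agez <- function(agez, ppt = NULL, seq = NULL) {
  if (is.null(ppt)) {
    return(list(start = agez$start, end = agez$end))
  }
  if (is.null(seq)) abort("`seq` is required when a PPT is supplied")
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  run_start <- ppt[["end"]]
  while (run_start - 1L >= ppt[["start"]] &&
         ch[pos_idx(run_start - 1L, n)] %in% c("C", "T")) {
    run_start <- run_start - 1L
  }
  end <- run_start - 1L
  if (end < agez$start) {
    abort("region error: shortened AGEZ is empty (no searchable space 5' of the PPT)")
  }
  list(start = agez$start, end = as.integer(end))
}

#' Compute PPT, AGEZ and shortened-AGEZ regions for a table of introns
#'
#' Runs the full region pipeline per intron: AGEZ from the defining AG, PPT
#' search within the AGEZ core (defining AG to the 3'ss, without the L
#' extension), then the shortened AGEZ. Regions are reported in
#' 3'ss-relative coordinates (position -1 = last intron base).
#'
#' @param introns Intron tibble (see [read_bps_fasta()]).
#' @param params An [agez_params()] object.
#' @param rules A [ppt_rules()] object.
#' @return A tibble with columns `intron_id`, `label` (one of `PPT`, `AGEZ`,
#'   `SHORT_AGEZ`), `start`, `end`. Introns lacking a PPT contribute no PPT
#'   row; an empty shortened AGEZ contributes no SHORT_AGEZ row.
#' @examples
#' introns <- simulate_introns(2, seed = 1)
#' locate_regions(introns)
#' @export
locate_regions <- function(introns, params = agez_params(), rules = ppt_rules()) {
  check_introns(introns)
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    seq <- introns$seq[i]
    id <- introns$id[i]
    agez <- find_agez(seq, params)
    core_start <- if (is.na(agez$defining_ag)) -nchar(seq) else agez$defining_ag
    ppt <- find_ppt(seq, core_start, -1L, rules)
    short <- tryCatch(shorten_agez(agez, ppt, seq), error = function(e) NULL)
    out <- tibble(
      intron_id = id,
      label = c("AGEZ", if (!is.null(ppt)) "PPT", if (!is.null(short)) "SHORT_AGEZ"),
      start = c(agez$start, if (!is.null(ppt)) ppt[["start"]],
                if (!is.null(short)) short$start),
      end = c(agez$end, if (!is.null(ppt)) ppt[["end"]],
              if (!is.null(short)) short$end)
    )
    out
  })
  bind_rows(rows)
}
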