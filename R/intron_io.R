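#' Read intron sequences with optional branch-site annotations
#'
#' Reads a multi-record FASTA of intron sequences written 5' to 3' and ending
#' at the 3' splice site, so the last two bases of each record are normally
#' the terminal AG. Branch-site annotations are carried in the header as a
#' `bp=` token holding comma-separated 3'ss-relative positions, e.g.
#' `>intron1 bp=-24,-31`. Position -1 is the last intron base.
#'
#' Sequences are uppercased and U is mapped to T; records containing symbols
#' other than A/C/G/T/N are rejected. A record whose sequence does not end in
#' AG is an error unless `permissive = TRUE`, in which case a warning is
#' raised and the record is kept (flagged in the `canonical_3ss` column).
#'
#' @param path Path to a FASTA file.
#' @param permissive Keep records without a terminal AG (with a warning)?
#'
#' @return A tibble with one row per record: `id` (first whitespace-separated
#'   header token), `seq`, `length`, `branch_sites` (list-column of integer
#'   vectors, possibly empty), `canonical_3ss` (logical).
#' @seealso [write_bps_fasta()], [simulate_introns()]
#' @export
read_bps_fasta <- function(path, permissive = FALSE) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("no FASTA records in %s", path))
  headers <- names(set)
  seqs <- chartr("u", "t", chartr("U", "T", toupper(as.character(set))))
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)

  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf(
      "record '%s': sequence contains symbols outside A/C/G/T/N (after U->T)",
      ids[which(bad)[1]]
    ))
  }
  n <- nchar(seqs)
  if (any(n == 0L)) abort(sprintf("record '%s': empty sequence", ids[which(n == 0L)[1]]))

  canonical <- substr(seqs, n - 1L, n) == "AG"
  if (any(!canonical)) {
    if (!permissive) {
      abort(sprintf(
        "record '%s': sequence does not end in the canonical 3'ss AG (use permissive = TRUE to keep it)",
        ids[which(!canonical)[1]]
      ))
    }
    warn(sprintf(
      "%d record(s) without a terminal AG kept (permissive mode): %s",
      sum(!canonical), paste(utils::head(ids[!canonical], 5), collapse = ", ")
    ))
  }

  bp <- lapply(seq_along(headers), function(i) {
    m <- str_match(headers[i], "\\bbp=(-?[0-9]+(?:,-?[0-9]+)*)")[, 2]
    if (is.na(m)) return(integer(0))
    p <- as.integer(strsplit(m, ",", fixed = TRUE)[[1]])
    if (any(p < -n[i] | p > -1L)) {
      abort(sprintf(
        "record '%s': branch site %d outside [-%d, -1]",
        ids[i], p[which(p < -n[i] | p > -1L)[1]], n[i]
      ))
    }
    p
  })

  tibble(
    id = ids, seq = unname(seqs), length = as.integer(n),
    branch_sites = bp, canonical_3ss = unname(canonical)
  )
}

#' Write introns to FASTA with `bp=` branch-site headers
#'
#' The inverse of [read_bps_fasta()]: headers are `id` followed by
#' ` bp=<p1,p2,...>` when the record carries branch sites, so a write/read
#' round trip preserves `id`, `seq` and `branch_sites`.
#'
#' @param introns Intron tibble (`id`, `seq`, and optionally `branch_sites`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bps_fasta <- function(introns, path) {
  check_introns(introns)
  bp <- introns$branch_sites %||% rep(list(integer(0)), nrow(introns))
  headers <- vapply(seq_len(nrow(introns)), function(i) {
    if (length(bp[[i]])) {
      paste0(introns$id[i], " bp=", paste(bp[[i]], collapse = ","))
    } else {
      introns$id[i]
    }
  }, character(1))
  set <- Biostrings::BStringSet(introns$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# Validate the intron-table contract shared by all data-frame-first functions.
check_introns <- function(introns) {
  if (!is.data.frame(introns) || !all(c("id", "seq") %in% names(introns))) {
    abort("`introns` must be a data frame with at least `id` and `seq` columns")
  }
  if (any(grepl("[^ACGTN]", introns$seq))) {
    abort("intron sequences must be uppercase A/C/G/T/N (see read_bps_fasta())")
  }
  invisible(introns)
}
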