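#' Build the hexamer/GUAGUA binding-energy table
#'
#' The U2 snRNA motif GUAGUA base-pairs with the BPS heptamer minus the
#' branch site (or one of its neighbors). Scoring therefore needs the
#' duplex minimum free energy of every RNA hexamer against GUAGUA; this
#' builds the complete 4096-entry table once so downstream scoring is a
#' lookup.
#'
#' Backends:
#' \describe{
#'   \item{`cofold`}{shells out once to `RNAcofold` (ViennaRNA) with default
#'     parameters (37 C, Turner 2004), co-folding `hexamer&GUAGUA`. This is
#'     the reference backend.}
#'   \item{`nn`}{a built-in nearest-neighbor duplex evaluator: the hexamer is
#'     slid against GUAGUA over all antiparallel registers and the best
#'     contiguous helix of Watson-Crick/wobble pairs is summed from the
#'     Turner 2004 stacking free energies plus duplex initiation (+4.10
#'     kcal/mol) and terminal AU/GU penalties (+0.50 each). No bulges or
#'     internal loops, and no dangling-end terms.}
#'   \item{`file`}{reads a previously serialized table (see
#'     [write_energy_table()]).}
#' }
#' In every backend a hexamer with no stable duplex gets 0 kcal/mol, so the
#' energy term of the score degrades gracefully to the pure PSSM score.
#'
#' @param backend `"cofold"`, `"nn"`, or `"file"`.
#' @param path Table path when `backend = "file"`.
#' @param cache Reuse a table already built in this session?
#' @return A `bps_energy_table`: list with `energy` (named numeric over all
#'   4096 RNA hexamers, kcal/mol), `backend_label` and `parameter_note`.
#' @examples
#' tab <- build_energy_table("nn")
#' tab$energy[["UACUAC"]]
#' @export
build_energy_table <- function(backend = c("cofold", "nn", "file"),
                               path = NULL, cache = TRUE) {
  backend <- match.arg(backend)
  key <- paste0("energy_", backend, "_", path %||% "")
  if (cache && !is.null(the[[key]])) return(the[[key]])
  hex <- all_hexamers()
  tab <- switch(backend,
    cofold = {
      exe <- Sys.which("RNAcofold")
      if (!nzchar(exe)) {
        abort(paste(
          "energy backend 'cofold' needs the RNAcofold binary on PATH;",
          "fall back to backend = \"nn\" (built-in nearest-neighbor) or",
          "backend = \"file\" with a serialized table"
        ))
      }
      new_energy_table(
        cofold_energies(hex),
        backend_label = "cofold",
        parameter_note = "RNAcofold default parameters (Turner 2004, 37 C)"
      )
    },
    nn = new_energy_table(
      nn_energies(hex),
      backend_label = "nn",
      parameter_note = "register-scan nearest-neighbor, Turner 2004 stacks, init 4.10, terminal AU/GU 0.50"
    ),
    file = {
      if (is.null(path)) abort("backend = \"file\" needs `path`")
      read_energy_table(path)
    }
  )
  if (cache) the[[key]] <- tab
  tab
}

new_energy_table <- function(energy, backend_label, parameter_note) {
  structure(
    list(energy = energy, backend_label = backend_label,
         parameter_note = parameter_note),
    class = "bps_energy_table"
  )
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "U")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  do.call(paste0, g)
}

cofold_energies <- function(hex, partner = "GUAGUA") {
  inp <- tempfile(fileext = ".seq")
  on.exit(unlink(inp), add = TRUE)
  writeLines(paste0(hex, "&", partner), inp)
  out <- suppressWarnings(
    system2("RNAcofold", c("--noPS"), stdin = inp, stdout = TRUE, stderr = FALSE)
  )
  lines <- out[seq(2L, length(out), by = 2L)]
  e <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", lines))
  if (length(e) != length(hex) || any(is.na(e))) {
    abort("could not parse RNAcofold output")
  }
  stats::setNames(e, hex)
}

# Pair types in the order used by the Turner 2004 stack table: the first
# letter is the 5' base of the top strand, the second its pairing partner.
.pair_types <- c("CG", "GC", "GU", "UG", "AU", "UA")

# Stacking free energies (kcal/mol, 37 C), Turner 2004:
# entry [p1, p2] is the stack 5'-X1 X2-3' / 3'-Y1 Y2-5' with p1 = X1Y1
# closing the helix on the 5' side of the top strand and p2 = X2Y2 next.
.stack37 <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30
), nrow = 6, byrow = TRUE, dimnames = list(.pair_types, .pair_types))

.duplex_init <- 4.10
.terminal_au <- 0.50

# Best contiguous-helix duplex energy of each hexamer against `partner`,
# scanning all antiparallel registers. Returns 0 where no helix of >= 2
# base pairs is stable.
nn_energies <- function(hex, partner = "GUAGUA") {
  top <- strsplit(partner, "", fixed = TRUE)[[1]]
  nt <- length(top)
  vapply(hex, function(h) {
    bot <- strsplit(h, "", fixed = TRUE)[[1]]
    nb <- length(bot)
    best <- 0
    for (cc in 2:(nt + nb)) {
      # register: top i pairs bottom (cc - i)
      i_lo <- max(1L, cc - nb)
      i_hi <- min(nt, cc - 1L)
      if (i_hi <= i_lo) next
      pair <- vapply(i_lo:i_hi, function(i) {
        pt <- paste0(top[i], bot[cc - i])
        if (pt %in% .pair_types) pt else NA_character_
      }, character(1))
      r <- rle(!is.na(pair))
      stop_at <- cumsum(r$lengths)
      for (k in which(r$values & r$lengths >= 2L)) {
        run <- pair[(stop_at[k] - r$lengths[k] + 1L):stop_at[k]]
        e <- .duplex_init + sum(.stack37[cbind(run[-length(run)], run[-1L])])
        if (run[1L] %in% c("AU", "UA", "GU", "UG")) e <- e + .terminal_au
        if (run[length(run)] %in% c("AU", "UA", "GU", "UG")) e <- e + .terminal_au
        if (e < best) best <- e
      }
    }
    # stack sums are exact 2-decimal quantities; drop float accumulation noise
    round(best, 2)
  }, numeric(1))
}

#' Binding energy between a heptamer and GUAGUA with one position deleted
#'
#' `BE(X/X_k)`: position `k` (the branch site, k = 6, or a neighbor,
#' k = 5 or 7) is deleted from the heptamer, T is mapped to U, and the
#' resulting hexamer's duplex energy with GUAGUA is looked up.
#'
#' @param x Character vector of 7-mers (DNA or RNA alphabet).
#' @param k Deleted position, one of 5, 6, 7 (scalar).
#' @param table A `bps_energy_table` from [build_energy_table()].
#' @return Numeric vector, kcal/mol; `NA` for heptamers containing N.
#' @examples
#' tab <- build_energy_table("nn")
#' binding_energy("TACTAAC", 6, tab)
#' @export
binding_energy <- function(x, k, table) {
  if (!inherits(table, "bps_energy_table")) abort("`table` must be a bps_energy_table")
  k <- as.integer(k)
  if (length(k) != 1L || !k %in% 5:7) abort("k must be one of 5, 6, 7")
  if (any(nchar(x) != 7L)) abort("heptamers must have length 7")
  hex <- chartr("T", "U", toupper(paste0(substr(x, 1L, k - 1L), substr(x, k + 1L, 7L))))
  e <- unname(table$energy[hex])
  e[grepl("N", hex, fixed = TRUE)] <- NA_real_
  if (any(is.na(e) & !grepl("N", hex, fixed = TRUE))) {
    abort("hexamer not found in energy table (invalid alphabet?)")
  }
  e
}

#' Serialize / read an energy table
#'
#' TSV with columns `hexamer`, `energy_kcal_mol`, `backend_label`; the
#' parameter note travels in a `# note:` comment line.
#'
#' @param table A `bps_energy_table`.
#' @param path File path.
#' @return `write_energy_table()` returns `path` invisibly;
#'   `read_energy_table()` returns a `bps_energy_table`.
#' @export
write_energy_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# note: ", table$parameter_note), con)
  writeLines("hexamer\tenergy_kcal_mol\tbackend_label", con)
  writeLines(
    paste(names(table$energy), formatC(table$energy, format = "g", digits = 10),
          table$backend_label, sep = "\t"),
    con
  )
  invisible(path)
}

#' @rdname write_energy_table
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("energy table not found: %s", path))
  lines <- readLines(path)
  note <- sub("^# note: ", "", grep("^# note:", lines, value = TRUE)[1])
  tb <- readr::read_tsv(path, comment = "#", col_types = "cdc", progress = FALSE)
  if (!all(c("hexamer", "energy_kcal_mol", "backend_label") %in% names(tb))) {
    abort("energy table must have columns hexamer, energy_kcal_mol, backend_label")
  }
  if (nrow(tb) != 4096L || anyDuplicated(tb$hexamer)) {
    abort(sprintf("energy table must cover all 4096 hexamers once, got %d rows", nrow(tb)))
  }
  new_energy_table(
    stats::setNames(tb$energy_kcal_mol, tb$hexamer),
    backend_label = tb$backend_label[1],
    parameter_note = if (is.na(note)) "" else note
  )
}
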