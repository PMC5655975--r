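#' Construct a branch-point frequency matrix
#'
#' A 4 x 7 matrix of relative nucleotide frequencies over the BPS heptamer
#' (rows A/C/G/T, columns positions 1-7; the branch site is position 6).
#' Columns must each sum to 1: sums within `1e-3` of 1 are renormalized,
#' anything further off is an error. Zero entries are allowed — a zero
#' frequency makes any heptamer carrying that base unscorable (-Inf), which
#' is how a TNA-fixed matrix restricts the search to T at position 4 and A
#' at position 6.
#'
#' @param f Numeric 4 x 7 matrix (or 7 x 4, auto-transposed) with A/C/G/T
#'   dimnames on the base axis.
#' @param source Label recording where the frequencies come from.
#' @return A `bps_matrix`: a 4 x 7 numeric matrix with a `source` attribute.
#' @export
bps_matrix <- function(f, source = "custom") {
  f <- as.matrix(f)
  bases <- c("A", "C", "G", "T")
  if (all(dim(f) == c(7L, 4L)) && !all(dim(f) == c(4L, 7L))) f <- t(f)
  if (!all(dim(f) == c(4L, 7L))) {
    abort(sprintf("frequency matrix must be 4 x 7, got %d x %d", nrow(f), ncol(f)))
  }
  if (!is.null(rownames(f))) {
    if (!setequal(toupper(rownames(f)), bases)) {
      abort("frequency matrix rows must be labelled A, C, G, T")
    }
    f <- f[match(bases, toupper(rownames(f))), , drop = FALSE]
  }
  rownames(f) <- bases
  colnames(f) <- paste0("pos", 1:7)
  storage.mode(f) <- "double"
  if (any(is.na(f)) || any(f < 0)) abort("frequencies must be non-negative and non-missing")
  cs <- colSums(f)
  if (any(abs(cs - 1) > 1e-3)) {
    abort(sprintf(
      "position %d frequencies sum to %.4f (must be 1 within 1e-3)",
      which(abs(cs - 1) > 1e-3)[1], cs[which(abs(cs - 1) > 1e-3)[1]]
    ))
  }
  f <- sweep(f, 2, cs, "/")
  structure(f, source = source, class = c("bps_matrix", "matrix", "array"))
}

#' Read a frequency matrix from TSV
#'
#' Expects either bases on rows (first column `base` with A/C/G/T, columns
#' `pos1`..`pos7`) or the transpose; orientation is detected from the
#' header. See [bps_matrix()] for validation.
#'
#' @param path TSV file path.
#' @param source Label for the matrix; defaults to the file name.
#' @return A `bps_matrix`.
#' @export
read_freq_matrix <- function(path, source = basename(path)) {
  if (!file.exists(path)) abort(sprintf("matrix file not found: %s", path))
  tb <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  first <- names(tb)[1]
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- as.character(tb[[first]])
  if (!is.numeric(m)) abort(sprintf("non-numeric entries in %s", path))
  bps_matrix(m, source = source)
}

#' Write a frequency matrix to TSV
#'
#' @param m A `bps_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_freq_matrix <- function(m, path) {
  tb <- tibble::as_tibble(unclass(m), .name_repair = "minimal")
  tb <- dplyr::bind_cols(tibble(base = rownames(m)), tb)
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Bundled synthetic frequency matrices
#'
#' Returns one of the two matrices shipped with the package. Both are
#' synthetic fixtures (they are not transcriptions of any published table):
#' `"tna_synthetic"` fixes T at position 4 and A at position 6 with a
#' TACTAAC-modal consensus elsewhere, mimicking the structure of a
#' TNA-restricted BPS set; `"degenerate_synthetic"` is strictly positive
#' everywhere with weak preferences, mimicking a large degenerate BPS set.
#'
#' @param name `"tna_synthetic"` or `"degenerate_synthetic"`.
#' @return A `bps_matrix`.
#' @export
bundled_matrix <- function(name = c("tna_synthetic", "degenerate_synthetic")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("bps_matrix_", name, ".tsv"),
                      package = "bpsfinder", mustWork = TRUE)
  read_freq_matrix(path, source = name)
}

#' Position-specific score of heptamers under a frequency matrix
#'
#' The log-likelihood of the heptamer under the per-position frequencies:
#' `S = sum_i log2 f(i, x_i)`. A zero frequency at any position gives
#' `-Inf`, effectively excluding the heptamer.
#'
#' @param x Character vector of 7-mers over A/C/G/T.
#' @param m A `bps_matrix`.
#' @return Numeric vector of scores in bits (may be `-Inf`).
#' @examples
#' m <- bundled_matrix("degenerate_synthetic")
#' position_score("TACTAAC", m)
#' @export
position_score <- function(x, m) {
  if (!inherits(m, "bps_matrix")) m <- bps_matrix(m)
  if (length(x) == 0L) return(numeric(0))
  if (any(nchar(x) != 7L)) abort("heptamers must have length 7")
  if (any(grepl("[^ACGT]", x))) abort("heptamers must be A/C/G/T only")
  ch <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
               ncol = 7L, byrow = TRUE)
  ridx <- match(ch, c("A", "C", "G", "T"))
  fr <- matrix(unclass(m)[cbind(as.vector(ridx), rep(1:7, each = length(x)))],
               ncol = 7L)
  rowSums(log2(fr))
}

#' Information content of a frequency matrix
#'
#' Per-position information content under a uniform background,
#' `IC_i = 2 + sum_x f(i,x) log2 f(i,x)` (with `0 log 0 = 0`), in bits:
#' 0 for a uniform position, 2 for an invariant one.
#'
#' @param m A `bps_matrix`.
#' @return A tibble with columns `position` and `ic`; the sum over positions
#'   is the total information content of the motif.
#' @examples
#' ic <- info_content(bundled_matrix("tna_synthetic"))
#' sum(ic$ic)
#' @export
info_content <- function(m) {
  if (!inherits(m, "bps_matrix")) m <- bps_matrix(m)
  f <- unclass(m)
  term <- ifelse(f > 0, f * log2(f), 0)
  tibble(position = 1:7, ic = 2 + unname(colSums(term)))
}
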