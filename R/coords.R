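#' Convert between 3'ss-relative positions and sequence offsets
#'
#' All intron coordinates in this package are 3'ss-relative and negative:
#' position -1 is the last intron nucleotide (the G of the terminal AG),
#' position -n the first. `bps_offset()` maps a 3'ss-relative position to a
#' 0-based offset from the intron start; `bps_position()` is its inverse.
#'
#' @param p Integer vector of 3'ss-relative positions, each in `[-n, -1]`.
#' @param n Intron length (scalar or vector recycled against `p`).
#' @param offset Integer vector of 0-based offsets, each in `[0, n - 1]`.
#'
#' @return An integer vector: 0-based offsets for `bps_offset()`, negative
#'   3'ss-relative positions for `bps_position()`.
#' @examples
#' bps_offset(-1, 40)  # 39, the last base
#' bps_position(0, 40) # -40, the first base
#' @export
bps_offset <- function(p, n) {
  p <- as.integer(p)
  n <- as.integer(n)
  bad <- p < -n | p > -1L
  if (any(bad)) {
    abort(sprintf(
      "coordinate error: position %d outside [-%d, -1]",
      p[which(bad)[1]], n[if (length(n) > 1L) which(bad)[1] else 1L]
    ))
  }
  as.integer(n + p)
}

#' @rdname bps_offset
#' @export
bps_position <- function(offset, n) {
  offset <- as.integer(offset)
  n <- as.integer(n)
  bad <- offset < 0L | offset > n - 1L
  if (any(bad)) {
    abort(sprintf("coordinate error: offset %d outside [0, n-1]", offset[which(bad)[1]]))
  }
  as.integer(offset - n)
}

# 1-based R string index for a 3'ss-relative position.
pos_idx <- function(p, n) n + p + 1L
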