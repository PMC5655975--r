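#' Scoring configurations for the S* family
#'
#' Each member of the S* family is selected by weight/exponent triples
#' `(P_1..P_3, Q_1..Q_3)` over the three deletable positions k = 5, 6, 7
#' (j = 1, 2, 3 respectively):
#' `S* = S - sum_j P_j * BE(X/X_{j+4}) * f(j+4, X_{j+4})^{Q_j} / sum_j P_j`,
#' with `S` the position-specific score. With all `P_j = 0` the energy term
#' is dropped and `S* = S` (that is `score0`); `score8` activates only the
#' branch-site term k = 6 with `Q_2 = 1`.
#'
#' The 15 named configurations `score0`..`score14` live in an editable TSV
#' (`inst/extdata/score_configs.tsv`): `score1`-`score7` are the seven
#' non-empty P subsets with Q = 0, `score8`-`score14` the same subsets with
#' Q = 1. Only `score0` and `score8` are canonical; the rest are a
#' systematic placeholder family (see the package vignette).
#'
#' @param name A configuration name (`score0`..`score14`) or `"custom"`.
#' @param P,Q Numeric triples in `[0, 1]`, required when `name = "custom"`
#'   and otherwise ignored.
#' @param path Optional path to an alternative config TSV.
#' @return A `score_config`: list with `name`, `P`, `Q`.
#' @examples
#' score_config("score8")
#' score_config("custom", P = c(1, 1, 1), Q = c(0, 0, 0))
#' @export
score_config <- function(name = "score8", P = NULL, Q = NULL, path = NULL) {
  if (name == "custom") {
    if (is.null(P) || is.null(Q)) abort("custom configs need P and Q triples")
  } else {
    cfgs <- score_configs(path)
    row <- cfgs[cfgs$name == name, ]
    if (nrow(row) != 1L) {
      abort(sprintf("unknown score config '%s' (known: %s)",
                    name, paste(cfgs$name, collapse = ", ")))
    }
    P <- c(row$P1, row$P2, row$P3)
    Q <- c(row$Q1, row$Q2, row$Q3)
  }
  P <- as.numeric(P)
  Q <- as.numeric(Q)
  if (length(P) != 3L || length(Q) != 3L ||
      any(P < 0 | P > 1) || any(Q < 0 | Q > 1)) {
    abort("P and Q must be numeric triples in [0, 1]")
  }
  structure(list(name = name, P = P, Q = Q), class = "score_config")
}

#' @rdname score_config
#' @return `score_configs()` returns the full table of named configurations
#'   as a tibble (`name`, `P1`..`P3`, `Q1`..`Q3`).
#' @export
score_configs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "score_configs.tsv",
                                package = "bpsfinder", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cdddddd", progress = FALSE)
}
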