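#' Benchmark data availability
#'
#' The published benchmark (two sets of experimentally verified human
#' introns and their three frequency matrices) is distributed as journal
#' supplementary material and is not redistributed with this package. To
#' reproduce the published comparison, place the files in a directory (by
#' default `inst/extdata/supplementary/` of the installed package, or any
#' directory named by `options(bpsfinder.supplementary_dir = ...)`):
#'
#' * `dataset_s1.fa`, `dataset_s2.fa` — annotated intron FASTA with `bp=`
#'   headers (see [read_bps_fasta()]);
#' * `table_s4.tsv`, `table_s5.tsv`, `table_s6.tsv` — frequency-matrix TSVs
#'   (see [read_freq_matrix()]).
#'
#' `supplementary_status()` reports which files are present;
#' `benchmark_accuracy()` runs the full published protocol (predict with a
#' given matrix and score over the shortened AGEZ at a given L, evaluate
#' against the annotations) on one dataset.
#'
#' @return `supplementary_status()`: a tibble with `file`, `path`, `available`.
#' @export
supplementary_status <- function() {
  dir <- getOption(
    "bpsfinder.supplementary_dir",
    system.file("extdata", "supplementary", package = "bpsfinder")
  )
  files <- c("dataset_s1.fa", "dataset_s2.fa",
             "table_s4.tsv", "table_s5.tsv", "table_s6.tsv")
  paths <- file.path(dir, files)
  tibble(file = files, path = paths, available = file.exists(paths))
}

#' @rdname supplementary_status
#' @param dataset `"s1"` or `"s2"`.
#' @param matrix Matrix file stem, e.g. `"table_s4"`; defaults to the
#'   dataset's own matrix (`s1` -> `table_s4`, `s2` -> `table_s5`).
#' @param config A [score_config()] (default `score8`).
#' @param L AGEZ extension (default 9).
#' @param backend Energy backend (default `"cofold"`, the reference).
#' @return `benchmark_accuracy()`: the [glance()] row of the evaluation,
#'   plus `dataset` and `matrix` columns.
#' @export
benchmark_accuracy <- function(dataset = c("s1", "s2"), matrix = NULL,
                               config = score_config("score8"), L = 9L,
                               backend = "cofold") {
  dataset <- match.arg(dataset)
  matrix <- matrix %||% switch(dataset, s1 = "table_s4", s2 = "table_s5")
  st <- supplementary_status()
  need <- c(paste0("dataset_", dataset, ".fa"), paste0(matrix, ".tsv"))
  missing <- need[!need %in% st$file[st$available]]
  if (length(missing)) {
    abort(paste0(
      "supplementary benchmark data unavailable: missing ",
      paste(missing, collapse = ", "),
      ". See ?supplementary_status for where to place the files."
    ))
  }
  introns <- read_bps_fasta(st$path[st$file == paste0("dataset_", dataset, ".fa")])
  m <- read_freq_matrix(st$path[st$file == paste0(matrix, ".tsv")], source = matrix)
  energy <- if (sum(config$P) > 0) build_energy_table(backend) else NULL
  preds <- predict_branch_points(introns, m, energy, config,
                                 params = agez_params(L = L))
  out <- glance(evaluate_predictions(preds, introns))
  out$dataset <- dataset
  out$matrix <- matrix
  out
}
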