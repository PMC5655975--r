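#' Evaluate branch-point predictions against annotations
#'
#' A prediction is correct iff its branch-site position equals any one of
#' the intron's annotated branch sites. Accuracy is the number of introns
#' with a correct prediction divided by the number of introns, in percent
#' rounded to two decimals.
#'
#' @param predictions Prediction tibble from [predict_branch_points()] (or a
#'   baseline); needs `intron_id` and `branch_pos`.
#' @param introns Annotated intron tibble; every intron must carry at least
#'   one branch site, and ids must match the predictions one to one.
#' @return A `bps_eval` object: list with `verdicts` (per-intron tibble with
#'   `intron_id`, `predicted`, `annotated` list-column, `correct`),
#'   `n_introns`, `n_correct`, `accuracy_percent`. Has [tidy()], [glance()],
#'   `print()` and [ggplot2::autoplot()] methods.
#' @examples
#' introns <- simulate_introns(5, seed = 1)
#' preds <- predict_branch_points(introns, bundled_matrix("tna_synthetic"),
#'                                build_energy_table("nn"))
#' glance(evaluate_predictions(preds, introns))
#' @export
evaluate_predictions <- function(predictions, introns) {
  check_introns(introns)
  if (!all(c("intron_id", "branch_pos") %in% names(predictions))) {
    abort("`predictions` needs columns intron_id and branch_pos")
  }
  if (!"branch_sites" %in% names(introns)) {
    abort("evaluation error: introns carry no branch_sites annotations")
  }
  if (!setequal(predictions$intron_id, introns$id) ||
      nrow(predictions) != nrow(introns)) {
    abort("evaluation error: prediction and intron ids do not match 1:1")
  }
  ann <- introns$branch_sites[match(predictions$intron_id, introns$id)]
  if (any(lengths(ann) == 0L)) {
    abort(sprintf(
      "evaluation error: intron '%s' has no annotated branch site",
      predictions$intron_id[which(lengths(ann) == 0L)[1]]
    ))
  }
  correct <- map_lgl(seq_len(nrow(predictions)), function(i) {
    !is.na(predictions$branch_pos[i]) && predictions$branch_pos[i] %in% ann[[i]]
  })
  verdicts <- tibble(
    intron_id = predictions$intron_id,
    predicted = predictions$branch_pos,
    annotated = ann,
    correct = correct
  )
  structure(
    list(
      verdicts = verdicts,
      n_introns = nrow(verdicts),
      n_correct = sum(correct),
      accuracy_percent = round(100 * sum(correct) / nrow(verdicts), 2)
    ),
    class = "bps_eval"
  )
}

#' @export
print.bps_eval <- function(x, ...) {
  cat(sprintf(
    "Branch-point evaluation: %d/%d introns correct (accuracy %.2f%%)\n",
    x$n_correct, x$n_introns, x$accuracy_percent
  ))
  invisible(x)
}

#' Tidy a branch-point evaluation
#'
#' @param x A `bps_eval` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-intron verdict tibble; `glance()` a
#'   one-row summary (`n_introns`, `n_correct`, `accuracy_percent`).
#' @method tidy bps_eval
#' @export
tidy.bps_eval <- function(x, ...) x$verdicts

#' @rdname tidy.bps_eval
#' @method glance bps_eval
#' @export
glance.bps_eval <- function(x, ...) {
  tibble(
    n_introns = x$n_introns,
    n_correct = x$n_correct,
    accuracy_percent = x$accuracy_percent
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
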