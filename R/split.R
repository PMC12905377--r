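#' Stratified train/test split
#'
#' Splits cell indices into train and test sets in a (1 - test_fraction) :
#' test_fraction ratio, stratified by class: each class contributes
#' `round(n_class * test_fraction)` test cells, so per-class test
#' proportions match the global fraction within one cell. Deterministic
#' given the seed.
#'
#' @param labels Class label per cell (character or factor), or a
#'   [trace_matrix()] whose `meta$group` is used.
#' @param test_fraction Fraction of cells held out (default 0.2).
#' @param seed RNG seed.
#'
#' @return A `split_spec` object with integer fields `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  if (inherits(labels, "trace_matrix")) labels <- labels$meta$group
  labels <- as.character(labels)
  check_scalar_number(test_fraction, "test_fraction", min = 0, max = 1)
  counts <- table(labels)
  if (any(counts < 2L)) {
    abort(sprintf("Every class needs >= 2 cells; too small: %s.",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  }
  test <- integer(0)
  withr::with_seed(seed, {
    for (cl in sort(names(counts))) {
      idx <- which(labels == cl)
      n_test <- as.integer(round(length(idx) * test_fraction))
      if (n_test > 0L) test <- c(test, sort(sample(idx, n_test)))
    }
  })
  test <- sort(test)
  train <- setdiff(seq_along(labels), test)
  structure(
    list(train = train, test = test, test_fraction = test_fraction,
         stratified = TRUE, seed = as.integer(seed), n = length(labels)),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test (test_fraction=%.2f, seed=%d)\n",
              length(x$train), length(x$test), x$test_fraction, x$seed))
  invisible(x)
}
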