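#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate select filter arrange group_by summarise ungroup
#'   bind_rows left_join across all_of n
#' @importFrom purrr map map_dfr imap imap_dfr
#' @importFrom stats rnorm runif rbinom prcomp predict sd var
#' @importFrom utils head
NULL

# Deterministic per-stage seed fan-out from one master seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, is.finite(master_seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master_seed) %% 1000003) * 2011 + h %% 65011) %% 2147483646L + 1L
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, min, max, x))
  }
  invisible(x)
}

# Accept a trace_matrix or a bare numeric matrix and return the value matrix.
as_trace_values <- function(x) {
  if (inherits(x, "trace_matrix")) return(x$values)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("Expected a trace_matrix or a numeric matrix.")
  }
  x
}

trace_groups <- function(x) {
  if (inherits(x, "trace_matrix")) x$meta$group else NULL
}
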