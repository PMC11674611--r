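# Internal argument checks shared across the package.

stop_hbnet <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "hbnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_hbnet(sprintf("`%s` must be a single finite number", name), "hbnet_argument_error")
  if (positive && x <= 0)
    stop_hbnet(sprintf("`%s` must be positive", name), "hbnet_argument_error")
  if (nonneg && x < 0)
    stop_hbnet(sprintf("`%s` must be nonnegative", name), "hbnet_argument_error")
  invisible(x)
}

check_matrix <- function(x, name, finite = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_hbnet(sprintf("`%s` must be a numeric matrix", name), "hbnet_argument_error")
  if (finite && !all(is.finite(x)))
    stop_hbnet(sprintf("`%s` contains non-finite values", name), "hbnet_data_error")
  invisible(x)
}

# Restore RNG state on exit so seeded helpers do not perturb the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
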