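#' @keywords internal
"_PACKAGE"

# -- input checking helpers ---------------------------------------------------

stop_config <- function(...) {
  stop(structure(
    class = c("hbshift_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_feature <- function(...) {
  stop(structure(
    class = c("hbshift_feature_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) {
    stop_config(sprintf("'%s' must be a scalar in [%s, %s], got: %s",
                        name, format(lower), format(upper),
                        paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the previous
#' RNG state afterwards, so library functions never disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  check_scalar(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a per-stage sub-seed from a master seed
#'
#' Deterministic mixing keeps every stage of a pipeline on an independent
#' stream while remaining reproducible from one master seed. Result is kept
#' below 2^31 - 1.
#'
#' @param master Master integer seed.
#' @param offset Stage index (small integer).
#' @return Integer seed.
#' @export
derive_seed <- function(master, offset) {
  check_scalar(master, "master")
  check_scalar(offset, "offset")
  as.integer((as.double(master) * 7919 + as.double(offset) * 104729) %%
               2147483629)
}
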