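# Internal helpers: error conditions, seeded evaluation, fast row/column medians.

pt_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pt_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

pt_validation_error <- function(message) pt_error(message, "pt_validation_error")
pt_parse_error <- function(message) {
  pt_error(message, c("pt_parse_error", "pt_validation_error"))
}
pt_config_error <- function(message) {
  pt_error(message, c("pt_config_error", "pt_validation_error"))
}
pt_io_error <- function(message) pt_error(message, "pt_io_error")

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the previous global
#' RNG state on exit, so seeded package functions never disturb the caller's
#' random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    pt_validation_error("'seed' must be a single finite integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

# Column medians of a numeric matrix, vectorized via a single radix order.
# Used where apply(m, 2, median) would dominate runtime (millions of cells).
col_medians <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  if (nc == 0L) return(numeric(0))
  if (nr == 0L) return(rep(NA_real_, nc))
  o <- order(col(m), m)
  s <- matrix(m[o], nrow = nr)
  k <- nr %/% 2L
  if (nr %% 2L == 1L) {
    s[k + 1L, ]
  } else {
    lo <- s[k, ]
    hi <- s[k + 1L, ]
    out <- (lo + hi) / 2
    out[lo == -Inf & hi == Inf] <- 0
    out
  }
}

row_medians <- function(m) col_medians(t(m))

# median on the extended real line; for even length the mean of the two
# central order statistics, with the (-Inf, Inf) central pair defined as 0.
median_extended <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  s <- sort(x)                       # Inf sorts; NA not expected upstream
  if (n %% 2L == 1L) {
    s[(n + 1L) %/% 2L]
  } else {
    lo <- s[n %/% 2L]
    hi <- s[n %/% 2L + 1L]
    if (lo == -Inf && hi == Inf) 0 else (lo + hi) / 2
  }
}
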