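# Internal helpers shared across modules.

# Validation: stop with a classed condition so callers/tests can catch
# "sheetloc_validation" specifically.
stop_invalid <- function(msg) {
  rlang::abort(msg, class = "sheetloc_validation")
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    stop_invalid(sprintf("`%s` = %g is outside its valid range", name, x))
  }
  invisible(x)
}

# Deterministic local RNG: runs `expr` under `seed` and restores the caller's
# RNG state afterwards, so seeded helpers do not perturb the session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    check_number(seed, "seed")
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
  }
  force(expr)
}

# Centered moving average with edge shrinkage (window truncated at the ends,
# never NA). `window` is in samples.
moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n == 0L) return(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Linear interpolation of a trace column onto arbitrary frames; constant
# extrapolation beyond the trace support.
interp_trace <- function(node_frames, node_values, frames) {
  if (length(node_frames) == 1L) return(rep(node_values, length(frames)))
  stats::approx(node_frames, node_values, xout = frames, rule = 2)$y
}
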