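# Internal helpers shared across modules.

.fail <- function(...) stop(..., call. = FALSE)

# Evaluate `expr` with a locally set RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE,
                          integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .fail(sprintf("'%s' must be a single finite number", name))
  if (integer && x != round(x))
    .fail(sprintf("'%s' must be an integer", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    .fail(sprintf("'%s' = %g is outside its valid range", name, x))
  invisible(x)
}

# cumsum down columns, robust to single-row matrices (apply() would drop dims)
.colcumsum <- function(x) {
  if (nrow(x) == 1L) return(x)
  apply(x, 2L, cumsum)
}

# Moving-window sum of an h x w window centred on each element, window
# shrinking at the borders (no padding). Works for real and complex matrices.
.boxsum <- function(x, h, w) {
  d <- nrow(x)
  p <- ncol(x)
  h <- min(h, d)
  w <- min(w, p)
  if (h > 1L) {
    rlo <- (h - 1L) %/% 2L
    rhi <- h - 1L - rlo
    cs <- rbind(0, .colcumsum(x))
    i <- seq_len(d)
    x <- cs[pmin(d, i + rhi) + 1L, , drop = FALSE] -
      cs[pmax(1L, i - rlo), , drop = FALSE]
  }
  if (w > 1L) {
    clo <- (w - 1L) %/% 2L
    chi <- w - 1L - clo
    cs <- rbind(0, .colcumsum(t(x)))
    j <- seq_len(p)
    x <- t(cs[pmin(p, j + chi) + 1L, , drop = FALSE] -
             cs[pmax(1L, j - clo), , drop = FALSE])
  }
  x
}
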