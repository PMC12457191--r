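# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded tie-breaking and sampling inside the
#' package never perturbs user-level randomness.
#'
#' @param seed Integer seed (must be < 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer", call. = FALSE)
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
  expr
}

# Deterministic substream seeds: one top-level seed fans out into named
# substreams (tie-breaking, block sampling, simulation) without collisions.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Clamp values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

check_prob <- function(x, name, allow_one = TRUE) {
  bad <- !is.finite(x) | x <= 0 | (if (allow_one) x > 1 else x >= 1)
  if (any(bad)) {
    stop(sprintf("'%s' must lie in (0,1%s]; %d value(s) violate this (first at row %d)",
                 name, if (allow_one) "" else ")", sum(bad), which(bad)[1L]),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Vectorized bilinear interpolation of a matrix `z` (length(gx) x length(gy))
# at query points (x, y). Queries outside the grid clamp to the nearest edge.
interp_bilinear <- function(gx, gy, z, x, y) {
  x <- clamp(x, gx[1L], gx[length(gx)])
  y <- clamp(y, gy[1L], gy[length(gy)])
  ix <- findInterval(x, gx, rightmost.closed = TRUE)
  iy <- findInterval(y, gy, rightmost.closed = TRUE)
  ix <- clamp(ix, 1L, length(gx) - 1L)
  iy <- clamp(iy, 1L, length(gy) - 1L)
  wx <- (x - gx[ix]) / (gx[ix + 1L] - gx[ix])
  wy <- (y - gy[iy]) / (gy[iy + 1L] - gy[iy])
  z00 <- z[cbind(ix, iy)]
  z10 <- z[cbind(ix + 1L, iy)]
  z01 <- z[cbind(ix, iy + 1L)]
  z11 <- z[cbind(ix + 1L, iy + 1L)]
  (1 - wx) * (1 - wy) * z00 + wx * (1 - wy) * z10 +
    (1 - wx) * wy * z01 + wx * wy * z11
}

# Linear interpolation with edge clamping.
interp_linear <- function(gx, gz, x) {
  stats::approx(gx, gz, xout = clamp(x, gx[1L], gx[length(gx)]),
                rule = 2, ties = "ordered")$y
}

# Trapezoid rule.
trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + y[-1L])) / 2
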