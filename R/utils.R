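# Internal helpers: classed conditions, seeded RNG streams, weighted moments.

gppiav_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "gppiav_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

validation_error <- function(message, ...) {
  gppiav_error("gppiav_validation_error", message, ...)
}

format_error <- function(message, ...) {
  gppiav_error("gppiav_format_error", message, ...)
}

io_error <- function(message, ...) {
  gppiav_error("gppiav_io_error", message, ...)
}

#' Derive an independent RNG stream seed from a master seed and a label
#'
#' Each random field of the synthetic world draws from its own stream keyed
#' by `(seed, name)`, so adding or reordering fields never perturbs the
#' others. The derived seed stays below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param name Character label of the stream.
#' @return An integer seed.
#' @keywords internal
stream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- as.double(seed %% 2147483647L)
  for (k in seq_along(codes)) {
    h <- (h * 31 + codes[k] * k) %% 2147483563
  }
  as.integer((h + 1) %% 2147483563)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

#' Weighted Pearson correlation
#'
#' Correlation of `x` and `y` under non-negative weights `w`, computed from
#' explicit weighted moments. Returns `NA` when fewer than 3 observations
#' carry positive weight or when either weighted variance vanishes.
#'
#' @param x,y Numeric vectors.
#' @param w Non-negative weights, same length.
#' @return Scalar correlation in \[-1, 1\], or `NA`.
#' @export
weighted_pearson <- function(x, y, w) {
  keep <- is.finite(x) & is.finite(y) & is.finite(w) & w > 0
  if (sum(keep) < 3) return(NA_real_)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cxy <- sum(w * (x - mx) * (y - my)) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  if (vx <= 0 || vy <= 0) return(NA_real_)
  cxy / sqrt(vx * vy)
}

weighted_mean_sd <- function(x, w) {
  keep <- is.finite(x) & is.finite(w) & w > 0
  if (!any(keep)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
  x <- x[keep]; w <- w[keep]
  m <- sum(w * x) / sum(w)
  s <- sqrt(sum(w * (x - m)^2) / sum(w))
  c(mean = m, sd = s, n = sum(keep))
}

# Population standard deviation (divide by N).
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}
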