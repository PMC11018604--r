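#' Wrap angles to [0, 2*pi)
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval [0, 2*pi).
#' @export
wrap_angle <- function(theta) {
  out <- theta %% (2 * pi)
  # %% can return 2*pi for tiny negative inputs due to float rounding
  out[out >= 2 * pi] <- 0
  out
}

#' Signed circular difference a - b in (-pi, pi]
#'
#' @param a,b angles in radians.
#' @return signed difference wrapped to (-pi, pi].
#' @export
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

#' Absolute circular distance between two angles
#' @param a,b angles in radians.
#' @return non-negative distance in [0, pi].
#' @export
circ_dist <- function(a, b) abs(circ_diff(a, b))

#' Circular mean of angles
#' @param theta angles in radians.
#' @param w optional non-negative weights.
#' @return mean direction in [0, 2*pi), or NA if the resultant is ~0.
#' @export
circ_mean <- function(theta, w = NULL) {
  if (length(theta) == 0L) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(theta))
  s <- sum(w * sin(theta))
  c_ <- sum(w * cos(theta))
  if (sqrt(s^2 + c_^2) < 1e-12 * sum(w)) return(NA_real_)
  wrap_angle(atan2(s, c_))
}

#' Circular standard deviation, sqrt(-2 log R)
#'
#' R is the mean resultant length. Zero dispersion gives 0; a uniform
#' distribution diverges, so R ~ 0 returns Inf.
#' @param theta angles in radians.
#' @return circular SD in radians.
#' @export
circ_sd <- function(theta) {
  n <- length(theta)
  if (n == 0L) return(NA_real_)
  R <- sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
  if (R <= 0) return(Inf)
  sqrt(pmax(0, -2 * log(R)))
}

# Run code with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Unwrap a wrapped angle series to a continuous one (cumulative).
unwrap_angle <- function(theta) {
  if (length(theta) <= 1L) return(theta)
  d <- circ_diff(theta[-1L], theta[-length(theta)])
  theta[1L] + c(0, cumsum(d))
}

# Boxcar smooth with edge shrinkage (window truncated at the borders).
boxcar <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
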