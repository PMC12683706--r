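# von Mises utilities. No circular-statistics dependency is used; the
# density, the closed-form MLE approximation for kappa (Best & Fisher A1
# inverse) and the Best-Fisher rejection sampler are standard results.

#' Wrap angles to (-pi, pi]
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' von Mises log-density
#' @param x angle (rad).
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0); `kappa = 0` is the circular uniform.
#' @return log-density values.
#' @export
dvonmises <- function(x, mu, kappa, log = FALSE) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  ld <- kappa * cos(x - mu) - (log(2 * pi) + log_bessel_i0(kappa))
  if (log) ld else exp(ld)
}

# log I0: exponentially scaled Bessel for moderate kappa; asymptotic
# expansion for large kappa (besselI slows and overflows there)
log_bessel_i0 <- function(kappa) {
  ifelse(kappa < 50,
         log(besselI(pmin(kappa, 50), 0, expon.scaled = TRUE)) +
           pmin(kappa, 50),
         kappa - 0.5 * log(2 * pi * pmax(kappa, 50)) +
           log1p(1 / (8 * pmax(kappa, 50)) +
                   9 / (128 * pmax(kappa, 50)^2)))
}

# A1(kappa) = I1/I0; its inverse maps mean resultant length to kappa
# (Best & Fisher 1981 approximation, as used by circular-statistics code).
a1inv <- function(R) {
  ifelse(R < 0.53, 2 * R + R^3 + 5 * R^5 / 6,
         ifelse(R < 0.85, -0.4 + 1.39 * R + 0.43 / (1 - R),
                1 / (R^3 - 4 * R^2 + 3 * R)))
}

#' von Mises maximum-likelihood fit
#' @param x angles (rad); `NA` dropped.
#' @return list with `mu` (rad) and `kappa`.
#' @export
fit_vonmises <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite angles")
  C <- mean(cos(x)); S <- mean(sin(x))
  R <- sqrt(C^2 + S^2)
  list(mu = atan2(S, C), kappa = max(0, a1inv(R)))
}

#' von Mises random angles (Best-Fisher rejection sampler)
#' @param n number of draws.
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-8) return(wrap_angle(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok]))))
  }
  wrap_angle(out[seq_len(n)] + mu)
}

# circular SD (rad) -> kappa, used to map restart draws of "turning-angle
# SD" onto the concentration parameter: sd = sqrt(-2 log Rbar).
circular_sd_to_kappa <- function(s) {
  s <- pmax(s, 0.01)
  a1inv(pmin(exp(-s^2 / 2), 0.999999))
}
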