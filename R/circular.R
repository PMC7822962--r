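#' Wrap a raw orientation difference onto the signed-error half-circle
#'
#' Orientation is 180-degree periodic, so a report-minus-target difference is
#' only defined up to a multiple of 180. `wrap_error()` maps any finite
#' difference onto the canonical signed-error interval (-90, +90], with the
#' boundary convention that -90 and +90 denote the same error and are
#' reported as +90.
#'
#' @param x numeric vector of raw differences in degrees.
#' @return numeric vector of wrapped errors in (-90, +90].
#' @examples
#' wrap_error(170)   # -10
#' wrap_error(-90)   # +90
#' @export
wrap_error <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be a finite numeric vector", call. = FALSE)
  }
  w <- ((x + 90) %% 180) - 90
  w[w == -90] <- 90
  w
}

#' Signed circular difference between two orientations
#'
#' Computes `a - b` on the 180-degree orientation circle, i.e. the estimation
#' error when `a` is a reported orientation and `b` the true target
#' orientation (zero indicates the target value).
#'
#' @param a,b numeric vectors of orientations in degrees (any representative
#'   of the 180-periodic equivalence class is accepted).
#' @return signed errors in (-90, +90], see [wrap_error()].
#' @examples
#' circ_diff(10, 170)  # +20
#' @export
circ_diff <- function(a, b) {
  wrap_error(a - b)
}

#' Wrap an orientation onto the canonical (0, 180] range
#'
#' @param x numeric vector of orientations in degrees.
#' @return orientations in (0, 180].
#' @export
wrap_ori <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be a finite numeric vector", call. = FALSE)
  }
  w <- x %% 180
  w[w == 0] <- 180
  w
}

# Orientation data are handled by angle doubling: an orientation error of
# theta degrees on the half circle corresponds to 2*theta degrees
# (theta * pi / 90 radians) on a full circle, where the von Mises
# distribution lives.
.deg2double <- function(theta) theta * pi / 90

#' Convert between report variability sigma and von Mises concentration
#'
#' The report-noise component is a von Mises distribution on the
#' angle-doubled circle with concentration `kappa`. Its spread is
#' parameterised by `sigma`, the circular standard deviation of the
#' doubled-angle distribution mapped back to orientation degrees:
#' `sigma = (90/pi) * sqrt(-2 * log(I1(kappa)/I0(kappa)))`, where `I0`, `I1`
#' are modified Bessel functions. `kappa_to_sigma()` evaluates this closed
#' form; `sigma_to_kappa()` inverts it numerically to better than 1e-8
#' degrees. `kappa` is strictly decreasing in `sigma`; `kappa -> 0` is the
#' uniform limit (`sigma -> Inf`).
#'
#' @param sigma numeric vector, report variability in degrees, > 0.
#' @param kappa numeric vector, concentration, >= 0.
#' @return `sigma_to_kappa()`: concentrations; `kappa_to_sigma()`: degrees.
#' @examples
#' kappa_to_sigma(sigma_to_kappa(15))  # 15
#' @export
sigma_to_kappa <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be finite and > 0", call. = FALSE)
  }
  # kappa is bracketed on a log grid; kappa_to_sigma is strictly decreasing.
  # besselI underflows above ~1e5, which still covers sigma down to ~0.1 deg.
  lo <- 1e-12
  hi <- 9e4
  if (any(sigma < kappa_to_sigma(hi))) {
    stop("`sigma` too small to invert (below ~0.1 degrees)", call. = FALSE)
  }
  vapply(sigma, function(s) {
    r <- stats::uniroot(
      function(lk) kappa_to_sigma(exp(lk)) - s,
      interval = c(log(lo), log(hi)),
      tol = 1e-13
    )
    exp(r$root)
  }, numeric(1))
}

#' @rdname sigma_to_kappa
#' @export
kappa_to_sigma <- function(kappa) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa < 0)) {
    stop("`kappa` must be finite and >= 0", call. = FALSE)
  }
  # mean resultant length of the doubled-angle von Mises
  r <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  out <- rep(Inf, length(kappa))
  pos <- r > 0
  out[pos] <- (90 / pi) * sqrt(-2 * log(r[pos]))
  out
}

#' Von Mises density on the 180-degree orientation circle
#'
#' Density of the zero-mean report-noise component: a von Mises on the
#' angle-doubled circle, expressed per degree of orientation so it
#' integrates to 1 over any 180-degree span:
#' `f(theta) = exp(kappa * cos(pi * theta / 90)) / (180 * I0(kappa))`.
#'
#' @param theta numeric vector of signed errors in degrees.
#' @param sigma report variability in degrees (scalar), > 0.
#' @return density per degree, same length as `theta`.
#' @export
vm_density <- function(theta, sigma) {
  if (length(sigma) != 1L) stop("`sigma` must be a scalar", call. = FALSE)
  kappa <- sigma_to_kappa(sigma)
  vm_density_kappa(theta, kappa)
}

# density given concentration directly; exp-scaled Bessel keeps large kappa
# finite: exp(k*cos) / I0(k) = exp(k*(cos - 1)) / (I0(k) * exp(-k))
vm_density_kappa <- function(theta, kappa) {
  exp(kappa * (cos(.deg2double(theta)) - 1)) /
    (180 * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Circular and linear moments of signed orientation errors
#'
#' Computes both the circular moments (on the doubled-angle circle, mapped
#' back to orientation degrees) and the plain linear moments of a set of
#' signed errors. Errors in a well-behaved estimation data set live well
#' inside (-90, 90], where the two nearly coincide; both are exposed so the
#' precision summary can use either.
#'
#' @param errors numeric vector of signed errors in degrees, length >= 2.
#' @return a list with `n`, `mean`, `sd`, `variance` (linear, degrees) and
#'   `circ_mean`, `circ_sd`, `circ_variance` (circular, degrees).
#' @examples
#' circ_moments(c(-5, 5))$mean  # 0
#' @export
circ_moments <- function(errors) {
  if (!is.numeric(errors) || length(errors) < 2L || any(!is.finite(errors))) {
    stop("`errors` must be a finite numeric vector of length >= 2",
         call. = FALSE)
  }
  a <- .deg2double(errors)
  cbar <- mean(cos(a))
  sbar <- mean(sin(a))
  rbar <- sqrt(cbar^2 + sbar^2)
  circ_mean <- wrap_error(atan2(sbar, cbar) * 90 / pi)
  circ_sd <- if (rbar > 0) (90 / pi) * sqrt(-2 * log(rbar)) else Inf
  list(
    n = length(errors),
    mean = mean(errors),
    sd = stats::sd(errors),
    variance = stats::var(errors),
    circ_mean = circ_mean,
    circ_sd = circ_sd,
    circ_variance = circ_sd^2
  )
}

#' Sample zero-mean von Mises report noise in orientation degrees
#'
#' Draws from the report-noise distribution whose density is
#' [vm_density()]: a von Mises on the doubled-angle circle, returned as
#' signed orientation errors in (-90, +90]. Uses the Best-Fisher
#' wrapped-Cauchy envelope rejection sampler.
#'
#' @param n number of draws.
#' @param sigma report variability in degrees, > 0.
#' @return numeric vector of length `n`, errors in degrees.
#' @export
rvm_deg <- function(n, sigma) {
  if (length(sigma) != 1L) stop("`sigma` must be a scalar", call. = FALSE)
  kappa <- sigma_to_kappa(sigma)
  wrap_error(.rvm_rad(n, kappa) * 90 / pi)
}

# Best & Fisher (1979) rejection sampler for von Mises(0, kappa) on (-pi, pi]
.rvm_rad <- function(n, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.5) + 8L
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(stats::runif(sum(keep)) - 0.5) *
      acos(pmax(pmin(f[keep], 1), -1))
    out <- c(out, theta)
  }
  out[seq_len(n)]
}
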