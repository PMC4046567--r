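# Forward physics of the four-pulse DEER experiment: dipolar kernel,
# Gaussian-mixture distance distribution, exponential intermolecular
# background, and the composite signal model.

# Dipolar coupling constant for a nitroxide pair (g ~ 2), MHz * nm^3.
# omega_dd(r) = 2*pi*D/r^3 in rad/us when r is in nm.
.DIPOLAR_D <- 52.04

#' Default distance grid
#'
#' Grid on which distance distributions are evaluated and the kernel
#' quadrature is carried out: 1.0 to 10.0 nm in 0.02 nm steps. Mixture
#' components are truncated to this range and renormalized on it.
#'
#' @return Numeric vector of distances (nm).
#' @export
default_r_grid <- function() seq(1.0, 10.0, by = 0.02)

#' Gaussian component of a distance distribution
#'
#' @param center Mean distance r0 in nm, within \[1, 10\].
#' @param width Standard deviation in nm, within \[0.02, 1.5\].
#' @param weight Non-negative population weight (normalized at the
#'   distribution level).
#' @return Object of class `gaussian_component`.
#' @export
gaussian_component <- function(center, width, weight = 1) {
  stopifnot(is.numeric(center), length(center) == 1L,
            is.numeric(width), length(width) == 1L,
            is.numeric(weight), length(weight) == 1L)
  if (!is.finite(center) || center < 1.0 || center > 10.0)
    stop("component center must lie in [1, 10] nm, got ", center)
  if (!is.finite(width) || width < 0.02 || width > 1.5)
    stop("component width must lie in [0.02, 1.5] nm, got ", width)
  if (!is.finite(weight) || weight < 0)
    stop("component weight must be non-negative")
  structure(list(center = center, width = width, weight = weight),
            class = "gaussian_component")
}

#' Gaussian-mixture distance distribution
#'
#' P(r) is a sum of Gaussians; weights are normalized to sum to one at
#' construction.
#'
#' @param ... `gaussian_component` objects, or a single list of them.
#' @return Object of class `distance_distribution`.
#' @export
distance_distribution <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && !inherits(comps[[1L]], "gaussian_component"))
    comps <- comps[[1L]]
  if (length(comps) < 1L) stop("at least one Gaussian component is required")
  ok <- vapply(comps, inherits, logical(1), "gaussian_component")
  if (!all(ok)) stop("all arguments must be gaussian_component objects")
  w <- vapply(comps, `[[`, numeric(1), "weight")
  if (sum(w) <= 0) stop("component weights must not all be zero")
  w <- w / sum(w)
  for (i in seq_along(comps)) comps[[i]]$weight <- w[i]
  structure(list(components = comps), class = "distance_distribution")
}

#' Intermolecular background model
#'
#' Homogeneous three-dimensional distribution of neighbouring molecules
#' gives a pure exponential background B(t) = exp(-k t); `rate` is the
#' log-signal slope k in 1/us. The dimension is fixed at 3 and is not a
#' fit parameter.
#'
#' @param rate Non-negative decay rate k (1/us).
#' @return Object of class `background_model`.
#' @export
background_model <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L)
  if (!is.finite(rate) || rate < 0) stop("background rate must be >= 0")
  structure(list(rate = rate, dimension = 3L), class = "background_model")
}

#' Composite DEER signal model
#'
#' V(t) = \[(1 - lambda) + lambda F(t)\] B(t), where F is the form factor of
#' the distance distribution, lambda the modulation depth and B the
#' intermolecular background.
#'
#' @param distribution A `distance_distribution`.
#' @param depth Modulation depth lambda in \[0, 1\].
#' @param background A `background_model`.
#' @return Object of class `signal_model`.
#' @export
signal_model <- function(distribution, depth, background) {
  stopifnot(inherits(distribution, "distance_distribution"),
            inherits(background, "background_model"),
            is.numeric(depth), length(depth) == 1L)
  if (!is.finite(depth) || depth < 0 || depth > 1)
    stop("modulation depth must lie in [0, 1]")
  structure(list(distribution = distribution, depth = depth,
                 background = background), class = "signal_model")
}

# Dipolar angular frequency (rad/us) at distance r (nm).
omega_dd <- function(r) 2 * pi * .DIPOLAR_D / r^3

# Kernel as a function of the dimensionless dipolar phase phi = omega*t,
# closed form via Fresnel integrals:
#   K = [cos(phi) C(z) + sin(phi) S(z)] / z,  z = sqrt(6 phi / pi).
# Small-phi series K = 1 - (2/5) phi^2 + O(phi^4) avoids 0/0.
kernel_of_phase <- function(phi) {
  out <- phi
  small <- phi < 1e-4
  if (any(!small)) {
    p <- phi[!small]
    z <- sqrt(6 * p / pi)
    out[!small] <- (cos(p) * pracma::fresnelC(z) +
                    sin(p) * pracma::fresnelS(z)) / z
  }
  if (any(small)) {
    p <- phi[small]
    out[small] <- 1 - 0.4 * p^2
  }
  out
}

# Gauss-Legendre nodes and weights on [0, 1], all roots refined at once by
# Newton iteration on the three-term recurrence (vectorized; handles the
# 1e4-node oracle in about a second, where per-root loops take minutes).
gauss_legendre_01 <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  m <- (n + 1L) %/% 2L
  x <- cos(pi * (seq_len(m) - 0.25) / (n + 0.5))
  pp <- x
  for (iter in 1:100) {
    p1 <- rep(1, m); p2 <- rep(0, m)
    for (k in seq_len(n)) {
      p3 <- p2; p2 <- p1
      p1 <- ((2 * k - 1) * x * p2 - (k - 1) * p3) / k
    }
    pp <- n * (x * p1 - p2) / (x^2 - 1)
    dx <- p1 / pp
    x <- x - dx
    if (max(abs(dx)) < 1e-15) break
  }
  w <- 2 / ((1 - x^2) * pp^2)
  if (n %% 2L == 1L) {
    # odd n: the m-th root is the centre x = 0, present only once
    x[m] <- 0
    xf <- c(-rev(x[-m]), x)
    wf <- c(rev(w[-m]), w)
  } else {
    xf <- c(-rev(x), x)
    wf <- c(rev(w), w)
  }
  list(x = (xf + 1) / 2, w = wf / 2)
}

#' Dipolar kernel K(t, r)
#'
#' Orientation-averaged two-spin dipolar signal,
#' K(t, r) = integral over x in \[0,1\] of cos\[(1 - 3 x^2) omega_dd(r) t\],
#' with omega_dd = 2 pi D / r^3 and D = 52.04 MHz nm^3. Evaluated either by
#' the Fresnel-integral closed form or by Gauss-Legendre quadrature of the
#' angular integral.
#'
#' @param t Time(s) in us, non-negative.
#' @param r Distance(s) in nm, positive.
#' @param method `"fresnel"` (closed form, default) or `"quadrature"`.
#' @param nodes Number of Gauss-Legendre nodes for `method = "quadrature"`.
#' @return If both `t` and `r` have length > 1, a `length(t)` x `length(r)`
#'   matrix; otherwise a vector.
#' @export
dipolar_kernel <- function(t, r, method = c("fresnel", "quadrature"),
                           nodes = 1000L) {
  method <- match.arg(method)
  stopifnot(is.numeric(t), is.numeric(r))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be finite and > 0")
  phi <- outer(t, omega_dd(r))
  K <- if (method == "fresnel") {
    kernel_of_phase(phi)
  } else {
    gl <- gauss_legendre_01(nodes)
    a <- 1 - 3 * gl$x^2
    pv <- as.vector(phi)
    kv <- numeric(length(pv))
    chunk <- max(1L, as.integer(2e6 / nodes))
    for (s in seq(1L, length(pv), by = chunk)) {
      ix <- s:min(s + chunk - 1L, length(pv))
      kv[ix] <- cos(pv[ix] %o% a) %*% gl$w
    }
    matrix(kv, nrow = nrow(phi))
  }
  if (length(t) > 1L && length(r) > 1L) K else drop(K)
}

# Kernel matrix cache: fits re-use the (t-grid, r-grid) kernel across
# starts, traces and replicates. Cached values are the exact matrices, so
# results are bit-identical with and without the cache.
.kernel_cache <- new.env(parent = emptyenv())

grid_key <- function(x) {
  paste(length(x),
        sprintf("%.17g", x[1L]),
        sprintf("%.17g", x[length(x)]),
        sprintf("%.17g", sum(x)),
        sep = ":")
}

#' Kernel matrix on a (t, r) grid, with caching
#'
#' @param t Time grid (us). @param r Distance grid (nm).
#' @param use_cache Re-use a previously computed matrix for the same grids.
#' @return `length(t)` x `length(r)` matrix.
#' @export
kernel_matrix <- function(t, r = default_r_grid(), use_cache = TRUE) {
  key <- paste(grid_key(t), grid_key(r), sep = "|")
  if (use_cache && !is.null(.kernel_cache[[key]]))
    return(.kernel_cache[[key]])
  K <- kernel_of_phase(outer(t, omega_dd(r)))
  if (!is.matrix(K)) K <- matrix(K, nrow = length(t))
  if (use_cache) .kernel_cache[[key]] <- K
  K
}

# Trapezoidal quadrature weights for an increasing grid.
trapz_weights <- function(x) {
  n <- length(x)
  d <- diff(x)
  c(d[1L] / 2, (d[-(n - 1L)] + d[-1L]) / 2, d[n - 1L] / 2)
}

#' Evaluate a distance distribution on a grid
#'
#' The Gaussian mixture is truncated to the grid range and renormalized so
#' its trapezoidal integral is one.
#'
#' @param dist A `distance_distribution`.
#' @param r_grid Increasing distance grid (nm).
#' @return Probability density (1/nm) on `r_grid`.
#' @export
evaluate_distribution <- function(dist, r_grid = default_r_grid()) {
  stopifnot(inherits(dist, "distance_distribution"))
  if (length(r_grid) < 3L || any(diff(r_grid) <= 0))
    stop("r_grid must be increasing with at least 3 points")
  widths <- vapply(dist$components, `[[`, numeric(1), "width")
  if (max(diff(r_grid)) > min(widths) / 2)
    warning("r_grid spacing exceeds half the narrowest component width; ",
            "the distribution is under-resolved")
  P <- numeric(length(r_grid))
  for (cp in dist$components)
    P <- P + cp$weight * dnorm(r_grid, cp$center, cp$width)
  Z <- sum(trapz_weights(r_grid) * P)
  if (Z <= 0) stop("distribution has no mass on the grid")
  P / Z
}

#' Form factor F(t) of a distance distribution
#'
#' F(t) = integral of P(r) K(t, r) dr, computed by trapezoidal quadrature
#' on `r_grid`.
#'
#' @param dist A `distance_distribution`.
#' @param t Time vector (us).
#' @param r_grid Distance grid (nm).
#' @param kernel Optional precomputed `kernel_matrix(t, r_grid)`.
#' @return Dimensionless vector with F(0) = 1.
#' @export
form_factor <- function(dist, t, r_grid = default_r_grid(), kernel = NULL) {
  P <- evaluate_distribution(dist, r_grid)
  if (is.null(kernel)) kernel <- kernel_matrix(t, r_grid)
  drop(kernel %*% (P * trapz_weights(r_grid)))
}

#' Intermolecular background B(t)
#'
#' Exponential decay from dipolar couplings to spins on other molecules,
#' B(t) = exp(-k t), the homogeneous 3D form. The modulation depth does not
#' enter this convention of the background.
#'
#' @param bg A `background_model`. @param t Time vector (us).
#' @return Dimensionless vector with B(0) = 1.
#' @export
background <- function(bg, t) {
  stopifnot(inherits(bg, "background_model"))
  exp(-bg$rate * t)
}

#' Simulate a composite DEER signal
#'
#' V(t) = \[(1 - lambda) + lambda F(t)\] exp(-k t).
#'
#' @param model A `signal_model`.
#' @param t Time vector (us).
#' @param r_grid Distance grid (nm).
#' @param kernel Optional precomputed `kernel_matrix(t, r_grid)`.
#' @return Dimensionless signal with V(0) = 1.
#' @export
simulate_signal <- function(model, t, r_grid = default_r_grid(),
                            kernel = NULL) {
  stopifnot(inherits(model, "signal_model"))
  Fv <- form_factor(model$distribution, t, r_grid, kernel)
  ((1 - model$depth) + model$depth * Fv) * background(model$background, t)
}
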