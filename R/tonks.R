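#' Parameters of the hard-rod (Tonks) nucleosome gas
#'
#' Bundles the two physical parameters of the one-dimensional hard-rod gas
#' used throughout the package: the particle footprint `b` (the nucleosomal
#' DNA length, 147 bp from the crystal structure) and the mean
#' center-to-center spacing `dbar` (the reciprocal of the mean density).
#' The mean linker (gap) length `ell = dbar - b` and the mean density
#' `rho = 1/dbar` are derived and stored alongside.
#'
#' @param b Particle footprint width in bp (default 147).
#' @param dbar Mean center-to-center spacing in bp; must exceed `b`.
#' @return An object of class `tonks_params`: a list with elements
#'   `b`, `dbar`, `ell` and `rho`.
#' @examples
#' p <- tonks_params(dbar = 177)
#' p$ell  # mean linker length, 30 bp
#' @export
tonks_params <- function(b = 147, dbar = 177) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("'b' must be a single positive number", call. = FALSE)
  if (!is.numeric(dbar) || length(dbar) != 1L || !is.finite(dbar) || dbar <= b)
    stop("'dbar' must be a single number larger than 'b'", call. = FALSE)
  structure(
    list(b = b, dbar = dbar, ell = dbar - b, rho = 1 / dbar),
    class = "tonks_params"
  )
}

#' @export
print.tonks_params <- function(x, ...) {
  cat(sprintf(
    "Tonks gas: b = %g bp, dbar = %g bp (linker ell = %g bp, rho = %.6g /bp)\n",
    x$b, x$dbar, x$ell, x$rho))
  invisible(x)
}

stopifnot_tonks <- function(params) {
  if (!inherits(params, "tonks_params"))
    stop("'params' must be created by tonks_params()", call. = FALSE)
  invisible(params)
}

#' Shifted Erlang density for the k-th neighbour particle
#'
#' In the hard-rod gas the gaps between neighbouring particles are
#' independent exponentials with mean `ell`, so the distance to the k-th
#' neighbour is a sum of k gaps plus k particle widths: a k-stage Erlang
#' density shifted by `k*b`,
#' \deqn{P_k(x) = \Theta(x - kb)\,\frac{(x - kb)^{k-1}}{\ell^k (k-1)!}
#'       e^{-(x - kb)/\ell}.}
#' The Heaviside factor makes the density identically zero for `x < k*b`.
#'
#' @param k Neighbour index (positive integer, scalar).
#' @param x Distance(s) from the reference particle midpoint, bp (vectorised).
#' @param params A [tonks_params()] object.
#' @return Numeric vector of per-bp probability densities, same length as `x`.
#' @examples
#' p <- tonks_params()
#' erlang_term(1, 147, p)  # 1/ell at contact
#' @export
erlang_term <- function(k, x, params) {
  stopifnot_tonks(params)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 1 || k != round(k))
    stop("'k' must be a single integer >= 1", call. = FALSE)
  if (any(!is.finite(x)))
    stop("'x' must be finite", call. = FALSE)
  ell <- params$ell
  u <- x - k * params$b
  out <- numeric(length(x))
  pos <- u > 0
  if (any(pos)) {
    # log-space evaluation keeps k up to floor(xmax/b) safe from overflow
    out[pos] <- exp((k - 1) * log(u[pos]) - u[pos] / ell -
                      k * log(ell) - lgamma(k))
  }
  # at exact contact u = 0 only the single-gap term is non-zero
  at0 <- u == 0
  if (any(at0)) out[at0] <- if (k == 1L) 1 / ell else 0
  out
}

#' Hard-rod gas density next to a perfectly positioned barrier particle
#'
#' The mean particle (midpoint) density at distance `x` from a particle with
#' perfectly fixed position is the sum of the shifted Erlang densities over
#' all neighbour indices,
#' \deqn{\rho(x) = \sum_{k \ge 1} P_k(x).}
#' Because `P_k` vanishes for `x < k*b`, the sum is exactly finite: only
#' terms with `k <= floor(x/b)` contribute, so there is no truncation error.
#' The density is zero on `[0, b)` (depletion layer), jumps to `1/ell` at
#' contact, oscillates with period ~`dbar`, and decays to the bulk value
#' `1/dbar`.
#'
#' @param x Distance(s) from the barrier particle midpoint, bp; must be >= 0.
#' @param params A [tonks_params()] object.
#' @return Numeric vector of per-bp densities.
#' @examples
#' p <- tonks_params()
#' barrier_density(c(100, 160, 2000), p)
#' @export
barrier_density <- function(x, params) {
  stopifnot_tonks(params)
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and >= 0", call. = FALSE)
  out <- numeric(length(x))
  kmax <- floor(max(x) / params$b)
  if (kmax < 1) return(out)
  for (k in seq_len(kmax)) out <- out + erlang_term(k, x, params)
  out
}

#' Two-particle distribution function of the bulk hard-rod gas
#'
#' The probability density of finding a particle at distance `x` from
#' another particle in the bulk is the mean density times the
#' barrier-conditioned density, `g(x) = rho * rho(x)`. Its limiting value
#' at large `x` is the square of the mean density.
#'
#' @inheritParams barrier_density
#' @return Numeric vector of pair densities (per bp^2).
#' @export
two_particle_g <- function(x, params) {
  stopifnot_tonks(params)
  params$rho * barrier_density(x, params)
}

#' Parameters of the profile fit function
#'
#' The model fitted to aligned read-density profiles is
#' `f(x) = A * rho(x - x0)`: the barrier density rescaled by a normalization
#' factor `A` (the read density is not normalized in absolute nucleosome
#' units) and shifted horizontally by `x0`. An offset near zero corresponds
#' to direct positioning of the anchor nucleosome; an offset near `-b`
#' corresponds to statistical positioning against a repelling region.
#'
#' @param A Normalization factor (> 0).
#' @param x0 Horizontal offset, bp.
#' @param tonks A [tonks_params()] object.
#' @return An object of class `fit_model_params`.
#' @export
fit_model_params <- function(A, x0, tonks) {
  stopifnot_tonks(tonks)
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop("'A' must be a single positive number", call. = FALSE)
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0))
    stop("'x0' must be a single finite number", call. = FALSE)
  structure(list(A = A, x0 = x0, tonks = tonks), class = "fit_model_params")
}

#' Evaluate the profile fit function
#'
#' Computes `A * rho(x - x0)` where `rho` is [barrier_density()]. The model
#' is evaluated only where `x - x0 >= 0`; to the left of the support it
#' returns 0 (evaluation is total, fit ranges never include that region).
#'
#' @param x Offsets from the alignment anchor, bp (vectorised).
#' @param p A [fit_model_params()] object.
#' @return Numeric vector of model read-density values.
#' @export
fit_model <- function(x, p) {
  if (!inherits(p, "fit_model_params"))
    stop("'p' must be created by fit_model_params()", call. = FALSE)
  u <- x - p$x0
  out <- numeric(length(x))
  ok <- is.finite(u) & u >= 0
  if (any(ok)) out[ok] <- p$A * barrier_density(u[ok], p$tonks)
  out
}

#' Normalize a convolution kernel over integer offsets
#'
#' @param kernel Named numeric vector: names are integer offsets, values are
#'   nonnegative masses. Masses are rescaled to sum to one.
#' @return Named numeric vector with unit total mass.
#' @keywords internal
normalize_kernel <- function(kernel) {
  if (is.null(names(kernel)) || anyNA(suppressWarnings(as.numeric(names(kernel)))))
    stop("kernel must be a named numeric vector with integer-offset names",
         call. = FALSE)
  if (any(!is.finite(kernel)) || any(kernel < 0))
    stop("kernel masses must be finite and nonnegative", call. = FALSE)
  s <- sum(kernel)
  if (s <= 0) stop("kernel has zero total mass", call. = FALSE)
  kernel / s
}

#' Evaluate the convolved profile fit function
#'
#' The fit function convolved with a discrete probability kernel over
#' integer offsets, `sum_j kernel(j) * f(x - j)`. The kernel is taken from
#' the empirical shape of the +1 peak, so the convolved model accounts for
#' the residual cell-to-cell positional variability of the anchor
#' nucleosome. With a point mass at offset 0 the convolved model equals
#' [fit_model()] exactly.
#'
#' @param x Offsets from the alignment anchor, bp (vectorised).
#' @param p A [fit_model_params()] object.
#' @param kernel Named numeric vector of nonnegative masses over integer
#'   offsets (names); normalized to unit mass on ingestion.
#' @return Numeric vector of model values.
#' @export
convolved_model <- function(x, p, kernel) {
  kernel <- normalize_kernel(kernel)
  offs <- as.numeric(names(kernel))
  out <- numeric(length(x))
  for (j in seq_along(offs))
    out <- out + kernel[[j]] * fit_model(x - offs[j], p)
  out
}

#' Kernel from the empirical anchor peak of an aligned profile
#'
#' Extracts the profile values in a window `[-w, +w]` around offset zero and
#' rescales them to unit mass, for use with [convolved_model()].
#'
#' @param profile An [align_average()] result.
#' @param w Half-width of the window, bp (default 80).
#' @return Named numeric vector of unit total mass.
#' @export
peak_kernel <- function(profile, w = 80) {
  stopifnot(inherits(profile, "aligned_profile"))
  sel <- profile$offset >= -w & profile$offset <= w
  if (!any(sel)) stop("profile does not cover the kernel window", call. = FALSE)
  mass <- pmax(profile$mean_weight[sel], 0)
  if (sum(mass) <= 0) stop("empty kernel region", call. = FALSE)
  stats::setNames(mass / sum(mass), profile$offset[sel])
}
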