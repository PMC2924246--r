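#' Exact canonical sampling of a hard-rod configuration
#'
#' Draws one configuration of `N` hard rods of width `b` in `[0, L]` from
#' the uniform (canonical) measure, using the classical mapping to point
#' particles: `N` points are drawn uniformly in `[0, L - N*b]`, sorted, and
#' the k-th point is shifted by `(k-1)*b` to give the rod left edges. Every
#' admissible configuration is equally likely. With `fixed_origin = TRUE`
#' an additional rod is pinned with its midpoint at 0 and the `N` free rods
#' occupy the interval `(b/2, b/2 + L]` to its right.
#'
#' @param L Length of the interval available to the free rods, bp.
#' @param N Number of free rods.
#' @param b Rod width, bp (default 147).
#' @param fixed_origin Pin a rod midpoint at 0 and sample to its right?
#' @return An object of class `gas_configuration`: list with `midpoints`
#'   (ordered, bp; includes the pinned rod when `fixed_origin`), `b`, and
#'   `pinned` (logical).
#' @examples
#' set.seed(1)
#' cfg <- sample_tonks(L = 177 * 20, N = 20)
#' min(diff(cfg$midpoints)) >= 147
#' @export
sample_tonks <- function(L, N, b = 147, fixed_origin = FALSE) {
  if (N < 0 || N != round(N)) stop("'N' must be a nonnegative integer", call. = FALSE)
  if (N * b > L) stop("infeasible packing: N*b exceeds L", call. = FALSE)
  free <- L - N * b
  pts <- sort(stats::runif(N, 0, free))
  left <- pts + (seq_len(N) - 1) * b
  mid <- left + b / 2
  if (fixed_origin) mid <- c(0, mid + b / 2)   # pinned rod ends at b/2
  structure(list(midpoints = mid, b = b, pinned = fixed_origin),
            class = "gas_configuration")
}

#' Half-line hard-rod gas in the thermodynamic limit
#'
#' Samples the rods to the right of a boundary from the exact
#' thermodynamic-limit (grand-canonical) law, in which successive linkers
#' are independent exponentials with mean `ell = dbar - b`. Two boundary
#' kinds are supported: `"pinned"`, a rod midpoint fixed at 0 (the k-th rod
#' then sits at `k*b + Gamma_k` with `Gamma_k` a k-stage Erlang), and
#' `"wall"`, a hard repelling edge at 0 with the first rod free (the k-th
#' rod sits at `(k-1)*b + Gamma_k`). Used by the cohort generator to fill
#' gene flanks; the canonical [sample_tonks()] remains the independent
#' Monte-Carlo oracle for the analytic barrier density.
#'
#' @param x_max Keep rods with midpoint <= `x_max` (bp from the boundary).
#' @param params A [tonks_params()] object.
#' @param boundary `"pinned"` or `"wall"`.
#' @return Numeric vector of rod midpoints in increasing distance from the
#'   boundary (excluding the pinned rod itself).
#' @export
sample_gas_halfline <- function(x_max, params, boundary = c("pinned", "wall")) {
  stopifnot_tonks(params)
  boundary <- match.arg(boundary)
  b <- params$b; ell <- params$ell
  n_guess <- ceiling(x_max / params$dbar) + 10L
  repeat {
    gaps <- stats::rexp(n_guess, rate = 1 / ell)
    # pinned: x_k = k*b + Gamma_k ; wall: x_k = (k-1)*b + Gamma_k
    pos <- if (boundary == "pinned") seq_len(n_guess) * b + cumsum(gaps)
           else (seq_len(n_guess) - 1) * b + cumsum(gaps)
    if (pos[n_guess] > x_max) return(pos[pos <= x_max])
    n_guess <- n_guess * 2L
  }
}

#' Monte-Carlo estimate of the barrier density from canonical samples
#'
#' Independent brute-force oracle for [barrier_density()]: repeatedly draws
#' exact canonical configurations with a rod pinned at the origin
#' ([sample_tonks()] with `fixed_origin`), bins the midpoints of the free
#' rods over `[0, x_max]`, and returns the binned density with its binomial
#' standard error. The canonical box is made much longer than `x_max`
#' (`N` rods at mean spacing `dbar`) so that finite-size effects at the far
#' edge are negligible over the histogram range.
#'
#' @param n_config Number of configurations.
#' @param params A [tonks_params()] object.
#' @param x_max Histogram range, bp.
#' @param bin Bin width, bp (default 5).
#' @param N Number of free rods per configuration (default 800).
#' @return data.frame with `x` (bin centers), `density` (per bp), `se`
#'   (standard error of the density, per bp).
#' @export
mc_barrier_density <- function(n_config, params, x_max = 2000, bin = 5,
                               N = 800) {
  stopifnot_tonks(params)
  b <- params$b; ell <- params$ell
  L <- N * b + (N + 1) * ell        # gives mean spacing dbar exactly
  free <- L - N * b
  breaks <- seq(0, x_max, by = bin)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  kmax <- min(N, ceiling(x_max / b) + 2L)
  for (i in seq_len(n_config)) {
    u <- sort.int(stats::runif(N, 0, free), method = "quick")[seq_len(kmax)]
    mid <- u + seq_len(kmax) * b    # midpoints relative to the pinned rod
    mid <- mid[mid <= x_max]
    if (length(mid))
      counts <- counts + tabulate(findInterval(mid, breaks,
                                               rightmost.closed = TRUE), nb)
  }
  p <- counts / n_config    # per-config bin occupancy (0/1: bin < rod width)
  data.frame(x = breaks[-1] - bin / 2,
             density = p / bin,
             se = sqrt(pmax(p * (1 - p), 0) / n_config) / bin)
}
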