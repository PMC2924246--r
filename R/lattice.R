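#' External energy landscape for the lattice gas
#'
#' Describes the effective free-energy landscape acting on a rod midpoint,
#' in units of kT (beta = 1). Positive energies are nucleosome-repellent,
#' negative energies attractive; `+Inf` means hard exclusion. The energy is
#' zero outside the stated region.
#'
#' @param shape One of `"flat"`, `"repellent_halfline"`, `"attractive_well"`,
#'   `"custom"`.
#' @param eps Energy amplitude in kT. For `repellent_halfline` it must be
#'   >= 0 (may be `Inf`); for `attractive_well` it must be < 0.
#' @param region Integer vector `c(from, to)` of midpoint coordinates (bp,
#'   1-based lattice sites) over which the energy applies. Ignored for
#'   `"flat"` and `"custom"`.
#' @param table For `shape = "custom"`: named numeric vector mapping midpoint
#'   sites to energies (kT).
#' @return An object of class `energy_profile`.
#' @export
energy_profile <- function(shape = c("flat", "repellent_halfline",
                                     "attractive_well", "custom"),
                           eps = 0, region = NULL, table = NULL) {
  shape <- match.arg(shape)
  if (shape == "repellent_halfline" && (is.na(eps) || eps < 0))
    stop("repellent region requires eps >= 0", call. = FALSE)
  if (shape == "attractive_well" && (!is.finite(eps) && eps > 0))
    stop("attractive well requires finite or -Inf eps < 0", call. = FALSE)
  if (shape == "attractive_well" && eps >= 0)
    stop("attractive well requires eps < 0", call. = FALSE)
  if (shape %in% c("repellent_halfline", "attractive_well")) {
    if (is.null(region) || length(region) != 2L || region[1] > region[2])
      stop("'region' must be c(from, to) with from <= to", call. = FALSE)
  }
  if (shape == "custom") {
    if (is.null(table) || is.null(names(table)))
      stop("custom shape requires a named energy table", call. = FALSE)
    if (any(is.nan(table)) || any(table == -Inf))
      stop("energies must be finite or +Inf", call. = FALSE)
  }
  structure(list(shape = shape, eps = eps, region = region, table = table),
            class = "energy_profile")
}

#' Evaluate an energy profile on lattice sites 1..L
#' @keywords internal
energy_on_lattice <- function(profile, L) {
  stopifnot(inherits(profile, "energy_profile"))
  E <- numeric(L)
  if (profile$shape %in% c("repellent_halfline", "attractive_well")) {
    from <- max(1L, profile$region[1])
    to <- min(L, profile$region[2])
    if (from <= to) E[from:to] <- profile$eps
  } else if (profile$shape == "custom") {
    m <- as.integer(names(profile$table))
    ok <- m >= 1L & m <= L
    E[m[ok]] <- profile$table[ok]
  }
  if (any(is.nan(E)) || any(E == -Inf))
    stop("energy landscape must be finite or +Inf everywhere", call. = FALSE)
  E
}

#' Grand-canonical lattice gas of hard rods
#'
#' @param L Lattice length in bp; must exceed `10 * b`.
#' @param b Rod width in bp; must be odd so the midpoint is a lattice site
#'   (default 147; half-width `h = (b - 1)/2`).
#' @param z Fugacity (dimensionless; the chemical potential is `mu = log z`
#'   in kT units).
#' @return An object of class `lattice_gas`.
#' @export
lattice_gas <- function(L, b = 147, z = 1) {
  if (b %% 2 == 0)
    stop("rod width 'b' must be odd so that the midpoint is a lattice site",
         call. = FALSE)
  if (L <= 10 * b) stop("'L' must exceed 10*b", call. = FALSE)
  if (!is.finite(z) || z <= 0) stop("'z' must be a positive number", call. = FALSE)
  structure(list(L = as.integer(L), b = as.integer(b),
                 h = (as.integer(b) - 1L) %/% 2L, z = z),
            class = "lattice_gas")
}

# log(exp(a) + exp(b)) robust to -Inf
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[m == -Inf] <- -Inf
  out
}

#' Midpoint density of hard rods in an external field (exact recursion)
#'
#' Solves the grand-canonical partition function of hard rods of width `b`
#' on a 1-bp lattice of length `L` with midpoint energies `E(m)` by the
#' standard forward/backward recursion
#' `F(i) = F(i-1) + w(i-h) F(i-b)` and `B(i) = B(i+1) + w(i+h) B(i+b)` with
#' Boltzmann weight `w(m) = z exp(-E(m))`, and returns the exact midpoint
#' occupancy `n(m) = w(m) F(m-h-1) B(m+h+1) / F(L)`. All partition values
#' are carried in log space, so arbitrarily long lattices cannot overflow.
#' Sites where the rod would overhang the lattice have zero density.
#'
#' @param profile An [energy_profile()].
#' @param gas A [lattice_gas()].
#' @param bulk_window Fraction of the lattice (centered) used to measure the
#'   achieved bulk spacing (default 0.5).
#' @return An object of class `gc_result`: list with `midpoint_density`
#'   (length `L`), `z_used`, and `bulk_spacing` (1 / mean midpoint density
#'   over the central window).
#' @export
solve_density <- function(profile, gas, bulk_window = 0.5) {
  stopifnot(inherits(gas, "lattice_gas"))
  L <- gas$L; b <- gas$b; h <- gas$h
  E <- energy_on_lattice(profile, L)
  logw <- log(gas$z) - E                      # -Inf where E = +Inf

  # forward: logF[i+1] = log F(i), F(i) = 1 for i <= 0
  logF <- numeric(L + 1L)
  for (i in seq_len(L)) {
    if (i < b) { logF[i + 1L] <- logF[i]; next }
    m <- i - h
    prev <- if (i - b >= 1L) logF[i - b + 1L] else 0
    a <- logF[i]; bb <- logw[m] + prev
    mx <- max(a, bb)
    logF[i + 1L] <- mx + log1p(exp(min(a, bb) - mx))
  }

  # backward: logB[i] = log B(i), B(i) = 1 for i > L
  logB <- numeric(L + 2L)                     # index i = position, B(L+1)=1
  for (i in seq.int(L, 1L)) {
    if (i > L - b + 1L) { logB[i] <- logB[i + 1L]; next }
    m <- i + h
    nxt <- if (i + b <= L) logB[i + b] else 0
    a <- logB[i + 1L]; bb <- logw[m] + nxt
    mx <- max(a, bb)
    logB[i] <- mx + log1p(exp(min(a, bb) - mx))
  }

  n <- numeric(L)
  m <- seq.int(h + 1L, L - h)                 # rods fully on the lattice
  logn <- logw[m] + logF[m - h - 1L + 1L] + logB[m + h + 1L] - logF[L + 1L]
  n[m] <- exp(logn)
  n[!is.finite(n)] <- 0

  ctr <- floor(L * (1 - bulk_window) / 2)
  win <- seq.int(ctr + 1L, L - ctr)
  dens <- mean(n[win])
  structure(list(midpoint_density = n, z_used = gas$z,
                 bulk_spacing = if (dens > 0) 1 / dens else Inf),
            class = "gc_result")
}

#' Tune the fugacity to a target bulk spacing
#'
#' Bisects on `log z` for a field-free lattice until the achieved bulk
#' spacing (reciprocal mean midpoint density over the central half of the
#' lattice) is within `tol` of `target_dbar`. The bulk density increases
#' monotonically with `z`, so bisection converges.
#'
#' @param gas A [lattice_gas()] (its `z` is ignored).
#' @param target_dbar Target mean center-to-center spacing, bp
#'   (must exceed `b`).
#' @param tol Spacing tolerance in bp (default 0.1).
#' @return The tuned fugacity `z` (scalar).
#' @export
tune_fugacity <- function(gas, target_dbar, tol = 0.1) {
  stopifnot(inherits(gas, "lattice_gas"))
  if (target_dbar <= gas$b) stop("target spacing must exceed rod width", call. = FALSE)
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  flat <- energy_profile("flat")
  spacing_at <- function(logz) {
    g <- lattice_gas(gas$L, gas$b, exp(logz))
    solve_density(flat, g)$bulk_spacing
  }
  lo <- -5; hi <- 5
  # spacing decreases with z: want spacing(lo) > target > spacing(hi)
  for (k in 1:12) {
    if (spacing_at(lo) > target_dbar) break
    lo <- lo - 5
    if (k == 12) stop("could not bracket the target spacing from below", call. = FALSE)
  }
  for (k in 1:12) {
    if (spacing_at(hi) < target_dbar) break
    hi <- hi + 5
    if (k == 12) stop("could not bracket the target spacing from above", call. = FALSE)
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    sp <- spacing_at(mid)
    if (abs(sp - target_dbar) < tol) return(exp(mid))
    if (sp > target_dbar) lo <- mid else hi <- mid
  }
  stop("fugacity bisection did not converge", call. = FALSE)
}

#' Family of boundary conditions for the barrier pattern
#'
#' Computes the midpoint density near boundaries of varying character: for
#' each nonnegative energy in `eps_values` a repellent region of strength
#' `eps` (length `20*b`, indistinguishable from a half-line beyond a
#' depletion layer), and for each negative energy an attractive well of the
#' given width. All members share one fugacity, tuned once on the field-free
#' lattice, and are reported on a common coordinate anchored at the
#' downstream edge of the energy region.
#'
#' @param eps_values Numeric vector of energies in kT (may include `Inf`).
#' @param gas A [lattice_gas()]; its `z` is replaced by the tuned value.
#' @param well_width Width of the attractive well in bp (default 20,
#'   roughly the width of the +1 nucleosome peak).
#' @param target_dbar Bulk spacing the shared fugacity is tuned to
#'   (default 177 bp).
#' @param edge Lattice coordinate of the region edge (default `4 * b`
#'   rounded up to leave room for the repellent region).
#' @return A data.frame with columns `eps`, `x` (bp relative to the region
#'   edge) and `density` (per-site midpoint occupancy).
#' @export
boundary_family <- function(eps_values, gas, well_width = 20,
                            target_dbar = 177, edge = NULL) {
  stopifnot(inherits(gas, "lattice_gas"))
  if (well_width < 1) stop("'well_width' must be >= 1", call. = FALSE)
  z <- tune_fugacity(gas, target_dbar)
  g <- lattice_gas(gas$L, gas$b, z)
  if (is.null(edge)) edge <- 20L * gas$b + 10L
  out <- vector("list", length(eps_values))
  for (i in seq_along(eps_values)) {
    e <- eps_values[i]
    prof <- if (e == 0) {
      energy_profile("flat")
    } else if (e > 0) {
      energy_profile("repellent_halfline", eps = e,
                     region = c(edge - 20L * gas$b + 1L, edge))
    } else {
      energy_profile("attractive_well", eps = e,
                     region = c(edge - as.integer(well_width) + 1L, edge))
    }
    res <- solve_density(prof, g)
    x <- seq_len(g$L) - edge
    out[[i]] <- data.frame(eps = e, x = x, density = res$midpoint_density)
  }
  do.call(rbind, out)
}
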