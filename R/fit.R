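#' Configuration of the least-squares fitting protocol
#'
#' @param fit_range Offsets (bp from the anchor) used for fitting; default
#'   `c(200, 2000)` (the alternative `c(200, 1200)` is used for range
#'   robustness checks).
#' @param n_starts Number of random restarts per fit (default 300).
#' @param b Nucleosome width, bp, kept fixed in all fits.
#' @param seed Seed for the restart generator (reproducible multi-start).
#' @param w Convolution kernel half-window, bp (default 80).
#' @param dbar_start Range the spacing starting values are drawn from, bp.
#' @param x0_bounds Bounds on the offset parameter, bp.
#' @param A_factor Range of the multiplicative factor applied to the
#'   data-scale guess of the normalization for starting values.
#' @param basin_halfwidth Half-width of the offset seeding window around
#'   each basin centre (0 for direct, -b for indirect), bp.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(fit_range = c(200, 2000), n_starts = 300, b = 147,
                       seed = 1L, w = 80, dbar_start = c(150, 250),
                       x0_bounds = c(-220, 220), A_factor = c(0.2, 5),
                       basin_halfwidth = 40) {
  if (length(fit_range) != 2L || fit_range[1] >= fit_range[2])
    stop("'fit_range' must be c(lo, hi) with lo < hi", call. = FALSE)
  if (n_starts < 1) stop("'n_starts' must be >= 1", call. = FALSE)
  structure(list(fit_range = fit_range, n_starts = as.integer(n_starts),
                 b = b, seed = seed, w = w, dbar_start = dbar_start,
                 x0_bounds = x0_bounds, A_factor = A_factor,
                 basin_halfwidth = basin_halfwidth),
            class = "fit_config")
}

# model curve A * rho(x - x0) at spacing dbar (zero left of the support)
tonks_curve <- function(x, A, x0, dbar, b) {
  u <- x - x0
  out <- numeric(length(x))
  ok <- u >= 0
  if (any(ok)) out[ok] <- A * barrier_density(u[ok], tonks_params(b, dbar))
  out
}

# extract (x, y) fitting data from a profile
fit_data <- function(profile, cfg, mirror = FALSE) {
  stopifnot(inherits(profile, "aligned_profile"))
  if (mirror && !isTRUE(attr(profile, "mirrored")))
    profile <- mirror_profile(profile)
  sel <- profile$offset >= cfg$fit_range[1] & profile$offset <= cfg$fit_range[2] &
    !is.na(profile$mean_weight)
  if (sum(sel) < 10) stop("profile does not cover the fit range", call. = FALSE)
  list(x = profile$offset[sel], y = profile$mean_weight[sel])
}

# offset bounds for a basin: scenario-imposing fits restrict x0 to the basin
# (|x0| < b/2 direct, x0 < -b/2 indirect) so the optimizer cannot escape it
basin_bounds <- function(basin, cfg) {
  switch(basin,
         free = cfg$x0_bounds,
         direct = c(-cfg$b / 2, cfg$b / 2),
         indirect = c(cfg$x0_bounds[1], -cfg$b / 2))
}

# draw an offset starting value for a basin
draw_x0 <- function(basin, cfg) {
  ctr <- switch(basin, direct = 0, indirect = -cfg$b,
                free = stats::runif(1, cfg$x0_bounds[1] + cfg$basin_halfwidth,
                                    cfg$x0_bounds[2] - cfg$basin_halfwidth))
  hw <- cfg$basin_halfwidth
  max(cfg$x0_bounds[1], min(cfg$x0_bounds[2], ctr + stats::runif(1, -hw, hw)))
}

# multi-start Levenberg-Marquardt driver
#   resid_fn(par) -> residual vector; start_fn() -> par; lower/upper bounds
multistart_lm <- function(resid_fn, start_fn, lower, upper, n_starts) {
  best <- NULL
  track <- matrix(NA_real_, n_starts, length(lower) + 1L)
  for (s in seq_len(n_starts)) {
    p0 <- start_fn()
    res <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-13,
                                           maxiter = 300)), silent = TRUE)
    if (inherits(res, "try-error")) next
    chi2 <- mean(res$fvec^2)
    track[s, ] <- c(unlist(res$par), chi2)
    if (is.null(best) || chi2 < best$chi2) best <- list(par = res$par, chi2 = chi2)
  }
  if (is.null(best)) stop("all restarts failed to converge", call. = FALSE)
  list(best = best, track = track)
}

# identifiability guard: restarts whose score ties the best must agree on dbar
converged_dbar <- function(track, dbar_col, best_chi2) {
  near <- which(track[, ncol(track)] <= best_chi2 + max(1e-8, 1e-6 * best_chi2))
  if (length(near) < 2) return(TRUE)
  diff(range(track[near, dbar_col])) < 20
}

scenario_of <- function(x0, b) if (abs(x0) < b / 2) "direct" else "indirect"

#' Fit the hard-rod model to an aligned profile
#'
#' Minimizes the mean squared deviation per data point between the profile
#' and `A * rho(x - x0)` over `(A, x0, dbar)` with the nucleosome width
#' fixed, using Levenberg-Marquardt from `n_starts` random starting points.
#' The offset basin can be constrained: `direct` seeds `x0` near 0,
#' `indirect` near `-b`, `free` spans the whole offset range. The returned
#' scenario label is `direct` when `|x0| < b/2`, `indirect` otherwise
#' (a tie at exactly `b/2` is indirect).
#'
#' @param profile An `aligned_profile` (+1 alignment, or -1 with
#'   `mirror = TRUE`).
#' @param cfg A [fit_config()].
#' @param basin `"free"`, `"direct"` or `"indirect"`.
#' @param mirror Mirror the profile at the origin first (for -1
#'   alignments)?
#' @return An object of class `fit_result`: list with `A`, `x0`, `dbar`,
#'   `chi2` (mean squared deviation per data point), `scenario`,
#'   `converged`, `n_starts`, `basin`.
#' @export
fit_profile <- function(profile, cfg = fit_config(),
                        basin = c("free", "direct", "indirect"),
                        mirror = FALSE) {
  basin <- match.arg(basin)
  d <- fit_data(profile, cfg, mirror)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ybar <- mean(d$y)
  flat <- stats::sd(d$y) < 1e-12 * max(abs(ybar), 1e-300)
  resid_fn <- function(p) d$y - tonks_curve(d$x, p[1], p[2], p[3], cfg$b)
  start_fn <- function() {
    dbar0 <- stats::runif(1, cfg$dbar_start[1], cfg$dbar_start[2])
    A0 <- ybar * dbar0 * stats::runif(1, cfg$A_factor[1], cfg$A_factor[2])
    c(A = max(A0, 1e-8), x0 = draw_x0(basin, cfg), dbar = dbar0)
  }
  bb <- basin_bounds(basin, cfg)
  fit <- multistart_lm(resid_fn, start_fn,
                       lower = c(1e-12, bb[1], cfg$b + 1),
                       upper = c(Inf, bb[2], 2.5 * cfg$b),
                       cfg$n_starts)
  p <- fit$best$par
  structure(list(A = unname(p[1]), x0 = unname(p[2]), dbar = unname(p[3]),
                 chi2 = fit$best$chi2,
                 scenario = scenario_of(p[2], cfg$b),
                 converged = !flat && converged_dbar(fit$track, 3L, fit$best$chi2),
                 n_starts = cfg$n_starts, basin = basin),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Tonks fit: A = %.4g, x0 = %.2f bp, dbar = %.2f bp, chi2/pt = %.4g (%s%s)\n",
    x$A, x$x0, x$dbar, x$chi2, x$scenario,
    if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' Fit the convolved hard-rod model
#'
#' As [fit_profile()], but the model is convolved with the empirical shape
#' of the anchor peak (profile values in `[-w, +w]` rescaled to unit mass),
#' which accounts for the residual cell-to-cell positional variability of
#' the anchor nucleosome. The offset is fixed at `x0 = 0`: the kernel
#' already carries the peak location. Only `A` and `dbar` are fitted.
#'
#' @inheritParams fit_profile
#' @param x0 Offset at which the convolved model is pinned (default 0,
#'   exposed as an override).
#' @return A `fit_result` (with `x0` as fixed).
#' @export
fit_convolved <- function(profile, cfg = fit_config(), x0 = 0) {
  d <- fit_data(profile, cfg)
  kern <- peak_kernel(profile, cfg$w)
  offs <- as.numeric(names(kern))
  ext <- seq.int(min(d$x) - max(offs), max(d$x) - min(offs))
  idx <- outer(d$x, offs, "-") - ext[1] + 1
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ybar <- mean(d$y)
  model_fn <- function(A, dbar) {
    fy <- tonks_curve(ext, A, x0, dbar, cfg$b)
    as.vector(matrix(fy[idx], nrow = length(d$x)) %*% kern)
  }
  resid_fn <- function(p) d$y - model_fn(p[1], p[2])
  start_fn <- function() {
    dbar0 <- stats::runif(1, cfg$dbar_start[1], cfg$dbar_start[2])
    c(A = max(ybar * dbar0 * stats::runif(1, cfg$A_factor[1], cfg$A_factor[2]),
              1e-8), dbar = dbar0)
  }
  fit <- multistart_lm(resid_fn, start_fn,
                       lower = c(1e-12, cfg$b + 1), upper = c(Inf, 2.5 * cfg$b),
                       cfg$n_starts)
  p <- fit$best$par
  structure(list(A = unname(p[1]), x0 = x0, dbar = unname(p[2]),
                 chi2 = fit$best$chi2, scenario = scenario_of(x0, cfg$b),
                 converged = converged_dbar(fit$track, 2L, fit$best$chi2),
                 n_starts = cfg$n_starts, basin = "convolved"),
            class = "fit_result")
}

#' Offset-only fit to the -1 alignment with parameters from the +1 fit
#'
#' Fits only the horizontal offset of the mirrored -1 profile, keeping the
#' normalization and spacing fixed at the values estimated from the +1
#' alignment. Restarts are seeded near both `+b` and `-b` (and 0) so both
#' basins are explored.
#'
#' @param profile_minus The -1 `aligned_profile` (unmirrored).
#' @param A_fixed,dbar_fixed Parameters from the +1 fit.
#' @param cfg A [fit_config()].
#' @return A `fit_result` with only `x0` estimated.
#' @export
fit_minus_fixed <- function(profile_minus, A_fixed, dbar_fixed,
                            cfg = fit_config()) {
  d <- fit_data(profile_minus, cfg, mirror = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  resid_fn <- function(p) d$y - tonks_curve(d$x, A_fixed, p[1], dbar_fixed, cfg$b)
  centres <- c(-cfg$b, 0, cfg$b)
  start_fn <- function() {
    ctr <- sample(centres, 1)
    c(x0 = max(cfg$x0_bounds[1],
               min(cfg$x0_bounds[2],
                   ctr + stats::runif(1, -cfg$basin_halfwidth,
                                      cfg$basin_halfwidth))))
  }
  fit <- multistart_lm(resid_fn, start_fn, lower = cfg$x0_bounds[1],
                       upper = cfg$x0_bounds[2], cfg$n_starts)
  x0 <- unname(fit$best$par[1])
  structure(list(A = A_fixed, x0 = x0, dbar = dbar_fixed,
                 chi2 = fit$best$chi2, scenario = scenario_of(x0, cfg$b),
                 converged = TRUE, n_starts = cfg$n_starts,
                 basin = "offset-only"),
            class = "fit_result")
}

scenario_pairs <- data.frame(
  pair = c("A", "B", "C", "D"),
  plus = c("direct", "indirect", "direct", "indirect"),
  minus = c("direct", "direct", "indirect", "indirect"),
  stringsAsFactors = FALSE)

#' Simultaneous fit of both NFR flanks under a boundary-condition pair
#'
#' Joint least squares to the +1 alignment and the mirrored -1 alignment
#' with the normalization `A` and spacing `dbar` constrained equal on both
#' sides and independent offsets `x0_plus`, `x0_minus` whose seeding basins
#' are fixed by the scenario pair: `A` = both direct, `B` = +1 indirect /
#' -1 direct, `C` = +1 direct / -1 indirect, `D` = both indirect. `chi2`
#' is the mean squared deviation per data point over both sides.
#'
#' @param profile_plus,profile_minus The +1 and (unmirrored) -1 profiles.
#' @param scenario_pair `"A"`, `"B"`, `"C"` or `"D"`.
#' @param cfg A [fit_config()].
#' @return An object of class `scenario_fit`.
#' @export
simultaneous_fit <- function(profile_plus, profile_minus, scenario_pair,
                             cfg = fit_config()) {
  sp <- scenario_pairs[scenario_pairs$pair == scenario_pair, ]
  if (nrow(sp) != 1L) stop("unknown scenario pair", call. = FALSE)
  dp <- fit_data(profile_plus, cfg)
  dm <- fit_data(profile_minus, cfg, mirror = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ybar <- mean(c(dp$y, dm$y))
  flat <- stats::sd(c(dp$y, dm$y)) < 1e-12 * max(abs(ybar), 1e-300)
  resid_fn <- function(p)
    c(dp$y - tonks_curve(dp$x, p[1], p[3], p[2], cfg$b),
      dm$y - tonks_curve(dm$x, p[1], p[4], p[2], cfg$b))
  start_fn <- function() {
    dbar0 <- stats::runif(1, cfg$dbar_start[1], cfg$dbar_start[2])
    c(A = max(ybar * dbar0 * stats::runif(1, cfg$A_factor[1], cfg$A_factor[2]),
              1e-8),
      dbar = dbar0, x0p = draw_x0(sp$plus, cfg), x0m = draw_x0(sp$minus, cfg))
  }
  bp_ <- basin_bounds(sp$plus, cfg); bm_ <- basin_bounds(sp$minus, cfg)
  fit <- multistart_lm(resid_fn, start_fn,
                       lower = c(1e-12, cfg$b + 1, bp_[1], bm_[1]),
                       upper = c(Inf, 2.5 * cfg$b, bp_[2], bm_[2]),
                       cfg$n_starts)
  p <- fit$best$par
  structure(list(A = unname(p[1]), dbar = unname(p[2]),
                 x0_plus = unname(p[3]), x0_minus = unname(p[4]),
                 chi2 = fit$best$chi2, scenario_pair = sp$pair,
                 scenario_plus = sp$plus, scenario_minus = sp$minus,
                 converged = !flat && converged_dbar(fit$track, 2L, fit$best$chi2),
                 n_starts = cfg$n_starts),
            class = "scenario_fit")
}

#' Rank all four boundary-condition pairs by joint fit quality
#'
#' Runs [simultaneous_fit()] for each of the four scenario pairs and
#' returns the results ordered by `chi2` per data point (best first).
#'
#' @inheritParams simultaneous_fit
#' @return List with `fits` (named list of `scenario_fit`) and `ranking`
#'   (data.frame sorted by chi2).
#' @export
rank_scenarios <- function(profile_plus, profile_minus, cfg = fit_config()) {
  fits <- lapply(scenario_pairs$pair, function(p)
    simultaneous_fit(profile_plus, profile_minus, p, cfg))
  names(fits) <- scenario_pairs$pair
  ranking <- do.call(rbind, lapply(fits, function(f)
    data.frame(pair = f$scenario_pair, plus = f$scenario_plus,
               minus = f$scenario_minus, A = f$A, dbar = f$dbar,
               x0_plus = f$x0_plus, x0_minus = f$x0_minus, chi2 = f$chi2,
               stringsAsFactors = FALSE)))
  ranking <- ranking[order(ranking$chi2), ]
  rownames(ranking) <- NULL
  list(fits = fits, ranking = ranking)
}

#' Intergenic-to-genic mean density ratio with NFR exclusion
#'
#' Partitions each chromosome into genic base pairs (between TSS and ORF
#' end of any gene) and intergenic base pairs (the complement), excludes
#' the per-gene NFR zone (the interval between the -1 and +1 dyads found
#' by [find_flanking()]) from both classes, and returns the ratio of the
#' mean intergenic weight per bp to the mean genic weight per bp.
#'
#' @param density A `density_map`.
#' @param genes Gene table.
#' @param calls Nucleosome-call table (for the NFR zones).
#' @return List with `ratio`, `intergenic_mean`, `genic_mean`,
#'   `intergenic_bp`, `genic_bp`.
#' @export
density_ratio <- function(density, genes, calls) {
  stopifnot(inherits(density, "density_map"))
  fl <- find_flanking(genes, calls)
  tot <- c(genic = 0, inter = 0); bp <- c(genic = 0, inter = 0)
  for (cn in names(density$tracks)) {
    tr <- density$tracks[[cn]]
    L <- length(tr)
    genic <- logical(L); excl <- logical(L)
    gsel <- genes$chrom == cn
    if (!any(gsel)) next
    for (i in which(gsel)) {
      rng <- sort(c(genes$tss[i], genes$orf_end[i]))
      lo <- max(0, rng[1]); hi <- min(L - 1, rng[2])
      if (lo <= hi) genic[(lo:hi) + 1] <- TRUE
      if (!is.na(fl$plus1[i]) && !is.na(fl$minus1[i])) {
        # strictly BETWEEN the flanking dyads: the dyad base pairs carry the
        # -1/+1 nucleosomes' own weight and stay in their partitions
        nf <- sort(c(fl$plus1[i], fl$minus1[i]))
        lo <- max(0, nf[1] + 1); hi <- min(L - 1, nf[2] - 1)
        if (lo <= hi) excl[(lo:hi) + 1] <- TRUE
      }
    }
    gm <- genic & !excl
    im <- !genic & !excl
    tot["genic"] <- tot["genic"] + sum(tr[gm])
    tot["inter"] <- tot["inter"] + sum(tr[im])
    bp["genic"] <- bp["genic"] + sum(gm)
    bp["inter"] <- bp["inter"] + sum(im)
  }
  if (bp["genic"] == 0 || bp["inter"] == 0)
    stop("empty genic or intergenic partition", call. = FALSE)
  gmean <- tot["genic"] / bp["genic"]
  imean <- tot["inter"] / bp["inter"]
  list(ratio = unname(imean / gmean), intergenic_mean = unname(imean),
       genic_mean = unname(gmean), intergenic_bp = unname(bp["inter"]),
       genic_bp = unname(bp["genic"]))
}
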