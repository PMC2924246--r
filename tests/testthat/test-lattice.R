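p177 <- tonks_params(147, 177)

# one tuned fugacity shared across this file; L = 8000 keeps the central
# measurement window clear of the boundary-induced oscillations at the
# lattice ends (they decay over ~1.5 kb)
gas0 <- lattice_gas(8000, 147)
z177 <- tune_fugacity(gas0, 177, tol = 0.05)
gas <- lattice_gas(8000, 147, z177)

test_that("constructors reject invalid gases and landscapes", {
  expect_error(lattice_gas(6000, 146), "odd")
  expect_error(lattice_gas(1000, 147), "exceed")
  expect_error(energy_profile("attractive_well", eps = 2, region = c(1, 10)),
               "eps < 0")
  expect_error(energy_profile("repellent_halfline", eps = -1,
                              region = c(1, 10)), "eps >= 0")
  expect_error(energy_profile("custom"), "named")
})

test_that("field-free solution is flat in the bulk at the tuned spacing", {
  # on a 20 kb lattice the central half is > 5 kb from either end, beyond
  # the reach of the end-induced oscillations
  r <- solve_density(energy_profile("flat"), lattice_gas(20000, 147, z177))
  expect_equal(r$bulk_spacing, 177, tolerance = 0.1 / 177)
  win <- r$midpoint_density[5001:15000]         # central 50%
  expect_lt(max(win) - min(win), 0.01 * mean(win))
  # rod overhang: no density within half a rod of either end
  expect_true(all(r$midpoint_density[1:73] == 0))
  expect_true(all(r$midpoint_density[19928:20000] == 0))
})

test_that("tuned fugacity matches the exact discrete hard-rod EOS", {
  # independent closed form: gaps geometric with mean ell give pressure
  # bP = ln((ell+1)/ell) and fugacity z = (1 - e^-bP) e^(b bP)
  ell <- 30
  bP <- log((ell + 1) / ell)
  z_eos <- (1 - exp(-bP)) * exp(147 * bP)
  expect_equal(z177, z_eos, tolerance = 5e-3)
})

test_that("hard wall and single-site deep well reproduce the analytic
           barrier pattern at the first three peaks", {
  x <- 1:2200
  # hard wall: midpoints excluded up to site 2000
  wall <- solve_density(energy_profile("repellent_halfline", eps = Inf,
                                       region = c(1, 2000)), gas)
  lat_wall <- wall$midpoint_density[2000 + x]
  ana_w <- barrier_density(x + 147, p177)
  pk_w <- c(1, (which(diff(sign(diff(ana_w))) == -2) + 1)[1:2])
  for (px in pk_w) {
    ref <- ana_bin_means(px - 1 + 147, 1, p177)  # site x <-> gap bin [x-1, x)
    expect_equal(lat_wall[px], ref, tolerance = 0.02)
  }
  # deep narrow well pins a particle: neighbours follow rho(x)
  well <- solve_density(energy_profile("attractive_well", eps = -12,
                                       region = c(2000, 2000)), gas)
  expect_gt(well$midpoint_density[2000], 0.99)
  lat_well <- well$midpoint_density[2000 + x]
  ana_p <- barrier_density(x, p177)
  pk_p <- (which(diff(sign(diff(ana_p))) == -2) + 1)[1:3]
  for (px in pk_p) {
    ref <- ana_bin_means(px, 1, p177)            # site x <-> bin [x, x+1)
    expect_equal(lat_well[px], ref, tolerance = 0.02)
  }
})

test_that("dilute limit: tiny fugacity gives a near-ideal gas", {
  dilute <- solve_density(energy_profile("flat"),
                          lattice_gas(6000, 147, 1e-9))
  expect_gt(dilute$bulk_spacing, 10 * 147)
})

test_that("mirroring the energy landscape mirrors the density exactly", {
  L <- 3000
  tab <- c("600" = 2, "601" = 2, "1200" = -1.5)
  g <- lattice_gas(L, 147, z177)
  fwd <- solve_density(energy_profile("custom", table = tab), g)
  mtab <- stats::setNames(as.numeric(tab), L + 1 - as.integer(names(tab)))
  rev_ <- solve_density(energy_profile("custom",
                                       table = mtab[order(names(mtab))]), g)
  expect_equal(rev(rev_$midpoint_density), fwd$midpoint_density,
               tolerance = 1e-12)
})

test_that("total particle number grows linearly with L at fixed fugacity", {
  flat <- energy_profile("flat")
  n1 <- sum(solve_density(flat, lattice_gas(4000, 147, z177))$midpoint_density)
  n2 <- sum(solve_density(flat, lattice_gas(8000, 147, z177))$midpoint_density)
  slope <- (n2 - n1) / 4000
  expect_equal(slope, 1 / 177, tolerance = 0.01)
})

test_that("boundary family: flat member, hard-wall member, common bulk and
           an oscillation period set by the spacing, not the energy", {
  fam <- run_boundary(c(-5, -2, 0, 2, 5, Inf), L = 12000)
  # eps = 0 member is flat away from the boundary region and lattice ends
  f0 <- fam[fam$eps == 0 & fam$x > 1000 & fam$x < 5000, ]
  expect_lt(max(f0$density) - min(f0$density), 0.01 * mean(f0$density))
  # all members reach the bulk density far from the boundary
  for (e in unique(fam$eps)) {
    far <- fam[fam$eps == e & fam$x >= 30 * 177 & fam$x <= 31 * 177, ]
    expect_equal(mean(far$density), 1 / 177, tolerance = 0.01)
  }
  # period is set by the spacing, not the boundary energy: the distance
  # between the 2nd and 3rd above-asymptote maxima varies < 2 bp with eps
  p23 <- sapply(c(-5, -2, 2, 5, Inf), function(e) {
    d <- fam[fam$eps == e & fam$x >= 1 & fam$x <= 2000, ]
    pk <- which(diff(sign(diff(d$density))) == -2) + 1
    pk <- pk[d$density[pk] > 1 / 177]      # oscillation maxima only
    diff(d$x[pk[2:3]])
  })
  expect_lt(diff(range(p23)), 2)
})
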