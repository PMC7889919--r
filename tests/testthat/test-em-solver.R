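adult26 <- build_adult_stack(26e9)
adult60 <- build_adult_stack(60e9)

test_that("complex wavenumber uses the principal root with decaying forward wave", {
  k <- complex_wavenumber(26e9, 1 + 0i)
  expect_equal(Re(k), 544.9197057074373, tolerance = 1e-12)
  expect_equal(Im(k), 0)
  expect_equal(complex_wavenumber(26e9, 4 + 0i), 2 * k)
  k60 <- complex_wavenumber(60e9, permittivity(7.98, 10.90))
  expect_equal(Im(k60), -2090.811189723249, tolerance = 1e-10)
  # consistency by squaring: (k/k0)^2 = eps*
  k0 <- 2 * pi * 60e9 / 299792458
  expect_equal((k60 / k0)^2, permittivity(7.98, 10.90), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    eps <- permittivity(runif(1, 1.5, 60), runif(1, 0, 40))
    kk <- complex_wavenumber(26e9, eps)
    expect_true(Re(kk) > 0 && Im(kk) <= 0)
  }
})

test_that("elementary reflection reproduces Fresnel limits and antisymmetry", {
  expect_equal(elementary_reflection(2 + 0i, 2 + 0i), 0 + 0i)
  expect_equal(elementary_reflection(1 + 0i, 2 + 0i), -1 / 3 + 0i)
  n1 <- 3.2 - 0.8i; n2 <- 1.7 - 2.1i
  expect_equal(elementary_reflection(n1, n2), -elementary_reflection(n2, n1))
  expect_error(elementary_reflection(1 + 1i, -1 - 1i), "degenerate")
})

test_that("cascade reflection: vacuum, Fresnel half-space, terminal condition", {
  vac <- lapply(1:3, function(i) {
    tissue_layer(paste0("v", i), if (i < 3) 1e-3 else Inf, 1 + 0i, 0.4, 1000,
                 if (i == 3) 2000 else 0)
  })
  st_vac <- tissue_stack(vac, vac, 26e9)
  expect_equal(max(Mod(cascade_reflection(st_vac))), 0)
  expect_equal(transmission_coefficient(st_vac), 1.0)

  half <- list(tissue_layer("m", Inf, 4 + 0i, 0.4, 1000, 2000))
  st_half <- tissue_stack(half, half, 26e9)
  expect_equal(cascade_reflection(st_half)[1], -1 / 3 + 0i)
  expect_equal(transmission_coefficient(st_half), 8 / 9)

  # deepest interface reflection equals its elementary coefficient
  g <- stack_eps_h(adult26)
  n <- refractive_index(g$eps)
  R <- cascade_reflection(adult26)
  expect_equal(R[length(R)], elementary_reflection(n[4], n[5]))
})

test_that("cascade reflection and fields match the transfer-matrix oracle", {
  # the paper-style SC-on-ED two-layer case plus random 2-6 layer stacks
  sc_ed <- list(
    tissue_layer("SC", 0.015e-3, permittivity(3.62, 0.74), 0.37, 1500, 0),
    tissue_layer("ED", Inf, permittivity(17.71, 16.87), 0.37, 1109, 2000))
  st <- tissue_stack(sc_ed, sc_ed, 26e9)
  g <- stack_eps_h(st)
  or <- tm_oracle(g$eps, g$h, 26e9)
  expect_equal(cascade_reflection(st)[1], or$R0, tolerance = 1e-12)

  set.seed(101)
  for (i in 1:40) {
    st <- random_stack(sample(2:6, 1))
    g <- stack_eps_h(st)
    or <- tm_oracle(g$eps, g$h, 26e9)
    R0 <- cascade_reflection(st)[1]
    expect_lt(Mod(R0 - or$R0), 1e-8 * max(Mod(or$R0), 1e-3))
    expect_lt(abs(transmission_coefficient(st) - or$TC), 1e-8)
    expect_lte(Mod(R0), 1)
    z <- sort(runif(100, 0, sum(g$h) + 0.5e-3))
    E_pkg <- field_profile(st, z, plane_wave(26e9, 10))
    E_or <- or$field(z)
    expect_lt(max(Mod(E_pkg - E_or) / Mod(E_or)), 1e-8)
  }
})

test_that("field is continuous across interfaces and unity in vacuum", {
  vac <- lapply(1:2, function(i) {
    tissue_layer(paste0("v", i), if (i < 2) 2e-3 else Inf, 1 + 0i, 0.4, 1000,
                 if (i == 2) 2000 else 0)
  })
  st_vac <- tissue_stack(vac, vac, 26e9)
  z <- seq(0, 5e-3, by = 1e-4)
  expect_equal(Mod(field_profile(st_vac, z, plane_wave(26e9, 10))),
               rep(1, length(z)), tolerance = 1e-12)

  for (st in list(adult26, adult60)) {
    h <- vapply(st$em, `[[`, numeric(1), "thickness")
    bounds <- cumsum(h[is.finite(h)])
    expo <- plane_wave(st$frequency, 10)
    above <- field_profile(st, bounds - 1e-15, expo)
    below <- field_profile(st, bounds + 1e-15, expo)
    expect_lt(max(Mod(above - below) / Mod(above)), 1e-10)
  }
})

test_that("incident amplitude follows from the incident power density", {
  sol <- em_solve(adult26, plane_wave(26e9, 10))
  expect_equal(sol$E0, sqrt(2 * 376.730313668 * 10), tolerance = 1e-12)
  # doubling IPD doubles SAR everywhere (linearity in power)
  z <- seq(0, 3e-3, by = 5e-5)
  s1 <- sar_at(adult26, z, plane_wave(26e9, 10))
  s2 <- sar_at(adult26, z, plane_wave(26e9, 20))
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
})

test_that("absorbed power density is TC x IPD", {
  expect_equal(absorbed_power_density(0.59, 10), 5.9)
  expect_equal(absorbed_power_density(0.4, 0), 0)
  expect_equal(absorbed_power_density(1, 12.3), 12.3)
  expect_error(absorbed_power_density(1.2, 1))
})

test_that("SAR: lossless media absorb nothing; peak sits at the SC/ED interface", {
  lossless <- list(
    tissue_layer("a", 1e-3, 4 + 0i, 0.4, 1000, 0),
    tissue_layer("b", Inf, permittivity(20, 15), 0.4, 1000, 2000))
  st <- tissue_stack(lossless, lossless, 26e9)
  expect_equal(sar_at(st, seq(0, 0.9e-3, by = 1e-4)), rep(0, 10))

  for (st_adult in list(adult26, adult60)) {
    pk <- peak_sar(st_adult)
    expect_equal(pk$depth, 0.015e-3, tolerance = 1e-9)
    expect_identical(pk$layer, "ED")
  }
})

test_that("SAR jumps across interfaces by the conductivity/density ratio", {
  for (st in list(adult26, adult60)) {
    f <- st$frequency
    sigma <- vapply(st$em, function(l) conductivity(l$eps, f), numeric(1))
    rho <- vapply(st$em, `[[`, numeric(1), "rho")
    h <- vapply(st$em, `[[`, numeric(1), "thickness")
    bounds <- cumsum(h[is.finite(h)])
    for (j in seq_along(bounds)) {
      s_above <- sar_at(st, bounds[j] - 1e-12)
      s_below <- sar_at(st, bounds[j] + 1e-12)
      expect_equal(s_below / s_above,
                   (sigma[j + 1] / rho[j + 1]) / (sigma[j] / rho[j]),
                   tolerance = 1e-6)
    }
  }
})

test_that("energy is conserved: reflected power plus layer budget is unity", {
  set.seed(202)
  for (i in 1:100) {
    st <- random_stack(sample(2:6, 1))
    R0 <- cascade_reflection(st)[1]
    fr <- layer_power_fractions(st)
    tc <- transmission_coefficient(st)
    expect_lt(abs(Mod(R0)^2 + tc * sum(fr) - 1), 1e-9)
    expect_true(all(fr > -1e-12))
  }
})

test_that("Poynting-difference and field-integral layer powers agree", {
  for (st in list(adult26, adult60)) {
    sol <- em_solve(st, plane_wave(st$frequency, 10))
    fr_poynting <- layer_power_fractions(st)
    p_int <- agederm:::.layer_power_integral(sol, st)
    fr_int <- p_int / sum(p_int)
    expect_equal(unname(fr_int), unname(fr_poynting), tolerance = 1e-6)
  }
  # single absorbing half-space dissipates everything in that layer
  half <- list(tissue_layer("m", Inf, permittivity(20, 15), 0.4, 1000, 2000))
  st_half <- tissue_stack(half, half, 26e9)
  expect_equal(unname(layer_power_fractions(st_half)), 1)
})

test_that("penetration depth matches the skin values and handles lossless input", {
  expect_equal(penetration_depth(permittivity(7.98, 10.90), 60e9) * 1e3,
               0.4782832638906842, tolerance = 1e-12)
  expect_equal(round(penetration_depth(permittivity(7.98, 10.90), 60e9) * 1e3, 1),
               0.5)
  expect_equal(penetration_depth(permittivity(17.71, 16.87), 26e9) * 1e3,
               0.9989962914415595, tolerance = 1e-12)
  expect_warning(d <- penetration_depth(4 + 0i, 26e9), "lossless")
  expect_identical(d, Inf)
})

test_that("removing the air/skin mismatch raises the peak SAR", {
  for (st in list(adult26, adult60)) {
    nr <- no_reflection_peak_sar(st)
    expect_gte(nr$normalized, 1)
    # re-run oracle: solving with the substituted ambient reproduces the value
    sol_nr <- em_solve(st, plane_wave(st$frequency, 10),
                       eps_ambient = st$em[[2]]$eps)
    h <- vapply(st$em, `[[`, numeric(1), "thickness")
    z <- sort(unique(c(seq(0, 6e-3, by = 1e-6), cumsum(h[is.finite(h)]))))
    pk_manual <- max(agederm:::.sar_from_sol(sol_nr, st, z))
    expect_equal(nr$peak_sar, pk_manual, tolerance = 1e-9)
  }
  # a stack already matched to the ambient has equal peaks
  ed <- permittivity(17.71, 16.87)
  matched <- list(tissue_layer("ED", Inf, ed, 0.37, 1109, 2000))
  st_m <- tissue_stack(matched, matched, 26e9)
  sol_m <- em_solve(st_m, plane_wave(26e9, 10), eps_ambient = ed)
  z <- seq(0, 2e-3, by = 1e-6)
  expect_equal(max(agederm:::.sar_from_sol(sol_m, st_m, z)),
               no_reflection_peak_sar(st_m)$peak_sar, tolerance = 1e-9)
})

test_that("adult peak SAR at 60 GHz is about twice the 26 GHz value", {
  r <- peak_sar(adult60)$value / peak_sar(adult26)$value
  expect_gt(r, 1.7)
  expect_lt(r, 2.3)
})

test_that("adult transmission coefficients fall in the reported age ranges", {
  expect_gt(transmission_coefficient(adult26), 0.54)
  expect_lt(transmission_coefficient(adult26), 0.59)
  expect_gt(transmission_coefficient(adult60), 0.605)
  expect_lt(transmission_coefficient(adult60), 0.66)
})
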