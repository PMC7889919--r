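#' @title Stratified-media plane-wave solver
#' @description Normal-incidence TEM plane wave on a layered half-space under
#'   the e^{+j omega t} convention (eps* = eps' - j eps'', forward wave
#'   e^{-jkz} decaying with depth). Computes cascade reflection coefficients,
#'   per-layer complex field amplitudes, the power transmission coefficient,
#'   absorbed power density, SAR depth profiles and the per-layer absorbed
#'   power budget.
#' @name em_solver
NULL

#' Plane-wave exposure
#'
#' @param frequency Hz, > 0.
#' @param ipd incident power density, W m-2, >= 0.
#' @return a `plane_wave` list.
#' @export
plane_wave <- function(frequency, ipd = 10) {
  stopifnot(frequency > 0, ipd >= 0)
  structure(list(frequency = frequency, ipd = ipd), class = "plane_wave")
}

#' Complex refractive index, principal root of eps*
#'
#' n = sqrt(eps*) with Re n > 0, Im n <= 0 for passive media.
#'
#' @param eps complex permittivity.
#' @return complex refractive index.
#' @export
refractive_index <- function(eps) {
  n <- sqrt(as.complex(eps))
  # principal root of eps' - j eps'' (eps'' >= 0) already has Re >= 0, Im <= 0;
  # guard the Re < 0 branch for generality
  flip <- Re(n) < 0
  n[flip] <- -n[flip]
  n
}

#' Complex wavenumber k = k0 sqrt(eps*)
#'
#' @param frequency Hz.
#' @param eps complex permittivity.
#' @param const constants registry.
#' @return complex rad m-1 with Im k <= 0, so e^{-jkz} decays with depth.
#' @export
complex_wavenumber <- function(frequency, eps, const = dosimetry_constants()) {
  stopifnot(frequency > 0)
  (2 * pi * frequency / const$c0) * refractive_index(eps)
}

#' Fresnel elementary reflection coefficient at one interface
#'
#' r = (n_upper - n_lower) / (n_upper + n_lower) for normal incidence.
#'
#' @param n_upper,n_lower complex refractive indices of the media above and
#'   below the interface.
#' @return complex reflection coefficient.
#' @export
elementary_reflection <- function(n_upper, n_lower) {
  den <- n_upper + n_lower
  if (any(abs(den) < 1e-300)) stop("degenerate interface: n_upper + n_lower = 0")
  (n_upper - n_lower) / den
}

#' Amplitude penetration depth
#'
#' Depth at which a plane wave's field amplitude decays to 1/e in an unbounded
#' medium: 1/(k0 |Im n|).
#'
#' @param eps complex permittivity with eps'' > 0.
#' @param frequency Hz.
#' @param const constants registry.
#' @return m; `Inf` with a warning for lossless media.
#' @export
penetration_depth <- function(eps, frequency, const = dosimetry_constants()) {
  n <- refractive_index(eps)
  k0 <- 2 * pi * frequency / const$c0
  if (abs(Im(n)) == 0) {
    warning("lossless medium: penetration depth is infinite")
    return(Inf)
  }
  1 / (k0 * abs(Im(n)))
}

#' Solve the stratified plane-wave problem
#'
#' Builds the cascade reflection coefficients by the inward-to-outward
#' recursion R_i = (r_i + R_{i+1} p) / (1 + r_i R_{i+1} p),
#' p = e^{-2 j k_{i+1} h_{i+1}}, with no reflection returned by the terminal
#' semi-infinite layer, then propagates the forward/backward amplitudes from
#' the incident field. The ambient medium is air unless `eps_ambient` is
#' overridden (used for the no-reflection diagnostic where the ambient is
#' assigned the ED permittivity).
#'
#' @param stack a [tissue_stack()] (its EM view is used).
#' @param exposure a [plane_wave()]; defaults to the stack frequency at
#'   10 W m-2.
#' @param eps_ambient complex permittivity of the ambient half-space.
#' @param const constants registry.
#' @return an `em_fields` object: layer names/boundaries, wavenumbers,
#'   elementary (`r`) and cascade (`R`) reflection coefficients, forward
#'   amplitude `A` and backward/forward ratio `B` at each layer top, incident
#'   amplitude `E0`, and the stack frequency.
#' @export
em_solve <- function(stack, exposure = plane_wave(stack$frequency, 10),
                     eps_ambient = 1 + 0i, const = dosimetry_constants()) {
  stopifnot(inherits(stack, "tissue_stack"))
  if (abs(exposure$frequency - stack$frequency) > 1e-6 * stack$frequency) {
    stop("exposure frequency does not match the stack's tabulation frequency")
  }
  layers <- stack$em
  eps <- c(as.complex(eps_ambient), layer_eps(layers))
  h <- c(Inf, layer_field(layers, "thickness"))
  nm <- c("ambient", layer_names(layers))
  N <- length(eps)
  n <- refractive_index(eps)
  k0 <- 2 * pi * exposure$frequency / const$c0
  k <- k0 * n

  r <- elementary_reflection(n[-N], n[-1])      # interfaces 1..N-1
  R <- complex(N - 1)
  R[N - 1] <- r[N - 1]
  if (N > 2) {
    for (j in (N - 2):1) {
      p <- exp(-2i * k[j + 1] * h[j + 1])
      R[j] <- (r[j] + R[j + 1] * p) / (1 + r[j] * R[j + 1] * p)
    }
  }

  # B[i]: backward/forward amplitude ratio at the top of layer i
  B <- complex(N)
  B[1] <- R[1]
  if (N > 2) for (i in 2:(N - 1)) B[i] <- R[i] * exp(-2i * k[i] * h[i])
  B[N] <- 0

  E0 <- sqrt(2 * const$eta0 * exposure$ipd)     # incident peak amplitude, V/m
  A <- complex(N)
  A[1] <- E0
  for (i in 1:(N - 1)) {
    e_interface <- if (i == 1) A[1] * (1 + R[1]) else
      A[i] * exp(-1i * k[i] * h[i]) * (1 + R[i])
    A[i + 1] <- e_interface / (1 + B[i + 1])
  }

  z_top <- c(-Inf, 0, cumsum(h[2:(N - 1)]))     # global depth of layer tops
  structure(list(frequency = exposure$frequency, ipd = exposure$ipd,
                 names = nm, eps = eps, n = n, k = k, h = h,
                 r = r, R = R, A = A, B = B, E0 = E0, z_top = z_top,
                 const = const),
            class = "em_fields")
}

# index of the layer containing global depth z (z >= 0; interfaces resolve to
# the deeper layer)
.layer_index <- function(sol, z) {
  bounds <- c(sol$z_top[-1], Inf)                    # tops of tissue layers
  pmin(findInterval(z, bounds[-1]) + 2, length(sol$eps))
}

#' Complex total electric field at depth
#'
#' Field (V/m, peak amplitude phasor) at global depths `z >= 0` measured from
#' the ambient/SC interface into tissue. Continuous across all interfaces.
#'
#' @param sol an `em_fields` solution from [em_solve()].
#' @param z numeric vector of depths, m, >= 0.
#' @return complex vector E(z).
#' @export
field_at <- function(sol, z) {
  stopifnot(inherits(sol, "em_fields"), all(z >= 0))
  i <- .layer_index(sol, z)
  zeta <- z - sol$z_top[i]
  sol$A[i] * (exp(-1i * sol$k[i] * zeta) + sol$B[i] * exp(1i * sol$k[i] * zeta))
}

#' Field profile relative to the incident amplitude
#'
#' @param stack a [tissue_stack()].
#' @param depth numeric vector of depths, m, >= 0.
#' @param exposure a [plane_wave()].
#' @param const constants registry.
#' @return complex vector E(z)/E0+.
#' @export
field_profile <- function(stack, depth,
                          exposure = plane_wave(stack$frequency, 10),
                          const = dosimetry_constants()) {
  sol <- em_solve(stack, exposure, const = const)
  field_at(sol, depth) / sol$E0
}

#' Cascade reflection coefficients of a stack
#'
#' @param stack a [tissue_stack()].
#' @param const constants registry.
#' @return complex vector, one total reflection coefficient per interface from
#'   the ambient/SC interface inward.
#' @export
cascade_reflection <- function(stack, const = dosimetry_constants()) {
  em_solve(stack, plane_wave(stack$frequency, 1), const = const)$R
}

#' Power transmission coefficient TC = 1 - |R0|^2
#'
#' Fraction of the incident power transferred into the body.
#'
#' @param stack a [tissue_stack()].
#' @param const constants registry.
#' @return dimensionless in [0, 1].
#' @export
transmission_coefficient <- function(stack, const = dosimetry_constants()) {
  R0 <- cascade_reflection(stack, const)[1]
  1 - Mod(R0)^2
}

#' Absorbed (epithelial) power density APD = TC x IPD
#'
#' @param tc power transmission coefficient in [0, 1].
#' @param ipd incident power density, W m-2.
#' @return W m-2.
#' @export
absorbed_power_density <- function(tc, ipd) {
  stopifnot(tc >= 0, tc <= 1, ipd >= 0)
  tc * ipd
}

# time-averaged Poynting flux (W m-2) at global depths z >= 0
.poynting_at <- function(sol, z) {
  i <- .layer_index(sol, z)
  zeta <- z - sol$z_top[i]
  fw <- exp(-1i * sol$k[i] * zeta)
  bw <- sol$B[i] * exp(1i * sol$k[i] * zeta)
  0.5 * Mod(sol$A[i])^2 / sol$const$eta0 *
    Re(Conj(sol$n[i]) * (fw + bw) * Conj(fw - bw))
}

#' SAR at depth
#'
#' SAR(z) = sigma_i |E(z)|^2 / (2 rho_i) with sigma_i = 2 pi f eps0 eps''_i of
#' the layer containing z (|E| is the peak amplitude, hence the factor 2 for
#' the rms value).
#'
#' @param stack a [tissue_stack()].
#' @param depth numeric vector, m, >= 0.
#' @param exposure a [plane_wave()].
#' @param const constants registry.
#' @return W kg-1.
#' @export
sar_at <- function(stack, depth, exposure = plane_wave(stack$frequency, 10),
                   const = dosimetry_constants()) {
  sol <- em_solve(stack, exposure, const = const)
  .sar_from_sol(sol, stack, depth)
}

.sar_from_sol <- function(sol, stack, depth) {
  i <- .layer_index(sol, depth)
  sigma <- conductivity(sol$eps, sol$frequency, sol$const)
  rho <- c(NA_real_, layer_field(stack$em, "rho"))
  E2 <- Mod(field_at(sol, depth))^2
  sigma[i] * E2 / (2 * rho[i])
}

#' SAR depth profile and peak
#'
#' Evaluates SAR at every interface (from the deeper side, where the jump
#' sigma/rho applies) and on a dense in-layer grid, and locates the global
#' peak.
#'
#' @param stack a [tissue_stack()].
#' @param exposure a [plane_wave()].
#' @param dz grid step, m (default 1 um).
#' @param max_depth deepest sample, m.
#' @param const constants registry.
#' @return list with `depth`, `sar` vectors and `peak` (value, depth, layer).
#' @export
sar_profile <- function(stack, exposure = plane_wave(stack$frequency, 10),
                        dz = 1e-6, max_depth = NULL,
                        const = dosimetry_constants()) {
  h <- layer_field(stack$em, "thickness")
  finite_depth <- sum(h[is.finite(h)])
  if (is.null(max_depth)) {
    mus_eps <- stack$em[[length(stack$em)]]$eps
    max_depth <- finite_depth +
      5 * penetration_depth(mus_eps, stack$frequency, const)
  }
  bounds <- c(0, cumsum(h[is.finite(h)]))
  depth <- sort(unique(c(seq(0, max_depth, by = dz), bounds,
                         pmin(bounds + 1e-12, max_depth))))
  sol <- em_solve(stack, exposure, const = const)
  sar <- .sar_from_sol(sol, stack, depth)
  imax <- which.max(sar)
  lay <- .layer_index(sol, depth[imax]) - 1L
  list(depth = depth, sar = sar,
       peak = list(value = sar[imax], depth = depth[imax],
                   layer = layer_names(stack$em)[lay]))
}

#' Peak SAR of a stack
#'
#' @inheritParams sar_profile
#' @return list(value, depth, layer).
#' @export
peak_sar <- function(stack, exposure = plane_wave(stack$frequency, 10),
                     dz = 1e-6, const = dosimetry_constants()) {
  sar_profile(stack, exposure, dz = dz, const = const)$peak
}

#' Per-layer absorbed power fractions
#'
#' Fraction of the power transmitted into tissue dissipated in each EM layer,
#' computed as the difference of time-averaged Poynting fluxes across the
#' layer; the terminal muscle absorbs the residual flux entering it. The
#' fractions sum to 1.
#'
#' @param stack a [tissue_stack()].
#' @param const constants registry.
#' @return named numeric vector of fractions.
#' @export
layer_power_fractions <- function(stack, const = dosimetry_constants()) {
  sol <- em_solve(stack, plane_wave(stack$frequency, 10), const = const)
  h <- layer_field(stack$em, "thickness")
  bounds <- c(0, cumsum(h[is.finite(h)]))
  S <- .poynting_at(sol, bounds)
  absorbed <- c(-diff(S), S[length(S)])
  fr <- absorbed / S[1]
  names(fr) <- layer_names(stack$em)
  fr
}

# per-layer absorbed power by closed-form depth integration of sigma|E|^2/2
# (independent of the Poynting route; used as an internal cross-check)
.layer_power_integral <- function(sol, stack) {
  h <- c(Inf, layer_field(stack$em, "thickness"))
  sigma <- conductivity(sol$eps, sol$frequency, sol$const)
  N <- length(sol$eps)
  out <- numeric(N - 1)
  int_e <- function(g, hh) {          # integral of e^{g z} on [0, hh]
    if (abs(g) < 1e-14) return(if (is.finite(hh)) hh + 0i else Inf + 0i)
    if (is.finite(hh)) (exp(g * hh) - 1) / g else {
      if (Re(g) < 0) -1 / g else Inf + 0i
    }
  }
  for (i in 2:N) {
    if (sigma[i] == 0) { out[i - 1] <- 0; next }
    k <- sol$k[i]; kr <- Re(k); ki <- Im(k)
    A2 <- Mod(sol$A[i])^2; B <- sol$B[i]
    hi <- h[i]
    val <- Re(int_e(2 * ki + 0i, hi))
    if (Mod(B) > 0) {
      val <- val + Mod(B)^2 * Re(int_e(-2 * ki + 0i, hi)) +
        Re(2 * Conj(B) * int_e(-2i * kr, hi))
    }
    out[i - 1] <- sigma[i] / 2 * A2 * val
  }
  names(out) <- layer_names(stack$em)
  out
}

#' Full electromagnetic dosimetry summary
#'
#' @param stack a [tissue_stack()].
#' @param exposure a [plane_wave()].
#' @param dz peak-search grid step, m.
#' @param const constants registry.
#' @return an `em_result` list: `tc`, `apd`, `peak_sar`, `peak_sar_depth`,
#'   `peak_sar_layer`, `fractions`, `R0`, plus the inputs.
#' @export
em_result <- function(stack, exposure = plane_wave(stack$frequency, 10),
                      dz = 1e-6, const = dosimetry_constants()) {
  sol <- em_solve(stack, exposure, const = const)
  tc <- 1 - Mod(sol$R[1])^2
  pk <- peak_sar(stack, exposure, dz = dz, const = const)
  structure(list(frequency = stack$frequency, ipd = exposure$ipd,
                 tc = tc, apd = absorbed_power_density(tc, exposure$ipd),
                 peak_sar = pk$value, peak_sar_depth = pk$depth,
                 peak_sar_layer = pk$layer,
                 fractions = layer_power_fractions(stack, const),
                 R0 = sol$R[1]),
            class = "em_result")
}

#' Peak SAR with the air/skin reflection removed
#'
#' Re-solves the stack with the ambient permittivity set to the ED value, so
#' no mismatch exists at the surface, and returns the resulting peak SAR
#' normalised by the with-reflection peak.
#'
#' @param stack a [tissue_stack()].
#' @param exposure a [plane_wave()].
#' @param dz peak-search grid step, m.
#' @param const constants registry.
#' @return list(peak_sar, normalized) where `normalized` is the no-reflection
#'   peak divided by the with-reflection peak.
#' @export
no_reflection_peak_sar <- function(stack,
                                   exposure = plane_wave(stack$frequency, 10),
                                   dz = 1e-6, const = dosimetry_constants()) {
  ed_idx <- match("ED", layer_names(stack$em))
  if (is.na(ed_idx)) ed_idx <- 2L
  eps_ed <- stack$em[[ed_idx]]$eps
  sol_nr <- em_solve(stack, exposure, eps_ambient = eps_ed, const = const)
  h <- layer_field(stack$em, "thickness")
  bounds <- c(0, cumsum(h[is.finite(h)]))
  mus_eps <- stack$em[[length(stack$em)]]$eps
  max_depth <- bounds[length(bounds)] +
    5 * penetration_depth(mus_eps, stack$frequency, const)
  depth <- sort(unique(c(seq(0, max_depth, by = dz), bounds)))
  sar_nr <- .sar_from_sol(sol_nr, stack, depth)
  pk_nr <- max(sar_nr)
  pk <- peak_sar(stack, exposure, dz = dz, const = const)$value
  list(peak_sar = pk_nr, normalized = pk_nr / pk)
}
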