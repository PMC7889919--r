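#' @title Steady-state multilayer Pennes bioheat solver
#' @description Analytic solution of lambda_i T_i'' = B_i (T_i - T_blood) -
#'   rho_i SAR_i(z_i) over the five-layer thermal stack with temperature and
#'   heat-flux continuity at interfaces, a convective (Robin) surface
#'   condition and T -> T_blood at depth. The electromagnetic heating enters
#'   as a sum of complex-exponential terms per layer, so the particular
#'   solutions are obtained in closed form by undetermined coefficients (with
#'   a polynomial lift in the resonant case). A finite-difference reference
#'   solver on a truncated domain serves as an independent numerical check.
#' @name thermal_solver
NULL

#' Thermal boundary conditions
#'
#' @param h_convective air-skin heat transfer coefficient, W m-2 degC-1.
#' @param T_air ambient temperature, degC.
#' @param T_blood arterial blood temperature, degC.
#' @return a `thermal_boundary` list.
#' @export
thermal_boundary <- function(h_convective = dosimetry_constants()$h_conv,
                             T_air = dosimetry_constants()$T_air,
                             T_blood = dosimetry_constants()$T_blood) {
  stopifnot(h_convective >= 0)
  structure(list(h = h_convective, T_air = T_air, T_blood = T_blood),
            class = "thermal_boundary")
}

.thermal_tops <- function(layers) {
  h <- layer_field(layers, "thickness")
  c(0, cumsum(h[is.finite(h)]))
}

#' Volumetric heat source over a thermal stack
#'
#' Represents q(z) = rho_i SAR_i(z) as, per thermal layer, a sum of terms
#' Re(c e^{gamma zeta}) in the layer-local coordinate zeta.
#'
#' @param stack a [tissue_stack()].
#' @param terms list (one element per thermal layer) of lists with complex
#'   fields `c` (W m-3) and `gamma` (m-1).
#' @return a `volumetric_source` with an evaluator `q(z)` in global depth.
#' @export
volumetric_source <- function(stack, terms) {
  layers <- stack$thermal
  stopifnot(length(terms) == length(layers))
  z_top <- .thermal_tops(layers)
  q <- function(z) {
    stopifnot(all(z >= 0))
    i <- pmin(findInterval(z, z_top[-1]) + 1L, length(layers))
    zeta <- z - z_top[i]
    out <- numeric(length(z))
    for (li in unique(i)) {
      sel <- i == li
      acc <- 0
      for (tm in terms[[li]]) {
        acc <- acc + Re(tm$c * exp(tm$gamma * zeta[sel]))
      }
      out[sel] <- acc
    }
    out
  }
  structure(list(terms = terms, z_top = z_top, q = q),
            class = "volumetric_source")
}

#' Uniform volumetric source (constant q0 in every layer)
#'
#' @param stack a [tissue_stack()].
#' @param q0 W m-3.
#' @return a [volumetric_source()].
#' @export
uniform_source <- function(stack, q0) {
  terms <- lapply(stack$thermal, function(l) list(list(c = q0 + 0i, gamma = 0 + 0i)))
  volumetric_source(stack, terms)
}

#' Electromagnetic heat source rho SAR(z) for the thermal stack
#'
#' Expands sigma |E(z)|^2 / 2 of the plane-wave solution into the
#' complex-exponential terms of each thermal layer (the viable epidermis and
#' dermis share the ED field).
#'
#' @param stack a [tissue_stack()].
#' @param exposure a [plane_wave()].
#' @param const constants registry.
#' @return a [volumetric_source()].
#' @export
em_source <- function(stack, exposure = plane_wave(stack$frequency, 10),
                      const = dosimetry_constants()) {
  sol <- em_solve(stack, exposure, const = const)
  sigma <- conductivity(sol$eps, sol$frequency, const)
  z_top_th <- .thermal_tops(stack$thermal)
  terms <- vector("list", length(stack$thermal))
  for (t in seq_along(stack$thermal)) {
    zt <- z_top_th[t]
    e <- .layer_index(sol, zt)                  # EM layer containing this slab
    offset <- zt - sol$z_top[e]
    k <- sol$k[e]; kr <- Re(k); ki <- Im(k)
    A2 <- Mod(sol$A[e])^2; B <- sol$B[e]; sg <- sigma[e]
    base <- list(list(c = sg / 2 * A2 + 0i, gamma = 2 * ki + 0i))
    if (Mod(B) > 0) {
      base <- c(base,
                list(list(c = sg / 2 * A2 * Mod(B)^2 + 0i, gamma = -2 * ki + 0i),
                     list(c = sg * A2 * Conj(B), gamma = -2i * kr)))
    }
    terms[[t]] <- lapply(base, function(tm) {
      list(c = tm$c * exp(tm$gamma * offset), gamma = tm$gamma)
    })
  }
  volumetric_source(stack, terms)
}

# particular solution terms for one layer: for each source term Re(c e^{g z})
# of lambda u'' - B u = -q, returns list(d, gamma, lift) with
# u_p = sum Re(d z^lift e^{g z})
.particular_terms <- function(terms, lambda, B, resonance_tol = 1e-6) {
  lapply(terms, function(tm) {
    g <- tm$gamma
    m <- sqrt(B / lambda)
    resonant <- abs(Im(g)) < 1e-9 &&
      min(abs(Re(g) - m), abs(Re(g) + m)) < resonance_tol
    if (abs(g) < 1e-12 && B == 0) {
      list(d = -tm$c / (2 * lambda), gamma = g, lift = 2L)
    } else if (resonant && B > 0) {
      list(d = -tm$c / (2 * lambda * g), gamma = g, lift = 1L)
    } else {
      list(d = -tm$c / (lambda * g^2 - B), gamma = g, lift = 0L)
    }
  })
}

.part_eval <- function(pterms, zeta) {
  out <- numeric(length(zeta))
  for (p in pterms) {
    out <- out + Re(p$d * zeta^p$lift * exp(p$gamma * zeta))
  }
  out
}

.part_deval <- function(pterms, zeta) {
  out <- numeric(length(zeta))
  for (p in pterms) {
    poly <- if (p$lift == 0L) p$gamma else
      p$lift * zeta^(p$lift - 1L) + p$gamma * zeta^p$lift
    out <- out + Re(p$d * poly * exp(p$gamma * zeta))
  }
  out
}

# homogeneous basis values/derivatives for a layer at local zeta
.hom_basis <- function(lambda, B, zeta, terminal = FALSE) {
  if (terminal) {
    m <- sqrt(B / lambda)
    list(phi = cbind(exp(-m * zeta)), dphi = cbind(-m * exp(-m * zeta)))
  } else if (B > 0) {
    m <- sqrt(B / lambda)
    list(phi = cbind(exp(m * zeta), exp(-m * zeta)),
         dphi = cbind(m * exp(m * zeta), -m * exp(-m * zeta)))
  } else {
    list(phi = cbind(rep(1, length(zeta)), zeta),
         dphi = cbind(rep(0, length(zeta)), rep(1, length(zeta))))
  }
}

#' Solve the steady-state multilayer bioheat problem
#'
#' Computes the absolute temperature profile T(z) (for `difference = FALSE`)
#' or the exposure-induced elevation profile with homogeneous boundary data
#' (`difference = TRUE`, i.e. the linear difference problem whose solution is
#' T_exposed - T_baseline).
#'
#' @param stack a [tissue_stack()] whose thermal view ends in a perfused
#'   semi-infinite layer.
#' @param source a [volumetric_source()]; use `NULL` for no heating.
#' @param bc a [thermal_boundary()].
#' @param difference logical; solve the elevation problem instead of the
#'   absolute one.
#' @return a `temperature_solution`: per-layer coefficients, particular terms,
#'   boundaries, and the offset (T_blood or 0) added to the homogeneous
#'   variable. Evaluate with [temperature_at()].
#' @export
solve_steady_bioheat <- function(stack, source = NULL,
                                 bc = thermal_boundary(),
                                 difference = FALSE) {
  layers <- stack$thermal
  M <- length(layers)
  lam <- layer_field(layers, "lambda")
  Bv <- layer_field(layers, "perfusion")
  hv <- layer_field(layers, "thickness")
  if (anyNA(lam) || anyNA(Bv)) stop("thermal view lacks lambda/perfusion values")
  if (!(Bv[M] > 0)) {
    stop("terminal layer must be perfused (B > 0) for T to approach T_blood")
  }
  if (is.null(source)) {
    source <- volumetric_source(stack, lapply(seq_len(M), function(i) list()))
  }
  pterms <- lapply(seq_len(M), function(i) {
    .particular_terms(source$terms[[i]], lam[i], Bv[i])
  })

  nun <- 2 * (M - 1) + 1
  Amat <- matrix(0, nun, nun)
  rhs <- numeric(nun)
  col_of <- function(i) if (i < M) (2 * i - 1):(2 * i) else nun

  # convective surface condition lambda_1 T'(0) = h (T(0) - T_air) (heat lost
  # to cooler air, surface coolest point of the baseline profile); in the
  # homogeneous variable u: lambda_1 u'(0) - h u(0) = h (T_blood - T_air),
  # with zero right-hand side for the elevation problem
  b1 <- .hom_basis(lam[1], Bv[1], 0, terminal = (M == 1))
  Amat[1, col_of(1)] <- lam[1] * b1$dphi[1, ] - bc$h * b1$phi[1, ]
  rhs[1] <- (if (difference) 0 else bc$h * (bc$T_blood - bc$T_air)) -
    (lam[1] * .part_deval(pterms[[1]], 0) - bc$h * .part_eval(pterms[[1]], 0))

  if (M > 1) {
    for (i in 1:(M - 1)) {
      bi <- .hom_basis(lam[i], Bv[i], hv[i], terminal = FALSE)
      bn <- .hom_basis(lam[i + 1], Bv[i + 1], 0, terminal = (i + 1 == M))
      rT <- 2 * i
      rF <- 2 * i + 1
      Amat[rT, col_of(i)] <- bi$phi[1, ]
      Amat[rT, col_of(i + 1)] <- Amat[rT, col_of(i + 1)] - bn$phi[1, ]
      rhs[rT] <- .part_eval(pterms[[i + 1]], 0) - .part_eval(pterms[[i]], hv[i])
      Amat[rF, col_of(i)] <- lam[i] * bi$dphi[1, ]
      Amat[rF, col_of(i + 1)] <- Amat[rF, col_of(i + 1)] - lam[i + 1] * bn$dphi[1, ]
      rhs[rF] <- lam[i + 1] * .part_deval(pterms[[i + 1]], 0) -
        lam[i] * .part_deval(pterms[[i]], hv[i])
    }
  }
  coef <- solve(Amat, rhs)

  structure(list(layers = layers, lambda = lam, B = Bv, h = hv,
                 z_top = .thermal_tops(layers), coef = coef,
                 col_of = col_of, pterms = pterms,
                 offset = if (difference) 0 else bc$T_blood,
                 difference = difference, bc = bc),
            class = "temperature_solution")
}

#' Evaluate a temperature solution at depth
#'
#' @param solution a `temperature_solution` from [solve_steady_bioheat()].
#' @param z global depths, m, >= 0.
#' @param derivative logical; return dT/dz instead of T.
#' @return degC (or degC m-1).
#' @export
temperature_at <- function(solution, z, derivative = FALSE) {
  stopifnot(inherits(solution, "temperature_solution"), all(z >= 0))
  M <- length(solution$layers)
  i <- pmin(findInterval(z, solution$z_top[-1]) + 1L, M)
  zeta <- z - solution$z_top[i]
  out <- numeric(length(z))
  for (li in unique(i)) {
    sel <- i == li
    b <- .hom_basis(solution$lambda[li], solution$B[li], zeta[sel],
                    terminal = (li == M))
    cf <- solution$coef[solution$col_of(li)]
    if (derivative) {
      out[sel] <- drop(b$dphi %*% cf) + .part_deval(solution$pterms[[li]], zeta[sel])
    } else {
      out[sel] <- drop(b$phi %*% cf) + .part_eval(solution$pterms[[li]], zeta[sel])
    }
  }
  if (derivative) out else out + solution$offset
}

#' Residuals of the bioheat boundary and interface equations
#'
#' Evaluates, from the piecewise solution itself, the surface convective
#' balance, the temperature and heat-flux jumps at every interface, and the
#' decay of the terminal layer, all in their natural units (degC and W m-2).
#'
#' @param solution a `temperature_solution`.
#' @return named numeric vector of absolute residuals.
#' @export
bioheat_residuals <- function(solution) {
  stopifnot(inherits(solution, "temperature_solution"))
  M <- length(solution$layers)
  lam <- solution$lambda; Bv <- solution$B; hv <- solution$h
  bc <- solution$bc
  val <- function(i, zeta, deriv = FALSE) {
    b <- .hom_basis(lam[i], Bv[i], zeta, terminal = (i == M))
    cf <- solution$coef[solution$col_of(i)]
    hom <- drop((if (deriv) b$dphi else b$phi) %*% cf)
    hom + (if (deriv) .part_deval(solution$pterms[[i]], zeta) else
      .part_eval(solution$pterms[[i]], zeta))
  }
  g <- if (solution$difference) 0 else bc$h * (bc$T_blood - bc$T_air)
  out <- c(surface = abs(lam[1] * val(1, 0, TRUE) - bc$h * val(1, 0) - g))
  if (M > 1) {
    for (i in 1:(M - 1)) {
      out[paste0("T_", i)] <- abs(val(i, hv[i]) - val(i + 1, 0))
      out[paste0("flux_", i)] <- abs(lam[i] * val(i, hv[i], TRUE) -
                                     lam[i + 1] * val(i + 1, 0, TRUE))
    }
  }
  out
}

.peak_search_grid <- function(solution, per_layer = 400) {
  M <- length(solution$layers)
  zt <- solution$z_top
  grids <- list()
  for (i in seq_len(M)) {
    if (i < M) {
      grids[[i]] <- seq(zt[i], zt[i + 1], length.out = per_layer)
    } else {
      decay <- sqrt(solution$lambda[M] / solution$B[M])
      grids[[i]] <- zt[M] + seq(0, 6 * decay, length.out = per_layer)
    }
  }
  sort(unique(c(unlist(grids))))
}

#' Steady-state temperature elevation under plane-wave exposure
#'
#' Solves for the exposure-induced temperature rise either through the linear
#' difference problem (one solve with homogeneous boundary data) or as the
#' difference of the exposed and baseline absolute profiles; the two routes
#' agree to solver precision.
#'
#' @param stack a [tissue_stack()].
#' @param exposure a [plane_wave()].
#' @param bc a [thermal_boundary()].
#' @param method "difference" (default) or "two_solves".
#' @param const constants registry.
#' @return list with `delta_T(z)` evaluator, `peak` (value, depth), the
#'   difference `solution`, and for "two_solves" also `baseline`/`exposed`.
#' @export
temperature_rise <- function(stack, exposure = plane_wave(stack$frequency, 10),
                             bc = thermal_boundary(),
                             method = c("difference", "two_solves"),
                             const = dosimetry_constants()) {
  method <- match.arg(method)
  src <- em_source(stack, exposure, const = const)
  out <- list(method = method)
  if (method == "difference") {
    sol <- solve_steady_bioheat(stack, src, bc, difference = TRUE)
    out$solution <- sol
    out$delta_T <- function(z) temperature_at(sol, z)
  } else {
    base <- solve_steady_bioheat(stack, NULL, bc, difference = FALSE)
    expo <- solve_steady_bioheat(stack, src, bc, difference = FALSE)
    out$baseline <- base
    out$exposed <- expo
    out$solution <- expo
    out$delta_T <- function(z) temperature_at(expo, z) - temperature_at(base, z)
  }
  grid_sol <- if (method == "difference") out$solution else out$baseline
  zg <- .peak_search_grid(grid_sol)
  dT <- out$delta_T(zg)
  imax <- which.max(dT)
  out$peak <- list(value = dT[imax], depth = zg[imax])
  out
}

#' Finite-difference reference bioheat solution
#'
#' Conservative second-order finite differences on a layer-aligned grid with
#' harmonic-mean face conductivities, a second-order Robin surface condition
#' and a Dirichlet condition (T = T_blood, or elevation 0) at a truncation
#' depth well beyond the muscle decay length sqrt(lambda/B) ~ 14 mm. Used as
#' an independent numerical check of the analytic solver.
#'
#' @param stack a [tissue_stack()].
#' @param source a [volumetric_source()] or `NULL`.
#' @param bc a [thermal_boundary()].
#' @param grid_step target node spacing, m, <= 10 um.
#' @param truncation_depth bottom Dirichlet depth, m, >= 0.06.
#' @param difference logical; solve the elevation problem.
#' @return list with grid `z`, values `T`, evaluator `at(z)` (spline
#'   interpolation), and `peak` for the elevation problem.
#' @export
fd_reference_solution <- function(stack, source = NULL,
                                  bc = thermal_boundary(),
                                  grid_step = 5e-6,
                                  truncation_depth = 60e-3,
                                  difference = FALSE) {
  stopifnot(grid_step <= 10e-6, truncation_depth >= 60e-3)
  layers <- stack$thermal
  M <- length(layers)
  lam <- layer_field(layers, "lambda")
  Bv <- layer_field(layers, "perfusion")
  hv <- layer_field(layers, "thickness")
  hv[M] <- truncation_depth - sum(hv[-M])
  stopifnot(hv[M] > 0)
  if (is.null(source)) {
    source <- volumetric_source(stack, lapply(seq_len(M), function(i) list()))
  }

  # layer-aligned grid: uniform within each layer
  z <- 0
  mat <- integer(0)                      # material of interval left of node
  for (i in seq_len(M)) {
    ni <- max(2L, ceiling(hv[i] / grid_step))
    zi <- utils::tail(z, 1) + seq_len(ni) * (hv[i] / ni)
    z <- c(z, zi)
    mat <- c(mat, rep(i, ni))
  }
  n <- length(z)
  dl <- diff(z)                          # interval widths; mat[j] material of interval j

  Tb <- if (difference) 0 else bc$T_blood
  Ta <- if (difference) 0 else bc$T_air
  qs <- function(zz) source$q(pmax(zz, 0))

  ii <- integer(0); jj <- integer(0); xx <- numeric(0); rhs <- numeric(n)
  add <- function(i, j, v) { ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v) }

  # surface node (half cell [0, dl[1]/2])
  d1 <- dl[1]; l1 <- lam[mat[1]]; B1 <- Bv[mat[1]]
  add(1, 1, -l1 / d1 - bc$h - (d1 / 2) * B1)
  add(1, 2, l1 / d1)
  rhs[1] <- -bc$h * Ta - (d1 / 2) * (B1 * Tb + qs(d1 / 4))

  # interior nodes
  iL <- 2:(n - 1)
  dL <- dl[iL - 1]; dR <- dl[iL]
  lamL <- lam[mat[iL - 1]]; lamR <- lam[mat[iL]]
  BL <- Bv[mat[iL - 1]]; BR <- Bv[mat[iL]]
  qL <- qs(z[iL] - dL / 4); qR <- qs(z[iL] + dR / 4)
  wB <- (dL * BL + dR * BR) / 2
  wq <- (dL * qL + dR * qR) / 2
  add(iL, iL - 1, lamL / dL)
  add(iL, iL, -lamL / dL - lamR / dR - wB)
  add(iL, iL + 1, lamR / dR)
  rhs[iL] <- -(wB * Tb + wq)

  # bottom Dirichlet
  add(n, n, 1)
  rhs[n] <- Tb

  Amat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Tz <- as.numeric(Matrix::solve(Amat, rhs))
  at <- stats::splinefun(z, Tz, method = "natural")
  imax <- which.max(Tz)
  list(z = z, T = Tz, at = at,
       peak = list(value = Tz[imax], depth = z[imax]))
}
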