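#' @title Tissue parameters and age models
#' @description Complex tissue permittivities (stored with the e^{+j omega t}
#'   convention, eps* = eps' - j eps''), the Lichtenecker hydration model that
#'   rescales adult permittivities to other ages through total body water, the
#'   forearm dermal blood-flow regression, and constructors for the layered
#'   tissue stacks used by the electromagnetic and thermal solvers.
#' @name tissue_model
NULL

#' Construct a complex tissue permittivity
#'
#' @param eps_real real part eps' (> 1 for any hydrated tissue; > 0 accepted
#'   to allow reference media such as vacuum).
#' @param eps_imag loss part eps'' supplied positive; the physical quantity is
#'   eps* = eps' - j eps''.
#' @return complex scalar eps* = eps' - 1i * eps''.
#' @export
permittivity <- function(eps_real, eps_imag) {
  stopifnot(is.numeric(eps_real), is.numeric(eps_imag),
            eps_real > 0, eps_imag >= 0)
  complex(real = eps_real, imaginary = -eps_imag)
}

#' Loss tangent eps''/eps' of a complex permittivity
#' @param eps complex permittivity eps* = eps' - j eps''.
#' @return dimensionless eps''/eps'.
#' @export
loss_tangent <- function(eps) -Im(eps) / Re(eps)

#' Conductivity from the loss part of the permittivity
#'
#' sigma = 2 pi f eps0 eps''.
#'
#' @param eps complex permittivity.
#' @param frequency Hz.
#' @param const constants registry.
#' @return S m-1.
#' @export
conductivity <- function(eps, frequency, const = dosimetry_constants()) {
  2 * pi * frequency * const$eps0 * (-Im(eps))
}

#' Hydration rate alpha = TBW * rho
#'
#' TBW is the total body water per unit body mass (L kg-1, numerically the
#' water mass fraction); rho is the tissue density in g cm-3, so alpha is the
#' dimensionless water volume fraction of the tissue.
#'
#' @param tbw total body water, L kg-1, >= 0.
#' @param density tissue mass density, g cm-3, > 0.
#' @return dimensionless alpha in [0, 1).
#' @export
hydration_rate <- function(tbw, density) {
  stopifnot(is.numeric(tbw), is.numeric(density), tbw >= 0, density > 0)
  alpha <- tbw * density
  if (any(alpha >= 1)) {
    stop(sprintf(
      "unphysical hydration rate alpha = %.4f >= 1 (tbw = %.4f, density = %.4f g/cm3)",
      max(alpha), tbw[which.max(alpha)][1], density[which.max(alpha)][1]))
  }
  alpha
}

#' Age-rescaled complex permittivity (Lichtenecker hydration model)
#'
#' The real part follows the logarithmic mixing rule between free water and
#' the organic tissue matrix; eliminating the unknown matrix permittivity in
#' favour of the adult value gives
#' eps* = eps'_W^((alpha - alpha_A)/(1 - alpha_A)) *
#'        eps'_A^((1 - alpha)/(1 - alpha_A)) * (1 - j eps''_A/eps'_A).
#' The loss tangent is age-invariant by construction, so the output's
#' eps''/eps' equals the adult loss tangent exactly.
#'
#' @param eps_adult adult complex permittivity eps*_A.
#' @param eps_water_real real part of the free-water permittivity at the same
#'   frequency.
#' @param alpha hydration rate at the target age, in [0, 1).
#' @param alpha_adult adult hydration rate, in (0, 1).
#' @return complex permittivity at the target age.
#' @export
age_permittivity <- function(eps_adult, eps_water_real, alpha, alpha_adult) {
  stopifnot(is.numeric(eps_water_real), eps_water_real > 0,
            alpha >= 0, alpha < 1, alpha_adult > 0)
  if (alpha_adult >= 1) {
    stop("alpha_adult must be < 1: the mixing exponent is singular at 1")
  }
  eps_real_adult <- Re(eps_adult)
  tan_delta <- loss_tangent(eps_adult)
  e_w <- (alpha - alpha_adult) / (1 - alpha_adult)
  e_a <- (1 - alpha) / (1 - alpha_adult)
  eps_real <- eps_water_real^e_w * eps_real_adult^e_a
  complex(real = eps_real, imaginary = -eps_real * tan_delta)
}

#' Dermal blood flow vs age (forearm, resting conditions)
#'
#' Linear regression BF_D(age) = 6.033e-4 - age * 3.55e-6 in s-1 (volumetric
#' blood flow rate). The fit covers resting forearm skin; ages outside 0-120
#' years are rejected.
#'
#' @param age years, in [0, 120].
#' @return volumetric blood flow rate, s-1.
#' @export
blood_flow_dermis <- function(age) {
  stopifnot(is.numeric(age))
  if (any(age < 0 | age > 120)) {
    stop("age outside the supported 0-120 year range of the forearm regression")
  }
  bf <- 6.033e-4 - age * 3.55e-6
  if (any(bf < 0)) stop("regression yields negative blood flow")
  bf
}

#' Blood perfusion coefficient B = BF * rho_b * C_b
#'
#' Converts a volumetric blood flow rate (s-1) into the heat-sink coefficient
#' of the Pennes equation (W m-3 degC-1).
#'
#' @param bf volumetric blood flow rate, s-1, >= 0.
#' @param const constants registry (blood density and specific heat).
#' @return W m-3 degC-1.
#' @export
perfusion_coefficient <- function(bf, const = dosimetry_constants()) {
  stopifnot(is.numeric(bf), all(bf >= 0))
  bf * const$rho_blood * const$c_blood
}

#' One tissue stratum
#'
#' @param name label.
#' @param thickness m; `Inf` marks the semi-infinite terminal layer.
#' @param eps complex permittivity eps* = eps' - j eps'' at the working
#'   frequency.
#' @param lambda thermal conductivity, W m-1 degC-1.
#' @param rho mass density, kg m-3.
#' @param perfusion blood perfusion coefficient B, W m-3 degC-1.
#' @return a `tissue_layer` list.
#' @export
tissue_layer <- function(name, thickness, eps, lambda = NA_real_,
                         rho = NA_real_, perfusion = NA_real_) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(thickness), thickness > 0,
            is.complex(eps) || is.numeric(eps))
  if (!is.na(lambda)) stopifnot(lambda > 0)
  if (!is.na(rho)) stopifnot(rho > 0)
  if (!is.na(perfusion)) stopifnot(perfusion >= 0)
  structure(list(name = name, thickness = thickness, eps = as.complex(eps),
                 lambda = lambda, rho = rho, perfusion = perfusion),
            class = "tissue_layer")
}

layer_field <- function(layers, field) vapply(layers, `[[`, numeric(1), field)
layer_eps <- function(layers) vapply(layers, `[[`, complex(1), "eps")
layer_names <- function(layers) vapply(layers, `[[`, character(1), "name")

#' Ordered tissue stack with electromagnetic and thermal views
#'
#' The electromagnetic view merges the viable epidermis and dermis (same water
#' content, hence same permittivity) into a single ED layer; the thermal view
#' keeps them separate because only the dermis is perfused. Both views span
#' identical depths and end in one semi-infinite layer.
#'
#' @param em_layers list of [tissue_layer()] from the outer surface inward
#'   (last layer `Inf` thick).
#' @param thermal_layers list of [tissue_layer()] for the thermal partition.
#' @param frequency Hz at which the permittivities are tabulated.
#' @return a `tissue_stack` list with elements `em`, `thermal`, `frequency`.
#' @export
tissue_stack <- function(em_layers, thermal_layers, frequency) {
  check_view <- function(layers, what) {
    th <- layer_field(layers, "thickness")
    if (!all(is.finite(th[-length(th)])) || is.finite(th[length(th)])) {
      stop(what, " view must have exactly one terminal semi-infinite layer, last")
    }
  }
  check_view(em_layers, "EM")
  check_view(thermal_layers, "thermal")
  d_em <- sum(layer_field(em_layers, "thickness")[seq_len(length(em_layers) - 1)])
  d_th <- sum(layer_field(thermal_layers, "thickness")[seq_len(length(thermal_layers) - 1)])
  if (abs(d_em - d_th) > 1e-12) {
    stop("EM and thermal views disagree on total finite depth: ",
         d_em, " vs ", d_th, " m")
  }
  structure(list(em = em_layers, thermal = thermal_layers,
                 frequency = frequency),
            class = "tissue_stack")
}

#' @export
print.tissue_stack <- function(x, ...) {
  cat(sprintf("tissue_stack at %.3g GHz\n", x$frequency / 1e9))
  for (view in c("em", "thermal")) {
    cat(" ", view, "view:\n")
    for (l in x[[view]]) {
      cat(sprintf("    %-16s h = %-9s eps = %.2f - j%.2f", l$name,
                  ifelse(is.finite(l$thickness),
                         sprintf("%.3f mm", l$thickness * 1e3), "semi-inf"),
                  Re(l$eps), -Im(l$eps)))
      if (!is.na(l$lambda)) {
        cat(sprintf("  lambda = %.2f rho = %4.0f B = %.1f", l$lambda, l$rho,
                    l$perfusion))
      }
      cat("\n")
    }
  }
  invisible(x)
}

# Tabulated adult tissue properties at the two working frequencies:
# permittivities for stratum corneum, ED (viable epidermis + dermis), fat and
# muscle, layer thicknesses, and the thermal columns (conductivity, density,
# perfusion). SC and fat/muscle permittivities follow the standard adult
# dielectric compilations; ED uses dry-skin values.
adult_tissue_table <- function() {
  list(
    sc     = list(eps = list(`26` = permittivity(3.62, 0.74),
                             `60` = permittivity(3.15, 0.50)),
                  thickness = 0.015e-3, lambda = 0.37, rho = 1500, B = 0),
    ed     = list(eps = list(`26` = permittivity(17.71, 16.87),
                             `60` = permittivity(7.98, 10.90)),
                  thickness = 1.396e-3, lambda = 0.37, rho = 1109, B = NA),
    fat    = list(eps = list(`26` = permittivity(3.76, 1.10),
                             `60` = permittivity(3.13, 0.84)),
                  thickness = 4e-3, lambda = 0.21, rho = 911, B = 1900),
    muscle = list(eps = list(`26` = permittivity(25.85, 21.84),
                             `60` = permittivity(12.86, 15.83)),
                  thickness = Inf, lambda = 0.49, rho = 1090, B = 2550)
  )
}

freq_key <- function(frequency) {
  key <- as.character(round(frequency / 1e9))
  if (!key %in% c("26", "60")) {
    stop("built-in permittivities cover 26 and 60 GHz only; supply ",
         "permittivity overrides for other frequencies")
  }
  key
}

# Split an ED slab into (viable epidermis, dermis) thicknesses. Default:
# 0.060 mm unperfused viable epidermis on top, remainder perfused dermis.
# literal_table_split reproduces the printed-table reading (1.396 mm viable
# epidermis over a 0.060 mm dermis).
split_ed <- function(ed_thickness, literal_table_split = FALSE) {
  if (literal_table_split) {
    c(ve = 1.396e-3, dermis = 0.060e-3)
  } else {
    if (ed_thickness <= 0.060e-3) {
      stop("ED thickness must exceed the 0.060 mm viable epidermis")
    }
    c(ve = 0.060e-3, dermis = ed_thickness - 0.060e-3)
  }
}

build_stack_from_parts <- function(frequency, eps, ed_thickness, dermal_B,
                                   literal_table_split = FALSE) {
  tab <- adult_tissue_table()
  sp <- split_ed(ed_thickness, literal_table_split)
  ed_total <- unname(sp["ve"] + sp["dermis"])
  em <- list(
    tissue_layer("SC", tab$sc$thickness, eps$sc, tab$sc$lambda, tab$sc$rho, 0),
    tissue_layer("ED", ed_total, eps$ed, tab$ed$lambda, tab$ed$rho, 0),
    tissue_layer("fat", tab$fat$thickness, eps$fat, tab$fat$lambda,
                 tab$fat$rho, tab$fat$B),
    tissue_layer("muscle", Inf, eps$muscle, tab$muscle$lambda, tab$muscle$rho,
                 tab$muscle$B)
  )
  thermal <- list(
    tissue_layer("SC", tab$sc$thickness, eps$sc, tab$sc$lambda, tab$sc$rho, 0),
    tissue_layer("viable_epidermis", unname(sp["ve"]), eps$ed, tab$ed$lambda,
                 tab$ed$rho, 0),
    tissue_layer("dermis", unname(sp["dermis"]), eps$ed, tab$ed$lambda,
                 tab$ed$rho, dermal_B),
    tissue_layer("fat", tab$fat$thickness, eps$fat, tab$fat$lambda,
                 tab$fat$rho, tab$fat$B),
    tissue_layer("muscle", Inf, eps$muscle, tab$muscle$lambda, tab$muscle$rho,
                 tab$muscle$B)
  )
  tissue_stack(em, thermal, frequency)
}

#' Adult reference tissue stack
#'
#' Four-layer electromagnetic partition (SC, ED, fat, semi-infinite muscle)
#' and five-layer thermal partition (SC, viable epidermis, dermis, fat,
#' muscle) with tabulated adult properties. Dermal perfusion is evaluated at
#' the given age through the blood-flow regression.
#'
#' @param frequency Hz; built-in permittivities exist at 26 and 60 GHz.
#' @param age years; sets dermal perfusion only (default: adult reference).
#' @param ed_thickness m, total viable epidermis + dermis thickness.
#' @param literal_table_split logical; see [tissue_stack()] details above.
#' @param const constants registry.
#' @return a [tissue_stack()].
#' @export
build_adult_stack <- function(frequency, age = dosimetry_constants()$adult_age,
                              ed_thickness = 1.396e-3,
                              literal_table_split = FALSE,
                              const = dosimetry_constants()) {
  key <- freq_key(frequency)
  tab <- adult_tissue_table()
  eps <- lapply(tab, function(t) t$eps[[key]])
  dermal_B <- perfusion_coefficient(blood_flow_dermis(age), const)
  build_stack_from_parts(frequency, eps, ed_thickness, dermal_B,
                         literal_table_split)
}

#' Age-specific tissue stack
#'
#' Rescales the ED, fat and muscle permittivities with the hydration model
#' (the thin stratum corneum keeps its adult permittivity: its state is set by
#' environment and physiology, not age), sets the ED thickness from the age
#' table and the dermal perfusion from the blood-flow regression.
#'
#' @param age years.
#' @param frequency Hz.
#' @param tables an `age_tables` set (see [make_age_tables()]) providing
#'   `skin_thickness_mm` and `tbw`.
#' @param eps_water_real real free-water permittivity at `frequency`; default
#'   from the Debye water model.
#' @param literal_table_split logical, see [build_adult_stack()].
#' @param const constants registry (adult reference age and TBW).
#' @return a [tissue_stack()].
#' @export
build_age_stack <- function(age, frequency, tables,
                            eps_water_real = water_permittivity_real(frequency, const),
                            literal_table_split = FALSE,
                            const = dosimetry_constants()) {
  key <- freq_key(frequency)
  tab <- adult_tissue_table()
  tbw <- eval_age_table(tables$tbw, age)
  tbw_adult <- eval_age_table(tables$tbw, const$adult_age)
  ed_thickness <- eval_age_table(tables$skin_thickness_mm, age) * 1e-3
  eps <- list(sc = tab$sc$eps[[key]])
  for (tis in c("ed", "fat", "muscle")) {
    rho_gcm3 <- tab[[tis]]$rho / 1000
    eps[[tis]] <- age_permittivity(
      tab[[tis]]$eps[[key]], eps_water_real,
      alpha = hydration_rate(tbw, rho_gcm3),
      alpha_adult = hydration_rate(tbw_adult, rho_gcm3))
  }
  dermal_B <- perfusion_coefficient(blood_flow_dermis(age), const)
  build_stack_from_parts(frequency, eps, ed_thickness, dermal_B,
                         literal_table_split)
}
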