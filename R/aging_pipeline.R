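#' @title Age sweeps, exposure limits and Monte Carlo uncertainty
#' @description Orchestrates the dosimetry over age: scenario definitions
#'   toggling which inputs (skin thickness, tissue permittivity, dermal blood
#'   flow) vary with age while the others stay pinned at their adult values,
#'   ICNIRP local-exposure limits resolving the incident power density, sweep
#'   drivers collecting EM and thermal outputs per age, relative-change
#'   metrics, and Monte Carlo propagation of inter-individual spread.
#' @name aging_pipeline
NULL

#' ICNIRP local-exposure incident power density limit
#'
#' 55 f_G^-0.177 W m-2 for the general public and 275 f_G^-0.177 W m-2 for
#' occupational exposure, valid for 6-300 GHz (f_G in GHz).
#'
#' @param frequency_GHz frequency in GHz, within [6, 300].
#' @param population "general" or "occupational".
#' @return W m-2.
#' @export
icnirp_local_limit <- function(frequency_GHz,
                               population = c("general", "occupational")) {
  population <- match.arg(population)
  stopifnot(is.numeric(frequency_GHz))
  if (any(frequency_GHz < 6 | frequency_GHz > 300)) {
    stop("local-exposure limit formula applies for 6-300 GHz only")
  }
  coef <- if (population == "general") 55 else 275
  coef * frequency_GHz^-0.177
}

#' Exposure scenario
#'
#' @param frequency Hz.
#' @param ipd fixed incident power density (W m-2) or one of
#'   "icnirp_general", "icnirp_occupational" to use the local limit at
#'   `frequency`.
#' @param factors character subset of c("thickness", "permittivity",
#'   "blood_flow"): which inputs follow their age curves. Omitted factors are
#'   pinned at their adult values (1.396 mm, tabulated adult permittivities,
#'   blood flow at the adult reference age).
#' @param no_reflection logical; also record the reflection-free peak SAR.
#' @return an `exposure_scenario`.
#' @export
exposure_scenario <- function(frequency, ipd = 10, factors = character(0),
                              no_reflection = FALSE) {
  stopifnot(frequency > 0)
  if (length(factors)) {
    factors <- match.arg(factors, c("thickness", "permittivity", "blood_flow"),
                         several.ok = TRUE)
  }
  if (is.character(ipd)) {
    ipd <- switch(ipd,
      icnirp_general = icnirp_local_limit(frequency / 1e9, "general"),
      icnirp_occupational = icnirp_local_limit(frequency / 1e9, "occupational"),
      stop("ipd must be numeric or 'icnirp_general'/'icnirp_occupational'"))
  }
  stopifnot(is.numeric(ipd), ipd >= 0)
  structure(list(frequency = frequency, ipd = ipd, factors = factors,
                 no_reflection = no_reflection),
            class = "exposure_scenario")
}

# build the stack for one age under a scenario's factor toggles
.scenario_stack <- function(age, scenario, tables,
                            const = dosimetry_constants(), ...) {
  f <- scenario$frequency
  adult_age <- const$adult_age
  thick_age <- if ("thickness" %in% scenario$factors) age else NA
  perm_age <- if ("permittivity" %in% scenario$factors) age else NA
  bf_age <- if ("blood_flow" %in% scenario$factors) age else adult_age
  ed_thickness <- if (is.na(thick_age)) 1.396e-3 else
    eval_age_table(tables$skin_thickness_mm, thick_age) * 1e-3
  if (is.na(perm_age)) {
    build_adult_stack(f, age = bf_age, ed_thickness = ed_thickness,
                      const = const, ...)
  } else {
    # permittivity from the age's TBW; thickness/blood flow per toggles
    stack <- build_age_stack(perm_age, f, tables, const = const, ...)
    eps <- list(sc = stack$em[[1]]$eps, ed = stack$em[[2]]$eps,
                fat = stack$em[[3]]$eps, muscle = stack$em[[4]]$eps)
    dermal_B <- perfusion_coefficient(blood_flow_dermis(bf_age), const)
    build_stack_from_parts(f, eps, ed_thickness, dermal_B, ...)
  }
}

#' Sweep the dosimetry over age
#'
#' For each age, builds the tissue stack with only the scenario's toggled
#' factors age-dependent, runs the electromagnetic and thermal solvers and
#' collects transmission coefficient, absorbed power density, peak SAR,
#' per-layer absorbed-power fractions and peak steady-state temperature
#' elevation.
#'
#' @param ages numeric vector of years.
#' @param scenario an [exposure_scenario()].
#' @param tables an `age_tables` set (see [default_age_tables()]).
#' @param thermal logical; solve the bioheat problem too.
#' @param bc a [thermal_boundary()].
#' @param const constants registry.
#' @return data.frame (class `sweep_result`) with one row per age and the
#'   scenario stored as attribute `scenario`.
#' @export
sweep_age <- function(ages, scenario, tables = default_age_tables(),
                      thermal = TRUE, bc = thermal_boundary(),
                      const = dosimetry_constants()) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  ages <- sort(ages)
  rows <- lapply(ages, function(a) {
    stack <- .scenario_stack(a, scenario, tables, const = const)
    expo <- plane_wave(scenario$frequency, scenario$ipd)
    em <- em_result(stack, expo, const = const)
    row <- data.frame(
      age = a, frequency_GHz = scenario$frequency / 1e9, ipd = scenario$ipd,
      tc = em$tc, apd = em$apd, peak_sar = em$peak_sar,
      peak_sar_depth_mm = em$peak_sar_depth * 1e3,
      frac_SC = em$fractions[["SC"]], frac_ED = em$fractions[["ED"]],
      frac_fat = em$fractions[["fat"]], frac_muscle = em$fractions[["muscle"]])
    if (scenario$no_reflection) {
      row$peak_sar_no_reflection_norm <-
        no_reflection_peak_sar(stack, expo, const = const)$normalized
    }
    if (thermal) {
      tr <- temperature_rise(stack, expo, bc, const = const)
      row$peak_delta_T <- tr$peak$value
      row$peak_delta_T_depth_mm <- tr$peak$depth * 1e3
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "scenario") <- scenario
  class(out) <- c("sweep_result", class(out))
  out
}

#' Relative change in percent
#'
#' 100 (value_old - value_young) / value_young.
#'
#' @param value_young reference (nonzero) value.
#' @param value_old comparison value.
#' @return percent.
#' @export
relative_change <- function(value_young, value_old) {
  if (any(value_young == 0)) stop("zero reference value")
  100 * (value_old - value_young) / value_young
}

# generic Monte Carlo propagation: draw inputs, map to outputs, summarise
.mc_propagate <- function(draw_fn, output_fn, n_trials) {
  draws <- draw_fn(n_trials)
  outs <- lapply(seq_len(n_trials), function(i) output_fn(draws[i, , drop = FALSE]))
  mat <- do.call(rbind, lapply(outs, unlist))
  apply(mat, 2, function(v) {
    qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    c(mean = mean(v), lo = qs[1], hi = qs[2])
  })
}

#' Monte Carlo inter-individual uncertainty at an anchor age
#'
#' Draws skin thickness, total body water and body weight from their
#' (truncated) Gaussians at the anchor age, recomputes the transmission
#' coefficient, absorbed power density and peak SAR (optionally the peak
#' temperature elevation) per trial, and returns the sample mean and the
#' central 95% interval of each output. Body weight is sampled and recorded
#' but enters the dosimetry only through the TBW ratio.
#'
#' @param scenario an [exposure_scenario()] (its factor toggles are ignored:
#'   all sampled inputs vary).
#' @param anchor_age years.
#' @param tables an `age_tables` set.
#' @param n_trials number of Monte Carlo trials.
#' @param include_delta_T logical; propagate to the peak temperature
#'   elevation too (slower).
#' @param bc a [thermal_boundary()].
#' @param const constants registry.
#' @return matrix with rows mean/lo/hi and one column per output quantity;
#'   attributes `n_trials`, `anchor_age`. Seed the RNG for reproducibility.
#' @export
monte_carlo_uncertainty <- function(scenario, anchor_age,
                                    tables = default_age_tables(),
                                    n_trials = 1e4,
                                    include_delta_T = FALSE,
                                    bc = thermal_boundary(),
                                    const = dosimetry_constants()) {
  stopifnot(n_trials >= 1)
  f <- scenario$frequency
  expo <- plane_wave(f, scenario$ipd)
  tbw_adult <- eval_age_table(tables$tbw, const$adult_age)
  key <- freq_key(f)
  tab <- adult_tissue_table()
  eps_w <- water_permittivity_real(f, const)
  dermal_B <- perfusion_coefficient(blood_flow_dermis(anchor_age), const)

  draw_fn <- function(n) {
    data.frame(
      thickness_mm = sample_individual(tables$skin_thickness_mm, anchor_age, n),
      tbw = sample_individual(tables$tbw, anchor_age, n),
      weight_kg = sample_individual(tables$body_weight_kg, anchor_age, n))
  }
  output_fn <- function(d) {
    eps <- list(sc = tab$sc$eps[[key]])
    for (tis in c("ed", "fat", "muscle")) {
      rho_gcm3 <- tab[[tis]]$rho / 1000
      eps[[tis]] <- age_permittivity(
        tab[[tis]]$eps[[key]], eps_w,
        alpha = hydration_rate(d$tbw, rho_gcm3),
        alpha_adult = hydration_rate(tbw_adult, rho_gcm3))
    }
    stack <- build_stack_from_parts(f, eps, d$thickness_mm * 1e-3, dermal_B)
    em <- em_result(stack, expo, dz = 20e-6, const = const)
    out <- list(tc = em$tc, apd = em$apd, peak_sar = em$peak_sar)
    if (include_delta_T) {
      out$peak_delta_T <- temperature_rise(stack, expo, bc, const = const)$peak$value
    }
    out
  }
  res <- .mc_propagate(draw_fn, output_fn, n_trials)
  attr(res, "n_trials") <- n_trials
  attr(res, "anchor_age") <- anchor_age
  res
}

#' Write sweep and uncertainty reports
#'
#' Emits a per-age sweep CSV, a per-layer absorbed-power percentage table
#' (rows summing to 100), a relative-change summary between the youngest and
#' oldest swept ages, an optional Monte Carlo summary, and (when ggplot2 is
#' installed) age-trend figures.
#'
#' @param results a `sweep_result` from [sweep_age()].
#' @param uncertainty optional named list of [monte_carlo_uncertainty()]
#'   matrices (names = anchor ages).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param plots logical; write figures if ggplot2 is available.
#' @return invisibly, the vector of files written.
#' @export
make_report <- function(results, uncertainty = NULL, dir = ".",
                        prefix = "sweep", plots = FALSE) {
  stopifnot(inherits(results, "sweep_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(df, name) {
    path <- file.path(dir, paste0(prefix, "_", name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  w(as.data.frame(results), "by_age")

  pct <- data.frame(age = results$age,
                    SC = 100 * results$frac_SC, ED = 100 * results$frac_ED,
                    fat = 100 * results$frac_fat,
                    muscle = 100 * results$frac_muscle)
  pct$total <- rowSums(pct[, c("SC", "ED", "fat", "muscle")])
  w(pct, "layer_power_pct")

  if (nrow(results) >= 2) {
    young <- results[1, ]; old <- results[nrow(results), ]
    qty <- intersect(c("tc", "apd", "peak_sar", "peak_delta_T"), names(results))
    rc <- data.frame(quantity = qty,
                     young_age = young$age, old_age = old$age,
                     young = unlist(young[qty]), old = unlist(old[qty]),
                     change_pct = vapply(qty, function(q)
                       relative_change(young[[q]], old[[q]]), numeric(1)))
    w(rc, "relative_change")
  }

  if (!is.null(uncertainty) && length(uncertainty)) {
    mc <- do.call(rbind, lapply(names(uncertainty), function(a) {
      m <- uncertainty[[a]]
      data.frame(anchor_age = as.numeric(a), quantity = colnames(m),
                 mean = m["mean", ], lo = m["lo", ], hi = m["hi", ],
                 row.names = NULL)
    }))
    w(mc, "monte_carlo")
  }

  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    df <- as.data.frame(results)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = age, y = tc)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "age (y)", y = "power transmission coefficient",
                    title = sprintf("%.0f GHz", df$frequency_GHz[1]))
    path <- file.path(dir, paste0(prefix, "_tc.svg"))
    ggplot2::ggsave(path, p, width = 6, height = 4)
    files <- c(files, path)
  }
  invisible(files)
}
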