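# Clothing layer, environment coupling and the resistance decomposition.

# Global scale of the still-air natural-convection correlation. Calibrated
# once so that the area-weighted whole-body convective coefficient of a
# steady run at 18 C, 50% RH, short-sleeves-and-shorts ensemble equals the
# reference overall value of 3.27 W/(m^2 K); see calibrate_convection_scale().
.conv_scale_default <- 1.5226

#' Packaged calibrated convection scale
#'
#' @return The global scale factor of the natural-convection correlation.
#' @export
default_convection_scale <- function() .conv_scale_default

#' Load a clothing ensemble
#'
#' An ensemble gives, per body segment, whether it is covered and the
#' fabric's thickness (m), thermal conductivity (W/(m K)) and specific heat
#' (J/(kg K)), plus the clothing area factor `fcl` (outer clothing surface
#' area relative to the skin it covers). Two ensembles are packaged:
#' `"winter"` (cold-weather suit covering everything but the head and hands)
#' and `"summer"` (short sleeves and shorts: lower arms, hands, calves and
#' feet bare).
#'
#' @param spec `"winter"`, `"summer"`, a TSV path, or a data frame with
#'   columns `segment, covered, thickness, conductivity, specific_heat`.
#' @param fcl Clothing area factor, dimensionless (>= 1).
#' @return Object of class `clothing_ensemble` (data frame plus `fcl`
#'   attribute), rows in canonical segment order.
#' @export
clothing_ensemble <- function(spec = "winter", fcl = 1.35) {
  stopifnot(fcl >= 1)
  name <- NULL
  if (is.character(spec)) {
    if (spec %in% c("winter", "summer")) {
      name <- spec
      spec <- system.file("extdata", paste0("clothing_", spec, ".tsv"),
                          package = "coldtherm", mustWork = TRUE)
    }
    spec <- utils::read.delim(spec, stringsAsFactors = FALSE)
  }
  need <- c("segment", "covered", "thickness", "conductivity", "specific_heat")
  miss <- setdiff(need, names(spec))
  if (length(miss)) stop("clothing table missing column(s): ", paste(miss, collapse = ", "))
  if (!setequal(spec$segment, .segments) || anyDuplicated(spec$segment))
    stop("clothing table must contain each of the 12 segments exactly once")
  spec <- spec[match(.segments, spec$segment), need]
  spec$covered <- as.logical(spec$covered)
  cov <- spec$covered
  if (any(cov & (!is.finite(spec$thickness) | spec$thickness <= 0)))
    stop("covered segments need thickness > 0")
  if (any(cov & (!is.finite(spec$conductivity) | spec$conductivity <= 0)))
    stop("covered segments need conductivity > 0")
  structure(spec, fcl = fcl, name = name, class = c("clothing_ensemble", "data.frame"))
}

# Attach body-dependent derived quantities: skin->clothing conductance K3
# (series of the outer skin half-thickness and the full fabric thickness,
# ideal contact) and the clothing node heat capacity.
.prepare_clothing <- function(clothing, model) {
  if (!is.null(clothing$K3)) return(clothing)
  seg <- model$segments
  K3 <- rep(NA_real_, 12)
  Cp <- rep(NA_real_, 12)
  cov <- clothing$covered
  K3[cov] <- seg$area[cov] /
    (0.5 * seg$d_skin[cov] / .tissue$k_skin +
       clothing$thickness[cov] / clothing$conductivity[cov])
  Cp[cov] <- .tissue$rho_clothing * clothing$specific_heat[cov] *
    seg$area[cov] * clothing$thickness[cov]
  clothing$K3 <- K3
  clothing$Cp_cl <- Cp
  clothing
}

#' Environment specification
#'
#' Still, cold air: ambient temperature, relative humidity (from which the
#' ambient vapor pressure is derived), zero wind and no radiative exchange —
#' the operating envelope of this model version.
#'
#' @param Ta Ambient air temperature, degrees C.
#' @param RH Relative humidity, fraction in `[0, 1]`.
#' @param wind Wind speed, m/s; must be 0 in this model version.
#' @return Object of class `environment_spec` with `Ta`, `RH`, `Pa` (kPa),
#'   `wind`, `radiation`.
#' @export
environment_spec <- function(Ta, RH = 0.5, wind = 0) {
  stopifnot(RH >= 0, RH <= 1)
  if (wind != 0) stop("wind speed must be 0: forced convection is not modelled")
  structure(list(Ta = Ta, RH = RH, Pa = ambient_vapor_pressure(Ta, RH),
                 wind = 0, radiation = FALSE),
            class = "environment_spec")
}

#' Ambient vapor pressure from relative humidity
#'
#' Magnus correlation for saturation vapor pressure over water,
#' `Psat = 0.61094 * exp(17.625*Ta / (Ta + 243.04))` kPa (constants after
#' Alduchov & Eskridge), scaled by the relative humidity.
#'
#' @param Ta Air temperature, degrees C.
#' @param RH Relative humidity, fraction.
#' @return Vapor pressure, kPa.
#' @export
ambient_vapor_pressure <- function(Ta, RH) {
  stopifnot(all(RH >= 0), all(RH <= 1))
  RH * 0.61094 * exp(17.625 * Ta / (Ta + 243.04))
}

#' Thermal conductivity from a transient hot-wire measurement
#'
#' The wire temperature rises linearly in the logarithm of heating time;
#' the sample conductivity is `lambda = q / (4*pi*slope)` with `q` the
#' heating power per unit wire length and `slope` the fitted `dT / d(ln t)`.
#'
#' @param q Heating power per unit length, W/m (> 0).
#' @param slope Temperature rise per ln-second, K (> 0).
#' @return Conductivity, W/(m K).
#' @export
hotwire_conductivity <- function(q, slope) {
  if (any(q <= 0) || any(slope <= 0))
    stop("domain error: q and slope must be > 0")
  q / (4 * pi * slope)
}

#' Area-weighted garment conductivity
#'
#' Combines per-region fabric conductivities into one static weighted value.
#' Lower body: `0.524*thigh + 0.476*calf`. Upper body:
#' `(back + abdomen)*0.101 + chest*0.195 + abdomen*0.128 + buttock*0.136 +
#' upper_arm*0.21 + lower_arm*0.128` (the published weight set, kept
#' verbatim; with equal inputs it sums to 0.999).
#'
#' @param components Named numeric vector/list of region conductivities,
#'   W/(m K). Lower mode needs `thigh`, `calf`; upper mode needs `back`,
#'   `chest`, `abdomen`, `buttock`, `upper_arm`, `lower_arm`.
#' @param mode `"upper"` or `"lower"`.
#' @return Weighted conductivity, W/(m K).
#' @export
weighted_conductivity <- function(components, mode = c("upper", "lower")) {
  mode <- match.arg(mode)
  components <- unlist(components)
  if (any(components <= 0)) stop("component conductivities must be > 0")
  need <- if (mode == "lower") c("thigh", "calf")
          else c("back", "chest", "abdomen", "buttock", "upper_arm", "lower_arm")
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("validation error: missing region(s): ", paste(miss, collapse = ", "))
  x <- as.list(components)
  if (mode == "lower") {
    0.524 * x$thigh + 0.476 * x$calf
  } else {
    (x$back + x$abdomen) * 0.101 + x$chest * 0.195 + x$abdomen * 0.128 +
      x$buttock * 0.136 + x$upper_arm * 0.21 + x$lower_arm * 0.128
  }
}

#' Thermal-resistance decomposition
#'
#' From mean skin temperature `Ts`, mean garment outer-surface temperature
#' `Tc`, ambient `Ta`, steady heat flow `Q_avg` (W) and body area `A`:
#' total resistance `Rt = A*(Ts - Ta)/Q_avg`, surface air-layer resistance
#' `Ra = A*(Tc - Ta)/Q_avg`, intrinsic clothing resistance
#' `Ri = (Rt - Ra)/fcl` (all m^2 K/W), and the air-layer share
#' `100*Ra/Rt` (%). `Ri*fcl + Ra = Rt` holds exactly.
#'
#' @param Ts,Tc,Ta Skin, garment-surface and ambient temperatures, degrees C.
#' @param Q_avg Steady total heat flow to the environment, W (> 0).
#' @param A Body surface area, m^2.
#' @param fcl Clothing area factor.
#' @return Object of class `resistance_summary`: list with `Rt`, `Ra`, `Ri`,
#'   `ra_fraction`.
#' @export
clothing_resistances <- function(Ts, Tc, Ta, Q_avg, A, fcl = 1.35) {
  if (Q_avg <= 0) stop("domain error: Q_avg must be > 0")
  Rt <- A * (Ts - Ta) / Q_avg
  Ra <- A * (Tc - Ta) / Q_avg
  Ri <- (Rt - Ra) / fcl
  structure(list(Rt = Rt, Ra = Ra, Ri = Ri, ra_fraction = 100 * Ra / Rt),
            class = "resistance_summary")
}

#' Convective heat exchange at a surface
#'
#' `Qc = hc * (Tsk - Ta) * Ask`, linear in each argument.
#'
#' @param hc Convective coefficient, W/(m^2 K) (>= 0).
#' @param Tsk Surface temperature, degrees C.
#' @param Ta Ambient temperature, degrees C.
#' @param Ask Exchange area, m^2 (> 0).
#' @return Heat flow, W (positive towards the environment).
#' @export
convective_exchange <- function(hc, Tsk, Ta, Ask) {
  stopifnot(all(hc >= 0), all(Ask > 0))
  hc * (Tsk - Ta) * Ask
}

#' Still-air natural-convection coefficient
#'
#' Buoyancy-driven power law `hc = scale * shape * max(dT, 0)^0.25` with
#' `dT` the surface-to-air temperature difference. `shape` is a per-segment
#' geometry constant (slender limbs convect better than the trunk); `scale`
#' is the single global calibration factor (see
#' [default_convection_scale()]). The coefficient vanishes at zero gradient
#' (no buoyancy) and is nondecreasing in `dT`.
#'
#' @param T_surface Outer-surface temperature, degrees C.
#' @param Ta Ambient temperature, degrees C.
#' @param shape Per-segment correlation constant(s) (> 0).
#' @param scale Global calibration factor; `NULL` for the packaged value.
#' @return Coefficient, W/(m^2 K).
#' @export
convection_coefficient <- function(T_surface, Ta, shape = 1, scale = NULL) {
  if (is.null(scale)) scale <- .conv_scale_default
  stopifnot(all(shape > 0), scale > 0)
  scale * shape * pmax(T_surface - Ta, 0)^0.25
}

#' Calibrate the global convection scale
#'
#' One-dimensional root finding on the global scale factor so that the
#' steady whole-body area-weighted convective coefficient in a reference
#' scenario matches a target value. Used once to fix the packaged constant
#' (18 C indoor air, 50% RH, summer ensemble, target 3.27 W/(m^2 K)).
#'
#' @param model,clothing,env Simulation inputs.
#' @param target_hc Target overall coefficient, W/(m^2 K).
#' @param interval Search interval for the scale.
#' @param ... Passed to [simulate_body()] options.
#' @return The calibrated scale factor.
#' @export
calibrate_convection_scale <- function(model, clothing, env, target_hc = 3.27,
                                       interval = c(0.5, 4), ...) {
  f <- function(s) {
    res <- simulate_body(model, clothing, env, mode = "steady",
                         options = list(conv_scale = s, ...))
    res$overall_hc - target_hc
  }
  stats::uniroot(f, interval, tol = 1e-4)$root
}

#' @export
print.resistance_summary <- function(x, ...) {
  cat(sprintf("<resistance_summary> Rt = %.5f, Ra = %.5f, Ri = %.5f m^2K/W (Ra share %.1f%%)\n",
              x$Rt, x$Ra, x$Ri, x$ra_fraction))
  invisible(x)
}
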