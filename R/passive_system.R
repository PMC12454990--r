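# Passive system: every heat-flow term of the tissue/clothing/blood network
# and the assembled node temperature derivatives.

#' Construct a body state
#'
#' @param T 12 x 4 temperature matrix (layers core, equivalent, skin,
#'   clothing; clothing entries may be `NA` on uncovered segments), degrees C.
#' @param T_blood Central blood-pool temperature, degrees C.
#' @param t Elapsed exposure time, s.
#' @return Object of class `body_state`.
#' @export
body_state <- function(T, T_blood, t = 0) {
  T <- as.matrix(T)
  if (nrow(T) != 12 || !ncol(T) %in% c(3, 4))
    stop("T must be a 12 x 3 or 12 x 4 matrix")
  if (ncol(T) == 3) T <- cbind(T, clothing = NA_real_)
  vals <- c(T[, 1:3], T_blood)
  if (any(!is.finite(vals)) || any(vals <= -50) || any(vals >= 50))
    stop("temperatures must be finite and within (-50, 50) degrees C")
  dimnames(T) <- list(.segments, .layers)
  structure(list(T = T, T_blood = T_blood, t = t), class = "body_state")
}

#' Metabolic heat production in the cold
#'
#' Basal metabolism rises as a node cools below its set point following a Q10
#' law: `Q* = Q0 - dQ` with `dQ = Q0*(2^(0.1*(T - T_set)) - 1)`, i.e.
#' `Q* = Q0*(2 - 2^(0.1*(T - T_set)))`, clamped at zero. At the set point
#' `Q* = Q0`; 10 degrees below it, `Q* = 1.5*Q0`.
#'
#' @param Q0 Basal metabolic heat, W (>= 0).
#' @param T Node temperature, degrees C.
#' @param T_set Set-point temperature, degrees C.
#' @return Adjusted metabolic heat, W.
#' @export
metabolic_rate_cold <- function(Q0, T, T_set) {
  stopifnot(all(Q0 >= 0))
  out <- Q0 * (2 - 2^(0.1 * (T - T_set)))
  out[out < 0] <- 0
  out
}

#' External work heat of a segment's equivalent layer
#'
#' Whole-body activity above basal level, `58.2*met*A_total - Q0_total` (one
#' met is 58.2 W per m^2 of body surface), distributed to equivalent layers by
#' the muscle-distribution weights `Metf`; negative values (activity below
#' basal) are treated as zero.
#'
#' @param met Metabolic activity, met units (>= 0).
#' @param Q0_total Whole-body basal metabolic heat, W.
#' @param A_total Body surface area, m^2.
#' @param Metf Segment distribution weight in `[0, 1]`.
#' @return Work heat for the segment's equivalent layer, W.
#' @export
external_work <- function(met, Q0_total, A_total, Metf) {
  stopifnot(met >= 0, all(Metf >= 0), all(Metf <= 1))
  max(0, 58.2 * met * A_total - Q0_total) * Metf
}

#' Shivering heat of a segment's equivalent layer
#'
#' Bilinear in the head-core cold signal and the integrated skin cold signal:
#' `Ch = gain * Cld(head, core) * Clds * Metf`, clamped at zero. Shivering
#' occurs only in the equivalent layer.
#'
#' @param Cld_core_head Head-core cold signal, degrees C (>= 0).
#' @param Clds Integrated skin cold signal, degrees C (>= 0).
#' @param control Control coefficients (uses `shiver_gain`).
#' @param Metf Segment distribution weight.
#' @return Shivering heat, W.
#' @export
shivering_heat <- function(Cld_core_head, Clds, control = default_control(), Metf) {
  stopifnot(Cld_core_head >= 0, Clds >= 0)
  pmax(0, control$shiver_gain * Cld_core_head * Clds * Metf)
}

#' Convective heat exchange between a node and the central blood pool
#'
#' `Q_b = a * rho_b * Bf * (T_node - T_blood)` with the countercurrent ratio
#' `a`, blood volumetric heat capacity `rho_b` (W h / (L K)) and flow `Bf`
#' (L/h); positive means the node loses heat to the blood.
#'
#' @param Bf Blood flow, L/h (>= 0).
#' @param T_node Node temperature, degrees C.
#' @param T_blood Blood-pool temperature, degrees C.
#' @param control Control coefficients (uses `a`, `rho_b`).
#' @return Heat exchanged, W.
#' @export
blood_heat_exchange <- function(Bf, T_node, T_blood, control = default_control()) {
  if (any(Bf < 0)) stop("domain error: blood flow must be >= 0")
  control$a * control$rho_b * Bf * (T_node - T_blood)
}

#' Cold-induced blood-flow adjustment
#'
#' In the default `"physiological"` mode flow follows a Q10 down-scaling,
#' `Bf* = Bb * 2^((T - 37)/10)`, so that cooling constricts the bed and
#' halves the flow every 10 degrees below 37. The `"literal"` mode applies
#' the change term with the opposite sign, `Bf* = Bb*(2 - 2^((T - 37)/10))`,
#' which increases flow in the cold; it is retained only for comparison.
#' Both are clamped at zero.
#'
#' @param Bb Basal blood flow, L/h (>= 0).
#' @param T Node temperature, degrees C.
#' @param mode `"physiological"` (default) or `"literal"`.
#' @return Adjusted flow, L/h.
#' @export
cold_blood_flow <- function(Bb, T, mode = c("physiological", "literal")) {
  stopifnot(all(Bb >= 0))
  mode <- match.arg(mode)
  if (mode == "physiological") pmax(0, Bb * 2^((T - 37) / 10))
  else pmax(0, Bb * (2 - 2^((T - 37) / 10)))
}

#' Respiratory heat loss
#'
#' `RES = 0.0014*Q_tot*(34 - Ta) + 0.017*Q_tot*(5.867 - Pa)`: sensible
#' warming of inhaled air plus latent humidification, both proportional to
#' total metabolic energy production `Q_tot`. Applied only to the chest core
#' node (the lungs).
#'
#' @param Q_tot Whole-body metabolic heat production, W (>= 0).
#' @param Ta Ambient air temperature, degrees C.
#' @param Pa Ambient vapor pressure, kPa.
#' @return Respiratory loss, W.
#' @export
respiratory_loss <- function(Q_tot, Ta, Pa) {
  stopifnot(Q_tot >= 0)
  0.0014 * Q_tot * (34 - Ta) + 0.017 * Q_tot * (5.867 - Pa)
}

.default_options <- function(options = list()) {
  defaults <- list(
    met = 0.7,
    blood_flow_mode = "physiological",
    core_wall = TRUE,
    wall_T = 37,
    conv_scale = NULL,        # NULL -> packaged calibrated scale
    eq_source_override = NULL,  # named numeric, W, replaces Q*+W+Ch per segment
    low_temperature = TRUE,
    atol = 1e-6, rtol = 1e-8,
    deriv_tol = 1e-6,         # K/s, steady-state declaration
    max_hours = 48,
    sample_interval = 60      # s, trajectory output cadence
  )
  bad <- setdiff(names(options), names(defaults))
  if (length(bad)) stop("unknown option(s): ", paste(bad, collapse = ", "))
  defaults[names(options)] <- options
  defaults
}

# Core heat-balance evaluation shared by node_derivatives() and the ODE
# right-hand side. Tt: 12x3 tissue temperatures; Tcl: clothing temperature for
# covered segments (length = n covered, in segment order); Tb: blood pool.
# Returns derivatives (same shapes) and every heat term.
.heat_balance <- function(Tt, Tcl, Tb, model, clothing, env, controls = NULL,
                          options = .default_options()) {
  seg <- model$segments
  ctl <- model$control
  A <- seg$area
  covered <- clothing$covered
  fcl <- attr(clothing, "fcl")

  if (is.null(controls)) controls <- control_state(Tt, model)

  # metabolic heat with cold boost, per node
  Qs <- metabolic_rate_cold(model$Q0, Tt, model$Tset)
  W <- external_work(options$met, sum(model$Q0), model$total_area, seg$Metf)
  Ch <- shivering_heat(controls$Cld[1, 1], controls$Clds, ctl, seg$Metf)
  Q_tot <- sum(Qs) + sum(W) + sum(Ch)

  # blood flows: Q10 constriction in core/equivalent, controlled skin bed
  Bf <- cbind(
    cold_blood_flow(model$Bb[, 1], Tt[, 1], options$blood_flow_mode),
    cold_blood_flow(model$Bb[, 2], Tt[, 2], options$blood_flow_mode),
    controls$BF_skin
  )
  Qb <- blood_heat_exchange(Bf, Tt, Tb, ctl)

  # respiration, chest core only
  RES <- numeric(12)
  RES[3] <- respiratory_loss(Q_tot, env$Ta, env$Pa)

  # conduction chain: 37C wall -> core -> equivalent -> skin -> (clothing)
  Qwall <- if (isTRUE(options$core_wall)) model$K0 * (options$wall_T - Tt[, 1]) else numeric(12)
  Qc1 <- model$K12 * (Tt[, 1] - Tt[, 2])
  Qc2 <- model$K23 * (Tt[, 2] - Tt[, 3])

  # outer surface: clothing node where covered, bare skin otherwise
  Tsurf <- Tt[, 3]
  Tsurf[covered] <- Tcl
  hc <- convection_coefficient(Tsurf, env$Ta, seg$hc_shape, scale = options$conv_scale)
  area_factor <- ifelse(covered, fcl, 1)
  Qconv <- convective_exchange(hc, Tsurf, env$Ta, A * area_factor)

  K3 <- clothing$K3
  Qc3 <- numeric(12)                       # skin -> clothing conduction
  Qc3[covered] <- K3[covered] * (Tt[covered, 3] - Tcl)
  Qskin_out <- ifelse(covered, Qc3, Qconv) # what leaves the skin outward
  E <- numeric(12)                         # evaporation off in low-temperature mode

  # equivalent-layer source, optionally overridden by a calibrated constant
  Qeq_src <- Qs[, 2] + W + Ch
  ov <- options$eq_source_override
  if (!is.null(ov)) {
    idx <- match(names(ov), .segments)
    if (any(is.na(idx))) stop("unknown segment in eq_source_override")
    Qeq_src[idx] <- ov
  }

  dcore <- (Qs[, 1] + Qwall - Qb[, 1] - Qc1 - RES) / model$Cp[, 1]
  deq <- (Qeq_src - Qb[, 2] + Qc1 - Qc2) / model$Cp[, 2]
  dskin <- (Qs[, 3] - Qb[, 3] + Qc2 - Qskin_out - E) / model$Cp[, 3]
  dcl <- (Qc3[covered] - Qconv[covered]) / clothing$Cp_cl[covered]
  dblood <- sum(Qb) / ctl$Cp_b

  list(
    dT = cbind(core = dcore, equivalent = deq, skin = dskin),
    dT_cl = dcl, dT_blood = dblood,
    terms = list(Q = Qs, W_work = W, Ch = Ch, Q_tot = Q_tot, Qb = Qb,
                 Qwall = Qwall, Qc1 = Qc1, Qc2 = Qc2, Qc3 = Qc3,
                 RES = RES[3], E = E, hc = hc, Tsurf = Tsurf, Qconv = Qconv,
                 controls = controls)
  )
}

#' Node temperature derivatives of the full system
#'
#' Assembles the heat balance of every tissue node, clothing node and the
#' central blood pool: metabolism (with cold boost), external work and
#' shivering (equivalent layer), blood convective exchange, inter-layer
#' conduction (antisymmetric between adjacent layers), the 37 degree core-wall
#' Dirichlet condition, respiration (chest core), clothing conduction and
#' surface convection. The blood pool integrates the sum of all node exchanges.
#'
#' @param state A [body_state()].
#' @param model A [build_body()] model.
#' @param clothing A [clothing_ensemble()].
#' @param env An [environment_spec()].
#' @param controls Optional precomputed active-system outputs (as from
#'   [control_state()]); when `NULL` they are evaluated from `state`. Passing
#'   a zeroed set freezes the controller.
#' @param options Simulation options, see [simulate_body()].
#' @return List with `dT` (12 x 4 matrix, K/s; clothing `NA` where uncovered),
#'   `dT_blood` (K/s) and `terms` (every heat-flow term, W).
#' @export
node_derivatives <- function(state, model, clothing, env, controls = NULL,
                             options = list()) {
  stopifnot(inherits(state, "body_state"))
  clothing <- .prepare_clothing(clothing, model)
  opt <- .default_options(options)
  Tt <- state$T[, 1:3, drop = FALSE]
  if (any(!is.finite(Tt)) || !is.finite(state$T_blood))
    stop("numerical error: non-finite temperature in state")
  covered <- clothing$covered
  Tcl <- state$T[covered, 4]
  if (any(!is.finite(Tcl)))
    stop("numerical error: non-finite clothing temperature (segment ",
         .segments[covered][which(!is.finite(Tcl))[1]], ")")
  hb <- .heat_balance(Tt, Tcl, state$T_blood, model, clothing, env, controls, opt)
  dT <- cbind(hb$dT, clothing = NA_real_)
  dT[covered, 4] <- hb$dT_cl
  dimnames(dT) <- list(.segments, .layers)
  list(dT = dT, dT_blood = hb$dT_blood, terms = hb$terms)
}
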