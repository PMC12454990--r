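# Active (hypothalamic) control system: receptor error signals, integrated
# skin signals, vasomotor effector signals, local Q10 multiplier and skin
# blood flow.

#' Receptor error signals
#'
#' `Err = T - T_set`; the warm-receptor signal is the positive part and the
#' cold-receptor signal the negative part, so `Warm * Cld = 0` elementwise.
#'
#' @param T Node temperatures, degrees C (vector or matrix).
#' @param T_set Set-point temperatures, same shape as `T`.
#' @return List with `Err`, `Warm`, `Cld`.
#' @export
error_signals <- function(T, T_set) {
  if (length(T) != length(T_set)) stop("T and T_set must have the same shape")
  Err <- T - T_set
  list(Err = Err, Warm = pmax(Err, 0), Cld = pmax(-Err, 0))
}

#' Integrated skin warm/cold signals
#'
#' Skin-sensor-weighted sums of the per-segment skin receptor signals with
#' weights `SKINR` (a convex combination; the weights must sum to 1).
#'
#' @param Warm_skin,Cld_skin Per-segment skin warm/cold signals, degrees C.
#' @param SKINR Sensor weight per segment.
#' @return List with scalars `Warms`, `Clds`.
#' @export
integrated_signals <- function(Warm_skin, Cld_skin, SKINR) {
  if (length(Warm_skin) != length(SKINR) || length(Cld_skin) != length(SKINR))
    stop("validation error: signal and weight vectors differ in length")
  if (abs(sum(SKINR) - 1) > 1e-6) stop("validation error: SKINR must sum to 1")
  list(Warms = sum(SKINR * Warm_skin), Clds = sum(SKINR * Cld_skin))
}

#' Vasodilation and vasoconstriction effector signals
#'
#' Central command from the head-core sensor plus integrated skin signals:
#' `DL = Cdl*Err(1,1) + Sdl*(Warms - Clds) + Pdl*Warm(1,1)*Warms` and
#' `ST = -Cst*Err(1,1) - Sst*(Warms - Clds) + Pst*Cld(1,1)*Clds`, both
#' clamped at zero before use in the skin blood-flow law (negative dilation
#' or constriction has no physiological meaning).
#'
#' @param Err_head_core,Warm_head_core,Cld_head_core Head-core signals, degrees C.
#' @param Warms,Clds Integrated skin signals.
#' @param control Control coefficients, see [default_control()].
#' @return List with nonnegative scalars `DL`, `ST`.
#' @export
vasomotor_signals <- function(Err_head_core, Warm_head_core, Cld_head_core,
                              Warms, Clds, control = default_control()) {
  DL <- control$Cdl * Err_head_core + control$Sdl * (Warms - Clds) +
    control$Pdl * Warm_head_core * Warms
  ST <- -control$Cst * Err_head_core - control$Sst * (Warms - Clds) +
    control$Pst * Cld_head_core * Clds
  list(DL = max(DL, 0), ST = max(ST, 0))
}

#' Local Q10 multiplier for skin blood flow
#'
#' `km = 2^(Err/RT)`: local skin warming doubles the vasomotor response every
#' `RT` degrees, local cooling halves it. `RT` defaults to 10 degrees C.
#'
#' @param Err_skin Local skin error signal, degrees C.
#' @param RT Sensitivity scale, degrees C (> 0).
#' @return Multiplier(s) in (0, Inf); 1 at zero error.
#' @export
local_multiplier <- function(Err_skin, RT = 10) {
  stopifnot(RT > 0)
  2^(Err_skin / RT)
}

#' Skin blood flow under vasomotor control
#'
#' `BF = (Bb + SKINV*DL) / (1 + SKINC*ST) * km` (L/h): dilation adds flow
#' with segment weight `SKINV`, constriction divides it with weight `SKINC`,
#' and the local multiplier scales the result.
#'
#' @param Bb Basal skin blood flow, L/h.
#' @param SKINV,SKINC Segment distribution weights.
#' @param DL,ST Effector signals (nonnegative, post-clamp).
#' @param km Local multiplier (> 0).
#' @return Skin blood flow, L/h (>= 0).
#' @export
skin_blood_flow <- function(Bb, SKINV, SKINC, DL, ST, km) {
  (Bb + SKINV * DL) / (1 + SKINC * ST) * km
}

#' Full control state from a body state
#'
#' Evaluates the whole active system for a state: receptor signals at every
#' tissue node, integrated skin signals, effector signals and per-segment
#' skin blood flow.
#'
#' @param T Tissue temperature matrix (12 x 3, layers core/equivalent/skin),
#'   degrees C.
#' @param model A [build_body()] model.
#' @return List with `Err`, `Warm`, `Cld` (12 x 3), `Warms`, `Clds`, `DL`,
#'   `ST`, `km` (per segment) and `BF_skin` (L/h per segment).
#' @export
control_state <- function(T, model) {
  ctl <- model$control
  sig <- error_signals(T, model$Tset)
  intg <- integrated_signals(sig$Warm[, 3], sig$Cld[, 3], model$segments$SKINR)
  eff <- vasomotor_signals(sig$Err[1, 1], sig$Warm[1, 1], sig$Cld[1, 1],
                           intg$Warms, intg$Clds, ctl)
  km <- local_multiplier(sig$Err[, 3], ctl$RT)
  BF <- skin_blood_flow(model$Bb[, 3], model$segments$SKINV, model$segments$SKINC,
                        eff$DL, eff$ST, km)
  c(sig, intg, eff, list(km = km, BF_skin = BF))
}
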