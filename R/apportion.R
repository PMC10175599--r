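# Cycle mass-balance apportionment: split the nitrogen removed over one SBR
# react phase between the anammox, nitrification (AOB/NOB) and heterotrophic
# denitrification (denitratation/denitritation) pathways using only the bulk
# NH4/NO2/NO3 concentrations at the start and end of the phase.

#' Stoichiometric constants for the mass-balance equations
#'
#' Two constants drive the apportionment: the total nitrogen removed per
#' ammonium removed by anammox (`r_tn_per_nh4`) and the nitrate produced per
#' TN removed (`r_no3_per_tn`). The conventional mass-balance literature
#' uses 2.04 and 0.26/2.04; the reaction vector itself implies
#' 1 + 1.32 - 0.26 = 2.06. Both conventions are supported:
#' `consistency_mode = "paper"` keeps the literature constants,
#' `"closed"` recomputes them from the configured anammox reaction so that
#' apportionment of data generated by that exact stoichiometry returns
#' zeros for the ignored pathways.
#'
#' @param consistency_mode `"paper"` (default) or `"closed"`.
#' @param anammox_no2,anammox_no3 Anammox stoichiometric coefficients
#'   (mol per mol NH3), used by `"closed"` mode.
#' @param r_tn_per_nh4,r_no3_per_tn Override either constant directly.
#' @return Object of class `"np_stoich_params"`.
#' @export
stoich_params <- function(consistency_mode = c("paper", "closed"),
                          anammox_no2 = 1.32, anammox_no3 = 0.26,
                          r_tn_per_nh4 = NULL, r_no3_per_tn = NULL) {
  consistency_mode <- match.arg(consistency_mode)
  if (is.null(r_tn_per_nh4))
    r_tn_per_nh4 <- switch(consistency_mode,
                           paper = 2.04,
                           closed = 1 + anammox_no2 - anammox_no3)
  if (is.null(r_no3_per_tn))
    r_no3_per_tn <- anammox_no3 / r_tn_per_nh4
  if (!is.finite(r_tn_per_nh4) || r_tn_per_nh4 <= 1)
    stop("r_tn_per_nh4 must be > 1", call. = FALSE)
  if (!is.finite(r_no3_per_tn) || r_no3_per_tn < 0 || r_no3_per_tn >= 1)
    stop("r_no3_per_tn must be in [0, 1)", call. = FALSE)
  structure(list(consistency_mode = consistency_mode,
                 r_tn_per_nh4 = r_tn_per_nh4,
                 r_no3_per_tn = r_no3_per_tn),
            class = "np_stoich_params")
}

#' Cycle endpoints
#'
#' Bulk ammonium, nitrite and nitrate concentrations (mg N/L) at the start
#' ("initial": immediately after feed mixing, see [mix_feed()]) and end
#' ("final": end of the anoxic react phase) of an SBR cycle. Settling and
#' decanting are assumed reaction-free.
#'
#' @param nh4_initial,no2_initial,no3_initial,nh4_final,no2_final,no3_final
#'   Concentrations in mg N/L, all finite and non-negative.
#' @return Object of class `"np_endpoints"`.
#' @export
cycle_endpoints <- function(nh4_initial, no2_initial, no3_initial,
                            nh4_final, no2_final, no3_final) {
  v <- c(nh4_initial = nh4_initial, no2_initial = no2_initial,
         no3_initial = no3_initial, nh4_final = nh4_final,
         no2_final = no2_final, no3_final = no3_final)
  if (any(!is.finite(v)) || any(v < 0))
    stop("endpoint concentrations must be finite and non-negative",
         call. = FALSE)
  structure(as.list(v), class = "np_endpoints")
}

#' Mix residual reactor liquor with fresh influent
#'
#' SBR feeding at a given volume exchange ratio replaces that fraction of
#' the reactor volume with influent, so every analyte becomes
#' `ratio * influent + (1 - ratio) * residual`. The result is the
#' react-phase initial concentration vector.
#'
#' @param residual Named numeric vector of concentrations left after decant.
#' @param influent Named numeric vector over the same analytes.
#' @param exchange_ratio Fraction of volume exchanged, in (0, 1].
#' @return Named numeric vector.
#' @examples
#' mix_feed(c(nh4 = 0), c(nh4 = 14.3), 0.5)  # 7.15
#' @export
mix_feed <- function(residual, influent, exchange_ratio = 0.5) {
  if (!is.numeric(exchange_ratio) || exchange_ratio <= 0 || exchange_ratio > 1)
    stop("exchange_ratio must be in (0, 1]", call. = FALSE)
  if (!setequal(names(residual), names(influent)))
    stop("residual and influent analyte sets differ", call. = FALSE)
  influent <- influent[names(residual)]
  exchange_ratio * influent + (1 - exchange_ratio) * residual
}

.delta_n <- function(ep) {
  (ep$nh4_initial + ep$no2_initial + ep$no3_initial) -
    (ep$nh4_final + ep$no2_final + ep$no3_final)
}

.new_apportionment <- function(mode, ep, params, fields, clamp) {
  warnings <- character(0)
  for (nm in names(fields)) {
    if (fields[[nm]] < -1e-12)
      warnings <- c(warnings, sprintf(
        "%s is negative (%.3f mg N/L): a pathway ignored by the %s balance is active",
        nm, fields[[nm]], mode))
  }
  if (clamp) fields <- lapply(fields, function(v) max(v, 0))
  structure(c(list(mode = mode, delta_n = .delta_n(ep)), fields,
              list(params = params, clamped = clamp, warnings = warnings)),
            class = "np_apportionment")
}

#' Apportion nitrogen removal in a low-carbon (nitrifying) cycle
#'
#' For cycles run with negligible biodegradable organics the denitrification
#' pathways are ignored and the balance attributes all net TN loss to
#' anammox, the remaining ammonium consumption to aerobic ammonium
#' oxidation (AOB), and the nitrate produced beyond the anammox yield to
#' nitrite oxidation (NOB):
#' \itemize{
#'   \item `tn_anammox = delta_n`
#'   \item `nh4_aob = (nh4_i - nh4_f) - tn_anammox / r_tn_per_nh4`
#'   \item `no3_nob = (no3_f - no3_i) - tn_anammox * r_no3_per_tn`
#' }
#' Negative components are retained (diagnostic of a violated assumption)
#' and flagged in `warnings`; `clamp = TRUE` floors them at zero after
#' flagging.
#'
#' @param endpoints A [cycle_endpoints()] object.
#' @param params A [stoich_params()] object.
#' @param clamp Floor negative components at zero (after warning).
#' @return Object of class `"np_apportionment"` with fields `mode`,
#'   `delta_n`, `tn_anammox`, `nh4_aob`, `no3_nob`, `warnings`.
#' @export
apportion_phase1 <- function(endpoints, params = stoich_params(),
                             clamp = FALSE) {
  stopifnot(inherits(endpoints, "np_endpoints"),
            inherits(params, "np_stoich_params"))
  ep <- endpoints
  tn_anammox <- .delta_n(ep)
  nh4_aob <- (ep$nh4_initial - ep$nh4_final) - tn_anammox / params$r_tn_per_nh4
  no3_nob <- (ep$no3_final - ep$no3_initial) - tn_anammox * params$r_no3_per_tn
  .new_apportionment("phase1", ep, params,
                     list(tn_anammox = tn_anammox, nh4_aob = nh4_aob,
                          no3_nob = no3_nob), clamp)
}

#' Apportion nitrogen removal in a carbon-dosed (denitrifying) cycle
#'
#' For strictly anoxic cycles with biodegradable organics the nitrification
#' pathway is ignored: all ammonium loss is assigned to anammox and the
#' nitrate/nitrite balances yield the two heterotrophic steps:
#' \itemize{
#'   \item `tn_anammox = (nh4_i - nh4_f) * r_tn_per_nh4`
#'   \item `no3_denitratation = no3_i + tn_anammox * r_no3_per_tn - no3_f`
#'   \item `tn_denitritation = delta_n - tn_anammox`
#' }
#' The identity `tn_anammox + tn_denitritation == delta_n` holds by
#' construction. Negative components are flagged (and optionally clamped),
#' e.g. a negative `no3_denitratation` means nitrate production exceeded
#' the anammox yield, so the no-nitrification assumption is violated.
#'
#' @inheritParams apportion_phase1
#' @return Object of class `"np_apportionment"` with fields `mode`,
#'   `delta_n`, `tn_anammox`, `no3_denitratation`, `tn_denitritation`,
#'   `warnings`.
#' @export
apportion_phase2 <- function(endpoints, params = stoich_params(),
                             clamp = FALSE) {
  stopifnot(inherits(endpoints, "np_endpoints"),
            inherits(params, "np_stoich_params"))
  ep <- endpoints
  tn_anammox <- (ep$nh4_initial - ep$nh4_final) * params$r_tn_per_nh4
  no3_denitratation <- ep$no3_initial + tn_anammox * params$r_no3_per_tn -
    ep$no3_final
  tn_denitritation <- .delta_n(ep) - tn_anammox
  .new_apportionment("phase2", ep, params,
                     list(tn_anammox = tn_anammox,
                          no3_denitratation = no3_denitratation,
                          tn_denitritation = tn_denitritation), clamp)
}

#' @export
print.np_apportionment <- function(x, ...) {
  cat(sprintf("<apportionment, %s>  dN = %.3f mg N/L\n", x$mode, x$delta_n))
  flds <- setdiff(names(x), c("mode", "delta_n", "params", "clamped", "warnings"))
  for (nm in flds) cat(sprintf("  %-18s %8.3f mg N/L\n", nm, x[[nm]]))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Percentage pathway contributions
#'
#' For a carbon-dosed (`phase2`) apportionment: shares of total nitrogen
#' removal by anammox vs denitritation. For a nitrifying (`phase1`)
#' apportionment: shares of the nitrate production by nitrification (NOB)
#' vs the anammox stoichiometric yield.
#'
#' @param app An `np_apportionment`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
pathway_contributions <- function(app) {
  stopifnot(inherits(app, "np_apportionment"))
  if (app$delta_n <= 0)
    stop("no net nitrogen removal (delta_n <= 0)", call. = FALSE)
  if (app$mode == "phase2") {
    anammox <- app$tn_anammox / app$delta_n * 100
    c(anammox = anammox, denitritation = 100 - anammox)
  } else {
    no3_anammox <- app$tn_anammox * app$params$r_no3_per_tn
    total <- no3_anammox + app$no3_nob
    if (total <= 0)
      stop("no nitrate production to apportion", call. = FALSE)
    c(nitrification = app$no3_nob / total * 100,
      anammox = no3_anammox / total * 100)
  }
}

#' Nitrate produced per ammonium removed
#'
#' The ratio `(no3_f - no3_i) / (nh4_i - nh4_f)` over a cycle. For a pure
#' anammox conversion this equals the stoichiometric 0.26; substantially
#' higher values indicate an additional nitrate source (nitrite oxidation),
#' negative values net nitrate consumption (denitrification).
#'
#' @param endpoints A [cycle_endpoints()] object.
#' @return Numeric ratio (may be negative).
#' @export
delta_nitrate_ammonium_ratio <- function(endpoints) {
  stopifnot(inherits(endpoints, "np_endpoints"))
  dnh4 <- endpoints$nh4_initial - endpoints$nh4_final
  if (dnh4 <= 0)
    stop("no ammonium removal: ratio undefined", call. = FALSE)
  (endpoints$no3_final - endpoints$no3_initial) / dnh4
}
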