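# shared scenario builders

# cycle endpoints produced by applying the anammox reaction (no2, no3 per
# mol NH3) to an ammonium-limited mixture, consuming all ammonium
anammox_endpoints <- function(nh4 = 10, no2_coef = 1.32, no3_coef = 0.26) {
  cycle_endpoints(nh4_initial = nh4, no2_initial = nh4 * no2_coef,
                  no3_initial = 0, nh4_final = 0, no2_final = 0,
                  no3_final = nh4 * no3_coef)
}

# kinetics with selected guilds only (fraction 0 disables a guild)
kin_guilds <- function(anammox = 0, aob = 0, nob = 0, oho = 0, ...) {
  kinetic_params(fractions = c(anammox = anammox, aob = aob, nob = nob,
                               oho = oho), ...)
}

endpoints_from_profile <- function(profile) {
  n <- nrow(profile)
  cycle_endpoints(profile$nh4_mgN_L[1], profile$no2_mgN_L[1],
                  profile$no3_mgN_L[1], profile$nh4_mgN_L[n],
                  profile$no2_mgN_L[n], profile$no3_mgN_L[n])
}

# the anammox-plus-heterotrophs validation cycle used by the oracle-recovery
# checks: anoxic, nitrite- and carbon-rich so every phase-2 pathway integral
# is well above the analytical noise floor
recovery_cycle <- function(rtol = 1e-8) {
  simulate_cycle(c(nh4 = 1, no2 = 8, no3 = 3, cod = 5),
                 c(nh4 = 8, no2 = 25, no3 = 5, cod = 60),
                 kinetics = kin_guilds(anammox = 0.10, oho = 0.20),
                 do_mode = do_prescribed(0), rtol = rtol)
}
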