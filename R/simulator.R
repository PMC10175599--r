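# Kinetic SBR cycle simulator: anammox, AOB, NOB and two-step heterotrophic
# denitrification with dual-Monod rate laws, integrated over the anoxic
# react phase of each cycle. Serves as the synthetic-data generator: every
# simulated cycle carries ground-truth time-integrated pathway fluxes
# against which the endpoint mass-balance apportionment can be validated.

#' SBR cycle schedule
#'
#' Default schedule: 10 min feed at 50 % volume exchange, 360 min anoxic
#' react, 30 min settle, 10 min decant, 70 min idle — 480 min, three cycles
#' per day. Feeding is treated as instantaneous mixing at react start
#' (10 min feed is short against 360 min react), and settling/decant/idle
#' are reaction-free, so cycle endpoints are exactly the react-phase
#' endpoints used by the mass balances.
#'
#' @param feed_min,react_min,settle_min,decant_min,idle_min Phase durations
#'   in minutes.
#' @param exchange_ratio Volume fraction exchanged per feed, in (0, 1].
#' @param cycles_per_day Cycles operated per day.
#' @return Object of class `"np_schedule"`.
#' @export
cycle_schedule <- function(feed_min = 10, react_min = 360, settle_min = 30,
                           decant_min = 10, idle_min = 70,
                           exchange_ratio = 0.5, cycles_per_day = 3) {
  dur <- c(feed_min, react_min, settle_min, decant_min, idle_min)
  if (any(!is.finite(dur)) || any(dur <= 0))
    stop("phase durations must be positive", call. = FALSE)
  if (exchange_ratio <= 0 || exchange_ratio > 1)
    stop("exchange_ratio must be in (0, 1]", call. = FALSE)
  structure(list(feed_min = feed_min, react_min = react_min,
                 settle_min = settle_min, decant_min = decant_min,
                 idle_min = idle_min, exchange_ratio = exchange_ratio,
                 cycles_per_day = cycles_per_day),
            class = "np_schedule")
}

#' Influent specification
#'
#' Each analyte is drawn from a normal distribution truncated at zero.
#' `influent_phase1()` and `influent_phase2()` give the two built-in
#' mainstream regimes: phase I carries essentially no biodegradable
#' organics; phase II adds acetate (readily biodegradable COD) at a
#' carbon/nitrogen ratio of about 0.9.
#'
#' @param phase Label.
#' @param nh4,no2,no3 `c(mean, sd)` in mg N/L.
#' @param cod `c(mean, sd)` readily biodegradable COD in mg/L (acetate).
#' @return Object of class `"np_influent_spec"`.
#' @export
influent_spec <- function(phase, nh4, no2, no3, cod = c(0, 0)) {
  chk <- function(v, nm) {
    if (length(v) != 2 || any(!is.finite(v)) || any(v < 0))
      stop("'", nm, "' must be c(mean, sd), both >= 0", call. = FALSE)
    v
  }
  structure(list(phase = phase, nh4 = chk(nh4, "nh4"), no2 = chk(no2, "no2"),
                 no3 = chk(no3, "no3"), cod = chk(cod, "cod")),
            class = "np_influent_spec")
}

#' @rdname influent_spec
#' @export
influent_phase1 <- function() {
  influent_spec("I", nh4 = c(14.3, 2.5), no2 = c(14.1, 2.4),
                no3 = c(1.2, 0.8), cod = c(0, 0))
}

#' @rdname influent_spec
#' @export
influent_phase2 <- function() {
  # acetate dosed via a raw-wastewater bypass; ~10 % relative variability
  influent_spec("II", nh4 = c(12.5, 1.8), no2 = c(12.3, 1.4),
                no3 = c(2.0, 0.6), cod = c(24.2, 2.4))
}

#' Draw one influent record
#'
#' Normal draws truncated at zero by resampling; deterministic given the
#' RNG state (or an explicit `seed`). Zero sd returns the means exactly.
#'
#' @param spec An [influent_spec()].
#' @param seed Optional integer seed (sets the RNG locally).
#' @return Named numeric vector `nh4, no2, no3, cod`.
#' @export
sample_influent <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "np_influent_spec"))
  if (!is.null(seed)) set.seed(seed)
  draw <- function(ms) {
    if (ms[2] == 0) return(ms[1])
    for (i in 1:1000) {
      x <- stats::rnorm(1, ms[1], ms[2])
      if (x >= 0) return(x)
    }
    0
  }
  c(nh4 = draw(spec$nh4), no2 = draw(spec$no2), no3 = draw(spec$no3),
    cod = draw(spec$cod))
}

#' Kinetic parameters for the simulated guilds
#'
#' Maximum specific rates (mg N or mg COD per g VSS per hour),
#' half-saturation constants (mg/L) and oxygen inhibition constants
#' (mg O2/L) for six processes: anammox, aerobic ammonium oxidation (AOB),
#' nitrite oxidation (NOB), denitratation (NO3- -> NO2-), denitritation
#' (NO2- -> N2) and aerobic COD oxidation. Anoxic guilds are inhibited by
#' dissolved oxygen through a `Ki/(Ki + DO)` switch; aerobic guilds follow
#' a DO Monod term. Defaults are order-of-magnitude literature values for
#' mainstream anammox sludge, chosen so a default cycle removes most of
#' its ammonium and nitrite within the 360-min react phase; they are
#' illustrative, not fitted.
#'
#' COD costs of the heterotrophic steps follow electron bookkeeping on
#' acetate: 16/14 mg COD per mg NO3-N denitratated, 24/14 mg COD per mg
#' NO2-N denitritated.
#'
#' @param x_total Total biomass, g VSS/L (default 4.9).
#' @param fractions Named fractions of `x_total` for `anammox`, `aob`,
#'   `nob`, `oho` (heterotrophs); the remainder is inert.
#' @param anammox,aob,nob,denitratation,denitritation,aerobic Per-guild
#'   parameter lists (see defaults for names/units).
#' @param anammox_no2,anammox_no3 Anammox stoichiometry, mol per mol NH3,
#'   shared with [builtin_reactions()].
#' @param n_deficit Mol N per mol NH3 routed to biomass by anammox (the
#'   element-balance deficit of the conventional equation, 0.02).
#' @return Object of class `"np_kinetics"`.
#' @export
kinetic_params <- function(
    x_total = 4.9,
    fractions = c(anammox = 0.10, aob = 0.02, nob = 0.02, oho = 0.20),
    anammox = list(mu = 5, K_nh4 = 0.07, K_no2 = 0.05, Ki_o2 = 0.2),
    aob = list(mu = 10, K_nh4 = 0.5, K_o2 = 0.3),
    nob = list(mu = 12, K_no2 = 0.3, K_o2 = 0.05),
    denitratation = list(mu = 8, K_no3 = 0.5, K_cod = 5, Ki_o2 = 0.1),
    denitritation = list(mu = 4, K_no2 = 0.5, K_cod = 5, Ki_o2 = 0.1),
    aerobic = list(mu = 20, K_cod = 5, K_o2 = 0.2),
    anammox_no2 = 1.32, anammox_no3 = 0.26, n_deficit = 0.02) {
  if (x_total < 0) stop("x_total must be >= 0", call. = FALSE)
  need <- c("anammox", "aob", "nob", "oho")
  if (!all(need %in% names(fractions)))
    stop("fractions must name ", paste(need, collapse = ", "), call. = FALSE)
  if (any(fractions < 0) || sum(fractions) > 1 + 1e-9)
    stop("fractions must be >= 0 and sum to <= 1", call. = FALSE)
  pars <- list(x_total = x_total, fractions = fractions, anammox = anammox,
               aob = aob, nob = nob, denitratation = denitratation,
               denitritation = denitritation, aerobic = aerobic,
               anammox_no2 = anammox_no2, anammox_no3 = anammox_no3,
               n_deficit = n_deficit)
  flat <- unlist(pars[c("anammox", "aob", "nob", "denitratation",
                        "denitritation", "aerobic")])
  if (any(!is.finite(flat)) || any(flat < 0))
    stop("all rates and constants must be finite and >= 0", call. = FALSE)
  structure(pars, class = "np_kinetics")
}

#' Dissolved-oxygen regime
#'
#' Either a prescribed constant bulk DO (the default; reactors of this kind
#' report DO as a measured near-constant range: ~0.06-0.08 mg/L without
#' organics, ~0.02-0.04 mg/L with organics) or a dynamic balance
#' `dDO/dt = kLa (DO_sat - DO) - uptake`.
#'
#' @param level Constant DO, mg O2/L.
#' @param kla Volumetric transfer coefficient, 1/h.
#' @param do_sat Saturation DO, mg/L.
#' @param do_init Initial DO, mg/L.
#' @return Object of class `"np_do_mode"`.
#' @export
do_prescribed <- function(level = 0.07) {
  stopifnot(is.finite(level), level >= 0)
  structure(list(type = "prescribed", level = level), class = "np_do_mode")
}

#' @rdname do_prescribed
#' @export
do_mass_transfer <- function(kla = 0.5, do_sat = 8.2, do_init = 0.05) {
  stopifnot(kla >= 0, do_sat >= 0, do_init >= 0)
  structure(list(type = "mass_transfer", kla = kla, do_sat = do_sat,
                 do_init = do_init), class = "np_do_mode")
}

# Process rates (mg/L/h) at concentration vector y = c(nh4,no2,no3,cod[,do]).
# Monod terms are evaluated at max(y, 0) so rates vanish smoothly as
# substrates deplete and no concentration can be driven negative beyond
# integrator error.
.rates <- function(y, kin, do) {
  p <- function(v) max(v, 0)
  nh4 <- p(y[["nh4"]]); no2 <- p(y[["no2"]])
  no3 <- p(y[["no3"]]); cod <- p(y[["cod"]])
  X <- kin$x_total * kin$fractions
  a <- kin$anammox
  r_an <- a$mu * X[["anammox"]] * nh4 / (a$K_nh4 + nh4) *
    no2 / (a$K_no2 + no2) * a$Ki_o2 / (a$Ki_o2 + do)
  b <- kin$aob
  r_aob <- b$mu * X[["aob"]] * nh4 / (b$K_nh4 + nh4) * do / (b$K_o2 + do)
  n <- kin$nob
  r_nob <- n$mu * X[["nob"]] * no2 / (n$K_no2 + no2) * do / (n$K_o2 + do)
  d1 <- kin$denitratation
  r_dnra <- d1$mu * X[["oho"]] * no3 / (d1$K_no3 + no3) *
    cod / (d1$K_cod + cod) * d1$Ki_o2 / (d1$Ki_o2 + do)
  d2 <- kin$denitritation
  r_dnri <- d2$mu * X[["oho"]] * no2 / (d2$K_no2 + no2) *
    cod / (d2$K_cod + cod) * d2$Ki_o2 / (d2$Ki_o2 + do)
  ox <- kin$aerobic
  r_codox <- ox$mu * X[["oho"]] * cod / (ox$K_cod + cod) * do / (ox$K_o2 + do)
  c(anammox = r_an, aob = r_aob, nob = r_nob, dnra = r_dnra, dnri = r_dnri,
    codox = r_codox)
}

# mg COD consumed per mg N for the two heterotrophic steps (acetate basis)
.COD_PER_DNRA <- 16 / 14  # NO3- -> NO2-: 2 e- eq/N
.COD_PER_DNRI <- 24 / 14  # NO2- -> N2:   3 e- eq/N
# mg O2 per mg N for nitrifier steps
.O2_PER_AOB <- 48 / 14    # NH3 -> NO2-: 1.5 mol O2/mol N
.O2_PER_NOB <- 16 / 14    # NO2- -> NO3-: 0.5 mol O2/mol N

.derivs <- function(kin, do_mode) {
  dyn_do <- do_mode$type == "mass_transfer"
  function(t, y) {
    do <- if (dyn_do) max(y[["do"]], 0) else do_mode$level
    r <- .rates(y, kin, do)
    a_no2 <- kin$anammox_no2; a_no3 <- kin$anammox_no3
    d <- c(
      nh4 = -r[["anammox"]] - r[["aob"]],
      no2 = -a_no2 * r[["anammox"]] + r[["aob"]] - r[["nob"]] +
        r[["dnra"]] - r[["dnri"]],
      no3 = a_no3 * r[["anammox"]] + r[["nob"]] - r[["dnra"]],
      cod = -.COD_PER_DNRA * r[["dnra"]] - .COD_PER_DNRI * r[["dnri"]] -
        r[["codox"]],
      # cumulative process integrals (the ground truth)
      i_anammox = r[["anammox"]],
      i_aob = r[["aob"]],
      i_nob = r[["nob"]],
      i_dnra = r[["dnra"]],
      i_dnri = r[["dnri"]],
      i_codox = r[["codox"]]
    )
    if (dyn_do) {
      d <- c(d, do = do_mode$kla * (do_mode$do_sat - do) -
               .O2_PER_AOB * r[["aob"]] - .O2_PER_NOB * r[["nob"]] -
               r[["codox"]])
    }
    d
  }
}

.truth_from_integrals <- function(yend, kin) {
  r_tn <- 1 + kin$anammox_no2 - kin$anammox_no3
  i_an <- yend[["i_anammox"]]
  list(
    tn_anammox = r_tn * i_an,
    nh4_anammox = i_an,
    no3_anammox = kin$anammox_no3 * i_an,
    nh4_aob = yend[["i_aob"]],
    no3_nob = yend[["i_nob"]],
    no3_denitratation = yend[["i_dnra"]],
    tn_denitritation = yend[["i_dnri"]],
    n2_n = (r_tn - kin$n_deficit) * i_an + yend[["i_dnri"]],
    n_incorporated = kin$n_deficit * i_an,
    cod_denitratation = .COD_PER_DNRA * yend[["i_dnra"]],
    cod_denitritation = .COD_PER_DNRI * yend[["i_dnri"]],
    cod_aerobic = yend[["i_codox"]]
  )
}

#' Simulate one SBR cycle
#'
#' Feed is mixed instantaneously into the residual liquor at the schedule's
#' exchange ratio, then the react phase is integrated with the configured
#' kinetics. Returns the concentration profile (sampled every
#' `sample_min` minutes), the ground-truth time-integrated pathway fluxes,
#' and the end state (which is also the effluent and the next cycle's
#' residual).
#'
#' @param state Named vector `nh4, no2, no3, cod` (mg/L): residual
#'   concentrations before feeding.
#' @param influent Named vector over the same analytes.
#' @param schedule A [cycle_schedule()].
#' @param kinetics A [kinetic_params()].
#' @param do_mode A [do_prescribed()] or [do_mass_transfer()].
#' @param sample_min Profile output resolution, minutes (<= 5 recommended).
#' @param rtol Integrator relative tolerance.
#' @return List with `profile` (an [batch_profile()]), `truth`
#'   (ground-truth integrals, mg N or COD per L of reactor volume),
#'   `initial` (post-mix concentrations) and `state` (end-of-react
#'   concentrations).
#' @export
simulate_cycle <- function(state, influent, schedule = cycle_schedule(),
                           kinetics = kinetic_params(),
                           do_mode = do_prescribed(0.07),
                           sample_min = 5, rtol = 1e-8) {
  need <- c("nh4", "no2", "no3", "cod")
  if (!all(need %in% names(state)) || !all(need %in% names(influent)))
    stop("state and influent must name nh4, no2, no3, cod", call. = FALSE)
  if (any(state[need] < 0) || any(influent[need] < 0))
    stop("negative concentrations in state or influent", call. = FALSE)
  y0c <- mix_feed(state[need], influent[need], schedule$exchange_ratio)
  y0 <- c(y0c, i_anammox = 0, i_aob = 0, i_nob = 0, i_dnra = 0, i_dnri = 0,
          i_codox = 0)
  if (do_mode$type == "mass_transfer") y0 <- c(y0, do = do_mode$do_init)
  t_h <- schedule$react_min / 60
  times <- unique(c(seq(0, t_h, by = sample_min / 60), t_h))
  sol <- ode_dopri(.derivs(kinetics, do_mode), y0, times,
                   rtol = rtol, atol = 1e-10)
  yend <- sol[nrow(sol), ]
  do_col <- if (do_mode$type == "mass_transfer") pmax(sol[, "do"], 0)
            else rep(do_mode$level, nrow(sol))
  profile <- batch_profile(
    time = times * 60,
    nh4 = pmax(sol[, "nh4"], 0), no2 = pmax(sol[, "no2"], 0),
    no3 = pmax(sol[, "no3"], 0), cod = pmax(sol[, "cod"], 0), do = do_col)
  list(profile = profile,
       truth = .truth_from_integrals(yend, kinetics),
       initial = y0c,
       state = c(nh4 = max(yend[["nh4"]], 0), no2 = max(yend[["no2"]], 0),
                 no3 = max(yend[["no3"]], 0), cod = max(yend[["cod"]], 0)))
}

#' Simulate an anoxic batch test
#'
#' A stirred flask stripped with nitrogen gas: no feed, DO = 0, integration
#' of the same kinetic system over `hours`. Used to emulate
#' partial-denitrification batch tests at varying COD/NO3-N ratios.
#'
#' @param initial Named vector `nh4, no2, no3, cod` (mg/L).
#' @param hours Duration.
#' @param kinetics A [kinetic_params()].
#' @param sample_min Output resolution, minutes.
#' @return List with `profile` and `truth` as in [simulate_cycle()].
#' @export
simulate_batch <- function(initial, hours = 6, kinetics = kinetic_params(),
                           sample_min = 5) {
  need <- c("nh4", "no2", "no3", "cod")
  if (!all(need %in% names(initial)))
    stop("initial must name nh4, no2, no3, cod", call. = FALSE)
  y0 <- c(initial[need], i_anammox = 0, i_aob = 0, i_nob = 0, i_dnra = 0,
          i_dnri = 0, i_codox = 0)
  times <- unique(c(seq(0, hours, by = sample_min / 60), hours))
  sol <- ode_dopri(.derivs(kinetics, do_prescribed(0)), y0, times,
                   rtol = 1e-8, atol = 1e-10)
  profile <- batch_profile(
    time = times * 60,
    nh4 = pmax(sol[, "nh4"], 0), no2 = pmax(sol[, "no2"], 0),
    no3 = pmax(sol[, "no3"], 0), cod = pmax(sol[, "cod"], 0))
  list(profile = profile,
       truth = .truth_from_integrals(sol[nrow(sol), ], kinetics))
}

#' Simulate a multi-day SBR campaign
#'
#' Iterates cycles with carry-over residual concentrations; one influent
#' batch is sampled per day from the phase's specification (a daily feed
#' tank) and fed to that day's cycles. One effluent record is
#' emitted per day (the last cycle's endpoint, recorded in the output
#' metadata). Optional slow linear biomass drift per guild per day.
#' Deterministic given `seed`.
#'
#' @param n_days Number of days (>= 1).
#' @param influent An [influent_spec()].
#' @param schedule,kinetics,do_mode As in [simulate_cycle()].
#' @param seed Integer seed for all randomness in the campaign.
#' @param initial_state Residual concentrations at day 1 cycle 1.
#' @param biomass_drift Named per-day additive change of `fractions`
#'   entries (e.g. `c(nob = 0.0005)`), applied after each day; fractions
#'   are floored at 0.
#' @param keep_truth Keep per-cycle ground truth.
#' @return List of class `"np_campaign"`: `daily` (data.frame: day, phase,
#'   influent/effluent analytes, TN, removal efficiency), `truth`
#'   (per-cycle list or NULL), `meta`.
#' @export
simulate_campaign <- function(n_days, influent = influent_phase1(),
                              schedule = cycle_schedule(),
                              kinetics = kinetic_params(),
                              do_mode = do_prescribed(0.07),
                              seed = 1L,
                              initial_state = c(nh4 = 2, no2 = 2, no3 = 2,
                                                cod = 0),
                              biomass_drift = NULL,
                              keep_truth = FALSE) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  set.seed(seed)
  state <- initial_state
  kin <- kinetics
  rows <- vector("list", n_days)
  truths <- if (keep_truth) list() else NULL
  for (d in seq_len(n_days)) {
    inf_day <- sample_influent(influent)   # daily feed batch composition
    last <- NULL
    for (cy in seq_len(schedule$cycles_per_day)) {
      last <- simulate_cycle(state, inf_day, schedule, kin, do_mode)
      state <- last$state
      if (keep_truth) truths[[length(truths) + 1L]] <-
          c(list(day = d, cycle = cy), last$truth)
    }
    eff <- last$state
    rows[[d]] <- data.frame(
      day = d, phase = influent$phase,
      inf_nh4 = inf_day[["nh4"]], inf_no2 = inf_day[["no2"]],
      inf_no3 = inf_day[["no3"]], inf_cod = inf_day[["cod"]],
      eff_nh4 = eff[["nh4"]], eff_no2 = eff[["no2"]],
      eff_no3 = eff[["no3"]], eff_cod = eff[["cod"]])
    if (!is.null(biomass_drift)) {
      fr <- kin$fractions
      fr[names(biomass_drift)] <- pmax(fr[names(biomass_drift)] +
                                         biomass_drift, 0)
      kin$fractions <- fr
    }
  }
  daily <- do.call(rbind, rows)
  daily$inf_tn <- daily$inf_nh4 + daily$inf_no2 + daily$inf_no3
  daily$eff_tn <- daily$eff_nh4 + daily$eff_no2 + daily$eff_no3
  daily$removal_pct <- nitrogen_removal_efficiency(daily$inf_tn, daily$eff_tn)
  structure(list(daily = daily, truth = truths,
                 meta = list(seed = seed, phase = influent$phase,
                             effluent_convention = "last cycle endpoint")),
            class = "np_campaign")
}

#' Add analytical measurement noise to a profile
#'
#' Each reading gets independent Gaussian noise with standard deviation
#' `sigma_abs + sigma_rel * value`, truncated at zero. Applies to the
#' concentration columns only (not time). Deterministic given `seed`.
#'
#' @param profile An [batch_profile()] or plain data.frame.
#' @param sigma_abs Absolute noise sd, mg/L.
#' @param sigma_rel Relative noise sd (fraction of the reading).
#' @param seed Optional integer seed.
#' @return Profile of the same shape.
#' @export
add_measurement_noise <- function(profile, sigma_abs = 0.2, sigma_rel = 0,
                                  seed = NULL) {
  if (sigma_abs < 0 || sigma_rel < 0)
    stop("noise sigmas must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- profile
  cols <- intersect(c("nh4_mgN_L", "no2_mgN_L", "no3_mgN_L", "cod_mg_L",
                      "do_mg_L"), names(profile))
  for (col in cols) {
    v <- out[[col]]
    sd <- sigma_abs + sigma_rel * v
    out[[col]] <- pmax(v + stats::rnorm(length(v), 0, sd), 0)
  }
  out
}

#' Nitrogen and COD closure of a simulated cycle
#'
#' Checks that the state-variable balances agree with the accumulated
#' process integrals: total inorganic N removed over the react phase must
#' equal dinitrogen-N produced plus N incorporated into biomass, and COD
#' consumed must equal the COD routed to denitratation, denitritation and
#' aerobic oxidation.
#'
#' @param cycle Result of [simulate_cycle()] or [simulate_batch()].
#' @return Named vector: `n_residual_rel`, `cod_residual_rel` (relative to
#'   the amounts converted; 0 when nothing converted).
#' @export
closure_residuals <- function(cycle) {
  pr <- cycle$profile
  first <- 1L; last <- nrow(pr)
  tin0 <- pr$nh4_mgN_L[first] + pr$no2_mgN_L[first] + pr$no3_mgN_L[first]
  tin1 <- pr$nh4_mgN_L[last] + pr$no2_mgN_L[last] + pr$no3_mgN_L[last]
  tr <- cycle$truth
  n_removed <- tin0 - tin1
  n_accounted <- tr$n2_n + tr$n_incorporated
  n_rel <- if (abs(n_accounted) > 0) (n_removed - n_accounted) / n_accounted
           else n_removed
  cod_used <- pr$cod_mg_L[first] - pr$cod_mg_L[last]
  cod_accounted <- tr$cod_denitratation + tr$cod_denitritation + tr$cod_aerobic
  cod_rel <- if (abs(cod_accounted) > 0)
    (cod_used - cod_accounted) / cod_accounted else cod_used
  c(n_residual_rel = n_rel, cod_residual_rel = cod_rel)
}
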