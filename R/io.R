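# File I/O, configuration and fixture generation.
#
# Cycle/batch CSV schema: time_min,nh4_mgN_L,no2_mgN_L,no3_mgN_L
#   [,cod_mg_L,do_mg_L] -- header required, UTF-8, '.' decimal separator.
# Daily campaign CSV schema: day,phase,inf_nh4,inf_no2,inf_no3,inf_cod,
#   eff_nh4,eff_no2,eff_no3,eff_cod (mg/L; TN derived as NH4+NO2+NO3).

.CYCLE_REQUIRED <- c("time_min", "nh4_mgN_L", "no2_mgN_L", "no3_mgN_L")
.CAMPAIGN_REQUIRED <- c("day", "phase", "inf_nh4", "inf_no2", "inf_no3",
                        "inf_cod", "eff_nh4", "eff_no2", "eff_no3", "eff_cod")

#' Read a cycle/batch concentration CSV
#'
#' Validates the schema, coerces numerics and sorts ascending by time.
#'
#' @param path CSV file with columns `time_min,nh4_mgN_L,no2_mgN_L,
#'   no3_mgN_L` and optionally `cod_mg_L`, `do_mg_L`.
#' @return An [batch_profile()].
#' @export
read_cycle_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.CYCLE_REQUIRED, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  cols <- intersect(c(.CYCLE_REQUIRED, "cod_mg_L", "do_mg_L"), names(df))
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "', row ", bad[1],
           " of ", path, call. = FALSE)
    df[[col]] <- v
  }
  df <- df[order(df$time_min), cols, drop = FALSE]
  if (any(duplicated(df$time_min)))
    stop("duplicated time_min values in ", path, call. = FALSE)
  batch_profile(df$time_min, df$nh4_mgN_L, df$no2_mgN_L, df$no3_mgN_L,
                cod = df$cod_mg_L, do = df$do_mg_L)
}

#' Write a cycle/batch profile to CSV
#' @param profile An [batch_profile()] (or compatible data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cycle_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a daily campaign CSV
#' @param path CSV with the campaign schema (see package docs).
#' @return Data frame with derived `inf_tn`, `eff_tn` columns.
#' @export
read_campaign_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.CAMPAIGN_REQUIRED, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$inf_tn <- df$inf_nh4 + df$inf_no2 + df$inf_no3
  df$eff_tn <- df$eff_nh4 + df$eff_no2 + df$eff_no3
  df[order(df$day), , drop = FALSE]
}

#' Write a campaign's daily table to CSV
#' @param campaign An `np_campaign` (from [simulate_campaign()]) or its
#'   `daily` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_campaign_csv <- function(campaign, path) {
  df <- if (inherits(campaign, "np_campaign")) campaign$daily else campaign
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default simulation configuration
#'
#' Bundles schedule, influent, kinetics, DO regime and noise settings for
#' one of the two built-in operating regimes: `"I"` (no organics, DO
#' ~0.07 mg/L) or `"II"` (acetate dosed, DO ~0.03 mg/L).
#'
#' @param phase `"I"` or `"II"`.
#' @param seed Campaign seed.
#' @return Nested list; serializable with [write_config()].
#' @export
default_config <- function(phase = c("I", "II"), seed = 1L) {
  phase <- match.arg(phase)
  list(
    schedule = cycle_schedule(),
    influent = if (phase == "I") influent_phase1() else influent_phase2(),
    kinetics = kinetic_params(),
    do_mode = if (phase == "I") do_prescribed(0.07) else do_prescribed(0.03),
    noise = list(sigma_abs = 0, sigma_rel = 0),
    seed = as.integer(seed)
  )
}

#' Serialize / load a configuration as JSON
#'
#' @param config A configuration list (see [default_config()]).
#' @param path JSON file path.
#' @return `write_config`: `path` invisibly; `read_config`: the list with
#'   classed components restored.
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)  # keep names
    else unclass(x)
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- list(
    schedule = do.call(cycle_schedule, raw$schedule),
    influent = do.call(influent_spec, raw$influent),
    kinetics = do.call(kinetic_params, c(
      raw$kinetics[c("x_total", "anammox_no2", "anammox_no3", "n_deficit")],
      list(fractions = unlist(raw$kinetics$fractions)),
      raw$kinetics[c("anammox", "aob", "nob", "denitratation",
                     "denitritation", "aerobic")])),
    noise = raw$noise,
    seed = raw$seed
  )
  cfg$do_mode <- if (identical(raw$do_mode$type, "prescribed"))
    do_prescribed(raw$do_mode$level)
  else do_mass_transfer(raw$do_mode$kla, raw$do_mode$do_sat,
                        raw$do_mode$do_init)
  cfg
}

#' Reproduce the theoretical demand table of the three process cases
#'
#' Builds the three built-in complete-removal cases from the five
#' half-reactions, solves the closure weights and compares the combined
#' molar O2/acetate coefficients and the oxygen/organic demands against
#' the conventionally published values at 2-decimal rounding (the
#' published demand columns derive from the 2-d.p.-rounded molar
#' coefficients, so the comparison follows the same arithmetic).
#'
#' @param anammox_no2,anammox_no3 Anammox stoichiometry override.
#' @param quiet Suppress printing.
#' @return Data frame with one row per case x quantity: `case`, `quantity`,
#'   `computed`, `reference`, `pass`.
#' @export
reproduce_table2 <- function(anammox_no2 = 1.32, anammox_no3 = 0.26,
                             quiet = FALSE) {
  ref <- list(
    I   = c(o2_molar = 0.85, cod_molar = 0.07, o2_demand = 1.94, cod_demand = 0.32),
    II  = c(o2_molar = 1.03, cod_molar = 0.16, o2_demand = 2.35, cod_demand = 0.73),
    III = c(o2_molar = 0.77, cod_molar = 0.03, o2_demand = 1.76, cod_demand = 0.14)
  )
  rows <- list()
  for (id in names(ref)) {
    cs <- builtin_case(id, anammox_no2, anammox_no3)
    dm <- demands(cs$combined, table_rounding = TRUE)
    for (q in names(ref[[id]])) {
      comp <- round(dm[[q]], 2)
      rows[[length(rows) + 1L]] <- data.frame(
        case = id, quantity = q, computed = comp,
        reference = ref[[id]][[q]],
        pass = isTRUE(all.equal(comp, ref[[id]][[q]], tolerance = 1e-9)))
    }
  }
  out <- do.call(rbind, rows)
  if (!quiet) {
    for (i in seq_len(nrow(out)))
      cat(sprintf("Case %-3s %-11s computed %5.2f  reference %5.2f  [%s]\n",
                  out$case[i], out$quantity[i], out$computed[i],
                  out$reference[i], if (out$pass[i]) "pass" else "MISMATCH"))
  }
  invisible(out)
}

#' Generate small deterministic fixture files
#'
#' Writes, under `out_dir`: a pure-anammox cycle CSV, a nitrifying
#' (phase-I-like) cycle CSV, a carbon-dosed (phase-II-like) cycle CSV,
#' one anoxic batch-test CSV per COD/NO3-N ratio in `ratios` (initial
#' nitrate 15 mg N/L; `batch_test2_*` variants also carry 10 mg N/L
#' ammonium), a 20-day campaign CSV, and a `manifest.json` recording the
#' seed, package version and file digests. Byte-identical for a given
#' seed.
#'
#' @param out_dir Writable directory (created if needed).
#' @param seed Integer seed.
#' @param ratios COD/NO3-N ratios for the batch fixtures.
#' @return Character vector of file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L, ratios = c(0.5, 1, 1.5, 2)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kin <- kinetic_params()
  sched <- cycle_schedule()
  paths <- character(0)
  emit <- function(profile, name) {
    p <- file.path(out_dir, name)
    write_cycle_csv(round(as.data.frame(profile), 6), p)
    paths <<- c(paths, p)
  }
  # pure anammox: nitrifiers and heterotrophs off
  kin_an <- kinetic_params(fractions = c(anammox = 0.10, aob = 0, nob = 0,
                                         oho = 0))
  cyc <- simulate_cycle(c(nh4 = 0.5, no2 = 0.5, no3 = 1, cod = 0),
                        c(nh4 = 14.3, no2 = 18.9, no3 = 1.2, cod = 0),
                        sched, kin_an, do_prescribed(0))
  emit(cyc$profile, "cycle_pure_anammox.csv")
  # nitrifying regime (no organics, DO 0.07)
  cyc1 <- simulate_cycle(c(nh4 = 1, no2 = 1, no3 = 6, cod = 0),
                         c(nh4 = 14.3, no2 = 14.1, no3 = 1.2, cod = 0),
                         sched, kin, do_prescribed(0.07))
  emit(cyc1$profile, "cycle_phase1_like.csv")
  # carbon-dosed regime (acetate, DO 0.03)
  cyc2 <- simulate_cycle(c(nh4 = 0.5, no2 = 0.5, no3 = 1.5, cod = 1),
                         c(nh4 = 12.5, no2 = 12.3, no3 = 2.0, cod = 24.2),
                         sched, kin, do_prescribed(0.03))
  emit(cyc2$profile, "cycle_phase2_like.csv")
  # anoxic batch tests: denitrification only (test I) and with ammonium
  # so anammox engages (test II); initial NO3 fixed at 15 mg N/L
  kin_oho <- kinetic_params(fractions = c(anammox = 0, aob = 0, nob = 0,
                                          oho = 0.20))
  kin_pda <- kinetic_params(fractions = c(anammox = 0.10, aob = 0, nob = 0,
                                          oho = 0.20))
  for (r in ratios) {
    b1 <- simulate_batch(c(nh4 = 0, no2 = 0, no3 = 15, cod = 15 * r),
                         hours = 6, kinetics = kin_oho)
    emit(b1$profile, sprintf("batch_test1_ratio_%.1f.csv", r))
    b2 <- simulate_batch(c(nh4 = 10, no2 = 0, no3 = 15, cod = 15 * r),
                         hours = 6, kinetics = kin_pda)
    emit(b2$profile, sprintf("batch_test2_ratio_%.1f.csv", r))
  }
  # 20-day campaign
  camp <- simulate_campaign(20, influent_phase2(),
                            do_mode = do_prescribed(0.03), seed = seed)
  p <- file.path(out_dir, "campaign_20d.csv")
  write_campaign_csv(cbind(camp$daily[1], camp$daily["phase"],
                           round(camp$daily[-(1:2)], 6)), p)
  paths <- c(paths, p)
  manifest <- list(
    package = "nitropath",
    version = as.character(utils::packageVersion("nitropath")),
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    files = as.list(tools::md5sum(paths))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mp))
}
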