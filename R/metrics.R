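# Batch-test and campaign performance statistics.

#' Batch (or cycle) concentration profile
#'
#' @param time Minutes, strictly increasing, at least two points.
#' @param nh4,no2,no3 Concentrations in mg N/L.
#' @param cod Optional COD in mg/L.
#' @param do Optional dissolved oxygen in mg/L.
#' @return A `data.frame` of class `"np_profile"` with columns `time_min`,
#'   `nh4_mgN_L`, `no2_mgN_L`, `no3_mgN_L` and optionally `cod_mg_L`,
#'   `do_mg_L`.
#' @export
batch_profile <- function(time, nh4, no2, no3, cod = NULL, do = NULL) {
  n <- length(time)
  if (n < 2) stop("at least two time points required", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  lens <- c(length(nh4), length(no2), length(no3))
  if (any(lens != n)) stop("analyte vectors must match time length", call. = FALSE)
  df <- data.frame(time_min = time, nh4_mgN_L = nh4, no2_mgN_L = no2,
                   no3_mgN_L = no3)
  if (!is.null(cod)) df$cod_mg_L <- cod
  if (!is.null(do)) df$do_mg_L <- do
  class(df) <- c("np_profile", "data.frame")
  df
}

#' Nitrate-to-nitrite transformation ratio (NTR)
#'
#' In an anoxic batch test dosed with nitrate and organics, the NTR tracks
#' what fraction of the nitrate reduced so far has accumulated as nitrite:
#' `NTR(t) = (NO2(t) - NO2(0)) / (NO3(0) - NO3(t)) * 100`. A high NTR
#' indicates partial denitrification (denitratation outpacing
#' denitritation), i.e. the batch supplies nitrite that anammox could use.
#' The ratio is only evaluated where at least `eps` mg N/L of nitrate has
#' been reduced, guarding against blow-up at the start of the trace; the
#' maximum is taken over the evaluated series (it can occur mid-test when
#' nitrite later drains to N2).
#'
#' @param profile An [batch_profile()] (or any data.frame with `time_min`,
#'   `no2_mgN_L`, `no3_mgN_L`).
#' @param eps Denominator guard, mg N/L of nitrate reduced (default 0.1,
#'   typical analytical precision).
#' @return List with `time_min`, `ntr` (percent, `NA` where the guard
#'   applies), `max_ntr` (`NA` if nitrate is never reduced beyond `eps`,
#'   with `defined = FALSE`), and `defined`.
#' @export
nitrate_to_nitrite_transformation <- function(profile, eps = 0.1) {
  no3 <- profile$no3_mgN_L
  no2 <- profile$no2_mgN_L
  if (length(no3) < 2) stop("profile needs at least two points", call. = FALSE)
  if (no3[1] <= 0) stop("initial nitrate must be positive", call. = FALSE)
  reduced <- no3[1] - no3
  ntr <- ifelse(reduced > eps, (no2 - no2[1]) / reduced * 100, NA_real_)
  defined <- any(!is.na(ntr))
  list(time_min = profile$time_min, ntr = ntr,
       max_ntr = if (defined) max(ntr, na.rm = TRUE) else NA_real_,
       defined = defined)
}

#' Nitrogen removal efficiency
#'
#' @param influent_tn,effluent_tn Total (inorganic) nitrogen, mg N/L.
#' @return Percent removed, `(1 - effluent/influent) * 100`.
#' @export
nitrogen_removal_efficiency <- function(influent_tn, effluent_tn) {
  if (any(influent_tn <= 0)) stop("influent TN must be positive", call. = FALSE)
  if (any(effluent_tn < 0)) stop("effluent TN must be non-negative", call. = FALSE)
  (1 - effluent_tn / influent_tn) * 100
}

#' Per-phase mean and standard deviation summary of a daily campaign
#'
#' Summarises influent (or effluent) analyte series by operating phase as
#' mean, sample standard deviation (n-1 denominator) and n, the layout in
#' which influent characterisation tables are conventionally reported.
#' TN is derived as NH4-N + NO2-N + NO3-N when the three columns are
#' present and no TN column is.
#'
#' @param campaign Data frame with a `phase` column and numeric analyte
#'   columns (e.g. `inf_nh4`, `inf_no2`, ...).
#' @param columns Analyte columns to summarise; default all numeric columns
#'   except `day`.
#' @return Data frame with one row per phase x analyte: `phase`, `analyte`,
#'   `mean`, `sd`, `n`.
#' @export
phase_summary <- function(campaign, columns = NULL) {
  if (!"phase" %in% names(campaign))
    stop("campaign must have a 'phase' column", call. = FALSE)
  num <- vapply(campaign, is.numeric, logical(1))
  if (is.null(columns))
    columns <- setdiff(names(campaign)[num], c("day", "cycle"))
  phases <- unique(campaign$phase)
  out <- list()
  for (ph in phases) {
    sub <- campaign[campaign$phase == ph, , drop = FALSE]
    if (nrow(sub) < 2)
      stop("phase '", ph, "' has fewer than 2 records", call. = FALSE)
    for (col in columns) {
      x <- sub[[col]]
      out[[length(out) + 1L]] <- data.frame(
        phase = ph, analyte = col, mean = mean(x), sd = stats::sd(x),
        n = length(x))
    }
  }
  do.call(rbind, out)
}
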