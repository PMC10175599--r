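# Process cases: linear combinations of three half-reactions whose weights
# close the nitrogen cycle (no net nitrite or nitrate) while consuming
# exactly 1 mol NH3, plus the resulting theoretical oxygen/organic demands.

#' Solve closure weights for a three-reaction process case
#'
#' Finds weights w >= 0 such that the weighted combination has zero net
#' nitrite, zero net nitrate, and consumes exactly one mol of ammonia:
#' a 3x3 linear system in the weights.
#'
#' @param reactions Ordered list of exactly three `np_reaction` objects.
#' @return Numeric weight vector of length 3 (named by reaction).
#' @examples
#' rx <- builtin_reactions()
#' solve_case_weights(list(rx$partial_nitritation, rx$anammox,
#'                         rx$complete_denitrification))
#' # ~ c(1.32, 1, 0.26) / 2.32
#' @export
solve_case_weights <- function(reactions) {
  if (length(reactions) != 3)
    stop("exactly three reactions required", call. = FALSE)
  A <- vapply(reactions, function(r)
    c(coefficient(r, "NO2-"), coefficient(r, "NO3-"), coefficient(r, "NH3")),
    numeric(3))
  b <- c(0, 0, -1)
  qrA <- qr(A)
  if (qrA$rank < 3)
    stop("singular closure system (rank ", qrA$rank,
         " of 3): the three reactions cannot close nitrite/nitrate while consuming NH3",
         call. = FALSE)
  w <- solve(qrA, b)
  if (any(w < -1e-12))
    stop("infeasible case: solved weights are negative (",
         paste(signif(w, 4), collapse = ", "), ")", call. = FALSE)
  stats::setNames(pmax(w, 0),
                  vapply(reactions, function(r) r$name, character(1)))
}

#' Demand summary of a combined reaction
#'
#' Theoretical oxygen and organic (COD) demands per unit ammonia nitrogen of
#' a combined reaction normalized to 1 mol NH3. Oxygen demand is
#' `|O2 coefficient| * 32/14` mg O2/mg N; organic demand sums, over organic
#' reactants, `|coefficient| * ThOD / 14` mg COD/mg N (acetate: ThOD
#' 64 g O2/mol). The nitrogen basis is NH3-N only (14 g N/mol).
#'
#' With `table_rounding = TRUE` the molar coefficients are rounded to two
#' decimals before the mg-basis conversion, which mirrors how such tables
#' are conventionally printed (demands recomputed from the rounded
#' published coefficients); full-precision values are the default.
#'
#' @param combined An `np_reaction` normalized to 1 mol NH3
#'   (see [normalize_to_basis()]).
#' @param registry Species registry for ThOD lookups.
#' @param table_rounding Round molar coefficients to 2 d.p. before
#'   converting, and round the demands to 2 d.p.
#' @return List of class `"np_demands"`: `o2_molar` (mol O2/mol NH3),
#'   `o2_demand` (mg O2/mg N), `cod_molar` (mol acetate-equivalent e-donor /
#'   mol NH3), `cod_demand` (mg COD/mg N).
#' @export
demands <- function(combined, registry = species_registry(),
                    table_rounding = FALSE) {
  stopifnot(inherits(combined, "np_reaction"))
  nh3 <- coefficient(combined, "NH3")
  if (abs(abs(nh3) - 1) > 1e-6)
    stop("combined reaction must be normalized to 1 mol NH3 (coefficient is ",
         signif(nh3, 4), ")", call. = FALSE)
  o2_molar <- abs(min(coefficient(combined, "O2"), 0))
  # organic reactants: carbonaceous species consumed
  cod_molar <- 0
  cod_g <- 0
  for (sym in names(combined$coeffs)) {
    k <- combined$coeffs[[sym]]
    sp <- registry[[sym]]
    if (is.null(sp) || k >= 0) next
    if (sp$composition[["C"]] == 0) next
    kk <- if (table_rounding) round(abs(k), 2) else abs(k)
    t <- thod(sp)
    if (t <= 0) next
    cod_molar <- cod_molar + kk
    cod_g <- cod_g + kk * t
  }
  if (table_rounding) o2_molar <- round(o2_molar, 2)
  out <- list(
    o2_molar = o2_molar,
    o2_demand = o2_molar * .MW_O2 / .MW_N,
    cod_molar = cod_molar,
    cod_demand = cod_g / .MW_N
  )
  if (table_rounding) {
    out$o2_demand <- round(out$o2_demand, 2)
    out$cod_demand <- round(out$cod_demand, 2)
  }
  structure(out, class = "np_demands")
}

#' @export
print.np_demands <- function(x, ...) {
  cat(sprintf("O2:  %.4f mol/mol NH3  = %.4f mg O2/mg N\n", x$o2_molar, x$o2_demand))
  cat(sprintf("COD: %.4f mol/mol NH3  = %.4f mg COD/mg N\n", x$cod_molar, x$cod_demand))
  invisible(x)
}

#' Build a closed process case from three reactions
#'
#' Solves the closure weights, forms the weighted combination, normalizes it
#' to 1 mol NH3 and attaches the demand summary.
#'
#' @param case_id Label (e.g. `"I"`, `"II"`, `"III"` or user-defined).
#' @param reactions Ordered list of three `np_reaction` objects.
#' @param registry Species registry.
#' @return Object of class `"np_process_case"` with elements `case_id`,
#'   `members` (reactions), `weights`, `combined` (normalized reaction) and
#'   `demands`.
#' @export
process_case <- function(case_id, reactions, registry = species_registry()) {
  w <- solve_case_weights(reactions)
  combined <- combine_reactions(reactions, weights = w,
                                name = paste0("case_", case_id, "_total"))
  combined <- normalize_to_basis(combined, "NH3")
  for (sp in c("NO2-", "NO3-")) {
    if (abs(coefficient(combined, sp)) > 1e-9)
      stop("closure failed for ", sp, call. = FALSE)
  }
  structure(
    list(case_id = case_id, members = reactions, weights = w,
         combined = combined,
         demands = demands(combined, registry)),
    class = "np_process_case"
  )
}

#' @export
print.np_process_case <- function(x, ...) {
  cat(sprintf("<process case %s>\n", x$case_id))
  for (i in seq_along(x$members))
    cat(sprintf("  %-26s w = %.4f\n", x$members[[i]]$name, x$weights[i]))
  cat("  total:", format_reaction(x$combined), "\n")
  print(x$demands)
  invisible(x)
}

#' Built-in complete-nitrogen-removal cases
#'
#' The three canonical routes to complete nitrogen removal around anammox:
#' \describe{
#'   \item{I}{partial nitritation/anammox with heterotrophic
#'     denitrification of the residual nitrate (PN/A + denitrification)}
#'   \item{II}{complete nitrification followed by partial
#'     denitrification/anammox (complete nitrification + PD/A)}
#'   \item{III}{partial nitritation/anammox with partial denitrification of
#'     the residual nitrate feeding nitrite back to anammox (PN/A + PD/A)}
#' }
#'
#' @param id One of `"I"`, `"II"`, `"III"`.
#' @param anammox_no2,anammox_no3 Anammox stoichiometry passed to
#'   [builtin_reactions()].
#' @return An `np_process_case`.
#' @examples
#' builtin_case("III")$demands
#' @export
builtin_case <- function(id = c("I", "II", "III"),
                         anammox_no2 = 1.32, anammox_no3 = 0.26) {
  id <- match.arg(id)
  rx <- builtin_reactions(anammox_no2, anammox_no3)
  members <- switch(id,
    I   = list(rx$partial_nitritation, rx$anammox, rx$complete_denitrification),
    II  = list(rx$complete_nitrification, rx$partial_denitrification, rx$anammox),
    III = list(rx$partial_nitritation, rx$anammox, rx$partial_denitrification))
  process_case(id, members)
}

#' Nitrate yield of partial nitritation/anammox
#'
#' Fraction of influent ammonium that ends up as nitrate when partial
#' nitritation and anammox are combined with nitrite closure only (no
#' denitrification step): the weight of partial nitritation is set so net
#' nitrite is zero, the combination is normalized to 1 mol NH3, and the net
#' NO3- coefficient is returned. With the default anammox stoichiometry
#' this is 0.26/2.32, about 11 % of the ammonium.
#'
#' @inheritParams builtin_case
#' @return Fraction (mol NO3-N per mol NH3-N fed).
#' @export
pna_nitrate_yield <- function(anammox_no2 = 1.32, anammox_no3 = 0.26) {
  rx <- builtin_reactions(anammox_no2, anammox_no3)
  pn <- rx$partial_nitritation
  am <- rx$anammox
  # weight on PN per unit anammox so that net NO2- is zero
  w_pn <- -coefficient(am, "NO2-") / coefficient(pn, "NO2-")
  comb <- combine_reactions(list(pn, am), weights = c(w_pn, 1), name = "PN/A")
  comb <- normalize_to_basis(comb, "NH3")
  coefficient(comb, "NO3-")
}
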