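# Reactions as signed molar coefficient vectors (reactants < 0, products > 0).
# All combination math is plain linear algebra over these vectors, which makes
# the closure constraints (net nitrite = net nitrate = 0) linear equalities.

#' Define a reaction
#'
#' @param name Label for the reaction.
#' @param coeffs Named numeric vector of signed molar coefficients over
#'   species symbols; reactants negative, products positive.
#' @param empirical Mark reactions with known element-balance residuals.
#'   The anammox equation as commonly written omits biomass synthesis and
#'   does not balance exactly; `empirical = TRUE` routes it through a
#'   relaxed balance check instead of silently loosening the global
#'   tolerance.
#' @return An object of class `"np_reaction"`.
#' @examples
#' reaction("partial_nitritation",
#'          c("NH3" = -1, "O2" = -1.5, "NO2-" = 1, "H2O" = 1, "H+" = 1))
#' @export
reaction <- function(name, coeffs, empirical = FALSE) {
  if (is.null(names(coeffs)) || any(names(coeffs) == ""))
    stop("`coeffs` must be a named numeric vector", call. = FALSE)
  if (any(!is.finite(coeffs)))
    stop("coefficients must be finite", call. = FALSE)
  if (!any(coeffs < 0) || !any(coeffs > 0))
    stop("a reaction needs at least one reactant (negative) and one product (positive) coefficient",
         call. = FALSE)
  structure(
    list(name = name, coeffs = coeffs, empirical = isTRUE(empirical)),
    class = "np_reaction"
  )
}

#' @export
print.np_reaction <- function(x, digits = 3, ...) {
  cat(sprintf("<reaction> %s%s\n", x$name,
              if (x$empirical) " (empirical)" else ""))
  cat(" ", format_reaction(x, digits = digits), "\n")
  invisible(x)
}

#' Format a reaction as a chemical equation string
#'
#' @param rxn An [reaction()] object.
#' @param digits Significant digits for coefficients.
#' @return Character scalar like `"NH3 + 1.32 NO2- -> ..."`.
#' @export
format_reaction <- function(rxn, digits = 3) {
  side <- function(co) {
    paste(vapply(seq_along(co), function(i) {
      v <- signif(abs(co[i]), digits)
      if (isTRUE(all.equal(v, 1))) names(co)[i]
      else paste0(format(v), " ", names(co)[i])
    }, character(1)), collapse = " + ")
  }
  lhs <- rxn$coeffs[rxn$coeffs < 0]
  rhs <- rxn$coeffs[rxn$coeffs > 0]
  paste(side(lhs), "->", side(rhs))
}

#' Built-in nitrogen-cycle reactions
#'
#' The five reactions used throughout the package, as conventionally written
#' per mol of the leading substrate:
#' \describe{
#'   \item{partial_nitritation}{NH3 + 1.5 O2 -> NO2- + H2O + H+}
#'   \item{complete_nitrification}{NH3 + 2 O2 -> NO3- + H2O + H+}
#'   \item{anammox}{NH3 + 1.32 NO2- + H+ -> 1.02 N2 + 0.26 NO3- + 2 H2O
#'     (empirical: the biomass-synthesis term is omitted, so element and
#'     charge residuals are nonzero)}
#'   \item{partial_denitrification}{NO3- + 0.25 CH3COO- -> NO2- +
#'     0.25 HCO3- + 0.25 CO2 + 0.25 H2O (denitratation)}
#'   \item{complete_denitrification}{NO3- + 0.625 CH3COO- + 0.625 H+ ->
#'     0.5 N2 + HCO3- + 0.25 CO2 + 0.75 H2O}
#' }
#'
#' @param anammox_no2 Nitrite consumed per ammonium by anammox (mol/mol).
#' @param anammox_no3 Nitrate produced per ammonium by anammox (mol/mol).
#'   The N2 coefficient adjusts so nitrogen closure of the anammox reaction
#'   keeps its default 0.02 mol biomass-N deficit per mol NH3.
#' @return Named list of `np_reaction` objects.
#' @export
builtin_reactions <- function(anammox_no2 = 1.32, anammox_no3 = 0.26) {
  stopifnot(is.finite(anammox_no2), anammox_no2 > 0,
            is.finite(anammox_no3), anammox_no3 >= 0)
  # keep the conventional 0.02 mol N biomass deficit: N2-N = 1 + no2 - no3 - 0.02
  n2 <- (1 + anammox_no2 - anammox_no3 - 0.02) / 2
  list(
    partial_nitritation = reaction(
      "partial_nitritation",
      c("NH3" = -1, "O2" = -1.5, "NO2-" = 1, "H2O" = 1, "H+" = 1)),
    complete_nitrification = reaction(
      "complete_nitrification",
      c("NH3" = -1, "O2" = -2, "NO3-" = 1, "H2O" = 1, "H+" = 1)),
    anammox = reaction(
      "anammox",
      c("NH3" = -1, "NO2-" = -anammox_no2, "H+" = -1,
        "N2" = n2, "NO3-" = anammox_no3, "H2O" = 2),
      empirical = TRUE),
    partial_denitrification = reaction(
      "partial_denitrification",
      c("NO3-" = -1, "CH3COO-" = -0.25,
        "NO2-" = 1, "HCO3-" = 0.25, "CO2" = 0.25, "H2O" = 0.25)),
    complete_denitrification = reaction(
      "complete_denitrification",
      c("NO3-" = -1, "CH3COO-" = -0.625, "H+" = -0.625,
        "N2" = 0.5, "HCO3-" = 1, "CO2" = 0.25, "H2O" = 0.75))
  )
}

#' Element and charge balance residuals of a reaction
#'
#' For each element e, residual(e) = sum over species of
#' coefficient x atom count, with products positive; a balanced reaction has
#' all residuals zero. The charge residual is computed the same way from the
#' species charges.
#'
#' @param rxn A [reaction()] object.
#' @param registry Species registry, default [species_registry()].
#' @return Named numeric vector with components `C`, `H`, `O`, `N`, `charge`
#'   (mol per formula unit).
#' @export
element_balance <- function(rxn, registry = species_registry()) {
  stopifnot(inherits(rxn, "np_reaction"))
  unknown <- setdiff(names(rxn$coeffs), names(registry))
  if (length(unknown))
    stop("unknown species in reaction '", rxn$name, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  res <- c(C = 0, H = 0, O = 0, N = 0, charge = 0)
  for (sym in names(rxn$coeffs)) {
    sp <- registry[[sym]]
    k <- rxn$coeffs[[sym]]
    res[c("C", "H", "O", "N")] <- res[c("C", "H", "O", "N")] + k * sp$composition
    res[["charge"]] <- res[["charge"]] + k * sp$charge
  }
  res
}

#' Check a reaction's balance against tolerance
#'
#' Non-empirical reactions must balance to `tol`; empirical reactions are
#' allowed residuals up to `empirical_tol` (the anammox equation's known
#' residuals are at most 0.14 mol).
#'
#' @inheritParams element_balance
#' @param tol,empirical_tol Absolute residual tolerances (mol).
#' @return `TRUE` invisibly, or an error describing the imbalance.
#' @export
assert_balanced <- function(rxn, registry = species_registry(),
                            tol = 1e-9, empirical_tol = 0.2) {
  res <- element_balance(rxn, registry)
  lim <- if (rxn$empirical) empirical_tol else tol
  bad <- abs(res) > lim
  if (any(bad))
    stop("reaction '", rxn$name, "' is unbalanced: ",
         paste(sprintf("%s %+0.3g", names(res)[bad], res[bad]), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Linear combination of reactions
#'
#' Coefficient-wise weighted sum of the member reactions; species whose
#' summed coefficient has magnitude below `drop_tol` are dropped.
#'
#' @param members List of `list(reaction, weight)` pairs, or a list of
#'   reactions together with a `weights` vector.
#' @param weights Numeric weights (finite, >= 0), one per member.
#' @param name Name for the combined reaction.
#' @param drop_tol Magnitude below which a summed coefficient is treated as
#'   zero and removed.
#' @return An `np_reaction`.
#' @examples
#' rx <- builtin_reactions()
#' combine_reactions(list(rx$partial_nitritation, rx$anammox),
#'                   weights = c(1.32, 1) / 2.32)
#' @export
combine_reactions <- function(members, weights = NULL, name = "combined",
                              drop_tol = 1e-9) {
  if (length(members) == 0)
    stop("empty member list", call. = FALSE)
  if (is.null(weights)) {
    weights <- vapply(members, function(m) m[[2]], numeric(1))
    members <- lapply(members, function(m) m[[1]])
  }
  if (length(weights) != length(members))
    stop("one weight per member reaction required", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  all_sp <- unique(unlist(lapply(members, function(r) names(r$coeffs))))
  total <- stats::setNames(numeric(length(all_sp)), all_sp)
  for (i in seq_along(members)) {
    co <- members[[i]]$coeffs
    total[names(co)] <- total[names(co)] + weights[i] * co
  }
  total <- total[abs(total) >= drop_tol]
  reaction(name, total,
           empirical = any(vapply(members, function(r) r$empirical, logical(1)) &
                             weights > 0))
}

#' Rescale a reaction to unit coefficient of a basis species
#'
#' Divides all coefficients by the magnitude of the basis species'
#' coefficient, so the basis ends at +1 or -1 with its original sign.
#' Combined process reactions are conventionally written per 1 mol NH3.
#'
#' @param rxn An `np_reaction`.
#' @param basis Species symbol, default `"NH3"`.
#' @return An `np_reaction`.
#' @export
normalize_to_basis <- function(rxn, basis = "NH3") {
  stopifnot(inherits(rxn, "np_reaction"))
  b <- rxn$coeffs[basis]
  if (is.na(b) || b == 0)
    stop("basis species '", basis, "' absent or zero in reaction '",
         rxn$name, "'", call. = FALSE)
  out <- rxn
  out$coeffs <- rxn$coeffs / abs(b)
  out
}

#' Coefficient of a species in a reaction (0 if absent)
#' @param rxn An `np_reaction`.
#' @param sp Species symbol.
#' @return Numeric scalar.
#' @export
coefficient <- function(rxn, sp) {
  v <- unname(rxn$coeffs[sp])
  if (is.na(v)) 0 else v
}
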