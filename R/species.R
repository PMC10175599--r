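# Species registry: elemental composition over {C,H,O,N} plus ionic charge.
# Everything downstream (element balances, ThOD) is bookkeeping over these.

#' Define a chemical species
#'
#' A species is a short symbol together with its elemental composition over
#' C, H, O and N and its net ionic charge. Species are the atoms of the
#' stoichiometric engine: reactions are signed molar coefficient vectors
#' over a registry of species.
#'
#' @param symbol Short identifier, e.g. `"NH3"`, `"CH3COO-"`.
#' @param C,H,O,N Non-negative atom counts.
#' @param charge Signed integer, elementary charges.
#' @return An object of class `"np_species"`.
#' @examples
#' species("CH3COO-", C = 2, H = 3, O = 2, charge = -1)
#' @export
species <- function(symbol, C = 0, H = 0, O = 0, N = 0, charge = 0) {
  comp <- c(C = C, H = H, O = O, N = N)
  if (any(!is.finite(comp)) || any(comp < 0))
    stop("atom counts must be finite and non-negative", call. = FALSE)
  if (!is.finite(charge))
    stop("charge must be finite", call. = FALSE)
  structure(
    list(symbol = symbol, composition = comp, charge = charge),
    class = "np_species"
  )
}

#' @export
print.np_species <- function(x, ...) {
  comp <- x$composition[x$composition > 0]
  cat(sprintf("<species> %s  [%s]  charge %+d\n", x$symbol,
              paste(names(comp), comp, sep = "", collapse = " "),
              as.integer(x$charge)))
  invisible(x)
}

#' Built-in species registry
#'
#' All species appearing in the built-in nitrogen-cycle reactions:
#' ammonia, oxygen, nitrite, nitrate, dinitrogen, water, protons, acetate,
#' bicarbonate and carbon dioxide.
#'
#' @param extra Optional named list of additional [species()] objects; names
#'   must match each species' symbol and not collide with built-ins.
#' @return Named list of `np_species`.
#' @export
species_registry <- function(extra = NULL) {
  reg <- list(
    "NH3"     = species("NH3",     N = 1, H = 3),
    "O2"      = species("O2",      O = 2),
    "NO2-"    = species("NO2-",    N = 1, O = 2, charge = -1),
    "NO3-"    = species("NO3-",    N = 1, O = 3, charge = -1),
    "N2"      = species("N2",      N = 2),
    "H2O"     = species("H2O",     H = 2, O = 1),
    "H+"      = species("H+",      H = 1, charge = +1),
    "CH3COO-" = species("CH3COO-", C = 2, H = 3, O = 2, charge = -1),
    "HCO3-"   = species("HCO3-",   C = 1, H = 1, O = 3, charge = -1),
    "CO2"     = species("CO2",     C = 1, O = 2)
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(names(extra) == ""))
      stop("`extra` must be a named list", call. = FALSE)
    for (nm in names(extra)) {
      sp <- extra[[nm]]
      if (!inherits(sp, "np_species"))
        stop("`extra` entries must be species() objects", call. = FALSE)
      if (!identical(sp$symbol, nm))
        stop("registry name '", nm, "' does not match species symbol '",
             sp$symbol, "'", call. = FALSE)
      if (nm %in% names(reg))
        stop("species '", nm, "' already in registry", call. = FALSE)
      reg[[nm]] <- sp
    }
  }
  reg
}

#' Theoretical oxygen demand of a carbonaceous species
#'
#' ThOD from electron equivalents: 8 g O2 per electron equivalent, with
#' `4*C + H - 2*O - charge` equivalents per mol. Only C/H/O (plus charge)
#' species are accepted; the carbonaceous/nitrogenous ThOD split is not
#' modelled, so nitrogen-containing organics are rejected. Fixed inorganic
#' nitrogen species are handled elsewhere and never passed here.
#'
#' @param sp A [species()] object.
#' @return g O2 per mol (never negative; fully oxidised species give 0).
#' @examples
#' thod(species("CH3COO-", C = 2, H = 3, O = 2, charge = -1)) # 64
#' @export
thod <- function(sp) {
  stopifnot(inherits(sp, "np_species"))
  comp <- sp$composition
  if (comp[["N"]] > 0)
    stop("ThOD of nitrogen-containing species '", sp$symbol,
         "' is not modelled (carbonaceous demand only)", call. = FALSE)
  eeq <- 4 * comp[["C"]] + comp[["H"]] - 2 * comp[["O"]] - sp$charge
  max(0, 8 * eeq)
}

# molar masses used for mg-basis conversions
.MW_N <- 14    # g N/mol
.MW_O2 <- 32   # g O2/mol
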