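# Reaction networks for the four metabolic media.
#
# Each medium is a list of solutes (with diffusivity and bulk Dirichlet value)
# and reactions. A reaction is driven by the biomass of one lineage and has a
# per-biomass rate
#     max_rate * prod_m C_m/(C_m + K_m) * prod_i Ki_i/(C_i + Ki_i)
# together with a stoichiometry map in g solute per g biomass formed
# (negative = consumed). Nutrient/by-product consumption is -1/Y, toxin and
# by-product release is +1, and every R growth route removes antibiotic at
# -alpha (growth-coupled detoxification; no enzyme is released).

MEDIUM_NAMES <- c("interference_competition", "exploitation_competition",
                  "non_crossfeeding", "crossfeeding")

#' Monod saturation factor
#'
#' @param C substrate concentration (g/L), non-negative.
#' @param K half-saturation constant (g/L), positive.
#' @return `C / (C + K)`, in `[0, 1)`.
#' @examples
#' monod_factor(3.5e-5, 3.5e-5) # 0.5
#' @export
monod_factor <- function(C, K) {
  if (any(C < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (any(K <= 0)) stop("half-saturation constant must be positive", call. = FALSE)
  C / (C + K)
}

#' Hyperbolic inhibition factor
#'
#' Bacteriostatic inhibition by an antibiotic or toxin: growth is scaled by
#' `Ki / (C + Ki)`, which is 1 with no inhibitor and decays hyperbolically.
#'
#' @param C inhibitor concentration (g/L), non-negative.
#' @param Ki inhibitory constant (g/L), positive.
#' @return `Ki / (C + Ki)`, in `(0, 1]`.
#' @examples
#' inhibition_factor(0.2, 0.1) # 1/3
#' @export
inhibition_factor <- function(C, Ki) {
  if (any(C < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (any(Ki <= 0)) stop("inhibitory constant must be positive", call. = FALSE)
  Ki / (C + Ki)
}

solute_spec <- function(name, diffusivity, bulk_value) {
  stopifnot(diffusivity > 0, bulk_value >= 0)
  list(name = name, diffusivity = diffusivity, bulk_value = bulk_value)
}

reaction_spec <- function(actor, max_rate, monod, inhibition, stoich) {
  list(actor = actor, max_rate = max_rate, monod = monod,
       inhibition = inhibition, stoich = stoich)
}

#' Construct the reaction network of one metabolic medium
#'
#' Builds the solute list and reaction set that define one of the four
#' ecological scenarios:
#' \describe{
#'   \item{`interference_competition`}{R and S share nutrient `N` and each
#'     releases a toxin (`T_R`, `T_S`) that inhibits the other's growth.}
#'   \item{`exploitation_competition`}{R and S share nutrient `N`; no toxins.}
#'   \item{`non_crossfeeding`}{private nutrients `N_R` and `N_S`; no coupling
#'     through solutes (only competition for space remains).}
#'   \item{`crossfeeding`}{private nutrients plus reciprocal by-product
#'     feeding: R releases `E_R` (food for S) while growing on `N_R` or on
#'     `E_S`, and vice versa; each lineage has two additive growth routes.}
#' }
#' S growth reactions always carry the antibiotic inhibition factor
#' `Ki_A/(A + Ki_A)`; R growth uses the reduced rate `mu_max - cost_c` and
#' removes antibiotic at `alpha_detox` g per g of new biomass on every route.
#' Both private nutrients share the bulk value `N_bulk`; by-products and
#' toxins have bulk value 0 (they are only produced inside the biofilm and
#' are washed out at the boundary).
#'
#' @param name medium name, one of `"interference_competition"`,
#'   `"exploitation_competition"`, `"non_crossfeeding"`, `"crossfeeding"`.
#' @param params a [parameter_set()].
#' @param cost_c cost of resistance (h^-1).
#' @param alpha_detox detoxification coefficient (g antibiotic per g biomass).
#' @return an object of class `medium_definition` with elements `name`,
#'   `solutes` (list of solute specs) and `reactions` (list of reaction
#'   specs).
#' @examples
#' med <- build_medium("crossfeeding", parameter_set())
#' length(med$reactions) # 4
#' @export
build_medium <- function(name, params = parameter_set(), cost_c = 0,
                         alpha_detox = 0) {
  if (!is.character(name) || length(name) != 1L || !(name %in% MEDIUM_NAMES)) {
    stop("unknown medium name: ", paste(name, collapse = ", "),
         " (must be one of ", paste(MEDIUM_NAMES, collapse = ", "), ")",
         call. = FALSE)
  }
  stopifnot(inherits(params, "parameter_set"))
  if (cost_c < 0 || cost_c >= params$mu_max) {
    stop("cost of resistance must satisfy 0 <= cost_c < mu_max", call. = FALSE)
  }
  if (alpha_detox < 0) stop("alpha_detox must be >= 0", call. = FALSE)

  p <- params
  mu_R <- p$mu_max - cost_c
  mu_S <- p$mu_max
  sol <- function(nm, bulk) {
    D <- switch(substr(nm, 1, 1), N = p$D_N, E = p$D_E, T = p$D_T, A = p$D_A)
    solute_spec(nm, D, bulk)
  }

  if (name == "exploitation_competition") {
    solutes <- list(sol("N", p$N_bulk), sol("A", p$A_bulk))
    reactions <- list(
      reaction_spec("R", mu_R,
                    monod = list(list(solute = "N", K = p$K_N)),
                    inhibition = list(),
                    stoich = c(N = -1 / p$Y_N, A = -alpha_detox)),
      reaction_spec("S", mu_S,
                    monod = list(list(solute = "N", K = p$K_N)),
                    inhibition = list(list(solute = "A", Ki = p$Ki_A)),
                    stoich = c(N = -1 / p$Y_N)))
  } else if (name == "interference_competition") {
    solutes <- list(sol("N", p$N_bulk), sol("T_R", 0), sol("T_S", 0),
                    sol("A", p$A_bulk))
    reactions <- list(
      reaction_spec("R", mu_R,
                    monod = list(list(solute = "N", K = p$K_N)),
                    inhibition = list(list(solute = "T_S", Ki = p$Ki_T)),
                    stoich = c(N = -1 / p$Y_N, T_R = 1, A = -alpha_detox)),
      reaction_spec("S", mu_S,
                    monod = list(list(solute = "N", K = p$K_N)),
                    inhibition = list(list(solute = "A", Ki = p$Ki_A),
                                      list(solute = "T_R", Ki = p$Ki_T)),
                    stoich = c(N = -1 / p$Y_N, T_S = 1)))
  } else if (name == "non_crossfeeding") {
    solutes <- list(sol("N_R", p$N_bulk), sol("N_S", p$N_bulk), sol("A", p$A_bulk))
    reactions <- list(
      reaction_spec("R", mu_R,
                    monod = list(list(solute = "N_R", K = p$K_N)),
                    inhibition = list(),
                    stoich = c(N_R = -1 / p$Y_N, A = -alpha_detox)),
      reaction_spec("S", mu_S,
                    monod = list(list(solute = "N_S", K = p$K_N)),
                    inhibition = list(list(solute = "A", Ki = p$Ki_A)),
                    stoich = c(N_S = -1 / p$Y_N)))
  } else { # crossfeeding
    solutes <- list(sol("N_R", p$N_bulk), sol("N_S", p$N_bulk),
                    sol("E_R", 0), sol("E_S", 0), sol("A", p$A_bulk))
    reactions <- list(
      reaction_spec("R", mu_R,
                    monod = list(list(solute = "N_R", K = p$K_N)),
                    inhibition = list(),
                    stoich = c(N_R = -1 / p$Y_N, E_R = 1, A = -alpha_detox)),
      reaction_spec("R", mu_R,
                    monod = list(list(solute = "E_S", K = p$K_E)),
                    inhibition = list(),
                    stoich = c(E_S = -1 / p$Y_E, E_R = 1, A = -alpha_detox)),
      reaction_spec("S", mu_S,
                    monod = list(list(solute = "N_S", K = p$K_N)),
                    inhibition = list(list(solute = "A", Ki = p$Ki_A)),
                    stoich = c(N_S = -1 / p$Y_N, E_S = 1)),
      reaction_spec("S", mu_S,
                    monod = list(list(solute = "E_R", K = p$K_E)),
                    inhibition = list(list(solute = "A", Ki = p$Ki_A)),
                    stoich = c(E_R = -1 / p$Y_E, E_S = 1)))
  }

  structure(list(name = name, params = p, cost_c = cost_c,
                 alpha_detox = alpha_detox, solutes = solutes,
                 reactions = reactions),
            class = "medium_definition")
}

#' @export
print.medium_definition <- function(x, ...) {
  cat(sprintf("Medium '%s': %d solutes (%s), %d reactions; cost = %g/h, alpha = %g g/g\n",
              x$name, length(x$solutes),
              paste(solute_names(x), collapse = ", "),
              length(x$reactions), x$cost_c, x$alpha_detox))
  invisible(x)
}

solute_names <- function(medium) vapply(medium$solutes, `[[`, "", "name")

solute_bulk_values <- function(medium) {
  stats::setNames(vapply(medium$solutes, `[[`, 0, "bulk_value"),
                  solute_names(medium))
}

solute_diffusivities <- function(medium) {
  stats::setNames(vapply(medium$solutes, `[[`, 0, "diffusivity"),
                  solute_names(medium))
}

# Per-biomass rate of one reaction given local concentrations (vectorised
# over concentrations: `local` may hold equal-length vectors per solute).
reaction_rate_per_biomass <- function(reaction, local) {
  rate <- reaction$max_rate
  for (m in reaction$monod) {
    C <- local[[m$solute]]
    if (is.null(C)) stop("missing solute '", m$solute, "' in local state",
                         call. = FALSE)
    rate <- rate * monod_factor(C, m$K)
  }
  for (i in reaction$inhibition) {
    C <- local[[i$solute]]
    if (is.null(C)) stop("missing solute '", i$solute, "' in local state",
                         call. = FALSE)
    rate <- rate * inhibition_factor(C, i$Ki)
  }
  rate
}

#' Specific growth rate of a lineage at given local concentrations
#'
#' Sums the per-biomass rates of all growth routes of the lineage in the
#' medium; for cross-feeding the nutrient and by-product routes are additive.
#'
#' @param species a [species_spec()] or a label `"R"`/`"S"`.
#' @param medium a [build_medium()] definition.
#' @param local named list or vector of local solute concentrations (g/L).
#' @return specific growth rate (h^-1).
#' @examples
#' med <- build_medium("exploitation_competition", parameter_set())
#' specific_growth_rate("S", med, c(N = 0.05, A = 0.2))
#' @export
specific_growth_rate <- function(species, medium, local) {
  label <- if (inherits(species, "species_spec")) species$label else
    match.arg(species, c("R", "S"))
  local <- as.list(local)
  bad <- vapply(local, function(C) any(C < 0), TRUE)
  if (any(bad)) stop("concentrations must be non-negative", call. = FALSE)
  mu <- 0
  for (r in medium$reactions) {
    if (r$actor == label) mu <- mu + reaction_rate_per_biomass(r, local)
  }
  mu
}

#' Volumetric solute production/consumption rates
#'
#' Evaluates every reaction at the given local concentrations and biomass
#' densities and accumulates the stoichiometric contributions per solute.
#'
#' @param medium a [build_medium()] definition.
#' @param biomass named vector/list with biomass densities `R` and `S` (g/L).
#' @param local named list or vector of local solute concentrations (g/L).
#' @return named numeric vector of net rates (g/L/h), one entry per solute of
#'   the medium; negative = net consumption.
#' @examples
#' med <- build_medium("exploitation_competition", parameter_set())
#' solute_source_terms(med, c(R = 10, S = 0), c(N = 0.05, A = 0))
#' @export
solute_source_terms <- function(medium, biomass, local) {
  biomass <- as.list(biomass)
  if (any(unlist(biomass) < 0)) stop("biomass must be non-negative", call. = FALSE)
  local <- as.list(local)
  out <- stats::setNames(numeric(length(medium$solutes)), solute_names(medium))
  for (r in medium$reactions) {
    X <- biomass[[r$actor]]
    if (is.null(X) || X == 0) next
    vol_rate <- reaction_rate_per_biomass(r, local) * X
    out[names(r$stoich)] <- out[names(r$stoich)] + r$stoich * vol_rate
  }
  out
}
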