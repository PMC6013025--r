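# Model parameters and lineage specifications.
#
# Unit system used throughout the package: lengths in um, time in h, mass in
# fg, concentrations in fg.um^-3 which is numerically identical to g.L^-1.
# Diffusivities are stored in um^2.h^-1 (7.2e-6 m^2.day^-1 = 3.0e5 um^2.h^-1).

#' Convert a diffusivity from m^2/day to um^2/h
#'
#' @param D_m2_day diffusivity in m^2 per day.
#' @return diffusivity in um^2 per hour.
#' @examples
#' m2day_to_um2h(7.2e-6) # 3e5
#' @export
m2day_to_um2h <- function(D_m2_day) D_m2_day * 1e12 / 24

#' Kinetic and environmental parameter set
#'
#' Bundles the shared kinetic constants of both lineages and the bulk-liquid
#' environment. Defaults are the standard conditions of the model: maximal
#' specific growth rate 1 h^-1, half-saturation constants 3.5e-5 g/L for both
#' the primary nutrient and the cross-fed by-products, biomass yields 0.5 g/g,
#' inhibitory constants 0.1 g/L for toxin and antibiotic, bulk nutrient
#' 0.05 g/L, and a common solute diffusivity of 7.2e-6 m^2/day.
#'
#' @param mu_max maximal specific growth rate (h^-1).
#' @param K_N half-saturation constant for growth on nutrient (g/L).
#' @param K_E half-saturation constant for growth on by-product (g/L).
#' @param Y_N biomass yield per nutrient consumed (g/g).
#' @param Y_E biomass yield per by-product consumed (g/g).
#' @param Ki_T toxin inhibitory constant (g/L).
#' @param Ki_A antibiotic inhibitory constant (g/L).
#' @param N_bulk bulk-liquid nutrient concentration (g/L).
#' @param A_bulk bulk-liquid antibiotic concentration (g/L); 0 (none),
#'   0.05 (low toxicity) or 0.2 (high toxicity) are the standard levels.
#' @param D_N,D_E,D_A,D_T solute diffusivities (um^2/h).
#' @return an object of class `parameter_set` (a named list).
#' @examples
#' p <- parameter_set()
#' p$D_N   # 3e5 um^2/h
#' @export
parameter_set <- function(mu_max = 1,
                          K_N = 3.5e-5,
                          K_E = 3.5e-5,
                          Y_N = 0.5,
                          Y_E = 0.5,
                          Ki_T = 0.1,
                          Ki_A = 0.1,
                          N_bulk = 0.05,
                          A_bulk = 0,
                          D_N = m2day_to_um2h(7.2e-6),
                          D_E = m2day_to_um2h(7.2e-6),
                          D_A = m2day_to_um2h(7.2e-6),
                          D_T = m2day_to_um2h(7.2e-6)) {
  p <- list(mu_max = mu_max, K_N = K_N, K_E = K_E, Y_N = Y_N, Y_E = Y_E,
            Ki_T = Ki_T, Ki_A = Ki_A, N_bulk = N_bulk, A_bulk = A_bulk,
            D_N = D_N, D_E = D_E, D_A = D_A, D_T = D_T)
  strict <- setdiff(names(p), "A_bulk")
  for (nm in strict) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be a single strictly positive number",
           call. = FALSE)
    }
  }
  if (!is.numeric(A_bulk) || length(A_bulk) != 1L || !is.finite(A_bulk) ||
      A_bulk < 0) {
    stop("A_bulk must be a single non-negative number", call. = FALSE)
  }
  structure(p, class = "parameter_set")
}

#' Lineage specification
#'
#' Describes one of the two lineages: the antibiotic-resistant type R or the
#' susceptible type S. Resistance may carry a growth-rate cost `cost_c`
#' (an absolute reduction in h^-1; with `mu_max = 1` h^-1 this coincides with
#' the fractional reading, e.g. 0.1 is a 10% cost) and a growth-coupled
#' detoxification coefficient `alpha_detox` (g antibiotic removed per g new
#' biomass). S is inhibited by the antibiotic; R is not.
#'
#' @param label `"R"` or `"S"`.
#' @param mu_max maximal specific growth rate (h^-1).
#' @param cost_c cost of resistance (h^-1), R only; must satisfy
#'   `0 <= cost_c < mu_max`.
#' @param alpha_detox antibiotic detoxification coefficient (g/g), R only.
#' @return an object of class `species_spec`.
#' @examples
#' species_spec("R", cost_c = 0.1, alpha_detox = 1)
#' @export
species_spec <- function(label, mu_max = 1, cost_c = 0, alpha_detox = 0) {
  label <- match.arg(label, c("R", "S"))
  if (label == "S" && (cost_c != 0 || alpha_detox != 0)) {
    stop("cost_c and alpha_detox apply to the resistant lineage only",
         call. = FALSE)
  }
  if (cost_c < 0 || cost_c >= mu_max) {
    stop("cost of resistance must satisfy 0 <= cost_c < mu_max", call. = FALSE)
  }
  if (alpha_detox < 0) stop("alpha_detox must be >= 0", call. = FALSE)
  structure(list(label = label,
                 mu_max = mu_max,
                 cost_c = cost_c,
                 susceptible = (label == "S"),
                 alpha_detox = alpha_detox),
            class = "species_spec")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Model parameter set (g/L, h, um):\n")
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("  %-7s %g\n", nm, v[[nm]]))
  invisible(x)
}

#' @export
print.species_spec <- function(x, ...) {
  cat(sprintf("Lineage %s: mu_max = %g/h, cost = %g/h, %s, alpha = %g g/g\n",
              x$label, x$mu_max, x$cost_c,
              if (x$susceptible) "antibiotic-susceptible" else "resistant",
              x$alpha_detox))
  invisible(x)
}
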