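# Inoculation: initial cell arrangements on the substratum.

#' Radius of a cell of given mass
#'
#' Cells are disks of unit depth (1 um) with fixed cytoplasm density, so
#' `mass = density * pi * radius^2 * 1`.
#'
#' @param mass cell mass (fg).
#' @param density cytoplasm density (g/L = fg/um^3).
#' @return radius (um).
#' @export
radius_from_mass <- function(mass, density = 200) sqrt(mass / (density * pi))

new_cell_table <- function(id = integer(), species = character(),
                           x = numeric(), y = numeric(), mass = numeric(),
                           density = 200) {
  data.frame(id = as.integer(id), species = as.character(species),
             x = as.numeric(x), y = as.numeric(y), mass = as.numeric(mass),
             radius = radius_from_mass(as.numeric(mass), density),
             stringsAsFactors = FALSE)
}

#' Inoculum specification
#'
#' @param n_R,n_S number of cells of each lineage (at least one cell total).
#' @param arrangement `"random"` (species randomly interleaved, x positions
#'   independent uniform) or `"segregated"` (R in the left half-domain, S in
#'   the right, as contiguous blocks).
#' @param initial_mass starting mass per cell (fg); the default is half the
#'   division mass, i.e. fresh daughters.
#' @return an object of class `inoculum_spec`.
#' @export
inoculum_spec <- function(n_R = 120, n_S = 120,
                          arrangement = c("random", "segregated"),
                          initial_mass = NULL) {
  arrangement <- match.arg(arrangement)
  stopifnot(n_R >= 0, n_S >= 0)
  if (n_R + n_S < 1) stop("inoculum must contain at least one cell", call. = FALSE)
  structure(list(n_R = as.integer(n_R), n_S = as.integer(n_S),
                 arrangement = arrangement, initial_mass = initial_mass),
            class = "inoculum_spec")
}

#' Generate an initial cell arrangement
#'
#' Places `n_R + n_S` cells on the substratum (`y = radius`). For random
#' seeding every cell gets an independent `Uniform(0, width)` x position and
#' the species labels are randomly interleaved; for segregated seeding the R
#' cells are spread uniformly over the left half-domain `[0, width/2)` and
#' the S cells over the right half. Overlaps are then resolved by the shoving
#' relaxation (which may stack cells into a second layer when the substratum
#' is crowded).
#'
#' @param spec an [inoculum_spec()].
#' @param geometry a [domain_geometry()].
#' @param density cytoplasm density (g/L), used for the mass-radius relation.
#' @param division_radius division radius (um); the default initial mass is
#'   half the corresponding division mass.
#' @return a cell table: `id`, `species`, `x`, `y`, `mass`, `radius`.
#' @examples
#' set.seed(1)
#' cells <- make_inoculum(inoculum_spec(10, 10), domain_geometry(64, 64))
#' @export
make_inoculum <- function(spec, geometry, density = 200, division_radius = 1) {
  stopifnot(inherits(spec, "inoculum_spec"), inherits(geometry, "domain_geometry"))
  n <- spec$n_R + spec$n_S
  m0 <- spec$initial_mass
  if (is.null(m0)) m0 <- density * pi * division_radius^2 / 2
  r0 <- radius_from_mass(m0, density)
  # crude feasibility: the domain must be able to hold the cells at all
  if (n * pi * r0^2 > 0.9 * geometry$width * geometry$height) {
    stop("requested inoculum does not fit in the domain", call. = FALSE)
  }
  if (spec$arrangement == "random") {
    species <- sample(c(rep("R", spec$n_R), rep("S", spec$n_S)))
    x <- stats::runif(n, 0, geometry$width)
  } else {
    species <- c(rep("R", spec$n_R), rep("S", spec$n_S))
    x <- c(stats::runif(spec$n_R, 0, geometry$width / 2),
           stats::runif(spec$n_S, geometry$width / 2, geometry$width))
  }
  cells <- new_cell_table(id = seq_len(n), species = species, x = x,
                          y = rep(r0, n), mass = rep(m0, n), density = density)
  shoved <- shove_cpp(cells$x, cells$y, cells$radius, geometry$width,
                      tol = 0.01, max_sweeps = 5000)
  cells$x <- shoved$x
  cells$y <- shoved$y
  cells
}

#' Build inoculum specifications for a ratio/mixing sweep
#'
#' Cartesian product of initial S proportions and arrangements at a fixed
#' total inoculum size; counts are rounded to the nearest integer while
#' preserving the total.
#'
#' @param total total number of cells.
#' @param proportions_S initial proportions of S cells, each in (0, 1).
#' @param arrangements subset of `c("random", "segregated")`.
#' @return list of [inoculum_spec()] objects with attributes `proportion_S`
#'   and `arrangement` on each element.
#' @examples
#' length(ratio_sweep_specs(240, c(0.05, 0.5, 0.95), c("random", "segregated")))
#' @export
ratio_sweep_specs <- function(total, proportions_S,
                              arrangements = c("random", "segregated")) {
  stopifnot(all(proportions_S > 0 & proportions_S < 1))
  out <- list()
  for (arr in arrangements) {
    for (p in proportions_S) {
      n_S <- as.integer(round(p * total))
      sp <- inoculum_spec(n_R = total - n_S, n_S = n_S, arrangement = arr)
      attr(sp, "proportion_S") <- p
      attr(sp, "arrangement") <- arr
      out[[length(out) + 1L]] <- sp
    }
  }
  out
}
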