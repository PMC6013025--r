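# Pseudo-steady-state solute fields.
#
# Solute concentrations are assumed to equilibrate instantaneously relative to
# biomass growth, so after every biomass update the coupled nonlinear
# diffusion-reaction system
#     0 = D * laplacian(C_s) + source_s(C, X)
# is re-solved on the lattice, warm-started from the previous fields.
# Boundary conditions: bulk Dirichlet values from one boundary-layer
# thickness above the biofilm front upward, zero flux at the substratum,
# periodic lateral wrap.

# encode reactions for the C++ kernel (0-based solute indices)
encode_reactions <- function(medium) {
  nms <- solute_names(medium)
  lapply(medium$reactions, function(r) {
    midx <- vapply(r$monod, function(m) match(m$solute, nms), 1L) - 1L
    mK <- vapply(r$monod, `[[`, 0, "K")
    iidx <- vapply(r$inhibition, function(i) match(i$solute, nms), 1L) - 1L
    iKi <- vapply(r$inhibition, `[[`, 0, "Ki")
    sidx <- match(names(r$stoich), nms) - 1L
    if (anyNA(c(midx, iidx, sidx))) {
      stop("reaction references a solute absent from the medium", call. = FALSE)
    }
    list(actor = if (r$actor == "R") 0L else 1L,
         max_rate = r$max_rate,
         monod_idx = as.integer(midx), monod_K = as.numeric(mK),
         inhib_idx = as.integer(iidx), inhib_Ki = as.numeric(iKi),
         stoich_idx = as.integer(sidx), stoich_coef = as.numeric(r$stoich))
  })
}

#' Initialise solute fields at their bulk values
#'
#' @param medium a [build_medium()] definition.
#' @param geometry a [domain_geometry()].
#' @param bulk optional named vector overriding bulk values (e.g. antibiotic
#'   still switched off).
#' @return named list of nrow x ncol matrices (g/L).
#' @export
init_fields <- function(medium, geometry, bulk = NULL) {
  b <- solute_bulk_values(medium)
  if (!is.null(bulk)) b[names(bulk)] <- bulk
  out <- lapply(b, function(v) matrix(v, geometry$nrow, geometry$ncol))
  names(out) <- names(b)
  out
}

# Solutes that are identically zero and can never become positive (bulk 0,
# no production) are skipped by the solver.
solver_mask <- function(medium, fields, bulk) {
  nms <- solute_names(medium)
  produced <- rep(FALSE, length(nms))
  names(produced) <- nms
  for (r in medium$reactions) {
    pos <- names(r$stoich)[r$stoich > 0]
    produced[pos] <- TRUE
  }
  vapply(nms, function(s) {
    bulk[[s]] > 0 || produced[[s]] || any(fields[[s]] > 0)
  }, TRUE)
}

#' Solve the coupled solute fields to pseudo-steady state
#'
#' Damped Picard iteration: the sources are linearised around the current
#' concentrations (self-consumption through a Monod factor goes on the
#' diagonal, keeping iterates non-negative) and relaxed with red-black
#' successive over-relaxation; the outer iteration cycles all solutes until
#' the joint relative field change drops below `tol`. Negative intermediate
#' values (possible under concentration-independent antibiotic sinks) are
#' truncated to zero.
#'
#' @param fields named list of solute matrices, used as warm start.
#' @param biomass output of [rasterize_biomass()].
#' @param medium a [build_medium()] definition.
#' @param geometry a [domain_geometry()].
#' @param bulk optional named vector overriding the medium's bulk values.
#' @param tol relative convergence tolerance.
#' @param max_outer maximum number of outer iterations.
#' @param omega SOR relaxation factor in (0, 2).
#' @param inner_sweeps red-black sweeps per solute per outer iteration.
#' @param warn warn on non-convergence (the final fields are still returned).
#' @return named list of updated solute matrices, with attributes
#'   `outer_iterations`, `max_rel_change`, `converged`, `clamp_row`.
#' @export
solve_pseudo_steady_state <- function(fields, biomass, medium, geometry,
                                      bulk = NULL, tol = 1e-6,
                                      max_outer = 20000, omega = 1.8,
                                      inner_sweeps = 2, warn = TRUE) {
  b <- solute_bulk_values(medium)
  if (!is.null(bulk)) b[names(bulk)] <- bulk
  clamp <- clamp_row_index(biomass, geometry)
  mask <- solver_mask(medium, fields, b)
  res <- pss_solve_cpp(fields, biomass$X_R, biomass$X_S,
                       encode_reactions(medium), solute_diffusivities(medium),
                       as.numeric(b), geometry$h, clamp, tol, max_outer,
                       omega, inner_sweeps, mask)
  if (warn && !res$converged) {
    warning(sprintf("pseudo-steady solve did not converge (relative change %.3g after %d iterations)",
                    res$max_rel_change, res$outer_iterations), call. = FALSE)
  }
  out <- res$fields
  attr(out, "outer_iterations") <- res$outer_iterations
  attr(out, "max_rel_change") <- res$max_rel_change
  attr(out, "converged") <- res$converged
  attr(out, "clamp_row") <- clamp
  out
}

# Volumetric net source of every solute on the lattice (g/L/h), vectorised.
field_source_terms <- function(medium, biomass, fields) {
  nms <- solute_names(medium)
  out <- lapply(nms, function(s) array(0, dim(biomass$X_R)))
  names(out) <- nms
  for (r in medium$reactions) {
    X <- if (r$actor == "R") biomass$X_R else biomass$X_S
    rate <- r$max_rate * X
    for (m in r$monod) rate <- rate * monod_factor(fields[[m$solute]], m$K)
    for (i in r$inhibition) rate <- rate * inhibition_factor(fields[[i$solute]], i$Ki)
    for (s in names(r$stoich)) out[[s]] <- out[[s]] + r$stoich[[s]] * rate
  }
  out
}

#' Pointwise residual of the pseudo-steady solve
#'
#' Recomputes `D * laplacian(C) + source` on the active (unclamped) nodes
#' with the same discretisation as the solver; useful to verify convergence
#' independently of the solver's own stopping rule.
#'
#' @inheritParams solve_pseudo_steady_state
#' @return named vector of the maximum absolute residual per solute (g/L/h).
#' @export
pss_residual <- function(fields, biomass, medium, geometry, bulk = NULL) {
  b <- solute_bulk_values(medium)
  if (!is.null(bulk)) b[names(bulk)] <- bulk
  clamp <- clamp_row_index(biomass, geometry)
  src <- field_source_terms(medium, biomass, fields)
  D <- solute_diffusivities(medium)
  h <- geometry$h
  out <- numeric(0)
  for (s in solute_names(medium)) {
    C <- fields[[s]]
    up <- rbind(C[-1, , drop = FALSE], C[nrow(C), , drop = FALSE])
    down <- rbind(C[1, , drop = FALSE], C[-nrow(C), , drop = FALSE]) # mirror at substratum
    left <- cbind(C[, ncol(C), drop = FALSE], C[, -ncol(C), drop = FALSE])
    right <- cbind(C[, -1, drop = FALSE], C[, 1, drop = FALSE])
    lap <- (up + down + left + right - 4 * C) / h^2
    resid <- D[[s]] * lap + src[[s]]
    active <- seq_len(max(clamp - 1L, 0L))
    # nodes truncated at zero under a net sink are the depletion free
    # boundary; their one-sided residual is not informative
    r <- resid[active, , drop = FALSE]
    r[C[active, , drop = FALSE] == 0 & r < 0] <- 0
    out[s] <- if (length(r)) max(abs(r)) else 0
  }
  out
}

#' Diffusive influx across the clamped interface
#'
#' Total diffusive flux (fg/h) entering the solved region from the Dirichlet
#' bulk region for one solute; at pseudo-steady state it balances the net
#' consumption inside the domain (discrete divergence theorem).
#'
#' @param field one solute matrix.
#' @param clamp_row first clamped row index.
#' @param D diffusivity (um^2/h).
#' @param geometry a [domain_geometry()].
#' @return influx in fg/h (positive = into the biofilm region).
#' @export
interface_influx <- function(field, clamp_row, D, geometry) {
  if (clamp_row <= 1L || clamp_row > geometry$nrow) return(0)
  # flux through the face between row clamp_row (bulk) and clamp_row-1
  dC <- field[clamp_row, ] - field[clamp_row - 1L, ]
  sum(D * dC / geometry$h * geometry$h * 1) # per-face area h x 1 um^2
}
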