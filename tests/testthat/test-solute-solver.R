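# Biomass rasterisation and the pseudo-steady reaction-diffusion solver.

test_that("rasterisation conserves mass and localises it correctly", {
  geom <- tiny_geom()
  empty <- new_cells <- data.frame(id = integer(), species = character(),
                                   x = numeric(), y = numeric(),
                                   mass = numeric(), radius = numeric())
  b <- rasterize_biomass(empty, geom)
  expect_true(all(b$X_R == 0) && all(b$X_S == 0))

  one <- data.frame(id = 1L, species = "R", x = 1, y = 1, mass = 500,
                    radius = 0.9)
  b <- rasterize_biomass(one, geom)
  expect_equal(b$X_R[1, 1], 125)      # 500 fg / 4 um^3
  expect_equal(sum(b$X_R > 0), 1)

  two <- rbind(one, data.frame(id = 2L, species = "R", x = 1.5, y = 0.5,
                               mass = 300, radius = 0.7))
  b <- rasterize_biomass(two, geom)
  expect_equal(b$X_R[1, 1], 200)      # additive within a voxel

  set.seed(3)
  cells <- random_cells(200, geom$width, geom$height / 2, seed = 3)
  b <- rasterize_biomass(cells, geom)
  expect_equal(sum(b$X_R) * geom$voxel_volume,
               sum(cells$mass[cells$species == "R"]))
  expect_equal(sum(b$X_S) * geom$voxel_volume,
               sum(cells$mass[cells$species == "S"]))

  outside <- data.frame(id = 1L, species = "R", x = -5, y = 1, mass = 500,
                        radius = 0.9)
  expect_error(rasterize_biomass(outside, geom), "outside")
})

test_that("clamping starts one boundary layer above the biofilm front", {
  geom <- domain_geometry(64, 128, 2, 40)
  biomass <- list(X_R = matrix(0, geom$nrow, geom$ncol),
                  X_S = matrix(0, geom$nrow, geom$ncol))
  biomass$X_R[15, 3] <- 10   # front at 30 um
  fc <- locate_front_and_clamp(biomass, geom)
  expect_equal(fc$front_height, 30)
  expect_equal(fc$clamp_height, 70)
  # empty biofilm: everything above one boundary layer is bulk
  empty <- list(X_R = matrix(0, geom$nrow, geom$ncol),
                X_S = matrix(0, geom$nrow, geom$ncol))
  expect_equal(locate_front_and_clamp(empty, geom)$clamp_height, 40)
})

test_that("zero biomass yields uniform bulk fields", {
  geom <- tiny_geom()
  med <- build_medium("crossfeeding", parameter_set(A_bulk = 0.2))
  biomass <- list(X_R = matrix(0, geom$nrow, geom$ncol),
                  X_S = matrix(0, geom$nrow, geom$ncol))
  f <- solve_pseudo_steady_state(init_fields(med, geom), biomass, med, geom)
  expect_equal(max(abs(f$N_R - 0.05)), 0)
  expect_equal(max(abs(f$A - 0.2)), 0)
  expect_equal(max(abs(f$E_R)), 0)
})

test_that("slab with first-order sink matches the closed-form profile", {
  pb <- slab_problem()
  f <- solve_pseudo_steady_state(init_fields(pb$medium, pb$geom), pb$biomass,
                                 pb$medium, pb$geom)
  expect_true(attr(f, "converged"))
  clamp <- attr(f, "clamp_row")
  y <- (seq_len(pb$geom$nrow) - 0.5) * pb$geom$h
  yD <- (clamp - 0.5) * pb$geom$h
  ana <- slab_closed_form(y, pb$L, yD, pb$C0, pb$k, pb$D)
  expect_lt(max(abs(f$N_R[, 1] - ana)) / pb$C0, 0.01)
  # independent residual check at the solver discretisation, against the
  # natural diffusion scale D*C0/h^2
  f2 <- solve_pseudo_steady_state(init_fields(pb$medium, pb$geom), pb$biomass,
                                  pb$medium, pb$geom, tol = 1e-9)
  resid <- pss_residual(f2, pb$biomass, pb$medium, pb$geom)
  expect_lt(resid[["N_R"]] / (pb$D * pb$C0 / pb$geom$h^2), 1e-6)
})

test_that("halving the grid spacing shrinks the slab error by about h^2", {
  # tight solver tolerance so the discretisation error dominates
  errs <- sapply(c(2, 1), function(h) {
    pb <- slab_problem(h = h)
    f <- solve_pseudo_steady_state(init_fields(pb$medium, pb$geom), pb$biomass,
                                   pb$medium, pb$geom, tol = 1e-10)
    clamp <- attr(f, "clamp_row")
    y <- (seq_len(pb$geom$nrow) - 0.5) * h
    yD <- (clamp - 0.5) * h
    ana <- slab_closed_form(y, pb$L, yD, pb$C0, pb$k, pb$D)
    max(abs(f$N_R[, 1] - ana)) / pb$C0
  })
  expect_gt(errs[1] / errs[2], 2.5)   # ~4 expected for O(h^2)
})

test_that("diffusive influx balances consumption (divergence theorem)", {
  pb <- slab_problem()
  geom <- pb$geom
  f <- solve_pseudo_steady_state(init_fields(pb$medium, geom), pb$biomass,
                                 pb$medium, geom)
  clamp <- attr(f, "clamp_row")
  influx <- interface_influx(f$N_R, clamp, pb$D, geom)
  rows <- seq_len(pb$L / geom$h)
  consumption <- sum((1 / pb$params$Y_N) * pb$params$mu_max *
                       monod_factor(f$N_R[rows, ], pb$params$K_N) * pb$X) *
    geom$voxel_volume
  expect_equal(influx, consumption, tolerance = 1e-3)
})

test_that("consumed-only solutes obey the maximum principle", {
  geom <- tiny_geom()
  med <- build_medium("exploitation_competition", parameter_set(A_bulk = 0.2),
                      alpha_detox = 0.5)
  set.seed(5)
  cells <- random_cells(150, geom$width, 20, seed = 5)
  biomass <- rasterize_biomass(cells, geom)
  f <- solve_pseudo_steady_state(init_fields(med, geom), biomass, med, geom)
  expect_lte(max(f$N), 0.05 + 1e-12)
  expect_gte(min(f$N), 0)
  expect_lte(max(f$A), 0.2 + 1e-12)
  expect_gte(min(f$A), 0)
})

test_that("toxins are non-negative and vanish at the clamped boundary", {
  geom <- tiny_geom()
  med <- build_medium("interference_competition", parameter_set())
  set.seed(6)
  cells <- random_cells(150, geom$width, 16, seed = 6)
  biomass <- rasterize_biomass(cells, geom)
  f <- solve_pseudo_steady_state(init_fields(med, geom), biomass, med, geom)
  clamp <- attr(f, "clamp_row")
  expect_gte(min(f$T_R), 0)
  expect_gt(max(f$T_R), 0)
  expect_equal(max(abs(f$T_R[clamp:geom$nrow, ])), 0)
})

test_that("the solved field is independent of the warm start", {
  pb <- slab_problem()
  tol <- 1e-6
  f1 <- solve_pseudo_steady_state(init_fields(pb$medium, pb$geom), pb$biomass,
                                  pb$medium, pb$geom, tol = tol)
  warm <- init_fields(pb$medium, pb$geom)
  set.seed(9)
  warm$N_R[] <- stats::runif(length(warm$N_R), 0, pb$C0)
  f2 <- solve_pseudo_steady_state(warm, pb$biomass, pb$medium, pb$geom,
                                  tol = tol)
  expect_lt(max(abs(f1$N_R - f2$N_R)) / pb$C0, 10 * tol)
})

test_that("lateral translation of the biomass translates the solution", {
  geom <- tiny_geom()
  med <- build_medium("exploitation_competition", parameter_set())
  biomass <- list(X_R = matrix(0, geom$nrow, geom$ncol),
                  X_S = matrix(0, geom$nrow, geom$ncol))
  biomass$X_R[1:5, 4:8] <- 80
  shift <- function(M, k) M[, c((ncol(M) - k + 1):ncol(M), 1:(ncol(M) - k))]
  biomass2 <- list(X_R = shift(biomass$X_R, 3), X_S = biomass$X_S)
  f1 <- solve_pseudo_steady_state(init_fields(med, geom), biomass, med, geom)
  f2 <- solve_pseudo_steady_state(init_fields(med, geom), biomass2, med, geom)
  # equal up to the solver's convergence tolerance (the red-black sweep
  # order is not itself translation-equivariant)
  expect_equal(shift(f1$N, 3), f2$N, tolerance = 1e-5)
})
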