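# Cell growth, division, shoving, and the step/run loop.

make_state <- function(cells, medium_name = "exploitation_competition",
                       A_bulk = 0, geom = tiny_geom(), sealed = FALSE) {
  cfg <- simulation_config(medium = medium_name, antibiotic_bulk = A_bulk,
                           inoculum = inoculum_spec(1, 1),
                           geometry = geom, duration_h = 1, seed = 1,
                           sealed = sealed, store_cells = FALSE)
  medium <- build_medium(medium_name, cfg$params, 0, 0)
  fields <- if (sealed) {
    b <- biofilmr:::solute_bulk_values(medium); b["A"] <- A_bulk; b
  } else {
    init_fields(medium, geom, bulk = c(A = A_bulk))
  }
  structure(list(time = 0, cells = cells, fields = fields, medium = medium,
                 geometry = geom, config = cfg,
                 next_id = max(c(0L, cells$id)) + 1L, antibiotic_dosed = TRUE),
            class = "simulation_state")
}

cell_row <- function(id, species, x, y, mass) {
  data.frame(id = as.integer(id), species = species, x = x, y = y,
             mass = mass, radius = radius_from_mass(mass),
             stringsAsFactors = FALSE)
}

test_that("growth follows the exponential Monod update", {
  # R cell at bulk nutrient: mass ratio exp(mu * dt) with mu = N/(N+K)
  st <- make_state(cell_row(1, "R", 5, 1, 400))
  st$fields$N[] <- 0.05
  st2 <- grow_cells(st, dt = 0.02)
  expect_equal(st2$cells$mass / 400, exp((0.05 / 0.050035) * 0.02),
               tolerance = 1e-6)
  # zero substrate: no growth
  st$fields$N[] <- 0
  expect_equal(grow_cells(st, 0.02)$cells$mass, 400)
  # S at A = 0.2 grows at exactly one third of its uninhibited rate
  stS <- make_state(cell_row(1, "S", 5, 1, 400), A_bulk = 0.2)
  stS$fields$N[] <- 0.05; stS$fields$A[] <- 0.2
  muA <- log(grow_cells(stS, 0.02)$cells$mass / 400) / 0.02
  stS$fields$A[] <- 0
  mu0 <- log(grow_cells(stS, 0.02)$cells$mass / 400) / 0.02
  expect_equal(muA, mu0 / 3, tolerance = 1e-9)
  expect_error(grow_cells(st, 0), "dt")
})

test_that("division conserves mass, splits near-evenly and leaves small cells alone", {
  m_div <- 200 * pi   # division mass at radius 1 um, density 200 g/L
  cells <- rbind(cell_row(1, "R", 5, 1, m_div * 1.01),
                 cell_row(2, "S", 15, 1, m_div * 0.5))
  st <- make_state(cells)
  set.seed(42)
  st2 <- divide_cells(st)
  expect_equal(nrow(st2$cells), 3)
  expect_equal(sum(st2$cells$mass), sum(cells$mass))
  daughters <- st2$cells[st2$cells$species == "R", ]
  expect_equal(nrow(daughters), 2)
  expect_true(all(daughters$id > 2))                 # fresh ids
  fr <- daughters$mass / sum(daughters$mass)
  expect_true(all(fr >= 0.45 & fr <= 0.55))
  expect_true(2 %in% st2$cells$id)                   # small cell untouched
  # daughters sit half a parent radius from the parent centre
  d <- sqrt((daughters$x - 5)^2 + (daughters$y - 1)^2)
  expect_equal(d, rep(radius_from_mass(m_div * 1.01) / 2, 2), tolerance = 1e-9)
})

test_that("shoving separates overlapping cells and respects boundaries", {
  # touching cells are untouched
  touching <- rbind(cell_row(1, "R", 10, 1, 314), cell_row(2, "S", 11.4127, 1, 314))
  r <- touching$radius[1]
  touching$x[2] <- 10 + 2 * r
  st <- relax_overlaps(make_state(touching))
  expect_equal(st$cells$x, touching$x, tolerance = 1e-12)
  # fully superposed cells are pushed to touching distance, midpoint preserved
  sup <- rbind(cell_row(1, "R", 10, 5, 314), cell_row(2, "S", 10, 5, 314))
  st <- relax_overlaps(make_state(sup))
  dx <- abs(st$cells$x[2] - st$cells$x[1])
  dy <- st$cells$y[2] - st$cells$y[1]
  expect_equal(sqrt(dx^2 + dy^2), 2 * r, tolerance = 0.02)
  expect_equal(mean(st$cells$x), 10, tolerance = 1e-6)
  # isolated cell unchanged
  one <- cell_row(1, "R", 10, 5, 314)
  expect_equal(relax_overlaps(make_state(one))$cells$x, 10)
  # crowded layer: all cells stay above the substratum, overlaps resolved
  set.seed(8)
  crowd <- do.call(rbind, lapply(1:40, function(i)
    cell_row(i, "R", stats::runif(1, 0, 30), 1, 314)))
  st <- relax_overlaps(make_state(crowd))
  expect_true(all(st$cells$y >= st$cells$radius - 1e-9))
  d <- biofilmr:::pair_distances(st$cells$x, st$cells$y, st$cells$x, st$cells$y,
                                 st$geometry$width)
  diag(d) <- Inf
  expect_gt(min(d), 2 * r - 0.011)
})

test_that("a zero-dt step only refreshes the solute fields", {
  st <- make_state(cell_row(1, "R", 5, 1, 400))
  st$fields$N[] <- 0  # stale fields
  st2 <- simulation_step(st, 0)
  expect_equal(st2$cells, st$cells)
  expect_equal(st2$time, 0)
  expect_gt(max(st2$fields$N), 0)   # refreshed toward bulk
})

test_that("runs are reproducible and cells never shrink", {
  cfg <- quick_config(duration_h = 2, seed = 5)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$cells, s2$cells)
  # different seed gives a different trajectory
  s3 <- run_simulation(quick_config(duration_h = 2, seed = 6))
  expect_false(identical(s1$cells, s3$cells))
  # biomass is non-decreasing (bacteriostatic: no shrinkage, no death)
  expect_true(all(diff(s1$metrics$biomass_R_fg + s1$metrics$biomass_S_fg) >= 0))
  expect_true(all(diff(s1$metrics$count_R + s1$metrics$count_S) >= 0))
})

test_that("delayed dosing equal to the duration matches the antibiotic-free run", {
  base <- quick_config(duration_h = 1, seed = 9)
  dosed <- quick_config(duration_h = 1, seed = 9, antibiotic_bulk = 0.2,
                        antibiotic_start_time = 1)
  m1 <- run_simulation(base)$metrics
  m2 <- run_simulation(dosed)$metrics
  expect_equal(m1, m2)
})

test_that("zero-duration runs return the single t = 0 snapshot", {
  cfg <- quick_config(duration_h = 0)
  sim <- run_simulation(cfg)
  expect_equal(nrow(sim$metrics), 1)
  expect_equal(sim$metrics$time_h, 0)
  expect_equal(sim$metrics$count_R, 10)
})

test_that("sealed well-mixed culture conserves nutrient-to-biomass stoichiometry", {
  geom <- tiny_geom()
  cfg <- simulation_config(medium = "exploitation_competition",
                           inoculum = inoculum_spec(10, 0),
                           geometry = geom, duration_h = 10, seed = 2,
                           sealed = TRUE, store_cells = FALSE)
  sim <- run_simulation(cfg)
  V <- geom$width * geom$height
  N0 <- 0.05 * V
  gained <- sim$metrics$biomass_R_fg[nrow(sim$metrics)] - sim$metrics$biomass_R_fg[1]
  remaining <- sim$fields[["N"]] * V
  expect_equal(gained / 0.5 + remaining, N0, tolerance = 5e-3)
  expect_gt(gained, 0)
})
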