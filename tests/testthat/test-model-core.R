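# Kinetic factors and reaction networks of the four media.

test_that("Monod and inhibition factors match hand-computed values", {
  expect_equal(monod_factor(3.5e-5, 3.5e-5), 0.5)
  expect_equal(monod_factor(0, 3.5e-5), 0)
  expect_equal(monod_factor(0.05, 3.5e-5), 0.05 / 0.050035, tolerance = 1e-10)
  expect_equal(inhibition_factor(0.1, 0.1), 0.5)
  expect_equal(inhibition_factor(0, 0.1), 1)
  expect_equal(inhibition_factor(0.2, 0.1), 1 / 3, tolerance = 1e-12)
  expect_error(monod_factor(-1, 0.1), "non-negative")
  expect_error(inhibition_factor(-1, 0.1), "non-negative")
})

test_that("media carry the expected reaction sets and stoichiometries", {
  p <- parameter_set()

  cf <- build_medium("crossfeeding", p, 0, 0)
  expect_length(cf$reactions, 4)
  # R growth on the S by-product: Monod on E_S, consumes at -1/Y_E, releases E_R
  r_es <- Filter(function(r) r$actor == "R" &&
                   any(vapply(r$monod, `[[`, "", "solute") == "E_S"),
                 cf$reactions)[[1]]
  expect_equal(r_es$monod[[1]]$K, 3.5e-5)
  expect_equal(unname(r_es$stoich["E_S"]), -2)   # -1/0.5
  expect_equal(unname(r_es$stoich["E_R"]), 1)
  expect_equal(unname(r_es$stoich["A"]), 0)
  expect_setequal(vapply(cf$solutes, `[[`, "", "name"),
                  c("N_R", "N_S", "E_R", "E_S", "A"))
  # both private nutrients share the bulk nutrient concentration
  bulks <- vapply(cf$solutes, `[[`, 0, "bulk_value")
  names(bulks) <- vapply(cf$solutes, `[[`, "", "name")
  expect_equal(unname(bulks[c("N_R", "N_S")]), c(0.05, 0.05))
  expect_equal(unname(bulks[c("E_R", "E_S")]), c(0, 0))

  ex <- build_medium("exploitation_competition", p, 0, 0.1)
  expect_length(ex$reactions, 2)
  r_R <- Filter(function(r) r$actor == "R", ex$reactions)[[1]]
  expect_equal(unname(r_R$stoich["A"]), -0.1)
  r_S <- Filter(function(r) r$actor == "S", ex$reactions)[[1]]
  expect_equal(r_S$inhibition[[1]]$solute, "A")

  ic <- build_medium("interference_competition", p, 0, 0)
  expect_length(ic$reactions, 2)
  r_R <- Filter(function(r) r$actor == "R", ic$reactions)[[1]]
  expect_equal(unname(r_R$stoich["T_R"]), 1)
  expect_true(any(vapply(r_R$inhibition, `[[`, "", "solute") == "T_S"))

  nc <- build_medium("non_crossfeeding", p, 0, 0)
  expect_length(nc$reactions, 2)
  expect_setequal(vapply(nc$solutes, `[[`, "", "name"), c("N_R", "N_S", "A"))

  expect_error(build_medium("chemostat", p), "unknown medium")
  expect_error(build_medium("crossfeeding", p, cost_c = 1), "cost")
})

test_that("specific growth rate composes Monod and inhibition factors", {
  p <- parameter_set()
  ex <- build_medium("exploitation_competition", p, 0, 0)
  mu_S <- specific_growth_rate("S", ex, c(N = 0.05, A = 0.2))
  expect_equal(mu_S, (0.05 / 0.050035) * (1 / 3), tolerance = 1e-6)
  mu_R <- specific_growth_rate("R", ex, c(N = 0.05, A = 0.2))
  expect_equal(mu_R, 0.05 / 0.050035, tolerance = 1e-6)
  # antibiotic level is irrelevant to R
  expect_equal(mu_R, specific_growth_rate("R", ex, c(N = 0.05, A = 0)))
  # no substrate, no growth (all media)
  for (nm in c("interference_competition", "exploitation_competition",
               "non_crossfeeding", "crossfeeding")) {
    med <- build_medium(nm, p, 0, 0)
    zero <- stats::setNames(rep(0, length(med$solutes)),
                            vapply(med$solutes, `[[`, "", "name"))
    expect_equal(specific_growth_rate("R", med, zero), 0)
    expect_equal(specific_growth_rate("S", med, zero), 0)
  }
  # cross-feeding growth routes are additive
  cf <- build_medium("crossfeeding", p, 0, 0)
  mu_both <- specific_growth_rate("R", cf,
                                  c(N_R = 0.05, N_S = 0, E_R = 0, E_S = 0.05, A = 0))
  mu_n <- specific_growth_rate("R", cf,
                               c(N_R = 0.05, N_S = 0, E_R = 0, E_S = 0, A = 0))
  mu_e <- specific_growth_rate("R", cf,
                               c(N_R = 0, N_S = 0, E_R = 0, E_S = 0.05, A = 0))
  expect_equal(mu_both, mu_n + mu_e, tolerance = 1e-12)
  expect_error(specific_growth_rate("S", ex, c(N = 0.05)), "missing solute")
})

test_that("solute source terms follow the stoichiometry", {
  p <- parameter_set()
  ex <- build_medium("exploitation_competition", p, 0, 0.1)
  src0 <- solute_source_terms(ex, c(R = 0, S = 0), c(N = 0.05, A = 0))
  expect_true(all(src0 == 0))
  src <- solute_source_terms(ex, c(R = 10, S = 0), c(N = 0.05, A = 0))
  mu <- 0.05 / 0.050035
  expect_equal(unname(src["A"]), -0.1 * mu * 10, tolerance = 1e-6)
  expect_equal(unname(src["N"]), -2 * mu * 10, tolerance = 1e-6)

  ic <- build_medium("interference_competition", p, 0, 0)
  src <- solute_source_terms(ic, c(R = 0, S = 10),
                             c(N = 0.05, A = 0, T_R = 0, T_S = 0))
  expect_equal(unname(src["T_S"]), mu * 10, tolerance = 1e-6)
})

test_that("rates are symmetric under a label swap in the symmetric baseline", {
  p <- parameter_set()
  swap <- c(N = "N", A = "A", N_R = "N_S", N_S = "N_R", E_R = "E_S",
            E_S = "E_R", T_R = "T_S", T_S = "T_R")
  set.seed(7)
  for (nm in c("interference_competition", "exploitation_competition",
               "non_crossfeeding", "crossfeeding")) {
    med <- build_medium(nm, p, 0, 0)
    nms <- vapply(med$solutes, `[[`, "", "name")
    for (rep in 1:10) {
      conc <- stats::setNames(stats::runif(length(nms), 0, 0.1), nms)
      conc["A"] <- 0
      mirrored <- stats::setNames(conc, unname(swap[names(conc)]))
      expect_equal(specific_growth_rate("R", med, conc),
                   specific_growth_rate("S", med, mirrored[nms]),
                   tolerance = 1e-12)
    }
  }
})

test_that("growth is monotone in substrates and anti-monotone in inhibitors", {
  p <- parameter_set()
  ic <- build_medium("interference_competition", p, 0, 0)
  set.seed(11)
  for (rep in 1:20) {
    base <- c(N = stats::runif(1, 0, 0.1), A = stats::runif(1, 0, 0.3),
              T_R = stats::runif(1, 0, 0.3), T_S = stats::runif(1, 0, 0.3))
    mu0 <- specific_growth_rate("S", ic, base)
    up_N <- base; up_N["N"] <- up_N["N"] * 2 + 1e-4
    expect_gte(specific_growth_rate("S", ic, up_N), mu0)
    up_A <- base; up_A["A"] <- up_A["A"] * 2 + 1e-4
    expect_lte(specific_growth_rate("S", ic, up_A), mu0)
    up_T <- base; up_T["T_R"] <- up_T["T_R"] * 2 + 1e-4
    expect_lte(specific_growth_rate("S", ic, up_T), mu0)
  }
})

test_that("species specification enforces the resistance constraints", {
  sp <- species_spec("R", cost_c = 0.1, alpha_detox = 1)
  expect_false(sp$susceptible)
  expect_error(species_spec("R", cost_c = 1), "cost")
  expect_error(species_spec("S", alpha_detox = 1), "resistant lineage only")
  expect_true(species_spec("S")$susceptible)
})
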