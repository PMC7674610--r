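test_that("simulation is deterministic given the scenario seed", {
  a <- simulate_thermal(thermal_scenario(seed = 42))
  b <- simulate_thermal(thermal_scenario(seed = 42))
  pa <- tempfile(fileext = ".csv"); pb <- tempfile(fileext = ".csv")
  write_scoring_table(a, pa); write_scoring_table(b, pb)
  expect_identical(readLines(pa), readLines(pb))
  c <- simulate_thermal(thermal_scenario(seed = 43))
  pc <- tempfile(fileext = ".csv"); write_scoring_table(c, pc)
  expect_false(identical(readLines(pa), readLines(pc)))
})

test_that("every generated dish satisfies the accounting identity", {
  dishes <- c(simulate_thermal(thermal_scenario(seed = 5)),
              simulate_hydro(hydro_scenario(seed = 6)))
  for (d in dishes) {
    if (d$stage != "germination") next
    expect_equal(max(d$cum_counts) + d$n_viable_ungerminated + d$n_dead,
                 d$n_sown)
  }
})

test_that("the noiseless thermal model is degenerate at the scoring grid", {
  s <- thermal_scenario(T_b = 2, theta_T = 1800, sigma_theta = 0,
                        temperatures = 20, viability = 1,
                        dormant_fraction = 0, seed = 1)
  d <- simulate_thermal(s)[[1]]
  # t = 1800/18 = 100 h, scored at the first 12 h multiple >= 100
  first <- min(d$times[d$cum_counts > 0])
  expect_equal(first, 108)
  expect_equal(max(d$cum_counts), 50)
})

test_that("at the base temperature no seed germinates", {
  s <- thermal_scenario(T_b = 4, temperatures = 4, viability = 1, seed = 2)
  d <- simulate_thermal(s)[[1]]
  expect_equal(max(d$cum_counts), 0)
  expect_equal(d$n_viable_ungerminated, 50)
})

test_that("dormant seeds are scored viable-ungerminated", {
  s <- thermal_scenario(temperatures = 20, viability = 1,
                        dormant_fraction = 1, seed = 3)
  d <- simulate_thermal(s)[[1]]
  expect_equal(max(d$cum_counts), 0)
  expect_equal(d$n_viable_ungerminated, 50)
})

test_that("the noiseless hydro model is degenerate at the scoring grid", {
  below <- hydro_scenario(psi_b50 = -0.5, sigma_psi_b = 0,
                          potentials = -0.6, viability = 1, seed = 1)
  d <- simulate_hydro(below)[[1]]
  expect_equal(max(d$cum_counts), 0)
  sharp <- hydro_scenario(psi_b50 = -1, sigma_psi_b = 0, theta_H = 50,
                          potentials = 0, viability = 1, seed = 1)
  g <- simulate_hydro(sharp)[[1]]
  # t = 50/1 = 50 h, scored at the first daily multiple >= 50
  expect_equal(min(g$times[g$cum_counts > 0]), 72)
  expect_equal(max(g$cum_counts), 50)
})

test_that("final germination responds monotonically to water potential", {
  s <- hydro_scenario(sigma_psi_b = 0, viability = 1, seed = 4)
  dishes <- simulate_hydro(s)
  germ <- Filter(function(d) d$stage == "germination", dishes)
  finals <- tapply(vapply(germ, function(d) max(d$cum_counts), 0),
                   vapply(germ, function(d) d$treatment_value, 0), mean)
  # psi sorted ascending (most negative first): germination non-decreasing
  expect_true(all(diff(finals[order(as.numeric(names(finals)))]) >= 0))
})

test_that("seedling series never exceed their paired germination counts", {
  dishes <- simulate_hydro(hydro_scenario(seed = 9))
  germ <- Filter(function(d) d$stage == "germination", dishes)
  sdl <- Filter(function(d) d$stage == "seedling", dishes)
  gid <- vapply(germ, `[[`, "", "dish_id")
  for (d in sdl) {
    g <- germ[[which(gid == d$dish_id)]]
    expect_lte(max(d$cum_counts), max(g$cum_counts))
  }
})

test_that("trait tables honour the copula target and reject non-PSD input", {
  tt <- simulate_trait_table(10, seed = 1)
  expect_s3_class(tt, "trait_table")
  expect_equal(dim(tt), c(10, 21))
  expect_identical(tt, simulate_trait_table(10, seed = 1))
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(
    simulate_trait_table(10, bad, traits = c("Tb_G", "Tb_S"), seed = 1),
    class = "st_domain_error")
  expect_error(
    simulate_trait_table(10, diag(3), traits = c("Tb_G", "Tb_S"), seed = 1),
    class = "st_domain_error")
})

test_that("a strong induced correlation is detected as an edge at alpha=.05", {
  target <- matrix(c(1, 0.95, 0.95, 1), 2)
  hits <- vapply(1:200, function(s) {
    tt <- simulate_trait_table(10, target, traits = c("Tb_G", "Tb_S"),
                               seed = s)
    cm <- correlation_matrix(tt)
    net <- build_network(cm)
    nrow(net$edges) == 1
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("null tables rarely produce large rank correlations", {
  meds <- vapply(1:50, function(s) {
    tt <- simulate_trait_table(10, seed = s + 1000)
    cm <- correlation_matrix(tt)
    median(abs(cm$rho[upper.tri(cm$rho)]))
  }, 0)
  expect_lt(median(meds), 0.4)
})

test_that("scenario validation rejects impossible designs", {
  expect_error(thermal_scenario(theta_T = -5), class = "st_domain_error")
  expect_error(thermal_scenario(viability = 1.2), class = "st_domain_error")
  expect_error(hydro_scenario(sigma_psi_b = -0.1), class = "st_domain_error")
  expect_error(hydro_scenario(censor_time = 2, scoring_interval = 24),
               class = "st_domain_error")
})
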