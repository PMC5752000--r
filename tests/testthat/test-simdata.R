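test_that("trap lattice has the documented geometry", {
  g <- make_grid(2, 2, 25)
  expect_equal(g$trap_x, c(0, 25, 0, 25))
  expect_equal(g$trap_y, c(0, 0, 25, 25))

  g2 <- make_grid(7, 6, 25)
  expect_equal(nrow(g2), 42)
  expect_equal(diff(range(g2$trap_x)), 125)
  expect_equal(diff(range(g2$trap_y)), 150)

  expect_error(make_grid(1, 6, 25), "rows")
  expect_error(make_grid(3, 3, 0), "spacing")
})

test_that("same seed reproduces the simulation byte for byte", {
  cfg <- sim_config(n_grids = 3, seed = 17)
  s1 <- simulate_dynamics(cfg)
  s2 <- simulate_dynamics(cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_captures(s1, cfg), simulate_captures(s2, cfg))
  iso1 <- simulate_isotope_data(default_sources(), c(0.5, 0.3, 0.2), 0.2,
                                10, seed = 3)
  iso2 <- simulate_isotope_data(default_sources(), c(0.5, 0.3, 0.2), 0.2,
                                10, seed = 3)
  expect_identical(iso1, iso2)
})

test_that("null coupling yields shrew densities independent of mice", {
  cfg <- sim_config(n_grids = 8, alpha_true = 0, noise_sd = 0,
                    habitat_coefs = c(nmds1 = 0, nmds2 = 0, elevation = 0),
                    seed = 4)
  st <- simulate_dynamics(cfg)
  sh <- st$abundance[st$abundance$species == "shrew", ]
  for (y in unique(sh$year)) {
    for (s in unique(sh$session)) {
      d <- sh$density[sh$year == y & sh$session == s]
      expect_equal(max(d) - min(d), 0)
    }
  }
})

test_that("certain detection realises the true population (MNKA = N)", {
  cfg <- sim_config(n_grids = 2, p_night = c(mouse = 1, shrew = 1),
                    mortality_prob = c(mouse = 0, shrew = 0), seed = 5)
  st <- simulate_dynamics(cfg)
  rec <- simulate_captures(st, cfg)
  for (g in 1:2) {
    n_true <- st$abundance$n_true[st$abundance$grid_id == g &
                                    st$abundance$year == 1 &
                                    st$abundance$session == 1 &
                                    st$abundance$species == "mouse"]
    expect_equal(mnka(rec[rec$species == "mouse", ], grid = g, year = 1,
                      session = 1), n_true)
  }
  # every alive individual appears every night
  m11 <- rec[rec$species == "mouse" & rec$grid_id == 1 & rec$year == 1 &
               rec$primary == 1, ]
  expect_true(all(table(m11$animal_id) == cfg$n_secondary))
})

test_that("zero capture probability yields an empty table", {
  cfg <- sim_config(n_grids = 2, p_night = c(mouse = 0, shrew = 0), seed = 6)
  rec <- simulate_captures(simulate_dynamics(cfg), cfg)
  expect_equal(nrow(rec), 0)
})

test_that("detection complement over a session matches 1-(1-p)^T", {
  # p = 0.3 over 5 nights: expected fraction ever caught = 0.83193
  frac <- vapply(1:40, function(r) {
    cfg <- sim_config(n_grids = 1, n_years = 1, n_primary = 1,
                      mouse_year_effect = 1, shrew_year_effect = 1,
                      p_night = c(mouse = 0.3, shrew = 0),
                      mortality_prob = c(mouse = 0, shrew = 0),
                      seed = 900 + r)
    st <- simulate_dynamics(cfg)
    rec <- simulate_captures(st, cfg)
    n_true <- st$abundance$n_true[st$abundance$species == "mouse"]
    mnka(rec) / n_true
  }, 0)
  expect_equal(mean(frac), 1 - 0.7^5, tolerance = 0.03)
})

test_that("without trap mortality the marked id set is session-constant", {
  cfg <- sim_config(n_grids = 2, mouse_density_sdlog = 0,
                    mouse_year_effect = c(1, 1, 1),
                    p_night = c(mouse = 0.9, shrew = 0),
                    mortality_prob = c(mouse = 0, shrew = 0), seed = 8)
  st <- simulate_dynamics(cfg)
  rec <- simulate_captures(st, cfg)
  m <- rec[rec$species == "mouse" & rec$grid_id == 1 & rec$year == 1, ]
  ids <- lapply(split(m$animal_id, m$primary), unique)
  pool <- sort(unique(unlist(ids)))
  # with constant abundance the candidate set is identical across sessions;
  # at p_night = 0.9 over 5 nights essentially everyone is seen
  for (s in seq_along(ids)) {
    expect_true(all(ids[[s]] %in% pool))
    expect_gt(length(ids[[s]]) / length(pool), 0.95)
  }
})

test_that("shrew ids are withheld and mortality ends a record stream", {
  cfg <- sim_config(n_grids = 2, seed = 9)
  rec <- simulate_captures(simulate_dynamics(cfg), cfg)
  expect_true(all(is.na(rec$animal_id[rec$species == "shrew"])))
  # a dead mouse never reappears
  mice <- rec[rec$species == "mouse", ]
  dead <- mice[mice$fate == "dead", ]
  for (i in seq_len(nrow(dead))) {
    rec <- mice
    later <- rec[rec$animal_id == dead$animal_id[i] &
                   (rec$year > dead$year[i] |
                      (rec$year == dead$year[i] &
                         (rec$primary > dead$primary[i] |
                            (rec$primary == dead$primary[i] &
                               rec$night > dead$night[i])))), ]
    expect_equal(nrow(later), 0)
  }
})

test_that("isotope simulator honours pure diets, symmetry and validation", {
  src <- equal_conc_sources()
  # pure diet: consumer sits exactly on the corrected source
  iso <- simulate_isotope_data(src, c(0, 1, 0), noise_sd = 0, n = 3,
                               seed = 1, offsets = c(d13c = 1.3, d15n = 2.5))
  expect_equal(iso$d13c, rep(1 + 1.3, 3))
  expect_equal(iso$d15n, rep(0 + 2.5, 3))
  # equal concentrations, equal proportions: the triangle centroid
  iso2 <- simulate_isotope_data(src, rep(1 / 3, 3), noise_sd = 0, n = 2,
                                seed = 1)
  expect_equal(iso2$d13c, rep(0.5, 2))
  expect_equal(iso2$d15n, rep(1 / 3, 2))
  expect_error(simulate_isotope_data(src, c(0.5, 0.3, 0.1), 0.1, 5, 1),
               "sum to 1")
})

test_that("mixing recovers the generating proportions from noisy samples", {
  src <- default_sources()
  truth <- c(0.5, 0.3, 0.2)
  iso <- simulate_isotope_data(src, truth, noise_sd = 0.2, n = 200, seed = 21)
  sol <- solve_mixing(c(mean(iso$d13c), mean(iso$d15n)), src)
  expect_true(sol$feasible)
  expect_true(all(abs(sol$mean - truth) < 0.05))
})

test_that("generated standardized densities reproduce the true coupling", {
  covered <- vapply(1:60, function(r) {
    tbl <- simulate_competition_table(n_grids = 21, alpha = -0.9,
                                      noise_sd = 0.3, seed = 4000 + r)
    f <- fit_ols(tbl$shrew_density,
                 tbl[c("shrew_density_lag", "mouse_density")])
    f$alpha_ci[1] <= -0.9 && -0.9 <= f$alpha_ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})
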