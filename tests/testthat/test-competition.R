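test_that("standardization centres, scales and rejects degenerate input", {
  expect_equal(standardize(c(2, 4, 6)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50, 10, 7)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_error(standardize(c(5, 5, 5)), "zero variance")
  expect_error(standardize(c(5, 5, 5), label = "2011 shrew"), "2011 shrew")
})

test_that("candidate model sets enumerate the two families", {
  reg <- build_model_set(FALSE)
  ar <- build_model_set(TRUE)
  expect_length(reg, 15)
  expect_length(ar, 16)
  expect_true(all(vapply(ar, function(s) "shrew_density_lag" %in% s, TRUE)))
  expect_false(any(vapply(reg, function(s) "shrew_density_lag" %in% s, TRUE)))
  expect_length(intersect(names(reg), names(ar)), 0)
  expect_equal(anyDuplicated(names(reg)), 0)
  expect_equal(anyDuplicated(names(ar)), 0)
})

test_that("OLS fit matches the normal-equations oracle and edge cases", {
  # noiseless linear data: exact interpolation
  X <- data.frame(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 6))
  y <- 1.5 + 2 * X$a - 0.5 * X$b
  f <- fit_ols(y, X)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(unname(f$coefficients), c(1.5, 2, -0.5), tolerance = 1e-10)

  # intercept-only: mean and zero R2
  f0 <- fit_ols(y, NULL)
  expect_equal(unname(f0$coefficients), mean(y))
  expect_equal(f0$r2, 0)

  # explicit normal equations on a noisy 5-row toy design
  set.seed(2)
  yn <- y + rnorm(5)
  fn <- fit_ols(yn, X)
  Xd <- cbind(1, as.matrix(X))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% yn)
  expect_equal(unname(fn$coefficients), as.numeric(beta), tolerance = 1e-10)

  # collinear design names the offending term
  Xc <- data.frame(a = 1:6, b = 2 * (1:6))
  expect_error(fit_ols(rnorm(6), Xc), "collinear.*b")
})

test_that("AICc applies the small-sample correction", {
  expect_equal(aicc(-10, 3, 20), 27.5)
  expect_equal(aicc(-10, 3, 1e9), 26, tolerance = 1e-6)
  expect_lt(aicc(-10, 3, 20), aicc(-10, 4, 20))
  expect_error(aicc(-10, 3, 4), "n > k")
})

test_that("ranking applies the AICc / R2 / parsimony rule", {
  fake <- function(aicc, k, r2, alpha = NA_real_) {
    structure(list(terms = character(0), coefficients = numeric(0),
                   alpha = alpha, loglik = -aicc / 2, k = k, n = 20,
                   aicc = aicc, r2 = r2), class = "competition_fit")
  }
  fits <- list(big = fake(100.0, 5, 0.50), small = fake(100.5, 3, 0.45),
               far = fake(103, 4, 0.52))
  rk <- rank_models(fits)
  expect_equal(rk$selected, "small")
  expect_equal(rk$table$delta_aicc[1], 0)
  expect_setequal(rk$supported, c("big", "small"))
  expect_setequal(rk$table$model, names(fits))

  single <- rank_models(fits["big"])
  expect_equal(single$selected, "big")
  expect_equal(single$table$delta_aicc, 0)
  expect_error(rank_models(list()), "no fits")
})

test_that("alpha is invariant to rescaling raw densities", {
  cfg <- sim_config(n_grids = 10, seed = 31)
  st <- simulate_dynamics(cfg)
  dens <- st$abundance[, c("grid_id", "year", "session", "species",
                           "density")]
  t1 <- session_table(dens, st$habitat)
  dens10 <- dens
  dens10$density[dens10$species == "mouse"] <-
    dens10$density[dens10$species == "mouse"] * 10
  t2 <- session_table(dens10, st$habitat)
  f1 <- fit_ols(t1$shrew_density, t1[c("shrew_density_lag", "mouse_density")])
  f2 <- fit_ols(t2$shrew_density, t2[c("shrew_density_lag", "mouse_density")])
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-12)
})

test_that("session table lags within grid and year only", {
  dens <- expand.grid(grid_id = 1:2, year = 1:2, session = 1:3,
                      species = c("mouse", "shrew"),
                      stringsAsFactors = FALSE)
  set.seed(5)
  dens$density <- runif(nrow(dens), 1, 10)
  hab <- data.frame(grid_id = 1:2, nmds1 = c(-1, 1), nmds2 = c(0.5, -0.5),
                    elevation_m = c(100, 300))
  tbl <- session_table(dens, hab)
  # response rows are sessions 2..3 only
  expect_setequal(unique(tbl$session), c(2, 3))
  expect_equal(nrow(tbl), 2 * 2 * 2)
  # the lag equals the standardized previous-session value of the same grid
  key <- function(d, g, y, s, sp) d$density[d$grid_id == g & d$year == y &
                                              d$session == s &
                                              d$species == sp]
  for (y in 1:2) {
    sh <- dens[dens$species == "shrew" & dens$year == y, ]
    z <- standardize(sh$density)
    names(z) <- paste(sh$grid_id, sh$session)
    for (g in 1:2) {
      for (s in 2:3) {
        row <- tbl[tbl$grid_id == g & tbl$year == y & tbl$session == s, ]
        expect_equal(row$shrew_density_lag, unname(z[paste(g, s - 1)]))
      }
    }
  }
})

test_that("per-year fitting shares no rows and recovers the structure", {
  tbl <- rbind(simulate_competition_table(seed = 61),
               transform(simulate_competition_table(seed = 62), year = 2L))
  res <- fit_model_set(tbl, autoregressive = TRUE, by_year = TRUE)
  expect_named(res, c("1", "2"))
  n1 <- res[["1"]]$table$model
  expect_length(n1, 16)
  # each year used only its own 42 rows
  expect_true(all(vapply(res, function(r)
    all(abs(r$table$aicc - r$table$aicc[1]) < 1e6), TRUE)))
  f1 <- res[["1"]]$table
  expect_false(isTRUE(all.equal(f1$aicc, res[["2"]]$table$aicc)))
})
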