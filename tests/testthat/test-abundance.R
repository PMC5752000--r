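test_that("MNKA counts live events for unmarked and ids for marked species", {
  unmarked <- make_records(night = rep(1:5, 3)[1:15], species = "shrew",
                           animal_id = NA_character_,
                           fate = c(rep("live", 12), rep("dead", 3)))
  expect_equal(mnka(unmarked), 12)
  marked <- make_records(night = rep(1:2, 5),
                         animal_id = rep(paste0("m", 1:5), each = 2))
  expect_equal(mnka(marked), 5)
  expect_equal(mnka(marked[0, ]), 0)
})

test_that("Horvitz-Thompson abundance is the documented arithmetic", {
  e <- ht_abundance(20, 5, 0.5, c(0.4, 0.6))
  expect_equal(e$n_hat, 45)
  expect_equal(e$interval, c(20 / 0.6 + 5, 20 / 0.4 + 5))
  e2 <- ht_abundance(20, 5, 1, c(1, 1))
  expect_equal(e2$n_hat, 25)
  expect_equal(e2$interval, c(25, 25))
  expect_equal(ht_abundance(0, 7, 0.3, c(0.2, 0.4))$n_hat, 7)
  expect_error(ht_abundance(5, 0, 0, c(0, 0.4)), "p_star")
  expect_error(ht_abundance(5, 0, 0.3, c(0, 0.4)), "unbounded")
  # zero-capture sessions get a rule-of-three upper bound
  z <- ht_abundance(0, 0, 0.3, c(0.2, 0.4))
  expect_equal(z$n_hat, 0)
  expect_equal(z$interval, c(0, 10))
})

test_that("HT estimate is monotone in detection and additive in deaths", {
  ps <- seq(0.2, 1, by = 0.1)
  nh <- vapply(ps, function(p) ht_abundance(30, 0, p, c(p, p))$n_hat, 0)
  expect_true(all(diff(nh) < 0))
  for (d in c(0, 3, 11)) {
    expect_equal(ht_abundance(30, d, 0.4, c(0.3, 0.5))$n_hat,
                 ht_abundance(30, 0, 0.4, c(0.3, 0.5))$n_hat + d)
  }
})

test_that("closed-population MLE handles saturation, censoring and Mt", {
  # saturated detection: boundary at the observed count
  sat <- matrix(1L, 30, 5)
  e <- m0_mle(sat)
  expect_equal(e$n_hat, 30)
  expect_equal(e$p_hat, 1)
  expect_true(e$boundary)

  # Lincoln-Petersen equivalence for the two-occasion time-varying model:
  # n1 = 50, n2 = 40, m2 = 20 -> N = 50*40/20 = 100
  cm <- rbind(cbind(rep(1L, 30), rep(0L, 30)),
              cbind(rep(1L, 20), rep(1L, 20)),
              cbind(rep(0L, 20), rep(1L, 20)))
  emt <- m0_mle(cm, model = "mt")
  expect_equal(emt$n_hat, 100, tolerance = 0.03)

  # censoring a death reduces exposure, so the estimate cannot drop
  cm2 <- matrix(rbinom(40 * 5, 1, 0.4), 40, 5)
  cm2 <- cm2[rowSums(cm2) > 0, , drop = FALSE]
  death <- rep(NA_integer_, nrow(cm2))
  death[1:5] <- 2L
  cm2[1:5, ] <- 0L
  cm2[1:5, 1] <- 1L
  cmd <- structure(cm2, death_occasion = death)
  e_cens <- m0_mle(cmd)
  e_plain <- m0_mle(unclass(cm2))
  expect_gte(e_cens$n_hat, nrow(cm2))
  expect_lte(e_cens$n_hat, e_plain$n_hat + 1e-9)
  expect_error(m0_mle(matrix(1L, 3, 1)), "occasions")
})

test_that("capture matrices are faithful to the records", {
  rec <- make_records(
    night = c(1, 3, 2, 5), animal_id = c("a", "a", "b", "b"),
    fate = c("live", "live", "live", "dead"))
  cm <- capture_matrix(rec, n_occasions = 5)
  expect_equal(dim(cm), c(2, 5))
  expect_equal(unname(rowSums(unclass(cm))), c(2, 2))
  expect_equal(unname(attr(cm, "death_occasion")), c(NA_integer_, 5L))
})

test_that("growth rates divide consecutive sessions with guarded zeros", {
  expect_equal(unname(growth_rates(c(10, 20, 30))), c(2, 1.5))
  expect_equal(unname(growth_rates(c(10, 10, 10))), c(1, 1))
  lam <- suppressWarnings(growth_rates(c(0, 5, 10)))
  expect_true(is.na(lam[1]))
  expect_equal(unname(lam[2]), 2)
})

test_that("MMDM is the mean of per-individual maximum consecutive moves", {
  one <- make_records(night = 1:2, trap_x = c(0, 0), trap_y = c(0, 52))
  expect_equal(mmdm(one), 52)
  three <- make_records(night = 1:3, trap_x = c(0, 0, 40),
                        trap_y = c(0, 30, 30))
  expect_equal(mmdm(three), 40)  # consecutive moves 30, 40
  two_inds <- rbind(
    make_records(night = 1:2, trap_x = c(0, 30), animal_id = "a"),
    make_records(night = 1:2, trap_x = c(0, 50), animal_id = "b"),
    make_records(night = 1, animal_id = "single"))
  expect_equal(mmdm(two_inds), 40)
  expect_warning(res <- mmdm(make_records()), "undefined")
  expect_true(is.na(res))
})

test_that("effective trapping area is the buffered-rectangle formula", {
  g <- make_grid(7, 6, 25)  # 125 x 150 m
  expect_equal(effective_area(g, 50),
               (150 * 125 + 550 * 50 + pi * 2500) / 1e4, tolerance = 1e-10)
  expect_equal(effective_area(g, 0), 1.875)
  sq <- make_grid(5, 5, 25)
  expect_equal(effective_area(sq, 50), (1e4 + 2e4 + pi * 2500) / 1e4)
  collinear <- data.frame(trap_x = c(0, 25, 50, 75), trap_y = 0)
  expect_error(effective_area(collinear, 50), "collinear")
})

test_that("density scales abundance by area and reconstructs it exactly", {
  est <- ht_abundance(20, 5, 0.5, c(0.4, 0.6))
  d <- density_estimate(est, 5.41)
  expect_equal(d$density, 45 / 5.41)
  expect_equal(d$interval, est$interval / 5.41)
  expect_equal(d$density * d$effective_area, est$n_hat, tolerance = 1e-12)
  z <- density_estimate(new_est <- ht_abundance(0, 0, 0.5, c(0.4, 0.6)), 2)
  expect_equal(z$density, 0)
  expect_error(density_estimate(est, 0), "area")
})
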