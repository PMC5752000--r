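test_that("discrimination correction shifts deltas per species", {
  s <- data.frame(name = "x", d13c = -26, d15n = 2, conc_c = 0.4,
                  conc_n = 0.1)
  sh <- correct_sources(s, "shrew")
  expect_equal(sh$d13c, -24.7)
  expect_equal(sh$d15n, 4.5)
  mo <- correct_sources(s, "mouse")
  expect_equal(mo$d13c, -25)
  expect_equal(mo$d15n, 5)
  idn <- correct_sources(s, "none", offsets = list(none = c(d13c = 0,
                                                            d15n = 0)))
  expect_equal(idn, s)
  expect_equal(sh$conc_c, s$conc_c)
  expect_error(correct_sources(s, "vole"), "vole")
})

test_that("three-source mixing solves vertices, centroids and infeasibility", {
  src <- equal_conc_sources()
  # mixture at a vertex
  v <- solve_mixing(c(src$d13c[2], src$d15n[2]), src)
  expect_equal(unname(v$mean), c(0, 1, 0), tolerance = 1e-9)
  expect_equal(v$type, "unique")
  expect_equal(unname(v$sd), c(0, 0, 0))
  # centroid symmetry
  ctr <- solve_mixing(c(mean(src$d13c), mean(src$d15n)), src)
  expect_equal(unname(ctr$mean), rep(1 / 3, 3), tolerance = 1e-9)
  # outside the triangle
  out <- solve_mixing(c(5, 5), src)
  expect_equal(out$type, "infeasible")
  expect_false(out$feasible)
  # collinear corrected sources are ill-conditioned
  col <- data.frame(name = c("a", "b", "c"), d13c = c(0, 1, 2),
                    d15n = c(0, 1, 2), conc_c = 1, conc_n = 1)
  expect_error(solve_mixing(c(1, 1), col), "collinear")
})

test_that("equal concentrations reduce to the standard linear mixing model", {
  src <- equal_conc_sources()
  mix <- c(0.4, 0.35)
  sol <- solve_mixing(mix, src)
  # standard dual-isotope linear system (no concentration weighting)
  A <- rbind(src$d13c, src$d15n, rep(1, 3))
  p_std <- solve(A, c(mix, 1))
  expect_equal(unname(sol$mean), as.numeric(p_std), tolerance = 1e-10)
})

test_that("feasible solutions satisfy mass balance and equivariance", {
  src4 <- four_sources()
  mix <- c(-23.5, 5)
  sol <- solve_mixing(mix, src4, n_samples = 2000, seed = 7)
  expect_equal(sol$type, "polytope")
  expect_true(all(sol$mean >= 0))
  expect_equal(sum(sol$mean), 1, tolerance = 1e-9)
  expect_lt(max(abs(implied_mixture(sol$mean, src4) - mix)), 1e-6)
  for (i in seq_len(nrow(sol$vertices))) {
    expect_lt(max(abs(implied_mixture(sol$vertices[i, ], src4) - mix)), 1e-6)
  }
  # permutation equivariance in source order
  perm <- c(3, 1, 4, 2)
  sol_p <- solve_mixing(mix, src4[perm, ], n_samples = 2000, seed = 7)
  expect_equal(unname(sol_p$mean), unname(sol$mean[perm]), tolerance = 0.02)
})

test_that("dietary overlap applies the >20 percent criterion per source", {
  mk_sol <- function(p, feasible = TRUE) {
    structure(list(mean = setNames(p, c("invertebrates", "mushrooms",
                                        "earthworms")),
                   sd = p * 0, type = "unique", feasible = feasible,
                   vertices = NULL, n_samples = 0L),
              class = "diet_solution")
  }
  shrew <- mk_sol(c(0.29, 0.05, 0.66))
  # 44% of mice above threshold on invertebrates
  mice <- c(lapply(1:11, function(i) mk_sol(c(0.3, 0.1, 0.6))),
            lapply(1:14, function(i) mk_sol(c(0.1, 0.3, 0.6))))
  ov <- dietary_overlap(shrew, mice)
  inv <- ov[ov$source == "invertebrates", ]
  expect_true(inv$overlap)
  expect_equal(inv$mouse_percent, 44)
  # shrew below threshold blocks overlap regardless of mice
  mush <- ov[ov$source == "mushrooms", ]
  expect_false(mush$overlap)
  expect_equal(mush$mouse_percent, 56)
  # a 0.19 shrew proportion never overlaps
  shrew2 <- mk_sol(c(0.19, 0.15, 0.66))
  ov2 <- dietary_overlap(shrew2, mice)
  expect_false(ov2$overlap[ov2$source == "invertebrates"])
  # no mice: undefined percent, no overlap, warning
  expect_warning(ov3 <- dietary_overlap(shrew, list()), "no feasible")
  expect_true(all(is.na(ov3$mouse_percent)))
  expect_false(any(ov3$overlap))
  # mismatched source lists
  bad <- structure(list(mean = setNames(c(0.5, 0.5), c("x", "y")),
                        sd = c(0, 0), type = "unique", feasible = TRUE),
                   class = "diet_solution")
  expect_error(dietary_overlap(shrew, list(bad)), "mismatched")
})

test_that("separated clusters give statistic 1 and a significant p", {
  set.seed(11)
  a <- cbind(rnorm(15), rnorm(15))
  b <- cbind(rnorm(15) + 50, rnorm(15))
  kt <- knn_randomization_test(a, b, k = 3, n_perm = 999, seed = 2)
  expect_equal(kt$statistic, 1)
  expect_lte(kt$p_value, 0.01)
})

test_that("knn p-values are seed-stable and label-swap invariant", {
  set.seed(12)
  a <- cbind(rnorm(12), rnorm(12))
  b <- cbind(rnorm(12) + 1, rnorm(12))
  k1 <- knn_randomization_test(a, b, seed = 9)
  k2 <- knn_randomization_test(a, b, seed = 9)
  expect_identical(k1, k2)
  k3 <- knn_randomization_test(b, a, seed = 9)
  expect_equal(k3$statistic, k1$statistic)
  expect_error(knn_randomization_test(a[1:3, ], b, k = 3), "k \\+ 1")
  expect_error(knn_randomization_test(a, b, n_perm = 10), "n_perm")
})

test_that("permutation p agrees with exhaustive enumeration on 8 points", {
  set.seed(3)
  pts <- cbind(rnorm(8), rnorm(8))
  lab <- rep(c("A", "B"), each = 4)
  nn <- shrewcomp:::knn_index(pts, 3)
  obs <- knn_statistic(pts, lab, 3)
  cmb <- combn(8, 4)
  stats <- apply(cmb, 2, function(ix) {
    l <- rep("B", 8)
    l[ix] <- "A"
    mean(matrix(l[nn], 8, 3) == l)
  })
  p_exact <- mean(stats >= obs - 1e-12)
  kt <- knn_randomization_test(pts[1:4, ], pts[5:8, ], k = 3, n_perm = 9999,
                               seed = 1)
  expect_equal(kt$statistic, obs)
  expect_equal(kt$p_value, p_exact, tolerance = 0.03)
  expect_gt(kt$p_value, 0.1)  # interleaved points: no separation
})
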