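# Shared fixtures built in code.

# minimal capture-record table
make_records <- function(grid_id = 1, year = 1, primary = 1, night = 1,
                         trap_x = 0, trap_y = 0, species = "mouse",
                         animal_id = "m1", fate = "live", mass_g = 20) {
  data.frame(grid_id = grid_id, year = year, primary = primary,
             night = night, trap_x = trap_x, trap_y = trap_y,
             species = species, animal_id = animal_id, fate = fate,
             mass_g = mass_g, stringsAsFactors = FALSE)
}

# three well-separated sources with equal concentrations: the corrected
# triangle is (0,0), (1,0), (0.5,1)
equal_conc_sources <- function() {
  data.frame(name = c("a", "b", "c"),
             d13c = c(0, 1, 0.5), d15n = c(0, 0, 1),
             conc_c = 1, conc_n = 1)
}

# four sources with unequal concentrations (polytope case)
four_sources <- function() {
  data.frame(name = c("a", "b", "c", "d"),
             d13c = c(-26, -22, -24, -20), d15n = c(2, 3, 8, 7),
             conc_c = c(0.5, 0.4, 0.45, 0.35),
             conc_n = c(0.05, 0.1, 0.08, 0.12))
}

# simplex-grid brute-force oracle for the concentration-dependent mixing
# system: enumerates four-source proportion vectors at the given step and
# keeps those whose implied consumer deltas match the mixture within tol
brute_force_mixing_mean <- function(sources, mixture, step = 0.002,
                                    tol = 0.01) {
  stopifnot(nrow(sources) == 4L)
  cc <- sources$conc_c; cn <- sources$conc_n
  dc <- sources$d13c; dn <- sources$d15n
  p3g <- seq(0, 1, by = step)
  keep_sum <- numeric(4)
  keep_n <- 0
  for (p1 in seq(0, 1, by = step)) {
    g <- expand.grid(p2 = seq(0, 1 - p1, by = step), p3 = p3g)
    g <- g[g$p2 + g$p3 <= 1 - p1 + 1e-12, ]
    p4 <- 1 - p1 - g$p2 - g$p3
    wc <- p1 * cc[1] + g$p2 * cc[2] + g$p3 * cc[3] + p4 * cc[4]
    wn <- p1 * cn[1] + g$p2 * cn[2] + g$p3 * cn[3] + p4 * cn[4]
    rc <- (p1 * cc[1] * dc[1] + g$p2 * cc[2] * dc[2] + g$p3 * cc[3] * dc[3] +
             p4 * cc[4] * dc[4]) / wc - mixture[1]
    rn <- (p1 * cn[1] * dn[1] + g$p2 * cn[2] * dn[2] + g$p3 * cn[3] * dn[3] +
             p4 * cn[4] * dn[4]) / wn - mixture[2]
    ok <- abs(rc) <= tol & abs(rn) <= tol
    if (any(ok)) {
      keep_sum <- keep_sum +
        c(sum(p1 * ok), sum(g$p2[ok]), sum(g$p3[ok]), sum(p4[ok]))
      keep_n <- keep_n + sum(ok)
    }
  }
  keep_sum / keep_n
}

# implied consumer deltas for a proportion vector (for mass-balance checks)
implied_mixture <- function(p, sources) {
  wc <- p * sources$conc_c
  wn <- p * sources$conc_n
  c(sum(wc * sources$d13c) / sum(wc), sum(wn * sources$d15n) / sum(wn))
}
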