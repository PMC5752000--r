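#' Configuration for a synthetic robust-design trapping study
#'
#' Bundles every parameter of the synthetic-data generator: the trapping
#' design (grids of Sherman traps at fixed spacing, sampled for several
#' consecutive nights in repeated primary sessions each year), the density
#' dynamics of the two species (a marked mouse and an unmarked shrew coupled
#' through a standardized-scale competition coefficient), the observation
#' process (per-night capture probability, trap mortality, home-range
#' movement scale) and body-mass distributions.
#'
#' The defaults emulate the study conditions the pipeline targets:
#' 25-m trap spacing, 7 x 6 = 42 traps per grid (within the 40-52 per-grid
#' range of the field design), three primary sessions of five nights per
#' year over three years, a mouse population that peaks in year 2 and
#' crashes in year 3, and a strong negative density coupling
#' (\code{alpha_true = -0.9}) from mice onto shrews.  Capture probabilities
#' are not reported for the field study; the defaults (mice 0.25, shrews
#' 0.10 per night) are generator choices, not field estimates.
#'
#' @param n_grids number of trapping grids.
#' @param grid_rows,grid_cols trap lattice dimensions (each >= 2).
#' @param trap_spacing distance between adjacent traps, metres.
#' @param n_years,n_primary,n_secondary study duration: years, primary
#'   sessions per year, trap-nights (secondary occasions) per session
#'   (\code{n_secondary >= 2}).
#' @param mouse_density_mean mean mouse density, animals/ha.
#' @param mouse_density_sdlog log-scale spread of mouse density across
#'   grid x session.
#' @param mouse_year_effect,shrew_year_effect multiplicative year effects on
#'   mean density, length \code{n_years}.
#' @param shrew_density_mean,shrew_density_sd mean and standardized-unit
#'   scale of shrew density, animals/ha.
#' @param alpha_true competition coefficient on the standardized scale
#'   (slope of standardized shrew density on standardized mouse density);
#'   typically <= 0.
#' @param lag_coef auto-regressive coefficient on the previous session's
#'   standardized shrew density.
#' @param habitat_coefs named vector \code{c(nmds1, nmds2, elevation)} of
#'   standardized habitat effects on shrew density.
#' @param noise_sd process noise standard deviation on the standardized scale.
#' @param p_night named per-night capture probabilities,
#'   \code{c(mouse = , shrew = )}.
#' @param mortality_prob named per-capture trap-mortality probabilities.
#' @param movement_sigma isotropic Gaussian home-range scale, metres.
#' @param buffer boundary-strip width used to convert densities to counts,
#'   metres.
#' @param mouse_mass_mean,mouse_mass_sd,shrew_mass_mean,shrew_mass_sd body
#'   mass distributions, grams.
#' @param seed master integer seed; all generator randomness derives from it.
#' @return an object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(n_grids = 4, seed = 42)
#' cfg$alpha_true
#' @export
sim_config <- function(n_grids = 21,
                       grid_rows = 7, grid_cols = 6, trap_spacing = 25,
                       n_years = 3, n_primary = 3, n_secondary = 5,
                       mouse_density_mean = 10, mouse_density_sdlog = 0.4,
                       mouse_year_effect = c(1, 1.6, 0.4),
                       shrew_density_mean = 6, shrew_density_sd = 2,
                       shrew_year_effect = c(1, 1, 1.5),
                       alpha_true = -0.9, lag_coef = 0.5,
                       habitat_coefs = c(nmds1 = 0, nmds2 = 0, elevation = 0),
                       noise_sd = 0.3,
                       p_night = c(mouse = 0.25, shrew = 0.10),
                       mortality_prob = c(mouse = 0.11, shrew = 0.40),
                       movement_sigma = 20, buffer = 50,
                       mouse_mass_mean = 21.2, mouse_mass_sd = 2.5,
                       shrew_mass_mean = 7, shrew_mass_sd = 1,
                       seed = 1L) {
  if (n_grids < 1) stop_invalid("n_grids must be >= 1")
  if (grid_rows < 2 || grid_cols < 2) {
    stop_invalid("grid_rows and grid_cols must both be >= 2")
  }
  if (trap_spacing <= 0) stop_invalid("trap_spacing must be > 0")
  if (n_secondary < 2) stop_invalid("n_secondary must be >= 2")
  if (any(p_night < 0 | p_night > 1)) {
    stop_invalid("p_night probabilities must lie in [0, 1]")
  }
  if (any(mortality_prob < 0 | mortality_prob > 1)) {
    stop_invalid("mortality_prob probabilities must lie in [0, 1]")
  }
  if (length(mouse_year_effect) != n_years ||
      length(shrew_year_effect) != n_years) {
    stop_invalid("year effects must have length n_years")
  }
  if (!all(c("mouse", "shrew") %in% names(p_night)) ||
      !all(c("mouse", "shrew") %in% names(mortality_prob))) {
    stop_invalid("p_night and mortality_prob need 'mouse' and 'shrew' entries")
  }
  if (movement_sigma <= 0) stop_invalid("movement_sigma must be > 0")
  cfg <- list(
    n_grids = as.integer(n_grids), grid_rows = as.integer(grid_rows),
    grid_cols = as.integer(grid_cols), trap_spacing = trap_spacing,
    n_years = as.integer(n_years), n_primary = as.integer(n_primary),
    n_secondary = as.integer(n_secondary),
    mouse_density_mean = mouse_density_mean,
    mouse_density_sdlog = mouse_density_sdlog,
    mouse_year_effect = mouse_year_effect,
    shrew_density_mean = shrew_density_mean,
    shrew_density_sd = shrew_density_sd,
    shrew_year_effect = shrew_year_effect,
    alpha_true = alpha_true, lag_coef = lag_coef,
    habitat_coefs = habitat_coefs, noise_sd = noise_sd,
    p_night = p_night, mortality_prob = mortality_prob,
    movement_sigma = movement_sigma, buffer = buffer,
    mouse_mass_mean = mouse_mass_mean, mouse_mass_sd = mouse_mass_sd,
    shrew_mass_mean = shrew_mass_mean, shrew_mass_sd = shrew_mass_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Rectangular trap lattice
#'
#' Lays out a rows x cols grid of traps at fixed spacing, indexed row-major
#' with the origin at the southwest trap.  Coordinates are grid-local metres.
#'
#' @param rows,cols lattice dimensions, each >= 2.
#' @param spacing trap spacing in metres (> 0).
#' @return data.frame with columns \code{trap}, \code{trap_x}, \code{trap_y}.
#' @examples
#' make_grid(2, 2, 25)
#' @export
make_grid <- function(rows, cols, spacing) {
  if (rows < 2 || cols < 2) stop_invalid("trap grid needs rows >= 2 and cols >= 2")
  if (spacing <= 0) stop_invalid("trap spacing must be > 0")
  idx <- seq_len(rows * cols)
  data.frame(
    trap = idx,
    trap_x = ((idx - 1L) %% cols) * spacing,
    trap_y = ((idx - 1L) %/% cols) * spacing
  )
}

#' Simulate true population dynamics with known competition structure
#'
#' Generates the latent state of a two-species trapping study: per-grid
#' habitat covariates (two ordination axes and elevation), per grid x
#' session x year true densities and abundances for both species, and the
#' individuals (activity centres and body masses) that realise those
#' abundances.
#'
#' Mouse densities are drawn log-normally around a year-specific mean.
#' Shrew densities follow the generative counterpart of the standardized
#' regression model the downstream competition stage fits: on the
#' standardized scale, shrew density in sessions 2+ equals
#' \code{lag_coef} times the previous session's value plus
#' \code{alpha_true} times the standardized mouse density plus habitat
#' effects plus Gaussian noise (\code{noise_sd}).  Densities are converted
#' to integer abundances through each grid's effective trapping area;
#' negative expected densities are truncated at zero and counted in the
#' \code{truncated} attribute.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{true_state}: list with elements
#'   \code{abundance} (grid x year x session x species densities and counts),
#'   \code{habitat}, \code{individuals}, \code{grid} (trap layout),
#'   \code{eta_ha} (effective trapping area per grid, hectares) and the
#'   originating \code{config}.
#' @examples
#' st <- simulate_dynamics(sim_config(n_grids = 3, seed = 7))
#' head(st$abundance)
#' @export
simulate_dynamics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- make_grid(config$grid_rows, config$grid_cols, config$trap_spacing)
  eta <- effective_area(grid, config$buffer)
  ng <- config$n_grids
  with_seed(derive_seed(config$seed, "dynamics"), {
    habitat <- data.frame(
      grid_id = seq_len(ng),
      nmds1 = rnorm(ng),
      nmds2 = rnorm(ng),
      elevation_m = runif(ng, 50, 500)
    )
    elev_sd <- sd(habitat$elevation_m)
    elev_z <- if (!is.na(elev_sd) && elev_sd > 0) {
      as.numeric(scale(habitat$elevation_m))
    } else {
      rep(0, ng)
    }
    hb <- config$habitat_coefs
    hab_lin <- hb[["nmds1"]] * habitat$nmds1 +
      hb[["nmds2"]] * habitat$nmds2 + hb[["elevation"]] * elev_z

    rows <- list()
    truncated <- 0L
    for (y in seq_len(config$n_years)) {
      mu_m <- config$mouse_density_mean * config$mouse_year_effect[y]
      # grid x session mouse densities, log-normal with mean mu_m
      xm <- matrix(
        exp(rnorm(ng * config$n_primary,
                  log(mu_m) - config$mouse_density_sdlog^2 / 2,
                  config$mouse_density_sdlog)),
        nrow = ng
      )
      sdx <- sd(xm)
      zx <- if (!is.na(sdx) && sdx > 0) (xm - mean(xm)) / sdx else xm * 0
      zs <- matrix(0, nrow = ng, ncol = config$n_primary)
      zs[, 1] <- hab_lin + rnorm(ng, 0, config$noise_sd)
      for (s in seq_len(config$n_primary)[-1]) {
        zs[, s] <- config$lag_coef * zs[, s - 1] +
          config$alpha_true * zx[, s] + hab_lin +
          rnorm(ng, 0, config$noise_sd)
      }
      ds <- config$shrew_density_mean * config$shrew_year_effect[y] +
        config$shrew_density_sd * zs
      truncated <- truncated + sum(ds < 0)
      ds[ds < 0] <- 0
      for (s in seq_len(config$n_primary)) {
        rows[[length(rows) + 1L]] <- data.frame(
          grid_id = seq_len(ng), year = y, session = s,
          species = "mouse", density = xm[, s],
          n_true = as.integer(round(xm[, s] * eta))
        )
        rows[[length(rows) + 1L]] <- data.frame(
          grid_id = seq_len(ng), year = y, session = s,
          species = "shrew", density = ds[, s],
          n_true = as.integer(round(ds[, s] * eta))
        )
      }
    }
    abundance <- do.call(rbind, rows)
    abundance <- abundance[order(abundance$year, abundance$session,
                                 abundance$grid_id, abundance$species), ]
    rownames(abundance) <- NULL

    # individual pools: activity centres uniform over grid rectangle + 50 m
    # margin, one pool per grid x year x species; session s realises the
    # first n_true individuals of the pool, so identities persist across
    # sessions for the marked species
    xmax <- (config$grid_cols - 1L) * config$trap_spacing
    ymax <- (config$grid_rows - 1L) * config$trap_spacing
    individuals <- list()
    for (sp in c("mouse", "shrew")) {
      mm <- if (sp == "mouse") config$mouse_mass_mean else config$shrew_mass_mean
      ms <- if (sp == "mouse") config$mouse_mass_sd else config$shrew_mass_sd
      for (g in seq_len(ng)) {
        for (y in seq_len(config$n_years)) {
          sub <- abundance[abundance$grid_id == g & abundance$year == y &
                             abundance$species == sp, ]
          npool <- max(sub$n_true, 0L)
          if (npool == 0L) next
          key <- paste(sp, g, y, sep = ":")
          individuals[[key]] <- data.frame(
            animal_id = sprintf("%s-g%02d-y%d-%04d", sp, g, y, seq_len(npool)),
            species = sp, grid_id = g, year = y,
            cx = runif(npool, -50, xmax + 50),
            cy = runif(npool, -50, ymax + 50),
            mass_g = pmax(0.5, rnorm(npool, mm, ms))
          )
        }
      }
    }
    out <- list(abundance = abundance, habitat = habitat,
                individuals = individuals, grid = grid, eta_ha = eta,
                config = config)
    attr(out, "truncated") <- truncated
    class(out) <- "true_state"
    out
  })
}

#' Simulate nightly capture records from a true state
#'
#' Runs the observation process over every grid, year, primary session and
#' trap-night.  Each alive individual present in a session is captured on a
#' given night with probability \code{p_night} for its species; its recorded
#' trap is the lattice trap nearest to its activity centre perturbed by an
#' isotropic Gaussian displacement (\code{movement_sigma}).  Each capture
#' independently becomes a trap mortality with probability
#' \code{mortality_prob}, after which the individual produces no further
#' records (in that session or any later one).  Mice are marked and keep
#' their identity across sessions; shrews are released without processing,
#' so their \code{animal_id} is withheld (\code{NA}) in the returned table.
#'
#' @param state a \code{\link{simulate_dynamics}} result.
#' @param config the same \code{\link{sim_config}} used to build the state.
#' @return data.frame of capture records with columns \code{grid_id},
#'   \code{year}, \code{primary}, \code{night}, \code{trap_x}, \code{trap_y},
#'   \code{species}, \code{animal_id}, \code{fate} (\code{"live"} or
#'   \code{"dead"}) and \code{mass_g}.
#' @examples
#' cfg <- sim_config(n_grids = 2, seed = 3)
#' rec <- simulate_captures(simulate_dynamics(cfg), cfg)
#' head(rec)
#' @export
simulate_captures <- function(state, config) {
  stopifnot(inherits(state, "true_state"), inherits(config, "sim_config"))
  spacing <- config$trap_spacing
  ncols <- config$grid_cols
  nrows <- config$grid_rows
  out <- vector("list", length(state$individuals) * config$n_primary)
  k <- 0L
  with_seed(derive_seed(config$seed, "captures"), {
    for (key in names(state$individuals)) {
      pool <- state$individuals[[key]]
      sp <- pool$species[1]
      g <- pool$grid_id[1]
      y <- pool$year[1]
      p <- config$p_night[[sp]]
      mort <- config$mortality_prob[[sp]]
      dead <- rep(FALSE, nrow(pool))
      ab <- state$abundance
      for (s in seq_len(config$n_primary)) {
        n_s <- ab$n_true[ab$grid_id == g & ab$year == y & ab$session == s &
                           ab$species == sp]
        if (length(n_s) == 0L || n_s == 0L) next
        active <- which(!dead)
        active <- active[seq_len(min(n_s, length(active)))]
        if (length(active) == 0L) next
        for (night in seq_len(config$n_secondary)) {
          alive <- active[!dead[active]]
          if (length(alive) == 0L) break
          caught <- alive[runif(length(alive)) < p]
          if (length(caught) == 0L) next
          px <- pool$cx[caught] + rnorm(length(caught), 0, config$movement_sigma)
          py <- pool$cy[caught] + rnorm(length(caught), 0, config$movement_sigma)
          tx <- pmin(pmax(round(px / spacing), 0), ncols - 1L) * spacing
          ty <- pmin(pmax(round(py / spacing), 0), nrows - 1L) * spacing
          dies <- runif(length(caught)) < mort
          dead[caught[dies]] <- TRUE
          k <- k + 1L
          out[[k]] <- data.frame(
            grid_id = g, year = y, primary = s, night = night,
            trap_x = tx, trap_y = ty, species = sp,
            animal_id = if (sp == "mouse") pool$animal_id[caught] else
              NA_character_,
            fate = ifelse(dies, "dead", "live"),
            mass_g = pool$mass_g[caught]
          )
        }
      }
    }
  })
  if (k == 0L) {
    return(data.frame(
      grid_id = integer(), year = integer(), primary = integer(),
      night = integer(), trap_x = numeric(), trap_y = numeric(),
      species = character(), animal_id = character(), fate = character(),
      mass_g = numeric()
    ))
  }
  rec <- do.call(rbind, out[seq_len(k)])
  rec <- rec[order(rec$grid_id, rec$year, rec$primary, rec$night,
                   rec$species, rec$trap_x, rec$trap_y), ]
  rownames(rec) <- NULL
  rec
}

#' Synthetic diet-source isotope profiles
#'
#' A small built-in table of diet sources (pooled macro-invertebrates,
#' earthworms, mushrooms) with delta-13C / delta-15N signatures and
#' elemental C and N mass fractions.  The values are synthetic fixtures
#' chosen to span a well-conditioned mixing triangle with realistic C:N
#' contrasts; they are not field measurements.
#'
#' @return data.frame with columns \code{name}, \code{d13c}, \code{d15n},
#'   \code{conc_c}, \code{conc_n}.
#' @export
default_sources <- function() {
  data.frame(
    name = c("invertebrates", "earthworms", "mushrooms"),
    d13c = c(-25.0, -27.5, -22.0),
    d15n = c(4.5, 9.0, 1.5),
    conc_c = c(0.45, 0.38, 0.42),
    conc_n = c(0.10, 0.09, 0.04)
  )
}

#' Simulate consumer isotope samples from known diet proportions
#'
#' Builds consumer delta values from the concentration-weighted mixing
#' identity: for each element the consumer's delta equals the
#' concentration-and-proportion weighted mean of the (discrimination
#' corrected) source deltas.  Gaussian measurement noise is added per
#' sample and the ground-truth proportions are attached so mixing-model
#' recovery can be tested.
#'
#' @param sources data.frame like \code{\link{default_sources}}.
#' @param true_props numeric vector (one group) or matrix (groups x sources)
#'   of diet proportions; each row must sum to 1 within 1e-9.
#' @param noise_sd measurement noise standard deviation, permil.
#' @param n samples per group.
#' @param seed integer seed.
#' @param offsets discrimination offsets \code{c(d13c = , d15n = )} added to
#'   the source deltas before mixing (consumer-diet discrimination).
#' @param group_names optional character names for the consumer groups.
#' @return data.frame with columns \code{sample_id}, \code{group},
#'   \code{d13c}, \code{d15n}; the true proportion matrix is attached as
#'   attribute \code{"true_props"}.
#' @examples
#' iso <- simulate_isotope_data(default_sources(), c(0.5, 0.3, 0.2),
#'                              noise_sd = 0.2, n = 20, seed = 1)
#' head(iso)
#' @export
simulate_isotope_data <- function(sources, true_props, noise_sd, n, seed,
                                  offsets = c(d13c = 0, d15n = 0),
                                  group_names = NULL) {
  if (is.null(dim(true_props))) true_props <- matrix(true_props, nrow = 1)
  if (ncol(true_props) != nrow(sources)) {
    stop_invalid("true_props must have one column per source")
  }
  if (any(abs(rowSums(true_props) - 1) > 1e-9)) {
    stop_invalid("diet proportions must sum to 1 (tolerance 1e-9)")
  }
  if (any(true_props < 0)) stop_invalid("diet proportions must be >= 0")
  corr <- sources
  corr$d13c <- corr$d13c + offsets[["d13c"]]
  corr$d15n <- corr$d15n + offsets[["d15n"]]
  if (is.null(group_names)) group_names <- paste0("group", seq_len(nrow(true_props)))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(true_props)), function(i) {
      p <- true_props[i, ]
      wc <- p * corr$conc_c
      wn <- p * corr$conc_n
      mu_c <- sum(wc * corr$d13c) / sum(wc)
      mu_n <- sum(wn * corr$d15n) / sum(wn)
      data.frame(
        sample_id = sprintf("%s-%03d", group_names[i], seq_len(n)),
        group = group_names[i],
        d13c = mu_c + rnorm(n, 0, noise_sd),
        d15n = mu_n + rnorm(n, 0, noise_sd)
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "true_props") <- true_props
    out
  })
}

#' Simulate a standardized competition session table
#'
#' A focused generator for the competition stage: emits the grid x session
#' table of shrew density, mouse density, lagged shrew density and habitat
#' covariates directly on the scale the regression consumes, built from the
#' auto-regressive standardized model with known coefficients.  Used by
#' recovery tests; \code{\link{simulate_dynamics}} embeds the same structure
#' inside the full trapping simulation.
#'
#' @param n_grids grids (rows per transition).
#' @param n_sessions primary sessions (yields \code{n_sessions - 1}
#'   transitions).
#' @param alpha standardized competition coefficient.
#' @param lag_coef auto-regressive coefficient.
#' @param habitat_coefs named \code{c(nmds1, nmds2, elevation)} effects.
#' @param noise_sd process noise SD.
#' @param seed integer seed.
#' @return data.frame with columns \code{grid_id}, \code{year},
#'   \code{session}, \code{shrew_density}, \code{mouse_density},
#'   \code{shrew_density_lag}, \code{nmds1}, \code{nmds2},
#'   \code{elevation_m}.  One row per grid x session for sessions 2..n.
#' @export
simulate_competition_table <- function(n_grids = 21, n_sessions = 3,
                                       alpha = -0.9, lag_coef = 0.5,
                                       habitat_coefs = c(nmds1 = 0, nmds2 = 0,
                                                         elevation = 0),
                                       noise_sd = 0.3, seed = 1L) {
  with_seed(seed, {
    nmds1 <- rnorm(n_grids)
    nmds2 <- rnorm(n_grids)
    elev <- runif(n_grids, 50, 500)
    elev_z <- as.numeric(scale(elev))
    hab <- habitat_coefs[["nmds1"]] * nmds1 + habitat_coefs[["nmds2"]] * nmds2 +
      habitat_coefs[["elevation"]] * elev_z
    zprev <- rnorm(n_grids)
    rows <- list()
    for (s in 2:n_sessions) {
      zx <- rnorm(n_grids)
      zy <- lag_coef * zprev + alpha * zx + hab + rnorm(n_grids, 0, noise_sd)
      rows[[s - 1L]] <- data.frame(
        grid_id = seq_len(n_grids), year = 1L, session = s,
        shrew_density = zy, mouse_density = zx, shrew_density_lag = zprev,
        nmds1 = nmds1, nmds2 = nmds2, elevation_m = elev
      )
      zprev <- zy
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a simulated dataset to disk
#'
#' Writes \code{captures.csv}, \code{habitat.csv}, \code{isotopes.csv} and
#' \code{truth.json} (ground-truth parameters and abundances) under
#' \code{dir}, in the plain CSV dialect the readers in this package expect
#' (UTF-8, comma separated, \code{.} decimal).
#'
#' @param state a \code{\link{simulate_dynamics}} result.
#' @param records a \code{\link{simulate_captures}} table.
#' @param isotopes an isotope sample table (consumers and sources bound
#'   together with a \code{role} column), or \code{NULL} to skip.
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_sim_data <- function(state, records, isotopes = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  f <- file.path(dir, "captures.csv")
  write.csv(records, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "habitat.csv")
  write.csv(state$habitat, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(isotopes)) {
    f <- file.path(dir, "isotopes.csv")
    write.csv(isotopes, f, row.names = FALSE)
    files <- c(files, f)
  }
  truth <- list(
    config = unclass(state$config),
    eta_ha = state$eta_ha,
    abundance = state$abundance
  )
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
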