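# Standardized-regression competition coefficients: candidate model sets
# over habitat and density predictors, OLS fits, AICc and the
# AICc / R-squared / parsimony selection rule.

#' Standardize to zero mean and unit standard deviation
#'
#' \code{(x - mean(x)) / sd(x)} with the sample (n-1) standard deviation.
#' Applied to density series per species (and, by convention here, per
#' year) so the competition coefficient does not depend on either species'
#' density variance.
#'
#' @param values numeric vector, length >= 2, with positive variance.
#' @param label optional label (e.g. "2011 shrew") used in the error message
#'   when the variance is zero.
#' @return z-scores with the same length as \code{values}.
#' @examples
#' standardize(c(2, 4, 6))  # -1 0 1
#' @export
standardize <- function(values, label = NULL) {
  if (length(values) < 2L) stop_invalid("need >= 2 values to standardize")
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    stop_invalid("zero variance%s: cannot standardize",
                 if (is.null(label)) "" else paste0(" in ", label))
  }
  (values - mean(values)) / s
}

#' Candidate model sets for competition regressions
#'
#' Enumerates the term configurations of the two model families over the
#' four predictors: competitor (mouse) density, two habitat ordination axes
#' and elevation.  The regressive family is every non-empty subset of the
#' four predictors (15 models).  The auto-regressive family always contains
#' the lagged focal-species density and adds every subset of the four
#' predictors, including the empty one (16 models).  Ordering is
#' deterministic: by subset size, then lexicographic in the fixed predictor
#' order.
#'
#' @param autoregressive logical; build the auto-regressive family?
#' @return named list of character vectors of term names
#'   (\code{mouse_density}, \code{nmds1}, \code{nmds2}, \code{elevation_m},
#'   plus \code{shrew_density_lag} in the auto-regressive family).
#' @examples
#' length(build_model_set(FALSE))  # 15
#' length(build_model_set(TRUE))   # 16
#' @export
build_model_set <- function(autoregressive = FALSE) {
  preds <- c("mouse_density", "nmds1", "nmds2", "elevation_m")
  subsets <- list()
  for (size in seq_along(preds)) {
    cc <- combn(preds, size, simplify = FALSE)
    subsets <- c(subsets, cc)
  }
  if (autoregressive) {
    configs <- c(list(character(0)), subsets)
    configs <- lapply(configs, function(s) c("shrew_density_lag", s))
  } else {
    configs <- subsets
  }
  names(configs) <- vapply(configs, paste, "", collapse = " + ")
  configs
}

#' Ordinary least squares fit with AICc bookkeeping
#'
#' Fits \code{y} on the given design (intercept always included) by least
#' squares — the Gaussian identity-link GLM — and records everything the
#' model-selection stage needs: coefficients, the competition coefficient
#' alpha (the slope on \code{mouse_density}, when present), the Gaussian
#' maximum log-likelihood (residual variance RSS/n), the parameter count k
#' (intercept, slopes and the residual variance), AICc and R-squared.
#'
#' @param y numeric response.
#' @param X data.frame or matrix of predictors (no intercept column), or
#'   \code{NULL} for an intercept-only fit.
#' @param terms optional character vector naming which columns of \code{X}
#'   to use; defaults to all.
#' @return object of class \code{competition_fit}.
#' @examples
#' tbl <- simulate_competition_table(seed = 5)
#' f <- fit_ols(tbl$shrew_density,
#'              tbl[c("shrew_density_lag", "mouse_density")])
#' f$alpha
#' @export
fit_ols <- function(y, X = NULL, terms = NULL) {
  n <- length(y)
  if (!is.null(X)) {
    X <- as.data.frame(X)
    if (!is.null(terms)) X <- X[, terms, drop = FALSE]
  }
  if (is.null(X) || ncol(X) == 0L) {
    dat <- data.frame(y = y)
    fit <- lm(y ~ 1, data = dat)
    term_names <- character(0)
  } else {
    term_names <- colnames(X)
    dat <- cbind(data.frame(y = y), X)
    fit <- lm(stats::reformulate(term_names, "y"), data = dat)
  }
  if (n <= length(coef(fit))) stop_invalid("need n > number of coefficients")
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_invalid("singular design: collinear term(s) %s",
                 paste(bad, collapse = ", "))
  }
  ll <- logLik(fit)
  k <- attr(ll, "df")  # slopes + intercept + residual variance
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  cf <- coef(fit)
  alpha <- if ("mouse_density" %in% names(cf)) unname(cf["mouse_density"]) else
    NA_real_
  # Wald 95% CI for alpha, used by recovery diagnostics
  alpha_ci <- if (!is.na(alpha)) {
    se <- sqrt(diag(stats::vcov(fit)))[["mouse_density"]]
    alpha + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(terms = term_names, coefficients = cf, alpha = alpha,
         alpha_ci = alpha_ci, loglik = as.numeric(ll), k = k, n = n,
         aicc = if (n > k + 1) aicc(as.numeric(ll), k, n) else NA_real_,
         r2 = r2, lm = fit),
    class = "competition_fit"
  )
}

#' @export
print.competition_fit <- function(x, ...) {
  lab <- if (length(x$terms)) paste(x$terms, collapse = " + ") else "intercept"
  cat(sprintf("competition_fit: y ~ %s\n  AICc %.2f, R2 %.3f, alpha %s\n",
              lab, x$aicc, x$r2,
              if (is.na(x$alpha)) "-" else sprintf("%.3f", x$alpha)))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' \code{AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)}, with k counting the
#' intercept, slopes and the residual-variance parameter.
#'
#' @param loglik maximized log-likelihood.
#' @param k parameter count.
#' @param n sample size; must exceed \code{k + 1}.
#' @return AICc value.
#' @examples
#' aicc(-10, 3, 20)  # 27.5
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop_invalid("AICc undefined: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate fits and apply the parsimony selection rule
#'
#' Sorts fits by AICc and computes delta-AICc.  Among the models with
#' considerable support (delta-AICc <= 2) the selected model is the one
#' with the fewest parameters, remaining ties broken by higher R-squared,
#' then by lower AICc — the AICc / R-squared / parsimony rule.
#'
#' @param fits named list of \code{competition_fit}s fitted to the same
#'   response rows.
#' @param support_delta support threshold (default 2).
#' @return list with \code{table} (a data.frame shaped like the reporting
#'   tables: model, k, AICc, delta-AICc, R2, alpha — all fits, ranked),
#'   \code{supported} (names with delta <= threshold) and \code{selected}
#'   (name of the chosen model).
#' @examples
#' tbl <- simulate_competition_table(seed = 5)
#' fits <- lapply(build_model_set(TRUE), function(tm)
#'   fit_ols(tbl$shrew_density, tbl, terms = tm))
#' rank_models(fits)$selected
#' @export
rank_models <- function(fits, support_delta = 2) {
  if (length(fits) == 0L) stop_invalid("no fits to rank")
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f)
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "intercept",
      "")
  }
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, function(f) f$k, 0),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aicc = vapply(fits, function(f) f$aicc, 0),
    r2 = vapply(fits, function(f) f$r2, 0),
    alpha = vapply(fits, function(f) f$alpha, 0),
    stringsAsFactors = FALSE
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab <- tab[order(tab$aicc, tab$k), ]
  rownames(tab) <- NULL
  supported <- tab$model[tab$delta_aicc <= support_delta]
  cand <- tab[tab$delta_aicc <= support_delta, ]
  cand <- cand[order(cand$k, -cand$r2, cand$aicc), ]
  list(
    table = tab[, c("model", "k", "loglik", "aicc", "delta_aicc", "r2",
                    "alpha")],
    supported = supported,
    selected = cand$model[1]
  )
}

#' Build the standardized session table for competition regressions
#'
#' Joins per grid x session x year density estimates of the two species
#' with habitat covariates, standardizes each species' density series to
#' zero mean and unit SD within year, and lays out the response rows:
#' sessions 2..S of each year, with the same grid's previous-session
#' (standardized) shrew density as the lag term.  No lag crosses a winter
#' (year boundary).  Habitat covariates are standardized across grids so
#' coefficients are comparable; this does not affect alpha.  Rows with any
#' missing value are dropped with a message.
#'
#' @param densities long data.frame with columns \code{grid_id},
#'   \code{year}, \code{session}, \code{species} (\code{"mouse"} /
#'   \code{"shrew"}) and \code{density}.
#' @param habitat data.frame with \code{grid_id}, \code{nmds1},
#'   \code{nmds2}, \code{elevation_m}.
#' @param scope \code{"year"} (default) standardizes densities within year;
#'   \code{"global"} pools all years.
#' @return data.frame with columns \code{grid_id}, \code{year},
#'   \code{session}, \code{shrew_density}, \code{mouse_density},
#'   \code{shrew_density_lag}, \code{nmds1}, \code{nmds2},
#'   \code{elevation_m} (standardized scales).
#' @export
session_table <- function(densities, habitat, scope = c("year", "global")) {
  scope <- match.arg(scope)
  req <- c("grid_id", "year", "session", "species", "density")
  if (!all(req %in% names(densities))) {
    stop_invalid("densities needs columns %s", paste(req, collapse = ", "))
  }
  densities$z <- NA_real_
  grp <- if (scope == "year") {
    interaction(densities$species, densities$year, drop = TRUE)
  } else {
    factor(densities$species)
  }
  for (g in levels(grp)) {
    ix <- which(grp == g)
    densities$z[ix] <- standardize(densities$density[ix], label = g)
  }
  hab <- habitat
  hab$nmds1 <- standardize(hab$nmds1, "nmds1")
  hab$nmds2 <- standardize(hab$nmds2, "nmds2")
  hab$elevation_m <- standardize(hab$elevation_m, "elevation_m")

  key <- function(g, y, s) paste(g, y, s, sep = "|")
  zmap <- function(sp) {
    d <- densities[densities$species == sp, ]
    setNames(d$z, key(d$grid_id, d$year, d$session))
  }
  zs <- zmap("shrew")
  zm <- zmap("mouse")
  sessions <- sort(unique(densities$session))
  combos <- unique(densities[densities$session != min(sessions),
                             c("grid_id", "year", "session")])
  out <- data.frame(
    grid_id = combos$grid_id, year = combos$year, session = combos$session,
    shrew_density = zs[key(combos$grid_id, combos$year, combos$session)],
    mouse_density = zm[key(combos$grid_id, combos$year, combos$session)],
    shrew_density_lag = zs[key(combos$grid_id, combos$year,
                               combos$session - 1L)]
  )
  out <- merge(out, hab, by = "grid_id", sort = FALSE)
  out <- out[order(out$year, out$session, out$grid_id), ]
  rownames(out) <- NULL
  keep <- stats::complete.cases(out)
  if (any(!keep)) {
    message(sum(!keep), " session-table row(s) dropped for missing values")
    out <- out[keep, ]
  }
  out
}

#' Fit and rank a full candidate model set
#'
#' Fits every configuration of \code{\link{build_model_set}} to one year's
#' (or one table's) response rows and ranks them with
#' \code{\link{rank_models}}.  When \code{by_year = TRUE} the table is split
#' by its \code{year} column and each year is fitted separately, sharing no
#' rows across years.
#'
#' @param tbl a \code{\link{session_table}} (already standardized).
#' @param autoregressive which model family to fit.
#' @param by_year fit each year separately?
#' @return for a single year, the \code{\link{rank_models}} list; with
#'   \code{by_year = TRUE}, a named list of those per year.
#' @export
fit_model_set <- function(tbl, autoregressive = TRUE, by_year = FALSE) {
  if (by_year) {
    years <- sort(unique(tbl$year))
    out <- lapply(years, function(y)
      fit_model_set(tbl[tbl$year == y, ], autoregressive, by_year = FALSE))
    names(out) <- years
    return(out)
  }
  configs <- build_model_set(autoregressive)
  fits <- lapply(configs, function(tm)
    fit_ols(tbl$shrew_density, tbl, terms = tm))
  rank_models(fits)
}
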