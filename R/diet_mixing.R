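# Concentration-dependent dual-isotope linear mixing over the feasible
# polytope, discrimination correction, the >20% dietary-overlap criterion
# and a K-nearest-neighbour randomization test for group differences.

#' Default consumer-diet discrimination offsets
#'
#' Trophic enrichment factors added to source deltas before mixing:
#' 1.0 permil delta-13C / 3.0 permil delta-15N for mice and 1.3 / 2.5 for
#' shrews.
#'
#' @return named list of \code{c(d13c, d15n)} vectors per species.
#' @export
default_offsets <- function() {
  list(
    mouse = c(d13c = 1.0, d15n = 3.0),
    shrew = c(d13c = 1.3, d15n = 2.5)
  )
}

#' Apply consumer-diet discrimination to source signatures
#'
#' Shifts every source's delta-13C and delta-15N by the consumer species'
#' discrimination offsets; elemental concentrations are unchanged.
#'
#' @param sources data.frame with \code{d13c}, \code{d15n} (and
#'   concentration) columns.
#' @param species consumer species tag, a name of \code{offsets}.
#' @param offsets named list of per-species offsets; defaults to
#'   \code{\link{default_offsets}}.
#' @return the corrected source data.frame.
#' @examples
#' s <- data.frame(name = "x", d13c = -26, d15n = 2,
#'                 conc_c = 0.4, conc_n = 0.1)
#' correct_sources(s, "shrew")  # -24.7, 4.5
#' @export
correct_sources <- function(sources, species, offsets = default_offsets()) {
  if (!species %in% names(offsets)) {
    stop_invalid("no discrimination offsets configured for species '%s'",
                 species)
  }
  off <- offsets[[species]]
  if (!all(is.finite(off))) stop_invalid("offsets must be finite")
  sources$d13c <- sources$d13c + off[["d13c"]]
  sources$d15n <- sources$d15n + off[["d15n"]]
  sources
}

# residual (permil) of the concentration-dependent mass balance for a
# proportion vector
mixing_residual <- function(p, sources, mixture) {
  wc <- p * sources$conc_c
  wn <- p * sources$conc_n
  c(sum(wc * sources$d13c) / sum(wc) - mixture[1],
    sum(wn * sources$d15n) / sum(wn) - mixture[2])
}

#' Solve the concentration-dependent dual-isotope mixing system
#'
#' Finds all diet-proportion vectors p (p >= 0, sum p = 1) satisfying the
#' concentration-dependent mass balance for both elements: the consumer's
#' delta for element e equals the concentration-and-proportion weighted
#' mean of the source deltas.  Rearranged, the balance is linear in p, so
#' the feasible set is the intersection of two hyperplanes with the
#' simplex:
#' with 3 sources the solution is unique when the (corrected) source
#' triangle contains the mixture; with more sources it is a polytope whose
#' vertices are enumerated as basic feasible solutions and which is
#' summarized by the mean and SD of points sampled uniformly from it.
#'
#' @param mixture length-2 numeric, the consumer's \code{c(d13c, d15n)}.
#' @param sources corrected source data.frame with \code{name},
#'   \code{d13c}, \code{d15n}, \code{conc_c}, \code{conc_n}.
#' @param n_samples points sampled uniformly from the polytope (>= 2
#'   sources beyond the unique case); default 10000.
#' @param seed integer seed for the polytope sampling.
#' @param tol mass-balance feasibility tolerance in permil (default 0.01).
#' @return object of class \code{diet_solution}: per-source \code{mean} and
#'   \code{sd}, \code{type} (\code{"unique"}, \code{"polytope"} or
#'   \code{"infeasible"}), \code{feasible} flag, polytope \code{vertices}
#'   and \code{n_samples}.
#' @examples
#' src <- default_sources()
#' sol <- solve_mixing(c(src$d13c[2], src$d15n[2]), src)
#' sol$mean  # pure source 2 diet
#' @export
solve_mixing <- function(mixture, sources, n_samples = 10000, seed = 1L,
                         tol = 0.01) {
  s <- nrow(sources)
  if (s < 2L) stop_invalid("need >= 2 sources")
  if (!all(is.finite(mixture)) || length(mixture) != 2L) {
    stop_invalid("mixture must be a finite (d13C, d15N) pair")
  }
  if (any(sources$conc_c <= 0 | sources$conc_n <= 0)) {
    stop_invalid("source concentrations must be > 0")
  }
  A <- rbind(
    sources$conc_c * (sources$d13c - mixture[1]),
    sources$conc_n * (sources$d15n - mixture[2]),
    rep(1, s)
  )
  b <- c(0, 0, 1)
  nm <- sources$name
  feasible_p <- function(p) all(p >= -1e-9) &&
    all(abs(mixing_residual(pmax(p, 0) / sum(pmax(p, 0)), sources, mixture)) <=
          tol)
  as_solution <- function(mean, sd, type, vertices = NULL, n_used = 0L) {
    structure(list(mean = setNames(mean, nm), sd = setNames(sd, nm),
                   type = type, feasible = type != "infeasible",
                   vertices = vertices, n_samples = n_used),
              class = "diet_solution")
  }
  infeasible <- function() as_solution(rep(NA_real_, s), rep(NA_real_, s),
                                       "infeasible")

  if (s == 2L) {
    # overdetermined: least squares, then feasibility check
    p <- qr.solve(A, b)
    if (!feasible_p(p)) return(infeasible())
    p <- pmax(p, 0); p <- p / sum(p)
    return(as_solution(p, rep(0, s), "unique"))
  }
  if (s == 3L) {
    if (rcond(A) < 1e-12) {
      stop_invalid("ill-conditioned mixing system: corrected sources are collinear")
    }
    p <- solve(A, b)
    if (!feasible_p(p)) return(infeasible())
    p <- pmax(p, 0); p <- p / sum(p)
    return(as_solution(p, rep(0, s), "unique"))
  }

  # >= 4 sources: enumerate polytope vertices as basic feasible solutions
  bases <- combn(s, 3L, simplify = FALSE)
  verts <- list()
  for (bi in bases) {
    M <- A[, bi, drop = FALSE]
    if (rcond(M) < 1e-10) next
    pb <- solve(M, b)
    if (any(pb < -1e-9)) next
    p <- numeric(s)
    p[bi] <- pmax(pb, 0)
    p <- p / sum(p)
    if (feasible_p(p)) verts[[length(verts) + 1L]] <- p
  }
  if (length(verts) == 0L) return(infeasible())
  V <- unique(round(do.call(rbind, verts), 9))
  if (nrow(V) == 1L) {
    return(as_solution(V[1, ], rep(0, s), "unique", vertices = V))
  }
  # uniform sampling from the polytope in null-space coordinates
  Bn <- MASS::Null(t(A))
  p0 <- colMeans(V)
  Z <- (V - matrix(p0, nrow(V), s, byrow = TRUE)) %*% Bn
  d <- ncol(Bn)
  samples <- with_seed(seed, {
    if (d == 1L) {
      u <- runif(n_samples, min(Z), max(Z))
      matrix(p0, n_samples, s, byrow = TRUE) + u %*% t(Bn)
    } else {
      lo <- apply(Z, 2, min)
      hi <- apply(Z, 2, max)
      acc <- matrix(NA_real_, 0, s)
      while (nrow(acc) < n_samples) {
        m <- max(2L * n_samples, 1000L)
        z <- matrix(runif(m * d), m, d)
        z <- sweep(sweep(z, 2, hi - lo, "*"), 2, lo, "+")
        cand <- matrix(p0, m, s, byrow = TRUE) + z %*% t(Bn)
        ok <- apply(cand, 1, function(p) all(p >= -1e-12))
        acc <- rbind(acc, cand[ok, , drop = FALSE])
      }
      acc[seq_len(n_samples), , drop = FALSE]
    }
  })
  samples[samples < 0] <- 0
  samples <- samples / rowSums(samples)
  as_solution(colMeans(samples), apply(samples, 2, sd), "polytope",
              vertices = V, n_used = n_samples)
}

#' @export
print.diet_solution <- function(x, ...) {
  cat(sprintf("diet_solution (%s)\n", x$type))
  if (x$feasible) {
    for (i in seq_along(x$mean)) {
      cat(sprintf("  %-14s %.3f +/- %.3f\n", names(x$mean)[i], x$mean[i],
                  x$sd[i]))
    }
  }
  invisible(x)
}

#' Dietary-overlap report under the >20 percent criterion
#'
#' Per diet source: whether the shrew population's mean assimilated
#' proportion exceeds the threshold, the percent of individual mice whose
#' proportion exceeds it, and the joint overlap flag (shrews include the
#' item and at least one mouse does too).
#'
#' @param shrew_solution a \code{diet_solution} for the shrew population
#'   mean.
#' @param mouse_solutions list of \code{diet_solution}s, one per individual
#'   mouse; infeasible ones are dropped with a message.
#' @param threshold inclusion threshold on the assimilated proportion
#'   (default 0.2, i.e. >20 percent).
#' @return data.frame with columns \code{source}, \code{shrew_mean},
#'   \code{shrew_included}, \code{mouse_percent}, \code{overlap}.
#' @export
dietary_overlap <- function(shrew_solution, mouse_solutions, threshold = 0.2) {
  src <- names(shrew_solution$mean)
  keep <- vapply(mouse_solutions, function(m) isTRUE(m$feasible), TRUE)
  if (any(!keep)) message(sum(!keep), " infeasible mouse solution(s) dropped")
  mouse_solutions <- mouse_solutions[keep]
  for (m in mouse_solutions) {
    if (!identical(names(m$mean), src)) {
      stop_invalid("mismatched source lists between shrew and mouse solutions")
    }
  }
  n_mice <- length(mouse_solutions)
  if (n_mice == 0L) warning("no feasible mouse solutions: overlap undefined")
  mouse_percent <- vapply(src, function(sn) {
    if (n_mice == 0L) return(NA_real_)
    100 * mean(vapply(mouse_solutions, function(m) m$mean[[sn]] > threshold,
                      TRUE))
  }, 0)
  shrew_mean <- shrew_solution$mean
  shrew_included <- shrew_mean > threshold
  overlap <- shrew_included & !is.na(mouse_percent) & mouse_percent > 0
  data.frame(
    source = src,
    shrew_mean = as.numeric(shrew_mean),
    shrew_included = as.logical(shrew_included),
    mouse_percent = as.numeric(mouse_percent),
    overlap = as.logical(overlap),
    row.names = NULL
  )
}

#' K-nearest-neighbour group statistic
#'
#' Mean, over all points, of the fraction of each point's k nearest
#' neighbours (Euclidean, self excluded, distance ties broken by smallest
#' index) that share its group label.  Values near 1 indicate separated
#' groups; near the label-frequency baseline, a single mixed cloud.
#'
#' @param points numeric matrix (n x 2) of isotope coordinates.
#' @param labels group labels, length n.
#' @param k neighbours per point.
#' @return the statistic in [0, 1].
#' @export
knn_statistic <- function(points, labels, k) {
  nn <- knn_index(points, k)
  mean(matrix(labels[nn], nrow(nn), k) == labels)
}

knn_index <- function(points, k) {
  D <- as.matrix(dist(points))
  diag(D) <- Inf
  t(apply(D, 1, function(r) order(r)[seq_len(k)]))
}

#' K-nearest-neighbour randomization test
#'
#' Tests whether two groups of dual-isotope points are distinguishable:
#' the observed \code{\link{knn_statistic}} is compared to its null
#' distribution under random reassignment of group labels, with
#' \code{p = (1 + #(permuted >= observed)) / (n_perm + 1)}.
#'
#' @param groupA,groupB numeric matrices or data.frames of (d13C, d15N)
#'   points; each group needs at least \code{k + 1} points.
#' @param k neighbours (default 3).
#' @param n_perm label permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return list with \code{statistic}, \code{p_value}, \code{k},
#'   \code{n_perm}.
#' @examples
#' a <- cbind(rnorm(15), rnorm(15))
#' b <- cbind(rnorm(15) + 10, rnorm(15))
#' knn_randomization_test(a, b, seed = 1)$p_value
#' @export
knn_randomization_test <- function(groupA, groupB, k = 3L, n_perm = 999L,
                                   seed = 1L) {
  A <- as.matrix(groupA)
  B <- as.matrix(groupB)
  if (nrow(A) < k + 1 || nrow(B) < k + 1) {
    stop_invalid("each group needs at least k + 1 points")
  }
  if (n_perm < 99L) stop_invalid("n_perm must be >= 99")
  pts <- rbind(A, B)
  labels <- rep(c("A", "B"), c(nrow(A), nrow(B)))
  nn <- knn_index(pts, k)
  obs <- mean(matrix(labels[nn], nrow(nn), k) == labels)
  n <- length(labels)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- labels[sample.int(n)]
      mean(matrix(lab[nn], n, k) == lab)
    }, 0)
  })
  p <- (1 + sum(perm_stats >= obs - 1e-12)) / (n_perm + 1)
  list(statistic = obs, p_value = p, k = k, n_perm = n_perm)
}
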