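#' Fit a group-based trajectory model
#'
#' Finite mixture of polynomial-in-time Gaussian regressions (group-based
#' trajectory modeling, a latent class analysis): conditional on class g,
#' `y_it ~ Normal(sum_j beta_gj t_i^j, sigma^2)` with a single residual
#' variance shared across classes and time points. Time is rescaled to the
#' unit interval over the windows for numerical conditioning. Fitting is by EM with
#' k-means-style initialization and multiple restarts; the log-likelihood is
#' non-decreasing across EM iterations and the best restart is returned.
#' Restarts whose classes collapse to (near) zero weight are discarded; an
#' error is raised only if every restart collapses.
#'
#' @param traj A `sofa_trajectories` object or n x K numeric matrix.
#' @param G Number of latent classes (>= 1).
#' @param degree Polynomial degree, 1, 2 or 3 (default 2).
#' @param seed Integer seed controlling initialization.
#' @param n_restarts Number of EM restarts (default 10).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Convergence threshold on the log-likelihood improvement.
#' @return Object of class `gbtm`: mixing weights `pi`, coefficient matrix
#'   `beta` (G x (degree + 1), on rescaled time), residual variance
#'   `sigma2`, `loglik`, `n_params`, `bic`, `converged`, plus the fitted
#'   class mean curves (`mean_curves`, G x K).
#' @export
fit_gbtm <- function(traj, G, degree = 2, seed = 1, n_restarts = 10,
                     max_iter = 500, tol = 1e-6) {
  Y <- trajectory_matrix(traj)
  storage.mode(Y) <- "double"
  n <- nrow(Y); K <- ncol(Y)
  stopifnot(G >= 1, degree %in% 1:3)
  if (n < G * (degree + 2)) stop("too few trajectories for G classes")
  tt <- seq(0, 1, length.out = K)
  X <- outer(tt, 0:degree, `^`) # K x (p+1)
  best <- NULL
  if (G == 1) n_restarts <- 1
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + 1000L * (r - 1L))
    fit <- .gbtm_em(Y, X, G, max_iter, tol)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("all EM restarts collapsed to an empty class")
  p1 <- degree + 1
  n_params <- G * p1 + (G - 1) + 1
  bic <- -2 * best$loglik + n_params * log(n)
  structure(list(G = G, degree = degree, pi = best$pi, beta = best$beta,
                 sigma2 = best$sigma2, loglik = best$loglik,
                 loglik_trace = best$trace, n_params = n_params, bic = bic,
                 converged = best$converged, mean_curves = best$beta %*% t(X),
                 time = tt, X = X, seed = seed),
            class = "gbtm")
}

.gbtm_em <- function(Y, X, G, max_iter, tol) {
  n <- nrow(Y); K <- ncol(Y)
  # k-means-style initialization on trajectory shapes
  r <- matrix(1 / G, n, G)
  if (G > 1) {
    km <- tryCatch(suppressWarnings(kmeans(Y, centers = G, nstart = 3,
                                           iter.max = 50)),
                   error = function(e) NULL)
    hard <- if (is.null(km)) sample.int(G, n, replace = TRUE) else km$cluster
    r <- matrix(0.05 / (G - 1), n, G)
    r[cbind(seq_len(n), hard)] <- 0.95
  }
  XtX <- crossprod(X)
  pi_g <- rep(1 / G, G)
  beta <- matrix(0, G, ncol(X))
  sigma2 <- 1
  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # M-step from current responsibilities
    cs <- colSums(r)
    if (any(cs < 1e-6)) return(NULL) # collapsed class
    pi_g <- cs / n
    rss_tot <- 0
    for (g in seq_len(G)) {
      ybar <- colSums(r[, g] * Y) / cs[g]
      beta[g, ] <- solve(XtX, crossprod(X, ybar))
      resid <- Y - matrix(X %*% beta[g, ], n, K, byrow = TRUE)
      rss_tot <- rss_tot + sum(r[, g] * rowSums(resid^2))
    }
    sigma2 <- max(rss_tot / (n * K), 1e-12)
    # E-step
    ll_mat <- matrix(0, n, G)
    for (g in seq_len(G)) {
      resid <- Y - matrix(X %*% beta[g, ], n, K, byrow = TRUE)
      ll_mat[, g] <- -K / 2 * log(2 * pi * sigma2) -
        rowSums(resid^2) / (2 * sigma2)
    }
    lw <- sweep(ll_mat, 2, log(pi_g), `+`)
    mx <- apply(lw, 1, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    r <- exp(lw - lse)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(prev_ll) && ll - prev_ll < tol) {
      converged <- TRUE
      prev_ll <- ll
      break
    }
    prev_ll <- ll
  }
  list(pi = pi_g, beta = beta, sigma2 = sigma2, loglik = prev_ll,
       trace = trace, converged = converged)
}

#' @export
print.gbtm <- function(x, ...) {
  cat(sprintf(
    "Group-based trajectory model: G = %d, degree = %d, BIC = %.1f\n",
    x$G, x$degree, x$bic))
  cat("mixing weights:", sprintf("%.3f", x$pi), "\n")
  invisible(x)
}

#' Select the number of trajectory classes by BIC
#'
#' Fits the mixture for each candidate class count and returns the
#' minimum-BIC model together with the full BIC table.
#'
#' @inheritParams fit_gbtm
#' @param G_range Candidate class counts, a subset of 1..8.
#' @param ... Passed on to [fit_gbtm()].
#' @return The best `gbtm` model, with the BIC table attached as attribute
#'   `bic_table` (data frame with `G`, `bic`, `loglik`, `converged`).
#' @export
select_model <- function(traj, G_range = 1:6, degree = 2, seed = 1, ...) {
  G_range <- sort(unique(as.integer(G_range)))
  if (any(G_range < 1) || any(G_range > 8))
    stop("G_range must lie in [1, 8]")
  fits <- lapply(G_range, function(g)
    fit_gbtm(traj, G = g, degree = degree, seed = seed, ...))
  tab <- data.frame(G = G_range,
                    bic = vapply(fits, function(f) f$bic, 0),
                    loglik = vapply(fits, function(f) f$loglik, 0),
                    converged = vapply(fits, function(f) f$converged, TRUE))
  best <- fits[[which.min(tab$bic)]]
  attr(best, "bic_table") <- tab
  best
}

#' Posterior class membership
#'
#' Bayes posterior probabilities of class membership for each trajectory
#' under a fitted model; rows sum to one and the hard assignment is the
#' row-wise argmax.
#'
#' @param model A fitted `gbtm` model.
#' @param traj Trajectories to score (defaults semantics: same shape used in
#'   fitting).
#' @return Object of class `gbtm_posterior`: list with `posterior` (n x G
#'   matrix) and `assignment` (integer vector).
#' @export
posterior_assign <- function(model, traj) {
  Y <- trajectory_matrix(traj)
  n <- nrow(Y); K <- ncol(Y)
  X <- model$X
  ll_mat <- matrix(0, n, model$G)
  for (g in seq_len(model$G)) {
    resid <- Y - matrix(X %*% model$beta[g, ], n, K, byrow = TRUE)
    ll_mat[, g] <- -K / 2 * log(2 * pi * model$sigma2) -
      rowSums(resid^2) / (2 * model$sigma2)
  }
  lw <- sweep(ll_mat, 2, log(model$pi), `+`)
  mx <- apply(lw, 1, max)
  post <- exp(lw - (mx + log(rowSums(exp(lw - mx)))))
  rownames(post) <- rownames(Y)
  structure(list(posterior = post, assignment = max.col(post,
                                                        ties.method = "first")),
            class = "gbtm_posterior")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed with the standard pair-counting formula.
#'
#' @param a,b Cluster label vectors of equal length (any label type).
#' @return Scalar; 1 for identical partitions (up to label permutation),
#'   about 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must cover the same items")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Agreement between two cluster assignments
#'
#' Adjusted Rand index plus the cross-tabulation of the two assignments,
#' used to quantify how consistently the trajectory-mixture classes
#' reproduce the clustering-based subphenotypes.
#'
#' @param a,b `cluster_assignment` objects (or data frames with
#'   `patient_id` and `cluster`) over the same patient set.
#' @return List with `ari` and `cross_tab`.
#' @export
agreement <- function(a, b) {
  ai <- as.character(a$patient_id); bi <- as.character(b$patient_id)
  if (!setequal(ai, bi) || length(ai) != length(bi))
    stop("assignments must cover the same patient set")
  ord <- match(ai, bi)
  la <- a$cluster
  lb <- b$cluster[ord]
  list(ari = adjusted_rand_index(la, lb), cross_tab = table(a = la, b = lb))
}
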