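# Independent reference implementations used as test oracles. These are
# deliberately naive (enumeration, double loops, hand recursions) and share
# no code with the package internals they check.

# ---- DTW oracles -----------------------------------------------------------

# all monotone warping paths from (1,1) to (n,m); cached per grid size
.path_cache <- new.env(parent = emptyenv())

all_warping_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  rec <- function(i, j) {
    if (i == n && j == m) return(list(matrix(c(i, j), 1, 2)))
    out <- list()
    if (i < n)
      out <- c(out, lapply(rec(i + 1, j), function(p) rbind(c(i, j), p)))
    if (j < m)
      out <- c(out, lapply(rec(i, j + 1), function(p) rbind(c(i, j), p)))
    if (i < n && j < m)
      out <- c(out, lapply(rec(i + 1, j + 1), function(p) rbind(c(i, j), p)))
    out
  }
  paths <- rec(1, 1)
  .path_cache[[key]] <- paths
  paths
}

# exhaustive enumeration oracle (feasible for short sequences)
dtw_enumerate <- function(x, y) {
  paths <- all_warping_paths(length(x), length(y))
  costs <- vapply(paths, function(p) sum((x[p[, 1]] - y[p[, 2]])^2), 0)
  sqrt(min(costs))
}

# independent plain-R top-down recursion with memoisation (for lengths where
# full enumeration is combinatorially infeasible)
dtw_recursive <- function(x, y) {
  n <- length(x); m <- length(y)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    if (i == 0 || j == 0) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- (x[i] - y[j])^2 + min(rec(i - 1, j), rec(i, j - 1),
                               rec(i - 1, j - 1))
    memo[i, j] <<- v
    v
  }
  sqrt(rec(n, m))
}

# ---- naive O(n^3) hierarchical agglomerator --------------------------------

# returns the cophenetic (merge-height) matrix, which determines the
# dendrogram for single/average/complete linkage
naive_hac_cophenetic <- function(d, linkage) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  coph <- matrix(0, n, n)
  cluster_dist <- function(a, b) {
    vals <- d[members[[a]], members[[b]], drop = FALSE]
    switch(linkage, single = min(vals), complete = max(vals),
           average = mean(vals))
  }
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        dd <- cluster_dist(active[ii], active[jj])
        if (dd < best_d - 1e-12) {
          best_d <- dd; best <- c(active[ii], active[jj])
        }
      }
    }
    a <- best[1]; b <- best[2]
    coph[members[[a]], members[[b]]] <- best_d
    coph[members[[b]], members[[a]]] <- best_d
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
  }
  coph
}

# ---- definitional silhouette -----------------------------------------------

silhouette_double_loop <- function(d, cl) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g)
      mean(d[i, cl == g]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# ---- hand product-limit and log-rank ---------------------------------------

km_hand <- function(time, event) {
  ev_times <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (k in seq_along(ev_times)) {
    t0 <- ev_times[k]
    n_risk <- sum(time >= t0)
    d <- sum(time == t0 & event)
    s <- s * (1 - d / n_risk)
    out$surv[k] <- s
  }
  out
}

logrank_hand_2g <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  ts <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (t0 in ts) {
    at <- time >= t0
    n <- sum(at); n1 <- sum(at & group == g1)
    d <- sum(time == t0 & event)
    d1 <- sum(time == t0 & event & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# ---- exhaustive Shapley over all feature orderings -------------------------

shapley_exact <- function(f, x, bg_row) {
  p <- length(x)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(rest) c(v[i], rest)))
    out
  }
  phi <- numeric(p)
  allp <- perms(seq_len(p))
  for (ord in allp) {
    z <- bg_row
    prev <- f(rbind(z))
    for (j in ord) {
      z[j] <- x[j]
      cur <- f(rbind(z))
      phi[j] <- phi[j] + (cur - prev)
      prev <- cur
    }
  }
  phi / length(allp)
}

# ---- shared fixtures -------------------------------------------------------

small_cohort <- function(n = 60, noise_sd = 0.5, seed = 42,
                         missing_rate = 0, full_missing_rate = 0) {
  generate_cohort(cohort_config(
    n_patients = n, archetypes = archetype_specs(noise_sd = noise_sd),
    missing_rate = missing_rate, full_missing_rate = full_missing_rate,
    seed = seed))
}

truth_for <- function(cohort, patient_id) {
  cohort$truth$archetype[match(patient_id, cohort$truth$patient_id)]
}
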