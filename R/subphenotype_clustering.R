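#' Hierarchical agglomerative clustering on a distance matrix
#'
#' Standard bottom-up agglomeration on a precomputed dissimilarity matrix.
#' Average linkage is the default: Ward-type criteria assume Euclidean
#' geometry, which DTW dissimilarities do not satisfy.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal.
#' @param linkage One of `"average"`, `"complete"`, `"single"`.
#' @return An object of class `hclust` (merge records, heights, labels).
#' @export
hac_linkage <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  d <- .validate_distance_matrix(d)
  if (nrow(d) < 2) stop("need at least two observations")
  hclust(as.dist(d), method = linkage)
}

#' Cut a linkage tree into k clusters
#'
#' Removes the k - 1 highest merges; the resulting connected components are
#' the clusters. Cluster ids 1..k are assigned by descending cluster size,
#' ties broken by smallest member index.
#'
#' @param tree An `hclust` tree from [hac_linkage()].
#' @param k Number of clusters, `2 <= k <= n`.
#' @return Object of class `cluster_assignment`: data frame with
#'   `patient_id` and `cluster`, plus attribute `k`.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels %||% integer(0))
  if (n == 0) n <- nrow(tree$merge) + 1
  if (k < 2 || k > n) stop("k must be between 2 and the number of patients")
  raw <- cutree(tree, k = k)
  ids <- tree$labels
  if (is.null(ids)) ids <- as.character(seq_len(n))
  cl <- .relabel_by_size(raw)
  structure(data.frame(patient_id = ids, cluster = cl,
                       stringsAsFactors = FALSE),
            class = c("cluster_assignment", "data.frame"), k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.relabel_by_size <- function(cl) {
  sizes <- table(cl)
  first <- tapply(seq_along(cl), cl, min)
  ord <- order(-as.integer(sizes), as.integer(first))
  map <- integer(length(sizes))
  map[ord] <- seq_along(ord)
  out <- map[match(cl, names(sizes))]
  as.integer(out)
}

#' Internal cluster-validity indices and choice of k
#'
#' Computes, for every candidate number of clusters, the mean silhouette
#' width (on the precomputed distances), the Dunn index (minimum
#' between-cluster distance over maximum cluster diameter) and the C-index
#' (`(S_w - S_min) / (S_max - S_min)` where `S_w` sums within-cluster
#' distances and `S_min`/`S_max` sum the same number of smallest/largest
#' distances overall). Each index votes for its optimal k (silhouette and
#' Dunn maximal, C-index minimal); the chosen k is the majority vote with
#' ties broken by the smallest k.
#'
#' @param d Distance matrix.
#' @param tree An `hclust` tree on `d`.
#' @param k_range Candidate cluster counts, a subset of `2:(n - 1)`.
#' @return Object of class `index_report`: data frame with one row per k
#'   (`silhouette`, `dunn`, `c_index`) plus attributes `chosen_k` and
#'   `votes`.
#' @export
select_k <- function(d, tree, k_range = 2:8) {
  d <- .validate_distance_matrix(d)
  n <- nrow(d)
  if (all(d == 0)) stop("degenerate all-zero distance matrix")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie in [2, n - 1]")
  lower <- d[lower.tri(d)]
  sorted <- sort(lower)
  tab <- data.frame(k = k_range, silhouette = NA_real_, dunn = NA_real_,
                    c_index = NA_real_)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cl <- .relabel_by_size(cutree(tree, k = k))
    sil <- cluster::silhouette(cl, dmatrix = d)
    tab$silhouette[i] <- mean(sil[, "sil_width"])
    tab$dunn[i] <- .dunn_index(d, cl)
    tab$c_index[i] <- .c_index(d, cl, sorted)
  }
  votes <- c(silhouette = tab$k[which.max(tab$silhouette)],
             dunn = tab$k[which.max(tab$dunn)],
             c_index = tab$k[which.min(tab$c_index)])
  vt <- table(votes)
  winners <- as.integer(names(vt)[vt == max(vt)])
  chosen <- min(winners)
  structure(tab, class = c("index_report", "data.frame"),
            chosen_k = chosen, votes = votes)
}

.dunn_index <- function(d, cl) {
  same <- outer(cl, cl, "==")
  lt <- lower.tri(d)
  inter <- d[lt & !same]
  intra <- d[lt & same]
  max_diam <- if (length(intra)) max(intra) else 0
  if (max_diam == 0) return(Inf)
  min(inter) / max_diam
}

.c_index <- function(d, cl, sorted = sort(d[lower.tri(d)])) {
  lt <- lower.tri(d)
  same <- outer(cl, cl, "==")
  within <- d[lt & same]
  nw <- length(within)
  if (nw == 0) return(NA_real_)
  sw <- sum(within)
  smin <- sum(sorted[seq_len(nw)])
  smax <- sum(sorted[seq(length(sorted) - nw + 1, length(sorted))])
  if (smax == smin) return(0)
  (sw - smin) / (smax - smin)
}

#' Label four clusters with trajectory archetypes
#'
#' Computes each cluster's mean SOFA curve and classifies its shape from the
#' early change (window 8 minus window 1, i.e. the first 48 h) and late
#' change (window 12 minus window 8, the last 24 h), with a tolerance `eps`
#' below which a change counts as flat: rising/still-rising is Rapidly
#' Worsening (RW), falling/still-falling Rapidly Improving (RI),
#' falling-then-rising Delayed Worsening (DW) and rising-then-falling
#' Delayed Improving (DI). If two clusters receive the same label, the one
#' with the larger absolute net change keeps the Rapid form and the other
#' becomes the corresponding Delayed form. Labeling is defined only for
#' k = 4; other k keep numeric cluster ids.
#'
#' @param assign A `cluster_assignment` from [cut_tree()].
#' @param traj A `sofa_trajectories` object or trajectory matrix with rows
#'   matching `assign$patient_id`.
#' @param eps Flatness tolerance in SOFA points (default 0.1).
#' @return Object of class `archetype_labeling`: list with `labels` (cluster
#'   id -> archetype), `mean_curves` (k x 12), `deltas` and `status`
#'   (`"ok"` or `"skipped"`). When labeling is skipped a warning is issued.
#' @export
label_archetypes <- function(assign, traj, eps = 0.1) {
  m <- trajectory_matrix(traj)
  m <- m[match(assign$patient_id, rownames(m) %||%
                 as.character(seq_len(nrow(m)))), , drop = FALSE]
  k <- attr(assign, "k") %||% length(unique(assign$cluster))
  curves <- do.call(rbind, lapply(sort(unique(assign$cluster)), function(g) {
    colMeans(m[assign$cluster == g, , drop = FALSE])
  }))
  rownames(curves) <- sort(unique(assign$cluster))
  d_early <- curves[, 8] - curves[, 1]
  d_late <- curves[, 12] - curves[, 8]
  net <- curves[, 12] - curves[, 1]
  if (k != 4) {
    warning("archetype labeling is defined only for k = 4; skipped")
    return(structure(list(labels = NULL, mean_curves = curves,
                          deltas = cbind(early = d_early, late = d_late),
                          status = "skipped"),
                     class = "archetype_labeling"))
  }
  sgn <- function(x) ifelse(x > eps, 1L, ifelse(x < -eps, -1L, 0L))
  se <- sgn(d_early); sl <- sgn(d_late); sn <- sgn(net)
  lab <- character(4)
  for (i in 1:4) {
    lab[i] <- if (se[i] > 0 && sl[i] >= 0) "RW"
      else if (se[i] < 0 && sl[i] <= 0) "RI"
      else if (se[i] < 0 && sl[i] > 0) "DW"
      else if (se[i] > 0 && sl[i] < 0) "DI"
      else if (se[i] == 0 && sl[i] > 0) { if (sn[i] > 0) "RW" else "DW" }
      else if (se[i] == 0 && sl[i] < 0) { if (sn[i] < 0) "RI" else "DI" }
      else if (sn[i] > 0) "RW" else "RI" # fully flat: net sign decides
  }
  # disambiguate duplicated labels by magnitude of net change
  rapid_of <- c(DW = "RW", DI = "RI", RW = "RW", RI = "RI")
  delayed_of <- c(RW = "DW", RI = "DI", DW = "DW", DI = "DI")
  for (l in unique(lab[duplicated(lab)])) {
    idx <- which(lab == l)
    idx <- idx[order(-abs(net[idx]))]
    lab[idx[1]] <- rapid_of[[l]]
    for (j in idx[-1]) lab[j] <- delayed_of[[l]]
  }
  names(lab) <- rownames(curves)
  structure(list(labels = lab, mean_curves = curves,
                 deltas = cbind(early = d_early, late = d_late),
                 status = if (anyDuplicated(lab)) "ambiguous" else "ok"),
            class = "archetype_labeling")
}

#' @export
print.archetype_labeling <- function(x, ...) {
  cat("Archetype labeling (status:", x$status, ")\n")
  if (!is.null(x$labels)) {
    for (i in seq_along(x$labels))
      cat(sprintf("  cluster %s -> %s  (early %+0.2f, late %+0.2f)\n",
                  names(x$labels)[i], x$labels[i],
                  x$deltas[i, "early"], x$deltas[i, "late"]))
  }
  invisible(x)
}

#' Archetype label per patient
#'
#' Convenience accessor joining a cluster assignment with its archetype
#' labeling.
#'
#' @param assign A `cluster_assignment`.
#' @param labeling An `archetype_labeling` with status `"ok"`.
#' @return Character vector of archetype labels aligned with
#'   `assign$patient_id`.
#' @export
patient_archetypes <- function(assign, labeling) {
  if (is.null(labeling$labels)) stop("labeling was skipped")
  unname(labeling$labels[as.character(assign$cluster)])
}
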