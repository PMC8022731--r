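# k-medoids clustering (PAM BUILD+SWAP and the CLARA subsampling variant)
# over a precomputed distance matrix, with silhouette-based model selection.
# Authored in-package because the pipeline requires deterministic lowest-
# index tie-breaking, full-data CLARA cost evaluation on an arbitrary
# precomputed dissimilarity, and NA silhouette at k = 1.

.as_dist_matrix <- function(d) {
  if (inherits(d, "nigon_dice")) d <- d$distance
  if (inherits(d, "dist")) d <- as.matrix(d)
  .assert(is.matrix(d) && nrow(d) == ncol(d), "`d` must be a square matrix")
  .assert(all(abs(diag(d)) < 1e-12), "`d` must have a zero diagonal")
  .assert(all(d >= -1e-12), "`d` must be non-negative")
  .assert(max(abs(d - t(d))) < 1e-8, "`d` must be symmetric")
  d
}

# Total cost of a medoid set: sum over points of distance to nearest medoid.
.pam_cost <- function(d, medoids) {
  if (length(medoids) == 1L) return(sum(d[, medoids]))
  sum(do.call(pmin, lapply(medoids, function(m) d[, m])))
}

# Nearest and second-nearest medoid distances (+ nearest index) per point.
.pam_nearest <- function(d, medoids) {
  dm <- d[, medoids, drop = FALSE]
  k <- length(medoids)
  if (k == 1L) {
    return(list(near = dm[, 1], second = rep(Inf, nrow(d)),
                which = rep(1L, nrow(d))))
  }
  wh <- apply(dm, 1L, which.min)
  near <- dm[cbind(seq_len(nrow(d)), wh)]
  dm2 <- dm
  dm2[cbind(seq_len(nrow(d)), wh)] <- Inf
  second <- do.call(pmin, lapply(seq_len(k), function(j) dm2[, j]))
  list(near = near, second = second, which = wh)
}

#' Partitioning around medoids (PAM) on a distance matrix
#'
#' Classic deterministic PAM: a greedy cost-minimising BUILD phase followed
#' by best-improvement SWAP until no swap lowers the total cost. All ties
#' (initial medoid, BUILD candidates, SWAP candidates, point assignment)
#' break to the lowest index, so results are fully deterministic.
#'
#' @param d Distance matrix (square, symmetric, zero diagonal, with
#'   dimnames), a `dist`, or a [dice_similarity()] result.
#' @param k Number of medoids, `1 <= k <= n`.
#' @return Object of class `nigon_pam`: list with `k`, `medoids` (names),
#'   `medoid_index`, `clustering` (named integer vector; cluster c is the
#'   set of points nearest medoid c), `cost`, `silhouette` (per-point
#'   widths; `NA` at k = 1), `avg_silhouette`.
#' @examples
#' d <- as.matrix(dist(c(0, 0.1, 5, 5.1)))
#' nigon_pam(d, 2)$medoids
#' @export
nigon_pam <- function(d, k) {
  d <- .as_dist_matrix(d)
  n <- nrow(d)
  .assert(is.numeric(k) && length(k) == 1 && k >= 1, "`k` must be a positive integer")
  .assert(k <= n, "k = %d exceeds number of points (%d)", k, n)
  k <- as.integer(k)

  # BUILD: first medoid minimises total distance; then greedily add the
  # candidate with maximal cost reduction.
  medoids <- which.min(colSums(d))
  near <- d[, medoids]
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    gain <- vapply(cand, function(j) sum(pmax(near - d[, j], 0)), numeric(1))
    best <- cand[which.max(gain)]
    medoids <- c(medoids, best)
    near <- pmin(near, d[, best])
  }
  medoids <- sort(medoids)

  # SWAP: best-improvement; ties to the lowest (medoid, candidate) index.
  repeat {
    st <- .pam_nearest(d, medoids)
    best_delta <- -1e-12
    best_swap <- NULL
    others <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      m <- medoids[mi]
      attached <- st$which == mi
      for (h in others) {
        dh <- d[, h]
        delta <- sum(pmin(dh[attached], st$second[attached])) -
          sum(st$near[attached]) +
          sum(pmin(dh[!attached] - st$near[!attached], 0))
        if (delta < best_delta) {
          best_delta <- delta
          best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    medoids <- sort(medoids)
  }

  .pam_result(d, medoids, k)
}

# Assemble a clustering result (assignment, cost, silhouettes) for a medoid set.
.pam_result <- function(d, medoids, k) {
  medoids <- sort(medoids)
  dm <- d[, medoids, drop = FALSE]
  clustering <- if (k == 1L) rep(1L, nrow(d)) else apply(dm, 1L, which.min)
  names(clustering) <- rownames(d)
  cost <- sum(dm[cbind(seq_len(nrow(d)), clustering)])
  sil <- if (k == 1L) rep(NA_real_, nrow(d)) else silhouette_widths(d, clustering)
  structure(list(k = k,
                 medoids = rownames(d)[medoids] %||% medoids,
                 medoid_index = medoids,
                 clustering = clustering,
                 cost = cost,
                 silhouette = sil,
                 avg_silhouette = if (k == 1L) NA_real_ else mean(sil)),
            class = "nigon_pam")
}

#' @export
print.nigon_pam <- function(x, ...) {
  cat(sprintf("k-medoids clustering: k = %d, cost = %.4f, avg silhouette = %s\n",
              x$k, x$cost,
              ifelse(is.na(x$avg_silhouette), "NA",
                     sprintf("%.3f", x$avg_silhouette))))
  invisible(x)
}

#' CLARA: PAM over independent subsamples, scored on the full data
#'
#' Draws `n_subsamples` independent subsamples of `ceiling(fraction * n)`
#' points, runs [nigon_pam()] on each, evaluates every resulting medoid set
#' by its total cost over \emph{all} points, and returns the lowest-cost set
#' with full-data assignments and silhouettes. With `fraction = 1` and one
#' subsample this reduces exactly to PAM.
#'
#' @inheritParams nigon_pam
#' @param n_subsamples Number of independent subsamples (default 5).
#' @param fraction Fraction of points per subsample (default 0.10).
#' @param seed Optional integer seed; fixed seed gives identical medoids.
#' @return A `nigon_pam` object (clustering over all points).
#' @export
nigon_clara <- function(d, k, n_subsamples = 5, fraction = 0.10, seed = NULL) {
  d <- .as_dist_matrix(d)
  n <- nrow(d)
  .assert(fraction > 0 && fraction <= 1, "`fraction` must be in (0, 1]")
  size <- ceiling(fraction * n)
  .assert(size >= k,
          "subsample size %d < k = %d; increase `fraction`", size, k)
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  best_cost <- Inf
  for (r in seq_len(n_subsamples)) {
    idx <- sort(sample.int(n, size))
    fit <- nigon_pam(d[idx, idx, drop = FALSE], k)
    med_global <- idx[fit$medoid_index]
    cost <- .pam_cost(d, med_global)
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- med_global
    }
  }
  .pam_result(d, best, as.integer(k))
}

#' Per-point silhouette widths
#'
#' `s(i) = (b - a) / max(a, b)` with `a` the mean distance of i to the other
#' members of its cluster and `b` the minimum over other clusters of the
#' mean distance to that cluster's members. Points in singleton clusters
#' get width 0.
#'
#' @param d Distance matrix.
#' @param clustering Integer cluster labels (length `nrow(d)`).
#' @return Numeric vector of silhouette widths.
#' @export
silhouette_widths <- function(d, clustering) {
  d <- .as_dist_matrix(d)
  n <- nrow(d)
  .assert(length(clustering) == n, "clustering length must match d")
  labs <- as.integer(factor(clustering))
  sizes <- tabulate(labs)
  # sums of distances from each point to every cluster: n x k
  agg <- t(rowsum(d, group = labs))
  own <- labs
  a <- ifelse(sizes[own] > 1,
              agg[cbind(seq_len(n), own)] / (sizes[own] - 1), NA_real_)
  mean_to <- sweep(agg, 2, sizes, "/")
  mean_to[cbind(seq_len(n), own)] <- Inf
  b <- do.call(pmin, lapply(seq_len(ncol(mean_to)), function(j) mean_to[, j]))
  s <- (b - a) / pmax(a, b)
  s[sizes[own] == 1] <- 0
  unname(s)
}

#' Silhouette scan over a range of cluster numbers
#'
#' Clusters the distance matrix for each `k` in `k_range` (CLARA by default)
#' and reports the average silhouette width. `k = 1` has no defined
#' silhouette and is reported as `NA`, excluded from the argmax; ties break
#' to the smaller k.
#'
#' @inheritParams nigon_clara
#' @param k_range Candidate cluster numbers (default `1:10`).
#' @param method `"clara"` (default) or `"pam"` (full-data PAM per k).
#' @return Object of class `nigon_silscan`: list with `table` (data.frame
#'   `k`, `avg_silhouette`), `best_k`, and `best_fit` (the `nigon_pam` at
#'   `best_k`).
#' @examples
#' d <- as.matrix(dist(c(0, 0.1, 0.2, 5, 5.1, 5.2)))
#' silhouette_scan(d, k_range = 1:4, method = "pam")$best_k  # 2
#' @export
silhouette_scan <- function(d, k_range = 1:10, method = c("clara", "pam"),
                            n_subsamples = 5, fraction = 0.10, seed = NULL) {
  method <- match.arg(method)
  d <- .as_dist_matrix(d)
  n <- nrow(d)
  .assert(n >= 3, "need at least 3 points")
  .assert(all(k_range >= 1 & k_range <= n), "k_range must lie in [1, n]")
  k_range <- sort(unique(as.integer(k_range)))

  fits <- vector("list", length(k_range))
  avg <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k == 1L) next
    fits[[i]] <- if (method == "clara") {
      nigon_clara(d, k, n_subsamples = n_subsamples, fraction = fraction,
                  seed = seed)
    } else {
      nigon_pam(d, k)
    }
    avg[i] <- fits[[i]]$avg_silhouette
  }
  .assert(any(!is.na(avg)), "k_range contains no k > 1")
  best_i <- which.max(avg)  # first maximum -> smallest k on ties
  structure(list(table = data.frame(k = k_range, avg_silhouette = avg),
                 best_k = k_range[best_i],
                 best_fit = fits[[best_i]],
                 method = method),
            class = "nigon_silscan")
}

#' @export
print.nigon_silscan <- function(x, ...) {
  cat("Silhouette scan (", x$method, "):\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("best k =", x$best_k, "\n")
  invisible(x)
}
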