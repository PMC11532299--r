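# K-means clustering of daily activity profiles with silhouette-based
# selection of k.
#
# Profiles are clustered as raw firing-count vectors: per-participant
# normalization would erase overall activity-volume differences, which are
# part of what distinguishes behavioral groups. A `normalize` flag offers
# per-profile mean-division for sensitivity analysis.

#' Mean silhouette score of a clustering
#'
#' Per point `i`: `a` = mean Euclidean distance to the other members of its
#' cluster, `b` = smallest mean distance to the members of another cluster,
#' `s_i = (b - a) / max(a, b)`. Points in singleton clusters score 0. The
#' returned score is the mean of `s_i` over all points.
#'
#' @param x numeric matrix (points in rows) or list of equal-length vectors.
#' @param labels cluster assignment, one label per point; >= 2 distinct
#'   labels, each non-empty.
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(x, labels) {
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- as.matrix(x)
  labels <- as.vector(labels)
  stopifnot(nrow(x) == length(labels))
  ulab <- unique(labels)
  if (length(ulab) < 2L)
    stop("silhouette_score: need at least 2 clusters")
  d <- as.matrix(stats::dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    n_own <- sum(own)
    if (n_own == 1L) return(0)
    a <- sum(d[i, own]) / (n_own - 1L)
    b <- min(vapply(ulab[ulab != labels[i]], function(l)
      mean(d[i, labels == l]), numeric(1)))
    if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center. Centers are chosen from distinct
# point indices; coincident points get weight 0 while any spread remains,
# so stats::kmeans never sees duplicated initial centers unless the data
# have fewer distinct points than k.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    free <- setdiff(seq_len(n), centers[seq_len(j)])
    w <- d2[free]
    pick <- if (sum(w) > 0) free[sample.int(length(free), 1L, prob = w)]
            else free[sample.int(length(free), 1L)]
    centers[j + 1L] <- pick
    nd <- rowSums((x - matrix(x[pick, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Cluster activity profiles with K-means
#'
#' Standard Euclidean K-means (Lloyd mean-update iterations via
#' [stats::kmeans()]) seeded k-means++-style, run `n_restarts` times with
#' sub-seeds derived from `seed`; the restart with the lowest within-cluster
#' sum of squares is kept. Deterministic given `(seed, n_restarts)`.
#'
#' @param profiles list of profiles or a [profile_matrix()].
#' @param k number of clusters, `2 <= k <=` number of profiles (k = n is
#'   allowed and gives zero within-cluster sum of squares).
#' @param seed integer master seed.
#' @param n_restarts independent restarts (default 50).
#' @param normalize divide each profile by its mean before clustering
#'   (default `FALSE`).
#' @param max_iter Lloyd iteration cap per restart.
#' @return an `activity_kmeans` object: list with `k`, `assignments` (named
#'   integer vector, home_id -> cluster), `centroids` (k x 24, on the
#'   original scale when `normalize = FALSE`), `tot_withinss`, `silhouette`,
#'   `seed`, `n_restarts`, `normalize`.
#' @export
cluster_profiles <- function(profiles, k, seed = 1L, n_restarts = 50L,
                             normalize = FALSE, max_iter = 100L) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  n <- nrow(m)
  if (k > n) stop("cluster_profiles: k exceeds number of profiles")
  stopifnot(k >= 1L)
  xm <- if (normalize) m / pmax(rowMeans(m), .Machine$double.eps) else m
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(derive_seed(seed, k, r), {
      ctr <- kmeanspp_centers(xm, k)
      suppressWarnings(
        stats::kmeans(xm, centers = ctr, iter.max = max_iter,
                      algorithm = "Lloyd"))
    })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12)
      best <- fit
  }
  sil <- if (k >= 2L && length(unique(best$cluster)) >= 2L)
    silhouette_score(xm, best$cluster) else NA_real_
  structure(list(
    k = k,
    assignments = stats::setNames(as.integer(best$cluster), rownames(m)),
    centroids = best$centers,
    tot_withinss = best$tot.withinss,
    silhouette = sil,
    seed = as.integer(seed), n_restarts = as.integer(n_restarts),
    normalize = normalize
  ), class = "activity_kmeans")
}

#' @export
print.activity_kmeans <- function(x, ...) {
  sizes <- table(x$assignments)
  cat(sprintf("K-means activity clustering: k = %d, sizes {%s}, WCSS %.3f",
              x$k, paste(sizes, collapse = ", "), x$tot_withinss))
  if (!is.na(x$silhouette))
    cat(sprintf(", mean silhouette %.3f", x$silhouette))
  cat("\n")
  invisible(x)
}

#' @export
summary.activity_kmeans <- function(object, ...) {
  cat(sprintf("K-means over %d profiles (seed %d, %d restarts%s)\n",
              length(object$assignments), object$seed, object$n_restarts,
              if (object$normalize) ", normalized" else ""))
  print(object)
  for (j in seq_len(object$k)) {
    members <- names(object$assignments)[object$assignments == j]
    cat(sprintf("  cluster %d (peak hour %d): %s\n", j,
                which.max(object$centroids[j, ]) - 1L,
                paste(members, collapse = ", ")))
  }
  invisible(object)
}

#' @export
predict.activity_kmeans <- function(object, newdata, ...) {
  m <- if (is.matrix(newdata)) newdata else profile_matrix(newdata)
  if (object$normalize) m <- m / pmax(rowMeans(m), .Machine$double.eps)
  d <- vapply(seq_len(object$k), function(j)
    rowSums((m - matrix(object$centroids[j, ], nrow(m), ncol(m),
                        byrow = TRUE))^2), numeric(nrow(m)))
  stats::setNames(max.col(-matrix(d, nrow = nrow(m))), rownames(m))
}

#' @export
plot.activity_kmeans <- function(x, ...) {
  graphics::matplot(0:23, t(x$centroids), type = "l", lty = 1,
                    col = seq_len(x$k) + 1L, lwd = 2,
                    xlab = "hour of day", ylab = "activity (firings/h)", ...)
  graphics::legend("topleft", legend = paste("cluster", seq_len(x$k)),
                   col = seq_len(x$k) + 1L, lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Select the number of clusters by the silhouette method
#'
#' Fits K-means for each candidate `k` and keeps the `k` maximizing the mean
#' silhouette score; ties break toward smaller `k` (parsimony).
#'
#' @inheritParams cluster_profiles
#' @param k_range candidate cluster counts (default `2:6`); must stay below
#'   the number of profiles.
#' @return list with `k` (the selected count), `silhouette_by_k` (named
#'   numeric), and `model` (the fitted [cluster_profiles()] object at the
#'   selected `k`).
#' @export
select_k_by_silhouette <- function(profiles, k_range = 2:6, seed = 1L,
                                   n_restarts = 50L, normalize = FALSE) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  if (max(k_range) >= nrow(m))
    stop("select_k_by_silhouette: k_range must stay below the number of profiles")
  stopifnot(all(k_range >= 2L))
  fits <- lapply(k_range, function(k)
    cluster_profiles(m, k, seed = seed, n_restarts = n_restarts,
                     normalize = normalize))
  sil <- stats::setNames(vapply(fits, `[[`, numeric(1), "silhouette"),
                         as.character(k_range))
  best <- which(sil >= max(sil) - 1e-12)[1L]  # ties -> smaller k
  list(k = k_range[best], silhouette_by_k = sil, model = fits[[best]])
}

#' Per-cluster activity curves and room occupancy
#'
#' @param model an [cluster_profiles()] fit.
#' @param profiles the clustered profiles (list or matrix; row/name order
#'   must match the model's assignment names).
#' @param timelines optional named list of [occupancy_timeline()] objects
#'   keyed by home_id; when given, per-cluster mean room-occupancy fractions
#'   are included.
#' @return list, one element per cluster, each holding `n`, `curve`
#'   (a [population_curve()]) and optionally `occupancy` (mean fractions).
#' @export
cluster_summary <- function(model, profiles, timelines = NULL) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  ids <- names(model$assignments)
  if (!setequal(rownames(m), ids))
    stop("cluster_summary: profiles do not match model assignments")
  m <- m[ids, , drop = FALSE]
  lapply(seq_len(model$k), function(j) {
    members <- ids[model$assignments == j]
    if (length(members) == 0L)
      stop("cluster_summary: cluster ", j, " is empty")
    out <- list(n = length(members),
                members = members,
                curve = population_curve(m[members, , drop = FALSE]))
    if (!is.null(timelines)) {
      fr <- do.call(rbind, lapply(members, function(id) {
        if (is.null(timelines[[id]]))
          stop("cluster_summary: no timeline for ", id)
        room_occupancy_fractions(timelines[[id]])
      }))
      out$occupancy <- colMeans(fr)
    }
    out
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical up to relabeling, 0 is the expectation under random
#' agreement.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical
  (sum_ij - expected) / denom
}
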