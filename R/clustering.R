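#' Ward agglomeration of the feature matrix
#'
#' Classical Ward clustering on squared Euclidean distances: at each step
#' the pair of clusters whose merger minimally increases the total
#' within-cluster sum of squares is joined. Heights are reported as the
#' merge-cost increments (the increase in within-cluster SS at each step),
#' so they telescope to the total sum of squares of the data.
#'
#' @param x Numeric matrix (n rows, features in columns) or a feature tibble
#'   with a `participant_id` column.
#' @return A `sed_ward_tree`: `merge` (hclust-style merge matrix), `height`
#'   (merge-cost increments, non-decreasing), `order`, `labels`,
#'   `n_leaves`.
#' @examples
#' tr <- ward_linkage(cbind(c(0, 1, 10, 11)))
#' tr$height
#' @export
ward_linkage <- function(x) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort("need at least two rows to cluster")
  if (anyNA(x)) abort("feature matrix contains missing values")
  hc <- hclust(dist(x), method = "ward.D2")
  structure(
    list(
      merge = hc$merge,
      height = hc$height^2 / 2, # ward.D2 height h satisfies h^2/2 = delta SS
      order = hc$order,
      labels = rownames(x),
      n_leaves = nrow(x)
    ),
    class = "sed_ward_tree"
  )
}

as_hclust <- function(tree) {
  structure(
    list(
      merge = tree$merge, height = sqrt(2 * tree$height),
      order = tree$order, labels = tree$labels,
      method = "ward.D2", call = match.call(), dist.method = "euclidean"
    ),
    class = "hclust"
  )
}

#' @export
print.sed_ward_tree <- function(x, ...) {
  cat("<sed_ward_tree> ", x$n_leaves, " leaves; total merge cost ",
    format(sum(x$height)), "\n", sep = "")
  invisible(x)
}

#' Cut a Ward tree into k clusters
#'
#' @param tree A [ward_linkage()] tree.
#' @param k Number of clusters.
#' @return Integer cluster assignments (1..k), named by leaf label.
#' @export
cut_ward <- function(tree, k) {
  cutree(as_hclust(tree), k = k)
}

#' Choose the number of clusters from merge costs
#'
#' Operationalizes choosing k from a dendrogram: for each candidate k, the
#' relative jump in merge cost when collapsing from k to k - 1 clusters is
#' compared with the preceding merge, and the k with the largest relative
#' jump is returned (ties favor the smaller k).
#'
#' @param tree A [ward_linkage()] tree.
#' @param k_min,k_max Candidate range (inclusive).
#' @return Integer k.
#' @export
select_k <- function(tree, k_min = 2L, k_max = 8L) {
  n <- tree$n_leaves
  if (!(2L <= k_min && k_min <= k_max && k_max <= n)) {
    abort("need 2 <= k_min <= k_max <= n_leaves")
  }
  h <- tree$height
  if (all(h <= .Machine$double.eps)) {
    warn("degenerate tree (all merge costs zero); returning k_min")
    return(as.integer(k_min))
  }
  ks <- seq.int(k_min, k_max)
  # cost of the merge collapsing j+1 -> j clusters is h[n - j]
  ratio <- vapply(ks, function(k) {
    if (k == n) return(0) # no preceding merge to compare against
    num <- h[n - k + 1L] # collapsing k -> k-1
    den <- h[n - k] # collapsing k+1 -> k
    if (den <= .Machine$double.eps) {
      if (num <= .Machine$double.eps) 1 else Inf
    } else {
      num / den
    }
  }, numeric(1))
  as.integer(ks[which.max(ratio)]) # which.max takes the first (smallest k)
}

#' Refine a Ward partition by deterministic k-means
#'
#' Lloyd iterations initialized from the centroids of the k Ward clusters:
#' assign each point to the nearest centroid (Euclidean; ties to the lowest
#' cluster index), recompute centroids as assigned means, and repeat until
#' assignments are unchanged or 100 iterations. There is no random
#' initialization, so the result is deterministic. If a cluster empties
#' during iteration, it is re-seeded with the point currently farthest from
#' its assigned centroid (logged via a message).
#'
#' @param x Feature matrix or feature tibble.
#' @param tree A [ward_linkage()] tree of the same rows.
#' @param k Number of clusters.
#' @return A `sed_cluster_model`: `k`, `centroids` (k x p), `assignments`
#'   (named integer vector), `within_ss`, `iterations`, `sizes`.
#' @examples
#' x <- cbind(c(0, 1, 10, 11))
#' m <- kmeans_refine(x, ward_linkage(x), k = 2)
#' m$within_ss # 1.0
#' @export
kmeans_refine <- function(x, tree, k) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1L || n < k) abort("need 1 <= k <= n")
  init <- if (k == 1L) rep(1L, n) else cut_ward(tree, k)
  centroids <- centroid_means(x, init, k)
  assign_old <- rep(0L, n)
  assign_new <- init
  iter <- 0L
  while (!identical(assign_new, assign_old) && iter < 100L) {
    assign_old <- assign_new
    d2 <- dist2_to_centroids(x, centroids)
    assign_new <- apply(d2, 1L, which.min) # first minimum = lowest index
    for (g in seq_len(k)) {
      if (!any(assign_new == g)) {
        far <- which.max(d2[cbind(seq_len(n), assign_new)])
        assign_new[far] <- g
        inform(paste0(
          "cluster ", g, " emptied; re-seeded with farthest point"
        ))
      }
    }
    centroids <- centroid_means(x, assign_new, k)
    iter <- iter + 1L
  }
  names(assign_new) <- rownames(x)
  d2 <- dist2_to_centroids(x, centroids)
  wss <- sum(d2[cbind(seq_len(n), assign_new)])
  structure(
    list(
      k = as.integer(k), centroids = centroids,
      assignments = assign_new, within_ss = wss,
      iterations = iter, sizes = tabulate(assign_new, k)
    ),
    class = "sed_cluster_model"
  )
}

centroid_means <- function(x, assign, k) {
  out <- matrix(NA_real_, k, ncol(x), dimnames = list(NULL, colnames(x)))
  for (g in seq_len(k)) {
    rows <- x[assign == g, , drop = FALSE]
    if (nrow(rows) > 0) out[g, ] <- colMeans(rows)
  }
  out
}

dist2_to_centroids <- function(x, centroids) {
  cross <- x %*% t(centroids)
  xs <- rowSums(x^2)
  cs <- rowSums(centroids^2)
  pmax(outer(xs, cs, "+") - 2 * cross, 0)
}

#' @export
print.sed_cluster_model <- function(x, ...) {
  cat("<sed_cluster_model> k = ", x$k,
    "; sizes: ", paste(x$sizes, collapse = ", "),
    "; within-SS = ", format(x$within_ss),
    " (", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Two-step clustering: Ward then k-means
#'
#' Convenience wrapper running [ward_linkage()], choosing k with
#' [select_k()] unless given, and refining with [kmeans_refine()].
#'
#' @param features Feature tibble or matrix.
#' @param k Fixed number of clusters, or `NULL` to select from the tree.
#' @param k_range Candidate range when selecting k.
#' @return List with `tree` and `model`.
#' @export
two_step_cluster <- function(features, k = NULL, k_range = c(2L, 8L)) {
  tree <- ward_linkage(features)
  if (is.null(k)) k <- select_k(tree, k_range[1], k_range[2])
  list(tree = tree, model = kmeans_refine(features, tree, k))
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

#' Match fitted centroids to archetype mean vectors
#'
#' Exhaustively finds the one-to-one assignment of clusters to archetypes
#' minimizing the summed Euclidean centroid-archetype distance.
#'
#' @param centroids k x p matrix of fitted centroids.
#' @param archetype_means k x p matrix of archetype mean vectors (or a list
#'   of [archetype_profile()] objects, whose `vl_mean`s are used).
#' @return Integer vector `perm` with `perm[j]` = index of the archetype
#'   matched to cluster j; the minimized cost is attached as attribute
#'   `"cost"`.
#' @export
match_clusters <- function(centroids, archetype_means) {
  if (is.list(archetype_means) && !is.matrix(archetype_means) &&
      !is.data.frame(archetype_means)) {
    archetype_means <- do.call(
      rbind, lapply(archetype_means, `[[`, "vl_mean")
    )
  }
  archetype_means <- as.matrix(archetype_means)
  k <- nrow(centroids)
  if (k != nrow(archetype_means)) {
    abort("centroid and archetype counts must match")
  }
  if (k > 8L) {
    abort("exhaustive matching supports k <= 8; use approximate matching")
  }
  best <- NULL
  best_cost <- Inf
  for (p in all_permutations(seq_len(k))) {
    cost <- sum(sqrt(rowSums((centroids - archetype_means[p, , drop = FALSE])^2)))
    if (cost < best_cost) {
      best_cost <- cost
      best <- p
    }
  }
  structure(as.integer(best), cost = best_cost)
}
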