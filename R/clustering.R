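#' Feature matrix for clustering
#'
#' Assembles the nine stratified network features (four partner-count
#' strata, four contact-frequency strata and the solitude frequency) into
#' the matrix clustered by the typology. Residents with no events get
#' all-zero rows (imputation by zero, not missingness). Features are
#' z-scored by default so no single scale dominates the Euclidean
#' distances; zero-variance columns are left centred at 0.
#'
#' @param features feature data.frame ([compute_features()]).
#' @param standardize z-score columns (default TRUE).
#' @return numeric matrix (residents x 9), rownames = resident ids, with
#'   attributes `center`/`scale` when standardized.
#' @export
feature_matrix <- function(features, standardize = TRUE) {
  m <- as.matrix(features[, FEATURE_COLS])
  rownames(m) <- features$resident_id
  m[is.na(m)] <- 0
  if (standardize) {
    ctr <- colMeans(m)
    scl <- apply(m, 2, stats::sd)
    scl[scl == 0] <- 1
    m <- scale(m, center = ctr, scale = scl)
    attr(m, "center") <- ctr
    attr(m, "scale") <- scl
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  m
}

#' k-means sweep over a range of k
#'
#' Fits k-means (Euclidean, best of `n_restarts` random starts) for each k
#' in `k_range`, recording the within-cluster sum of squares for elbow
#' inspection. Deterministic under a fixed seed.
#'
#' @param x numeric feature matrix ([feature_matrix()]).
#' @param k_range integer vector of cluster counts (default 1:10).
#' @param n_restarts random restarts per k (default 50).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return object of class `kmeans_sweep`: list with `fits` (one
#'   [stats::kmeans()] object per k), `k_range`, `wcss`, `seed`.
#' @export
kmeans_sweep <- function(x, k_range = 1:10, n_restarts = 50, seed) {
  if (missing(seed)) stop_config("seed is required")
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(x)) {
    stop_invalid("k = %d exceeds the number of rows (%d)", max(k_range), nrow(x))
  }
  set.seed(assert_count(seed, "seed", min = 0L))
  fits <- lapply(k_range, function(k) {
    if (k == nrow(x)) {
      # degenerate solution: every row its own cluster, WCSS exactly 0
      totss <- sum(scale(x, scale = FALSE)^2)
      structure(list(cluster = stats::setNames(seq_len(nrow(x)), rownames(x)),
                     centers = x, totss = totss,
                     withinss = rep(0, nrow(x)), tot.withinss = 0,
                     betweenss = totss, size = rep(1L, nrow(x)),
                     iter = 0L, ifault = 0L),
                class = "kmeans")
    } else {
      stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
    }
  })
  wcss <- vapply(fits, function(f) f$tot.withinss, 0)
  structure(list(fits = stats::setNames(fits, paste0("k", k_range)),
                 k_range = k_range, wcss = wcss, seed = seed),
            class = "kmeans_sweep")
}

#' @export
print.kmeans_sweep <- function(x, ...) {
  cat("<kmeans_sweep> k =", paste(range(x$k_range), collapse = ".."), "\n")
  print(data.frame(k = x$k_range, wcss = round(x$wcss, 2)), row.names = FALSE)
  invisible(x)
}

#' Elbow selection of k
#'
#' Picks the k at the bend of the within-cluster sum-of-squares curve: the
#' interior k maximising the (central) second difference
#' `wcss[k-1] - 2 wcss[k] + wcss[k+1]`. Ties break to the smallest k. A
#' manual override is supported, since cluster solutions must also be
#' interpretable conceptually.
#'
#' @param wcss numeric vector of within-cluster sums of squares.
#' @param k_range the k each entry corresponds to (default `seq_along`).
#' @param override if non-NULL, returned as-is.
#' @return selected k (integer).
#' @export
#' @examples
#' elbow_select(c(100, 40, 35, 33)) # 2
elbow_select <- function(wcss, k_range = seq_along(wcss), override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  if (length(wcss) < 3L) stop_invalid("need WCSS for at least 3 consecutive k")
  if (any(diff(wcss) > 0)) {
    warning("WCSS increases with k somewhere; elbow may be unreliable")
  }
  d2 <- wcss[-c(length(wcss) - 1L, length(wcss))] - 2 * wcss[-c(1L, length(wcss))] +
    wcss[-c(1L, 2L)]
  as.integer(k_range[which.max(d2) + 1L])
}

TYPOLOGY_LABELS <- c("Diverse (common area)", "Diverse (bedroom)",
                     "Non-roommate-focused", "Roommate-focused", "Restricted")

#' Rule-based typology labels for clusters
#'
#' Names k-means clusters after the social typology by comparing raw-scale
#' centroids, applying the characterisations in priority order over the
#' still-unlabelled clusters:
#' \enumerate{
#'   \item Restricted: smallest total of all nine features (least partners,
#'     least interaction).
#'   \item Diverse (common area): highest frequency of interacting with
#'     roommates in common areas (the cluster socialising with everyone in
#'     the common areas).
#'   \item Diverse (bedroom): highest bedroom-area interaction frequency
#'     (roommates in own bedrooms + non-roommates in other bedrooms).
#'   \item Non-roommate-focused: highest frequency of interacting with
#'     non-roommates in common areas.
#'   \item Roommate-focused: the remaining cluster (substantial roommate
#'     partners, low non-roommate frequency).
#' }
#' With more clusters than rules, leftovers are labelled `"unclassified"`.
#' Ties (identical centroids) break deterministically to the lowest cluster
#' index and are flagged.
#'
#' @param model a single [stats::kmeans()] fit, or a [kmeans_sweep()]
#'   element.
#' @param features raw-scale feature data.frame used for the fit (centroids
#'   are recomputed on the raw scale from assignments, so it does not
#'   matter whether the fit used standardized features).
#' @return data.frame: `cluster`, `label`, `tied` flag, plus the raw-scale
#'   centroid columns.
#' @export
label_clusters <- function(model, features) {
  assign <- model$cluster
  k <- length(unique(assign))
  fm <- as.matrix(features[, FEATURE_COLS])
  cent <- do.call(rbind, lapply(sort(unique(assign)), function(cl) {
    colMeans(fm[assign == cl, , drop = FALSE])
  }))
  rownames(cent) <- sort(unique(assign))
  bed_freq <- cent[, "freq_roommates_own_bedroom"] +
    cent[, "freq_nonroommates_other_bedrooms"]
  total <- rowSums(cent)
  crit <- list(
    Restricted = -total,  # argmax of negative total = argmin
    `Diverse (common area)` = cent[, "freq_roommates_common"],
    `Diverse (bedroom)` = bed_freq,
    `Non-roommate-focused` = cent[, "freq_nonroommates_common"]
  )
  labels <- rep(NA_character_, k)
  tied <- rep(FALSE, k)
  remaining <- seq_len(k)
  for (nm in names(crit)) {
    if (length(remaining) == 0L) break
    v <- crit[[nm]][remaining]
    top <- which(v == max(v))
    if (length(top) > 1L) tied[remaining[top]] <- TRUE
    pick <- remaining[top[1L]]
    labels[pick] <- nm
    remaining <- setdiff(remaining, pick)
  }
  if (length(remaining) > 0L) {
    labels[remaining[1L]] <- "Roommate-focused"
    remaining <- remaining[-1L]
  }
  if (length(remaining) > 0L) labels[remaining] <- "unclassified"
  out <- data.frame(cluster = sort(unique(assign)), label = labels,
                    tied = tied, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cent))
}

#' Flag cluster means far from the overall mean
#'
#' Reproduces the bolding rule of typology tables: a cluster mean is
#' flagged when it lies at least half a standard deviation above or below
#' the overall mean of that feature. The reference SD defaults to the
#' across-resident SD of each feature; zero SD yields no flags.
#'
#' @param cluster_means numeric matrix (clusters x features).
#' @param overall_mean numeric vector of per-feature overall means.
#' @param sd numeric vector of per-feature reference SDs.
#' @param threshold multiplier on the SD (default 0.5).
#' @return logical matrix of flags, same shape as `cluster_means`.
#' @export
flag_extremes <- function(cluster_means, overall_mean, sd, threshold = 0.5) {
  cluster_means <- as.matrix(cluster_means)
  dev <- abs(sweep(cluster_means, 2, overall_mean, "-"))
  lim <- matrix(rep(threshold * sd, each = nrow(cluster_means)),
                nrow = nrow(cluster_means))
  flags <- dev >= lim - 1e-9 & lim > 0
  dimnames(flags) <- dimnames(cluster_means)
  flags
}

#' Cluster x bedroom-type contingency table
#'
#' Counts residents per (cluster, bedroom type), with within-bedroom-type
#' column percentages, a marker for the largest proportion in each column,
#' and each cluster's share of the whole sample.
#'
#' @param assignments named vector mapping `resident_id` to cluster (or
#'   typology label).
#' @param fac the [facility()] providing bedroom types.
#' @return list with `counts` (matrix clusters x bedroom types), `col_pct`
#'   (column percentages), `largest` (logical matrix marking each column's
#'   maximum), `share_of_sample` (per-cluster % of all residents).
#' @export
cluster_by_bedroom_table <- function(assignments, fac) {
  r <- fac$residents
  miss <- setdiff(r$resident_id, names(assignments))
  if (length(miss) > 0L) {
    stop_invalid("assignments do not cover roster: %s", paste(miss, collapse = ", "))
  }
  cl <- assignments[r$resident_id]
  counts <- table(cluster = as.character(cl),
                  bedroom_type = factor(r$bedroom_type, levels = BEDROOM_TYPES))
  counts <- unclass(counts)
  col_tot <- colSums(counts)
  col_pct <- sweep(counts, 2, ifelse(col_tot == 0, 1, col_tot), "/") * 100
  largest <- sweep(col_pct, 2, apply(col_pct, 2, max), "==") & col_pct > 0
  share <- rowSums(counts) / sum(counts) * 100
  list(counts = counts, col_pct = col_pct, largest = largest,
       share_of_sample = share)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items,
#' used to measure recovery of planted cluster structure.
#'
#' @param a,b vectors of cluster labels (same length/order).
#' @return ARI in \[-1, 1\]; 1 iff the partitions are identical.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("partitions differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
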