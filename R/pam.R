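#' Dissimilarity matrix between temporal expression profiles
#'
#' The default metric is 1 - Pearson correlation of the log2 profiles, a
#' shape-based dissimilarity that ignores baseline offsets and amplitude;
#' the alternative is Euclidean distance between z-scored profiles. A
#' zero-variance profile has no defined correlation; its dissimilarity to
#' everything is set to 1 (uncorrelated) with a warning.
#'
#' @param profiles numeric matrix, genes x time points (log2 scale for the
#'   correlation metric).
#' @param method \code{"correlation"} or \code{"euclidean"}.
#' @return symmetric dissimilarity matrix with zero diagonal, dimnames from
#'   \code{profiles} rownames.
#' @export
profileDissimilarity <- function(profiles,
                                 method = c("correlation", "euclidean")) {
  method <- match.arg(method)
  if (anyNA(profiles)) stop("profiles must not contain missing values")
  if (method == "correlation") {
    v <- apply(profiles, 1, var)
    flat <- v < 1e-24
    if (any(flat))
      warning(sum(flat), " zero-variance profile(s): dissimilarity set to 1")
    d <- 1 - suppressWarnings(cor(t(profiles)))
    if (any(flat)) { d[flat, ] <- 1; d[, flat] <- 1 }
  } else {
    z <- t(scale(t(profiles)))
    z[is.nan(z)] <- 0
    d <- as.matrix(dist(z))
  }
  diag(d) <- 0
  d[d < 0] <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(rownames(profiles), rownames(profiles))
  d
}

#' Partitioning around medoids (BUILD + SWAP)
#'
#' From-scratch k-medoid clustering in the Kaufman-Rousseeuw style. BUILD
#' greedily seeds the k medoids (each new medoid maximally reduces the total
#' dissimilarity of items to their nearest medoid); SWAP repeatedly applies
#' the first (medoid index, candidate index)-ordered exchange of a medoid
#' with a non-medoid that strictly decreases the total cost, until no
#' improving exchange exists. Both phases are deterministic given the
#' dissimilarity matrix; ties break to the lowest item index.
#'
#' @param d symmetric dissimilarity matrix (zero diagonal).
#' @param k number of clusters, 1 <= k < n.
#' @return a \code{\linkS4class{ClusterResult}}.
#' @export
pamCluster <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  # BUILD: first medoid minimises total dissimilarity; subsequent medoids
  # maximise the decrease of sum(pmin(dnear, d[, candidate]))
  medoids <- integer(0)
  dnear <- rep(Inf, n)
  for (j in seq_len(k)) {
    if (j == 1L) {
      tot <- colSums(d)
      cand <- which.min(tot)             # lowest index wins ties
    } else {
      gain <- colSums(pmax(dnear - d, 0))
      gain[medoids] <- -Inf
      cand <- which.max(gain)
    }
    medoids <- c(medoids, cand)
    dnear <- pmin(dnear, d[, cand])
  }

  nearestTwo <- function(medoids) {
    dm <- d[, medoids, drop = FALSE]
    o1 <- max.col(-dm, ties.method = "first")
    d1 <- dm[cbind(seq_len(n), o1)]
    dm2 <- dm
    dm2[cbind(seq_len(n), o1)] <- Inf
    d2 <- if (length(medoids) > 1L) dm2[cbind(seq_len(n),
      max.col(-dm2, ties.method = "first"))] else rep(Inf, n)
    list(which1 = o1, d1 = d1, d2 = d2)
  }

  # SWAP: first-improvement over (medoid position, candidate index) order.
  # The cost change of exchanging medoid m for candidate h decomposes into a
  # medoid-independent term (items whose nearest medoid is not m) plus a
  # correction over m's own items, so one O(n^2) pass prices all k*(n-k)
  # exchanges of a sweep.
  repeat {
    nt <- nearestTwo(medoids)
    A <- pmin(d - nt$d1, 0)           # [i,h] = min(d(i,h) - d1_i, 0)
    S <- colSums(A)
    improved <- FALSE
    for (mi in seq_along(medoids)) {
      own <- nt$which1 == mi
      if (any(own)) {
        corr <- colSums(pmin(d[own, , drop = FALSE], nt$d2[own]) -
                          nt$d1[own]) -
          colSums(A[own, , drop = FALSE])
        tot <- S + corr
      } else tot <- S
      tot[medoids] <- Inf               # only non-medoids are candidates
      hit <- which(tot < -1e-12)
      if (length(hit)) {
        medoids[mi] <- hit[1L]          # lowest candidate index
        nt <- nearestTwo(medoids)
        A <- pmin(d - nt$d1, 0)
        S <- colSums(A)
        improved <- TRUE
      }
    }
    if (!improved) break
  }

  medoids <- as.integer(medoids)
  nt <- nearestTwo(medoids)
  # renumber clusters by medoid index order for determinism
  o <- order(medoids)
  medoids <- medoids[o]
  assignment <- match(nt$which1, o)
  assignment[medoids] <- seq_along(medoids)   # each medoid in its own cluster
  cost <- sum(d[cbind(seq_len(n), medoids[assignment])])
  new("ClusterResult", k = k, ids = ids, medoids = medoids,
      assignment = as.integer(assignment), cost = cost,
      metric = "precomputed")
}

#' Exhaustive-search optimal k-medoid clustering (test oracle)
#'
#' Enumerates all \code{choose(n, k)} medoid sets and returns the one with
#' minimal total cost. Only feasible for small n; intended as an
#' independent optimality oracle for \code{\link{pamCluster}}.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k number of clusters.
#' @return list with \code{medoids} and \code{cost}.
#' @export
bruteForceMedoids <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  combs <- utils::combn(n, k)
  costs <- apply(combs, 2, function(m)
    sum(apply(d[, m, drop = FALSE], 1, min)))
  best <- which.min(costs)
  list(medoids = combs[, best], cost = costs[best])
}

#' Silhouette scores for a clustering
#'
#' The classical silhouette of item i is (b_i - a_i) / max(a_i, b_i), with
#' a_i the mean dissimilarity to its own cluster (excluding itself) and b_i
#' the smallest mean dissimilarity to any other cluster; items in singleton
#' clusters score 0. The \code{"medoid"} variant replaces the cluster means
#' by the dissimilarity to the own medoid (a) and to the closest other
#' medoid (b), the reading suggested by describing silhouettes as similarity
#' to the own medoid versus the other medoids.
#'
#' @param result a \code{\linkS4class{ClusterResult}}.
#' @param d the dissimilarity matrix used for clustering.
#' @param variant \code{"classical"} (default) or \code{"medoid"}.
#' @return list with \code{widths} (per item, named), \code{average},
#'   \code{clusterAverage} (per cluster), \code{negativeFraction} (per
#'   cluster fraction of negative widths).
#' @export
silhouetteScores <- function(result, d, variant = c("classical", "medoid")) {
  variant <- match.arg(variant)
  d <- as.matrix(d)
  k <- result@k
  if (k < 2L) stop("silhouette undefined for k = 1")
  n <- nrow(d)
  cl <- result@assignment
  sizes <- tabulate(cl, k)
  if (variant == "classical") {
    Z <- matrix(0, n, k)
    Z[cbind(seq_len(n), cl)] <- 1
    sums <- d %*% Z                       # item x cluster dissimilarity sums
    means <- sweep(sums, 2, sizes, "/")
    a <- ifelse(sizes[cl] > 1L,
                sums[cbind(seq_len(n), cl)] / (sizes[cl] - 1L), NA)
    other <- means
    other[cbind(seq_len(n), cl)] <- Inf
    b <- apply(other, 1, min)
    s <- ifelse(sizes[cl] == 1L, 0, (b - a) / pmax(a, b))
    zero <- sizes[cl] > 1L & !is.na(a) & pmax(a, b) == 0
    s[zero] <- 0
  } else {
    dm <- d[, result@medoids, drop = FALSE]
    a <- dm[cbind(seq_len(n), cl)]
    other <- dm
    other[cbind(seq_len(n), cl)] <- Inf
    b <- apply(other, 1, min)
    s <- ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b))
  }
  names(s) <- result@ids
  clusterAverage <- vapply(seq_len(k), function(j) mean(s[cl == j]),
                           numeric(1))
  negativeFraction <- vapply(seq_len(k), function(j) mean(s[cl == j] < 0),
                             numeric(1))
  list(widths = s, average = mean(s), clusterAverage = clusterAverage,
       negativeFraction = negativeFraction)
}

#' Scan cluster numbers and pick k by average silhouette
#'
#' Runs \code{\link{pamCluster}} for each k in \code{kRange}, scores each
#' result with the average silhouette and returns the scan table together
#' with the chosen k (the silhouette argmax by default; an explicit
#' \code{chooseK} overrides, mirroring choosing a grouping by inspection).
#'
#' @param d dissimilarity matrix.
#' @param kRange integer vector of candidate k (within [2, n - 1]).
#' @param chooseK optional explicit k overriding the silhouette argmax.
#' @param variant silhouette variant passed to \code{silhouetteScores}.
#' @return list with \code{table} (k, avg_silhouette, cost), \code{chosen},
#'   \code{results} (named list of \code{ClusterResult}).
#' @export
scanK <- function(d, kRange = 2:30, chooseK = NULL,
                  variant = "classical") {
  n <- nrow(as.matrix(d))
  kRange <- kRange[kRange >= 2L & kRange <= n - 1L]
  if (length(kRange) == 0L) stop("kRange must lie within [2, n-1]")
  results <- list()
  tab <- data.frame(k = integer(0), avg_silhouette = numeric(0),
                    cost = numeric(0))
  for (k in kRange) {
    cr <- pamCluster(d, k)
    sil <- silhouetteScores(cr, d, variant)
    results[[as.character(k)]] <- cr
    tab <- rbind(tab, data.frame(k = k, avg_silhouette = sil$average,
                                 cost = cr@cost))
  }
  chosen <- if (is.null(chooseK)) tab$k[which.max(tab$avg_silhouette)]
            else as.integer(chooseK)
  list(table = tab, chosen = chosen, results = results)
}

#' Min-max normalise profiles and order them for heat-map display
#'
#' Each gene profile is scaled to [0, 1] by its own minimum and maximum
#' (constant profiles map to 0.5 with a warning). When a clustering is
#' given, rows are ordered by cluster, with the medoid first and the
#' remaining genes by increasing dissimilarity to their medoid.
#'
#' @param profiles genes x time matrix.
#' @param result optional \code{\linkS4class{ClusterResult}}.
#' @param d dissimilarity matrix (required with \code{result}).
#' @return normalised matrix (reordered if \code{result} given), with a
#'   \code{cluster} attribute when ordered.
#' @export
normalizeForHeatmap <- function(profiles, result = NULL, d = NULL) {
  rng <- t(apply(profiles, 1, range))
  flat <- rng[, 2] - rng[, 1] < 1e-12
  if (any(flat)) warning(sum(flat), " constant profile(s) set to 0.5")
  z <- (profiles - rng[, 1]) / ifelse(flat, 1, rng[, 2] - rng[, 1])
  z[flat, ] <- 0.5
  if (is.null(result)) return(z)
  stopifnot(!is.null(d))
  d <- as.matrix(d)
  cl <- result@assignment
  dmed <- d[cbind(seq_len(nrow(d)), result@medoids[cl])]
  o <- order(cl, dmed, seq_len(nrow(d)))
  z <- z[o, , drop = FALSE]
  attr(z, "cluster") <- cl[o]
  z
}
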