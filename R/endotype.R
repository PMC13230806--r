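#' Unscaled PCA reduction to a variance target
#'
#' Centres each aptamer (no scaling) and returns principal-component scores
#' for the smallest number of leading components whose cumulative variance
#' fraction reaches `variance_target`. Component signs are fixed so each
#' component's largest-magnitude loading is positive, making results
#' reproducible across linear-algebra backends.
#'
#' @param matrix an `AbundanceMatrix` or numeric matrix (samples x aptamers).
#' @param variance_target cumulative variance fraction to retain, in (0, 1].
#' @return A `ReducedSpace`: list with `scores` (samples x N_d),
#'   `variance_fraction` (all positive eigenvalue fractions, decreasing) and
#'   `n_d` (retained dimension count).
#' @export
pca_reduce <- function(matrix, variance_target = 0.80) {
  if (!is.numeric(variance_target) || length(variance_target) != 1 ||
      variance_target <= 0 || variance_target > 1)
    stop("'variance_target' must lie in (0, 1]")
  X <- if (inherits(matrix, "AbundanceMatrix")) matrix$values else as.matrix(matrix)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 samples")
  Xc <- scale(X, scale = FALSE)

  if (p <= n) {
    ee <- eigen(crossprod(Xc), symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    keep_rank <- ev > max(ev) * 1e-12
    V <- ee$vectors[, keep_rank, drop = FALSE]
    ev <- ev[keep_rank]
    scores <- Xc %*% V
  } else {
    ee <- eigen(tcrossprod(Xc), symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    keep_rank <- ev > max(ev) * 1e-12
    U <- ee$vectors[, keep_rank, drop = FALSE]
    ev <- ev[keep_rank]
    scores <- U %*% diag(sqrt(ev), length(ev))
    V <- crossprod(Xc, U) %*% diag(1 / sqrt(ev), length(ev))
  }
  vf <- ev / sum(ev)
  n_d <- which(cumsum(vf) >= variance_target - 1e-12)[1]
  if (is.na(n_d)) n_d <- length(vf)
  ## sign convention: largest-|loading| entry positive
  for (k in seq_len(n_d)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) scores[, k] <- -scores[, k]
  }
  scores <- scores[, seq_len(n_d), drop = FALSE]
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_d)))
  structure(list(scores = scores, variance_fraction = vf, n_d = n_d),
            class = "ReducedSpace")
}

#' @export
print.ReducedSpace <- function(x, ...) {
  cat(sprintf("ReducedSpace: %d samples, %d components (%.1f%% variance)\n",
              nrow(x$scores), x$n_d, 100 * sum(x$variance_fraction[seq_len(x$n_d)])))
  invisible(x)
}

## one seeded k-means (Lloyd, random-point initialisation, best of n_init
## starts), retried if an unlucky start yields an empty cluster
kmeans_best <- function(X, K, n_init, iter_max = 100) {
  for (attempt in 1:8) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = K, iter.max = iter_max,
                                     nstart = n_init, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km)) return(km)
  }
  stop("k-means failed for K = ", K)
}

#' Multi-start k-means scan over cluster numbers
#'
#' For each K in 1..`k_max`, runs Lloyd's k-means with `n_init` random
#' initialisations and records the minimum distortion S_K (total
#' within-cluster sum of squared distances) and the best run's labels.
#' Monotone non-increase of S_K is a checked invariant: rare local-optimum
#' violations trigger extra restarts.
#'
#' @param space a `ReducedSpace` (or numeric score matrix).
#' @param k_max largest cluster number scanned (must be < sample count).
#' @param n_init number of random initialisations per K.
#' @param seed RNG seed; the scan is deterministic given it.
#' @return A `ClusterScan`: list with `K`, `S`, `labels` (samples x k_max),
#'   `n_d`, `n_init`, `seed`.
#' @export
kmeans_scan <- function(space, k_max = 9, n_init = 10, seed = 1L) {
  X <- if (inherits(space, "ReducedSpace")) space$scores else as.matrix(space)
  n_d <- if (inherits(space, "ReducedSpace")) space$n_d else ncol(X)
  n <- nrow(X)
  assert_scalar_count(n_init, "n_init")
  assert_scalar_count(k_max, "k_max")
  if (k_max > n) stop("k_max must not exceed the sample count")
  set.seed(seed)
  S <- numeric(k_max)
  labels <- matrix(1L, n, k_max, dimnames = list(rownames(X), paste0("K", seq_len(k_max))))
  S[1] <- sum(scale(X, scale = FALSE)^2)
  for (K in seq_len(k_max)[-1]) {
    km <- kmeans_best(X, K, n_init)
    ## invariant repair: S_K must not exceed S_{K-1}
    extra <- 0
    while (km$tot.withinss > S[K - 1] + 1e-8 && extra < 3) {
      extra <- extra + 1
      km2 <- kmeans_best(X, K, n_init)
      if (km2$tot.withinss < km$tot.withinss) km <- km2
    }
    if (km$tot.withinss > S[K - 1] + 1e-8)
      warning(sprintf("distortion not monotone at K = %d despite restarts", K))
    S[K] <- km$tot.withinss
    labels[, K] <- km$cluster
  }
  structure(list(K = seq_len(k_max), S = S, labels = labels,
                 n_d = n_d, n_init = n_init, seed = seed),
            class = "ClusterScan")
}

#' @export
print.ClusterScan <- function(x, ...) {
  cat(sprintf("ClusterScan: K = 1..%d, N_d = %d\n", length(x$K), x$n_d))
  if (!is.null(x$f)) {
    cat(sprintf("min f(K) = %.4f at K = %d\n",
                min(x$f[-1]), which.min(x$f[-1]) + 1L))
  }
  invisible(x)
}

#' The f(K) cluster-number statistic
#'
#' Ratio-of-distortions statistic for validating k-means cluster numbers:
#' `f(1) = 1`; `f(K) = S_K / (a_K * S_(K-1))` (1 if `S_(K-1) = 0`) with
#' weights `a_2 = 1 - 3/(4 N_d)` and `a_K = a_(K-1) + (1 - a_(K-1))/6` for
#' K > 2, where N_d is the clustered-space dimension. Values near 1 indicate
#' no cluster structure.
#'
#' @param scan a `ClusterScan`, or a numeric vector of distortions S_1..S_Kmax.
#' @param n_d clustered-space dimension; taken from the scan when omitted.
#' @return If given a scan, the scan with `f` and `a` added; otherwise a
#'   list with `f` and `a`.
#' @export
f_of_k <- function(scan, n_d = NULL) {
  is_scan <- inherits(scan, "ClusterScan")
  S <- if (is_scan) scan$S else as.numeric(scan)
  n_d <- n_d %||% (if (is_scan) scan$n_d else NULL)
  if (is.null(n_d) || n_d < 1) stop("'n_d' must be >= 1")
  if (length(S) < 1 || anyNA(S)) stop("distortions S_1..S_Kmax required")
  kmax <- length(S)
  a <- rep(NA_real_, kmax); f <- rep(NA_real_, kmax)
  f[1] <- 1
  if (kmax >= 2) {
    a[2] <- 1 - 3 / (4 * n_d)
    f[2] <- if (S[1] == 0) 1 else S[2] / (a[2] * S[1])
    for (k in seq_len(kmax)[-(1:2)]) {
      a[k] <- a[k - 1] + (1 - a[k - 1]) / 6
      f[k] <- if (S[k - 1] == 0) 1 else S[k] / (a[k] * S[k - 1])
    }
  }
  if (is_scan) { scan$f <- f; scan$a <- a; scan } else list(f = f, a = a)
}

#' Decide whether the data are significantly clustered
#'
#' Declares clustering when f(K) drops below `threshold` (0.85, specified a
#' priori) for any K >= 2, and reports the K attaining the minimum.
#'
#' @param f a `ClusterScan` carrying `f`, or a numeric f(K) vector
#'   (position k = f at K = k).
#' @param threshold decision threshold on f(K).
#' @return A `ClusterDecision`: list with `clustered`, `k_min` (argmin over
#'   K >= 2), `f_min`, `threshold`.
#' @export
decide_clustering <- function(f, threshold = 0.85) {
  if (inherits(f, "ClusterScan")) {
    if (is.null(f$f)) stop("run f_of_k() on the scan first")
    f <- f$f
  }
  f <- as.numeric(f)
  if (length(f) < 2) stop("need f(K) values for K >= 2")
  fk <- f[-1]
  k_min <- which.min(fk) + 1L
  structure(list(clustered = min(fk) < threshold,
                 k_min = k_min, f_min = min(fk), threshold = threshold),
            class = "ClusterDecision")
}

#' @export
print.ClusterDecision <- function(x, ...) {
  cat(sprintf("%s (min f(K) = %.4f at K = %d; threshold %.2f)\n",
              if (x$clustered) "significantly clustered" else "not clustered",
              x$f_min, x$k_min, x$threshold))
  invisible(x)
}

## modal vote with parsimony tie-break: among equally supported cluster
## numbers, the smallest wins
modal_vote <- function(votes) {
  tb <- table(votes)
  min(as.integer(names(tb)[tb == max(tb)]))
}

## internal index calculators; labels from the scan's best runs ----------

index_silhouette <- function(X, labels, D) {
  mean(cluster::silhouette(labels, D)[, 3])
}

index_ch <- function(S1, SK, n, K) ((S1 - SK) / (K - 1)) / (SK / (n - K))

index_db <- function(X, labels) {
  ks <- sort(unique(labels))
  cent <- rowsum(X, labels) / as.vector(table(labels))
  wd <- vapply(seq_along(ks), function(i) {
    pts <- X[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[i, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(cent)); diag(cd) <- Inf
  mean(vapply(seq_along(ks), function(i) max((wd[i] + wd[-i]) / cd[i, -i]),
              numeric(1)))
}

## Gap statistic (uniform reference over the bounding box of the reduced
## space); vote by the standard one-standard-error rule.
index_gap_vote <- function(X, scan, B = 10, n_init = 2) {
  kmax <- length(scan$K)
  logW <- log(scan$S)
  logWref <- matrix(NA_real_, B, kmax)
  rng <- apply(X, 2, range)
  n <- nrow(X)
  for (b in seq_len(B)) {
    R <- apply(rng, 2, function(r) stats::runif(n, r[1], r[2]))
    logWref[b, 1] <- log(sum(scale(R, scale = FALSE)^2))
    for (K in seq_len(kmax)[-1])
      logWref[b, K] <- log(kmeans_best(R, K, n_init)$tot.withinss)
  }
  gap <- colMeans(logWref) - logW
  sk <- apply(logWref, 2, stats::sd) * sqrt(1 + 1 / B)
  for (K in seq_len(kmax - 1)[-1])
    if (gap[K] >= gap[K + 1] - sk[K + 1]) return(K)
  kmax
}

#' Majority-vote choice of the optimal cluster number
#'
#' Each configured index votes for its optimal K over 2..Kmax using the
#' scan's best-run labels; the chosen K is the modal vote, ties broken by
#' the smallest K. Available indices: `"silhouette"` (max mean width),
#' `"ch"` (max Calinski-Harabasz), `"db"` (min Davies-Bouldin), `"fk"`
#' (argmin f(K)), `"gap"` (gap statistic, one-SE rule).
#'
#' @param space a `ReducedSpace`.
#' @param scan a `ClusterScan` that has been through [f_of_k()].
#' @param indices character vector of index names (>= 3).
#' @param decision optional `ClusterDecision`; voting is refused when the
#'   data were not declared clustered.
#' @param seed seed for the gap statistic's reference draws.
#' @return List with `chosen_k` and the named `votes` vector.
#' @export
majority_vote_k <- function(space, scan,
                            indices = c("silhouette", "ch", "db", "fk"),
                            decision = NULL, seed = 1L) {
  if (length(indices) < 3) stop("configure at least 3 indices")
  if (is.null(decision)) decision <- decide_clustering(scan)
  if (!decision$clustered)
    stop("majority_vote_k called on data not declared clustered")
  X <- space$scores
  kmax <- length(scan$K)
  n <- nrow(X)
  D <- if ("silhouette" %in% indices) stats::dist(X) else NULL
  votes <- stats::setNames(integer(length(indices)), indices)
  for (ind in indices) {
    votes[ind] <- switch(ind,
      silhouette = {
        v <- vapply(2:kmax, function(K) index_silhouette(X, scan$labels[, K], D),
                    numeric(1))
        which.max(v) + 1L
      },
      ch = {
        v <- vapply(2:kmax, function(K) index_ch(scan$S[1], scan$S[K], n, K),
                    numeric(1))
        which.max(v) + 1L
      },
      db = {
        v <- vapply(2:kmax, function(K) index_db(X, scan$labels[, K]), numeric(1))
        which.min(v) + 1L
      },
      fk = {
        if (is.null(scan$f)) scan <- f_of_k(scan)
        which.min(scan$f[-1]) + 1L
      },
      gap = { set.seed(seed); index_gap_vote(X, scan) },
      stop("unknown index: ", ind))
  }
  list(chosen_k = modal_vote(votes), votes = votes)
}

#' Elbow diagnostics
#'
#' @param scan a `ClusterScan`.
#' @param plot_file optional PNG path for the elbow plot.
#' @return data.frame with columns `K` and `S`, sorted by K.
#' @export
elbow_curve <- function(scan, plot_file = NULL) {
  tab <- data.frame(K = scan$K, S = scan$S)
  tab <- tab[order(tab$K), ]
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 600, height = 450)
    on.exit(grDevices::dev.off())
    graphics::plot(tab$K, tab$S, type = "b", xlab = "K", ylab = "distortion S_K",
         main = "Elbow plot")
  }
  tab
}

#' Two-dimensional embedding for visualisation
#'
#' Deterministic given the seed. The default method projects onto the first
#' two principal components of the reduced space; `method = "umap"` uses
#' UMAP when the `uwot` package is installed.
#'
#' @param space a `ReducedSpace`.
#' @param seed RNG seed.
#' @param method `"pca"` or `"umap"`.
#' @return samples x 2 numeric matrix (columns `D1`, `D2`).
#' @export
embed_2d <- function(space, seed = 1L, method = c("pca", "umap")) {
  method <- match.arg(method)
  X <- space$scores
  if (nrow(X) < 10) stop("need at least 10 samples to embed")
  out <- if (method == "umap") {
    if (!requireNamespace("uwot", quietly = TRUE))
      stop("method 'umap' requires the uwot package")
    set.seed(seed)
    as.matrix(uwot::umap(X, n_neighbors = 15, n_threads = 1))
  } else {
    if (ncol(X) == 1) cbind(X[, 1], 0) else X[, 1:2]
  }
  dimnames(out) <- list(rownames(X), c("D1", "D2"))
  out
}

#' Run the full endotype-detection engine
#'
#' Chains [pca_reduce()], [kmeans_scan()], [f_of_k()], [decide_clustering()]
#' and, when clustering is declared, [majority_vote_k()].
#'
#' @param matrix `AbundanceMatrix` or numeric matrix (log scale, batch
#'   adjusted, optionally IPS-residualised; centred internally, not scaled).
#' @param variance_target PCA variance fraction to retain.
#' @param k_max,n_init,threshold,indices,seed passed to the stages.
#' @return An `EndotypeResult`: list with `space`, `scan` (incl. f and a),
#'   `decision`, `chosen_k` (NA when not clustered), `labels` (best-run
#'   labels at the chosen K, or NULL), `votes`.
#' @export
detect_endotypes <- function(matrix, variance_target = 0.80, k_max = 9,
                             n_init = 10, threshold = 0.85,
                             indices = c("silhouette", "ch", "db", "fk"),
                             seed = 1L) {
  space <- pca_reduce(matrix, variance_target)
  scan <- kmeans_scan(space, k_max = min(k_max, nrow(space$scores) - 1),
                      n_init = n_init, seed = substream_seed(seed, "kmeans"))
  scan <- f_of_k(scan)
  decision <- decide_clustering(scan, threshold)
  chosen_k <- NA_integer_; labels <- NULL; votes <- NULL
  if (decision$clustered) {
    mv <- majority_vote_k(space, scan, indices, decision,
                          seed = substream_seed(seed, "gap"))
    chosen_k <- mv$chosen_k
    votes <- mv$votes
    labels <- scan$labels[, chosen_k]
  }
  structure(list(space = space, scan = scan, decision = decision,
                 chosen_k = chosen_k, labels = labels, votes = votes),
            class = "EndotypeResult")
}

#' @export
print.EndotypeResult <- function(x, ...) {
  print(x$decision)
  if (x$decision$clustered)
    cat(sprintf("majority-vote K = %d (votes: %s)\n", x$chosen_k,
                paste(sprintf("%s=%d", names(x$votes), x$votes), collapse = ", ")))
  invisible(x)
}
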