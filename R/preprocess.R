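#' Natural-log transform
#'
#' @param matrix an `AbundanceMatrix` (strictly positive values).
#' @return The matrix on the natural-log scale; ledger gains `"log"`.
#' @export
log_transform <- function(matrix) {
  x <- as_abundance(matrix)
  forbid_transform(x, "log", "log_transform")
  bad <- which(x$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive abundance at sample %s, aptamer %s",
                 rownames(x$values)[bad[1, 1]], colnames(x$values)[bad[1, 2]]))
  }
  x$values <- log(x$values)
  add_transform(x, "log")
}

#' Median normalisation
#'
#' Subtracts each sample's median log abundance and adds back the grand
#' median (the median of the per-sample medians), so all per-sample medians
#' coincide afterwards. A simplified stand-in for the platform's
#' normalisation pipeline.
#'
#' @param matrix a log-transformed `AbundanceMatrix`.
#' @return Normalised matrix; ledger gains `"median_norm"`.
#' @export
median_normalize <- function(matrix) {
  x <- as_abundance(matrix)
  require_transform(x, "log", "median_normalize")
  if (length(x$values) == 0) stop("empty matrix")
  med <- apply(x$values, 1, stats::median)
  x$values <- x$values - med + stats::median(med)
  add_transform(x, "median_norm")
}

#' Empirical-Bayes location/scale batch adjustment
#'
#' The parametric empirical-Bayes adjustment for batch effects: per aptamer,
#' values are standardised against the batch-design fit, per-batch location
#' and scale parameters are estimated, shrunk toward moment-matched normal
#' (location) and inverse-gamma (scale) priors across aptamers, removed, and
#' the original scale restored. Each aptamer is finally re-centred on its
#' pre-adjustment mean so the grand mean per aptamer is preserved exactly.
#'
#' @param matrix a log-transformed `AbundanceMatrix`.
#' @param batch character/factor vector of batch labels per sample (e.g.
#'   spin status), at least 2 samples per batch.
#' @return Adjusted matrix; ledger gains `"batch_adjust"`.
#' @export
batch_adjust_eb <- function(matrix, batch) {
  x <- as_abundance(matrix)
  require_transform(x, "log", "batch_adjust_eb")
  forbid_transform(x, "batch_adjust", "batch_adjust_eb")
  X <- x$values
  n <- nrow(X)
  if (length(batch) != n) stop("batch labels must match sample count")
  batch <- factor(batch)
  nb <- table(batch)
  if (nlevels(batch) < 2) {
    warning("single batch: adjustment is a no-op")
    return(add_transform(x, "batch_adjust"))
  }
  if (any(nb < 2))
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(nb)[nb < 2], collapse = ", "))

  grand_mean <- colMeans(X)
  levs <- levels(batch)
  B <- length(levs)
  idx <- lapply(levs, function(l) which(batch == l))
  w <- as.numeric(nb) / n

  ## batch means per aptamer, weighted stand mean and pooled variance
  bm <- t(vapply(idx, function(i) colMeans(X[i, , drop = FALSE]),
                 numeric(ncol(X))))               # B x p
  stand_mean <- colSums(bm * w)                   # p
  res <- X
  for (b in seq_len(B)) res[idx[[b]], ] <- sweep(X[idx[[b]], , drop = FALSE], 2, bm[b, ])
  pooled_var <- colSums(res^2) / n
  if (any(pooled_var <= 0))
    stop("aptamer(s) constant within batches; cannot batch-adjust: ",
         paste(colnames(X)[pooled_var <= 0][1], collapse = ", "))

  Z <- sweep(sweep(X, 2, stand_mean), 2, sqrt(pooled_var), "/")

  adj <- Z
  for (b in seq_len(B)) {
    Zb <- Z[idx[[b]], , drop = FALSE]
    nbk <- nrow(Zb)
    g_hat <- colMeans(Zb)                                   # per-aptamer batch location
    d_hat <- colSums(sweep(Zb, 2, g_hat)^2) / (nbk - 1)     # per-aptamer batch scale
    ## moment-matched priors across aptamers
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    aprior <- (2 * s2 + m^2) / s2
    bprior <- (m * s2 + m^3) / s2
    ## iterative joint posterior solution
    g_new <- g_hat; d_new <- d_hat
    for (it in seq_len(100)) {
      g_old <- g_new; d_old <- d_new
      g_new <- (t2 * nbk * g_hat + d_new * g_bar) / (t2 * nbk + d_new)
      sum2 <- colSums(sweep(Zb, 2, g_new)^2)
      d_new <- (0.5 * sum2 + bprior) / (nbk / 2 + aprior - 1)
      if (max(abs(g_new - g_old), abs(d_new - d_old)) < 1e-8) break
    }
    adj[idx[[b]], ] <- sweep(sweep(Zb, 2, g_new), 2, sqrt(d_new), "/")
  }
  out <- sweep(sweep(adj, 2, sqrt(pooled_var), "*"), 2, stand_mean, "+")
  ## exact grand-mean restoration per aptamer
  out <- sweep(out, 2, colMeans(out) - grand_mean)
  x$values <- out
  add_transform(x, "batch_adjust")
}

#' Intracellular protein score (IPS)
#'
#' Per-sample mean of per-aptamer-standardised log abundance over the
#' intracellular-flagged aptamers; a proxy for cell-lysis contamination.
#' Constant intracellular aptamers are dropped with a warning; it is an
#' error if all of them are constant.
#'
#' @param matrix a log-transformed `AbundanceMatrix`.
#' @param annotation data.frame with `aptamer_id` and `intracellular`.
#' @return An `IPSVector`: list with `score` (named numeric, one per
#'   sample) and `aptamers` (contributing aptamer ids).
#' @export
compute_ips <- function(matrix, annotation) {
  x <- as_abundance(matrix)
  require_transform(x, "log", "compute_ips")
  ids <- annotation$aptamer_id[as.logical(annotation$intracellular)]
  ids <- intersect(ids, colnames(x$values))
  if (length(ids) == 0) stop("no intracellular-flagged aptamers in the matrix")
  sub <- x$values[, ids, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (all(sds == 0)) stop("all intracellular aptamers are constant")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant intracellular aptamer(s) dropped from IPS")
    sub <- sub[, sds > 0, drop = FALSE]
    ids <- colnames(sub)
  }
  score <- rowMeans(scale(sub))
  structure(list(score = stats::setNames(as.numeric(score), rownames(sub)),
                 aptamers = ids), class = "IPSVector")
}

#' @export
print.IPSVector <- function(x, ...) {
  cat(sprintf("IPSVector over %d samples (%d intracellular aptamers)\n",
              length(x$score), length(x$aptamers)))
  invisible(x)
}

#' Residual adjustment for a per-sample covariate
#'
#' Replaces each aptamer's values by the residuals of an ordinary
#' least-squares fit on intercept + covariate (typically the IPS). Residuals
#' are centred, so the output is mean-zero per aptamer; the operation is
#' idempotent.
#'
#' @param matrix a log-transformed `AbundanceMatrix`.
#' @param covariate numeric per-sample vector (or an `IPSVector`).
#' @return Residualised matrix; ledger gains `"ips_regressed"`.
#' @export
residualize <- function(matrix, covariate) {
  x <- as_abundance(matrix)
  require_transform(x, "log", "residualize")
  if (inherits(covariate, "IPSVector")) covariate <- covariate$score
  covariate <- as.numeric(covariate)
  if (length(covariate) != nrow(x$values))
    stop("covariate length must match sample count")
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  qrX <- qr(cbind(1, covariate))
  x$values <- qr.resid(qrX, x$values)
  if (!has_transform(x, "ips_regressed")) x <- add_transform(x, "ips_regressed")
  x
}

#' Per-protein standardisation within dataset groups
#'
#' Within each group (e.g. Discovery / Replication / Combined), each
#' aptamer's log abundance is centred and divided by its sample SD
#' (denominator n-1), making regression slopes comparable across proteins.
#'
#' @param matrix a log-transformed `AbundanceMatrix`.
#' @param grouping optional per-sample labels; `NULL` standardises over all
#'   samples jointly.
#' @return Standardised matrix; ledger gains `"standardized"`.
#' @export
standardize_per_protein <- function(matrix, grouping = NULL) {
  x <- as_abundance(matrix)
  require_transform(x, "log", "standardize_per_protein")
  groups <- if (is.null(grouping)) rep("all", nrow(x$values)) else as.character(grouping)
  if (length(groups) != nrow(x$values)) stop("grouping length must match sample count")
  for (g in unique(groups)) {
    i <- groups == g
    sub <- x$values[i, , drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    if (any(sds == 0))
      stop("constant aptamer(s) within group '", g, "': ",
           paste(colnames(sub)[sds == 0][seq_len(min(5, sum(sds == 0)))], collapse = ", "))
    x$values[i, ] <- scale(sub)
  }
  if (!has_transform(x, "standardized")) x <- add_transform(x, "standardized")
  x
}
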