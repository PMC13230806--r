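#' Scenario grid for the endotype-detection power simulator
#'
#' @param scenarios data.frame with columns `n`, `k_endotypes`,
#'   `separation`, `frac_informative` (one row per scenario).
#' @param n_reps Monte-Carlo replicates per scenario (>= 20).
#' @param seed RNG seed.
#' @param threshold f(K) decision threshold.
#' @return A `PowerGrid` list.
#' @export
power_grid <- function(scenarios, n_reps = 50, seed = 1L, threshold = 0.85) {
  need <- c("n", "k_endotypes", "separation", "frac_informative")
  miss <- setdiff(need, names(scenarios))
  if (length(miss)) stop("scenarios missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(scenarios) == 0) stop("scenarios must be non-empty")
  if (n_reps < 20) stop("n_reps must be >= 20")
  if (any(scenarios$k_endotypes >= scenarios$n))
    stop("scenario with k_endotypes >= n")
  structure(list(scenarios = scenarios, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), threshold = threshold),
            class = "PowerGrid")
}

## one detection run: generate a cohort at desk scale and push it through
## the preprocessing + clustering pipeline
run_detection_once <- function(n, k, separation, frac_informative, seed,
                               n_aptamers = 500, ips_regress = TRUE,
                               threshold = 0.85, k_max = 9, n_init = 10) {
  cfg <- cohort_config(n_discovery = n, n_replication = 0L,
                       n_aptamers = n_aptamers,
                       n_intracellular = round(0.55 * n_aptamers),
                       k_endotypes = k,
                       endotype_separation = separation,
                       frac_informative = if (k > 1) frac_informative else 0.1,
                       clinical_effects = list(),
                       seed = seed)
  coh <- generate_cohort(cfg)
  m <- log_transform(coh$abundance)
  m <- median_normalize(m)
  m <- batch_adjust_eb(m, coh$sample_metadata$spin)
  if (ips_regress) {
    ips <- compute_ips(m, coh$annotation)
    m <- residualize(m, ips)
  }
  space <- pca_reduce(m)
  scan <- kmeans_scan(space, k_max = k_max, n_init = n_init,
                      seed = substream_seed(seed, "kmeans"))
  scan <- f_of_k(scan)
  dec <- decide_clustering(scan, threshold)
  chosen <- NA_integer_
  if (dec$clustered) {
    chosen <- tryCatch(
      majority_vote_k(space, scan, decision = dec,
                      seed = substream_seed(seed, "gap"))$chosen_k,
      error = function(e) NA_integer_)
  }
  list(clustered = dec$clustered, chosen_k = chosen, f_min = dec$f_min)
}

#' Estimate endotype-detection power by simulation
#'
#' For each scenario, generates `n_reps` synthetic cohorts, runs the full
#' preprocess-and-cluster pipeline (IPS regression on by default, matching
#' the primary analysis) and aggregates the f(K) < threshold detection
#' outcomes.
#'
#' @param grid a [power_grid()].
#' @param n_aptamers aptamer count per simulated cohort (reduced from full
#'   scale; the decision operates in PC space, so a few hundred suffice).
#' @param ips_regress residualise on the intracellular protein score first.
#' @param k_max,n_init clustering scan parameters.
#' @return A `PowerResult` data.frame: one row per scenario with
#'   `detection` (proportion), `mc_error` (binomial SE), `mean_chosen_k`
#'   (mean vote among detections).
#' @export
estimate_power <- function(grid, n_aptamers = 500, ips_regress = TRUE,
                           k_max = 9, n_init = 10) {
  stopifnot(inherits(grid, "PowerGrid"))
  sc <- grid$scenarios
  out <- cbind(sc, detection = NA_real_, mc_error = NA_real_,
               mean_chosen_k = NA_real_)
  for (i in seq_len(nrow(sc))) {
    det <- logical(grid$n_reps)
    ks <- rep(NA_integer_, grid$n_reps)
    for (r in seq_len(grid$n_reps)) {
      seed_r <- substream_seed(grid$seed, sprintf("power_%d_%d", i, r))
      res <- run_detection_once(sc$n[i], sc$k_endotypes[i], sc$separation[i],
                                sc$frac_informative[i], seed_r,
                                n_aptamers = n_aptamers,
                                ips_regress = ips_regress,
                                threshold = grid$threshold,
                                k_max = k_max, n_init = n_init)
      det[r] <- res$clustered
      ks[r] <- res$chosen_k
    }
    p <- mean(det)
    out$detection[i] <- p
    out$mc_error[i] <- sqrt(p * (1 - p) / grid$n_reps)
    out$mean_chosen_k[i] <- if (any(det)) mean(ks[det], na.rm = TRUE) else NA_real_
  }
  class(out) <- c("PowerResult", "data.frame")
  out
}

#' Power curve along one varied factor
#'
#' @param results a `PowerResult`.
#' @param factor name of the varied scenario column (default: the single
#'   column that actually varies).
#' @param plot_file optional PNG path.
#' @return data.frame sorted by the varied factor, with a `monotone`
#'   attribute: TRUE when detection is non-decreasing within twice the
#'   pooled Monte-Carlo error.
#' @export
power_curve <- function(results, factor = NULL, plot_file = NULL) {
  if (nrow(results) < 2) stop("need >= 2 scenarios to draw a curve")
  cand <- c("n", "k_endotypes", "separation", "frac_informative")
  varying <- cand[vapply(cand, function(cn) length(unique(results[[cn]])) > 1,
                         logical(1))]
  factor <- factor %||% {
    if (length(varying) != 1)
      stop("scenarios vary in ", length(varying),
           " factors; specify 'factor' explicitly")
    varying
  }
  out <- results[order(results[[factor]]), ]
  d <- diff(out$detection)
  tol <- 2 * (utils::head(out$mc_error, -1) + utils::tail(out$mc_error, -1))
  attr(out, "monotone") <- all(d >= -tol)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 600, height = 450)
    on.exit(grDevices::dev.off())
    graphics::plot(out[[factor]], out$detection, type = "b", ylim = c(0, 1),
         xlab = factor, ylab = "detection proportion", main = "Power curve")
    graphics::arrows(out[[factor]], pmax(0, out$detection - out$mc_error),
                     out[[factor]], pmin(1, out$detection + out$mc_error),
                     angle = 90, code = 3, length = 0.04)
  }
  out
}
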