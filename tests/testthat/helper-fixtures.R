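## Shared fixtures, built in code at test time.

## A small cohort for unit tests: 150 + 120 samples, 300 aptamers, 55%
## intracellular (same proportion as the calibrated default).
small_cohort <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(n_discovery = 150L, n_replication = 120L, n_aptamers = 300L,
         n_intracellular = 165L, seed = seed),
    list(...))
  generate_cohort(do.call(cohort_config, args))
}

## A bare log-scale AbundanceMatrix with iid noise.
noise_matrix <- function(n = 40, p = 20, sd = 1, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p, mean = 5, sd = sd), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("A%03d", 1:p)))
  abundance_matrix(m, ledger = "log")
}

## Exhaustive-partition k-means oracle: minimal distortion over all label
## assignments with at most K clusters (vectorised over the 3^n labelings).
## Independent of the scan implementation.
oracle_min_distortion <- function(X, K) {
  n <- nrow(X)
  stopifnot(n <= 10, K <= 3)
  L <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  total <- sum(X^2)
  between <- 0
  for (k in seq_len(K)) {
    M <- (L == k) * 1
    cnt <- rowSums(M)
    sums <- M %*% X
    contrib <- rowSums(sums^2) / ifelse(cnt == 0, Inf, cnt)
    between <- between + contrib
  }
  min(total - between)
}

## Literal running-sum walk, kept deliberately naive as the enrichment
## oracle.
oracle_es <- function(genes, metric, set, exponent = 1) {
  N <- length(genes)
  hit <- genes %in% set
  nr <- sum(abs(metric[hit])^exponent)
  nm <- N - sum(hit)
  rs <- 0; best <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (hit[i]) abs(metric[i])^exponent / nr else -1 / nm
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

## Quick linear association stats without the package path (oracle for the
## scan): plain lm per column.
oracle_lm_scan <- function(Z, y, C = NULL) {
  t(apply(Z, 2, function(z) {
    d <- if (is.null(C)) data.frame(y = y, z = z) else cbind(data.frame(y = y, z = z), C)
    sm <- summary(lm(y ~ ., d))$coefficients
    sm["z", c(1, 4)]
  }))
}
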