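## standardised matrix + metadata for direct scan tests
mk_scan_data <- function(n = 300, p = 30, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%04d", 1:n), sprintf("seq.%04d", 1:p)))
  Z <- scale(Z)
  md <- data.frame(sample_id = rownames(Z),
                   age = rnorm(n, 64, 11),
                   sex = factor(sample(c("F", "M"), n, TRUE)),
                   bmi = rnorm(n, 30, 5),
                   cohort = sample(paste0("C", 1:4), n, TRUE))
  list(Z = Z, md = md)
}

test_that("linear scan recovers an exact relationship", {
  d <- mk_scan_data(n = 50, p = 3)
  md <- d$md
  md$y <- 2 * d$Z[, 2] + 3
  res <- fit_protein_association(d$Z, md, "y", covariates = character(0))
  expect_equal(res$effect[2], 2.0, tolerance = 1e-10)
  expect_equal(res$p[2], 0)
  expect_equal(res$direction, sign(res$effect))
  expect_true(all(res$padj >= res$p))
})

test_that("scan agrees with a per-protein lm oracle including covariates", {
  d <- mk_scan_data(n = 120, p = 8, seed = 5)
  md <- d$md
  md$y <- 0.5 * d$Z[, 1] + 0.05 * md$age + rnorm(120)
  res <- fit_protein_association(d$Z, md, "y", covariates = c("age", "sex"))
  orc <- oracle_lm_scan(d$Z, md$y, md[, c("age", "sex")])
  expect_equal(res$effect, unname(orc[, 1]), tolerance = 1e-8)
  expect_equal(res$p, unname(orc[, 2]), tolerance = 1e-8)
})

test_that("null p-values are uniform", {
  d <- mk_scan_data(n = 300, p = 150, seed = 7)
  md <- d$md
  md$y <- rnorm(300)
  res <- fit_protein_association(d$Z, md, "y")
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(sum(res$padj <= 0.05), 2)
})

test_that("logistic and ordinal families estimate per-SD log odds", {
  set.seed(11)
  n <- 1000
  z <- as.numeric(scale(rnorm(n)))
  y <- rbinom(n, 1, plogis(-0.3 + 0.5 * z))
  Z <- matrix(z, n, 1, dimnames = list(sprintf("S%04d", 1:n), "seq.0001"))
  md <- data.frame(sample_id = rownames(Z), age = rnorm(n, 60, 10),
                   sex = factor(sample(c("F", "M"), n, TRUE)), y = y)
  res <- fit_protein_association(Z, md, "y", covariates = character(0))
  glmfit <- glm(y ~ z, family = binomial())
  expect_equal(res$effect[1], unname(coef(glmfit)["z"]), tolerance = 1e-6)
  expect_lt(abs(res$effect[1] - 0.5), 0.2)

  ## ordinal: proportional-odds slope recovered with correct sign
  yo <- cut(0.8 * z + rlogis(n), c(-Inf, -1, 0, 1, Inf), labels = FALSE) - 1
  mdo <- data.frame(sample_id = rownames(Z), ord = yo)
  reso <- fit_protein_association(Z, mdo, "ord", family = "ordinal",
                                  covariates = character(0))
  expect_lt(abs(reso$effect[1] - 0.8), 0.2)
  expect_lt(reso$p[1], 1e-6)
  ## fewer than 3 observed levels is refused
  md2 <- data.frame(sample_id = rownames(Z), ord = as.integer(yo >= 2))
  expect_error(fit_protein_association(Z, md2, "ord", family = "ordinal",
                                       covariates = character(0)),
               ">= 3 observed levels")
})

test_that("complete separation is flagged, not silently dropped", {
  set.seed(2)
  n <- 120
  z <- as.numeric(scale(rnorm(n)))
  Z <- matrix(z, n, 1, dimnames = list(sprintf("S%03d", 1:n), "seq.0001"))
  md <- data.frame(sample_id = rownames(Z), y = as.integer(z > 0))
  expect_warning(
    res <- fit_protein_association(Z, md, "y", covariates = character(0)),
    "separation")
  expect_identical(res$flag[1], "separation")
  expect_true(is.na(res$p[1]))
})

test_that("minimum-n and constant-outcome guards hold", {
  d <- mk_scan_data(n = 40, p = 2)
  md <- d$md
  md$y <- rep(1, 40)
  expect_error(fit_protein_association(d$Z, md, "y"), "constant")
  md$y2 <- rnorm(40)
  res <- fit_protein_association(d$Z, md, "y2", min_n = 50)
  expect_true(all(res$flag == "too_few"))
  expect_true(all(is.na(res$effect)))
})

test_that("BH step-up is exact and matches the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.031), 0.031)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  ## NAs pass through and do not count toward m
  p <- c(0.01, NA, 0.03)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.03))
})

test_that("replication logic matches its definition exactly", {
  mk <- function(padj, dir) {
    data.frame(aptamer_id = "a1", gene = "G1", effect = dir * 1, se = 0.1,
               p = padj / 2, padj = padj, n = 100L, direction = dir,
               flag = "", stringsAsFactors = FALSE)
  }
  expect_true(call_replication(mk(0.04, 1), mk(0.03, 1))$replicated)
  expect_false(call_replication(mk(0.04, 1), mk(0.03, -1))$replicated)
  expect_false(call_replication(mk(0.06, 1), mk(0.01, 1))$replicated)
  expect_false(call_replication(mk(0.06, -1), mk(0.07, -1))$replicated)
  rc <- call_replication(mk(0.05, 1), mk(0.05, 1))
  expect_true(rc$replicated)   # <= is inclusive
  expect_equal(unname(attr(rc, "summary")["replicated"]), 1L)
  expect_error(call_replication(mk(0.01, 1),
                                transform(mk(0.01, 1), aptamer_id = "zz")),
               "no overlapping")
})

test_that("interaction scan detects a planted differential slope", {
  set.seed(13)
  n <- 800; p <- 10
  Z <- scale(matrix(rnorm(n * p), n, p,
                    dimnames = list(sprintf("S%04d", 1:n), sprintf("seq.%03d", 1:p))))
  md <- data.frame(sample_id = rownames(Z), age = rnorm(n, 60, 10),
                   sex = factor(sample(c("F", "M"), n, TRUE)),
                   bmi = rnorm(n, 30, 5))
  mod <- as.integer(md$bmi >= 30)
  md$y <- 0.3 * Z[, 4] + 1.0 * Z[, 4] * mod + rnorm(n)
  res <- test_interaction(Z, md, "y", modifier = "obese",
                          covariates = c("age", "sex"))
  expect_lte(res$padj[4], 0.05)
  expect_lt(abs(res$interaction[4] - 1.0), 0.25)
  expect_gt(min(res$p[-4]), 0.001)
  expect_error(test_interaction(Z, transform(md, bmi = 20), "y", "obese"),
               "constant")
})

test_that("duplicate aptamers collapse to the most significant record", {
  res <- data.frame(
    aptamer_id = c("a1", "a2", "a3", "a4"),
    gene = c("G1", "G1", "G2", "G3"),
    effect = c(1, 2, 3, 4), se = 1,
    p = c(0.002, 0.001, 0.01, 0.02),
    padj = c(0.01, 0.03, 0.04, 0.05),
    n = 10L, direction = 1, flag = "", stringsAsFactors = FALSE)
  out <- select_best_aptamer(res)
  expect_equal(nrow(out), 3L)
  expect_true("a1" %in% out$aptamer_id)   # smaller padj wins for G1
  expect_false("a2" %in% out$aptamer_id)
  ## exact padj tie -> smaller p, then lexicographic aptamer id
  res$padj[2] <- 0.01
  expect_true("a2" %in% select_best_aptamer(res)$aptamer_id)  # smaller p
})

test_that("stratified runs split correctly and drop collinear covariates", {
  coh <- small_cohort(
    seed = 17, n_discovery = 800L, n_replication = 0L,
    clinical_effects = list(womac_pain = list(n_aptamers = 60L, effect = 0.8)))
  m <- standardize_per_protein(median_normalize(log_transform(coh$abundance)))
  md <- coh$sample_metadata
  expect_message(
    out <- run_stratified(m, md, md$sex, function(mx, mdx)
      fit_protein_association(mx, mdx, "womac_pain",
                              covariates = c("age", "sex"),
                              annotation = coh$annotation)),
    "constant; dropped")
  expect_setequal(names(out$strata), c("F", "M"))
  expect_equal(sum(out$sizes), nrow(md))
  expect_true(is.matrix(out$effect_correlation))
  ## the pain link is shared across sexes -> strong cross-stratum corr
  expect_gt(out$effect_correlation["F", "M"], 0.6)
  expect_error(run_stratified(m, md, rep("x", nrow(md)), identity), ">= 2")
})

test_that("effects are invariant to affine rescaling of raw abundance", {
  coh <- small_cohort(seed = 19, n_discovery = 80L, n_replication = 0L,
                      n_aptamers = 40L, n_intracellular = 20L)
  md <- coh$sample_metadata
  scan_of <- function(raw) {
    m <- standardize_per_protein(log_transform(raw))
    fit_protein_association(m, md, "womac_pain")
  }
  r1 <- scan_of(coh$abundance)
  r2 <- scan_of(abundance_matrix(coh$abundance$values * 3.7))
  expect_equal(r1$effect, r2$effect, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})

test_that("cohort adjustment: fixed effects and random intercept agree in sign", {
  skip_if_not_installed("lme4")
  set.seed(23)
  n <- 400
  coh_lab <- sample(paste0("C", 1:4), n, TRUE)
  coh_eff <- c(C1 = -1, C2 = 0, C3 = 1, C4 = 2)[coh_lab]
  z <- as.numeric(scale(rnorm(n)))
  Z <- matrix(z, n, 1, dimnames = list(sprintf("S%04d", 1:n), "seq.0001"))
  md <- data.frame(sample_id = rownames(Z), age = rnorm(n, 60, 10),
                   sex = factor(sample(c("F", "M"), n, TRUE)),
                   cohort = coh_lab)
  md$y <- 0.6 * z + coh_eff + rnorm(n)
  rf <- fit_protein_association(Z, md, "y", cohort = "fixed")
  rr <- fit_protein_association(Z, md, "y", cohort = "random")
  expect_equal(sign(rf$effect[1]), sign(rr$effect[1]))
  expect_lt(abs(rf$effect[1] - rr$effect[1]), 0.1)
})
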