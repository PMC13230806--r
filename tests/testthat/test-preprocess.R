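mk <- function(vals, ledger = character()) {
  m <- matrix(vals, nrow = length(vals) / 3, ncol = 3,
              dimnames = list(NULL, NULL))
  rownames(m) <- sprintf("S%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("A%d", seq_len(ncol(m)))
  abundance_matrix(m, ledger)
}

test_that("log transform is exact and guards its domain", {
  m <- mk(c(exp(1), 1, exp(2), 1, exp(1), 1))
  lt <- log_transform(m)
  expect_equal(lt$values[1, 1], 1.0)
  expect_equal(lt$values[2, 1], 0.0)
  expect_identical(lt$ledger, "log")
  expect_error(log_transform(lt), "already applied")
  bad <- mk(c(1, 0, 2, 3, 4, 5))
  expect_error(log_transform(bad), "non-positive abundance at sample S2, aptamer A1")
})

test_that("ledger enforces pipeline order", {
  raw <- mk(1:6 + 0)
  expect_error(median_normalize(raw), "requires 'log'")
  expect_error(standardize_per_protein(raw), "requires 'log'")
  expect_error(batch_adjust_eb(raw, c("a", "b")), "requires 'log'")
  expect_error(residualize(raw, c(1, 2)), "requires 'log'")
})

test_that("median normalisation equalises per-sample medians", {
  ## two samples with medians 5 and 7 -> both 6
  m <- abundance_matrix(
    matrix(c(4, 5, 6, 6, 7, 8), 2, 3, byrow = TRUE,
           dimnames = list(c("s1", "s2"), c("a", "b", "c"))),
    ledger = "log")
  mn <- median_normalize(m)
  expect_equal(unname(apply(mn$values, 1, median)), c(6, 6))
  ## fixed point: already-equal medians
  expect_equal(median_normalize(mn)$values, mn$values)
  ## degenerate single aptamer: every sample lands on the grand median
  one <- abundance_matrix(matrix(c(2, 4, 9), 3, 1,
                                 dimnames = list(c("s1", "s2", "s3"), "a")),
                          ledger = "log")
  expect_equal(unname(median_normalize(one)$values[, 1]), c(4, 4, 4))
})

test_that("EB batch adjustment is a no-op on a single batch", {
  m <- noise_matrix()
  expect_warning(out <- batch_adjust_eb(m, rep("spun", 40)), "single batch")
  expect_equal(out$values, m$values, tolerance = 1e-10)
  expect_true("batch_adjust" %in% out$ledger)
  expect_error(batch_adjust_eb(m, c("a", rep("b", 39))), "fewer than 2")
})

test_that("EB batch adjustment removes planted shifts and is calibrated", {
  set.seed(42)
  n <- 400; p <- 200
  batch <- rep(c("spun", "unspun"), each = n / 2)
  X <- matrix(rnorm(n * p, 5, 1), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("A%02d", 1:p)))
  m0 <- abundance_matrix(X, "log")

  ## identical distributions: adjustment barely moves the data
  out0 <- batch_adjust_eb(m0, batch)
  expect_lt(mean(abs(out0$values - X)), 0.05)

  ## planted location shift (mean +1.0, heterogeneous across aptamers as in
  ## real batch effects) on the unspun batch is removed
  X1 <- X
  X1[batch == "unspun", ] <- sweep(X1[batch == "unspun", ], 2,
                                   rnorm(p, 1.0, 0.2), "+")
  out1 <- batch_adjust_eb(abundance_matrix(X1, "log"), batch)
  gap <- colMeans(out1$values[batch == "unspun", , drop = FALSE]) -
    colMeans(out1$values[batch == "spun", , drop = FALSE])
  expect_lt(mean(abs(gap)), 0.05)

  ## grand mean per aptamer preserved
  expect_equal(colMeans(out1$values), colMeans(X1), tolerance = 1e-6)

  ## variance homogenisation: planted scale imbalance shrinks
  X2 <- X; X2[batch == "unspun", ] <- 5 + (X2[batch == "unspun", ] - 5) * 2
  out2 <- batch_adjust_eb(abundance_matrix(X2, "log"), batch)
  vr <- apply(out2$values[batch == "unspun", ], 2, var) /
    apply(out2$values[batch == "spun", ], 2, var)
  expect_lt(abs(median(vr) - 1), 0.3)
})

test_that("IPS averages standardised intracellular aptamers", {
  vals <- cbind(ic1 = c(1, 2, 3), ic2 = c(3, 2, 1), ec = c(5, 5, 6))
  rownames(vals) <- c("s1", "s2", "s3")
  m <- abundance_matrix(vals, "log")
  ann <- data.frame(aptamer_id = c("ic1", "ic2", "ec"),
                    gene = c("G1", "G2", "G3"),
                    intracellular = c(TRUE, TRUE, FALSE))
  ips <- compute_ips(m, ann)
  expect_equal(unname(ips$score), c(0, 0, 0))  # opposite columns cancel
  expect_setequal(ips$aptamers, c("ic1", "ic2"))

  ## constant intracellular aptamer dropped with a warning
  vals2 <- cbind(ic1 = c(1, 2, 3), ic2 = c(4, 4, 4), ec = c(5, 5, 6))
  rownames(vals2) <- rownames(vals)
  expect_warning(ips2 <- compute_ips(abundance_matrix(vals2, "log"), ann),
                 "constant")
  expect_identical(ips2$aptamers, "ic1")
  ## all constant -> error
  vals3 <- cbind(ic1 = c(1, 1, 1), ic2 = c(4, 4, 4), ec = c(5, 5, 6))
  rownames(vals3) <- rownames(vals)
  expect_error(compute_ips(abundance_matrix(vals3, "log"), ann), "all intracellular")
  ## no flagged aptamers -> error
  ann0 <- transform(ann, intracellular = FALSE)
  expect_error(compute_ips(m, ann0), "no intracellular")
})

test_that("residualisation matches closed-form least squares", {
  m <- abundance_matrix(matrix(c(1, 2, 3, 4), 4, 1,
                               dimnames = list(paste0("s", 1:4), "a")),
                        ledger = "log")
  r <- residualize(m, c(0, 0, 1, 1))
  expect_equal(unname(r$values[, 1]), c(-0.5, 0.5, -0.5, 0.5))

  ## exact linear dependence -> zero residuals
  cov <- c(0.3, -1, 2, 0.7)
  m2 <- abundance_matrix(matrix(2 * cov + 5, 4, 1,
                                dimnames = dimnames(m$values)), "log")
  expect_equal(max(abs(residualize(m2, cov)$values)), 0, tolerance = 1e-10)

  ## orthogonal covariate -> centred input
  x <- c(1, 2, 3, 4)
  covo <- c(1, -1, -1, 1)  # orthogonal to centred x
  m3 <- abundance_matrix(matrix(x, 4, 1, dimnames = dimnames(m$values)), "log")
  expect_equal(unname(residualize(m3, covo)$values[, 1]), x - mean(x))

  ## idempotence and residual-covariate orthogonality
  mm <- noise_matrix(n = 30, p = 5, seed = 9)
  cv <- rnorm(30)
  r1 <- residualize(mm, cv)
  r2 <- residualize(r1, cv)
  expect_equal(r1$values, r2$values, tolerance = 1e-10)
  expect_lt(max(abs(cor(r1$values, cv))), 1e-8)
  expect_error(residualize(mm, rep(2, 30)), "constant")
})

test_that("per-protein standardisation uses sample SD within groups", {
  m <- abundance_matrix(matrix(c(1, 2, 3), 3, 1,
                               dimnames = list(paste0("s", 1:3), "a")),
                        ledger = "log")
  s <- standardize_per_protein(m)
  expect_equal(unname(s$values[, 1]), c(-1, 0, 1))
  expect_equal(standardize_per_protein(s)$values, s$values, tolerance = 1e-12)

  mm <- noise_matrix(n = 40, p = 6, seed = 2)
  grp <- rep(c("D", "R"), each = 20)
  sg <- standardize_per_protein(mm, grp)
  for (g in c("D", "R")) {
    expect_equal(unname(colMeans(sg$values[grp == g, ])), rep(0, 6))
    expect_equal(unname(apply(sg$values[grp == g, ], 2, sd)), rep(1, 6))
  }
  const <- mm
  const$values[, 3] <- 7
  expect_error(standardize_per_protein(const), "constant aptamer")
})
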