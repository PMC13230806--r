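#' Derive a clinical outcome from sample metadata
#'
#' Known derivations: `advanced_kl` (KL grade 3-4, binary), `obese`
#' (BMI >= 30 kg/m^2, binary), `kl_grade` (ordinal 0-4), `womac_pain`
#' (continuous 0-100). Any other name is taken directly as a metadata
#' column.
#'
#' @param metadata sample metadata data.frame.
#' @param outcome outcome name.
#' @return List with `value` (vector) and `family` (`"linear"`,
#'   `"logistic"` or `"ordinal"`).
#' @export
derive_outcome <- function(metadata, outcome) {
  switch(outcome,
    advanced_kl = list(value = as.integer(metadata$kl_grade >= 3), family = "logistic"),
    obese = list(value = as.integer(metadata$bmi >= 30), family = "logistic"),
    kl_grade = list(value = metadata$kl_grade, family = "ordinal"),
    womac_pain = list(value = metadata$womac_pain, family = "linear"),
    {
      if (!outcome %in% names(metadata))
        stop("unknown outcome and no metadata column named '", outcome, "'")
      v <- metadata[[outcome]]
      fam <- if (is.numeric(v) && length(unique(stats::na.omit(v))) == 2) "logistic"
             else if (is.numeric(v)) "linear"
             else stop("cannot infer model family for outcome '", outcome, "'")
      list(value = v, family = fam)
    })
}

## covariate design matrix (no intercept column duplication); constant
## covariates are dropped with a message -- this is the collinearity guard
## that removes e.g. sex from sex-stratified analyses automatically
build_covariate_design <- function(metadata, covariates, cohort = "none") {
  keep <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(metadata)) stop("covariate '", cv, "' not in metadata")
    if (length(unique(stats::na.omit(metadata[[cv]]))) < 2) {
      message("covariate '", cv, "' is constant; dropped")
    } else keep <- c(keep, cv)
  }
  vars <- keep
  if (cohort == "fixed") {
    if (!"cohort" %in% names(metadata)) stop("no 'cohort' column in metadata")
    if (length(unique(metadata$cohort)) > 1) vars <- c(vars, "cohort")
  }
  if (length(vars) == 0)
    return(list(C = matrix(1, nrow(metadata), 1,
                           dimnames = list(NULL, "(Intercept)")), vars = keep))
  fm <- stats::as.formula(paste("~", paste(vars, collapse = " + ")))
  mf <- stats::model.frame(fm, metadata, na.action = stats::na.pass)
  list(C = stats::model.matrix(fm, mf), vars = keep)
}

fit_one_linear <- function(y, D) {
  fit <- stats::lm.fit(D, y)
  df <- length(y) - fit$rank
  if (df <= 0) return(c(NA, NA, NA))
  sigma2 <- sum(fit$residuals^2) / df
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  j <- which(colnames(D) == "z")
  jq <- match(j, fit$qr$pivot)
  se <- sqrt(sigma2 * XtXinv[jq, jq])
  b <- fit$coefficients["z"]
  if (is.na(b) || !is.finite(se)) return(c(NA, NA, NA))
  tval <- b / se
  c(b, se, 2 * stats::pt(-abs(tval), df))
}

fit_one_logistic <- function(y, D) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(D, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit)) return(c(NA, NA, NA, 1))
  b <- fit$coefficients["z"]
  w <- fit$weights
  XtWXinv <- tryCatch(chol2inv(chol(crossprod(D * sqrt(w)))), error = function(e) NULL)
  if (is.null(XtWXinv) || is.na(b)) return(c(NA, NA, NA, 1))
  se <- sqrt(XtWXinv[which(colnames(D) == "z"), which(colnames(D) == "z")])
  ## separation flag: divergent coefficient or exploding SE
  if (!fit$converged || abs(b) > 15 || se > 50) return(c(b, se, NA, 1))
  c(b, se, 2 * stats::pnorm(-abs(b / se)), 0)
}

fit_one_ordinal <- function(y, D) {
  yl <- factor(y, ordered = TRUE)
  if (nlevels(yl) < 3) stop("ordinal outcome needs >= 3 observed levels")
  dd <- as.data.frame(D[, colnames(D) != "(Intercept)", drop = FALSE])
  dd$.y <- yl
  fit <- tryCatch(
    suppressWarnings(MASS::polr(.y ~ ., data = dd, Hess = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(c(NA, NA, NA))
  b <- fit$coefficients["z"]
  se <- tryCatch(sqrt(diag(stats::vcov(fit))["z"]), error = function(e) NA)
  if (is.na(b) || is.na(se)) return(c(NA, NA, NA))
  c(b, se, 2 * stats::pnorm(-abs(b / se)))
}

#' Per-protein association scan
#'
#' Fits one regression per aptamer with the clinical outcome as the
#' dependent variable and the standardised log protein abundance as the
#' independent variable: linear for continuous outcomes, logistic for
#' binary, proportional-odds ordinal for ordered categories. Effects are
#' therefore the mean outcome change (beta) or logOR per SD of log protein
#' abundance. Complete cases per aptamer; models with fewer than `min_n`
#' observations are returned as NA records. Logistic fits showing
#' separation are flagged and given p = NA with a warning.
#'
#' @param matrix standardised `AbundanceMatrix` (ledger must contain
#'   `"standardized"`) or a bare numeric matrix assumed standardised.
#' @param metadata sample metadata aligned with the matrix rows.
#' @param outcome outcome name (see [derive_outcome()]).
#' @param family model family; default inferred from the outcome.
#' @param covariates adjustment covariates (default age + sex).
#' @param cohort `"none"`, `"fixed"` (cohort dummies) or `"random"` (random
#'   intercept via lme4, linear outcomes only; others fall back to fixed).
#' @param annotation optional aptamer annotation to attach gene symbols.
#' @param min_n minimum complete cases per model.
#' @return A `ProteinAssociation` data.frame: aptamer_id, gene, effect, se,
#'   p, padj (BH within this scan), n, direction, flag.
#' @export
fit_protein_association <- function(matrix, metadata, outcome,
                                    family = NULL,
                                    covariates = c("age", "sex"),
                                    cohort = c("none", "fixed", "random"),
                                    annotation = NULL, min_n = 30) {
  cohort <- match.arg(cohort)
  x <- as_abundance(matrix)
  if (length(x$ledger) && !has_transform(x, "standardized"))
    stop("matrix must be standardised per protein (see standardize_per_protein)")
  Z <- x$values
  if (nrow(Z) != nrow(metadata)) stop("metadata rows must match matrix rows")
  der <- derive_outcome(metadata, outcome)
  family <- family %||% der$family
  y_all <- der$value
  if (length(unique(stats::na.omit(y_all))) < 2) stop("outcome is constant")

  use_random <- cohort == "random"
  if (use_random && family != "linear") {
    message("random-intercept cohort adjustment supported for linear outcomes; using fixed effects")
    cohort <- "fixed"; use_random <- FALSE
  }
  des <- build_covariate_design(metadata,
                                covariates,
                                if (use_random) "none" else cohort)
  C <- des$C

  p_apt <- ncol(Z)
  out <- data.frame(aptamer_id = colnames(Z),
                    gene = NA_character_, effect = NA_real_, se = NA_real_,
                    p = NA_real_, padj = NA_real_, n = NA_integer_,
                    direction = NA_real_, flag = "",
                    stringsAsFactors = FALSE)
  if (!is.null(annotation))
    out$gene <- annotation$gene[match(out$aptamer_id, annotation$aptamer_id)]

  n_sep <- 0
  for (j in seq_len(p_apt)) {
    z <- Z[, j]
    D <- cbind(C, z = z)
    cc <- stats::complete.cases(D) & !is.na(y_all)
    nn <- sum(cc)
    out$n[j] <- nn
    if (nn < min_n) { out$flag[j] <- "too_few"; next }
    y <- y_all[cc]; Dj <- D[cc, , drop = FALSE]
    res <- if (use_random) {
      if (!requireNamespace("lme4", quietly = TRUE))
        stop("cohort = 'random' requires the lme4 package")
      dd <- as.data.frame(Dj[, colnames(Dj) != "(Intercept)", drop = FALSE])
      dd$.y <- y; dd$.cohort <- metadata$cohort[cc]
      fit <- lme4::lmer(stats::as.formula(
        paste(".y ~", paste(setdiff(names(dd), c(".y", ".cohort")), collapse = " + "),
              "+ (1 | .cohort)")), data = dd, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore"))
      sm <- summary(fit)$coefficients
      c(sm["z", 1], sm["z", 2], 2 * stats::pnorm(-abs(sm["z", 1] / sm["z", 2])))
    } else switch(family,
      linear = fit_one_linear(y, Dj),
      logistic = { r <- fit_one_logistic(y, Dj)
                   if (r[4] == 1) { n_sep <- n_sep + 1; out$flag[j] <- "separation" }
                   r[1:3] },
      ordinal = fit_one_ordinal(y, Dj),
      stop("unknown family: ", family))
    out$effect[j] <- res[1]; out$se[j] <- res[2]; out$p[j] <- res[3]
  }
  if (n_sep > 0)
    warning(n_sep, " logistic fit(s) showed separation; p set to NA and flagged")
  out$padj <- bh_adjust(out$p)
  out$direction <- sign(out$effect)
  class(out) <- c("ProteinAssociation", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in \[0, 1\] (NAs passed through; the number
#'   of tests m counts only non-missing values).
#' @return Adjusted p-values (padj), monotone in p, each in \[p, 1\].
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Call replication across Discovery and Replication scans
#'
#' A protein replicates when it is significant at `padj <= alpha` in both
#' datasets with effects in the same direction.
#'
#' @param discovery,replication `ProteinAssociation` results sharing
#'   aptamer ids.
#' @param alpha significance cutoff on padj.
#' @return A `ReplicationCall` data.frame (one row per shared aptamer) with
#'   a `summary` attribute counting replicated / discovery-only /
#'   replication-only aptamers.
#' @export
call_replication <- function(discovery, replication, alpha = 0.05) {
  shared <- intersect(discovery$aptamer_id, replication$aptamer_id)
  if (length(shared) == 0) stop("no overlapping aptamers between datasets")
  d <- discovery[match(shared, discovery$aptamer_id), ]
  r <- replication[match(shared, replication$aptamer_id), ]
  sig_d <- !is.na(d$padj) & d$padj <= alpha
  sig_r <- !is.na(r$padj) & r$padj <= alpha
  same_dir <- !is.na(d$direction) & !is.na(r$direction) &
    d$direction == r$direction & d$direction != 0
  out <- data.frame(aptamer_id = shared, gene = d$gene,
                    effect_discovery = d$effect, padj_discovery = d$padj,
                    effect_replication = r$effect, padj_replication = r$padj,
                    replicated = sig_d & sig_r & same_dir,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(replicated = sum(out$replicated),
                            discovery_only = sum(sig_d & !out$replicated),
                            replication_only = sum(sig_r & !out$replicated))
  class(out) <- c("ReplicationCall", "data.frame")
  out
}

#' Protein-by-modifier interaction scan
#'
#' Adds a protein-abundance-by-modifier interaction to each per-aptamer
#' model (main effects included) and reports the interaction coefficient
#' with BH adjustment across aptamers. The modifier must be dichotomous
#' (e.g. biological sex, or obesity as BMI >= 30).
#'
#' @inheritParams fit_protein_association
#' @param modifier modifier name, derived via [derive_outcome()] or taken
#'   from metadata (two levels required).
#' @return data.frame: aptamer_id, gene, interaction, se, p, padj, n.
#' @export
test_interaction <- function(matrix, metadata, outcome, modifier,
                             family = NULL, covariates = c("age", "sex"),
                             annotation = NULL, min_n = 30) {
  x <- as_abundance(matrix)
  Z <- x$values
  der <- derive_outcome(metadata, outcome)
  family <- family %||% der$family
  y_all <- der$value
  mod_raw <- if (modifier %in% c("obese", "advanced_kl"))
    derive_outcome(metadata, modifier)$value
  else metadata[[modifier]] %||% stop("modifier '", modifier, "' not found")
  mod_lv <- unique(stats::na.omit(mod_raw))
  if (length(mod_lv) < 2) stop("modifier is constant")
  if (length(mod_lv) > 2) stop("modifier must be dichotomous")
  m01 <- as.numeric(factor(mod_raw, levels = sort(mod_lv))) - 1
  covariates <- setdiff(covariates, modifier)
  des <- build_covariate_design(metadata, covariates)
  C <- cbind(des$C, mod = m01)

  out <- data.frame(aptamer_id = colnames(Z), gene = NA_character_,
                    interaction = NA_real_, se = NA_real_, p = NA_real_,
                    padj = NA_real_, n = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(annotation))
    out$gene <- annotation$gene[match(out$aptamer_id, annotation$aptamer_id)]
  for (j in seq_len(ncol(Z))) {
    z <- Z[, j]
    D <- cbind(C, z = z, zmod = z * m01)
    cc <- stats::complete.cases(D) & !is.na(y_all)
    out$n[j] <- sum(cc)
    if (sum(cc) < min_n) next
    y <- y_all[cc]; Dj <- D[cc, , drop = FALSE]
    res <- switch(family,
      linear = {
        fit <- stats::lm.fit(Dj, y)
        df <- length(y) - fit$rank
        sigma2 <- sum(fit$residuals^2) / df
        XtXinv <- chol2inv(qr.R(fit$qr))
        jq <- match(which(colnames(Dj) == "zmod"), fit$qr$pivot)
        se <- sqrt(sigma2 * XtXinv[jq, jq])
        b <- fit$coefficients["zmod"]
        c(b, se, 2 * stats::pt(-abs(b / se), df))
      },
      logistic = {
        fit <- suppressWarnings(stats::glm.fit(Dj, y, family = stats::binomial()))
        b <- fit$coefficients["zmod"]
        XtWXinv <- tryCatch(chol2inv(chol(crossprod(Dj * sqrt(fit$weights)))),
                            error = function(e) NULL)
        if (is.null(XtWXinv) || is.na(b)) c(NA, NA, NA)
        else {
          jj <- which(colnames(Dj) == "zmod")
          se <- sqrt(XtWXinv[jj, jj])
          c(b, se, 2 * stats::pnorm(-abs(b / se)))
        }
      },
      stop("interaction testing implemented for linear and logistic families"))
    out$interaction[j] <- res[1]; out$se[j] <- res[2]; out$p[j] <- res[3]
  }
  out$padj <- bh_adjust(out$p)
  out
}

#' Collapse duplicate aptamers to one record per protein target
#'
#' Several aptamers can target one protein; keep the most significant by
#' padj (ties: smaller p, then lexicographic aptamer id).
#'
#' @param results a `ProteinAssociation` data.frame with gene symbols.
#' @return Deduplicated results, one row per gene.
#' @export
select_best_aptamer <- function(results) {
  if (all(is.na(results$gene))) stop("gene symbols are required for deduplication")
  o <- order(results$padj, results$p, results$aptamer_id, na.last = TRUE)
  res <- results[o, ]
  res <- res[!duplicated(res$gene), ]
  res[order(res$aptamer_id), ]
}

#' Subset an AbundanceMatrix by sample index, keeping the ledger
#'
#' @param matrix an `AbundanceMatrix`.
#' @param idx row (sample) indices or logical mask.
#' @return The subsetted `AbundanceMatrix`.
#' @export
subset_samples <- function(matrix, idx) {
  x <- as_abundance(matrix)
  abundance_matrix(x$values[idx, , drop = FALSE], x$ledger)
}

#' Run an analysis within strata
#'
#' Splits samples by `strata` (a per-sample vector, e.g.
#' `metadata$bmi >= 30` or `metadata$sex`), applies `analysis(matrix_s,
#' metadata_s)` within each stratum and, when the per-stratum results carry
#' an `effect` column, reports the cross-stratum Pearson correlation of
#' effects.
#'
#' @param matrix `AbundanceMatrix` (any stage; the analysis function decides
#'   what it needs).
#' @param metadata aligned sample metadata.
#' @param strata per-sample stratum labels (>= 2 non-empty groups).
#' @param analysis function of (matrix, metadata) returning the per-stratum
#'   result.
#' @return List with `strata` (per-stratum results), `sizes`, and
#'   `effect_correlation` (matrix of pairwise correlations, or NULL).
#' @export
run_stratified <- function(matrix, metadata, strata, analysis) {
  x <- as_abundance(matrix)
  strata <- as.character(strata)
  if (length(strata) != nrow(x$values)) stop("strata length must match sample count")
  levs <- unique(strata[!is.na(strata)])
  if (length(levs) < 2) stop("need >= 2 non-empty strata")
  res <- list()
  for (s in levs) {
    i <- which(strata == s)
    if (length(i) == 0) stop("empty stratum: ", s)
    res[[s]] <- analysis(subset_samples(x, i), metadata[i, , drop = FALSE])
  }
  eff_cor <- NULL
  if (all(vapply(res, function(r) is.data.frame(r) && "effect" %in% names(r),
                 logical(1)))) {
    effs <- do.call(cbind, lapply(res, function(r) r$effect))
    eff_cor <- stats::cor(effs, use = "pairwise.complete.obs")
  }
  list(strata = res, sizes = table(strata), effect_correlation = eff_cor)
}
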