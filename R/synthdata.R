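#' Configuration for a synthetic synovial-fluid proteomics cohort
#'
#' Collects every knob of the cohort generator. Defaults reproduce the
#' structure the downstream analysis assumes on real data: a Discovery set
#' of 708 and Replication set of 653 participants, a dominant intracellular
#' contamination factor calibrated so the leading principal component of the
#' standardised log matrix carries about 48% of total variance, spin-status
#' batch effects, and clinical covariate links (radiographic severity, pain,
#' a BMI-linked adipokine, a blood-staining haemoglobin marker).
#'
#' @param n_discovery,n_replication sample counts for the two datasets.
#'   `n_replication = 0` is allowed (single-dataset cohorts, used by the
#'   power simulator).
#' @param n_aptamers number of aptamers (measurement channels).
#' @param n_intracellular number of aptamers flagged intracellular; these
#'   carry the contamination-factor loadings.
#' @param k_endotypes number of true endotypes; 1 means continuum only.
#' @param endotype_separation between-endotype range of the per-aptamer
#'   location shift, in units of the residual (per-protein) log-scale SD.
#' @param frac_informative fraction of aptamers carrying endotype effects.
#' @param ips_variance_share target fraction of total variance carried by
#'   the contamination factor in the standardised log matrix; must be < 1.
#' @param spillover_frac fraction of non-intracellular aptamers receiving a
#'   weak (quarter-share) contamination loading, so the intracellular
#'   protein score is an imperfect proxy for the factor.
#' @param batch_shift mean per-aptamer location offset (log scale) for
#'   unspun samples.
#' @param batch_scale residual variance ratio (unspun / spun).
#' @param prob_unspun probability a sample is unspun.
#' @param clinical_effects named list; each element is
#'   `list(n_aptamers =, effect =)` linking that many designated aptamers to
#'   the named metadata outcome with the given effect (residual-SD units per
#'   SD of the outcome). Recognised outcomes: `kl_grade`, `womac_pain`.
#' @param adipokine_bmi_corr target correlation between the designated
#'   adipokine aptamer's log abundance and BMI.
#' @param noise_sd residual log-scale SD.
#' @param n_cohorts number of recruitment cohorts (split across datasets).
#' @param seed integer RNG seed; generation is bit-reproducible given it.
#' @return A validated list of class `CohortConfig`.
#' @export
cohort_config <- function(n_discovery = 708L,
                          n_replication = 653L,
                          n_aptamers = 2000L,
                          n_intracellular = 1100L,
                          k_endotypes = 1L,
                          endotype_separation = 0,
                          frac_informative = 0.1,
                          ips_variance_share = 0.48,
                          spillover_frac = 0.05,
                          batch_shift = 0.5,
                          batch_scale = 1.5,
                          prob_unspun = 0.15,
                          clinical_effects = list(
                            kl_grade  = list(n_aptamers = 50L, effect = 0.5),
                            womac_pain = list(n_aptamers = 30L, effect = 0.4)),
                          adipokine_bmi_corr = 0.5,
                          noise_sd = 0.5,
                          n_cohorts = 8L,
                          seed = 1L) {
  assert_scalar_count(n_discovery, "n_discovery")
  assert_scalar_count(n_replication, "n_replication", min = 0L)
  assert_scalar_count(n_aptamers, "n_aptamers")
  assert_scalar_count(n_intracellular, "n_intracellular")
  assert_scalar_count(k_endotypes, "k_endotypes")
  assert_scalar_count(n_cohorts, "n_cohorts")
  assert_fraction(frac_informative, "frac_informative")
  assert_fraction(ips_variance_share, "ips_variance_share", hi_open = TRUE)
  assert_fraction(spillover_frac, "spillover_frac")
  assert_fraction(prob_unspun, "prob_unspun")
  if (n_intracellular >= n_aptamers)
    stop("'n_intracellular' must be smaller than 'n_aptamers'")
  if (k_endotypes > 1 && frac_informative <= 0)
    stop("k_endotypes > 1 with frac_informative = 0: endotype effects are unplaceable")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  if (batch_scale <= 0) stop("'batch_scale' must be positive")
  if (abs(adipokine_bmi_corr) >= 1) stop("'adipokine_bmi_corr' must lie in (-1, 1)")
  structure(list(
    n_discovery = as.integer(n_discovery),
    n_replication = as.integer(n_replication),
    n_aptamers = as.integer(n_aptamers),
    n_intracellular = as.integer(n_intracellular),
    k_endotypes = as.integer(k_endotypes),
    endotype_separation = endotype_separation,
    frac_informative = frac_informative,
    ips_variance_share = ips_variance_share,
    spillover_frac = spillover_frac,
    batch_shift = batch_shift,
    batch_scale = batch_scale,
    prob_unspun = prob_unspun,
    clinical_effects = clinical_effects,
    adipokine_bmi_corr = adipokine_bmi_corr,
    noise_sd = noise_sd,
    n_cohorts = as.integer(n_cohorts),
    seed = as.integer(seed)), class = "CohortConfig")
}

## Truncated-normal draw by resampling (truncation far in the tail, so the
## expected number of rounds is ~1).
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic synovial-fluid proteomics cohort
#'
#' Log abundance for sample i, aptamer j is
#' `mu_j + lambda_j * c_i + endotype shift + clinical links + batch term + eps_ij`
#' with `c_i ~ N(0,1)` the contamination factor, `lambda_j` nonzero on
#' intracellular-flagged aptamers (plus a weak spillover on a small fraction
#' of the rest), and `eps_ij ~ N(0, noise_sd)` (variance inflated by
#' `batch_scale` for unspun samples). Reported abundance is the exponential
#' of the log value, i.e. strictly positive RFU-like numbers.
#'
#' Contamination loadings are calibrated from `ips_variance_share`: the
#' per-aptamer variance share rho solves
#' `share * p = n_ic * rho + n_spill * rho / 4`, capped at 0.97, so the
#' leading PC of the standardised log matrix carries about the requested
#' share of total variance.
#'
#' @param config a [cohort_config()] object.
#' @return A list of class `SyntheticCohort` with elements `abundance`
#'   (an [abundance_matrix()], raw positive scale), `sample_metadata`
#'   (data.frame: sample_id, age, sex, bmi, cohort, dataset, spin,
#'   kl_grade, womac_pain, blood_staining), `annotation` (data.frame:
#'   aptamer_id, gene, intracellular), `gene_sets` (named list of gene
#'   vectors, incl. a `PLANTED` set), `truth` (labels, contamination values,
#'   informative aptamer ids, per-outcome designations, config).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "CohortConfig")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  n <- config$n_discovery + config$n_replication
  p <- config$n_aptamers
  if (n < 2) stop("need at least 2 samples")
  sid <- sprintf("S%05d", seq_len(n))
  aid <- sprintf("seq.%05d", seq_len(p))

  ## annotation: intracellular flags, gene symbols (~2% of aptamers share a
  ## gene with another, emulating duplicate SOMAmers for one target)
  intracellular <- c(rep(TRUE, config$n_intracellular),
                     rep(FALSE, p - config$n_intracellular))
  gene_idx <- seq_len(p)
  n_dup <- floor(0.02 * p)
  if (n_dup >= 1) {
    dup_from <- sample(seq_len(p), n_dup)
    dup_to <- sample(setdiff(seq_len(p), dup_from), n_dup)
    gene_idx[dup_to] <- gene_idx[dup_from]
  }
  gene <- sprintf("GENE%05d", gene_idx)
  ## designated special aptamers: haemoglobin marker (intracellular) and a
  ## BMI-linked adipokine (extracellular)
  hb_j <- 1L; gene[hb_j] <- "HBA1"; intracellular[hb_j] <- TRUE
  adipo_j <- p             # last aptamer is extracellular by construction
  gene[adipo_j] <- "LEP"

  ## metadata
  age <- stats::rnorm(n, 64.46, 11.0)
  sex <- factor(ifelse(stats::runif(n) < 596 / 1134, "F", "M"), levels = c("F", "M"))
  bmi <- rnorm_trunc(n, 30.68, 5.92, lower = 15)
  dataset <- rep(c("Discovery", "Replication"),
                 c(config$n_discovery, config$n_replication))
  n_coh_d <- max(1L, round(config$n_cohorts *
                             config$n_discovery / max(n, 1L)))
  n_coh_r <- max(0L, config$n_cohorts - n_coh_d)
  cohort <- character(n)
  cohort[dataset == "Discovery"] <-
    paste0("C", sample(seq_len(n_coh_d), config$n_discovery, replace = TRUE))
  if (config$n_replication > 0)
    cohort[dataset == "Replication"] <-
      paste0("C", sample(n_coh_d + seq_len(max(n_coh_r, 1L)),
                         config$n_replication, replace = TRUE))
  spin <- ifelse(stats::runif(n) < config$prob_unspun, "unspun", "spun")
  blood <- sample(1:4, n, replace = TRUE, prob = c(394, 77, 26, 18) / 515)
  ## KL grade via a latent proportional-odds model (age and BMI shift the
  ## latent scale); thresholds give ~76% advanced (grades 3-4) as in knee-OA
  ## surgical cohorts
  eta <- 0.02 * (age - 64.46) + 0.03 * (bmi - 30.68)
  u <- eta + stats::rlogis(n)
  cuts <- stats::qlogis(c(0.03, 0.09, 0.24, 0.70))
  kl_grade <- as.integer(cut(u, c(-Inf, cuts, Inf), labels = FALSE)) - 1L
  womac_pain <- pmin(100, pmax(0, stats::rnorm(n, 44.91, 21.08)))

  ## endotype structure
  k <- config$k_endotypes
  labels <- if (k > 1) sample.int(k, n, replace = TRUE) else rep(1L, n)
  informative <- integer(0)
  if (k > 1 && config$frac_informative > 0) {
    pool <- setdiff(which(!intracellular), c(adipo_j))
    informative <- sort(sample(pool, min(length(pool),
                                         ceiling(config$frac_informative * p))))
  }

  ## contamination loadings calibrated to the target variance share
  cvec <- stats::rnorm(n)
  spill <- setdiff(which(!intracellular), adipo_j)
  spill <- spill[stats::runif(length(spill)) < config$spillover_frac]
  n_ic <- sum(intracellular)
  rho <- 0
  if (config$ips_variance_share > 0) {
    rho <- config$ips_variance_share * p / (n_ic + length(spill) / 4)
    if (rho > 0.97) {
      warning("ips_variance_share too large for the flagged aptamer count; capping")
      rho <- 0.97
    }
  }
  lambda <- numeric(p)
  lambda[intracellular] <- sqrt(rho / (1 - rho)) * config$noise_sd
  lambda[spill] <- sqrt((rho / 4) / (1 - rho / 4)) * config$noise_sd

  ## assemble log abundance
  mu <- stats::rnorm(p, 7, 0.8)
  X <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  unspun <- spin == "unspun"
  if (any(unspun)) X[unspun, ] <- X[unspun, ] * sqrt(config$batch_scale)
  X <- X + outer(cvec, lambda)
  X <- sweep(X, 2, mu, "+")

  if (length(informative)) {
    base_off <- config$endotype_separation * config$noise_sd *
      (seq_len(k) - (k + 1) / 2) / max(k - 1, 1)
    for (j in informative) X[, j] <- X[, j] + sample(base_off)[labels]
  }

  ## clinical covariate -> protein links
  effects <- list()
  taken <- c(informative, hb_j, adipo_j)
  for (nm in names(config$clinical_effects)) {
    ce <- config$clinical_effects[[nm]]
    if (is.null(ce) || ce$n_aptamers < 1) next
    val <- switch(nm,
                  kl_grade = kl_grade,
                  womac_pain = womac_pain,
                  stop("unknown clinical effect outcome: ", nm))
    pool <- setdiff(which(!intracellular), taken)
    js <- sort(sample(pool, min(length(pool), ce$n_aptamers)))
    taken <- c(taken, js)
    z <- as.numeric(scale(val))
    X[, js] <- X[, js] + (ce$effect * config$noise_sd) * z
    effects[[nm]] <- list(aptamers = aid[js], effect = ce$effect)
  }

  ## BMI-linked adipokine: coefficient chosen so corr(log abundance, BMI)
  ## approaches the target
  r <- config$adipokine_bmi_corr
  X[, adipo_j] <- X[, adipo_j] +
    (config$noise_sd * r / sqrt(1 - r^2)) * as.numeric(scale(bmi))
  ## blood-staining haemoglobin marker: additive shift per grade
  X[, hb_j] <- X[, hb_j] + 0.35 * (blood - 1)

  dimnames(X) <- list(sid, aid)
  annotation <- data.frame(aptamer_id = aid, gene = gene,
                           intracellular = intracellular,
                           stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = sid, age = age, sex = sex, bmi = bmi,
                         cohort = cohort, dataset = dataset, spin = spin,
                         kl_grade = kl_grade, womac_pain = womac_pain,
                         blood_staining = blood, stringsAsFactors = FALSE)

  ## planted-enriched gene set: endotype-informative genes when endotypes
  ## exist, else the KL-linked genes (the association-scan signal)
  planted_genes <- if (length(informative)) unique(gene[informative])
                   else unique(gene[match(effects$kl_grade$aptamers %||% character(0), aid)])
  gene_sets <- tryCatch(
    make_gene_sets(annotation, planted_genes,
                   seed = substream_seed(config$seed, "gene_sets")),
    error = function(e) list())

  structure(list(
    abundance = abundance_matrix(exp(X)),
    sample_metadata = metadata,
    annotation = annotation,
    gene_sets = gene_sets,
    truth = list(labels = labels,
                 contamination = cvec,
                 informative = aid[informative],
                 effects = effects,
                 adipokine = aid[adipo_j],
                 haemoglobin = aid[hb_j],
                 config = config)), class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d samples x %d aptamers (%d endotypes)\n",
              nrow(x$abundance$values), ncol(x$abundance$values),
              x$truth$config$k_endotypes))
  invisible(x)
}

#' Build a gene-set collection with one planted-enriched set
#'
#' Emits a GMT-compatible named list: a `PLANTED` set containing the genes
#' of the planted informative aptamers plus decoy sets drawn uniformly from
#' the annotation.
#'
#' @param annotation data.frame with a `gene` column.
#' @param planted_genes character vector of genes forming the planted set.
#' @param n_decoys number of decoy sets.
#' @param decoy_size genes per decoy set; default matches the planted size
#'   (at least 10).
#' @param seed RNG seed.
#' @return Named list of character gene vectors.
#' @export
make_gene_sets <- function(annotation, planted_genes, n_decoys = 5,
                           decoy_size = NULL, seed = 1L) {
  if (is.null(annotation) || nrow(annotation) == 0)
    stop("annotation is empty")
  genes <- unique(annotation$gene)
  planted_genes <- unique(planted_genes)
  if (length(planted_genes) == 0)
    stop("planted set requested but no informative genes available")
  if (!all(planted_genes %in% genes))
    stop("planted genes missing from annotation")
  decoy_size <- decoy_size %||% max(10L, length(planted_genes))
  if (decoy_size > length(genes))
    stop(sprintf("decoy size %d exceeds number of genes (%d)",
                 decoy_size, length(genes)))
  set.seed(seed)
  sets <- c(list(PLANTED = planted_genes),
            stats::setNames(lapply(seq_len(n_decoys), function(i)
              sample(genes, decoy_size)),
              if (n_decoys > 0) sprintf("DECOY_%02d", seq_len(n_decoys)) else NULL))
  sets
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `abundance.tsv` (wide, first column `sample_id`), `metadata.tsv`,
#' `annotation.tsv`, `gene_sets.gmt` and `truth.json` into `directory`.
#' Numeric values are serialised with 17 significant digits so a read-back
#' reproduces the matrix exactly.
#'
#' @param cohort a `SyntheticCohort`.
#' @param directory output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- c(abundance = file.path(directory, "abundance.tsv"),
             metadata = file.path(directory, "metadata.tsv"),
             annotation = file.path(directory, "annotation.tsv"),
             gene_sets = file.path(directory, "gene_sets.gmt"),
             truth = file.path(directory, "truth.json"))
  write_abundance(cohort$abundance, paths["abundance"])
  utils::write.table(cohort$sample_metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, paths["gene_sets"])
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
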