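#' Build a pipeline run configuration
#'
#' Either pass a named list of overrides or a path to a JSON file with the
#' same structure. A single global `seed` is fanned out to named substreams
#' per stage, so any stage rerun in isolation sees the same randomness.
#'
#' @param config named list or path to a JSON config file.
#' @return A validated `RunConfig` list with elements `seed`, `cohort`
#'   (arguments to [cohort_config()]), `preprocess` (`ips_regress`,
#'   `batch_column`), `cluster` (`k_max`, `n_init`, `threshold`,
#'   `variance_target`), `assoc` (list of outcome specs), `enrich`
#'   (`n_perm`, `min_size`), `power` (`enabled`, `scenarios`, `n_reps`).
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  def <- list(
    seed = 1L,
    cohort = list(n_discovery = 300L, n_replication = 300L,
                  n_aptamers = 500L, n_intracellular = 275L),
    preprocess = list(ips_regress = TRUE, batch_column = "spin"),
    cluster = list(k_max = 9L, n_init = 10L, threshold = 0.85,
                   variance_target = 0.80),
    assoc = list(list(outcome = "womac_pain", covariates = c("age", "sex"))),
    enrich = list(n_perm = 500L, min_size = 5L),
    power = list(enabled = TRUE,
                 scenarios = data.frame(n = 120L, k_endotypes = 2L,
                                        separation = 4, frac_informative = 0.1),
                 n_reps = 20L, n_aptamers = 150L))
  for (nm in names(config)) {
    if (is.list(def[[nm]]) && is.list(config[[nm]]) && nm != "assoc") {
      for (k in names(config[[nm]])) def[[nm]][[k]] <- config[[nm]][[k]]
    } else def[[nm]] <- config[[nm]]
  }
  structure(def, class = "RunConfig")
}

stage_hashes <- function(paths) {
  paths <- paths[grepl("\\.(tsv|json|gmt)$", paths) & file.exists(paths)]
  h <- tools::md5sum(paths)
  names(h) <- basename(names(h))
  as.list(h)
}

#' Run the full pipeline: simulate, preprocess, cluster, associate, enrich,
#' power
#'
#' Executes the six stages in ledger-enforced order on a synthetic cohort,
#' writing each stage's text outputs plus a `manifest.json` (config, seeds,
#' per-stage status, elapsed seconds, and md5 hashes of the text outputs).
#' Rerunning with an identical config reproduces all numeric outputs and
#' hashes.
#'
#' @param config a [run_config()] (or list / JSON path coerced through it).
#' @param out output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = run_config(), out) {
  if (!inherits(config, "RunConfig")) config <- run_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "sfendotyper",
                   version = as.character(utils::packageVersion("sfendotyper")),
                   seed = config$seed, stages = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    manifest$stages[[name]] <<- list(
      name = name, status = "completed",
      seed = substream_seed(config$seed, name),
      elapsed_s = round(proc.time()[3] - t0, 3),
      outputs = stage_hashes(res))
    res
  }

  ## 1. simulate
  coh <- NULL
  sim_paths <- run_stage("simulate", function() {
    cohort_args <- config$cohort
    cohort_args$seed <- substream_seed(config$seed, "simulate")
    coh <<- generate_cohort(do.call(cohort_config, cohort_args))
    write_cohort(coh, file.path(out, "simulate"))
  })

  ## 2. preprocess
  pre <- new.env()
  run_stage("preprocess", function() {
    d <- file.path(out, "preprocess"); dir.create(d, showWarnings = FALSE)
    m <- log_transform(coh$abundance)
    m <- median_normalize(m)
    batch <- coh$sample_metadata[[config$preprocess$batch_column]]
    if (length(unique(batch)) > 1) m <- batch_adjust_eb(m, batch)
    ips <- compute_ips(m, coh$annotation)
    pre$matrix <- m
    pre$ips <- ips
    pre$matrix_reg <- residualize(m, ips)
    write_abundance(m, file.path(d, "processed.tsv"))
    utils::write.table(data.frame(sample_id = names(ips$score), ips = ips$score),
                       file.path(d, "ips.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(m$ledger, file.path(d, "ledger.json"))
    file.path(d, c("processed.tsv", "ips.tsv", "ledger.json"))
  })

  ## 3. cluster (both without and with IPS regression)
  clus <- new.env()
  run_stage("cluster", function() {
    d <- file.path(out, "cluster"); dir.create(d, showWarnings = FALSE)
    paths <- character(0)
    for (variant in c("non_ips_regressed", "ips_regressed")) {
      m <- if (variant == "ips_regressed") pre$matrix_reg else pre$matrix
      res <- detect_endotypes(m,
                              variance_target = config$cluster$variance_target,
                              k_max = config$cluster$k_max,
                              n_init = config$cluster$n_init,
                              threshold = config$cluster$threshold,
                              seed = substream_seed(config$seed, paste0("cluster_", variant)))
      clus[[variant]] <- res
      pj <- file.path(d, paste0(variant, "_scan.json"))
      jsonlite::write_json(list(S = res$scan$S, a = res$scan$a, f = res$scan$f,
                                n_d = res$scan$n_d,
                                clustered = res$decision$clustered,
                                chosen_k = res$chosen_k,
                                votes = as.list(res$votes)),
                           pj, auto_unbox = TRUE, digits = NA)
      emb <- embed_2d(res$space, seed = substream_seed(config$seed, "embed"))
      lt <- data.frame(sample_id = rownames(emb), emb,
                       label = if (is.null(res$labels)) NA_integer_ else res$labels,
                       ips = pre$ips$score)
      pt <- file.path(d, paste0(variant, "_embedding.tsv"))
      utils::write.table(lt, pt, sep = "\t", quote = FALSE, row.names = FALSE)
      elbow_curve(res$scan, file.path(d, paste0(variant, "_elbow.png")))
      paths <- c(paths, pj, pt)
    }
    paths
  })

  ## 4. associate (per outcome; Discovery vs Replication with replication
  ## calls when both datasets are present)
  assoc_res <- list()
  run_stage("associate", function() {
    d <- file.path(out, "associate"); dir.create(d, showWarnings = FALSE)
    md <- coh$sample_metadata
    paths <- character(0)
    for (spec in config$assoc) {
      nm <- spec$outcome
      res_sets <- list()
      for (ds in intersect(c("Discovery", "Replication"), unique(md$dataset))) {
        i <- which(md$dataset == ds)
        mz <- standardize_per_protein(subset_samples(pre$matrix, i))
        res_sets[[ds]] <- fit_protein_association(
          mz, md[i, ], nm, covariates = spec$covariates %||% c("age", "sex"),
          annotation = coh$annotation)
        pth <- file.path(d, sprintf("%s_%s.tsv", nm, tolower(ds)))
        utils::write.table(res_sets[[ds]], pth, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, pth)
      }
      if (length(res_sets) == 2) {
        rc <- call_replication(res_sets$Discovery, res_sets$Replication)
        pth <- file.path(d, sprintf("%s_replication.tsv", nm))
        utils::write.table(rc, pth, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, pth)
      }
      assoc_res[[nm]] <<- res_sets
    }
    paths
  })

  ## 5. enrich (first outcome, first dataset scan)
  run_stage("enrich", function() {
    d <- file.path(out, "enrich"); dir.create(d, showWarnings = FALSE)
    first <- assoc_res[[1]][[1]]
    ranked <- build_ranked_list(first)
    er <- permutation_nes(ranked, coh$gene_sets,
                          n_perm = config$enrich$n_perm,
                          min_size = config$enrich$min_size,
                          seed = substream_seed(config$seed, "enrich"))
    pth <- file.path(d, "enrichment.tsv")
    utils::write.table(er, pth, sep = "\t", quote = FALSE, row.names = FALSE)
    pth
  })

  ## 6. power
  run_stage("power", function() {
    d <- file.path(out, "power"); dir.create(d, showWarnings = FALSE)
    if (!isTRUE(config$power$enabled)) return(character(0))
    grid <- power_grid(as.data.frame(config$power$scenarios),
                       n_reps = config$power$n_reps,
                       seed = substream_seed(config$seed, "power"))
    pr <- estimate_power(grid, n_aptamers = config$power$n_aptamers %||% 500)
    pth <- file.path(d, "power.tsv")
    utils::write.table(pr, pth, sep = "\t", quote = FALSE, row.names = FALSE)
    pth
  })

  manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
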