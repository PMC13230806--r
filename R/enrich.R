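#' Build a preranked gene list from association results
#'
#' Rank metric: `-log(p) * sign(effect)` (natural log). Genes measured by
#' several aptamers are collapsed to the entry with the smallest p; the list
#' is ordered by decreasing metric with lexicographic gene tie-break.
#' Zero p-values are clamped to the smallest positive double with a warning.
#'
#' @param associations `ProteinAssociation` data.frame carrying `gene`,
#'   `p` and `effect` (or `direction`).
#' @return A `RankedList` data.frame with columns `gene` and `metric`.
#' @export
build_ranked_list <- function(associations) {
  a <- as.data.frame(associations)
  if (!all(c("gene", "p") %in% names(a)))
    stop("associations need 'gene' and 'p' columns")
  dir <- if ("direction" %in% names(a)) a$direction else sign(a$effect)
  a <- a[!is.na(a$p) & !is.na(a$gene) & !is.na(dir), ]
  dir <- if ("direction" %in% names(a)) a$direction else sign(a$effect)
  if (any(a$p == 0)) {
    warning("p = 0 clamped to smallest positive double")
    a$p[a$p == 0] <- .Machine$double.xmin
  }
  ## collapse duplicate genes: keep smallest p
  o <- order(a$p, a$gene)
  a <- a[o, ]; dir <- dir[o]
  keep <- !duplicated(a$gene)
  a <- a[keep, ]; dir <- dir[keep]
  metric <- -log(a$p) * dir
  out <- data.frame(gene = a$gene, metric = metric, stringsAsFactors = FALSE)
  out <- out[order(-out$metric, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("RankedList", "data.frame")
  out
}

#' Running-sum enrichment score
#'
#' Walks the ranked list: set members increment the running sum by
#' `|metric|^exponent / N_R` (N_R sums that quantity over the members),
#' non-members decrement by `1 / (N - N_hits)`. The default ES is the
#' running-sum value of maximal absolute deviation from zero (signed);
#' `mode = "max"` uses the maximum value only. The leading edge is the set
#' members at or before the extremum (at or after, for a negative ES).
#'
#' @param ranked a `RankedList` (or data.frame with `gene`, `metric`).
#' @param gene_set character vector of genes.
#' @param exponent weighting exponent on |metric|.
#' @param mode `"signed"` (maximal absolute deviation, signed) or `"max"`.
#' @return List with `es`, `leading_edge`, `hits` (indices into the list).
#' @export
enrichment_score <- function(ranked, gene_set, exponent = 1,
                             mode = c("signed", "max")) {
  mode <- match.arg(mode)
  genes <- ranked$gene; metric <- ranked$metric
  hit <- genes %in% gene_set
  N <- length(genes); Nh <- sum(hit)
  if (Nh == 0) stop("gene set does not intersect the ranked list")
  w <- abs(metric)^exponent
  nr <- sum(w[hit])
  steps <- numeric(N)
  if (nr == 0) steps[hit] <- 1 / Nh else steps[hit] <- w[hit] / nr
  if (Nh < N) steps[!hit] <- -1 / (N - Nh)
  rs <- cumsum(steps)
  es <- if (mode == "max") max(rs) else rs[which.max(abs(rs))]
  hit_idx <- which(hit)
  le <- if (es >= 0) {
    ext <- if (mode == "max") which.max(rs) else which.max(abs(rs))
    genes[hit_idx[hit_idx <= ext]]
  } else {
    ext <- which.max(abs(rs))
    genes[hit_idx[hit_idx >= ext]]
  }
  list(es = es, leading_edge = le, hits = hit_idx)
}

#' Permutation-normalised enrichment scores
#'
#' For each gene set, draws `n_perm` random same-size gene sets from the
#' ranked list (gene-label permutation), computes null enrichment scores,
#' and reports NES = ES / mean(|null ES| of matching sign) with a
#' permutation p (proportion of same-sign null ES at least as extreme, +1
#' pseudo-count) and BH adjustment across sets.
#'
#' @param ranked a `RankedList`.
#' @param gene_sets named list of gene vectors.
#' @param n_perm permutations per set (>= 100).
#' @param seed RNG seed; results are reproducible given it.
#' @param min_size,max_size set-size bounds (genes present in the list);
#'   sets outside the bounds are skipped.
#' @param exponent passed to [enrichment_score()].
#' @return An `EnrichmentRecord` data.frame: set, size, es, nes, p, padj,
#'   leading_edge (comma-separated).
#' @export
permutation_nes <- function(ranked, gene_sets, n_perm = 1000, seed = 1L,
                            min_size = 10, max_size = 500, exponent = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives coarse permutation p-values")
  if (length(gene_sets) == 0 || is.null(names(gene_sets)))
    stop("gene_sets must be a named list")
  genes <- ranked$gene
  N <- length(genes)
  sizes <- vapply(gene_sets, function(s) sum(genes %in% s), integer(1))
  if (any(sizes > N)) stop("gene set larger than the ranked list")
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no gene sets within the size bounds")
  gene_sets <- gene_sets[keep]; sizes <- sizes[keep]

  set.seed(seed)
  out <- data.frame(set = names(gene_sets), size = sizes, es = NA_real_,
                    nes = NA_real_, p = NA_real_, padj = NA_real_,
                    leading_edge = NA_character_, stringsAsFactors = FALSE)
  ## cache null distributions per distinct size
  null_cache <- list()
  for (i in seq_along(gene_sets)) {
    obs <- enrichment_score(ranked, gene_sets[[i]], exponent)
    sz <- as.character(sizes[i])
    if (is.null(null_cache[[sz]])) {
      null_cache[[sz]] <- vapply(seq_len(n_perm), function(b)
        enrichment_score(ranked, sample(genes, sizes[i]), exponent)$es,
        numeric(1))
    }
    null_es <- null_cache[[sz]]
    same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    denom <- if (length(same)) mean(abs(same)) else mean(abs(null_es))
    out$es[i] <- obs$es
    out$nes[i] <- if (denom > 0) obs$es / denom else 0
    out$p[i] <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    out$leading_edge[i] <- paste(obs$leading_edge, collapse = ",")
  }
  out$padj <- bh_adjust(out$p)
  class(out) <- c("EnrichmentRecord", "data.frame")
  out
}
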