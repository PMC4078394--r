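# Marginal regression: the standard single-marker GWAS baseline.

#' Genome-wide marginal-regression scan
#'
#' Regresses the phenotype on every marker separately and records the
#' two-tailed t-test P-value of each slope (see [marginal_pvalues()]).
#'
#' @inheritParams marginal_pvalues
#' @return object of class `mr_scan` with `pvalues`.
#' @export
mr_scan <- function(A, y) {
  structure(list(pvalues = marginal_pvalues(A, y)), class = "mr_scan")
}

#' Threshold selection from a marginal scan
#'
#' Selects the markers with P-value strictly below the significance
#' threshold; ties at the cutoff are excluded.
#'
#' @param scan an [mr_scan()] (or a bare P-value vector).
#' @param threshold significance cutoff in (0, 1\].
#' @return integer vector of selected marker indices.
#' @export
mr_select <- function(scan, threshold) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  p <- if (inherits(scan, "mr_scan")) scan$pvalues else scan
  which(p < threshold)
}

#' Marginal-regression selection surfaces
#'
#' For every combination of sample size and P-value threshold: subsample
#' subjects, rerun the scan, select survivors, and score them with the
#' proximity-adjusted PPV and the threshold-adjusted median P-value. Cells
#' with no survivors carry `NA`, never 0.
#'
#' @param geno a [genotype_matrix()] pool of subjects.
#' @param model a [true_model()] (the phenotype is simulated per subsample
#'   at `model$h2`).
#' @param truth a [proximity_truth()] scoring reference.
#' @param thresholds vector of significance cutoffs.
#' @param n_values vector of sample sizes.
#' @param seed integer seed.
#' @return data frame with one row per (n, threshold) cell: `n_selected`,
#'   `ppv_star`, `mu_star`.
#' @export
mr_sweep <- function(geno, model, truth, thresholds, n_values, seed = 1) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(model, "true_model"))
  rows <- list()
  k <- 0
  for (i in seq_along(n_values)) {
    n <- n_values[i]
    rs <- derive_seed(seed, i)
    sub <- if (n < geno$n) {
      seed_rng(derive_seed(rs, 1))
      subset_subjects(geno, sample.int(geno$n, n), monomorphic = "zero")
    } else {
      geno
    }
    ph <- simulate_phenotype(sub, model, seed = derive_seed(rs, 2))
    scan <- mr_scan(sub, ph$y)
    for (thr in thresholds) {
      sel <- mr_select(scan, thr)
      ap <- adjusted_ppv(sub$markers[sel, , drop = FALSE], truth)
      k <- k + 1
      rows[[k]] <- data.frame(
        n = n, threshold = thr, n_selected = length(sel),
        ppv_star = ap$ppv_star,
        mu_star = adjusted_mu_pvalue(scan$pvalues, thr)
      )
    }
  }
  do.call(rbind, rows)
}

#' Overlap between two selected marker sets
#'
#' @param a,b integer index vectors (e.g. L1-selected and MR-selected
#'   supports on the same data).
#' @return list with `n_a`, `n_b`, `n_common`, `common`.
#' @export
selection_overlap <- function(a, b) {
  common <- intersect(a, b)
  list(n_a = length(a), n_b = length(b), n_common = length(common),
       common = sort(common))
}
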