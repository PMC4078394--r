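# Selection-quality measures, with and without knowledge of the true support.

#' Normalized coefficient error
#'
#' \eqn{NE = \|x - \hat x\|_2 / \|x\|_2}. Equals 0 for perfect recovery and 1
#' for the all-zero estimate.
#'
#' @param x_true true coefficient vector (must be nonzero).
#' @param x_hat estimated coefficient vector of the same length.
#' @return nonnegative scalar.
#' @export
normalized_error <- function(x_true, x_hat) {
  if (length(x_true) != length(x_hat)) stop("length mismatch")
  denom <- sqrt(sum(x_true^2))
  if (denom == 0) stop("true coefficient vector is identically zero")
  sqrt(sum((x_true - x_hat)^2)) / denom
}

#' Confusion-matrix selection measures
#'
#' False positive rate, positive predictive value, and false discovery rate
#' of a selected marker set against the true support. `ppv` and `fdr` are
#' `NA` for an empty selection, and `fpr` is `NA` when every marker is truly
#' nonzero — missingness is deliberate, never silently 0.
#'
#' @param true_support indices of truly nonzero markers.
#' @param selected indices returned by the selection procedure.
#' @param p total marker count.
#' @return list with `fpr`, `ppv`, `fdr`, `n_true_positive`, `n_selected`.
#' @export
confusion_metrics <- function(true_support, selected, p) {
  true_support <- unique(as.integer(true_support))
  selected <- unique(as.integer(selected))
  if (length(true_support) > 0 &&
      (min(true_support) < 1 || max(true_support) > p)) {
    stop("true_support outside 1..p")
  }
  if (length(selected) > 0 && (min(selected) < 1 || max(selected) > p)) {
    stop("selected outside 1..p")
  }
  tp <- length(intersect(selected, true_support))
  fp <- length(selected) - tp
  n_null <- p - length(true_support)
  fpr <- if (n_null > 0) fp / n_null else NA_real_
  ppv <- if (length(selected) > 0) tp / length(selected) else NA_real_
  list(fpr = fpr, ppv = ppv, fdr = 1 - ppv,
       n_true_positive = tp, n_selected = length(selected))
}

#' Single-marker regression P-values
#'
#' For each requested marker, simple linear regression of the phenotype on
#' that column (with intercept) and the two-tailed t-test P-value on the
#' slope, with n - 2 degrees of freedom. A constant column yields P = 1.
#'
#' @param A a [genotype_matrix()] or numeric matrix.
#' @param y phenotype vector.
#' @param indices marker subset (default: all columns).
#' @return numeric vector of P-values.
#' @export
marginal_pvalues <- function(A, y, indices = NULL) {
  S <- as_std_matrix(A)
  n <- nrow(S)
  if (n < 3) stop("need n >= 3")
  if (is.null(indices)) indices <- seq_len(ncol(S))
  if (length(indices) == 0) return(numeric(0))
  X <- S[, indices, drop = FALSE]
  yc <- y - mean(y)
  mx <- colMeans(X)
  sxx <- colSums(X^2) - n * mx^2
  sxy <- as.vector(crossprod(X, yc))
  syy <- sum(yc^2)
  out <- rep(1, length(indices))
  ok <- sxx > .Machine$double.eps * n
  b <- sxy[ok] / sxx[ok]
  rss <- pmax(syy - b * sxy[ok], 0)
  se2 <- rss / ((n - 2) * sxx[ok])
  tstat <- ifelse(se2 > 0, b / sqrt(se2), Inf * sign(b))
  out[ok] <- 2 * pt(-abs(tstat), df = n - 2)
  out
}

#' Median P-value of a selected set
#'
#' The median univariate-regression P-value over the selected markers, an
#' observable diagnostic of the selection phase transition: roughly uniform
#' P-values (median near 0.5) indicate that selections behave like noise,
#' while a collapse toward 0 indicates genuine signal.
#'
#' @param pvals P-values of the selected markers.
#' @return median (mean of the central two for even length); `NA` for an
#'   empty selection.
#' @export
mu_pvalue <- function(pvals) {
  if (length(pvals) == 0) return(NA_real_)
  median(pvals)
}

#' Proximity truth set
#'
#' Reference positions (e.g. externally validated trait-associated markers)
#' plus a basepair window; a selected marker within `window_bp` of any
#' reference position on the same chromosome counts as a true positive for
#' [adjusted_ppv()]. The window is inclusive: |distance| <= `window_bp`.
#'
#' @param chromosome character vector of reference chromosomes.
#' @param bp_position integer vector of reference positions (1-based).
#' @param window_bp window half-width in basepairs (default 500 kb).
#' @return object of class `proximity_truth`.
#' @export
proximity_truth <- function(chromosome, bp_position, window_bp = 500000L) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  if (length(chromosome) != length(bp_position)) stop("length mismatch")
  structure(list(
    reference = data.frame(chromosome = as.character(chromosome),
                           bp_position = as.integer(bp_position),
                           stringsAsFactors = FALSE),
    window_bp = as.integer(window_bp)
  ), class = "proximity_truth")
}

#' Read a proximity truth set from a file
#'
#' Accepts a 3+ column BED file (0-based half-open intervals; each interval
#' is converted to a 1-based point at its midpoint) or a two-column
#' (chromosome, bp) table with a header.
#'
#' @param path file path.
#' @param window_bp window half-width in basepairs.
#' @param format `"bed"` or `"table"`.
#' @return a [proximity_truth()].
#' @export
read_proximity_truth <- function(path, window_bp = 500000L,
                                 format = c("bed", "table")) {
  format <- match.arg(format)
  if (format == "bed") {
    b <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "integer", "integer", NA)[
                      seq_len(min(4, max(count.fields(path, sep = "\t"))))])
    mid <- floor((b[[2]] + b[[3]]) / 2) + 1L # 0-based half-open -> 1-based point
    proximity_truth(b[[1]], mid, window_bp)
  } else {
    b <- read.table(path, header = TRUE)
    proximity_truth(b[[1]], b[[2]], window_bp)
  }
}

# TRUE for each selected marker lying within the truth window
proximity_hits <- function(selected_markers, truth) {
  stopifnot(inherits(truth, "proximity_truth"))
  ref <- truth$reference
  vapply(seq_len(nrow(selected_markers)), function(i) {
    same <- ref$chromosome == selected_markers$chromosome[i]
    any(same & abs(ref$bp_position - selected_markers$bp_position[i]) <=
          truth$window_bp)
  }, logical(1))
}

#' Proximity-adjusted positive predictive value
#'
#' PPV* counts a selected marker as a true positive when it falls within the
#' truth window of any reference position on the same chromosome, crediting
#' selections that tag a causal region without hitting the exact marker.
#'
#' @param selected_markers data frame with columns `chromosome`,
#'   `bp_position` for the selected markers.
#' @param truth a [proximity_truth()].
#' @return list with `ppv_star` (`NA` for empty selection), `n_true_positive`,
#'   `n_selected`.
#' @export
adjusted_ppv <- function(selected_markers, truth) {
  n_sel <- nrow(selected_markers)
  if (n_sel == 0) {
    return(list(ppv_star = NA_real_, n_true_positive = 0L, n_selected = 0L))
  }
  hits <- proximity_hits(selected_markers, truth)
  list(ppv_star = sum(hits) / n_sel, n_true_positive = sum(hits),
       n_selected = n_sel)
}

#' Threshold-adjusted median P-value
#'
#' The median of the P-values falling strictly below the significance
#' threshold, divided by the threshold; near 0 when the survivors carry real
#' signal, near 0.5 when they are uniform false positives. `NA` when nothing
#' survives.
#'
#' @param pvals P-values.
#' @param threshold significance cutoff (> 0).
#' @return scalar in \[0, 1\] or `NA`.
#' @export
adjusted_mu_pvalue <- function(pvals, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  surv <- pvals[pvals < threshold]
  if (length(surv) == 0) return(NA_real_)
  median(surv) / threshold
}

#' Maximum LD of candidate markers to the true support
#'
#' For each candidate, the maximum over true nonzeros of the positive root of
#' the r-squared LD measure (i.e. |r|); used to show that false positives
#' tend to be in strong LD with true causal markers.
#'
#' @inheritParams marginal_pvalues
#' @param candidates candidate marker indices.
#' @param true_support indices of true nonzeros (nonempty).
#' @return numeric vector, one value per candidate.
#' @export
max_ld_to_truth <- function(A, candidates, true_support) {
  if (length(true_support) == 0) stop("true_support is empty")
  S <- as_std_matrix(A)
  if (length(candidates) == 0) return(numeric(0))
  C <- abs(cor(S[, candidates, drop = FALSE],
               S[, true_support, drop = FALSE]))
  apply(C, 1, max)
}

#' Null distribution of the proximity-adjusted PPV
#'
#' PPV* when `n_select` markers are drawn uniformly at random instead of
#' being returned by the selection algorithm; the reference for judging
#' whether an observed PPV* exceeds chance.
#'
#' @param markers marker data frame with `chromosome`, `bp_position`.
#' @param n_select number of markers drawn per replicate.
#' @param truth a [proximity_truth()].
#' @param reps number of replicates.
#' @param seed integer seed.
#' @return numeric vector of `reps` null PPV* values.
#' @export
null_adjusted_ppv <- function(markers, n_select, truth, reps = 1000,
                              seed = NULL) {
  p <- nrow(markers)
  if (n_select > p) stop("n_select exceeds the number of markers")
  seed_rng(seed)
  hits_all <- proximity_hits(markers, truth) # hit status is per-marker
  vapply(seq_len(reps), function(r) {
    idx <- sample.int(p, n_select)
    mean(hits_all[idx])
  }, numeric(1))
}
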