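# Replicate experiments over the sparsity-undersampling (rho, delta) plane,
# transition detection, and the asymptotic L1 recovery boundary.

#' One phase-plane experiment
#'
#' Runs `reps` independent replicates at a single design point: subsample `n`
#' subjects without replacement (re-standardizing within the subsample), draw
#' signed coefficients from the ensemble, place them on markers, simulate a
#' phenotype at heritability `h2`, fit the warm-started lasso path down to the
#' theoretical noise-dependent penalty floor (with `sigma_e2 = 1 - h2`), and
#' score the terminal selection with every metric. Replicates are aggregated
#' by the median.
#'
#' When `n` equals the full subject count the analyzed matrix is identical in
#' every replicate, so the Monte-Carlo penalty floor is evaluated once for the
#' point rather than once per replicate.
#'
#' @param geno a [genotype_matrix()] pool of subjects.
#' @param n subjects per replicate (<= `geno$n`).
#' @param s number of true nonzeros (<= `geno$p`).
#' @param h2 narrow-sense heritability in \[0, 1\].
#' @param ensemble `"signs"`, `"hyper1"`, or `"hyper2"`.
#' @param support_strategy `"uniform"` or `"maf_window"` (see
#'   [place_support()]).
#' @param maf_low,maf_high MAF window for `support_strategy = "maf_window"`.
#' @param reps number of replicates.
#' @param seed integer seed; replicate `r` runs on an independent substream.
#' @param config a [lasso_config()] (grid length, tolerance, noise draws).
#' @return object of class `phase_point`: design coordinates, a per-replicate
#'   metric data frame, and the median `aggregates`.
#' @export
run_experiment <- function(geno, n, s, h2, ensemble = "signs",
                           support_strategy = "uniform",
                           maf_low = 0, maf_high = 0.5,
                           reps = 5, seed = 1, config = lasso_config()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (n > geno$n) stop("n exceeds the subject pool")
  if (s > geno$p) stop("s exceeds p")
  p <- geno$p
  sigma_e2 <- 1 - h2
  full_sample <- (n == geno$n)
  lmin_cache <- if (full_sample) {
    lambda_min_theoretical(geno, sigma_e2, config$n_noise_draws,
                           seed = derive_seed(seed, 0))
  } else {
    NULL
  }
  spec <- ensemble_spec(ensemble, s = s, p = p)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    rs <- derive_seed(seed, r)
    sub <- if (full_sample) {
      geno
    } else {
      seed_rng(derive_seed(rs, 1))
      subset_subjects(geno, sample.int(geno$n, n), monomorphic = "zero")
    }
    vals <- draw_coefficients(spec, p, seed = derive_seed(rs, 2))
    x <- place_support(vals, sub, strategy = support_strategy,
                       maf_low = maf_low, maf_high = maf_high,
                       seed = derive_seed(rs, 3))
    model <- true_model(x, h2)
    ph <- simulate_phenotype(sub, model, seed = derive_seed(rs, 4))
    lmin <- if (full_sample) {
      lmin_cache
    } else {
      lambda_min_theoretical(sub, sigma_e2, config$n_noise_draws,
                             seed = derive_seed(rs, 5))
    }
    path <- lasso_path(sub, ph$y, config, lambda_min = lmin)
    sel <- lasso_select(path)
    conf <- confusion_metrics(model$support, sel$support, p)
    pv <- marginal_pvalues(sub, ph$y, sel$support)
    rows[[r]] <- data.frame(
      rep = r,
      ne = normalized_error(ph$x, sel$x_hat),
      fpr = conf$fpr, ppv = conf$ppv, fdr = conf$fdr,
      n_true_positive = conf$n_true_positive,
      n_selected = conf$n_selected,
      mu_pvalue = mu_pvalue(pv),
      lambda_max = path$lambda_max, lambda_min = path$lambda_min,
      converged = all(path$converged)
    )
  }
  replicates <- do.call(rbind, rows)
  agg_cols <- c("ne", "fpr", "ppv", "fdr", "mu_pvalue", "n_selected",
                "n_true_positive")
  aggregates <- vapply(agg_cols, function(cn) {
    median(replicates[[cn]], na.rm = TRUE)
  }, numeric(1))
  structure(list(
    delta = n / p, rho = s / n, n = n, s = s, p = p, h2 = h2,
    ensemble = ensemble, replicates = replicates, aggregates = aggregates,
    seed = seed
  ), class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  cat(sprintf(
    "phase_point: n=%d s=%d p=%d (delta=%.3f rho=%.4f) h2=%.2f, %d reps\n",
    x$n, x$s, x$p, x$delta, x$rho, x$h2, nrow(x$replicates)))
  print(round(x$aggregates, 4))
  invisible(x)
}

# shared scaffolding for the fixed-n and fixed-s scans
scan_points <- function(points, geno, h2, ensemble, support_strategy,
                        maf_low, maf_high, reps, seed, config) {
  res <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    res[[i]] <- run_experiment(
      geno, n = points$n[i], s = points$s[i], h2 = h2, ensemble = ensemble,
      support_strategy = support_strategy, maf_low = maf_low,
      maf_high = maf_high, reps = reps, seed = derive_seed(seed, i),
      config = config)
  }
  surface <- do.call(rbind, lapply(res, function(pt) {
    data.frame(n = pt$n, s = pt$s, delta = pt$delta, rho = pt$rho,
               t(pt$aggregates))
  }))
  list(points = res, surface = surface)
}

#' Sparsity scan at fixed sample size
#'
#' Sweeps the sparsity ratio \eqn{\rho = s/n} at fixed `n`, setting
#' `s = max(1, round(rho * n))` per grid value. The resulting median-NE curve
#' locates the selection phase transition via [detect_transition()].
#'
#' @inheritParams run_experiment
#' @param rhos increasing grid of target sparsity ratios.
#' @return list of class `phase_scan` with `surface` (one row per grid point,
#'   median metrics) and `points` (the underlying `phase_point`s).
#' @export
sweep_rho <- function(geno, n, rhos, h2, ensemble = "signs", reps = 3,
                      seed = 1, config = lasso_config(), ...) {
  s <- pmax(1L, as.integer(round(rhos * n)))
  pts <- data.frame(n = n, s = s)
  out <- scan_points(pts, geno, h2, ensemble, "uniform", 0, 0.5,
                     reps, seed, config)
  structure(c(out, list(scan = "rho")), class = "phase_scan")
}

#' Sample-size scan at fixed sparsity
#'
#' Sweeps `n` at fixed `s`, the design used to watch each selection measure
#' cross its own transition as the sample grows.
#'
#' @inheritParams run_experiment
#' @param ns increasing grid of sample sizes.
#' @param support_strategy,maf_low,maf_high passed to [run_experiment()].
#' @return a `phase_scan` (see [sweep_rho()]).
#' @export
sweep_n <- function(geno, ns, s, h2, ensemble = "signs",
                    support_strategy = "uniform", maf_low = 0,
                    maf_high = 0.5, reps = 3, seed = 1,
                    config = lasso_config()) {
  pts <- data.frame(n = as.integer(ns), s = as.integer(s))
  out <- scan_points(pts, geno, h2, ensemble, support_strategy,
                     maf_low, maf_high, reps, seed, config)
  structure(c(out, list(scan = "n")), class = "phase_scan")
}

#' Sweep a (delta, rho) grid
#'
#' Evaluates [run_experiment()] at each grid point with
#' `n = round(delta * p)` and `s = max(1, round(rho * n))`; stored
#' coordinates are recomputed from the rounded integers. Infeasible points
#' (n exceeding the subject pool, or n < 2) are skipped with a warning.
#'
#' @inheritParams run_experiment
#' @param grid data frame with columns `delta` and `rho`.
#' @return list of class `phase_plane` with `surface` and `points`.
#' @export
sweep_plane <- function(geno, grid, h2, ensemble = "signs", reps = 3,
                        seed = 1, config = lasso_config()) {
  p <- geno$p
  n <- as.integer(round(grid$delta * p))
  s <- pmax(1L, as.integer(round(grid$rho * n)))
  ok <- n >= 2 & n <= geno$n & s <= p
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " infeasible grid point(s)")
  }
  pts <- data.frame(n = n[ok], s = s[ok])
  out <- scan_points(pts, geno, h2, ensemble, "uniform", 0, 0.5,
                     reps, seed, config)
  structure(c(out, list(grid = grid[ok, , drop = FALSE])),
            class = "phase_plane")
}

#' Detect a selection phase transition along a scan
#'
#' Formalizes the transition criteria:
#' \describe{
#'   \item{`"ne_rho"`}{largest \eqn{\rho} whose median NE is below `cut`
#'     (default 0.5), linearly interpolated between the last sub-`cut` grid
#'     point and its successor; censored at the scan edge when every NE is
#'     below `cut`.}
#'   \item{`"ne_n"`}{the sample size at which NE first drops below `cut`,
#'     interpolated between the bracketing grid points.}
#'   \item{`"mu_n"`}{the smallest scanned value at which the normalized
#'     median P-value (divided by its maximum over the scan) falls below
#'     `frac` and stays below for the rest of the scan — i.e. the last
#'     downward crossing, robust to the characteristic rise-then-fall of the
#'     median P-value across the transition.}
#' }
#'
#' @param x scan coordinate (rho or n), increasing.
#' @param values metric values at `x` (median NE or median P-value).
#' @param criterion one of `"ne_rho"`, `"ne_n"`, `"mu_n"`.
#' @param cut NE threshold (default 0.5).
#' @param frac sustained-drop fraction for `"mu_n"` (default 0.05).
#' @return list with `critical` (`NA` when the criterion is never met),
#'   `censored`, and the scan (`x`, `values`).
#' @export
detect_transition <- function(x, values, criterion = c("ne_rho", "ne_n",
                                                       "mu_n"),
                              cut = 0.5, frac = 0.05) {
  criterion <- match.arg(criterion)
  if (length(x) < 3) stop("need at least 3 scan points")
  if (is.unsorted(x)) stop("scan coordinate must be increasing")
  K <- length(x)
  out <- list(critical = NA_real_, censored = FALSE, x = x, values = values)

  if (criterion == "ne_rho") {
    below <- values < cut
    if (!any(below)) return(out)
    i <- max(which(below))
    if (i == K) {
      out$critical <- x[K]
      out$censored <- TRUE
    } else {
      out$critical <- x[i] +
        (cut - values[i]) / (values[i + 1] - values[i]) * (x[i + 1] - x[i])
    }
  } else if (criterion == "ne_n") {
    below <- values < cut
    if (!any(below)) return(out)
    i <- min(which(below))
    if (i == 1) {
      out$critical <- x[1]
      out$censored <- TRUE
    } else {
      out$critical <- x[i - 1] +
        (cut - values[i - 1]) / (values[i] - values[i - 1]) *
          (x[i] - x[i - 1])
    }
  } else {
    mx <- max(values, na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) return(out)
    good <- values / mx < frac
    good[is.na(good)] <- FALSE
    sustained <- rev(cumprod(rev(good))) == 1
    if (!any(sustained)) return(out)
    i <- min(which(sustained))
    out$critical <- x[i]
    out$censored <- i == 1
  }
  out
}

#' Detect convergence of the selection measures along a sample-size scan
#'
#' Two rules. `"absolute"`: the smallest scanned `n` from which PPV stays
#' above `ppv_min`, FPR (when given) stays below `fpr_max`, and the
#' normalized median P-value stays below `mu_frac` — the good-recovery
#' corner. `"plateau"`: the smallest `n` from which PPV stays within
#' `plateau_tol` of its value at the largest `n` and the normalized median
#' P-value stays below `mu_frac` — convergence to the asymptote without
#' presuming its level.
#'
#' @param n increasing sample-size grid.
#' @param ppv median PPV at each `n`.
#' @param mu median P-value at each `n`.
#' @param fpr optional median FPR at each `n`.
#' @param rule `"absolute"` or `"plateau"`.
#' @param ppv_min,fpr_max,mu_frac,plateau_tol rule thresholds.
#' @return list with `critical` (`NA` if never reached) and `censored`
#'   (TRUE when the conditions hold from the first scanned point).
#' @export
detect_convergence <- function(n, ppv, mu, fpr = NULL,
                               rule = c("absolute", "plateau"),
                               ppv_min = 0.95, fpr_max = 0.001,
                               mu_frac = 0.05, plateau_tol = 0.05) {
  rule <- match.arg(rule)
  K <- length(n)
  if (is.unsorted(n)) stop("n must be increasing")
  mx <- max(mu, na.rm = TRUE)
  mu_ok <- if (is.finite(mx) && mx > 0) mu / mx < mu_frac else rep(TRUE, K)
  ppv_ok <- if (rule == "absolute") {
    ppv > ppv_min
  } else {
    abs(ppv - ppv[K]) <= plateau_tol
  }
  good <- mu_ok & ppv_ok
  if (!is.null(fpr) && rule == "absolute") good <- good & (fpr < fpr_max)
  good[is.na(good)] <- FALSE
  sustained <- rev(cumprod(rev(good))) == 1
  if (!any(sustained)) {
    return(list(critical = NA_real_, censored = FALSE))
  }
  i <- min(which(sustained))
  list(critical = n[i], censored = i == 1)
}

#' Asymptotic L1 recovery boundary
#'
#' The weak phase-transition curve \eqn{\rho_{L1}(\delta)} for noiseless
#' recovery of signed sparse vectors by L1 minimization under Gaussian
#' sensing, evaluated from its variational Gaussian-integral form
#' \deqn{\rho(\delta) = \max_{z \ge 0} \frac{1 - (2/\delta)\,[(1+z^2)\Phi(-z)
#'   - z\phi(z)]}{1 + z^2 - 2[(1+z^2)\Phi(-z) - z\phi(z)]}.}
#' Designs below the curve (\eqn{\rho < \rho_{L1}(\delta)}) recover the full
#' support with probability approaching one as the problem grows; designs
#' above it fail.
#'
#' @param delta undersampling ratio(s) n/p, each in (0, 1).
#' @return \eqn{\rho_{L1}(\delta)}, vectorized over `delta`.
#' @export
theoretical_boundary <- function(delta) {
  if (any(delta <= 0 | delta >= 1)) stop("delta must lie in (0, 1)")
  one <- function(d) {
    obj <- function(z) {
      m <- (1 + z^2) * pnorm(-z) - z * dnorm(z)
      (1 - 2 * m / d) / (1 + z^2 - 2 * m)
    }
    optimize(obj, c(0, 20), maximum = TRUE, tol = 1e-10)$objective
  }
  vapply(delta, one, numeric(1))
}

#' Rule-of-thumb minimal sample size
#'
#' Inverts the empirical critical sparsity ratio: full selection needs
#' \eqn{s/n \le \rho_{crit}}, i.e. \eqn{n \ge s/\rho_{crit}}. At the noisy
#' (heritability 0.5) critical ratio of about 0.03 this is the
#' "n of roughly 30 times s" rule.
#'
#' @param s assumed number of nonzero coefficients.
#' @param rho_crit critical sparsity ratio (default 0.03).
#' @return minimal sample size, rounded up.
#' @export
min_sample_size <- function(s, rho_crit = 0.03) {
  if (rho_crit <= 0) stop("rho_crit must be > 0")
  ceiling(s / rho_crit)
}
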