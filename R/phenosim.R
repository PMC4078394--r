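#' Coefficient-ensemble specification
#'
#' Describes how the `s` nonzero effect sizes are generated. Two families:
#' `"signs"` draws every magnitude equal to 1; the hyperexponential families
#' give the rank-`i` magnitude as the sum of two exponential decays with equal
#' amplitude, \eqn{\exp(-i/\tau_1) + \exp(-i/\tau_2)}, for \eqn{i = 1..s} —
#' a few large effects followed by a long tail of weak ones. Presets:
#' `"hyper1"` uses \eqn{(\tau_1, \tau_2) = (0.05 s, p)} and `"hyper2"` uses
#' \eqn{(0.2 s, p)}. In every ensemble exactly `floor(s/2)` coefficients are
#' flipped negative, at positions chosen uniformly at random.
#'
#' @param kind one of `"signs"`, `"hyper1"`, `"hyper2"`, or
#'   `"hyperexponential"` with explicit `tau1`, `tau2`.
#' @param s number of nonzero coefficients (>= 1).
#' @param p total marker count (sets the slow decay constant of the presets).
#' @param tau1,tau2 decay constants, only for `kind = "hyperexponential"`.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(kind = c("signs", "hyper1", "hyper2",
                                   "hyperexponential"),
                          s, p, tau1 = NULL, tau2 = NULL) {
  kind <- match.arg(kind)
  if (s < 1) stop("s must be >= 1")
  spec <- list(kind = kind, s = as.integer(s))
  if (kind == "hyper1") {
    spec$tau1 <- 0.05 * s
    spec$tau2 <- p
  } else if (kind == "hyper2") {
    spec$tau1 <- 0.2 * s
    spec$tau2 <- p
  } else if (kind == "hyperexponential") {
    if (is.null(tau1) || is.null(tau2) || tau1 <= 0 || tau2 <= 0) {
      stop("hyperexponential ensembles need tau1 > 0 and tau2 > 0")
    }
    spec$tau1 <- tau1
    spec$tau2 <- tau2
  }
  structure(spec, class = "ensemble_spec")
}

#' Draw signed coefficient magnitudes from an ensemble
#'
#' Magnitudes follow the ensemble's deterministic rank curve (all 1 for
#' `"signs"`; strictly decreasing for the hyperexponential families); exactly
#' `floor(s/2)` entries, chosen uniformly at random, are made negative.
#'
#' @param spec an [ensemble_spec()].
#' @param p total marker count; must satisfy `s <= p`.
#' @param seed integer seed for the sign assignment.
#' @return numeric vector of length `s` (rank order, signed).
#' @export
draw_coefficients <- function(spec, p, seed = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  s <- spec$s
  if (s > p) stop("s (", s, ") exceeds p (", p, ")")
  seed_rng(seed)
  mags <- if (spec$kind == "signs") {
    rep(1, s)
  } else {
    i <- seq_len(s)
    exp(-i / spec$tau1) + exp(-i / spec$tau2)
  }
  n_neg <- floor(s / 2)
  if (n_neg > 0) {
    neg <- sample.int(s, n_neg)
    mags[neg] <- -mags[neg]
  }
  mags
}

#' Place nonzero coefficients on markers
#'
#' Assigns the `s` signed coefficient values to marker positions sampled
#' without replacement, either uniformly over all `p` markers or restricted to
#' a MAF window (used to test whether the allele-frequency spectrum of the
#' causal set moves the selection phase boundary).
#'
#' @param values signed coefficients from [draw_coefficients()].
#' @param geno a [genotype_matrix()] (supplies `p` and the MAF per marker).
#' @param strategy `"uniform"` or `"maf_window"`.
#' @param maf_low,maf_high inclusive MAF window bounds for
#'   `strategy = "maf_window"`.
#' @param seed integer seed.
#' @return length-`p` coefficient vector with attribute `"support"` (the
#'   sampled indices, in assignment order).
#' @export
place_support <- function(values, geno, strategy = c("uniform", "maf_window"),
                          maf_low = 0, maf_high = 0.5, seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(geno, "genotype_matrix"))
  s <- length(values)
  p <- geno$p
  eligible <- if (strategy == "uniform") {
    seq_len(p)
  } else {
    which(geno$markers$maf >= maf_low & geno$markers$maf <= maf_high)
  }
  if (length(eligible) < s) {
    stop("only ", length(eligible), " eligible markers for s = ", s)
  }
  seed_rng(seed)
  support <- if (length(eligible) == 1) eligible else sample(eligible, s)
  x <- numeric(p)
  x[support] <- values
  attr(x, "support") <- support
  x
}

#' Bundle a true sparse model
#'
#' @param x length-`p` coefficient vector (typically from [place_support()]).
#' @param h2 target narrow-sense heritability in \[0, 1\]; the residual
#'   variance is `1 - h2`.
#' @return an object of class `true_model` with `x`, `support`, `s`, `h2`,
#'   `sigma_e2`.
#' @export
true_model <- function(x, h2) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  support <- attr(x, "support")
  if (is.null(support)) support <- which(x != 0)
  structure(
    list(x = as.numeric(x), support = sort(support),
         s = length(support), h2 = h2, sigma_e2 = 1 - h2),
    class = "true_model"
  )
}

#' Simulate a phenotype at a target heritability
#'
#' Forms breeding values \eqn{g_0 = Ax}, rescales them so their empirical
#' (1/n) variance equals `h2` exactly, and adds i.i.d. Gaussian residuals of
#' variance `1 - h2`. The phenotype `y = g + e` is not rescaled afterward, so
#' its variance is 1 in expectation but not exactly per realization.
#'
#' Because the breeding values are rescaled, the coefficient vector that
#' actually relates `y` to the standardized design is the rescaled
#' \eqn{c\,x} with \eqn{c = \sqrt{h^2/\widehat{Var}(Ax)}}; it is returned as
#' `x` and is the ground truth against which estimates (and the normalized
#' error) must be compared.
#'
#' @param geno a [genotype_matrix()] (standardized design).
#' @param model a [true_model()].
#' @param seed integer seed.
#' @return list with `y`, `g` (scaled breeding values), `x` (effective
#'   length-p coefficient vector on the phenotype scale), `scale` (the factor
#'   c), `realized_h2`.
#' @export
simulate_phenotype <- function(geno, model, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(model, "true_model"))
  if (length(model$x) != geno$p) stop("coefficient vector length != p")
  n <- geno$n
  sup <- model$support
  g0 <- if (length(sup) > 0) {
    as.vector(geno$std[, sup, drop = FALSE] %*% model$x[sup])
  } else {
    numeric(n)
  }
  v0 <- mean(g0^2) - mean(g0)^2
  if (model$h2 > 0 && v0 <= 0) {
    stop("breeding values identically zero with h2 > 0")
  }
  cscale <- if (model$h2 > 0) sqrt(model$h2 / v0) else 0
  g <- g0 * cscale
  seed_rng(seed)
  e <- rnorm(n, 0, sqrt(model$sigma_e2))
  list(y = g + e, g = g, x = model$x * cscale, scale = cscale,
       realized_h2 = mean(g^2) - mean(g)^2)
}
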