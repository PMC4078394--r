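#' Column-standardize a raw genotype matrix
#'
#' Centers and scales every column of a 0/1/2 dosage matrix to zero mean and
#' unit variance under the population (1/n) variance convention, computing both
#' moments over the non-missing entries only. Entries that were missing are set
#' to exactly 0 (the column mean) after standardization, so they contribute
#' nothing to inner products with the phenotype.
#'
#' With no missing entries every standardized column satisfies
#' \eqn{\|A_j\|^2 = n} exactly, which is the normalization assumed by the
#' coordinate-descent update in [coordinate_descent()].
#'
#' @param raw integer or numeric matrix, subjects in rows, markers in columns;
#'   missing genotypes as `NA`.
#' @param marker_ids optional character vector used to name offending columns
#'   in error messages.
#' @return numeric matrix of the same dimension.
#' @examples
#' standardize_genotypes(cbind(m1 = c(0L, 1L, 2L), m2 = c(0L, 2L, NA)))
#' @export
standardize_genotypes <- function(raw, marker_ids = colnames(raw)) {
  if (!is.matrix(raw)) stop("`raw` must be a matrix")
  n <- nrow(raw)
  p <- ncol(raw)
  if (is.null(marker_ids)) marker_ids <- as.character(seq_len(p))
  raw <- matrix(as.numeric(raw), n, p)
  miss <- is.na(raw)
  n_obs <- n - colSums(miss)
  work <- raw
  work[miss] <- 0
  mu <- colSums(work) / n_obs
  # population variance over non-missing entries
  v <- colSums(work^2) / n_obs - mu^2
  v[v < 0] <- 0
  bad <- which(v <= 0 | n_obs < 2)
  if (length(bad) > 0) {
    stop("monomorphic or all-missing column(s): ",
         paste(marker_ids[bad], collapse = ", "))
  }
  std <- sweep(raw, 2, mu, "-")
  std <- sweep(std, 2, sqrt(v), "/")
  std[miss] <- 0
  dimnames(std) <- dimnames(raw)
  std
}

#' Construct a genotype-matrix object
#'
#' Bundles a raw dosage matrix, its standardized counterpart (the sensing
#' matrix of the linear model \eqn{y = Ax + e}), and per-marker metadata.
#'
#' @param raw integer matrix of 0/1/2 dosages with `NA` for missing.
#' @param markers data frame with columns `marker_id`, `chromosome`,
#'   `bp_position`; a `maf` column is recomputed from the data if absent.
#' @return an object of class `genotype_matrix` with elements `raw`, `std`,
#'   `n`, `p`, `markers`.
#' @export
genotype_matrix <- function(raw, markers = NULL) {
  n <- nrow(raw)
  p <- ncol(raw)
  if (is.null(markers)) {
    markers <- data.frame(
      marker_id = sprintf("snp%d", seq_len(p)),
      chromosome = "1",
      bp_position = seq_len(p) * 10000L,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(markers) == p)
  if (anyDuplicated(markers$marker_id) > 0) stop("duplicate marker ids")
  if (any(markers$bp_position < 1)) stop("bp positions must be >= 1")
  raw <- matrix(as.integer(raw), n, p)
  freq <- colMeans(raw, na.rm = TRUE) / 2
  markers$maf <- pmin(freq, 1 - freq)
  if (any(markers$maf <= 0)) {
    stop("monomorphic marker(s): ",
         paste(markers$marker_id[markers$maf <= 0], collapse = ", "))
  }
  std <- standardize_genotypes(raw, markers$marker_id)
  structure(
    list(raw = raw, std = std, n = n, p = p, markers = markers),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d markers\n", x$n, x$p))
  cat(sprintf("  MAF range: %.4f - %.4f\n",
              min(x$markers$maf), max(x$markers$maf)))
  cat(sprintf("  missing genotypes: %d\n", sum(is.na(x$raw))))
  invisible(x)
}

# Accept either a genotype_matrix or a bare standardized matrix.
as_std_matrix <- function(A) {
  if (inherits(A, "genotype_matrix")) A$std
  else if (is.matrix(A)) A
  else stop("expected a genotype_matrix or a numeric matrix")
}

#' Simulate a SNP genotype matrix
#'
#' Draws dosages per marker as Binomial(2, MAF) across subjects. Columns are
#' either independent or organized in contiguous blocks of linked markers: all
#' markers of a block share one MAF and each is a per-entry mixture that copies
#' a latent block dosage with probability \eqn{\sqrt{r}} (fresh draw
#' otherwise), giving pairwise genotype correlation approximately `r` within
#' the block. Markers are placed at fixed spacing on one synthetic chromosome.
#'
#' @param n subject count (>= 2).
#' @param p marker count (>= 1).
#' @param maf either a length-2 vector giving a uniform MAF range in (0, 0.5],
#'   or a length-`p` vector of explicit MAFs.
#' @param ld `"independent"`, or a list with `block_size` and `r` (target
#'   within-block pairwise correlation).
#' @param spacing_bp basepair spacing between adjacent markers.
#' @param seed integer seed.
#' @param max_retries redraws allowed for a simulated monomorphic column
#'   before erroring.
#' @return a [genotype_matrix()].
#' @examples
#' g <- simulate_genotypes(200, 10, maf = c(0.1, 0.5), seed = 1)
#' @export
simulate_genotypes <- function(n, p, maf = c(0.05, 0.5), ld = "independent",
                               spacing_bp = 10000L, seed = NULL,
                               max_retries = 50L) {
  if (n < 2 || p < 1) stop("need n >= 2 and p >= 1")
  seed_rng(seed)
  if (length(maf) == 1) {
    mafs <- rep(as.numeric(maf), p)
  } else if (length(maf) == 2) {
    mafs <- runif(p, maf[1], maf[2]) # (low, high) uniform range
  } else if (length(maf) == p) {
    mafs <- as.numeric(maf)
  } else {
    stop("`maf` must be one value, a (low, high) range, or one value per marker")
  }
  if (any(mafs <= 0 | mafs > 0.5)) stop("MAF must lie in (0, 0.5]")

  draw_col <- function(f) {
    for (i in seq_len(max_retries)) {
      g <- rbinom(n, 2L, f)
      if (length(unique(g)) > 1) return(g)
    }
    stop("could not draw a polymorphic column at MAF ", f,
         " after ", max_retries, " tries")
  }

  raw <- matrix(0L, n, p)
  if (identical(ld, "independent")) {
    for (j in seq_len(p)) raw[, j] <- draw_col(mafs[j])
  } else {
    if (!is.list(ld) || is.null(ld$block_size) || is.null(ld$r)) {
      stop("`ld` must be \"independent\" or list(block_size=, r=)")
    }
    k <- as.integer(ld$block_size)
    a <- sqrt(ld$r) # per-marker copy probability; pairwise cor = a^2 = r
    if (ld$r < 0 || ld$r > 1) stop("LD target r must lie in [0, 1]")
    starts <- seq(1L, p, by = k)
    for (b in starts) {
      cols <- b:min(b + k - 1L, p)
      f <- mafs[cols[1]]
      mafs[cols] <- f # one MAF per block
      for (i in seq_len(max_retries)) {
        latent <- rbinom(n, 2L, f)
        blk <- vapply(cols, function(j) {
          keep <- runif(n) < a
          g <- ifelse(keep, latent, rbinom(n, 2L, f))
          as.integer(g)
        }, integer(n))
        if (all(apply(blk, 2, function(g) length(unique(g)) > 1))) break
        if (i == max_retries) {
          stop("could not draw a polymorphic block at MAF ", f)
        }
      }
      raw[, cols] <- blk
    }
  }
  markers <- data.frame(
    marker_id = sprintf("snp%d", seq_len(p)),
    chromosome = "1",
    bp_position = as.integer(seq_len(p)) * as.integer(spacing_bp),
    stringsAsFactors = FALSE
  )
  genotype_matrix(raw, markers)
}

#' Subset subjects and re-standardize
#'
#' Extracts a subject subsample and re-standardizes each column within the
#' subsample, so column norms are exact for the solver. A marker that is
#' polymorphic in the pool can be monomorphic within a small subsample
#' (likely for rare alleles); `monomorphic = "zero"` maps such columns to
#' all zeros — excluding them from that subsample's analysis without
#' reindexing the markers — while the default errors as
#' [standardize_genotypes()] does.
#'
#' @param geno a [genotype_matrix()].
#' @param rows integer vector of subject indices.
#' @param monomorphic `"error"` or `"zero"`.
#' @return a [genotype_matrix()] on the subsample.
#' @export
subset_subjects <- function(geno, rows, monomorphic = c("error", "zero")) {
  monomorphic <- match.arg(monomorphic)
  stopifnot(inherits(geno, "genotype_matrix"))
  raw <- geno$raw[rows, , drop = FALSE]
  if (monomorphic == "error") {
    return(genotype_matrix(raw, geno$markers))
  }
  n <- nrow(raw)
  work <- matrix(as.numeric(raw), n, ncol(raw))
  miss <- is.na(work)
  work[miss] <- 0
  n_obs <- n - colSums(miss)
  mu <- colSums(work) / n_obs
  v <- colSums(work^2) / n_obs - mu^2
  v[v < 0] <- 0
  dead <- v <= 0 | n_obs < 2
  scale <- ifelse(dead, 1, sqrt(v))
  std <- sweep(matrix(as.numeric(raw), n, ncol(raw)), 2, mu, "-")
  std <- sweep(std, 2, scale, "/")
  std[miss] <- 0
  std[, dead] <- 0
  markers <- geno$markers
  freq <- colMeans(raw, na.rm = TRUE) / 2
  markers$maf <- ifelse(dead, 0, pmin(freq, 1 - freq))
  structure(
    list(raw = raw, std = std, n = n, p = ncol(raw), markers = markers),
    class = "genotype_matrix"
  )
}

#' Coherence of a standardized genotype matrix
#'
#' The smallest \eqn{\gamma} bounding every squared entry of the standardized
#' matrix, i.e. \eqn{\max_{ij} a_{ij}^2}. Rare alleles inflate coherence
#' because the standardized dosage of a minor-allele homozygote grows like
#' \eqn{1/\sqrt{\mathrm{MAF}}}; low-MAF pruning keeps a genotype matrix
#' incoherent enough for sparse recovery.
#'
#' @param A a [genotype_matrix()] or standardized matrix.
#' @return nonnegative scalar.
#' @export
coherence <- function(A) {
  max(as_std_matrix(A)^2)
}

#' Deviation from isotropy
#'
#' Maximum absolute off-diagonal entry of \eqn{A'A/n}, a diagnostic for
#' linkage equilibrium: independent markers give values shrinking like
#' \eqn{1/\sqrt{n}}, while linked markers pin entries near their LD
#' correlation.
#'
#' @inheritParams coherence
#' @return nonnegative scalar (0 for exactly orthogonal columns).
#' @export
isotropy_deviation <- function(A) {
  S <- as_std_matrix(A)
  G <- crossprod(S) / nrow(S)
  diag(G) <- 0
  max(abs(G))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between two standardized marker columns.
#'
#' @inheritParams coherence
#' @param j,k marker indices.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(A, j, k) {
  S <- as_std_matrix(A)
  if (j == k) return(1)
  cor(S[, j], S[, k])^2
}

#' Full LD r-squared surface
#'
#' @inheritParams coherence
#' @param indices optional marker subset.
#' @return symmetric matrix of squared correlations.
#' @export
ld_matrix <- function(A, indices = NULL) {
  S <- as_std_matrix(A)
  if (!is.null(indices)) S <- S[, indices, drop = FALSE]
  cor(S)^2
}
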