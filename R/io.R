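# Genotype file input/output: PLINK binary (bed/bim/fam) and delimited text.
#
# The bed codec is the SNP-major 2-bit layout: magic bytes 0x6c 0x1b 0x01,
# then ceil(n/4) bytes per marker, subject i of a byte occupying bits
# 2i..2i+1 (low to high). Two-bit codes count copies of allele A1 (the
# minor allele here): 00 = 2 copies, 10 = 1, 11 = 0, 01 = missing.

#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix; writes `prefix.bed`, `.bim`, `.fam`.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- geno$n
  p <- geno$p
  code <- matrix(3L, n, p) # dosage 0 -> 11
  code[geno$raw == 1L] <- 2L # het -> 10
  code[geno$raw == 2L] <- 0L # hom minor -> 00
  code[is.na(geno$raw)] <- 1L # missing -> 01
  n_bytes <- ceiling(n / 4)
  pad <- n_bytes * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, p))
  # pack 4 subjects per byte, low bits first
  i1 <- seq(1, n_bytes * 4, by = 4)
  bytes <- code[i1, , drop = FALSE] +
    4L * code[i1 + 1, , drop = FALSE] +
    16L * code[i1 + 2, , drop = FALSE] +
    64L * code[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  bim <- data.frame(
    chrom = geno$markers$chromosome,
    id = geno$markers$marker_id,
    cm = 0,
    bp = geno$markers$bp_position,
    a1 = "A", a2 = "B"
  )
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(
    fid = sprintf("F%d", seq_len(n)), iid = sprintf("I%d", seq_len(n)),
    pid = 0, mid = 0, sex = 0, pheno = -9
  )
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK bed/bim/fam genotypes
#'
#' @param prefix path prefix of the `.bed`, `.bim`, `.fam` triple.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), sep = "\t",
                    col.names = c("chrom", "id", "cm", "bp", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paste0(prefix, ".fam"), sep = "\t")
  n <- nrow(fam)
  p <- nrow(bim)
  n_bytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK bed file: ", prefix, ".bed")
  }
  body <- readBin(con, "raw", n_bytes * p)
  if (length(body) != n_bytes * p) stop("truncated bed file")
  v <- as.integer(body)
  # unpack 2-bit fields, low bits first
  codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, v %/% 64L)
  codes <- matrix(as.vector(codes), n_bytes * 4, p)[seq_len(n), , drop = FALSE]
  raw <- matrix(NA_integer_, n, p)
  raw[codes == 0L] <- 2L
  raw[codes == 2L] <- 1L
  raw[codes == 3L] <- 0L
  markers <- data.frame(
    marker_id = bim$id, chromosome = bim$chrom, bp_position = bim$bp,
    stringsAsFactors = FALSE
  )
  genotype_matrix(raw, markers)
}

#' Write genotypes as delimited text
#'
#' Writes `prefix.geno.tsv` (subjects x markers dosage matrix) and
#' `prefix.markers.tsv` (marker_id, chromosome, bp_position).
#'
#' @param geno a [genotype_matrix()].
#' @param prefix output path prefix.
#' @param missing token used for missing genotypes.
#' @return the prefix, invisibly.
#' @export
write_geno_text <- function(geno, prefix, missing = "NA") {
  stopifnot(inherits(geno, "genotype_matrix"))
  m <- geno$raw
  colnames(m) <- geno$markers$marker_id
  write.table(m, paste0(prefix, ".geno.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = missing)
  write.table(geno$markers[, c("marker_id", "chromosome", "bp_position")],
              paste0(prefix, ".markers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Read genotypes from delimited text
#'
#' @param prefix path prefix written by [write_geno_text()].
#' @param missing missing-genotype token.
#' @return a [genotype_matrix()].
#' @export
read_geno_text <- function(prefix, missing = "NA") {
  m <- as.matrix(read.table(paste0(prefix, ".geno.tsv"), sep = "\t",
                            header = TRUE, na.strings = missing,
                            check.names = FALSE))
  mk <- read.table(paste0(prefix, ".markers.tsv"), sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "integer"))
  genotype_matrix(m, mk)
}
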