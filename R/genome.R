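#' Define a genome map for the simulator
#'
#' A diploid genome of `n_chr` chromosomes, each carrying `loci_per_chr`
#' biallelic loci equally spaced on a genetic map of `chr_len` Morgans.
#' The default (12 chromosomes x 137 loci, 1 Morgan each) gives 1644
#' segregating loci, the rice-like configuration used throughout.
#'
#' @param n_chr Number of chromosomes.
#' @param loci_per_chr Loci per chromosome (equally spaced).
#' @param chr_len Genetic length of each chromosome in Morgans (scalar or
#'   vector of length `n_chr`).
#' @return An object of class `bg_genome`: a list with the per-locus map
#'   (`pos`, within-chromosome positions in Morgans), chromosome index
#'   bookkeeping, and the total locus count `n_loci`.
#' @examples
#' g <- bg_genome()
#' g$n_loci # 1644
#' @export
bg_genome <- function(n_chr = 12, loci_per_chr = 137, chr_len = 1.0) {
  stopifnot(n_chr >= 1, loci_per_chr >= 1, all(chr_len > 0))
  chr_len <- rep_len(chr_len, n_chr)
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    (seq_len(loci_per_chr) - 0.5) / loci_per_chr * chr_len[c]
  }))
  structure(list(
    n_chr = n_chr,
    loci_per_chr = loci_per_chr,
    chr_len = chr_len,
    pos = pos,
    chr_start = as.integer((seq_len(n_chr) - 1L) * loci_per_chr),
    chr_nloci = rep(as.integer(loci_per_chr), n_chr),
    chr_of = rep(seq_len(n_chr), each = loci_per_chr),
    n_loci = as.integer(n_chr * loci_per_chr)
  ), class = "bg_genome")
}

#' @export
print.bg_genome <- function(x, ...) {
  cat("<bg_genome> ", x$n_chr, " chromosomes x ", x$loci_per_chr,
      " loci (", x$n_loci, " total), ",
      format(sum(x$chr_len)), " Morgans\n", sep = "")
  invisible(x)
}

#' Assign a quantitative trait architecture to a genome
#'
#' Samples non-overlapping QTN and SNP-marker positions on each chromosome,
#' draws additive QTN effects from a Gamma(shape = 1, scale = 1) with a
#' random sign per QTN, and dominance degrees from
#' Normal(`mu_delta`, `sigma2_delta`). The dominance effect of QTN i is
#' `d_i = |a_i| * delta_i`, so a negative degree gives a deviation toward
#' the low homozygote and a degree above 1 gives overdominance. With the
#' defaults (0.22, 0.125) about 26% of degrees are negative and about 1%
#' exceed 1.
#'
#' The affine calibration constants mapping the raw genetic score to the
#' trait scale are unset until [calibrate_architecture()] is called on a
#' reference (founder) population.
#'
#' @param genome A [bg_genome()].
#' @param n_qtn_per_chr,n_snp_per_chr QTN and SNP counts per chromosome
#'   (defaults 30 and 45: 360 QTN and 540 markers on the default genome).
#' @param mu_delta,sigma2_delta Mean and variance of the dominance degrees.
#' @param seed Optional integer seed.
#' @return An object of class `bg_arch` with fields `qtl` and `snp`
#'   (0-based locus indices), `a`, `delta`, `d`, and calibration constants
#'   `intercept`/`scale`.
#' @export
assign_architecture <- function(genome, n_qtn_per_chr = 30, n_snp_per_chr = 45,
                                mu_delta = 0.22, sigma2_delta = 0.125,
                                seed = NULL) {
  stopifnot(inherits(genome, "bg_genome"),
            n_qtn_per_chr + n_snp_per_chr <= genome$loci_per_chr,
            sigma2_delta >= 0)
  if (!is.null(seed)) set.seed(seed)
  qtl <- integer(0); snp <- integer(0)
  for (c in seq_len(genome$n_chr)) {
    pick <- sample.int(genome$loci_per_chr, n_qtn_per_chr + n_snp_per_chr)
    off <- genome$chr_start[c]
    qtl <- c(qtl, off + sort(pick[seq_len(n_qtn_per_chr)]) - 1L)
    snp <- c(snp, off + sort(pick[n_qtn_per_chr + seq_len(n_snp_per_chr)]) - 1L)
  }
  stopifnot(length(intersect(qtl, snp)) == 0)
  nq <- length(qtl)
  a <- stats::rgamma(nq, shape = 1, scale = 1) *
    sample(c(-1, 1), nq, replace = TRUE)
  delta <- stats::rnorm(nq, mu_delta, sqrt(sigma2_delta))
  structure(list(
    qtl = as.integer(qtl), snp = as.integer(snp),
    a = a, delta = delta, d = abs(a) * delta,
    mu_delta = mu_delta, sigma2_delta = sigma2_delta,
    intercept = 0, scale = 1
  ), class = "bg_arch")
}

#' @export
print.bg_arch <- function(x, ...) {
  cat("<bg_arch> ", length(x$qtl), " QTN, ", length(x$snp), " SNP markers",
      if (x$scale != 1 || x$intercept != 0) " (calibrated)", "\n", sep = "")
  invisible(x)
}

#' Calibrate the trait scale on a reference population
#'
#' Sets the affine constants of the architecture so that the reference
#' population (normally the founders) has genetic-value mean 0 and genetic
#' variance 1. The rescale is exact: on the reference set
#' `|mean| < 1e-8` and `|var - 1| < 1e-8` afterwards.
#'
#' @param arch A [bg_arch][assign_architecture()].
#' @param pop Reference population.
#' @return The architecture with `intercept` and `scale` set.
#' @export
calibrate_architecture <- function(arch, pop) {
  raw <- cpp_genetic_values(pop$hap1, pop$hap2, arch$qtl, arch$a, arch$d)
  v <- stats::var(raw)
  if (v <= 0) stop("reference population has zero genetic variance; cannot calibrate")
  arch$scale <- 1 / sqrt(v)
  arch$intercept <- -mean(raw) / sqrt(v)
  arch
}

#' Empirical stage heritabilities of the breeding program
#'
#' Broad- (`H2`) and narrow-sense (`h2`) heritabilities of grain yield as
#' observed at each generation stage of the program; these drive the
#' phenotyping error at each simulated evaluation.
#'
#' @return A tibble with columns `stage`, `h2`, `H2`.
#' @export
heritability_schedule <- function() {
  tibble::tibble(
    stage = c("F2", "F3", "F4", "F5", "F6", "F7"),
    h2 = c(0.03, 0.15, 0.40, 0.60, 0.70, 0.80),
    H2 = c(0.06, 0.20, 0.45, 0.63, 0.72, 0.81)
  )
}
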