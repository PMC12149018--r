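#' @useDynLib breedgain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

new_bg_pop <- function(hap1, hap2, info, genome) {
  stopifnot(nrow(hap1) == genome$n_loci, identical(dim(hap1), dim(hap2)),
            ncol(hap1) == nrow(info))
  structure(list(hap1 = hap1, hap2 = hap2, info = info, genome = genome),
            class = "bg_pop")
}

#' @export
print.bg_pop <- function(x, ...) {
  cat("<bg_pop> ", nrow(x$info), " individuals, ", x$genome$n_loci,
      " loci; generations: ",
      paste(unique(x$info$generation), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `bg_pop`.
#' @return Integer count.
#' @export
pop_size <- function(pop) nrow(pop$info)

#' Per-individual records of a simulated population
#'
#' @param x A `bg_pop`.
#' @param ... Unused.
#' @return A tibble with one row per individual: `id`, `parent1`, `parent2`,
#'   `line_id`, `generation`, `genetic_value`, `phenotype`.
#' @export
tidy.bg_pop <- function(x, ...) x$info

#' Simulate a founder population of fully inbred lines
#'
#' Founder haplotypes are drawn locus by locus: each locus gets an allele
#' frequency from Uniform(0.1, 0.9), each founder a homozygous genotype at
#' that frequency, and any locus that comes out monomorphic is redrawn so
#' every locus segregates in the founder set.
#'
#' @param n_individuals Number of founder inbreds (>= 2).
#' @param genome A [bg_genome()].
#' @param seed Optional integer seed.
#' @return A `bg_pop` of homozygous founders (dosages 0 or 2 everywhere).
#' @export
simulate_founders <- function(n_individuals, genome = bg_genome(), seed = NULL) {
  stopifnot(n_individuals >= 2, inherits(genome, "bg_genome"))
  if (!is.null(seed)) set.seed(seed)
  L <- genome$n_loci
  p <- stats::runif(L, 0.1, 0.9)
  g <- matrix(stats::rbinom(L * n_individuals, 1L, rep(p, times = n_individuals)),
              nrow = L, ncol = n_individuals)
  for (tries in seq_len(1000)) {
    cs <- rowSums(g)
    bad <- which(cs == 0L | cs == n_individuals)
    if (length(bad) == 0) break
    g[bad, ] <- matrix(
      stats::rbinom(length(bad) * n_individuals, 1L,
                    rep(stats::runif(length(bad), 0.1, 0.9),
                        times = n_individuals)),
      nrow = length(bad))
    if (tries == 1000)
      stop("could not make every locus segregate; increase n_individuals")
  }
  h <- matrix(as.raw(g), nrow = L, ncol = n_individuals)
  info <- tibble::tibble(
    id = seq_len(n_individuals),
    parent1 = NA_integer_, parent2 = NA_integer_,
    line_id = seq_len(n_individuals),
    generation = "founder",
    genetic_value = NA_real_, phenotype = NA_real_
  )
  new_bg_pop(h, h, info, genome)
}

#' Genetic values of a population under a trait architecture
#'
#' The raw score of an individual sums, over QTN, the additive contribution
#' `a * (dosage - 1)` and, for heterozygotes only, the dominance effect
#' `d = |a| * delta`; the calibrated affine constants then map the score to
#' the trait scale (founder mean 0, founder genetic variance 1).
#'
#' @param pop A `bg_pop`.
#' @param arch A calibrated [bg_arch][assign_architecture()].
#' @return Numeric vector of genetic values (trait units).
#' @export
genetic_values <- function(pop, arch) {
  if (pop_size(pop) == 0) stop("empty population")
  raw <- cpp_genetic_values(pop$hap1, pop$hap2, arch$qtl, arch$a, arch$d)
  arch$intercept + arch$scale * raw
}

#' Store genetic values on the population records
#' @inheritParams genetic_values
#' @return The population with `genetic_value` filled in.
#' @export
set_genetic_values <- function(pop, arch) {
  pop$info$genetic_value <- genetic_values(pop, arch)
  pop
}

#' Phenotype a population at a target broad-sense heritability
#'
#' Adds Gaussian noise to the genetic values. The error variance is anchored
#' to the evaluated set itself: `var_e = var(G) * (1 - H2) / H2` where
#' `var(G)` is the genetic variance of this population, so the realized
#' plot-basis heritability of the evaluated cohort matches the stage's `H2`.
#'
#' @param pop A `bg_pop`.
#' @param arch A calibrated architecture.
#' @param H2 Target broad-sense heritability in (0, 1]; `H2 = 1` returns the
#'   genetic values unchanged.
#' @param seed Optional integer seed.
#' @return The population with `phenotype` (and `genetic_value`) filled in.
#' @export
phenotype <- function(pop, arch, H2, seed = NULL) {
  stopifnot(H2 > 0, H2 <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (anyNA(pop$info$genetic_value)) pop <- set_genetic_values(pop, arch)
  g <- pop$info$genetic_value
  if (H2 == 1) {
    pop$info$phenotype <- g
  } else {
    ve <- stats::var(g) * (1 - H2) / H2
    pop$info$phenotype <- g + stats::rnorm(length(g), 0, sqrt(max(ve, 0)))
  }
  pop
}

gametes_for <- function(pop, cols) {
  cpp_gametes(pop$hap1, pop$hap2, as.integer(cols - 1L), pop$genome$pos,
              pop$genome$chr_start, pop$genome$chr_nloci, pop$genome$chr_len)
}

#' Cross pairs of parents
#'
#' Each progeny receives one recombinant gamete from each parent; crossover
#' counts per chromosome are Poisson in the map length with no interference.
#'
#' @param pop A `bg_pop` containing the parents.
#' @param parent_pairs Two-column matrix (or data frame) of parent ids, one
#'   row per cross.
#' @param n_progeny_per_cross Progeny per cross.
#' @param generation Generation label for the progeny (default "F1").
#' @param seed Optional integer seed.
#' @param id_start First id for the progeny (default continues from `pop`).
#' @return A `bg_pop` of progeny (`line_id` = own id).
#' @export
make_cross <- function(pop, parent_pairs, n_progeny_per_cross = 1,
                       generation = "F1", seed = NULL, id_start = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parent_pairs <- as.matrix(parent_pairs)
  stopifnot(ncol(parent_pairs) == 2)
  r1 <- match(parent_pairs[, 1], pop$info$id)
  r2 <- match(parent_pairs[, 2], pop$info$id)
  if (anyNA(r1) || anyNA(r2)) stop("unknown parent id in parent_pairs")
  rows1 <- rep(r1, each = n_progeny_per_cross)
  rows2 <- rep(r2, each = n_progeny_per_cross)
  h1 <- gametes_for(pop, rows1)
  h2 <- gametes_for(pop, rows2)
  if (is.null(id_start)) id_start <- max(pop$info$id) + 1L
  n <- length(rows1)
  ids <- seq.int(id_start, length.out = n)
  info <- tibble::tibble(
    id = ids,
    parent1 = pop$info$id[rows1], parent2 = pop$info$id[rows2],
    line_id = ids, generation = generation,
    genetic_value = NA_real_, phenotype = NA_real_
  )
  new_bg_pop(h1, h2, info, pop$genome)
}

#' Self-pollinate plants
#'
#' As [make_cross()] with both gametes drawn from the same parent.
#'
#' @param pop A `bg_pop`.
#' @param n_progeny_per_plant Selfed progeny per plant.
#' @param parents Ids of the plants to self (default: all).
#' @param generation Generation label for the progeny.
#' @param inherit_line If `TRUE` the progeny keep the parent's `line_id`
#'   (single-seed-descent advance of a line); otherwise each progeny starts
#'   its own line.
#' @param seed Optional integer seed.
#' @param id_start First id for the progeny.
#' @return A `bg_pop` of selfed progeny.
#' @export
self_progeny <- function(pop, n_progeny_per_plant = 1, parents = NULL,
                         generation = "self", inherit_line = FALSE,
                         seed = NULL, id_start = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(parents)) parents <- pop$info$id
  r <- match(parents, pop$info$id)
  if (anyNA(r)) stop("unknown parent id")
  rows <- rep(r, each = n_progeny_per_plant)
  h1 <- gametes_for(pop, rows)
  h2 <- gametes_for(pop, rows)
  if (is.null(id_start)) id_start <- max(pop$info$id) + 1L
  n <- length(rows)
  ids <- seq.int(id_start, length.out = n)
  info <- tibble::tibble(
    id = ids,
    parent1 = pop$info$id[rows], parent2 = pop$info$id[rows],
    line_id = if (inherit_line) pop$info$line_id[rows] else ids,
    generation = generation,
    genetic_value = NA_real_, phenotype = NA_real_
  )
  new_bg_pop(h1, h2, info, pop$genome)
}

#' Subset a population by individual id
#' @param pop A `bg_pop`.
#' @param ids Ids to keep (order preserved).
#' @return A `bg_pop` with the selected individuals.
#' @export
pop_subset <- function(pop, ids) {
  r <- match(ids, pop$info$id)
  if (anyNA(r)) stop("unknown id in subset")
  new_bg_pop(pop$hap1[, r, drop = FALSE], pop$hap2[, r, drop = FALSE],
             pop$info[r, ], pop$genome)
}

#' Allele-dosage matrix of a population
#' @param pop A `bg_pop`.
#' @param loci 0-based locus indices (default: all loci).
#' @return Integer matrix, individuals x loci, values 0/1/2.
#' @export
dosage_matrix <- function(pop, loci = NULL) {
  if (is.null(loci)) loci <- seq_len(pop$genome$n_loci) - 1L
  m <- cpp_dosage(pop$hap1, pop$hap2, as.integer(loci))
  rownames(m) <- pop$info$id
  m
}

#' SNP marker codes (1/0/-1) of a population
#' @param pop A `bg_pop`.
#' @param arch Architecture providing the SNP map.
#' @return Numeric matrix, individuals x markers, coded `dosage - 1`.
#' @export
marker_codes <- function(pop, arch) {
  m <- cpp_marker_codes(pop$hap1, pop$hap2, arch$snp)
  rownames(m) <- pop$info$id
  m
}

#' Per-individual heterozygosity
#' @param pop A `bg_pop`.
#' @return Numeric vector, fraction of heterozygous loci per individual.
#' @export
heterozygosity <- function(pop) cpp_heterozygosity(pop$hap1, pop$hap2)

# Fused progeny generation used by the cycle engine: one recombinant gamete
# per parent per progeny, with the genetic value (and, when a GS model is
# given, the GEBV) computed in the same pass over the fresh haplotypes.
breed_progeny <- function(pop, rows1, rows2, arch, model = NULL,
                          generation = "progeny", inherit_line = FALSE,
                          id_start = NULL) {
  g <- pop$genome
  res <- cpp_progeny(pop$hap1, pop$hap2,
                     as.integer(rows1 - 1L), as.integer(rows2 - 1L),
                     g$pos, g$chr_start, g$chr_nloci, g$chr_len,
                     arch$qtl, arch$a, arch$d, arch$snp,
                     if (is.null(model)) numeric(0) else model$u,
                     !is.null(model))
  if (is.null(id_start)) id_start <- max(pop$info$id) + 1L
  n <- length(rows1)
  ids <- seq.int(id_start, length.out = n)
  info <- tibble::tibble(
    id = ids,
    parent1 = pop$info$id[rows1], parent2 = pop$info$id[rows2],
    line_id = if (inherit_line) pop$info$line_id[rows1] else ids,
    generation = generation,
    genetic_value = arch$intercept + arch$scale * res$gv,
    phenotype = NA_real_
  )
  out <- new_bg_pop(res$hap1, res$hap2, info, g)
  if (!is.null(model)) attr(out, "gebv") <- res$gebv
  out
}

# Restrict a genome map to a subset of loci (0-based indices); positions on
# the genetic map are preserved, so recombination patterns at the retained
# loci are statistically unchanged.
genome_subset <- function(genome, keep) {
  keep <- sort(as.integer(keep))
  chr_of <- genome$chr_of[keep + 1L]
  nloci <- as.integer(tabulate(chr_of, nbins = genome$n_chr))
  g <- genome
  g$pos <- genome$pos[keep + 1L]
  g$chr_nloci <- nloci
  g$chr_start <- as.integer(cumsum(c(0L, nloci[-genome$n_chr])))
  g$chr_of <- chr_of
  g$n_loci <- length(keep)
  g$loci_per_chr <- NA_integer_
  g
}

#' Marginalize a population to its functional loci
#'
#' Drops the neutral loci, keeping only QTN and SNP positions (with their
#' original map positions), and remaps the architecture accordingly. Since
#' crossovers are Poisson on the map and neutral loci influence neither
#' genetic values, markers, nor phenotypes, the retained loci's inheritance
#' is statistically identical — this is an exact marginalization used to
#' speed up large scheme simulations.
#'
#' @param pop A `bg_pop`.
#' @param arch Its (calibrated) architecture.
#' @return A list: `pop` and `arch` on the reduced genome.
#' @export
reduce_to_functional <- function(pop, arch) {
  keep <- sort(c(arch$qtl, arch$snp))
  g2 <- genome_subset(pop$genome, keep)
  pop2 <- new_bg_pop(pop$hap1[keep + 1L, , drop = FALSE],
                     pop$hap2[keep + 1L, , drop = FALSE],
                     pop$info, g2)
  arch2 <- arch
  arch2$qtl <- as.integer(match(arch$qtl, keep) - 1L)
  arch2$snp <- as.integer(match(arch$snp, keep) - 1L)
  list(pop = pop2, arch = arch2)
}
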