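# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

small_genome <- function() bg_genome(n_chr = 3, loci_per_chr = 40)

# an additive-only architecture (no dominance): exact mid-parent algebra
additive_arch <- function(genome, seed = 1) {
  assign_architecture(genome, n_qtn_per_chr = 10, n_snp_per_chr = 15,
                      mu_delta = 0, sigma2_delta = 0, seed = seed)
}

# full-size founders + calibrated architecture (functional-locus form)
get_base <- function() {
  if (is.null(.fixtures$base)) {
    set.seed(101)
    g <- bg_genome()
    found <- simulate_founders(1000, g)
    arch <- calibrate_architecture(assign_architecture(g), found)
    red <- reduce_to_functional(found, arch)
    .fixtures$base <- red
  }
  .fixtures$base
}

# a post-burn-in state with an initial GS training set attached
get_state <- function() {
  if (is.null(.fixtures$state)) {
    base <- get_base()
    set.seed(202)
    st <- run_burn_in(base$pop, base$arch)
    b <- build_initial_ts(st)
    st <- b$state
    st$ts_archive <- list(b$ts)
    .fixtures$state <- st
  }
  .fixtures$state
}

# kinship-recursion oracle for the additive relationship matrix: memoized
# pairwise recursion, independent of the tabular implementation
amatrix_oracle <- function(ped) {
  ids <- as.character(ped$id)
  p1 <- stats::setNames(as.character(ped$parent1), ids)
  p2 <- stats::setNames(as.character(ped$parent2), ids)
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      0.5 * (1 + phi(p1[[a]], p2[[a]]))
    } else {
      # recurse on the later-born individual (ids are topologically sorted)
      ia <- match(a, ids); ib <- match(b, ids)
      if (ia < ib) { t <- a; a <- b; b <- t }
      0.5 * (phi(p1[[a]], b) + phi(p2[[a]], b))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * phi(ids[i], ids[j])
  }
  A
}

random_pedigree <- function(n, seed) {
  set.seed(seed)
  id <- paste0("I", seq_len(n))
  p1 <- p2 <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) < 0.7) {
      pick <- sample(i - 1L, 2)
      p1[i] <- id[pick[1]]
      p2[i] <- if (stats::runif(1) < 0.2) id[pick[1]] else id[pick[2]]
    }
  }
  tibble::tibble(id = id, parent1 = p1, parent2 = p2)
}

# balanced RCBD trial generator shared across test files
make_rcbd <- function(n_geno = 20, n_rep = 2, mu = 100, sg = 4, se = 2,
                      trial = "T1", year = 2000, seed = 1) {
  set.seed(seed)
  g <- rnorm(n_geno, 0, sg)
  tibble::tibble(
    trial_id = trial, year = year, location = "L1",
    replicate = rep(paste0("R", seq_len(n_rep)), each = n_geno),
    genotype_id = rep(sprintf("g%02d", seq_len(n_geno)), n_rep),
    trait = "grain_yield",
    value = mu + rep(g, n_rep) + rnorm(n_geno * n_rep, 0, se)
  )
}
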