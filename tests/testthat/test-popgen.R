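test_that("founder populations are fully inbred with every locus segregating", {
  g <- bg_genome()
  expect_equal(g$n_loci, 1644L)
  pop <- simulate_founders(1000, g, seed = 1)
  expect_equal(pop_size(pop), 1000L)
  dm <- dosage_matrix(pop)
  expect_true(all(dm %in% c(0L, 2L)))
  # brute-force minor-allele count per locus over the dosage matrix
  cs <- colSums(dm) / 2
  expect_true(all(cs > 0 & cs < 1000))
  expect_equal(max(heterozygosity(pop)), 0)
})

test_that("small founder sets still segregate at every locus", {
  pop <- simulate_founders(4, small_genome(), seed = 2)
  cs <- colSums(dosage_matrix(pop)) / 2
  expect_true(all(cs > 0 & cs < 4))
  expect_error(simulate_founders(1, small_genome()), "n_individuals")
})

test_that("trait architecture has the configured counts and dominance law", {
  g <- bg_genome()
  arch <- assign_architecture(g, seed = 3)
  expect_length(arch$qtl, 360)
  expect_length(arch$snp, 540)
  expect_length(intersect(arch$qtl, arch$snp), 0)
  expect_equal(arch$d, abs(arch$a) * arch$delta)
  # overlap impossible by construction even on a crowded chromosome
  g2 <- bg_genome(n_chr = 1, loci_per_chr = 80)
  a2 <- assign_architecture(g2, n_qtn_per_chr = 30, n_snp_per_chr = 45,
                            seed = 4)
  expect_length(intersect(a2$qtl, a2$snp), 0)
  expect_error(assign_architecture(g2, n_qtn_per_chr = 50,
                                   n_snp_per_chr = 45))
})

test_that("dominance-degree tails match the normal-CDF oracle", {
  g <- bg_genome()
  set.seed(5)
  deltas <- unlist(lapply(1:400, function(i) assign_architecture(g)$delta))
  n <- length(deltas)  # 36,000 draws
  p_neg <- pnorm(-0.22 / sqrt(0.125))      # ~0.267, the ~26% chance
  p_over <- 1 - pnorm((1 - 0.22) / sqrt(0.125))  # ~0.0136, the ~1% chance
  expect_lt(abs(mean(deltas < 0) - p_neg), 3 * sqrt(p_neg * (1 - p_neg) / n))
  expect_lt(abs(mean(deltas > 1) - p_over),
            3 * sqrt(p_over * (1 - p_over) / n))
})

test_that("genetic values match an exhaustive two-QTN hand computation", {
  g <- bg_genome(n_chr = 1, loci_per_chr = 4)
  arch <- assign_architecture(g, n_qtn_per_chr = 2, n_snp_per_chr = 1,
                              seed = 6)
  # three individuals with hand-set haplotypes
  h1 <- matrix(as.raw(c(0, 0, 0, 0,  1, 1, 1, 1,  1, 0, 1, 0)), 4, 3)
  h2 <- matrix(as.raw(c(0, 0, 0, 0,  1, 1, 1, 1,  0, 1, 0, 1)), 4, 3)
  info <- tibble::tibble(id = 1:3, parent1 = NA_integer_,
                         parent2 = NA_integer_, line_id = 1:3,
                         generation = "toy", genetic_value = NA_real_,
                         phenotype = NA_real_)
  pop <- breedgain:::new_bg_pop(h1, h2, info, g)
  dos <- dosage_matrix(pop)[, arch$qtl + 1, drop = FALSE]
  hand <- sapply(1:3, function(i) {
    sum(arch$a * (dos[i, ] - 1) + arch$d * (dos[i, ] == 1))
  })
  expect_equal(genetic_values(pop, arch), hand, tolerance = 1e-12)
})

test_that("founder calibration is exact and clones have zero variance", {
  base <- get_base()
  gv <- genetic_values(base$pop, base$arch)
  expect_lt(abs(mean(gv)), 1e-8)
  expect_lt(abs(stats::var(gv) - 1), 1e-8)
  clones <- pop_subset(base$pop, rep(base$pop$info$id[1], 5))
  expect_equal(stats::var(genetic_values(clones, base$arch)), 0)
})

test_that("phenotyping hits the target heritability", {
  base <- get_base()
  ph1 <- phenotype(base$pop, base$arch, H2 = 1)
  expect_equal(ph1$info$phenotype, ph1$info$genetic_value)
  set.seed(7)
  ph <- phenotype(base$pop, base$arch, H2 = 0.63)
  err <- ph$info$phenotype - ph$info$genetic_value
  expect_equal(stats::var(err), (1 - 0.63) / 0.63, tolerance = 0.08)
  expect_error(phenotype(base$pop, base$arch, H2 = 0), "H2")
})

test_that("crossing identical inbreds clones them; divergent F1 is fully heterozygous", {
  g <- small_genome()
  L <- g$n_loci
  h_lo <- matrix(as.raw(0), L, 1); h_hi <- matrix(as.raw(1), L, 1)
  info <- function(id) tibble::tibble(id = id, parent1 = NA_integer_,
                                      parent2 = NA_integer_, line_id = id,
                                      generation = "founder",
                                      genetic_value = NA_real_,
                                      phenotype = NA_real_)
  pop <- breedgain:::new_bg_pop(cbind(h_lo, h_lo, h_hi),
                                cbind(h_lo, h_lo, h_hi),
                                dplyr::bind_rows(info(1L), info(2L), info(3L)), g)
  same <- make_cross(pop, cbind(1, 2), 5, seed = 8)
  expect_true(all(dosage_matrix(same) == 0L))
  div <- make_cross(pop, cbind(1, 3), 5, seed = 9)
  expect_true(all(dosage_matrix(div) == 1L))
  expect_equal(heterozygosity(div), rep(1, 5))
  expect_error(make_cross(pop, cbind(1, 99), 2), "unknown parent")
})

test_that("selfing halves heterozygosity per generation and segregates 1:2:1", {
  g <- small_genome()
  pop <- simulate_founders(10, g, seed = 10)
  f1 <- make_cross(pop, cbind(1, 2), 1, seed = 11)
  # selfing chain: mean heterozygosity ~ h0 * 0.5^t
  h0 <- heterozygosity(f1)
  cur <- f1
  set.seed(12)
  for (t in 1:3) {
    cur <- self_progeny(cur, if (t == 1) 400 else 1,
                        generation = paste0("S", t))
    expect_lt(abs(mean(heterozygosity(cur)) - h0 * 0.5^t), 0.02)
  }
  # F2 of a divergent cross: pooled dosage frequencies ~ 1:2:1
  L <- g$n_loci
  h_lo <- matrix(as.raw(0), L, 1); h_hi <- matrix(as.raw(1), L, 1)
  info <- tibble::tibble(id = 1:2, parent1 = NA_integer_,
                         parent2 = NA_integer_, line_id = 1:2,
                         generation = "founder", genetic_value = NA_real_,
                         phenotype = NA_real_)
  divp <- breedgain:::new_bg_pop(cbind(h_lo, h_hi), cbind(h_lo, h_hi),
                                 info, g)
  f1d <- make_cross(divp, cbind(1, 2), 1, seed = 13)
  f2 <- self_progeny(f1d, 3000, generation = "F2", seed = 14)
  expect_equal(pop_size(f2), 3000L)
  tab <- table(dosage_matrix(f2)) / (3000 * L)
  expect_equal(as.numeric(tab), c(0.25, 0.5, 0.25), tolerance = 0.02)
})

test_that("every progeny allele traces to a parental allele", {
  g <- small_genome()
  pop <- simulate_founders(6, g, seed = 15)
  # make parents artificially heterozygous so both haplotypes differ
  pop$hap2[, 1] <- as.raw(1 - as.integer(pop$hap1[, 1]))
  prog <- make_cross(pop, cbind(1, 2), 50, seed = 16)
  for (i in 1:50) {
    a1 <- as.integer(prog$hap1[, i])
    ok1 <- a1 == as.integer(pop$hap1[, 1]) | a1 == as.integer(pop$hap2[, 1])
    a2 <- as.integer(prog$hap2[, i])
    ok2 <- a2 == as.integer(pop$hap1[, 2]) | a2 == as.integer(pop$hap2[, 2])
    expect_true(all(ok1) && all(ok2))
  }
})

test_that("without selection the population mean drifts around zero", {
  g <- small_genome()
  set.seed(17)
  arch0 <- additive_arch(g)
  changes <- replicate(50, {
    pop <- simulate_founders(60, g)
    arch <- calibrate_architecture(arch0, pop)
    par_ids <- sample(pop$info$id, 10)
    f1 <- make_cross(pop, cbind(par_ids[1:5], par_ids[6:10]), 20)
    kids <- self_progeny(f1, 2, generation = "F2")
    mean(genetic_values(kids, arch)) -
      mean(genetic_values(pop_subset(pop, par_ids), arch))
  })
  expect_lt(abs(mean(changes)), 3 * stats::sd(changes) / sqrt(50))
})

test_that("the fused progeny kernel agrees with the separate kernels", {
  base <- get_base()
  pop <- pop_subset(base$pop, 1:20)
  set.seed(18)
  u <- runif(540)
  prog <- breedgain:::breed_progeny(pop, 1:10, 11:20, base$arch,
                                    model = list(u = u),
                                    generation = "F1")
  expect_equal(prog$info$genetic_value, genetic_values(prog, base$arch),
               tolerance = 1e-12)
  expect_equal(attr(prog, "gebv"),
               unname(drop(marker_codes(prog, base$arch) %*% u)),
               tolerance = 1e-12)
})

test_that("genome marginalization preserves values and marker codes", {
  set.seed(19)
  g <- bg_genome()
  pop <- simulate_founders(50, g)
  arch <- calibrate_architecture(assign_architecture(g), pop)
  red <- reduce_to_functional(pop, arch)
  expect_equal(genetic_values(red$pop, red$arch), genetic_values(pop, arch))
  expect_equal(marker_codes(red$pop, red$arch), marker_codes(pop, arch))
  expect_equal(red$pop$genome$n_loci, 900L)
  # map positions of retained loci unchanged
  keep <- sort(c(arch$qtl, arch$snp)) + 1
  expect_equal(red$pop$genome$pos, g$pos[keep])
})
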