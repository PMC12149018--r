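test_that("Bonferroni filter removes a planted contaminant and only it", {
  d <- make_rcbd(seed = 51)
  sigma <- sd(d$value)
  d$value[7] <- d$value[7] + 10 * sigma
  out <- bonferroni_outlier_filter(d)
  expect_equal(nrow(out$removals), 1)
  expect_equal(out$removals$genotype_id, d$genotype_id[7])
  expect_equal(nrow(out$records), nrow(d) - 1)
  # adjusted p arithmetic: min(1, n * p)
  expect_true(all(out$removals$p_adjusted <= 0.05))
})

test_that("Bonferroni filter rarely removes anything under the null", {
  removals <- sapply(1:20, function(i) {
    d <- make_rcbd(n_geno = 50, seed = 100 + i)
    nrow(bonferroni_outlier_filter(d)$removals)
  })
  expect_gte(sum(removals == 0), 17)  # ~95% clean at alpha = 0.05
})

test_that("the max-studentized-residual test agrees with car::outlierTest", {
  skip_if_not_installed("car")
  d <- make_rcbd(seed = 52)
  d$value[3] <- d$value[3] + 25
  f <- lm(value ~ factor(genotype_id) + factor(replicate), data = d)
  ot <- car::outlierTest(f, cutoff = Inf, n.max = 1)
  out <- bonferroni_outlier_filter(d)
  expect_equal(out$removals$p_adjusted[1],
               unname(ot$bonf.p[1]), tolerance = 1e-6)
})

test_that("stage 1 on a balanced RCBD equals raw genotype means", {
  d <- make_rcbd(n_geno = 15, n_rep = 3, seed = 53)
  s1 <- stage1_fit(d)
  raw <- tapply(d$value, d$genotype_id, mean)
  expect_equal(s1$means$value, as.numeric(raw[s1$means$genotype_id]),
               tolerance = 1e-8)
  expect_lt(diff(range(s1$means$se)), 1e-8)  # equal SEs, balanced design
  expect_equal(s1$means$weight, 1 / s1$means$se^2)
})

test_that("stage 1 recovers variance components and heritability", {
  # sigma2_G = sigma2_E  =>  H2 ~ 0.5
  h2s <- sapply(1:8, function(i) {
    d <- make_rcbd(n_geno = 100, n_rep = 2, sg = 3, se = 3, seed = 200 + i)
    stage1_fit(d)$summaries$H2_plot
  })
  expect_equal(mean(h2s), 0.5, tolerance = 0.08)
  # true H2 = 0.6 at the plot level
  h2b <- sapply(1:8, function(i) {
    d <- make_rcbd(n_geno = 100, n_rep = 2, sg = sqrt(0.6), se = sqrt(0.4),
                   seed = 300 + i)
    stage1_fit(d)$summaries$H2_plot
  })
  expect_lt(abs(mean(h2b) - 0.6), 0.1)
})

test_that("trial filtering keeps the boundary and drops below it", {
  s <- tibble::tibble(trial_id = c("a", "b", "c", "d"),
                      year = 2000, sigma2_G = 1, sigma2_E = 1,
                      H2_plot = c(0.35, 0.349, 0.9, NA),
                      n_obs = 10, excluded = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(filter_trials(s), c("a", "c"))
  expect_equal(filter_trials(s, threshold = 0.95), character(0))
})

test_that("connectivity counts and percentages are exact", {
  m <- tibble::tibble(
    genotype_id = c("A", "B", "C", "B", "C", "D", "E"),
    year = c(2000, 2000, 2000, 2001, 2001, 2001, 2001))
  cc <- connectivity(m)
  expect_equal(cc$shared, 2)
  expect_equal(cc$pct, 40)  # 2 shared / 5 in the union
  disj <- tibble::tibble(genotype_id = c("A", "B"), year = c(2000, 2001))
  expect_equal(connectivity(disj)$pct, 0)
  ident <- tibble::tibble(genotype_id = c("A", "B", "A", "B"),
                          year = c(2000, 2000, 2001, 2001))
  expect_equal(connectivity(ident)$pct, 100)
})

test_that("check-trend audit applies the presence threshold and recovers slopes", {
  set.seed(54)
  years <- 1999:2022
  rec <- dplyr::bind_rows(
    tibble::tibble(genotype_id = "chk", year = years,
                   value = 500 + 20 * (years - 1999) + rnorm(24, 0, 5)),
    tibble::tibble(genotype_id = "rare", year = years[1:14],
                   value = rnorm(14, 500, 5)),
    tibble::tibble(genotype_id = "flat", year = years,
                   value = rep(700, 24)))
  tr <- check_trend(rec)
  expect_setequal(tr$genotype_id, c("chk", "flat"))  # 14/24 = 58% excluded
  expect_equal(tr$slope[tr$genotype_id == "chk"], 20, tolerance = 1)
  expect_equal(tr$slope[tr$genotype_id == "flat"], 0)
  expect_warning(check_trend(rec, checks = "absent"), "presence")
})

test_that("stage-2 joint WLS matches oracles and handles structure", {
  # two years, known year offset, connected by shared genotypes
  set.seed(55)
  g_eff <- c(A = 0, B = 2, C = 4, D = 6)
  mk <- function(year, genos, delta) {
    tibble::tibble(genotype_id = genos, trial_id = paste0("T", year),
                   year = year, value = g_eff[genos] + delta,
                   se = 1, weight = 1)
  }
  means <- dplyr::bind_rows(mk(2000, c("A", "B", "C"), 0),
                            mk(2001, c("B", "C", "D"), 5))
  fit <- stage2_joint_fit(means)
  ye <- attr(fit, "year_effects")
  expect_equal(ye$effect[2], 5, tolerance = 1e-10)
  v <- stats::setNames(fit$value, fit$genotype_id)
  expect_equal(unname(v["B"] - v["A"]), 2, tolerance = 1e-10)
  expect_equal(unname(v["D"] - v["A"]), 6, tolerance = 1e-10)
  # single year: reduces to the weighted average of stage-1 means
  one <- dplyr::bind_rows(
    tibble::tibble(genotype_id = "A", trial_id = c("T1", "T2"), year = 2000,
                   value = c(10, 14), se = 1, weight = c(3, 1)),
    tibble::tibble(genotype_id = "B", trial_id = "T1", year = 2000,
                   value = 20, se = 1, weight = 2))
  f1 <- stage2_joint_fit(one)
  expect_equal(f1$value[f1$genotype_id == "A"],
               (3 * 10 + 1 * 14) / 4, tolerance = 1e-10)
  # equal weights equal the unweighted fit
  eqw <- dplyr::mutate(means, weight = 7)
  f_eq <- stage2_joint_fit(eqw)
  expect_equal(f_eq$value, fit$value, tolerance = 1e-10)
  # disconnected genotype-year blocks are an error naming the blocks
  disc <- dplyr::bind_rows(mk(2000, c("A", "B"), 0),
                           mk(2001, c("C", "D"), 5))
  expect_error(stage2_joint_fit(disc), "disconnected")
})

test_that("the A-matrix reproduces textbook values", {
  founders <- tibble::tibble(id = c("f1", "f2", "f3"),
                             parent1 = NA_character_,
                             parent2 = NA_character_)
  expect_equal(build_amatrix(founders), diag(3),
               ignore_attr = TRUE)
  ped <- tibble::tibble(
    id = c("f1", "f2", "kid", "sib", "selfed"),
    parent1 = c(NA, NA, "f1", "f1", "kid"),
    parent2 = c(NA, NA, "f2", "f2", "kid"))
  A <- build_amatrix(ped)
  expect_equal(A["f1", "kid"], 0.5)
  expect_equal(A["kid", "sib"], 0.5)     # full sibs
  expect_equal(A["selfed", "selfed"], 1.5)  # one selfing, non-inbred parent
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) >= 1))
})

test_that("the A-matrix agrees with the kinship-recursion oracle", {
  for (seed in 1:25) {
    ped <- random_pedigree(n = sample(4:8, 1), seed = 600 + seed)
    A <- build_amatrix(ped)
    oracle <- amatrix_oracle(ped)
    expect_equal(A, oracle[rownames(A), colnames(A)], tolerance = 1e-12)
  }
})

test_that("out-of-order pedigrees are sorted; cycles and selfs are errors", {
  ped <- tibble::tibble(id = c("kid", "f1", "f2"),
                        parent1 = c("f1", NA, NA),
                        parent2 = c("f2", NA, NA))
  A <- build_amatrix(ped)
  expect_equal(colnames(A), c("f1", "f2", "kid"))
  cyc <- tibble::tibble(id = c("a", "b"), parent1 = c("b", "a"),
                        parent2 = c(NA, NA))
  expect_error(build_amatrix(cyc), "cycle")
  own <- tibble::tibble(id = "a", parent1 = "a", parent2 = NA)
  expect_error(build_amatrix(own), "self-parentage")
})

test_that("generation counting follows the one-plus-max-parent rule", {
  ped <- tibble::tibble(
    id = c("f", "g2a", "g2b", "mix"),
    parent1 = c(NA, "f", "g2a", "f"),
    parent2 = c(NA, "f", "g2a", "g2b"))
  gen <- count_generations(ped)
  expect_equal(gen$generation, c(0L, 1L, 2L, 3L))
  # a chain of length 23
  chain <- tibble::tibble(
    id = paste0("c", 0:23),
    parent1 = c(NA, paste0("c", 0:22)),
    parent2 = c(NA, paste0("c", 0:22)))
  expect_equal(max(count_generations(chain)$generation), 23L)
})

test_that("the animal model with A = I matches a ridge oracle", {
  set.seed(56)
  n_g <- 12
  ped <- tibble::tibble(id = paste0("g", 1:n_g), parent1 = NA_character_,
                        parent2 = NA_character_)
  means <- tibble::tibble(
    genotype_id = rep(ped$id, 2),
    trial_id = rep(c("T1", "T2"), each = n_g),
    year = rep(c(2000, 2001), each = n_g),
    value = rnorm(2 * n_g, 10), se = 1,
    weight = runif(2 * n_g, 0.5, 2))
  blup <- stage2_pedigree_blup(means, ped)
  lam <- attr(blup, "sigma2_e") / attr(blup, "sigma2_a")
  # direct mixed-model-equations oracle with identity covariance
  X <- model.matrix(~factor(means$year))
  Z <- model.matrix(~0 + factor(means$genotype_id, levels = ped$id))
  W <- diag(means$weight)
  C <- rbind(cbind(t(X) %*% W %*% X, t(X) %*% W %*% Z),
             cbind(t(Z) %*% W %*% X, t(Z) %*% W %*% Z + diag(lam, n_g)))
  rhs <- c(t(X) %*% W %*% means$value, t(Z) %*% W %*% means$value)
  sol <- solve(C, rhs)
  alpha_or <- sol[-(1:2)] + mean(X %*% sol[1:2])
  expect_equal(blup$value, unname(alpha_or), tolerance = 1e-8)
})

test_that("pedigree BLUP predicts unphenotyped relatives reasonably", {
  cfg <- synthetic_config(seed = 57)
  syn <- generate_synthetic(cfg)
  qc <- bonferroni_outlier_filter(syn$trials)
  s1 <- stage1_fit(qc$records)
  keep <- filter_trials(s1$summaries)
  means <- dplyr::filter(s1$means, trial_id %in% keep)
  blup <- stage2_pedigree_blup(means, syn$pedigree)
  truth <- stats::setNames(syn$pedigree$true_bv, syn$pedigree$id)
  phen <- blup[blup$phenotyped, ]
  expect_gt(cor(phen$value, truth[phen$genotype_id]), 0.6)
  # founders get predictions too ("predict the past")
  expect_true(all(syn$pedigree$id %in% blup$genotype_id))
})

test_that("stage-3 regression matches the closed form and guards the intercept", {
  vals <- tibble::tibble(genotype_id = paste0("g", 1:10),
                         value = 100 + 2 * (0:9),
                         origin_time = 2000:2009)
  g <- suppressWarnings(stage3_gain(vals))  # exact-fit summary warning
  expect_equal(g$intercept, 100, tolerance = 1e-10)
  expect_equal(g$slope, 2, tolerance = 1e-10)
  expect_equal(g$gain_pct, 2, tolerance = 1e-10)
  expect_equal(glance(g)$gain_pct, g$gain_pct)
  td <- suppressWarnings(tidy(g))
  expect_equal(td$estimate, c(100, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  zero <- dplyr::mutate(vals, value = value - 100 - 2 * (0:9))
  expect_error(stage3_gain(zero), "intercept")
  expect_error(stage3_gain(vals[1:2, ]), "3 distinct")
  expect_s3_class(ggplot2::autoplot(g), "ggplot")
})

test_that("the full pipeline recovers an injected trend on one dataset", {
  cfg <- synthetic_config(seed = 58)
  syn <- generate_synthetic(cfg)
  res <- estimate_gain(syn$trials, origin = syn$origin, path = "joint")
  expect_equal(res$gain$slope, cfg$true_gain_per_year, tolerance = 0.25)
  expect_equal(length(res$retained) + sum(res$summaries$excluded |
                                            res$summaries$H2_plot < 0.35),
               nrow(res$summaries))
  # pedigree path runs end to end and trends the same direction
  resp <- estimate_gain(syn$trials, path = "pedigree", ped = syn$pedigree)
  expect_gt(resp$gain$slope, 0)
})
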