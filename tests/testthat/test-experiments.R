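test_that("annualized gain matches closed forms and an OLS oracle", {
  flat <- tibble::tibble(scheme = "s", replicate = 1,
                         elapsed_years = c(0, 5, 10, 15),
                         population_mean = rep(4, 4))
  expect_equal(annualized_gain(flat)$gain_pct, 0)
  lin <- tibble::tibble(scheme = "s", replicate = 1,
                        elapsed_years = 0:15,
                        population_mean = 10 + 0.3 * (0:15))
  expect_equal(annualized_gain(lin)$gain_pct, 3, tolerance = 1e-10)
  set.seed(41)
  jit <- tibble::tibble(scheme = "s", replicate = 1,
                        elapsed_years = seq(0, 15, by = 3),
                        population_mean = 8 + 0.2 * seq(0, 15, by = 3) +
                          rnorm(6, 0, 0.3))
  oracle <- lm(population_mean ~ elapsed_years, jit)
  expect_equal(annualized_gain(jit)$gain_pct,
               100 * coef(oracle)[[2]] / jit$population_mean[1],
               tolerance = 1e-10)
  neg <- dplyr::mutate(flat, population_mean = -1)
  expect_error(annualized_gain(neg), "not positive")
})

test_that("scenario runs are paired and correctly shaped", {
  traj <- run_scenarios(schemes = c("Previous", "GS_F2"), n_reps = 1,
                        seed = 5)
  expect_s3_class(traj, "bg_scenarios")
  expect_equal(sort(unique(traj$scheme)), c("GS_F2", "Previous"))
  expect_equal(sum(traj$scheme == "Previous"), 4)  # cycle 0 + 3 cycles
  expect_equal(sum(traj$scheme == "GS_F2"), 6)     # cycle 0 + 5 cycles
  # paired: both schemes start from the identical burn-in state
  start <- dplyr::filter(traj, cycle == 0)
  expect_equal(start$population_mean[1], start$population_mean[2])
  expect_true(all(diff(dplyr::filter(traj, scheme == "GS_F2")$elapsed_years)
                  > 0))
  expect_true(all(traj$genetic_variance >= 0, na.rm = TRUE))
  p <- ggplot2::autoplot(traj)
  expect_s3_class(p, "ggplot")
})

test_that("three-way ANOVA variance shares behave and match an EMS oracle", {
  lv <- c(1, 2, 3, 4)
  grid <- expand.grid(P = lv, C = lv, S = lv, rep = 1:25)
  # constant response: everything in the residual
  cells0 <- tibble::tibble(P = grid$P, C = grid$C, S = grid$S,
                           response = 1)
  vc0 <- anova_vc(cells0)
  expect_equal(vc0$ss[vc0$source != "Residuals"], rep(0, 7))
  expect_equal(vc0$vc_pct[vc0$source == "Residuals"], 100)
  # response driven by S only (+noise): S dominates, C and P ~ 0
  set.seed(42)
  s_eff <- c(0, 1, 2, 3)
  cells <- tibble::tibble(P = grid$P, C = grid$C, S = grid$S,
                          response = s_eff[grid$S] + rnorm(nrow(grid), 0, 0.5))
  vc <- anova_vc(cells)
  get <- function(s, col) vc[[col]][vc$source == s]
  expect_gt(get("S", "vc_pct"), 10 * max(get("P", "vc_pct"), 1e-9))
  expect_lt(get("C", "vc_pct"), 5)
  # sum of squares decomposes exactly
  tot <- sum((cells$response - mean(cells$response))^2)
  expect_equal(sum(vc$ss), tot, tolerance = 1e-8 * tot)
  # expected-mean-squares oracle, written out independently
  ms <- stats::setNames(vc$ms, vc$source)
  n <- 25; a <- b <- cc <- 4
  s2 <- c(
    P = (ms[["P"]] - ms[["P:C"]] - ms[["P:S"]] + ms[["P:C:S"]]) / (n * b * cc),
    C = (ms[["C"]] - ms[["P:C"]] - ms[["C:S"]] + ms[["P:C:S"]]) / (n * a * cc),
    S = (ms[["S"]] - ms[["P:S"]] - ms[["C:S"]] + ms[["P:C:S"]]) / (n * a * b),
    `P:C` = (ms[["P:C"]] - ms[["P:C:S"]]) / (n * cc),
    `P:S` = (ms[["P:S"]] - ms[["P:C:S"]]) / (n * b),
    `C:S` = (ms[["C:S"]] - ms[["P:C:S"]]) / (n * a),
    `P:C:S` = (ms[["P:C:S"]] - ms[["Residuals"]]) / n,
    Residuals = ms[["Residuals"]])
  s2 <- pmax(s2, 0)
  expect_equal(vc$vc_pct, unname(100 * s2[vc$source] / sum(s2)),
               tolerance = 1e-10)
  # unbalanced input is rejected
  expect_error(anova_vc(cells[-1, ]), "unbalanced")
})

test_that("variance shares recover a known random-effects generating model", {
  set.seed(43)
  lv <- 1:4
  n_rep <- 60
  # fixed factor effects with spreads S > C > P
  base_eff <- c(-1.5, -0.5, 0.5, 1.5)
  pe <- base_eff * 0.5; ce <- base_eff * 1; se <- base_eff * 2
  grid <- expand.grid(P = lv, C = lv, S = lv, rep = seq_len(n_rep))
  cells <- tibble::tibble(
    P = grid$P, C = grid$C, S = grid$S,
    response = pe[grid$P] + ce[grid$C] + se[grid$S] + rnorm(nrow(grid), 0, 1))
  vc <- anova_vc(cells)
  ord <- vc$vc_pct[match(c("S", "C", "P"), vc$source)]
  # with variances 4 > 2 > 1 the shares must come out in that order
  expect_true(ord[1] > ord[2] && ord[2] > ord[3])
})

test_that("Scott-Knott grouping matches a brute-force reference", {
  # reference: independent recursive implementation over ordered splits
  sk_ref <- function(y, s2y, nu, alpha) {
    out <- integer(length(y))
    nextg <- 0
    rec <- function(idx) {
      k <- length(idx)
      if (k == 1) { nextg <<- nextg + 1; out[idx] <<- nextg; return() }
      yk <- y[idx]
      b <- sapply(seq_len(k - 1), function(j) {
        g1 <- yk[1:j]; g2 <- yk[(j + 1):k]
        length(g1) * (mean(g1) - mean(yk))^2 +
          length(g2) * (mean(g2) - mean(yk))^2
      })
      j <- which.max(b)
      sig <- (sum((yk - mean(yk))^2) + nu * s2y) / (k + nu)
      lam <- if (sig > 0) pi * max(b) / (2 * (pi - 2) * sig) else
        if (max(b) > 1e-12) Inf else 0
      if (lam > qchisq(1 - alpha, k / (pi - 2))) {
        rec(idx[1:j]); rec(idx[(j + 1):k])
      } else { nextg <<- nextg + 1; out[idx] <<- nextg }
    }
    rec(order(y, decreasing = TRUE))
    out[order(y, decreasing = TRUE)]
  }
  set.seed(44)
  for (case in 1:20) {
    k <- sample(3:6, 1)
    m <- stats::setNames(rnorm(k, 0, sample(c(0.2, 1, 3), 1)),
                         paste0("t", 1:k))
    mse <- runif(1, 0.01, 1); df <- sample(5:50, 1)
    got <- scott_knott(m, mse, df)
    ref <- sk_ref(sort(m, decreasing = TRUE), mse, df, 0.05)
    expect_equal(as.integer(factor(got$group, levels = unique(got$group))),
                 ref)
  }
  # all-equal means collapse to one group
  eq <- scott_knott(c(a = 1, b = 1, c = 1), ms_error = 0, df_error = 10)
  expect_equal(unique(eq$group), "a")
  # two well-separated clusters split exactly once
  two <- scott_knott(c(a = 10, b = 10.1, c = 0, d = -0.1),
                     ms_error = 0.01, df_error = 20)
  expect_equal(unname(table(two$group)), c(2L, 2L), ignore_attr = TRUE)
})

test_that("a reduced factorial produces the right bookkeeping", {
  cells <- run_factorial(P_levels = c(10, 20), C_levels = 12,
                         S_levels = c(10, 20), n_reps = 2, seed = 9)
  expect_s3_class(cells, "bg_factorial")
  expect_equal(nrow(cells), 8)
  expect_true(all(is.finite(cells$response)))
  expect_equal(dplyr::count(cells, P, C, S)$n, rep(2, 4))
  p <- ggplot2::autoplot(cells)
  expect_s3_class(p, "ggplot")
})
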