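#' Run one scheme forward from a breeding state
#'
#' For GS schemes the initial training set is assembled (if the state does
#' not already carry one) and the RRBLUP model is refit at the start of
#' every cycle from the sliding three-cycle training archive.
#'
#' @param state A post-burn-in [bg_state][run_burn_in()].
#' @param scheme A [build_scheme()].
#' @param n_cycles Number of cycles to run.
#' @param lambda_rule Ridge-parameter rule passed to [fit_rrblup()].
#' @return A list: `trajectory` (tibble, one row per cycle incl. cycle 0)
#'   and the final `state`.
#' @export
run_scheme <- function(state, scheme, n_cycles, lambda_rule = "reml") {
  if (scheme$uses_gs && length(state$ts_archive) == 0) {
    b <- build_initial_ts(state)
    state <- b$state
    state$ts_archive <- list(b$ts)
  }
  state$parents <- set_genetic_values(state$parents, state$arch)
  best0 <- if (!is.null(state$ayt_pop)) {
    max(set_genetic_values(state$ayt_pop, state$arch)$info$genetic_value)
  } else max(state$parents$info$genetic_value)
  rows <- list(tibble::tibble(
    cycle = 0L, elapsed_years = 0,
    population_mean = mean(state$parents$info$genetic_value),
    best_line_value = best0,
    genetic_variance = state$last_f2_var,
    n_evaluated = NA_integer_
  ))
  for (k in seq_len(n_cycles)) {
    model <- if (scheme$uses_gs) {
      fit_rrblup(combine_ts(state$ts_archive), lambda_rule = lambda_rule)
    }
    state <- advance_cycle(state, scheme, gs_model = model)
    rows[[k + 1L]] <- state$last_record
  }
  list(trajectory = dplyr::bind_rows(rows), state = state)
}

#' Replicated comparison of breeding frameworks
#'
#' One founder population, trait architecture, and traditional burn-in are
#' simulated from the master seed; every replicate of every scheme then
#' advances from that same post-burn-in state, so replicates differ only
#' in downstream stochasticity (recombination, selection, phenotypic
#' expression) and the scheme comparison is paired. Per cycle the
#' trajectory records the mean genetic value of the recycled parent pool,
#' the best advanced-trial line, and the F2 genetic variance.
#'
#' @param schemes Character vector of framework names, or a list of
#'   [build_scheme()] objects.
#' @param n_reps Replicates (paper-scale default 100).
#' @param n_cycles Cycles per scheme; default: as many as fit in
#'   `horizon_years`.
#' @param horizon_years Comparison horizon (default 15).
#' @param seed Master seed; the burn-in and the per-replicate streams all
#'   derive from it.
#' @param n_founders Founder population size (default 1000).
#' @param genome Genome map.
#' @param long_grain Scale cohort counts to 80% (the long-grain share).
#' @param lambda_rule Ridge rule for [fit_rrblup()].
#' @return A tibble of class `bg_scenarios`: one row per scheme x replicate
#'   x cycle with `population_mean`, `best_line_value`, `genetic_variance`.
#' @export
run_scenarios <- function(schemes = c("Previous", "Current_Trad", "GS_F3",
                                      "GS_F2", "GS.F2_HTP.F3"),
                          n_reps = 100, n_cycles = NULL, horizon_years = 15,
                          seed = 1, n_founders = 1000, genome = bg_genome(),
                          long_grain = TRUE, lambda_rule = "reml") {
  if (is.character(schemes)) {
    schemes <- lapply(schemes, build_scheme, long_grain = long_grain)
  }
  names(schemes) <- vapply(schemes, `[[`, "", "name")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  founders <- simulate_founders(n_founders, genome)
  arch <- assign_architecture(genome)
  arch <- calibrate_architecture(arch, founders)
  red <- reduce_to_functional(founders, arch)  # exact marginalization
  state0 <- run_burn_in(red$pop, red$arch)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    per_scheme <- lapply(schemes, function(sc) {
      nc <- if (is.null(n_cycles)) cycles_in_horizon(sc, horizon_years)
            else n_cycles
      run_scheme(state0, sc, nc, lambda_rule = lambda_rule)$trajectory
    })
    out[[r]] <- dplyr::bind_rows(per_scheme, .id = "scheme") |>
      dplyr::mutate(replicate = r, .after = "scheme")
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("bg_scenarios", class(res))
  attr(res, "rep_seeds") <- rep_seeds
  res
}

#' Annualized genetic gain over a horizon
#'
#' Per scheme and replicate: 100 x (least-squares slope of the population
#' mean on elapsed years, within the horizon) / (population mean at the
#' start of the horizon). The reference mean is the post-burn-in
#' population mean, which is positive after phenotypic burn-in on the
#' calibrated scale.
#'
#' @param traj A [run_scenarios()] trajectory tibble (or any tibble with
#'   `scheme`, `replicate`, `elapsed_years`, `population_mean`).
#' @param horizon_years Horizon (default 15).
#' @return Tibble with one row per scheme x replicate and `gain_pct`
#'   (% per year).
#' @export
annualized_gain <- function(traj, horizon_years = 15) {
  stopifnot(all(c("scheme", "replicate", "elapsed_years",
                  "population_mean") %in% names(traj)))
  traj |>
    dplyr::filter(.data$elapsed_years <= horizon_years + 1e-9) |>
    dplyr::group_by(.data$scheme, .data$replicate) |>
    dplyr::summarise(gain_pct = {
      if (max(.data$elapsed_years) < min(.data$elapsed_years))
        stop("trajectory does not cover the horizon")
      x <- .data$elapsed_years
      y <- .data$population_mean
      ref <- y[which.min(x)]
      if (!is.finite(ref) || ref <= 0)
        stop("reference mean is not positive; calibrate the trait scale ",
             "so the horizon starts at a positive population mean")
      slope <- if (length(unique(x)) < 2) 0 else
        sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      100 * slope / ref
    }, .groups = "drop")
}

#' Factorial optimization of parents, crosses and progeny size
#'
#' Runs the best framework (`GS.F2_HTP.F3`, with the 70% F2 screen) over
#' every combination of number of parents (P), number of crosses (C) and
#' progeny per cross (S) and records the annualized response over the
#' horizon. A single burn-in population is simulated from the master seed
#' and shared by every run, so replicates vary only in downstream
#' stochasticity. Default levels give the 64-cell design (paper scale:
#' 100 replicates, 6400 runs).
#'
#' The crossing block of a cell draws its C pairs uniformly from the
#' unordered pairs of the P parents (never selfs); the initial parent pool
#' of each cell is the top P lines of the shared burn-in's
#' preliminary-trial cohort.
#'
#' @param P_levels,C_levels,S_levels Factor levels.
#' @param n_reps Replicates per cell.
#' @param horizon_years Horizon (default 15).
#' @param seed Master seed.
#' @param n_founders,genome Founder configuration.
#' @param lambda_rule Ridge rule for [fit_rrblup()].
#' @return A tibble of class `bg_factorial`: one row per run with `P`,
#'   `C`, `S`, `replicate`, `response` (% per year) and `final_mean`.
#' @export
run_factorial <- function(P_levels = c(20, 40, 60, 80),
                          C_levels = c(80, 120, 160, 200),
                          S_levels = c(50, 100, 150, 200),
                          n_reps = 100, horizon_years = 15, seed = 1,
                          n_founders = 1000, genome = bg_genome(),
                          lambda_rule = "reml") {
  cells <- expand.grid(P = P_levels, C = C_levels, S = S_levels,
                       KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  founders <- simulate_founders(n_founders, genome)
  arch <- assign_architecture(genome)
  arch <- calibrate_architecture(arch, founders)
  red <- reduce_to_functional(founders, arch)  # exact marginalization
  state0 <- run_burn_in(red$pop, red$arch)
  b <- build_initial_ts(state0)
  state0 <- b$state
  state0$ts_archive <- list(b$ts)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    rows <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      sc <- build_scheme("GS.F2_HTP.F3", n_parents = cells$P[i],
                         n_crosses = cells$C[i], n_progeny = cells$S[i],
                         screen_f2 = TRUE)
      st <- state0
      pool <- state0$pyt_pop
      st$parents <- pop_subset(pool, select_top(pool$info,
                                                pool$info$phenotype,
                                                cells$P[i]))
      tr <- run_scheme(st, sc, cycles_in_horizon(sc, horizon_years),
                       lambda_rule = lambda_rule)$trajectory
      g <- annualized_gain(dplyr::mutate(tr, scheme = "cell", replicate = r),
                           horizon_years)
      rows[[i]] <- tibble::tibble(
        P = cells$P[i], C = cells$C[i], S = cells$S[i], replicate = r,
        response = g$gain_pct,
        final_mean = tr$population_mean[which.max(tr$elapsed_years)]
      )
    }
    out[[r]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("bg_factorial", class(res))
  attr(res, "rep_seeds") <- rep_seeds
  res
}

#' Three-way ANOVA and variance-component shares of a factorial
#'
#' Fits the balanced three-way fixed-effects ANOVA of the response on P, C
#' and S and, treating all factors and interactions as random, solves the
#' expected-mean-squares equations (method of moments) for the variance
#' components; negative solutions are truncated at zero. `vc_pct` is each
#' component's share of the summed components (including the residual),
#' `ss_pct` the raw sum-of-squares share.
#'
#' @param cells A [run_factorial()] result (needs columns `P`, `C`, `S`,
#'   `response`, balanced replication).
#' @return Tibble with one row per source (`P`, `C`, `S`, interactions,
#'   `Residuals`): `df`, `ss`, `ms`, `f`, `p`, `ss_pct`, `vc_pct`.
#' @export
anova_vc <- function(cells) {
  stopifnot(all(c("P", "C", "S", "response") %in% names(cells)))
  counts <- dplyr::count(cells, .data$P, .data$C, .data$S)
  if (length(unique(counts$n)) != 1)
    stop("unbalanced factorial: unequal replication across cells")
  n <- counts$n[1]
  a <- length(unique(cells$P)); b <- length(unique(cells$C))
  cc <- length(unique(cells$S))
  d <- data.frame(P = factor(cells$P), C = factor(cells$C),
                  S = factor(cells$S), y = cells$response)
  fit <- stats::aov(y ~ P * C * S, data = d)
  tab <- summary(fit)[[1]]
  src <- trimws(rownames(tab))
  ms <- stats::setNames(tab[["Mean Sq"]], src)
  get <- function(s) if (s %in% src) ms[[s]] else 0
  vc <- c(
    P = (get("P") - get("P:C") - get("P:S") + get("P:C:S")) / (n * b * cc),
    C = (get("C") - get("P:C") - get("C:S") + get("P:C:S")) / (n * a * cc),
    S = (get("S") - get("P:S") - get("C:S") + get("P:C:S")) / (n * a * b),
    `P:C` = (get("P:C") - get("P:C:S")) / (n * cc),
    `P:S` = (get("P:S") - get("P:C:S")) / (n * b),
    `C:S` = (get("C:S") - get("P:C:S")) / (n * a),
    `P:C:S` = (get("P:C:S") - get("Residuals")) / n,
    Residuals = get("Residuals")
  )
  vc <- pmax(vc, 0)
  out <- tibble::tibble(
    source = src,
    df = tab[["Df"]],
    ss = tab[["Sum Sq"]],
    ms = tab[["Mean Sq"]],
    f = tab[["F value"]],
    p = tab[["Pr(>F)"]]
  )
  out$ss_pct <- 100 * out$ss / sum(out$ss)
  out$vc_pct <- unname(100 * vc[out$source] / sum(vc))
  out
}

#' Scott-Knott clustering of treatment means
#'
#' The classic procedure: treatments are ordered by mean and recursively
#' split at the cut that maximizes the between-group sum of squares; a
#' split is accepted when the likelihood-ratio statistic
#' `lambda = pi / (2 (pi - 2)) * B0 / sigma0^2` exceeds the chi-squared
#' critical value with `k / (pi - 2)` degrees of freedom at level `alpha`.
#' Groups are therefore disjoint, each treatment belonging to exactly one,
#' lettered in descending order of mean.
#'
#' @param means Named numeric vector of treatment means, or a two-column
#'   data frame (treatment, mean).
#' @param ms_error Error mean square from the ANOVA.
#' @param df_error Its degrees of freedom.
#' @param alpha Significance level (default 0.05).
#' @param n_rep Replicates behind each mean (so the variance of a mean is
#'   `ms_error / n_rep`).
#' @return Tibble with `treatment`, `mean`, `group` (letters).
#' @export
scott_knott <- function(means, ms_error, df_error, alpha = 0.05, n_rep = 1) {
  if (is.data.frame(means)) {
    m <- stats::setNames(means[[2]], means[[1]])
  } else m <- means
  stopifnot(length(m) >= 2, !is.null(names(m)))
  s2y <- ms_error / n_rep
  ord <- order(m, decreasing = TRUE)
  y <- m[ord]
  groups <- integer(length(y))
  next_group <- 0L
  recurse <- function(idx) {
    k <- length(idx)
    if (k == 1) {
      next_group <<- next_group + 1L
      groups[idx] <<- next_group
      return(invisible())
    }
    yk <- y[idx]
    tot <- sum(yk)
    b0 <- -Inf; cut <- 0L
    for (j in seq_len(k - 1)) {
      s1 <- sum(yk[seq_len(j)])
      b <- s1^2 / j + (tot - s1)^2 / (k - j) - tot^2 / k
      if (b > b0) { b0 <- b; cut <- j }
    }
    sigma02 <- (sum((yk - mean(yk))^2) + df_error * s2y) / (k + df_error)
    lambda <- if (sigma02 > 0) {
      pi / (2 * (pi - 2)) * b0 / sigma02
    } else if (b0 > 1e-12) Inf else 0
    crit <- stats::qchisq(1 - alpha, df = k / (pi - 2))
    if (lambda > crit) {
      recurse(idx[seq_len(cut)])
      recurse(idx[(cut + 1):k])
    } else {
      next_group <<- next_group + 1L
      groups[idx] <<- next_group
    }
  }
  recurse(seq_along(y))
  letter <- function(i) {
    paste(rep(letters[(i - 1) %% 26 + 1], (i - 1) %/% 26 + 1), collapse = "")
  }
  tibble::tibble(
    treatment = names(y),
    mean = unname(y),
    group = vapply(groups, letter, "")
  )
}

#' Plot scheme trajectories
#'
#' Replicate-averaged population mean, best-line value and F2 genetic
#' variance over elapsed years for each scheme.
#'
#' @param object A [run_scenarios()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bg_scenarios <- function(object, ...) {
  d <- object |>
    tidyr::pivot_longer(c("population_mean", "best_line_value",
                          "genetic_variance"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$scheme, .data$metric, .data$elapsed_years) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$elapsed_years, .data$value,
                                  colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "years of breeding", y = NULL, colour = "scheme")
}

#' Plot factorial responses
#'
#' Boxplots of the annualized response per P x C x S combination,
#' faceted by progeny size.
#'
#' @param object A [run_factorial()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bg_factorial <- function(object, ...) {
  d <- dplyr::mutate(object,
                     combo = paste0("P", .data$P, "_C", .data$C))
  ggplot2::ggplot(d, ggplot2::aes(.data$combo, .data$response)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~S, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "response to selection (% / year)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
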