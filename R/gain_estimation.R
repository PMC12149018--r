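#' Bonferroni outlier removal for trial records
#'
#' Within each trial x trait, fits the linear model
#' `value ~ genotype + replicate`, tests the observation with the largest
#' absolute studentized residual as a mean-shift outlier, and removes it
#' while the Bonferroni-adjusted p-value `min(1, n * p)` stays below
#' `alpha`; the model is refit after every removal, for at most
#' `max_iter` rounds. Trials without residual degrees of freedom are
#' skipped with a warning.
#'
#' @param records Trial records: `trial_id`, `year`, `location`,
#'   `replicate`, `genotype_id`, `trait`, `value`.
#' @param alpha Significance level for the adjusted p-value (default 0.05).
#' @param max_iter Maximum removals per trial x trait (default 10).
#' @return A list: `records` (clean tibble) and `removals` (log tibble
#'   with the removed rows and their adjusted p-values).
#' @export
bonferroni_outlier_filter <- function(records, alpha = 0.05, max_iter = 10) {
  records <- tibble::as_tibble(records)
  records$.row <- seq_len(nrow(records))
  removed <- list()
  keep <- rep(TRUE, nrow(records))
  for (grp in split(seq_len(nrow(records)),
                    paste(records$trial_id, records$trait, sep = "\r"))) {
    idx <- grp
    for (it in seq_len(max_iter)) {
      d <- records[idx, ]
      ok <- tryCatch({
        f <- stats::lm(value ~ factor(genotype_id) + factor(replicate),
                       data = d)
        stats::df.residual(f) >= 3
      }, error = function(e) FALSE)
      if (!ok) {
        if (it == 1)
          warning("trial ", d$trial_id[1], " / ", d$trait[1],
                  ": too few residual degrees of freedom; outlier test skipped")
        break
      }
      rs <- stats::rstudent(f)
      rs[!is.finite(rs)] <- 0
      w <- which.max(abs(rs))
      n <- length(idx)
      p_raw <- 2 * stats::pt(-abs(rs[w]), df = stats::df.residual(f) - 1)
      p_adj <- min(1, n * p_raw)
      if (p_adj >= alpha) break
      removed[[length(removed) + 1L]] <-
        dplyr::mutate(d[w, ], p_adjusted = p_adj, iteration = it)
      keep[d$.row[w]] <- FALSE
      idx <- idx[-w]
    }
  }
  clean <- records[keep, ]
  clean$.row <- NULL
  log <- if (length(removed)) {
    out <- dplyr::bind_rows(removed)
    out$.row <- NULL
    out
  } else {
    tibble::tibble(trial_id = character(), year = integer(),
                   location = character(), replicate = character(),
                   genotype_id = character(), trait = character(),
                   value = double(), p_adjusted = double(),
                   iteration = integer())
  }
  list(records = clean, removals = log)
}

#' Stage 1: per-trial mixed models
#'
#' For each trial of the chosen trait, fits `value ~ genotype + (1 |
#' replicate)` by REML with genotype fixed, yielding one adjusted mean per
#' genotype with its standard error and weight `1 / SE^2`; then refits with
#' genotype random to estimate the variance components and the plot-basis
#' broad-sense heritability `H2 = sigma2_G / (sigma2_G + sigma2_E)`.
#' Trials whose model cannot be fit (or gives non-finite weights) are
#' flagged and excluded from the means.
#'
#' @param records Clean trial records (see
#'   [bonferroni_outlier_filter()]).
#' @param trait Trait to analyse (default: the single trait present).
#' @return A list: `means` (tibble `genotype_id`, `trial_id`, `year`,
#'   `value`, `se`, `weight`) and `summaries` (tibble `trial_id`, `year`,
#'   `sigma2_G`, `sigma2_E`, `H2_plot`, `n_obs`, `excluded`).
#' @export
stage1_fit <- function(records, trait = NULL) {
  records <- tibble::as_tibble(records)
  if (is.null(trait)) {
    trait <- unique(records$trait)
    stopifnot(length(trait) == 1)
  }
  records <- dplyr::filter(records, .data$trait == !!trait)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  means <- list(); summaries <- list()
  for (tid in unique(records$trial_id)) {
    d <- dplyr::filter(records, .data$trial_id == tid)
    d$genotype_id <- factor(d$genotype_id)
    d$replicate <- factor(d$replicate)
    res <- tryCatch({
      fit_f <- if (nlevels(d$replicate) > 1) {
        suppressMessages(lme4::lmer(value ~ 0 + genotype_id + (1 | replicate),
                                    data = d, REML = TRUE, control = ctrl))
      } else {
        stats::lm(value ~ 0 + genotype_id, data = d)
      }
      est <- if (inherits(fit_f, "merMod")) lme4::fixef(fit_f) else
        stats::coef(fit_f)
      se <- sqrt(Matrix::diag(as.matrix(stats::vcov(fit_f))))
      fit_r <- if (nlevels(d$replicate) > 1) {
        suppressMessages(lme4::lmer(value ~ 1 + (1 | genotype_id) +
                                      (1 | replicate),
                                    data = d, REML = TRUE, control = ctrl))
      } else {
        suppressMessages(lme4::lmer(value ~ 1 + (1 | genotype_id),
                                    data = d, REML = TRUE, control = ctrl))
      }
      vc <- as.data.frame(lme4::VarCorr(fit_r))
      s2g <- vc$vcov[vc$grp == "genotype_id"]
      s2e <- vc$vcov[vc$grp == "Residual"]
      list(est = est, se = se, s2g = s2g, s2e = s2e)
    }, error = function(e) NULL)
    bad <- is.null(res) || any(!is.finite(res$se)) || any(res$se <= 0)
    summaries[[tid]] <- tibble::tibble(
      trial_id = tid, year = d$year[1],
      sigma2_G = if (bad) NA_real_ else res$s2g,
      sigma2_E = if (bad) NA_real_ else res$s2e,
      H2_plot = if (bad) NA_real_ else res$s2g / (res$s2g + res$s2e),
      n_obs = nrow(d), excluded = bad
    )
    if (!bad) {
      means[[tid]] <- tibble::tibble(
        genotype_id = sub("^genotype_id", "", names(res$est)),
        trial_id = tid, year = d$year[1],
        value = unname(res$est), se = unname(res$se),
        weight = 1 / unname(res$se)^2
      )
    }
  }
  list(means = dplyr::bind_rows(means),
       summaries = dplyr::bind_rows(summaries))
}

#' Heritability-based trial quality control
#'
#' Drops trials with plot-basis heritability strictly below the threshold
#' ("lower than 0.35"): a trial at exactly the threshold is retained.
#' Trials already flagged as excluded (failed fits) are also dropped.
#'
#' @param summaries Stage-1 trial summaries.
#' @param threshold Minimum heritability retained (default 0.35).
#' @return Character vector of retained trial ids.
#' @export
filter_trials <- function(summaries, threshold = 0.35) {
  keep <- !summaries$excluded & summaries$H2_plot >= threshold
  summaries$trial_id[keep]
}

#' Year-to-year genotype connectivity
#'
#' For each pair of years, the number of shared genotypes and the
#' percentage `100 * |shared| / |union|` of the two years' genotype sets.
#'
#' @param means Stage-1 adjusted means (needs `genotype_id`, `year`).
#' @return Tibble `year_i`, `year_j` (i < j), `shared`, `pct`.
#' @export
connectivity <- function(means) {
  sets <- split(means$genotype_id, means$year)
  sets <- lapply(sets, unique)
  yrs <- sort(as.numeric(names(sets)))
  if (length(yrs) < 2) stop("connectivity needs at least two years")
  pairs <- utils::combn(seq_along(yrs), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- sets[[as.character(yrs[i])]]; b <- sets[[as.character(yrs[j])]]
    sh <- length(intersect(a, b))
    tibble::tibble(year_i = yrs[i], year_j = yrs[j], shared = sh,
                   pct = 100 * sh / length(union(a, b)))
  })
}

#' Environmental-trend audit on check genotypes
#'
#' Regresses each qualifying check's plot values on the trial year; checks
#' qualify when present in at least `min_presence` of the years. The
#' slopes are an audit of non-genetic trend only and are not used to
#' adjust the data.
#'
#' @param records Trial records of one trait.
#' @param min_presence Minimum fraction of years a check must appear in
#'   (default 0.60).
#' @param checks Optional explicit check ids; by default every genotype
#'   meeting the presence threshold.
#' @return Tibble `genotype_id`, `n_years`, `presence`, `slope`.
#' @export
check_trend <- function(records, min_presence = 0.60, checks = NULL) {
  total_years <- length(unique(records$year))
  pres <- records |>
    dplyr::distinct(.data$genotype_id, .data$year) |>
    dplyr::count(.data$genotype_id, name = "n_years") |>
    dplyr::mutate(presence = .data$n_years / !!total_years)
  if (is.null(checks)) {
    checks <- pres$genotype_id[pres$presence >= min_presence]
  } else {
    checks <- intersect(checks,
                        pres$genotype_id[pres$presence >= min_presence])
  }
  if (length(checks) == 0) {
    warning("no check genotype meets the presence threshold")
    return(tibble::tibble(genotype_id = character(), n_years = integer(),
                          presence = double(), slope = double()))
  }
  purrr::map_dfr(checks, function(g) {
    d <- dplyr::filter(records, .data$genotype_id == g)
    slope <- if (length(unique(d$year)) < 2) 0 else
      unname(stats::coef(stats::lm(value ~ year, data = d))[2])
    tibble::tibble(genotype_id = g,
                   n_years = pres$n_years[pres$genotype_id == g],
                   presence = pres$presence[pres$genotype_id == g],
                   slope = slope)
  })
}

# connected components of the genotype-year incidence graph
gy_components <- function(genotype, year) {
  gs <- unique(genotype); ys <- unique(year)
  comp <- stats::setNames(rep(NA_integer_, length(gs) + length(ys)),
                          c(paste0("g:", gs), paste0("y:", ys)))
  adj_g <- split(paste0("y:", year), paste0("g:", genotype))
  adj_y <- split(paste0("g:", genotype), paste0("y:", year))
  adj <- c(adj_g, adj_y)
  k <- 0L
  for (start in names(comp)) {
    if (!is.na(comp[[start]])) next
    k <- k + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- k
      queue <- c(queue, unlist(adj[[v]], use.names = FALSE))
    }
  }
  comp
}

#' Stage 2, phenotypic path: weighted joint analysis across years
#'
#' Weighted least squares of the stage-1 adjusted means on genotype and
#' year (both fixed), with weights `1 / SE^2` from stage 1 (the diagonal
#' residual weight matrix of the joint model). The returned genotype
#' values are year-corrected: each genotype's effect plus the average
#' estimated year effect, so values are on the scale of a typical
#' evaluation year. Requires the genotype-year incidence graph to be
#' connected; disconnected blocks are reported by name.
#'
#' @param means Stage-1 adjusted means (`genotype_id`, `year`, `value`,
#'   `weight`).
#' @return Tibble `genotype_id`, `value`, with attribute `"year_effects"`
#'   (tibble `year`, `effect` relative to the first year).
#' @export
stage2_joint_fit <- function(means) {
  stopifnot(nrow(means) > 0)
  comp <- gy_components(means$genotype_id, means$year)
  if (length(unique(comp)) > 1) {
    blocks <- split(names(comp), comp)
    stop("genotype-year incidence is disconnected; blocks: ",
         paste(vapply(blocks, function(b)
           paste(utils::head(b, 4), collapse = ","), ""), collapse = " | "))
  }
  d <- dplyr::mutate(means, genotype_id = factor(.data$genotype_id),
                     year_f = factor(.data$year))
  single_year <- nlevels(d$year_f) == 1
  f <- if (single_year) {
    stats::lm(value ~ 0 + genotype_id, data = d, weights = d$weight)
  } else {
    stats::lm(value ~ 0 + genotype_id + year_f, data = d,
              weights = d$weight)
  }
  cf <- stats::coef(f)
  g <- cf[startsWith(names(cf), "genotype_id")]
  yr <- cf[startsWith(names(cf), "year_f")]
  yr_all <- c(0, unname(yr))  # first year is the reference
  out <- tibble::tibble(
    genotype_id = sub("^genotype_id", "", names(g)),
    value = unname(g) + mean(yr_all)
  )
  attr(out, "year_effects") <- tibble::tibble(
    year = as.numeric(levels(d$year_f)), effect = yr_all)
  out
}

#' Stage 2, additive path: pedigree animal-model BLUP
#'
#' Mixed model for the stage-1 adjusted means: year fixed, additive
#' genetic effect random with covariance `A sigma2_a` (the pedigree
#' relationship matrix), residual `N(0, sigma2_e W)` with `W` the diagonal
#' of stage-1 weights. The variance ratio is estimated by single-ratio
#' REML profiling; breeding values for every pedigree member — including
#' unphenotyped founders — are then solved from the mixed-model equations
#' and re-expressed on the trait scale of an average evaluation year (the
#' additive effect plus the mean fitted year effect).
#'
#' @param means Stage-1 adjusted means (`genotype_id`, `year`, `value`,
#'   `weight`); genotype ids must appear in the pedigree.
#' @param ped Pedigree data frame (`id`, `parent1`, `parent2`).
#' @return Tibble `genotype_id`, `value` (breeding value), `phenotyped`
#'   (logical), with attributes `sigma2_a`, `sigma2_e`.
#' @export
stage2_pedigree_blup <- function(means, ped) {
  A <- build_amatrix(ped)
  ids <- colnames(A)
  miss <- setdiff(unique(as.character(means$genotype_id)), ids)
  if (length(miss))
    stop("genotype(s) not in the pedigree: ",
         paste(utils::head(miss, 5), collapse = ", "))
  n <- nrow(means)
  gi <- match(as.character(means$genotype_id), ids)
  yrs <- factor(means$year)
  X <- stats::model.matrix(~yrs)
  Agg <- A[gi, gi]
  est <- reml_onevc(means$value, X, Agg, weights = means$weight)
  if (est$at_boundary)
    warning("additive variance ratio estimated at the search boundary")
  lambda <- est$sigma2_e / max(est$sigma2_g, 1e-12)
  N <- length(ids)
  Zf <- Matrix::sparseMatrix(i = seq_len(n), j = gi, x = 1,
                             dims = c(n, N))
  W <- means$weight
  Ainv <- solve(A)
  XtW <- t(X * W)
  C <- rbind(
    cbind(XtW %*% X, as.matrix(XtW %*% Zf)),
    cbind(t(as.matrix(XtW %*% Zf)),
          as.matrix(Matrix::crossprod(Zf, Zf * W)) + Ainv * lambda)
  )
  rhs <- c(XtW %*% means$value,
           as.vector(Matrix::crossprod(Zf, W * means$value)))
  sol <- solve(C, rhs)
  beta <- sol[seq_len(ncol(X))]
  alpha <- sol[-seq_len(ncol(X))]
  # express breeding values on the trait scale of an average evaluation
  # year, so downstream slope/intercept ratios are interpretable
  baseline <- mean(X %*% beta)
  out <- tibble::tibble(genotype_id = ids, value = unname(alpha) + baseline,
                        phenotyped = ids %in% as.character(means$genotype_id))
  attr(out, "sigma2_a") <- est$sigma2_g
  attr(out, "sigma2_e") <- est$sigma2_e
  out
}

#' Stage 3: the gain regression
#'
#' Ordinary least squares of the stage-2 genotype values on their origin
#' time (year the cross was made, or generation index), with time centred
#' at the earliest origin so the intercept is the baseline performance.
#' The genetic gain is `100 * slope / intercept` (% of baseline per unit
#' time). No weights are applied at this stage.
#'
#' @param values Stage-2 output joined with an origin time: columns
#'   `genotype_id`, `value`, `origin_time`.
#' @return An object of class `bg_gain`; see [tidy.bg_gain()] and
#'   [glance.bg_gain()].
#' @export
stage3_gain <- function(values) {
  stopifnot(all(c("value", "origin_time") %in% names(values)))
  d <- values[stats::complete.cases(values[, c("value", "origin_time")]), ]
  if (length(unique(d$origin_time)) < 3)
    stop("need at least 3 distinct origin times")
  t0 <- min(d$origin_time)
  f <- stats::lm(value ~ I(origin_time - t0), data = d)
  a <- unname(stats::coef(f)[1]); i <- unname(stats::coef(f)[2])
  if (abs(a) < 1e-10)
    stop("intercept is ~0; the gain percentage is undefined on this scale")
  structure(list(
    intercept = a, slope = i, gain_pct = 100 * i / a,
    se_slope = summary(f)$coefficients[2, 2],
    n = nrow(d), t0 = t0, fit = f, data = tibble::as_tibble(d)
  ), class = "bg_gain")
}

#' @export
print.bg_gain <- function(x, ...) {
  cat("<bg_gain> baseline ", format(x$intercept, digits = 5),
      ", slope ", format(x$slope, digits = 5),
      " per unit time (se ", format(x$se_slope, digits = 3),
      "), gain ", format(x$gain_pct, digits = 4), "% per unit time, n = ",
      x$n, "\n", sep = "")
  invisible(x)
}

#' Coefficients of a gain regression
#' @param x A [stage3_gain()] result.
#' @param ... Unused.
#' @return Tibble of the regression terms.
#' @export
tidy.bg_gain <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' One-row summary of a gain regression
#' @param x A [stage3_gain()] result.
#' @param ... Unused.
#' @return Tibble with `intercept`, `slope`, `se_slope`, `gain_pct`, `n`.
#' @export
glance.bg_gain <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope,
                 se_slope = x$se_slope, gain_pct = x$gain_pct, n = x$n)
}

#' Plot a gain regression
#' @param object A [stage3_gain()] result.
#' @param ... Unused.
#' @return A ggplot of genotype values against origin time with the
#'   fitted trend.
#' @export
autoplot.bg_gain <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$origin_time, .data$value)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$intercept -
                           object$slope * object$t0,
                         slope = object$slope, colour = "red") +
    ggplot2::labs(x = "origin time", y = "genotype value")
}

#' Realized genetic gain from historical trial data
#'
#' The full three-stage pipeline: Bonferroni outlier removal, per-trial
#' mixed models (adjusted means, weights, plot-basis heritability),
#' heritability-based trial filtering, the weighted joint analysis
#' (`path = "joint"`) or pedigree animal-model BLUP (`path = "pedigree"`),
#' and the gain regression on origin time.
#'
#' @param records Trial records (see [read_trials()]).
#' @param origin Data frame `genotype_id`, `origin_time` (year of cross or
#'   generation index). For `path = "pedigree"` with `origin = NULL`, the
#'   generation count from the pedigree is used.
#' @param trait Trait analysed.
#' @param path `"joint"` (year-corrected means) or `"pedigree"` (additive
#'   breeding values, requires `ped`).
#' @param ped Pedigree data frame (for the pedigree path).
#' @param h2_threshold Trial-retention threshold (default 0.35).
#' @param alpha_outlier Bonferroni level (default 0.05).
#' @return A list of class `bg_gain_pipeline`: `gain` (a [stage3_gain()]
#'   object), `values`, `means`, `summaries`, `retained`, `removals`,
#'   `connectivity`.
#' @export
estimate_gain <- function(records, origin = NULL, trait = NULL,
                          path = c("joint", "pedigree"), ped = NULL,
                          h2_threshold = 0.35, alpha_outlier = 0.05) {
  path <- match.arg(path)
  if (path == "pedigree" && is.null(ped))
    stop("the pedigree path needs `ped`")
  qc <- bonferroni_outlier_filter(records, alpha = alpha_outlier)
  s1 <- stage1_fit(qc$records, trait = trait)
  retained <- filter_trials(s1$summaries, threshold = h2_threshold)
  means <- dplyr::filter(s1$means, .data$trial_id %in% retained)
  conn <- if (length(unique(means$year)) >= 2) connectivity(means) else NULL
  values <- if (path == "joint") {
    stage2_joint_fit(means)
  } else {
    v <- stage2_pedigree_blup(means, ped)
    v[, c("genotype_id", "value")]
  }
  if (is.null(origin)) {
    if (path != "pedigree")
      stop("`origin` is required for the joint path")
    gen <- count_generations(ped)
    origin <- tibble::tibble(genotype_id = as.character(gen$id),
                             origin_time = gen$generation)
  }
  values <- dplyr::inner_join(values,
                              dplyr::mutate(origin,
                                            genotype_id =
                                              as.character(.data$genotype_id)),
                              by = "genotype_id")
  gain <- stage3_gain(values)
  structure(list(gain = gain, values = values, means = means,
                 summaries = s1$summaries, retained = retained,
                 removals = qc$removals, connectivity = conn),
            class = "bg_gain_pipeline")
}

#' @export
print.bg_gain_pipeline <- function(x, ...) {
  cat("<bg_gain_pipeline> ", length(x$retained), " trials retained (of ",
      nrow(x$summaries), "), ", nrow(x$removals),
      " outlier plot(s) removed\n", sep = "")
  print(x$gain)
  invisible(x)
}
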