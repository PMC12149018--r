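#' Configuration for the synthetic historical-trial generator
#'
#' Defaults emulate the structure of a two-decade rice breeding archive at
#' about one tenth of its plot count (fast enough for routine testing):
#' 24 trial years, two trials per year, ~25 entries per trial in two
#' replicates (RCBD), moderate year-to-year genotype overlap, plot-basis
#' heritability around 0.64, and a six-generation pedigree with founders.
#' A `paper_scale = TRUE` preset generates roughly ten times the plots.
#'
#' Units are kg/ha-like: baseline 6000, additive trend 56.54 per year,
#' genetic standard deviation 400 within a cohort.
#'
#' @param n_years,start_year Trial-year span.
#' @param trials_per_year Trials conducted each year (entries shared).
#' @param locations Location labels cycled over trials.
#' @param genotypes_per_year Entries per trial year (including checks).
#' @param overlap_fraction Target consecutive-year connectivity, on the
#'   shared/union percentage scale used by [connectivity()] (0-1).
#' @param reps_per_trial RCBD replicates.
#' @param baseline_mean Trait baseline (intercept of the true trend).
#' @param sigma2_g Genetic variance within an origin cohort.
#' @param sigma2_year,sigma2_trial,sigma2_rep,sigma2_e Year, trial-within-
#'   year, replicate and plot-residual variances.
#' @param true_gain_per_year Injected additive genetic trend (trait units
#'   per origin year).
#' @param n_checks Long-term check genotypes present in every year.
#' @param check_trend Environmental (non-genetic) trend added to the year
#'   effects, trait units per year; the check audit should recover it.
#' @param pedigree_depth Generations beyond the founders.
#' @param n_founders,fam_per_gen,prog_per_fam Pedigree sizes.
#' @param paper_scale If `TRUE`, scale counts to ~27,000 plots.
#' @param seed Integer seed.
#' @return A list of class `bg_syn_config`.
#' @export
synthetic_config <- function(n_years = 24, start_year = 1999,
                             trials_per_year = 2,
                             locations = c("RRS", "NE", "SW"),
                             genotypes_per_year = 25,
                             overlap_fraction = 0.25,
                             reps_per_trial = 2,
                             baseline_mean = 6000,
                             sigma2_g = 160000,
                             sigma2_year = 90000,
                             sigma2_trial = 10000,
                             sigma2_rep = 2500,
                             sigma2_e = 90000,
                             true_gain_per_year = 56.54,
                             n_checks = 2,
                             check_trend = 0,
                             pedigree_depth = 6,
                             n_founders = 30,
                             fam_per_gen = 12,
                             prog_per_fam = 8,
                             paper_scale = FALSE,
                             seed = 1L) {
  if (paper_scale) {
    trials_per_year <- 7
    genotypes_per_year <- 80
    n_founders <- 60
    fam_per_gen <- 30
    prog_per_fam <- 14
  }
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1,
            sigma2_g >= 0, sigma2_e >= 0, pedigree_depth >= 1,
            n_checks < genotypes_per_year)
  structure(as.list(environment()), class = "bg_syn_config")
}

#' Generate a pedigree with known breeding values and an additive trend
#'
#' Founders are generation 0; each later generation is produced by
#' crossing pairs from the previous one, with offspring true breeding
#' value = mid-parent + Mendelian-sampling noise (variance `sigma2_g / 2`)
#' plus a common selection shift that places each cohort's mean breeding
#' value exactly on the injected trend line
#' `true_gain_per_year * (origin_year - start_year)`. With zero Mendelian
#' variance the centred offspring value is therefore exactly the centred
#' mid-parent value.
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble `id`, `parent1`, `parent2`, `generation`,
#'   `origin_year`, `true_bv`.
#' @export
generate_pedigree <- function(cfg) {
  set.seed(cfg$seed)
  # founder cohort predates the trial span so early trial years have
  # material; the last cohort originates near the final trial year
  origin_of <- function(g)
    (cfg$start_year - 4) + round(g * (cfg$n_years + 3) / cfg$pedigree_depth)
  id0 <- sprintf("G%04d", seq_len(cfg$n_founders))
  bv0 <- stats::rnorm(cfg$n_founders, 0, sqrt(cfg$sigma2_g))
  bv0 <- bv0 - mean(bv0) +
    cfg$true_gain_per_year * (origin_of(0) - cfg$start_year)
  rows <- list(tibble::tibble(
    id = id0, parent1 = NA_character_, parent2 = NA_character_,
    generation = 0L, origin_year = origin_of(0), true_bv = bv0))
  prev_ids <- id0; prev_bv <- bv0
  counter <- cfg$n_founders
  for (g in seq_len(cfg$pedigree_depth)) {
    n_off <- cfg$fam_per_gen * cfg$prog_per_fam
    fams <- t(replicate(cfg$fam_per_gen, sample(seq_along(prev_ids), 2)))
    p1 <- rep(fams[, 1], each = cfg$prog_per_fam)
    p2 <- rep(fams[, 2], each = cfg$prog_per_fam)
    mid <- (prev_bv[p1] + prev_bv[p2]) / 2
    bv <- mid + stats::rnorm(n_off, 0, sqrt(cfg$sigma2_g / 2))
    target <- cfg$true_gain_per_year * (origin_of(g) - cfg$start_year)
    bv <- bv - mean(bv) + target
    ids <- sprintf("G%04d", counter + seq_len(n_off))
    counter <- counter + n_off
    rows[[g + 1L]] <- tibble::tibble(
      id = ids, parent1 = prev_ids[p1], parent2 = prev_ids[p2],
      generation = g, origin_year = origin_of(g), true_bv = bv)
    prev_ids <- ids; prev_bv <- bv
  }
  dplyr::bind_rows(rows)
}

#' Generate RCBD trial records from a pedigree
#'
#' Each year carries `genotypes_per_year` entries: the checks, a carried
#' share of the previous year's entries sized so the consecutive-year
#' connectivity (shared/union) matches `overlap_fraction`, and fresh
#' entries drawn from the most recent origin cohorts available — so later
#' years evaluate genetically newer material, which is what lets the
#' pipeline separate the genetic trend from year effects. A plot value
#' decomposes exactly as
#' `value = baseline + BV + year + trial + replicate + residual`,
#' and every component is stored in the truth table.
#'
#' @param cfg A [synthetic_config()].
#' @param ped A [generate_pedigree()] table.
#' @return A list: `trials` (record tibble ready for [stage1_fit()]),
#'   `truth` (per-plot decomposition), `origin` (tibble `genotype_id`,
#'   `origin_time`), `checks` (check ids).
#' @export
generate_trials <- function(cfg, ped) {
  set.seed(cfg$seed + 1L)
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  m <- cfg$genotypes_per_year
  f <- cfg$overlap_fraction
  k_shared <- max(cfg$n_checks, round(2 * m * f / (1 + f)))
  checks <- ped$id[ped$generation == 0][seq_len(cfg$n_checks)]
  year_eff <- stats::rnorm(cfg$n_years, 0, sqrt(cfg$sigma2_year)) +
    cfg$check_trend * (years - cfg$start_year)
  names(year_eff) <- years
  used <- character(0)
  prev <- character(0)
  sets <- list()
  for (y in years) {
    carry <- if (length(prev)) {
      pool <- setdiff(prev, checks)
      sample(pool, min(length(pool), k_shared - cfg$n_checks))
    } else character(0)
    need <- m - cfg$n_checks - length(carry)
    eligible <- ped[ped$origin_year <= y & !(ped$id %in% c(used, checks)), ]
    if (nrow(eligible) < need) {  # allow reuse of older retired material
      eligible <- ped[ped$origin_year <= y &
                        !(ped$id %in% c(prev, checks)), ]
    }
    if (nrow(eligible) < need)
      stop("overlap/overall sizes infeasible: not enough genotypes by ", y)
    w <- exp(-(y - eligible$origin_year) / 2)
    fresh <- sample(eligible$id, need, prob = w)
    sets[[as.character(y)]] <- c(checks, carry, fresh)
    used <- union(used, fresh)
    prev <- sets[[as.character(y)]]
  }
  bv <- stats::setNames(ped$true_bv, ped$id)
  plots <- list()
  for (yi in seq_along(years)) {
    y <- years[yi]
    gset <- sets[[as.character(y)]]
    for (tr in seq_len(cfg$trials_per_year)) {
      tid <- sprintf("T%d_%d", y, tr)
      loc <- cfg$locations[(tr - 1) %% length(cfg$locations) + 1]
      t_eff <- stats::rnorm(1, 0, sqrt(cfg$sigma2_trial))
      r_eff <- stats::rnorm(cfg$reps_per_trial, 0, sqrt(cfg$sigma2_rep))
      for (r in seq_len(cfg$reps_per_trial)) {
        res <- stats::rnorm(length(gset), 0, sqrt(cfg$sigma2_e))
        plots[[length(plots) + 1L]] <- tibble::tibble(
          trial_id = tid, year = y, location = loc,
          replicate = paste0("R", r), genotype_id = gset,
          trait = "grain_yield",
          baseline = cfg$baseline_mean, bv = unname(bv[gset]),
          year_effect = unname(year_eff[as.character(y)]),
          trial_effect = t_eff, rep_effect = r_eff[r], residual = res
        )
      }
    }
  }
  truth <- dplyr::bind_rows(plots)
  truth$value <- truth$baseline + truth$bv + truth$year_effect +
    truth$trial_effect + truth$rep_effect + truth$residual
  trials <- truth[, c("trial_id", "year", "location", "replicate",
                      "genotype_id", "trait", "value")]
  list(trials = trials, truth = truth,
       origin = tibble::tibble(genotype_id = ped$id,
                               origin_time = ped$origin_year),
       checks = checks)
}

#' Generate a complete synthetic dataset
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `pedigree`, `trials`, `truth`, `origin`, `checks`,
#'   `config`.
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  ped <- generate_pedigree(cfg)
  tr <- generate_trials(cfg, ped)
  c(list(pedigree = ped), tr, list(config = cfg))
}
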