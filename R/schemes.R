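#' The five breeding frameworks
#'
#' Builds the stage pipeline of one of the program's five frameworks:
#'
#' * `Previous`: the traditional phenotypic pipeline (5-year cycle) —
#'   crossing, F2, panicle-row phenotypic selection at F3, preliminary
#'   yield trial (PYT) at F4, regional trial (RYT) at F5, advanced trial
#'   (AYT) at F6; parents recycled from the PYT and AYT pools.
#' * `Current_Trad`: `Previous` plus one more phenotypic evaluation (a
#'   second regional-trial year, H2 = 0.72) before the AYT.
#' * `GS_F3`: genomic selection (GEBV truncation) at F3 replaces the
#'   panicle-row phenotypic selection; parents are recycled at F3 from the
#'   top GEBVs (3.75-year cycle); the training set is updated with
#'   PYT-level data from the last three cycles.
#' * `GS_F2`: GEBV truncation directly on the (screened) F2 and parent
#'   recycling at F2 (3-year cycle); training updates use the F3:5
#'   material of the last three cycles.
#' * `GS.F2_HTP.F3`: as `GS_F2` plus a high-throughput-phenotyping
#'   selection round at the F3 progeny-row stage (accuracy 0.40, 1200
#'   genotypes kept); parents are the top GEBVs among the HTP survivors.
#'
#' Within a 15-year horizon the cycle lengths (5, 5, 3.75, 3, 3 years)
#' give 3, 3, 4, 5 and 5 completed cycles respectively.
#'
#' A negative phenotypic pre-screen of the F2 (only the top 70% advance)
#' is on by default for the three GS schemes.
#'
#' @param name One of `"Previous"`, `"Current_Trad"`, `"GS_F3"`,
#'   `"GS_F2"`, `"GS.F2_HTP.F3"`.
#' @param n_parents,n_crosses,n_progeny Crossing-block numbers (defaults
#'   40 parents, 160 crosses, 100 F2 per cross).
#' @param long_grain If `TRUE`, all cohort counts (crosses, progeny, stage
#'   survivors) are scaled to 80%, representing the long-grain share of
#'   the program; the number of parents is unchanged.
#' @param screen_f2 Override the F2 pre-screen flag.
#' @return An object of class `bg_scheme`.
#' @export
build_scheme <- function(name = c("Previous", "Current_Trad", "GS_F3",
                                  "GS_F2", "GS.F2_HTP.F3"),
                         n_parents = 40, n_crosses = 160, n_progeny = 100,
                         long_grain = FALSE, screen_f2 = NULL) {
  name <- match.arg(name)
  ypc <- c(Previous = 5, Current_Trad = 5, GS_F3 = 3.75,
           GS_F2 = 3, "GS.F2_HTP.F3" = 3)[[name]]
  gs_stage <- switch(name, Previous = , Current_Trad = "none",
                     GS_F3 = "F3", GS_F2 = , "GS.F2_HTP.F3" = "F2")
  uses_gs <- gs_stage != "none"
  if (is.null(screen_f2)) screen_f2 <- uses_gs
  numbers <- list(
    n_parents = n_parents, n_crosses = n_crosses, n_progeny = n_progeny,
    n_pyt = 1500L, n_ryt = 200L, n_ryt2 = 40L, n_ayt = 10L,
    n_htp = 1200L, n_htp_pool = 3000L,
    parents_from_ayt = max(1L, min(10L, round(0.25 * n_parents)))
  )
  numbers$parents_from_pyt <- n_parents - numbers$parents_from_ayt
  if (long_grain) {
    for (f in c("n_crosses", "n_progeny", "n_pyt", "n_ryt", "n_ryt2",
                "n_ayt", "n_htp", "n_htp_pool"))
      numbers[[f]] <- max(1L, as.integer(round(0.8 * numbers[[f]])))
  }
  h2 <- stats::setNames(heritability_schedule()$H2, heritability_schedule()$stage)
  structure(list(
    name = name, years_per_cycle = ypc, uses_gs = uses_gs,
    gs_stage = gs_stage, htp = name == "GS.F2_HTP.F3",
    ryt2 = name == "Current_Trad", screen_f2 = screen_f2,
    screen_keep = 0.70, htp_accuracy = 0.40,
    numbers = numbers, H2 = h2
  ), class = "bg_scheme")
}

#' @export
print.bg_scheme <- function(x, ...) {
  cat("<bg_scheme> ", x$name, ": ", x$numbers$n_parents, " parents, ",
      x$numbers$n_crosses, " crosses x ", x$numbers$n_progeny,
      " F2; cycle = ", x$years_per_cycle, " years",
      if (x$uses_gs) paste0("; GS at ", x$gs_stage),
      if (x$htp) "; HTP at F3", "\n", sep = "")
  invisible(x)
}

#' Stage table of a breeding scheme
#' @param x A `bg_scheme`.
#' @param ... Unused.
#' @return Tibble of ordered stages with the selection signal, the
#'   evaluation accuracy or heritability, and the number kept.
#' @export
tidy.bg_scheme <- function(x, ...) {
  np <- x$numbers
  n_f2 <- np$n_crosses * np$n_progeny
  rows <- list(
    tibble::tibble(stage = "F2", signal = if (x$screen_f2)
      "negative-phenotypic" else "none",
      value = if (x$screen_f2) x$H2[["F2"]] else NA_real_,
      n_kept = if (x$screen_f2) floor(x$screen_keep * n_f2) else n_f2))
  rows <- c(rows, switch(
    x$gs_stage,
    none = list(
      tibble::tibble(stage = "F3", signal = "phenotype",
                     value = x$H2[["F3"]], n_kept = np$n_pyt),
      tibble::tibble(stage = "F4 (PYT)", signal = "phenotype",
                     value = x$H2[["F4"]], n_kept = np$n_ryt),
      tibble::tibble(stage = "F5 (RYT)", signal = "phenotype",
                     value = x$H2[["F5"]],
                     n_kept = if (x$ryt2) np$n_ryt2 else np$n_ayt),
      if (x$ryt2)
        tibble::tibble(stage = "F6 (RYT2)", signal = "phenotype",
                       value = x$H2[["F6"]], n_kept = np$n_ayt),
      tibble::tibble(stage = "AYT", signal = "phenotype",
                     value = x$H2[["F7"]], n_kept = np$n_ayt)),
    F3 = list(
      tibble::tibble(stage = "F3", signal = "GEBV", value = NA_real_,
                     n_kept = np$n_pyt),
      tibble::tibble(stage = "F4 (PYT)", signal = "phenotype",
                     value = x$H2[["F4"]], n_kept = np$n_ryt)),
    F2 = c(
      if (x$htp) list(
        tibble::tibble(stage = "F2 (GS)", signal = "GEBV", value = NA_real_,
                       n_kept = np$n_htp_pool),
        tibble::tibble(stage = "F3 (HTP)", signal = "HTP-proxy",
                       value = x$htp_accuracy, n_kept = np$n_htp))
      else list(
        tibble::tibble(stage = "F2 (GS)", signal = "GEBV", value = NA_real_,
                       n_kept = np$n_pyt)),
      list(tibble::tibble(stage = "F4 (PYT)", signal = "phenotype",
                          value = x$H2[["F4"]], n_kept = np$n_ryt)))
  ))
  dplyr::bind_rows(rows)
}

#' Completed cycles within a horizon
#' @param scheme A `bg_scheme`.
#' @param horizon_years Horizon in years (default 15).
#' @return Integer number of full cycles that fit in the horizon.
#' @export
cycles_in_horizon <- function(scheme, horizon_years = 15) {
  as.integer(floor(horizon_years / scheme$years_per_cycle + 1e-9))
}

# ids of the top-n individuals by a score; ties broken by id order
select_top <- function(info, score, n) {
  if (n > nrow(info))
    stop("requesting ", n, " survivors from ", nrow(info), " candidates")
  info$id[order(-score, info$id)][seq_len(n)]
}

# unordered cross pairs from a parent pool; every parent used at least once
# when feasible, pairs sampled with replacement (never selfs) only when the
# requested number exceeds the distinct pairs available
sample_cross_pairs <- function(ids, n_crosses) {
  n <- length(ids)
  stopifnot(n >= 2)
  all_pairs <- t(utils::combn(ids, 2))
  npairs <- nrow(all_pairs)
  if (n_crosses <= npairs) {
    for (try in seq_len(100)) {
      pick <- all_pairs[sample.int(npairs, n_crosses), , drop = FALSE]
      if (length(unique(as.vector(pick))) == n || n_crosses < ceiling(n / 2))
        return(pick)
    }
    return(pick)
  }
  extra <- all_pairs[sample.int(npairs, n_crosses - npairs, replace = TRUE), ,
                     drop = FALSE]
  rbind(all_pairs, extra)
}

pop_bind <- function(a, b) {
  new_bg_pop(cbind(a$hap1, b$hap1), cbind(a$hap2, b$hap2),
             dplyr::bind_rows(a$info, b$info), a$genome)
}

#' Proxy selection by high-throughput phenotyping
#'
#' Ranks individuals on a proxy trait correlated with the true genetic
#' value at a stated accuracy: `proxy = scale(G) * r + noise * sqrt(1 - r^2)`,
#' and keeps the top `n_keep`.
#'
#' @param pop A `bg_pop` with genetic values set.
#' @param accuracy Correlation of the proxy with the genetic value, in (0, 1].
#' @param n_keep Number of individuals kept (default 1200).
#' @param seed Optional integer seed.
#' @return The selected sub-population; the proxy values of all candidates
#'   are attached as attribute `"htp_proxy"`.
#' @export
htp_select <- function(pop, accuracy = 0.40, n_keep = 1200, seed = NULL) {
  stopifnot(accuracy > 0, accuracy <= 1)
  if (n_keep > pop_size(pop))
    stop("n_keep exceeds the number of candidates")
  if (!is.null(seed)) set.seed(seed)
  g <- pop$info$genetic_value
  if (anyNA(g)) stop("genetic values must be set before htp_select()")
  gs <- if (stats::sd(g) > 0) as.numeric(scale(g)) else rep(0, length(g))
  proxy <- gs * accuracy + stats::rnorm(length(g)) * sqrt(1 - accuracy^2)
  out <- pop_subset(pop, select_top(pop$info, proxy, n_keep))
  attr(out, "htp_proxy") <- tibble::tibble(id = pop$info$id, proxy = proxy)
  out
}

new_bg_state <- function(parents, arch, next_id) {
  structure(list(cycle_index = 0L, elapsed_years = 0,
                 parents = parents, pyt_pop = NULL, ayt_pop = NULL,
                 arch = arch, next_id = as.integer(next_id),
                 ts_archive = list(), last_f2_var = NA_real_,
                 last_record = NULL),
            class = "bg_state")
}

#' @export
print.bg_state <- function(x, ...) {
  cat("<bg_state> cycle ", x$cycle_index, ", ", x$elapsed_years,
      " years elapsed, ", pop_size(x$parents), " parents\n", sep = "")
  invisible(x)
}

#' Burn-in: the common improved starting population
#'
#' Selects the base parents as the top `n_parents` founders by phenotype
#' (evaluated at the program's initial broad-sense heritability of 0.63)
#' and runs `n_cycles` cycles of the traditional `Previous` scheme. All
#' downstream scenario comparisons start from the returned state.
#'
#' @param founders Founder `bg_pop` (>= 1000 individuals recommended).
#' @param arch Calibrated trait architecture.
#' @param n_cycles Burn-in cycles (default 3, i.e. 15 years).
#' @param n_parents Size of the recurrent parent pool (default 40).
#' @param scheme Scheme used during burn-in (default `Previous`).
#' @param select If `FALSE`, parents are picked at random (drift control).
#' @param seed Optional integer seed.
#' @return A `bg_state` positioned after the burn-in.
#' @export
run_burn_in <- function(founders, arch, n_cycles = 3, n_parents = 40,
                        scheme = build_scheme("Previous",
                                              n_parents = n_parents),
                        select = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  founders <- phenotype(founders, arch, H2 = 0.63)
  ids <- if (select) {
    select_top(founders$info, founders$info$phenotype, n_parents)
  } else {
    sample(founders$info$id, n_parents)
  }
  parents <- pop_subset(founders, ids)
  state <- new_bg_state(parents, arch, max(founders$info$id) + 1L)
  for (k in seq_len(n_cycles)) {
    state <- advance_cycle(state, scheme, select = select)
  }
  state$cycle_index <- 0L
  state$elapsed_years <- 0
  state
}

#' Advance a breeding state by one full cycle
#'
#' Runs crossing, F2 production, the optional 70% negative F2 screen, the
#' scheme's stagewise selection (phenotypic, GEBV, and/or HTP), the variety
#' track up to the advanced trial, parent recycling, and the
#' training-archive update for GS schemes.
#'
#' @param state A `bg_state`.
#' @param scheme A `bg_scheme`.
#' @param gs_model Fitted [fit_rrblup()] model; required iff the scheme
#'   uses GEBV signals.
#' @param select If `FALSE`, all selection steps pick at random (drift
#'   control for neutrality checks).
#' @return The updated state; the per-cycle summary is in
#'   `state$last_record`.
#' @export
advance_cycle <- function(state, scheme, gs_model = NULL, select = TRUE) {
  if (scheme$uses_gs && is.null(gs_model))
    stop("scheme ", scheme$name, " needs a fitted gs_model")
  np <- scheme$numbers
  arch <- state$arch
  next_id <- state$next_id
  reg <- function(pop) { next_id <<- max(pop$info$id) + 1L; pop }
  rscore <- function(n, score) if (select) score else stats::runif(n)
  # top-n row indices among `rows` ranked by score (ties by row order)
  pick <- function(rows, score, n) rows[order(-score, rows)][seq_len(min(n, length(rows)))]
  need <- function(n, avail, what) {
    if (n > avail)
      stop("requesting ", n, " ", what, " from ", avail, " candidates")
  }

  pairs <- sample_cross_pairs(state$parents$info$id, np$n_crosses)
  r1 <- match(pairs[, 1], state$parents$info$id)
  r2 <- match(pairs[, 2], state$parents$info$id)
  f1 <- reg(breed_progeny(state$parents, r1, r2, arch, generation = "F1",
                          id_start = next_id))
  rows <- rep(seq_len(pop_size(f1)), each = np$n_progeny)
  gebv_at_f2 <- scheme$uses_gs && scheme$gs_stage == "F2"
  f2 <- reg(breed_progeny(f1, rows, rows, arch,
                          model = if (gebv_at_f2) gs_model,
                          generation = "F2", id_start = next_id))
  gv2 <- f2$info$genetic_value
  n2 <- pop_size(f2)
  f2_var <- stats::var(gv2)
  active <- seq_len(n2)
  if (scheme$screen_f2) {
    ve <- f2_var * (1 - scheme$H2[["F2"]]) / scheme$H2[["F2"]]
    ph <- gv2 + stats::rnorm(n2, 0, sqrt(max(ve, 0)))
    f2$info$phenotype <- ph
    active <- pick(seq_len(n2), rscore(n2, ph),
                   floor(scheme$screen_keep * n2))
  }
  advance <- function(pop, rows, gen, model = NULL) {
    reg(breed_progeny(pop, rows, rows, arch, model = model,
                      generation = gen, inherit_line = TRUE,
                      id_start = next_id))
  }
  ts_new <- NULL

  if (!scheme$uses_gs) {
    # panicle rows: every F2 plant sends one F3 row, phenotyped
    f3 <- advance(f2, active, "F3")
    f3 <- phenotype(f3, arch, H2 = scheme$H2[["F3"]])
    k <- pick(seq_len(pop_size(f3)),
              rscore(pop_size(f3), f3$info$phenotype), np$n_pyt)
    f4 <- advance(f3, k, "F4")
    f4 <- phenotype(f4, arch, H2 = scheme$H2[["F4"]])
    pyt_pop <- f4
    k <- pick(seq_len(pop_size(f4)),
              rscore(pop_size(f4), f4$info$phenotype), np$n_ryt)
    f5 <- advance(f4, k, "F5")
    f5 <- phenotype(f5, arch, H2 = scheme$H2[["F5"]])
    if (scheme$ryt2) {
      k <- pick(seq_len(pop_size(f5)),
                rscore(pop_size(f5), f5$info$phenotype), np$n_ryt2)
      f6 <- advance(f5, k, "F6")
      f6 <- phenotype(f6, arch, H2 = scheme$H2[["F6"]])
      k <- pick(seq_len(pop_size(f6)),
                rscore(pop_size(f6), f6$info$phenotype), np$n_ayt)
      ayt <- advance(f6, k, "F7")
    } else {
      k <- pick(seq_len(pop_size(f5)),
                rscore(pop_size(f5), f5$info$phenotype), np$n_ayt)
      ayt <- advance(f5, k, "F6")
    }
    ayt <- phenotype(ayt, arch, H2 = scheme$H2[["F7"]])
    # parents: best advanced-trial lines plus the best remaining PYT lines
    n_ayt_par <- min(np$parents_from_ayt, pop_size(ayt))
    ayt_sel <- pop_subset(ayt, pick(ayt$info$id,
                                    rscore(pop_size(ayt),
                                           ayt$info$phenotype), n_ayt_par))
    cand <- which(!(pyt_pop$info$line_id %in% ayt_sel$info$line_id))
    n_pyt_par <- np$n_parents - n_ayt_par
    need(n_pyt_par, length(cand), "parents")
    kp <- pick(cand, rscore(length(cand), pyt_pop$info$phenotype[cand]),
               n_pyt_par)
    parents <- pop_bind(ayt_sel, pop_subset(pyt_pop, pyt_pop$info$id[kp]))
  } else if (scheme$gs_stage == "F3") {
    f3 <- advance(f2, active, "F3", model = gs_model)
    gebv <- attr(f3, "gebv")
    nf3 <- pop_size(f3)
    need(np$n_parents, nf3, "parents")
    sc3 <- rscore(nf3, gebv)
    parents <- pop_subset(f3, f3$info$id[pick(seq_len(nf3), sc3,
                                              np$n_parents)])
    k <- pick(seq_len(nf3), sc3, np$n_pyt)
    f4 <- advance(f3, k, "F4")
    f4 <- phenotype(f4, arch, H2 = scheme$H2[["F4"]])
    pyt_pop <- f4
    ts_new <- training_set(marker_codes(f4, arch), f4$info$phenotype,
                           ids = f4$info$line_id,
                           cycle = state$cycle_index + 1L)
    ayt <- gs_variety_track(f4, np, scheme, arch, rscore, pick, advance)
  } else {
    gebv2 <- attr(f2, "gebv")
    sc2 <- rscore(length(active), gebv2[active])
    if (scheme$htp) {
      pool <- pick(active, sc2, np$n_htp_pool)
      f3 <- advance(f2, pool, "F3")
      f3 <- htp_select(f3, scheme$htp_accuracy,
                       min(np$n_htp, pop_size(f3)))
      gebv3 <- gebv_pop(f3, arch, gs_model)
      nf3 <- pop_size(f3)
      need(np$n_parents, nf3, "parents")
      sc3 <- rscore(nf3, gebv3)
      parents <- pop_subset(f3, f3$info$id[pick(seq_len(nf3), sc3,
                                                np$n_parents)])
      k3 <- pick(seq_len(nf3), sc3, np$n_pyt)
    } else {
      need(np$n_parents, length(active), "parents")
      parents <- pop_subset(f2, f2$info$id[pick(active, sc2,
                                                np$n_parents)])
      f3 <- advance(f2, pick(active, sc2, np$n_pyt), "F3")
      k3 <- seq_len(pop_size(f3))
    }
    f4 <- advance(f3, k3, "F4")
    f4 <- phenotype(f4, arch, H2 = scheme$H2[["F4"]])
    pyt_pop <- f4
    ts_new <- training_set(marker_codes(f4, arch), f4$info$phenotype,
                           ids = f4$info$line_id,
                           cycle = state$cycle_index + 1L)
    ayt <- gs_variety_track(f4, np, scheme, arch, rscore, pick, advance)
  }

  state$parents <- parents
  state$pyt_pop <- pyt_pop
  state$ayt_pop <- ayt
  state$next_id <- next_id
  state$last_f2_var <- f2_var
  state$cycle_index <- state$cycle_index + 1L
  state$elapsed_years <- state$elapsed_years + scheme$years_per_cycle
  if (scheme$uses_gs)
    state$ts_archive <- update_training(state$ts_archive, ts_new)$archive
  state$last_record <- tibble::tibble(
    cycle = state$cycle_index,
    elapsed_years = state$elapsed_years,
    population_mean = mean(parents$info$genetic_value),
    best_line_value = max(ayt$info$genetic_value),
    genetic_variance = f2_var,
    n_evaluated = n2
  )
  state
}

# the phenotypic variety-development track of the GS schemes (PYT -> RYT ->
# AYT); only feeds the best-line trajectory, parents are recycled earlier
gs_variety_track <- function(f4, np, scheme, arch, rscore, pick, advance) {
  k <- pick(seq_len(pop_size(f4)),
            rscore(pop_size(f4), f4$info$phenotype), np$n_ryt)
  f5 <- advance(f4, k, "F5")
  f5 <- phenotype(f5, arch, H2 = scheme$H2[["F5"]])
  k <- pick(seq_len(pop_size(f5)),
            rscore(pop_size(f5), f5$info$phenotype), np$n_ayt)
  ayt <- advance(f5, k, "F6")
  phenotype(ayt, arch, H2 = scheme$H2[["F7"]])
}
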