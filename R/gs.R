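#' Construct a genomic-selection training set
#'
#' @param codes Numeric matrix of marker codes, lines x markers, coded 1
#'   (homozygous A1A1), 0 (heterozygous), -1 (homozygous A2A2).
#' @param y Adjusted phenotypic means, one per line.
#' @param ids Line identifiers.
#' @param cycle Breeding-cycle index the data came from.
#' @return An object of class `bg_ts`.
#' @export
training_set <- function(codes, y, ids = rownames(codes), cycle = 0L) {
  codes <- as.matrix(codes)
  rng <- range(codes)
  stopifnot(nrow(codes) == length(y), rng[1] >= -1, rng[2] <= 1)
  if (is.null(ids)) ids <- seq_len(nrow(codes))
  y <- as.numeric(y)
  structure(list(codes = codes, y = y, ids = ids,
                 meta = tibble::tibble(cycle = cycle, n = nrow(codes)),
                 stats = ts_stats(codes, y)),
            class = "bg_ts")
}

# sufficient statistics for RRBLUP; additive over row-blocks, so a sliding
# training window combines cached per-cycle blocks instead of re-reducing
# the stacked matrix
ts_stats <- function(codes, y) {
  list(G0 = crossprod(codes), zy = drop(crossprod(codes, y)),
       cs = colSums(codes), sy = sum(y), syy = sum(y^2),
       n = length(y))
}

#' @export
print.bg_ts <- function(x, ...) {
  cat("<bg_ts> ", nrow(x$codes), " lines x ", ncol(x$codes),
      " markers; cycles: ", paste(x$meta$cycle, collapse = ", "), "\n", sep = "")
  invisible(x)
}

combine_ts <- function(ts_list) {
  ts_list <- ts_list[!vapply(ts_list, is.null, logical(1))]
  stopifnot(length(ts_list) >= 1)
  if (length(ts_list) == 1) return(ts_list[[1]])
  st <- lapply(ts_list, `[[`, "stats")
  structure(list(
    codes = do.call(rbind, lapply(ts_list, `[[`, "codes")),
    y = unlist(lapply(ts_list, `[[`, "y"), use.names = FALSE),
    ids = unlist(lapply(ts_list, `[[`, "ids"), use.names = FALSE),
    meta = dplyr::bind_rows(lapply(ts_list, `[[`, "meta")),
    stats = list(
      G0 = Reduce(`+`, lapply(st, `[[`, "G0")),
      zy = Reduce(`+`, lapply(st, `[[`, "zy")),
      cs = Reduce(`+`, lapply(st, `[[`, "cs")),
      sy = sum(vapply(st, `[[`, 0, "sy")),
      syy = sum(vapply(st, `[[`, 0, "syy")),
      n = sum(vapply(st, `[[`, 0L, "n")))
  ), class = "bg_ts")
}

#' Fit ridge-regression BLUP marker effects
#'
#' Solves the RRBLUP mixed-model equations for `y = 1 mu + Z u + e` with
#' `u ~ N(0, I sigma2_u)`: the intercept is the generalized-least-squares
#' mean and the marker effects solve `(Z'Z + lambda I) u = Z'(y - 1 mu)`.
#' The ridge parameter is `lambda = sigma2_e / sigma2_u` with the variance
#' components estimated by single-ratio REML profiling on the training data
#' (`lambda_rule = "reml"`); if REML fails to bracket an interior optimum,
#' or with `lambda_rule = "h2"`, the fallback `lambda = m (1 - h2) / h2`
#' is used with `h2 = 0.60`.
#'
#' Monomorphic markers are excluded from the solve and re-inserted with a
#' zero effect.
#'
#' @param ts A [training_set()].
#' @param lambda_rule `"reml"` (default) or `"h2"`.
#' @param h2 Trait heritability for the `"h2"` rule / REML fallback.
#' @return An object of class `bg_gs_model` with fields `mu`, `u`, `lambda`,
#'   `sigma2_u`, `sigma2_e`, and `training_meta`.
#' @export
fit_rrblup <- function(ts, lambda_rule = c("reml", "h2"), h2 = 0.60) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(inherits(ts, "bg_ts"))
  st <- ts$stats
  if (is.null(st)) st <- ts_stats(ts$codes, ts$y)
  n <- st$n
  stopifnot(n >= 2)
  m <- length(st$cs)
  var_j <- (diag(st$G0) - st$cs^2 / n) / (n - 1)
  poly <- which(var_j > 1e-12)
  if (length(poly) == 0) stop("no segregating marker in the training set")
  u <- numeric(m)
  ybar <- st$sy / n
  var_y <- (st$syy - n * ybar^2) / (n - 1)
  if (var_y <= 0) {
    warning("constant training phenotypes; all marker effects set to 0")
    out <- list(mu = ybar, u = u, lambda = Inf,
                sigma2_u = 0, sigma2_e = 0, training_meta = ts$meta)
    return(structure(out, class = "bg_gs_model"))
  }
  G0p <- st$G0[poly, poly, drop = FALSE]
  csp <- st$cs[poly]
  zyp <- st$zy[poly]
  mp <- length(poly)
  lam_h2 <- mp * (1 - h2) / h2
  s2u <- NA_real_; s2e <- NA_real_
  # centered system: (Zc'Zc + lambda I) u = Zc'(y - ybar); mu = ybar - cm'u.
  # This is algebraically the Henderson MME solution for (mu, u) with an
  # unpenalized intercept.
  Gc <- G0p - tcrossprod(csp) / n
  w <- zyp - ybar * csp
  up <- NULL
  if (lambda_rule == "reml") {
    eg <- eigen(Gc, symmetric = TRUE)
    xi_full <- pmax(eg$values, 0)
    fit <- rrblup_reml_eigen(eg$vectors, xi_full, w,
                             st$syy - n * ybar^2, n)
    if (fit$at_boundary) {
      lambda <- lam_h2
    } else {
      lambda <- fit$sigma2_e / fit$sigma2_g
      s2u <- fit$sigma2_g; s2e <- fit$sigma2_e
    }
    up <- drop(eg$vectors %*% (crossprod(eg$vectors, w) / (xi_full + lambda)))
  } else {
    lambda <- lam_h2
  }
  if (is.null(up)) up <- drop(solve(Gc + diag(lambda, mp), w))
  u[poly] <- up
  mu <- ybar - sum(csp / n * up)
  structure(list(mu = mu, u = u, lambda = lambda,
                 sigma2_u = s2u, sigma2_e = s2e, training_meta = ts$meta),
            class = "bg_gs_model")
}

#' @export
print.bg_gs_model <- function(x, ...) {
  cat("<bg_gs_model> ", length(x$u), " marker effects, lambda = ",
      format(x$lambda, digits = 4), ", trained on ", sum(x$training_meta$n),
      " lines\n", sep = "")
  invisible(x)
}

#' Marker effects of a fitted RRBLUP model
#' @param x A `bg_gs_model`.
#' @param ... Unused.
#' @return Tibble with `marker` index and `effect`.
#' @export
tidy.bg_gs_model <- function(x, ...) {
  tibble::tibble(marker = seq_along(x$u), effect = x$u)
}

#' Predict genomic estimated breeding values
#'
#' `GEBV = M u` for candidate marker codes `M`; the intercept is excluded
#' (it does not change the ranking).
#'
#' @param model A fitted [fit_rrblup()] model.
#' @param M Candidate marker codes (lines x markers) or a `bg_ts`.
#' @return Numeric vector of GEBVs.
#' @export
predict_gebv <- function(model, M) {
  if (inherits(M, "bg_ts")) M <- M$codes
  if (ncol(M) != length(model$u))
    stop("candidate marker columns do not match the model (",
         ncol(M), " vs ", length(model$u), ")")
  drop(M %*% model$u)
}

#' Assemble the first genomic-selection training set after burn-in
#'
#' Takes the top `n_parents` lines (by phenotype) of the last burn-in
#' cycle's preliminary-yield-trial cohort, mates them in `n_crosses`
#' disjoint pairs, produces ~`n_lines / n_crosses` F2 per cross, advances
#' each line by single-seed descent to F5, and phenotypes the lines at the
#' preliminary-trial heritability (H2 = 0.45). Defaults give 1152 inbred
#' lines from 30 crosses among 60 parents.
#'
#' @param state A burn-in [bg_state][run_burn_in()].
#' @param n_lines,n_crosses,n_parents Training-set dimensions.
#' @param seed Optional integer seed.
#' @return A list: `ts` (the [training_set()]) and the updated `state`
#'   (id counter advanced).
#' @export
build_initial_ts <- function(state, n_lines = 1152, n_crosses = 30,
                             n_parents = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- state$pyt_pop
  stopifnot(pop_size(pool) >= n_parents)
  ord <- order(pool$info$phenotype, decreasing = TRUE)
  parents <- pool$info$id[ord[seq_len(n_parents)]]
  parents <- sample(parents)
  pairs <- matrix(parents[seq_len(2 * n_crosses)], ncol = 2, byrow = TRUE)
  f1 <- make_cross(pool, pairs, 1, "F1", id_start = state$next_id)
  # distribute n_lines as evenly as possible over the crosses
  sizes <- diff(round(seq(0, n_lines, length.out = n_crosses + 1)))
  f2 <- self_progeny(f1, max(sizes), generation = "F2",
                     id_start = max(f1$info$id) + 1L)
  keep <- unlist(lapply(seq_len(n_crosses), function(k) {
    f2$info$id[f2$info$parent1 == f1$info$id[k]][seq_len(sizes[k])]
  }))
  lines <- pop_subset(f2, keep)
  for (gen in c("F3", "F4", "F5")) {
    lines <- self_progeny(lines, 1, generation = gen, inherit_line = TRUE,
                          id_start = max(lines$info$id) + 1L)
  }
  lines <- phenotype(lines, state$arch, H2 = 0.45)
  state$next_id <- max(lines$info$id) + 1L
  ts <- training_set(marker_codes(lines, state$arch), lines$info$phenotype,
                     ids = lines$info$line_id, cycle = state$cycle_index)
  list(ts = ts, state = state)
}

#' Slide the training archive over the most recent cycles
#'
#' Keeps at most `window` cycles of training data (the most recent ones) and
#' returns both the pruned archive and the combined training set.
#'
#' @param archive List of per-cycle [training_set()] objects.
#' @param new_ts Training set from the cycle just completed (or `NULL`).
#' @param window Number of cycles retained (default 3).
#' @return List with `archive` (pruned) and `ts` (combined `bg_ts`).
#' @export
update_training <- function(archive, new_ts = NULL, window = 3L) {
  if (!is.null(new_ts)) archive <- c(archive, list(new_ts))
  if (length(archive) > window)
    archive <- archive[(length(archive) - window + 1L):length(archive)]
  list(archive = archive, ts = combine_ts(archive))
}

# GEBV of a population via the fused C++ kernel; identical to
# predict_gebv(model, marker_codes(pop, arch)) without materialising the
# code matrix.
gebv_pop <- function(pop, arch, model) {
  cpp_gebv(pop$hap1, pop$hap2, arch$snp, model$u)
}
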