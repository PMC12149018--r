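# Pedigree utilities: topological ordering, generation counting, and the
# additive (numerator) relationship matrix by the tabular method.

# Order a pedigree so that parents precede offspring; errors on cycles.
ped_topo_sort <- function(ped) {
  stopifnot(all(c("id", "parent1", "parent2") %in% names(ped)))
  ids <- ped$id
  if (anyDuplicated(ids)) stop("duplicate individual ids in pedigree")
  self <- !is.na(ped$parent1) & ped$parent1 == ped$id |
    !is.na(ped$parent2) & ped$parent2 == ped$id
  if (any(self))
    stop("self-parentage for id(s): ",
         paste(ped$id[self], collapse = ", "))
  absent <- (!is.na(ped$parent1) & !(ped$parent1 %in% ids)) |
    (!is.na(ped$parent2) & !(ped$parent2 %in% ids))
  if (any(absent))
    stop("parent id(s) absent from the pedigree for: ",
         paste(ped$id[absent], collapse = ", "))
  idx <- stats::setNames(seq_along(ids), ids)
  p1 <- idx[as.character(ped$parent1)]
  p2 <- idx[as.character(ped$parent2)]
  placed <- logical(length(ids))
  order_out <- integer(0)
  remaining <- seq_along(ids)
  while (length(remaining) > 0) {
    ready <- remaining[
      (is.na(p1[remaining]) | placed[p1[remaining]]) &
      (is.na(p2[remaining]) | placed[p2[remaining]])]
    if (length(ready) == 0)
      stop("pedigree cycle involving id(s): ",
           paste(ids[remaining], collapse = ", "))
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
    remaining <- setdiff(remaining, ready)
  }
  ped[order_out, , drop = FALSE]
}

#' Count pedigree generations
#'
#' Each individual's generation is one plus the highest generation number
#' of its known parents, or zero for founders (both parents unknown).
#'
#' @param ped Pedigree data frame with columns `id`, `parent1`, `parent2`
#'   (`NA` = unknown parent).
#' @return Tibble with `id` and `generation`, in the input row order.
#' @export
count_generations <- function(ped) {
  sorted <- ped_topo_sort(ped)
  gen <- stats::setNames(rep(NA_integer_, nrow(sorted)),
                         as.character(sorted$id))
  for (i in seq_len(nrow(sorted))) {
    g1 <- if (is.na(sorted$parent1[i])) -1L else
      gen[[as.character(sorted$parent1[i])]]
    g2 <- if (is.na(sorted$parent2[i])) -1L else
      gen[[as.character(sorted$parent2[i])]]
    gen[[as.character(sorted$id[i])]] <- 1L + max(g1, g2, -1L)
  }
  tibble::tibble(id = ped$id, generation = unname(gen[as.character(ped$id)]))
}

#' Additive relationship matrix from a pedigree
#'
#' The tabular (recursive) method: with individuals ordered parents-first,
#' `A[i,i] = 1 + 0.5 A[p1,p2]` and `A[i,j] = 0.5 (A[j,p1] + A[j,p2])`,
#' unknown parents contributing zero relationship and no inbreeding.
#' Rows given out of order are topologically sorted first.
#'
#' @param ped Pedigree data frame (`id`, `parent1`, `parent2`; `NA` =
#'   unknown).
#' @return Dense symmetric matrix with dimnames = individual ids (in
#'   sorted, parents-first order).
#' @export
build_amatrix <- function(ped) {
  sorted <- ped_topo_sort(ped)
  n <- nrow(sorted)
  ids <- as.character(sorted$id)
  idx <- stats::setNames(seq_len(n), ids)
  p1 <- ifelse(is.na(sorted$parent1), 0L,
               idx[as.character(sorted$parent1)])
  p2 <- ifelse(is.na(sorted$parent2), 0L,
               idx[as.character(sorted$parent2)])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    a1 <- p1[i]; a2 <- p2[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      r1 <- if (a1 > 0) A[j, a1] else rep(0, i - 1L)
      r2 <- if (a2 > 0) A[j, a2] else rep(0, i - 1L)
      A[j, i] <- A[i, j] <- 0.5 * (r1 + r2)
    }
    A[i, i] <- 1 + if (a1 > 0 && a2 > 0) 0.5 * A[a1, a2] else 0
  }
  A
}
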