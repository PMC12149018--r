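#' Read trial records from CSV
#'
#' Comma-separated, UTF-8, header row required, `.` decimal, missing
#' values as empty fields. Validates the required columns, that `value`
#' is numeric, and that no (trial, replicate, genotype, trait) key is
#' duplicated.
#'
#' @param path CSV file with columns `trial_id`, `year`, `location`,
#'   `replicate`, `genotype_id`, `trait`, `value`.
#' @return A tibble of trial records.
#' @export
read_trials <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  req <- c("trial_id", "year", "location", "replicate", "genotype_id",
           "trait", "value")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0) {
    warning("empty trial file: ", path)
    return(tibble::as_tibble(d))
  }
  val <- suppressWarnings(as.numeric(d$value))
  if (anyNA(val) & !all(is.na(d$value[is.na(val)])))
    stop("non-numeric value(s) in rows: ",
         paste(utils::head(which(is.na(val) & !is.na(d$value)), 5),
               collapse = ", "))
  d$value <- val
  d$year <- as.integer(d$year)
  key <- paste(d$trial_id, d$replicate, d$genotype_id, d$trait)
  if (anyDuplicated(key))
    stop("duplicate (trial, replicate, genotype, trait) key(s), e.g.: ",
         key[anyDuplicated(key)])
  d
}

#' Read a pedigree from CSV
#'
#' Columns `id`, `parent1`, `parent2`; empty fields are unknown parents.
#' Rows may be in any order: the table is topologically sorted so parents
#' precede offspring; cycles and self-parentage are errors naming the ids
#' involved.
#'
#' @param path CSV file.
#' @return A parents-first tibble.
#' @export
read_pedigree <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  req <- c("id", "parent1", "parent2")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  tibble::as_tibble(ped_topo_sort(as.data.frame(d)))
}

#' Write result tables and a reproducibility manifest
#'
#' Writes every element of `results` as `<name>.csv` under `dir` plus a
#' `manifest.json` recording the command, package version, master seed,
#' per-replicate seeds (when attached to a result as attribute
#' `"rep_seeds"`), the configuration snapshot, and the file list — enough
#' to reproduce the run exactly.
#'
#' @param results Named list of data frames.
#' @param dir Output directory (created if missing).
#' @param seed Master seed of the run.
#' @param command Label of the producing command.
#' @param config Configuration snapshot (list).
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(results, dir, seed = NULL, command = "report",
                         config = list()) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  rep_seeds <- NULL
  for (nm in names(results)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    rs <- attr(results[[nm]], "rep_seeds")
    if (!is.null(rs)) rep_seeds <- rs
    readr::write_csv(tibble::as_tibble(results[[nm]]), f)
    files <- c(files, basename(f))
  }
  manifest <- list(
    command = command,
    package = "breedgain",
    version = as.character(utils::packageVersion("breedgain")),
    master_seed = seed,
    rep_seeds = rep_seeds,
    config = config,
    files = files
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Export a population as CSV
#'
#' Writes the per-individual records (`individual`, `parent1`, `parent2`,
#' `generation`, `genetic_value`, `phenotype`) and the integer dosage
#' matrix (individuals x loci).
#'
#' @param pop A `bg_pop`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_population <- function(pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  info <- pop$info |>
    dplyr::select(individual = "id", "parent1", "parent2", "generation",
                  "genetic_value", "phenotype")
  f1 <- file.path(dir, "population.csv")
  readr::write_csv(info, f1)
  dm <- tibble::as_tibble(dosage_matrix(pop), .name_repair = ~paste0("L", seq_along(.x)))
  dm <- dplyr::bind_cols(tibble::tibble(individual = pop$info$id), dm)
  f2 <- file.path(dir, "dosages.csv")
  readr::write_csv(dm, f2)
  invisible(c(f1, f2))
}

#' Write / read a scheme or generator configuration
#'
#' Structured-text (YAML) serialization of a [build_scheme()] or
#' [synthetic_config()] so that runs are reproducible from a config file.
#'
#' @param x A `bg_scheme` or `bg_syn_config`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_config <- function(x, path) {
  if (inherits(x, "bg_scheme")) {
    obj <- list(type = "scheme", name = x$name, screen_f2 = x$screen_f2,
                numbers = x$numbers)
  } else if (inherits(x, "bg_syn_config")) {
    obj <- c(list(type = "synthetic"), unclass(x))
  } else stop("unsupported configuration object")
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @return For `read_config()`, the reconstructed object.
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (identical(obj$type, "scheme")) {
    sc <- build_scheme(obj$name, n_parents = obj$numbers$n_parents,
                       n_crosses = obj$numbers$n_crosses,
                       n_progeny = obj$numbers$n_progeny,
                       screen_f2 = obj$screen_f2)
    sc$numbers <- utils::modifyList(sc$numbers, obj$numbers)
    sc
  } else if (identical(obj$type, "synthetic")) {
    obj$type <- NULL
    do.call(synthetic_config, obj[names(obj) %in%
                                    names(formals(synthetic_config))])
  } else stop("unknown configuration type in ", path)
}
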