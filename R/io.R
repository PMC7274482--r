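# Readers and writers for the package's plain-text interchange formats.
# Every writer round-trips through its reader.

#' Read and write community parameter files
#'
#' Parameter files are YAML (or JSON) with a `species` list (each entry
#' `name`, `r`, optional `K`), an optional `unit` (`per_day` or
#' `per_hour`, applying to all rates), and an `alpha` matrix given
#' row-major with row = affected species.  Validation failures raise
#' classed errors with explicit messages.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @param params an [lv_params] object.
#' @return `read_params` returns an [lv_params]; `write_params` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  x <- read_config(path)
  if (is.null(x$species) || !length(x$species)) {
    stop_lv("lvdilute_invalid_params", sprintf("%s: missing 'species' list", path))
  }
  name <- vapply(x$species, function(s) as.character(s$name %||% NA_character_), "")
  r <- vapply(x$species, function(s) as.numeric(s$r %||% NA_real_), 0)
  if (any(is.na(name)) || any(is.na(r))) {
    stop_lv("lvdilute_invalid_params", sprintf("%s: every species entry needs 'name' and 'r'", path))
  }
  Ks <- lapply(x$species, function(s) s$K)
  K <- if (all(vapply(Ks, is.null, TRUE))) NULL else {
    vapply(Ks, function(k) as.numeric(k %||% NA_real_), 0)
  }
  if (is.null(x$alpha)) stop_lv("lvdilute_invalid_params", sprintf("%s: missing 'alpha' matrix", path))
  rows <- lapply(x$alpha, as.numeric)
  if (length(unique(lengths(rows))) != 1 || length(rows) != length(rows[[1]])) {
    stop_lv("lvdilute_invalid_params", sprintf("%s: 'alpha' must be a square row-major matrix", path))
  }
  alpha <- do.call(rbind, rows)
  lv_params(r = r, alpha = alpha, species = name, K = K,
            unit = x$unit %||% "per_day")
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  assert_lv_params(params)
  obj <- list(
    unit = "per_day",
    species = lapply(seq_along(params$species), function(i) {
      s <- list(name = params$species[i], r = unname(params$r[i]))
      if (!is.null(params$K)) s$K <- unname(params$K[i])
      s
    }),
    alpha = lapply(seq_len(nrow(params$alpha)), function(i) unname(params$alpha[i, ]))
  )
  write_config(obj, path)
}

read_config <- function(path) {
  if (!file.exists(path)) stop_lv("lvdilute_io_error", sprintf("file not found: %s", path))
  if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

write_config <- function(obj, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path, precision = 15)
  }
  invisible(path)
}

#' Read and write dilution schedules
#'
#' Schedules serialize as `{dfs: [...], cycle_hours: h}` in YAML or JSON.
#'
#' @param schedule an [lv_schedule] or numeric vector of DFs.
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @return `read_schedule` returns an [lv_schedule].
#' @export
read_schedule <- function(path) {
  x <- read_config(path)
  if (is.null(x$dfs)) stop_lv("lvdilute_invalid_dilution", sprintf("%s: missing 'dfs'", path))
  dilution_schedule(as.numeric(unlist(x$dfs)), x$cycle_hours %||% 24)
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  schedule <- as_schedule(schedule)
  write_config(list(dfs = schedule$dfs, cycle_hours = schedule$cycle_hours), path)
}

#' Read and write trajectories, diagrams and count tables as tidy CSV
#'
#' Trajectories export as `(cycle, species, abundance, fraction,
#' df_applied)`; bifurcation diagrams as `(df, branch_type, fraction)` plus
#' the endpoint map; count tables as `(condition, day, replicate, species,
#' colonies)`.  CSVs are comma-separated, UTF-8, with a header row.
#'
#' @param trajectory,diagram an `lv_trajectory` / `lv_bifurcation`.
#' @param counts a count-table data frame.
#' @param path file path.
#' @return Readers return the corresponding data frame (`read_trajectory`
#'   reconstitutes an `lv_trajectory`).
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- read.csv(path)
  need <- c("cycle", "species", "abundance", "fraction", "df_applied")
  if (!all(need %in% names(d))) {
    stop_lv("lvdilute_io_error", sprintf("%s: expected columns %s", path,
                                         paste(need, collapse = ", ")))
  }
  species <- unique(d$species)
  cycles <- sort(unique(d$cycle))
  ab <- matrix(d$abundance[order(d$cycle, match(d$species, species))],
               nrow = length(cycles), byrow = TRUE)
  fr <- matrix(d$fraction[order(d$cycle, match(d$species, species))],
               nrow = length(cycles), byrow = TRUE)
  colnames(ab) <- colnames(fr) <- species
  dfs <- d$df_applied[!duplicated(d$cycle)][order(unique(d$cycle))]
  structure(list(cycle = cycles, abundance = ab, fraction = fr,
                 df_applied = dfs, converged = NA, species = species,
                 initial_fractions = NULL, schedule = NULL),
            class = "lv_trajectory")
}

#' @rdname write_trajectory
#' @export
write_diagram <- function(diagram, path) {
  write.csv(as.data.frame(diagram), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_diagram <- function(path) {
  d <- read.csv(path)
  if (!all(c("df", "branch_type", "fraction") %in% names(d))) {
    stop_lv("lvdilute_io_error", sprintf("%s: expected df, branch_type, fraction", path))
  }
  d
}

#' @rdname write_trajectory
#' @export
write_counts <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_counts <- function(path) {
  d <- read.csv(path)
  if (!all(c("species", "colonies") %in% names(d))) {
    stop_lv("lvdilute_io_error", sprintf("%s: expected species and colonies columns", path))
  }
  check_counts(d$colonies)
  d
}

#' Write a synthetic bundle to a directory
#'
#' Writes the observation files (counts and OD curves as CSV), the design's
#' schedules, the ground-truth parameters as a separate sidecar
#' (`truth_params.yaml` -- kept out of the observation files' schema), and a
#' JSON manifest recording the seed and every file written.
#'
#' @param bundle an `lv_bundle`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "lv_bundle")) stop_lv("lvdilute_io_error", "expected an 'lv_bundle'")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  p <- file.path(dir, "counts.csv"); write_counts(bundle$counts, p); files$counts <- "counts.csv"
  p <- file.path(dir, "od_curves.csv"); write.csv(bundle$od_curves, p, row.names = FALSE)
  files$od_curves <- "od_curves.csv"
  p <- file.path(dir, "truth_params.yaml"); write_params(bundle$params, p)
  files$truth_params <- "truth_params.yaml"
  write.csv(bundle$trajectory_index, file.path(dir, "trajectory_index.csv"),
            row.names = FALSE)
  files$trajectory_index <- "trajectory_index.csv"
  for (k in seq_along(bundle$trajectories)) {
    fn <- sprintf("trajectory_%03d.csv", k)
    write_trajectory(bundle$trajectories[[k]], file.path(dir, fn))
    files[[fn]] <- fn
  }
  manifest <- list(seed = bundle$seed, species = bundle$species,
                   equalized_od = bundle$design$equalized_od,
                   days = bundle$design$days, files = files)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
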