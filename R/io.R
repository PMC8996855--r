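# Serialization of trajectories, configuration files, and the wide
# stream-plot table. Trajectories travel as plain CSV with a JSON sidecar
# (config + seed + checksum) so a stored run can be reproduced exactly.

manifest_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_manifest.json")
}

params_to_list <- function(params) {
  unclass(params)
}

#' Write a trajectory to CSV with a provenance sidecar
#'
#' The long-format trajectory is written as plain CSV (driver-event ids
#' joined by semicolons) together with a JSON sidecar
#' `<path>_manifest.json` holding the full configuration, seed, driver
#' event registry, package version and an MD5 checksum of the CSV — enough
#' to re-run the simulation bit-identically. [read_trajectory()] restores
#' the trajectory losslessly.
#'
#' @param traj A `tumor_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- tibble::as_tibble(traj)
  df$drivers <- vapply(df$drivers, paste, character(1), collapse = ";")
  # format doubles at full precision so the round-trip is exact
  for (col in c("size", "DR", "AR", "MR", "TMB")) {
    df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "clonedyn",
    version = as.character(utils::packageVersion("clonedyn")),
    seed = attr(traj, "seed"),
    iterations = attr(traj, "iterations"),
    stopped_early = attr(traj, "stopped_early"),
    params = params_to_list(attr(traj, "params")),
    founders = attr(traj, "founders"),
    schedule = attr(traj, "schedule"),
    events = events(traj),
    trajectory_file = basename(path),
    trajectory_md5 = unname(tools::md5sum(path))
  )
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path; the JSON sidecar `<path>_manifest.json` is read
#'   too when present, restoring parameters, founders, schedule, seed and
#'   the driver-event registry.
#' @return A `tumor_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  header <- names(utils::read.csv(path, nrows = 1))
  need <- c("time", "subpop_id", "parent_id", "origin_time", "size",
            "DR", "AR", "MR", "TMB", "drivers", "alive")
  if (!all(need %in% header)) {
    rlang::abort("malformed trajectory file: missing columns")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(drivers = "character"))
  df <- tibble::as_tibble(df)
  df$drivers <- lapply(strsplit(df$drivers, ";", fixed = TRUE), as.integer)
  df$time <- as.integer(df$time)
  df$subpop_id <- as.integer(df$subpop_id)
  df$parent_id <- as.integer(df$parent_id)
  df$origin_time <- as.integer(df$origin_time)
  df$alive <- as.logical(df$alive)
  mp <- manifest_path(path)
  attrs <- list()
  if (file.exists(mp)) {
    m <- jsonlite::read_json(mp, simplifyVector = TRUE)
    params <- m$params
    if (!is.null(params)) class(params) <- "clonedyn_params"
    attrs <- list(
      params = params,
      founders = if (!is.null(m$founders)) tibble::as_tibble(m$founders),
      schedule = if (!is.null(m$schedule) && length(m$schedule) > 0)
        tibble::as_tibble(m$schedule),
      seed = m$seed,
      events = if (!is.null(m$events)) tibble::as_tibble(m$events),
      iterations = m$iterations,
      stopped_early = m$stopped_early
    )
  }
  out <- structure(df, class = c("tumor_trajectory", class(df)))
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  out
}

#' Wide stream-plot table of subclone sizes
#'
#' Pivots a trajectory into a time-by-subclone matrix of sizes, zero-filled
#' before each subclone's origin and after its extinction — the layout used
#' for Muller/streamgraph plotting. Row sums equal the total size `N(t)`;
#' columns are ordered by subclone origin time.
#'
#' @param traj A `tumor_trajectory`.
#' @param path Optional CSV path to also write the table to.
#' @return A tibble with a `time` column and one `subpop_<id>` column per
#'   subclone.
#' @export
export_stream_table <- function(traj, path = NULL) {
  df <- tibble::as_tibble(traj)[, c("time", "subpop_id", "origin_time", "size")]
  ord <- dplyr::arrange(dplyr::distinct(df[, c("subpop_id", "origin_time")]),
                        origin_time, subpop_id)
  wide <- tidyr::pivot_wider(df[, c("time", "subpop_id", "size")],
                             names_from = "subpop_id", values_from = "size",
                             values_fill = 0, names_prefix = "subpop_")
  wide <- wide[order(wide$time),
               c("time", paste0("subpop_", ord$subpop_id))]
  if (!is.null(path)) utils::write.csv(wide, path, row.names = FALSE)
  wide
}

config_known_keys <- list(
  top = c("founders", "globals", "therapies", "iterations", "seed",
          "stop_at_size", "strict_schedule"),
  founder = c("size", "DR", "AR", "MR"),
  therapy = c("kind", "start", "duration")
)

#' Load a simulation configuration file
#'
#' Reads a YAML (or JSON) configuration describing a complete run: the
#' `founders` list (each with `size`, `DR`, `AR`, `MR`; model defaults fill
#' omitted fields), a `globals` section overriding any [global_params()]
#' entry, an optional `therapies` list (`kind`, `start`, `duration`), plus
#' `iterations` and `seed`. Unknown keys at any level are rejected, and the
#' assembled objects are fully validated.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `founders`, `params`, `schedule` (or
#'   `NULL`), `iterations`, `seed`, `stop_at_size`, `strict_schedule` —
#'   ready to splice into [simulate_tumor()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), config_known_keys$top)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  globals <- raw$globals %||% list()
  bad_g <- setdiff(names(globals), names(formals(global_params)))
  if (length(bad_g) > 0) {
    rlang::abort(paste0("unknown globals key(s): ",
                        paste(bad_g, collapse = ", ")))
  }
  params <- do.call(global_params, globals)
  fl <- raw$founders
  if (is.null(fl) || length(fl) == 0) {
    fdf <- founders()
  } else {
    rows <- lapply(fl, function(f) {
      bad_f <- setdiff(names(f), config_known_keys$founder)
      if (length(bad_f) > 0) {
        rlang::abort(paste0("unknown founder key(s): ",
                            paste(bad_f, collapse = ", ")))
      }
      tibble::tibble(size = f$size %||% 30, DR = f$DR %||% 0.2,
                     AR = f$AR %||% 0.05, MR = f$MR %||% 100)
    })
    fdf <- dplyr::bind_rows(rows)
    class(fdf) <- c("clonedyn_founders", class(fdf))
  }
  bad <- validate_founders(fdf, params)
  if (length(bad) > 0) {
    rlang::abort(c("Invalid founders in config:", stats::setNames(bad, rep("x", length(bad)))))
  }
  schedule <- NULL
  if (!is.null(raw$therapies) && length(raw$therapies) > 0) {
    rows <- lapply(raw$therapies, function(th) {
      bad_t <- setdiff(names(th), config_known_keys$therapy)
      if (length(bad_t) > 0) {
        rlang::abort(paste0("unknown therapy key(s): ",
                            paste(bad_t, collapse = ", ")))
      }
      therapy_course(th$kind, start = th$start, duration = th$duration %||% 1L)
    })
    schedule <- dplyr::bind_rows(rows)
  }
  iterations <- raw$iterations %||% 200
  strict <- raw$strict_schedule %||% TRUE
  bad <- validate_schedule(schedule, iterations, strict = strict)
  if (length(bad) > 0) {
    rlang::abort(c("Invalid therapy schedule in config:",
                   stats::setNames(bad, rep("x", length(bad)))))
  }
  list(founders = fdf, params = params, schedule = schedule,
       iterations = iterations, seed = raw$seed,
       stop_at_size = raw$stop_at_size, strict_schedule = strict)
}

#' Write a configuration list back to YAML
#'
#' Inverse of [load_config()]: serializes founders, global-parameter
#' overrides, therapy schedule and run options so that
#' `load_config(save_config(cfg, path))` is semantically identical to
#' `cfg`.
#'
#' @param config A list as returned by [load_config()].
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  defaults <- global_params()
  globals <- unclass(config$params)
  globals <- globals[vapply(names(globals),
                            function(nm) !identical(globals[[nm]], defaults[[nm]]),
                            logical(1))]
  out <- list(
    founders = lapply(seq_len(nrow(config$founders)), function(i) {
      as.list(config$founders[i, c("size", "DR", "AR", "MR")])
    }),
    globals = globals,
    iterations = config$iterations,
    seed = config$seed
  )
  if (!is.null(config$schedule)) {
    out$therapies <- lapply(seq_len(nrow(config$schedule)), function(i) {
      as.list(config$schedule[i, ])
    })
  }
  if (!is.null(config$stop_at_size)) out$stop_at_size <- config$stop_at_size
  if (!isTRUE(config$strict_schedule)) out$strict_schedule <- config$strict_schedule
  yaml::write_yaml(out, path)
  invisible(path)
}
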