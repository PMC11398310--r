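#' Column dialect for delimited track tables
#'
#' Names the columns of a delimited text file holding centroid tracks. One
#' file may hold many individuals. Either a time column (seconds) or a
#' frame-index column plus a frame rate must be given; times are stored in
#' seconds internally.
#'
#' @param id,x,y Column names for the individual id and coordinates.
#' @param time Column name of a time column in seconds, or `NULL`.
#' @param frame Column name of an integer frame column, or `NULL`.
#' @param frame_rate Acquisition rate in Hz, used to convert frames to
#'   seconds and to flag dropped samples.
#' @return A `track_dialect` list.
#' @export
track_dialect <- function(id = "id", x = "x", y = "y", time = "t",
                          frame = NULL, frame_rate = 30) {
  if (is.null(time) && is.null(frame)) {
    stop("dialect needs either a `time` or a `frame` column", call. = FALSE)
  }
  structure(list(id = id, x = x, y = y, time = time, frame = frame,
                 frame_rate = frame_rate),
            class = "track_dialect")
}

#' Build a track table from coordinates
#'
#' Internal-facing constructor shared by [read_tracks()] and the
#' simulators: validates monotone time per individual and flags gaps
#' (missing samples) where consecutive times are more than 1.5 frame
#' intervals apart.
#'
#' @param df Data frame with columns `id`, `t`, `x`, `y`.
#' @param frame_rate Acquisition rate in Hz.
#' @param species One of `"fly"`, `"human"`, `"agent"`.
#' @param group Free-text group/genotype tag.
#' @return A `ymaze_tracks` tibble with columns `id`, `t`, `x`, `y`,
#'   `gap_before` and attributes `frame_rate`, `species`, `group`.
#' @export
tracks <- function(df, frame_rate = 30, species = c("fly", "human", "agent"),
                   group = "wt") {
  species <- match.arg(species)
  need <- c("id", "t", "x", "y")
  if (!all(need %in% names(df))) {
    stop("track table must have columns id, t, x, y", call. = FALSE)
  }
  df <- tibble::as_tibble(df)[, need]
  df$id <- as.character(df$id)
  for (cl in c("t", "x", "y")) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))) &
                     !is.na(df[[cl]]))
      stop(sprintf("non-numeric value in column `%s` at row %d", cl,
                   if (length(bad)) bad[1] else 1L), call. = FALSE)
    }
  }
  df <- dplyr::arrange(df, .data$id, .data$t)
  for (ind in unique(df$id)) {
    tt <- df$t[df$id == ind]
    if (anyNA(tt) || any(diff(tt) <= 0)) {
      stop(sprintf("non-monotonic or duplicated times for individual `%s`",
                   ind), call. = FALSE)
    }
  }
  gap <- unlist(lapply(split(df$t, df$id)[unique(df$id)], function(tt) {
    c(FALSE, diff(tt) > 1.5 / frame_rate)
  }), use.names = FALSE)
  df$gap_before <- gap
  structure(df, frame_rate = frame_rate, species = species, group = group,
            class = c("ymaze_tracks", class(df)))
}

#' Read centroid tracks from a delimited text file
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from the
#'   extension, `.tsv`/`.txt` tab, otherwise comma).
#' @param dialect A [track_dialect()] mapping file columns to track fields.
#' @param species,group Passed to [tracks()].
#' @return A `ymaze_tracks` tibble; rows are sorted by individual and time,
#'   dropped samples are flagged in `gap_before`, never silently removed.
#' @export
read_tracks <- function(path, dialect = track_dialect(),
                        species = c("fly", "human", "agent"), group = "wt") {
  species <- match.arg(species)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  need <- c(dialect$id, dialect$x, dialect$y, dialect$time %||% dialect$frame)
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed value in column `%s` at data row %d of %s",
                   col, bad[1], path), call. = FALSE)
    }
    v
  }
  t <- if (!is.null(dialect$time)) {
    num(dialect$time)
  } else {
    num(dialect$frame) / dialect$frame_rate
  }
  df <- tibble::tibble(id = as.character(raw[[dialect$id]]), t = t,
                       x = num(dialect$x), y = num(dialect$y))
  tracks(df, frame_rate = dialect$frame_rate, species = species, group = group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result table to tab-separated text
#'
#' @param x A data frame (any pipeline result table).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(x)
}

#' Read back a table written by [write_table()]
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

default_config_list <- function() {
  list(
    geometry = list(arm = "short", arm_length = NULL, arm_width = 1),
    yc = 0.34,
    bins = list(
      spatial = list(lo = -1.3, hi = 1.3, n = 26L),
      temporal = list(half_span = 1.275, n_half = 17L)
    ),
    min_trials = list(fly = 80L, human = 28L, agent = 80L),
    frame_rate = 30,
    seed = 1L
  )
}

check_config_keys <- function(cfg, ref, prefix = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown)) {
    stop(sprintf("unknown config key: %s%s", prefix, unknown[1]),
         call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(cfg[[k]])) {
        stop(sprintf("config key %s%s must be a mapping", prefix, k),
             call. = FALSE)
      }
      check_config_keys(cfg[[k]], ref[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills defaults (26 spatial bins over
#' \[-1.3, 1.3\], 17 + 17 temporal bins, cul-de-sac threshold 0.34,
#' minimum 80 trials per fly / 28 per human), and rejects unknown keys.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config_list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    check_config_keys(user, cfg)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(cfg$geometry$arm_length) && cfg$geometry$arm_length <= 0) {
    stop("config key geometry.arm_length must be positive", call. = FALSE)
  }
  if (cfg$yc <= 0 || cfg$yc >= 1) {
    stop("config key yc must lie in (0, 1)", call. = FALSE)
  }
  for (sp in names(cfg$min_trials)) {
    if (cfg$min_trials[[sp]] < 1) {
      stop(sprintf("config key min_trials.%s must be >= 1", sp), call. = FALSE)
    }
  }
  cfg$geometry_obj <- maze_geometry(
    arm = cfg$geometry$arm,
    arm_length = cfg$geometry$arm_length,
    arm_width = cfg$geometry$arm_width
  )
  cfg
}
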