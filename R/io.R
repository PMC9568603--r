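#' Trajectory CSV input/output
#'
#' Trajectories travel as CSV with header `t_s,x_um,y_um` plus a JSON sidecar
#' (`<path>.json`) carrying the metadata (frame rate, pole flag).
#'
#' @param traj A [trajectory()].
#' @param path CSV path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(t_s = traj$t, x_um = traj$x, y_um = traj$y)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(frame_rate = frame_rate(traj),
               pole = inherits(traj, "pole_track"))
  heading <- attr(traj, "heading", exact = TRUE)
  if (!is.null(heading)) meta$heading <- heading
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "x_um", "y_um") %in% names(df))) {
    stop("trajectory CSV must have columns t_s, x_um, y_um")
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  traj <- trajectory(df$t_s, df$x_um, df$y_um,
                     frame_rate = meta$frame_rate,
                     pole = isTRUE(meta$pole))
  if (!is.null(meta$heading)) attr(traj, "heading") <- meta$heading
  traj
}

#' Event table CSV input/output
#'
#' Events travel as CSV with columns `state,start_s,end_s,attributes`, the
#' attributes serialized as a JSON string per row.
#'
#' @param events An [event_table()].
#' @param path CSV path.
#' @return `write_event_table` returns `path` invisibly; `read_event_table`
#'   returns an [event_table()].
#' @export
write_event_table <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  attr_json <- vapply(events$attributes, function(a) {
    if (is.null(a) || !length(a)) "{}" else
      as.character(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA))
  }, character(1))
  df <- data.frame(state = events$state, start_s = events$start,
                   end_s = events$end, attributes = attr_json)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("state", "start_s", "end_s") %in% names(df))) {
    stop("event CSV must have columns state, start_s, end_s")
  }
  attrs <- if ("attributes" %in% names(df)) {
    lapply(df$attributes, function(s) {
      if (is.na(s) || s == "" || s == "{}") list() else
        jsonlite::fromJSON(s, simplifyVector = TRUE)
    })
  } else {
    NULL
  }
  event_table(df$state, df$start_s, df$end_s, attrs)
}
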