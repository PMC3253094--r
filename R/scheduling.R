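#' The default target-frame schedule (villin-sized chains)
#'
#' Ordered step-range to frame-index lookup used in "table" mode: early
#' folding steps target the very first frame of each freshly optimised CG
#' trajectory (the chain moves far per unit time there, so small hops keep
#' the refinement accurate), while late steps target frames near the end so
#' the hop stays large enough that refinement does not fall back to the
#' previous state.
#'
#' @return data frame with columns `from`, `to`, `frame`.
#' @export
default_schedule_table <- function() {
  data.frame(
    from  = c(1L, 5L, 10L, 15L, 20L, 25L, 30L, 35L, 40L, 45L, 51L),
    to    = c(4L, 9L, 14L, 19L, 24L, 29L, 34L, 39L, 44L, 50L, .Machine$integer.max),
    frame = c(1L, 2L, 3L, 5L, 7L, 11L, 15L, 23L, 31L, 47L, 50L))
}

#' Target-frame selection configuration
#'
#' @param mode `"table"` (default; explicit step-range lookup) or
#'   `"adaptive"` (earliest frame at least `delta_min` away from the
#'   current conformation).
#' @param table step-range lookup, as from [default_schedule_table()]:
#'   columns `from`, `to`, `frame`, non-overlapping increasing ranges.
#' @param delta_min adaptive-mode RMSD threshold (default 0.5).
#' @param max_index number of frames per CG trajectory (default 50).
#' @return a `schedule_config`.
#' @export
schedule_config <- function(mode = c("table", "adaptive"),
                            table = default_schedule_table(),
                            delta_min = 0.5, max_index = 50L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(table),
            all(c("from", "to", "frame") %in% names(table)))
  if (any(table$frame < 1L) || any(table$frame > max_index))
    stop("table frame indices must lie in [1, ", max_index, "]")
  if (any(table$from > table$to))
    stop("table ranges must satisfy from <= to")
  if (nrow(table) > 1L && any(diff(table$from) <= 0L))
    stop("table ranges must be increasing")
  if (nrow(table) > 1L && any(table$from[-1L] <= table$to[-nrow(table)]))
    stop("table ranges must be non-overlapping")
  if (delta_min < 0) stop("delta_min must be >= 0")
  structure(list(mode = mode, table = table,
                 delta_min = delta_min, max_index = as.integer(max_index)),
            class = "schedule_config")
}

#' Select which frame of the CG optimal trajectory to target next
#'
#' Table mode looks the folding step up in the configured range table.
#' Adaptive mode returns the smallest frame index whose RMSD from the
#' current conformation is at least `delta_min` (the smallest hop that is
#' still large enough), falling back to the last frame when no frame
#' reaches the threshold.
#'
#' @param step folding step number (>= 1).
#' @param traj the current `cg_trajectory` (needs `max_index` frames, with
#'   absolute frames attached for adaptive mode).
#' @param current the current conformation, a [cg_structure()] (adaptive
#'   mode only).
#' @param cfg a [schedule_config()].
#' @return 1-based frame index into `traj`.
#' @export
select_target_frame <- function(step, traj, current, cfg = schedule_config()) {
  if (step < 1L) stop("step must be >= 1")
  if (!inherits(cfg, "schedule_config")) stop("cfg must be a schedule_config")
  if (!inherits(traj, "cg_trajectory")) stop("traj must be a cg_trajectory")
  if (length(traj$frames) == 0L) stop("empty trajectory")
  if (length(traj$frames) != cfg$max_index)
    stop("trajectory has ", length(traj$frames), " frames, expected ",
         cfg$max_index)
  if (cfg$mode == "table") {
    hit <- which(cfg$table$from <= step & step <= cfg$table$to)
    if (length(hit) != 1L)
      stop("step ", step, " not covered by the schedule table")
    return(cfg$table$frame[hit])
  }
  # adaptive
  if (is.null(traj$absolute_frames))
    stop("adaptive scheduling needs absolute frames (propagate with native=)")
  stopifnot_cg(current)
  for (j in seq_len(cfg$max_index)) {
    if (rmsd_ca(current, traj$absolute_frames[[j]]) >= cfg$delta_min)
      return(j)
  }
  cfg$max_index
}
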