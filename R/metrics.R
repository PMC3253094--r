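#' Root-mean-square fluctuation of a scalar series
#'
#' \eqn{\sqrt{\langle (E_i - \bar E)^2 \rangle}} (population convention,
#' divisor n). Used to compare internal-energy fluctuations along the
#' folding trajectory with the equilibrium fluctuation of the native state.
#'
#' @param series numeric vector, length >= 2.
#' @return nonnegative scalar.
#' @export
energy_rmsf <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2L) stop("series must have length >= 2")
  if (!all(is.finite(series))) stop("series contains non-finite values")
  sqrt(mean((series - mean(series))^2))
}

#' Centred moving average with shrinking edge windows
#'
#' For index i the window is the `window` consecutive points centred on i,
#' truncated at the series ends, so the output has the same length as the
#' input. Window 1 is the identity. Used to filter fast local fluctuations
#' out of per-step metric series and expose the slow folding trend.
#'
#' @param series numeric vector.
#' @param window window width, 1 <= window <= length(series).
#' @return numeric vector, same length as `series`.
#' @export
moving_average <- function(series, window) {
  series <- as.numeric(series)
  m <- length(series)
  if (window < 1L) stop("window must be >= 1")
  if (window > m) stop("window (", window, ") exceeds series length (", m, ")")
  half_lo <- floor((window - 1L) / 2L)
  half_hi <- ceiling((window - 1L) / 2L)
  vapply(seq_len(m), function(i) {
    lo <- max(1L, i - half_lo)
    hi <- min(m, i + half_hi)
    mean(series[lo:hi])
  }, numeric(1))
}

#' Per-step metrics table for a folding trajectory
#'
#' One row per folding step: RMSD to native, radius of gyration, contact
#' count, energy, and the moving-average-smoothed energy. When
#' `rmsf_intervals` is given (or left at its default split of the run into
#' equal blocks), a windowed energy-RMSF table is attached as attribute
#' `"energy_rmsf"`, mirroring the usual interval layout of folding-energy
#' fluctuation reports.
#'
#' @param traj a `folding_trajectory` from [run_folding()].
#' @param native the native reference, a [cg_structure()].
#' @param ma_window smoothing window for the energy column (default 10,
#'   capped at the series length).
#' @param rmsf_intervals data frame with columns `from`, `to` (step
#'   numbers), or `NULL` for an automatic split into up to 4 equal blocks.
#' @return data frame with columns `step`, `target_frame`, `rmsd_to_native`,
#'   `rg`, `n_contacts`, `energy`, `energy_moving_avg`.
#' @export
trajectory_metrics <- function(traj, native, ma_window = 10L,
                               rmsf_intervals = NULL) {
  if (!inherits(traj, "folding_trajectory"))
    stop("traj must be a folding_trajectory")
  rec <- traj$records
  if (nrow(rec) == 0L) stop("empty trajectory")
  w <- min(ma_window, nrow(rec))
  out <- rec[, c("step", "target_frame", "rmsd_to_native", "rg",
                 "n_contacts", "energy"), drop = FALSE]
  out$energy_moving_avg <- moving_average(rec$energy, w)
  if (is.null(rmsf_intervals) && nrow(rec) >= 4L) {
    edges <- unique(round(seq(rec$step[1L], rec$step[nrow(rec)], length.out = 5L)))
    rmsf_intervals <- data.frame(from = edges[-length(edges)],
                                 to = edges[-1L])
  }
  if (!is.null(rmsf_intervals)) {
    rmsf <- vapply(seq_len(nrow(rmsf_intervals)), function(k) {
      sel <- rec$step >= rmsf_intervals$from[k] & rec$step <= rmsf_intervals$to[k]
      if (sum(sel) >= 2L) energy_rmsf(rec$energy[sel]) else NA_real_
    }, numeric(1))
    attr(out, "energy_rmsf") <- cbind(rmsf_intervals, rmsf = rmsf)
  }
  out
}
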