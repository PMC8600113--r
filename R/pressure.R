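#' Paired aortic / distal coronary pressure tracing
#'
#' Simultaneously sampled resting aortic (Pa) and distal coronary (Pd)
#' pressures from the pressure-wire recording, uniformly sampled in time.
#'
#' @param time time stamps in seconds, uniformly spaced.
#' @param pa aortic pressure, mmHg.
#' @param pd distal coronary pressure, mmHg.
#' @param pd_tol tolerance (mmHg) by which `pd` may exceed `pa` (noise).
#' @return object of class `"pressure_tracing"`.
#' @export
pressure_tracing <- function(time, pa, pd, pd_tol = 2) {
  if (length(time) != length(pa) || length(pa) != length(pd))
    stop("time, pa and pd must have the same length")
  if (length(time) < 8L) stop("tracing too short")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) / min(dt) - 1 > 0.01)
    stop("sampling interval must be constant within 1%")
  if (any(pa <= 10 | pa >= 300) || any(pd <= 10 | pd >= 300))
    stop("pressures outside the physiological range (10, 300) mmHg")
  if (any(pd > pa + pd_tol))
    stop("distal pressure exceeds aortic pressure beyond noise tolerance")
  structure(list(time = as.numeric(time), pa = as.numeric(pa),
                 pd = as.numeric(pd)), class = "pressure_tracing")
}

#' Read a pressure tracing from CSV
#'
#' Expects columns `time_s`, `pa_mmhg`, `pd_mmhg`.
#' @param path CSV file path.
#' @return a [pressure_tracing()].
#' @export
read_pressure_tracing <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "pa_mmhg", "pd_mmhg")
  if (!all(need %in% names(d)))
    stop("tracing CSV must have columns ", paste(need, collapse = ", "))
  pressure_tracing(d$time_s, d$pa_mmhg, d$pd_mmhg)
}

#' Write a pressure tracing to CSV
#' @param tracing a [pressure_tracing()]; `path` output file.
#' @export
write_pressure_tracing <- function(tracing, path) {
  utils::write.csv(data.frame(time_s = tracing$time, pa_mmhg = tracing$pa,
                              pd_mmhg = tracing$pd),
                   path, row.names = FALSE)
  invisible(path)
}

#' Extract one representative beat from a tracing
#'
#' Segments the aortic channel into beats between consecutive diastolic feet
#' (local minima) and returns the beat with the largest pulse pressure, the
#' distal channel cut at the same indices. Deterministic by construction.
#'
#' @param tracing a [pressure_tracing()] spanning at least one full beat.
#' @return a [pressure_tracing()] holding a single beat (foot to foot).
#' @export
extract_representative_beat <- function(tracing) {
  pa <- tracing$pa
  n <- length(pa)
  # period estimate from the autocorrelation of the demeaned signal
  ac <- stats::acf(pa - mean(pa), lag.max = n - 1L, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lag_min <- max(4L, floor(0.25 / mean(diff(tracing$time))))  # >= 0.25 s (240 bpm)
  cand <- which(diff(sign(diff(ac))) < 0) + 1L   # local maxima of acf
  cand <- cand[cand > lag_min & ac[cand] > 0.2]
  if (!length(cand)) {
    # maybe a single-beat recording: return as is if it looks like one beat
    imin <- which.min(pa)
    if (max(pa) - min(pa) > 5 && (imin <= 3L || imin >= n - 2L))
      return(tracing)
    stop("no detectable periodicity in the aortic tracing")
  }
  period <- cand[1] - 1L
  w <- max(2L, floor(period / 3))
  feet <- integer(0)
  for (i in seq.int(w + 1L, n - w)) {
    if (pa[i] == min(pa[(i - w):(i + w)]) &&
        (!length(feet) || i - feet[length(feet)] > w))
      feet <- c(feet, i)
  }
  # boundary feet (clamped windows): a record edge that truncates an
  # upstroke/downstroke must not be mistaken for a diastolic foot, so an
  # edge candidate needs either a verified approach slope on its accessible
  # side, or loose period alignment together with a foot-level value
  if (length(feet)) {
    pp <- max(pa) - min(pa)
    tol <- max(2L, round(0.25 * period))
    foot_lvl <- max(pa[feet]) + 0.05 * pp
    left <- which.min(pa[1:w])
    ok_left <- (left >= 4L && pa[left] <= pa[left - 3L] - 0.02 * pp) ||
      (abs((feet[1] - left) - period) <= tol && pa[left] <= foot_lvl)
    if (left < feet[1] - w && ok_left) feet <- c(left, feet)
    right <- (n - w) + which.min(pa[(n - w + 1L):n])
    ok_right <- (right <= n - 3L && pa[right] <= pa[right + 3L] - 0.02 * pp) ||
      (abs((right - feet[length(feet)]) - period) <= tol &&
         pa[right] <= foot_lvl)
    if (right > feet[length(feet)] + w && ok_right) feet <- c(feet, right)
  }
  if (length(feet) < 2L) return(tracing)
  best <- 0; b_lo <- feet[1]; b_hi <- feet[2]
  for (k in seq_len(length(feet) - 1L)) {
    seg <- feet[k]:feet[k + 1L]
    pp <- max(pa[seg]) - min(pa[seg])
    if (pp > best) { best <- pp; b_lo <- feet[k]; b_hi <- feet[k + 1L] }
  }
  idx <- b_lo:b_hi
  pressure_tracing(tracing$time[idx], tracing$pa[idx], tracing$pd[idx])
}

#' Pressure-ratio pullback curve
#'
#' The pullback of the OCT-derived pressure ratio (optical flow ratio, an FFR
#' surrogate) along the vessel, from the distal sensor position toward the
#' ostium. Values are Pd/Pa-like ratios in (0, 1].
#'
#' @param position position along the pullback in mm, strictly increasing
#'   (distal to proximal).
#' @param value ratio values in (0, 1].
#' @return object of class `"ofr_pullback"`.
#' @export
ofr_pullback <- function(position, value) {
  if (length(position) != length(value)) stop("position/value length mismatch")
  if (any(diff(position) <= 0)) stop("pullback positions must be strictly increasing")
  if (any(value <= 0 | value > 1)) stop("pullback values must be in (0, 1]")
  structure(list(position = as.numeric(position), value = as.numeric(value)),
            class = "ofr_pullback")
}

#' Read / write a pullback curve (CSV columns `position_mm`, `ofr`)
#' @param path CSV file path.
#' @return an [ofr_pullback()].
#' @export
read_ofr_pullback <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("position_mm", "ofr") %in% names(d)))
    stop("pullback CSV must have columns position_mm, ofr")
  ofr_pullback(d$position_mm, d$ofr)
}

#' @rdname read_ofr_pullback
#' @param pullback an [ofr_pullback()] to write.
#' @export
write_ofr_pullback <- function(pullback, path) {
  utils::write.csv(data.frame(position_mm = pullback$position,
                              ofr = pullback$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' Position-specific intracoronary pressure
#'
#' Estimates the pressure waveform at pullback position `x` by normalizing the
#' pullback ratio curve between the aortic and distal tracings:
#' \deqn{P(x,t) = P_d(t) + (P_a(t) - P_d(t))
#'   \frac{OFR(x) - OFR_w}{OFR_p - OFR_w}}
#' where \eqn{OFR_p} is the value at the proximal end of the pullback (where
#' the local pressure is aortic) and \eqn{OFR_w} the value at the distal
#' pressure-sensor position (where it is Pd). `OFR(x)` is linearly
#' interpolated. This linear map is the minimal normalization consistent with
#' anchoring the two tracings at the two ends of the pullback.
#'
#' @param tracing a [pressure_tracing()] (typically one representative beat).
#' @param pullback an [ofr_pullback()].
#' @param x pullback position in mm, within the pullback range.
#' @return numeric vector: pressure time series at `x`, mmHg.
#' @export
position_pressure <- function(tracing, pullback, x) {
  rng <- range(pullback$position)
  if (x < rng[1] || x > rng[2])
    stop(sprintf("position %.2f mm outside the pullback range [%.2f, %.2f]",
                 x, rng[1], rng[2]))
  ofr_w <- pullback$value[1L]                         # distal sensor position
  ofr_p <- pullback$value[length(pullback$value)]     # proximal end
  if (abs(ofr_p - ofr_w) < 1e-9) {
    warning("flat pullback curve: no gradient to distribute; returning Pa(t)")
    return(tracing$pa)
  }
  ofr_x <- stats::approx(pullback$position, pullback$value, xout = x)$y
  w <- (ofr_x - ofr_w) / (ofr_p - ofr_w)
  tracing$pd + (tracing$pa - tracing$pd) * w
}

#' Relative-pressure load
#'
#' Converts a position-specific pressure waveform into the cyclic load used by
#' the solver: the estimated diastolic pressure (the beat minimum of the
#' waveform itself) is subtracted, and the remainder converted to kPa
#' (1 mmHg = 0.133322 kPa). The imaged diastolic geometry is thereby the
#' stress-free reference: only the pressure change loads the model.
#'
#' @param p pressure time series in mmHg (one representative beat).
#' @param time optional time stamps (s), kept for bookkeeping.
#' @return object of class `"pressure_load"`: `time`, `delta_p` (kPa,
#'   min exactly 0), `peak_index`.
#' @export
relative_pressure <- function(p, time = seq_along(p) - 1) {
  if (!length(p) || any(!is.finite(p))) stop("invalid pressure series")
  dp <- (p - min(p)) * MMHG_TO_KPA
  if (max(dp) == 0) warning("constant pressure: all-zero load")
  structure(list(time = as.numeric(time), delta_p = dp,
                 peak_index = which.max(dp)),
            class = "pressure_load")
}

#' mmHg to kPa conversion factor
#' @export
MMHG_TO_KPA <- 0.133322

#' @export
print.pressure_load <- function(x, ...) {
  cat(sprintf("<pressure_load> %d samples, peak %.3f kPa at index %d\n",
              length(x$delta_p), max(x$delta_p), x$peak_index))
  invisible(x)
}

#' Write a relative-pressure load to CSV (columns `time_s`, `delta_p_kpa`)
#' @param load a [relative_pressure()] result; `path` output file.
#' @export
write_pressure_load <- function(load, path) {
  utils::write.csv(data.frame(time_s = load$time, delta_p_kpa = load$delta_p),
                   path, row.names = FALSE)
  invisible(path)
}
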