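# Crash-signal postprocessing: channel container, channel-frequency-class
# (CFC) phaseless filtering, deflection channels, force-deflection curves
# and corridor scoring.

#' Uniformly sampled signal channel
#'
#' @param time sample times (ms), uniformly spaced, monotone increasing.
#' @param value sample values.
#' @param units value units (`"kN"`, `"mm"`, `"deg"`, ...).
#' @param name channel name.
#' @param filter filter annotation (`"raw"` or e.g. `"CFC180"`).
#' @return Object of class `hbm_channel`.
#' @export
signal_channel <- function(time, value, units = "", name = "channel",
                           filter = "raw") {
  time <- as.numeric(time); value <- as.numeric(value)
  stopifnot(length(time) == length(value), length(time) >= 2)
  dt <- diff(time)
  if (any(dt <= 0)) stop("channel time base must be monotone increasing")
  if (max(dt) - min(dt) > 1e-9)
    stop("channel is not uniformly sampled")
  structure(list(time = time, value = value, dt = stats::median(dt),
                 units = units, name = name, filter = filter),
            class = "hbm_channel")
}

#' @export
print.hbm_channel <- function(x, ...) {
  cat(sprintf("Channel '%s' [%s, %s]: %d samples at %g ms\n", x$name,
              x$units, x$filter, length(x$time), x$dt))
  invisible(x)
}

# one pass of the channel-class two-pole low-pass (difference equation of
# the channel-class standard); wd = 2*pi*cfc*2.0775
cfc_coefficients <- function(cfc, dt_ms) {
  T <- dt_ms * 1e-3                      # s
  wd <- 2 * pi * cfc * 2.0775
  wa <- sin(wd * T / 2) / cos(wd * T / 2)
  den <- 1 + sqrt(2) * wa + wa^2
  list(b = c(wa^2, 2 * wa^2, wa^2) / den,
       a = c(1, -(-2 * (wa^2 - 1) / den), -((-1 + sqrt(2) * wa - wa^2) / den)))
}

#' Channel-frequency-class (CFC) filtering
#'
#' Phaseless four-pole low-pass per the channel-class convention for crash
#' signals: a two-pole low-pass with the class's published coefficients
#' applied forward and backward (zero phase, squared magnitude).  The ends
#' are mirror-padded by `pad_ms` before filtering to suppress edge
#' transients.  DC gain is exactly 1.
#'
#' @param channel `hbm_channel` (uniformly sampled, >= 10 samples).
#' @param cfc channel class (e.g. 180 or 600); the nominal -3 dB cutoff of
#'   each pass is `2.0775 * cfc / (2 pi)` rad/s prewarped, i.e. roughly
#'   `1.25 * cfc` Hz.
#' @param pad_ms mirror-padding length at each end (ms).
#' @return Filtered `hbm_channel` with updated filter annotation.
#' @export
cfc_filter <- function(channel, cfc = 180, pad_ms = 10) {
  stopifnot(inherits(channel, "hbm_channel"))
  x <- channel$value
  if (length(x) < 10) stop("channel too short to filter (need >= 10 samples)")
  co <- cfc_coefficients(cfc, channel$dt)
  npad <- min(length(x) - 1L, max(1L, round(pad_ms / channel$dt)))
  # mirror padding (reflection about the end samples)
  head_pad <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  tail_pad <- 2 * x[length(x)] - x[seq(length(x) - 1L,
                                       length(x) - npad)]
  xx <- c(head_pad, x, tail_pad)
  # each pass starts at steady state for its first sample (the filter has
  # unit DC gain), so no start-up transient leaks into the signal
  pass <- function(v)
    as.numeric(signal::filter(co$b, co$a, v,
                              init.x = c(v[1], v[1]),
                              init.y = c(v[1], v[1])))
  y <- rev(pass(rev(pass(xx))))
  y <- y[(npad + 1L):(npad + length(x))]
  out <- channel
  out$value <- y
  out$filter <- paste0("CFC", cfc)
  out
}

#' Analytic magnitude of the four-pole channel-class filter
#'
#' The two-pass filter realizes the squared magnitude of a two-pole
#' Butterworth prototype under the bilinear transform; at frequency
#' `f_hz` on a channel sampled at `dt_ms` the expected gain is
#' `1 / (1 + (w_eff / wd_eff)^4)` with prewarped frequencies.  Useful as
#' an independent oracle for attenuation checks.
#'
#' @param f_hz signal frequency (Hz).
#' @param cfc channel class.
#' @param dt_ms sampling interval (ms).
#' @return Expected amplitude gain of [cfc_filter()].
#' @export
cfc_expected_gain <- function(f_hz, cfc, dt_ms) {
  T <- dt_ms * 1e-3
  wd <- 2 * pi * cfc * 2.0775
  warp <- function(w) (2 / T) * tan(w * T / 2)
  1 / (1 + (warp(2 * pi * f_hz) / warp(wd))^4)
}

resample_history <- function(h) {
  h <- as.data.frame(h)
  stopifnot(all(c("time", "x", "y", "z") %in% names(h)))
  h
}

check_history_names <- function(histories, needed, case_type) {
  missing <- setdiff(needed, names(histories))
  if (length(missing))
    stop("missing landmark history for ", case_type, " deflection: ",
         paste(missing, collapse = ", "))
}

#' Deflection channel for an impact case
#'
#' Builds the case-appropriate deflection measure from landmark /
#' impactor time histories (each a data.frame with `time` in ms and
#' `x`, `y`, `z` in mm, all on a common uniform time base):
#' \describe{
#'   \item{front, back}{change in the sternum-to-T8 relative displacement
#'     projected on the impact axis;}
#'   \item{lateral}{displacement of the impactor centre along the impact
#'     axis;}
#'   \item{shoulder}{change in the acromion-to-acromion distance;}
#'   \item{abdomen}{change in the impactor-to-L3 relative displacement
#'     projected on the impact axis.}
#' }
#' Compression is positive.  All measures are relative, hence exactly
#' invariant under a global rigid translation of every history.
#'
#' @param case_type one of `"front"`, `"back"`, `"lateral"`,
#'   `"shoulder"`, `"abdomen"`.
#' @param histories named list of history data.frames.  Required names:
#'   `sternum` and `T8` (front/back), `impactor` (lateral),
#'   `acromion_left` and `acromion_right` (shoulder), `impactor` and `L3`
#'   (abdomen).
#' @param axis impact travel axis (default -x, the impactor launch
#'   direction).
#' @return `hbm_channel` of deflection in mm.
#' @export
deflection_channel <- function(case_type = c("front", "back", "lateral",
                                             "shoulder", "abdomen"),
                               histories, axis = c(-1, 0, 0)) {
  case_type <- match.arg(case_type)
  axis <- axis / sqrt(sum(axis^2))
  needed <- switch(case_type,
                   front = c("sternum", "T8"), back = c("sternum", "T8"),
                   lateral = "impactor",
                   shoulder = c("acromion_left", "acromion_right"),
                   abdomen = c("impactor", "L3"))
  check_history_names(histories, needed, case_type)
  hs <- lapply(histories[needed], resample_history)
  tm <- hs[[1]]$time
  for (h in hs) if (!isTRUE(all.equal(h$time, tm)))
    stop("histories do not share a common time base")
  mat <- function(h) as.matrix(h[c("x", "y", "z")])
  d <- switch(case_type,
    front = ,
    back = {
      rel <- mat(hs$sternum) - mat(hs$T8)
      as.numeric((rel - rel[rep(1, nrow(rel)), ]) %*% axis)
    },
    lateral = {
      p <- mat(hs$impactor)
      as.numeric((p - p[rep(1, nrow(p)), ]) %*% axis)
    },
    shoulder = {
      dd <- sqrt(rowSums((mat(hs$acromion_left) -
                            mat(hs$acromion_right))^2))
      dd[1] - dd
    },
    abdomen = {
      rel <- mat(hs$impactor) - mat(hs$L3)
      as.numeric((rel - rel[rep(1, nrow(rel)), ]) %*% axis)
    })
  signal_channel(tm, d, units = "mm",
                 name = paste0(case_type, "_deflection"))
}

#' Force-deflection curve
#'
#' Pairs a force channel with a deflection channel over the analysis
#' window into a parametric curve (deflection(t), force(t)).  Samples are
#' kept in time order; non-monotone deflection is preserved, never
#' sorted.
#'
#' @param force,deflection `hbm_channel` objects on the same time base.
#' @param window_ms analysis window; samples after `window_ms` are
#'   dropped (the evaluation focuses on the first ~20 ms of the impact).
#' @return data.frame with `time`, `deflection`, `force`.
#' @export
force_deflection <- function(force, deflection, window_ms = 20) {
  if (!isTRUE(all.equal(force$time, deflection$time)))
    stop("force and deflection channels have mismatched time bases")
  keep <- force$time <= force$time[1] + window_ms
  data.frame(time = force$time[keep], deflection = deflection$value[keep],
             force = force$value[keep])
}

#' Force-deflection corridor
#'
#' Experimental lower/upper force bounds versus deflection.
#'
#' @param deflection_mm abscissa grid (mm), increasing.
#' @param lower_kN,upper_kN bound values; `lower <= upper` everywhere.
#' @return Object of class `hbm_corridor`.
#' @export
corridor <- function(deflection_mm, lower_kN, upper_kN) {
  stopifnot(length(deflection_mm) == length(lower_kN),
            length(lower_kN) == length(upper_kN),
            !is.unsorted(deflection_mm))
  if (any(lower_kN > upper_kN))
    stop("corridor lower bound exceeds upper bound")
  structure(list(deflection = deflection_mm, lower = lower_kN,
                 upper = upper_kN), class = "hbm_corridor")
}

#' Score a force-deflection curve against a corridor
#'
#' Fraction of curve samples whose force lies within the linearly
#' interpolated [lower, upper] corridor band at the sample's deflection.
#' Samples outside the corridor's abscissa range are flagged
#' `"outside_grid"` and excluded from the denominator.
#'
#' @param curve data.frame from [force_deflection()].
#' @param corridor `hbm_corridor`.
#' @return List with `score` (fraction in \[0, 1\]), `n_scored`, and
#'   `flags` (per sample: `inside`, `below`, `above`, `outside_grid`).
#' @export
corridor_score <- function(curve, corridor) {
  d <- curve$deflection
  rng <- range(corridor$deflection)
  in_grid <- d >= rng[1] & d <= rng[2]
  if (!any(in_grid))
    stop("curve does not overlap the corridor's deflection range")
  lo <- stats::approx(corridor$deflection, corridor$lower, xout = d)$y
  hi <- stats::approx(corridor$deflection, corridor$upper, xout = d)$y
  flags <- rep("outside_grid", length(d))
  flags[in_grid & curve$force < lo] <- "below"
  flags[in_grid & curve$force > hi] <- "above"
  flags[in_grid & curve$force >= lo & curve$force <= hi] <- "inside"
  list(score = sum(flags == "inside") / sum(in_grid),
       n_scored = sum(in_grid), flags = flags)
}

#' Read a plain-text time-history table
#'
#' Reads solver time-history exports: whitespace-separated tables with a
#' header and columns `time`, `x`, `y`, `z` (or `time` plus one value
#' column for force channels).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_history <- function(path) {
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
}
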