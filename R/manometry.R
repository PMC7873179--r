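#' Construct a multi-channel pressure recording
#'
#' @param pressure_mmhg channels x samples matrix (mmHg), channels ordered
#'   proximal to distal
#' @param sampling_rate_hz sampling rate (Hz)
#' @param channel_positions_mm strictly increasing arc-length positions
#'   (mm); the catheter used here has 100 mm inter-sensor spacing by
#'   default
#' @param labels optional channel labels
#' @return a `pressure_recording`
#' @export
pressure_recording <- function(pressure_mmhg, sampling_rate_hz,
                               channel_positions_mm, labels = NULL) {
  P <- as.matrix(pressure_mmhg)
  check_that(is_scalar_num(sampling_rate_hz) && sampling_rate_hz > 0,
             "pressure_recording: sampling_rate_hz must be > 0")
  check_that(nrow(P) == length(channel_positions_mm),
             "pressure_recording: one position per channel required")
  check_that(length(channel_positions_mm) < 2 ||
               all(diff(channel_positions_mm) > 0),
             "pressure_recording: channel positions must be strictly increasing")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(P)))
  structure(list(pressure_mmhg = unname(P),
                 sampling_rate_hz = sampling_rate_hz,
                 channel_positions_mm = channel_positions_mm,
                 labels = labels,
                 times_s = (seq_len(ncol(P)) - 1) / sampling_rate_hz),
            class = "pressure_recording")
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf("pressure_recording: %d channels x %d samples at %.3g Hz, positions %s mm\n",
              nrow(x$pressure_mmhg), ncol(x$pressure_mmhg),
              x$sampling_rate_hz,
              paste(x$channel_positions_mm, collapse = ", ")))
  invisible(x)
}

#' Detect contraction events per channel
#'
#' Per channel, the slowly drifting baseline is a centred rolling median
#' over `baseline_window_s` (robust to the contractions themselves).
#' Candidate events are maximal intervals where the excess pressure stays
#' above `min_amplitude/2`; an event is retained if its peak excess
#' reaches `min_amplitude`. The onset is the last upward crossing of 20 %
#' of the peak excess before the peak, located with linear interpolation
#' between samples.
#'
#' @param rec a [pressure_recording()]
#' @param min_amplitude_mmhg detection amplitude (mmHg)
#' @param baseline_window_s rolling-median window (s)
#' @return data frame of events: `channel`, `onset_s`, `peak_s`, `end_s`,
#'   `amplitude_mmhg` (peak excess over baseline), sorted by onset
#' @export
detect_contractions <- function(rec, min_amplitude_mmhg = 30,
                                baseline_window_s = 120) {
  check_that(inherits(rec, "pressure_recording"),
             "detect_contractions: rec must be a pressure_recording")
  P <- rec$pressure_mmhg
  if (any(!is.finite(P))) {
    bad <- which(!is.finite(P), arr.ind = TRUE)[1, ]
    stop(sprintf("detect_contractions: non-finite sample at channel %d, sample %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  fs <- rec$sampling_rate_hz
  n <- ncol(P)
  check_that(n / fs >= 2 * baseline_window_s,
             "detect_contractions: recording must be at least twice the baseline window")
  k <- floor(baseline_window_s * fs)
  if (k %% 2 == 0) k <- k + 1
  k <- max(3, min(k, if (n %% 2 == 1) n else n - 1))

  out <- list()
  for (ch in seq_len(nrow(P))) {
    x <- P[ch, ]
    excess <- x - stats::runmed(x, k, endrule = "median")
    active <- excess > min_amplitude_mmhg / 2
    runs <- rle(active)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (j in which(runs$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      seg <- excess[i0:i1]
      pk_rel <- which.max(seg)
      amp <- seg[pk_rel]
      if (amp < min_amplitude_mmhg) next
      pk <- i0 + pk_rel - 1
      thr <- 0.2 * amp
      ## last upward crossing of 20 % of peak excess before the peak
      pre <- excess[seq_len(pk)]
      below <- which(pre < thr)
      if (length(below) == 0 || max(below) == pk) {
        onset <- (i0 - 1) / fs
      } else {
        ib <- max(below)
        frac <- (thr - pre[ib]) / (pre[ib + 1] - pre[ib])
        onset <- (ib - 1 + frac) / fs
      }
      out[[length(out) + 1]] <- data.frame(
        channel = ch, onset_s = onset, peak_s = (pk - 1) / fs,
        end_s = i1 / fs, amplitude_mmhg = amp)
    }
  }
  if (length(out) == 0)
    return(data.frame(channel = integer(0), onset_s = numeric(0),
                      peak_s = numeric(0), end_s = numeric(0),
                      amplitude_mmhg = numeric(0)))
  ev <- do.call(rbind, out)
  ev[order(ev$onset_s, ev$channel), , drop = FALSE]
}

#' Detect high-amplitude propagating contractions (HAPCs)
#'
#' An HAPC is a cluster of contractions with amplitude >= 60 mmHg
#' propagating antegradely over at least three adjacent recording sites.
#' Chains are built greedily: starting from each unused event in onset
#' order, the chain is extended to the next adjacent distal channel's
#' earliest unused event whose onset is strictly later by at most
#' `max_lag_s` and whose implied velocity does not exceed
#' `max_velocity_mm_s`. A chain qualifies if it spans >= 3 adjacent
#' channels and (per-site mode, the default) every participating event
#' reaches `amp_threshold_mmhg`; in `"mean"` mode the mean peak amplitude
#' must reach the threshold. Each event joins at most one HAPC. The input
#' order of events is irrelevant.
#'
#' @param events event data frame from [detect_contractions()]
#' @param rec the [pressure_recording()] the events came from
#' @param amp_threshold_mmhg amplitude criterion (mmHg)
#' @param max_lag_s maximum onset lag between adjacent channels (s)
#' @param max_velocity_mm_s maximum plausible propagation velocity (mm/s)
#' @param amplitude_mode `"per_site"` (default) or `"mean"`
#' @return list of `hapc_event` lists with `channels`, `onsets_s`,
#'   `amplitudes_mmhg`, `min_amplitude_mmhg`, `velocity_mm_s` (least
#'   squares, see [estimate_velocity()]), and half-open `window_s`
#' @export
detect_hapcs <- function(events, rec, amp_threshold_mmhg = 60,
                         max_lag_s = 60, max_velocity_mm_s = 50,
                         amplitude_mode = c("per_site", "mean")) {
  check_that(inherits(rec, "pressure_recording"),
             "detect_hapcs: rec must be a pressure_recording")
  amplitude_mode <- match.arg(amplitude_mode)
  if (nrow(events) == 0) return(list())
  ev <- events[order(events$onset_s, events$channel), , drop = FALSE]
  pos <- rec$channel_positions_mm
  used <- rep(FALSE, nrow(ev))
  hapcs <- list()

  for (i in seq_len(nrow(ev))) {
    if (used[i]) next
    chain <- i
    repeat {
      tail_row <- chain[length(chain)]
      next_ch <- ev$channel[tail_row] + 1L
      if (next_ch > length(pos)) break
      dt_all <- ev$onset_s - ev$onset_s[tail_row]
      gap <- pos[next_ch] - pos[ev$channel[tail_row]]
      cand <- which(!used & ev$channel == next_ch & dt_all > 0 &
                      dt_all <= max_lag_s &
                      gap / dt_all <= max_velocity_mm_s)
      cand <- setdiff(cand, chain)
      if (length(cand) == 0) break
      chain <- c(chain, cand[which.min(ev$onset_s[cand])])
    }
    if (length(chain) < 3) next
    amps <- ev$amplitude_mmhg[chain]
    amp_ok <- if (amplitude_mode == "per_site") all(amps >= amp_threshold_mmhg)
    else mean(amps) >= amp_threshold_mmhg
    if (!amp_ok) next
    used[chain] <- TRUE
    h <- structure(list(
      channels = ev$channel[chain],
      onsets_s = ev$onset_s[chain],
      amplitudes_mmhg = amps,
      min_amplitude_mmhg = min(amps),
      window_s = c(ev$onset_s[chain[1]], max(ev$end_s[chain]))),
      class = "hapc_event")
    h$velocity_mm_s <- estimate_velocity(h, pos)$velocity_mm_s
    hapcs[[length(hapcs) + 1]] <- h
  }
  hapcs
}

#' Propagation velocity of an HAPC
#'
#' Ordinary least-squares slope of channel position versus onset time
#' over the participating channels; positive values are antegrade.
#'
#' @param hapc an `hapc_event`
#' @param positions_mm all channel arc-length positions (mm)
#' @return list with `velocity_mm_s` and `degenerate` (TRUE, with NA
#'   velocity, when the onsets have zero time spread)
#' @export
estimate_velocity <- function(hapc, positions_mm) {
  check_that(length(hapc$channels) >= 3,
             "estimate_velocity: need >= 3 participating channels")
  t_on <- hapc$onsets_s
  pos <- positions_mm[hapc$channels]
  if (stats::sd(t_on) < 1e-12)
    return(list(velocity_mm_s = NA_real_, degenerate = TRUE))
  fit <- stats::lm.fit(cbind(1, t_on), pos)
  list(velocity_mm_s = unname(fit$coefficients[2]), degenerate = FALSE)
}
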