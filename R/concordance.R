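#' Restrict manometry channels to the imaged segment
#'
#' Only the manometry channels that lie inside the cine-MRI field of view
#' can be compared; the segment is a half-open arc-length interval
#' `[start, end)`.
#'
#' @param channel_positions_mm channel arc-length positions (mm)
#' @param imaged_segment_mm `c(start, end)` of the imaged segment (mm)
#' @return integer indices of the included channels
#' @export
map_channels_to_segment <- function(channel_positions_mm, imaged_segment_mm) {
  check_that(length(imaged_segment_mm) == 2 &&
               imaged_segment_mm[2] > imaged_segment_mm[1],
             "map_channels_to_segment: segment must be c(start, end) with end > start")
  inc <- which(channel_positions_mm >= imaged_segment_mm[1] &
                 channel_positions_mm < imaged_segment_mm[2])
  if (length(inc) == 0)
    stop("map_channels_to_segment: no manometry channel lies inside the imaged segment; no cross-modality comparison is possible",
         call. = FALSE)
  inc
}

#' Align the two modalities into one session
#'
#' Puts the MRI residual map and the manometric HAPC list on a common
#' clock (`clock_offset_s` = manometry time minus MRI time) and restricts
#' the channel set to those inside the imaged segment.
#'
#' @param rmap a [residual_map()] (MRI clock)
#' @param hapcs list of `hapc_event`s (manometry clock)
#' @param channel_positions_mm all channel positions (mm)
#' @param imaged_segment_mm `c(start, end)` arc-length interval covered by
#'   the MRI (mm)
#' @param clock_offset_s manometry clock minus MRI clock (s)
#' @return an `aligned_session`
#' @export
aligned_session <- function(rmap, hapcs, channel_positions_mm,
                            imaged_segment_mm, clock_offset_s = 0) {
  check_that(inherits(rmap, "residual_map"), "aligned_session: rmap must be a residual_map")
  check_that(is_scalar_num(clock_offset_s), "aligned_session: clock_offset_s must be finite")
  included <- map_channels_to_segment(channel_positions_mm, imaged_segment_mm)
  spacing <- if (length(channel_positions_mm) >= 2)
    stats::median(diff(channel_positions_mm)) else
      diff(imaged_segment_mm)
  structure(list(rmap = rmap, hapcs = hapcs,
                 channel_positions_mm = channel_positions_mm,
                 included_channels = included,
                 channel_spacing_mm = spacing,
                 imaged_segment_mm = imaged_segment_mm,
                 clock_offset_s = clock_offset_s),
            class = "aligned_session")
}

#' Classify MRI activity during one HAPC window
#'
#' The score is the deepest negative residual (luminal narrowing, mm)
#' over the arc-length band of the included channels (each channel +/-
#' half the inter-channel spacing) and the HAPC window translated to the
#' MRI clock and padded by `pad_s` on both sides, counting only valid
#' cells. Labels: `high` if score >= `theta_high_mm`, `minimal` if
#' `theta_min_mm <= score < theta_high_mm`, else `absent`. A window
#' lying entirely outside the MRI recording is `not_recorded`, kept
#' distinct from `absent`.
#'
#' @param session an [aligned_session()]
#' @param hapc one `hapc_event`
#' @param theta_high_mm,theta_min_mm residual-depth thresholds (mm),
#'   `theta_high_mm > theta_min_mm > 0`
#' @param pad_s window padding tolerating alignment uncertainty (s)
#' @return list with `label`, `score_mm`, `window_mri_s`
#' @export
classify_mri_activity <- function(session, hapc, theta_high_mm = 4,
                                  theta_min_mm = 1, pad_s = 15) {
  check_that(inherits(session, "aligned_session"),
             "classify_mri_activity: session must be an aligned_session")
  check_that(theta_high_mm > theta_min_mm && theta_min_mm > 0,
             "classify_mri_activity: need theta_high_mm > theta_min_mm > 0")
  rmap <- session$rmap
  win <- hapc$window_s - session$clock_offset_s
  win_pad <- c(win[1] - pad_s, win[2] + pad_s)
  t_rng <- range(rmap$times_s)
  if (win_pad[2] <= t_rng[1] || win_pad[1] > t_rng[2])
    return(list(label = "not_recorded", score_mm = NA_real_,
                window_mri_s = win_pad))

  half <- session$channel_spacing_mm / 2
  ch_pos <- session$channel_positions_mm[session$included_channels]
  pos_ok <- Reduce(`|`, lapply(ch_pos, function(p)
    abs(rmap$positions_mm - p) <= half))
  t_ok <- rmap$times_s >= win_pad[1] & rmap$times_s < win_pad[2]
  r <- rmap$residual_mm[pos_ok, t_ok, drop = FALSE]
  score <- if (all(is.na(r))) 0 else max(-r, na.rm = TRUE)
  label <- if (score >= theta_high_mm) "high"
  else if (score >= theta_min_mm) "minimal"
  else "absent"
  list(label = label, score_mm = score, window_mri_s = win_pad)
}

#' Detect MRI-only activity episodes
#'
#' Maximal time intervals during which the deepest instantaneous residual
#' trough `max_s(-r(s, t))` stays at or above `theta_min_mm` for at least
#' `min_duration_s`, labelled `high`/`minimal` by `theta_high_mm` and
#' annotated with whether they overlap any (padded, clock-shifted) HAPC
#' window — episodes that do not are activity seen only on MRI.
#'
#' @param session an [aligned_session()]
#' @param theta_min_mm,theta_high_mm residual-depth thresholds (mm)
#' @param min_duration_s minimum episode duration (s)
#' @param pad_s HAPC-window padding used for the overlap annotation (s)
#' @return data frame: `start_s`, `end_s` (half-open, MRI clock),
#'   `peak_mm`, `label`, `overlaps_hapc`
#' @export
detect_mri_episodes <- function(session, theta_min_mm = 1,
                                theta_high_mm = 4, min_duration_s = 5,
                                pad_s = 15) {
  check_that(inherits(session, "aligned_session"),
             "detect_mri_episodes: session must be an aligned_session")
  rmap <- session$rmap
  trough <- apply(rmap$residual_mm, 2, function(col)
    if (all(is.na(col))) 0 else max(-col, na.rm = TRUE))
  dt <- if (length(rmap$times_s) > 1) diff(rmap$times_s[1:2]) else 1
  active <- trough >= theta_min_mm
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  rows <- list()
  hapc_windows <- lapply(session$hapcs, function(h)
    h$window_s - session$clock_offset_s + c(-pad_s, pad_s))
  for (j in which(runs$values)) {
    t0 <- rmap$times_s[starts[j]]
    t1 <- rmap$times_s[ends[j]] + dt
    if (t1 - t0 < min_duration_s) next
    pk <- max(trough[starts[j]:ends[j]])
    overlaps <- any(vapply(hapc_windows, function(w)
      t0 < w[2] && t1 > w[1], logical(1)))
    rows[[length(rows) + 1]] <- data.frame(
      start_s = t0, end_s = t1, peak_mm = pk,
      label = if (pk >= theta_high_mm) "high" else "minimal",
      overlaps_hapc = overlaps)
  }
  if (length(rows) == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_mm = numeric(0), label = character(0),
                      overlaps_hapc = logical(0)))
  do.call(rbind, rows)
}

#' Summarise cross-modality agreement
#'
#' Counts HAPCs by MRI-activity label and converts the counts to integer
#' percentages (round half up), plus the number of MRI-only activity
#' episodes. `not_recorded` HAPCs (window outside the MRI acquisition)
#' are tallied separately from `absent`, and a merged count
#' (`absent_or_not_recorded`) is also reported since a visual comparison
#' cannot distinguish the two.
#'
#' @param classifications list of results from [classify_mri_activity()]
#' @param episodes optional episode data frame from
#'   [detect_mri_episodes()]
#' @return a `concordance_summary`: `n_hapcs`, `counts`, `percentages`
#'   (NA when there are no HAPCs), `n_mri_only_episodes`
#' @export
concordance_summary <- function(classifications, episodes = NULL) {
  labels <- vapply(classifications, function(x) x$label, character(1))
  lev <- c("high", "minimal", "absent", "not_recorded")
  check_that(all(labels %in% lev),
             "concordance_summary: unknown classification label")
  counts <- vapply(lev, function(l) sum(labels == l), integer(1))
  n <- length(labels)
  pct <- if (n == 0) stats::setNames(rep(NA_real_, length(lev)), lev)
  else round_half_up(100 * counts / n)
  n_mri_only <- if (is.null(episodes)) NA_integer_
  else sum(!episodes$overlaps_hapc)
  structure(list(n_hapcs = n, counts = as.list(counts),
                 percentages = as.list(pct),
                 absent_or_not_recorded = unname(counts["absent"] +
                                                   counts["not_recorded"]),
                 n_mri_only_episodes = n_mri_only),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("concordance_summary: %d HAPCs\n", x$n_hapcs))
  for (l in names(x$counts))
    cat(sprintf("  %-13s %d (%s%%)\n", l, x$counts[[l]],
                if (is.na(x$percentages[[l]])) "-" else x$percentages[[l]]))
  if (!is.na(x$n_mri_only_episodes))
    cat(sprintf("  MRI-only episodes: %d\n", x$n_mri_only_episodes))
  invisible(x)
}

#' Aggregate per-patient HAPC counts
#'
#' Table-level arithmetic over a cohort: the total number of HAPCs and
#' how many patients showed at least one.
#'
#' @param counts integer vector, one HAPC count per patient
#' @return list with `total_hapcs`, `patients_with_hapcs`, `n_patients`
#' @export
summarise_hapc_counts <- function(counts) {
  check_that(all(counts >= 0 & counts == round(counts)),
             "summarise_hapc_counts: counts must be non-negative integers")
  list(total_hapcs = sum(counts),
       patients_with_hapcs = sum(counts > 0),
       n_patients = length(counts))
}
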