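#' Screen and AoI geometry configuration
#'
#' Defaults describe the recording setup: a 1024 x 768 px display viewed so
#' that 1 cm subtends 1 degree, planet stimuli of radius 2.5 cm diagonally
#' offset 13 cm from a central fixation cross, and elliptical cue AoIs with
#' semi-major axis twice the planet radius and semi-minor axis equal to it.
#' Coordinates are in pixels, origin top-left, y increasing downward.
#'
#' @param px_per_cm Pixels per centimetre of screen.
#' @param screen c(width, height) in pixels.
#' @param planet_radius_cm Planet stimulus radius (cm).
#' @param offset_cm Diagonal offset of each planet from fixation (cm).
#' @param semi_major_cm,semi_minor_cm Simple-cue AoI semi-axes (cm).
#' @return List of class `aoi_geometry`.
#' @export
aoi_geometry <- function(px_per_cm = 28.2, screen = c(1024, 768),
                         planet_radius_cm = 2.5, offset_cm = 13,
                         semi_major_cm = 2 * planet_radius_cm,
                         semi_minor_cm = planet_radius_cm) {
  structure(list(px_per_cm = px_per_cm, screen = screen,
                 planet_radius_cm = planet_radius_cm, offset_cm = offset_cm,
                 semi_major_cm = semi_major_cm, semi_minor_cm = semi_minor_cm),
            class = "aoi_geometry")
}

#' Build rotated-elliptical AoIs for a trial
#'
#' Each simple cue gets a full ellipse centred on its planet; a compound's
#' parent ellipse has sqrt(2)-scaled semi-axes (twice the area) and is split
#' along its minor axis into two half-ellipses, one per cue, so every cue's
#' AoI area equals the full simple-cue ellipse area. Major axes are angled
#' +45 degrees from vertical for the left stimulus and -45 for the right.
#' Planets sit diagonally above-left and above-right of the central fixation
#' cross.
#'
#' @param trial One trial (a one-row trial data.frame or a list with
#'   `left_cues`, `right_cues`).
#' @param geometry An [aoi_geometry()].
#' @return Data.frame of AoIs: `cue_id`, `side`, `half` ("none", "neg",
#'   "pos": sign of the major-axis coordinate for half-ellipses), `cx`,
#'   `cy`, `a`, `b` (px), `angle_deg` (rotation from vertical).
#' @export
build_aois <- function(trial, geometry = aoi_geometry()) {
  g <- geometry
  ctr <- g$screen / 2
  off <- g$offset_cm / sqrt(2) * g$px_per_cm
  centers <- list(left = c(ctr[1] - off, ctr[2] - off),
                  right = c(ctr[1] + off, ctr[2] - off))
  angles <- c(left = 45, right = -45)
  a0 <- g$semi_major_cm * g$px_per_cm
  b0 <- g$semi_minor_cm * g$px_per_cm
  rows <- list()
  for (side in c("left", "right")) {
    cue <- stim_cues(trial[[paste0(side, "_cues")]])
    if (!length(cue)) next
    if (length(cue) == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        cue_id = cue, side = side, half = "none",
        cx = centers[[side]][1], cy = centers[[side]][2],
        a = a0, b = b0, angle_deg = angles[[side]],
        stringsAsFactors = FALSE)
    } else {
      # parent ellipse scaled by sqrt(2): area doubles, each half-ellipse
      # keeps the full simple-cue AoI area
      rows[[length(rows) + 1L]] <- data.frame(
        cue_id = cue, side = side, half = c("neg", "pos"),
        cx = centers[[side]][1], cy = centers[[side]][2],
        a = sqrt(2) * a0, b = sqrt(2) * b0, angle_deg = angles[[side]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(cue_id = character(0), side = character(0),
                                       half = character(0), cx = numeric(0),
                                       cy = numeric(0), a = numeric(0),
                                       b = numeric(0), angle_deg = numeric(0)))
  do.call(rbind, rows)
}

#' Major/minor-axis coordinates of a point in an AoI's rotated frame
#' @noRd
aoi_frame_coords <- function(x, y, aoi) {
  th <- aoi$angle_deg * pi / 180
  # major-axis unit vector: vertical ("up" = -y) rotated by angle_deg
  # (positive = toward +x)
  ux <- sin(th); uy <- -cos(th)
  dx <- x - aoi$cx; dy <- y - aoi$cy
  list(major = dx * ux + dy * uy, minor = dx * -uy + dy * ux)
}

#' Assign a fixation to a cue AoI
#'
#' Point-in-rotated-(half-)ellipse test; the boundary counts as inside.
#' Returns `NA` when the point lies outside every AoI.
#'
#' @param x,y Fixation coordinates (px).
#' @param aois AoIs from [build_aois()].
#' @return The cue id, or `NA_character_`.
#' @export
assign_fixation <- function(x, y, aois) {
  for (i in seq_len(nrow(aois))) {
    aoi <- aois[i, ]
    fc <- aoi_frame_coords(x, y, aoi)
    inside <- (fc$major / aoi$a)^2 + (fc$minor / aoi$b)^2 <= 1 + 1e-12
    ok_half <- switch(aoi$half, none = TRUE,
                      neg = fc$major <= 1e-12, pos = fc$major >= -1e-12)
    if (inside && ok_half) return(aoi$cue_id)
  }
  NA_character_
}

#' Relative looking time per cue in the pre-choice window
#'
#' Sums in-AoI fixation durations before `choice_time` per cue and
#' normalizes by the total in-AoI duration. Fixations straddling the choice
#' are clipped at `choice_time` (the pre-choice portion counts). The total
#' in-AoI duration is returned for downstream duration weighting of trials.
#'
#' @param fixations Data.frame with `onset`, `offset` (ms from trial start)
#'   and `x`, `y` (px).
#' @param aois AoIs from [build_aois()].
#' @param choice_time Choice response time (ms, > 0).
#' @return List: `rlt` (named proportions per cue on screen; NA when no
#'   in-AoI time), `total_in_aoi` (ms), `flagged` (TRUE when no in-AoI
#'   time).
#' @export
relative_looking_time <- function(fixations, aois, choice_time) {
  if (choice_time <= 0) stop("choice_time must be > 0")
  if (any(fixations$offset <= fixations$onset)) stop("fixation offset must exceed onset")
  dur <- pmin(fixations$offset, choice_time) - fixations$onset
  keep <- dur > 0
  cue <- rep(NA_character_, nrow(fixations))
  cue[keep] <- vapply(which(keep), function(i) {
    assign_fixation(fixations$x[i], fixations$y[i], aois)
  }, "")
  cues_on_screen <- aois$cue_id
  tot <- stats::setNames(numeric(length(cues_on_screen)), cues_on_screen)
  in_aoi <- keep & !is.na(cue)
  if (any(in_aoi)) {
    sums <- tapply(dur[in_aoi], cue[in_aoi], sum)
    tot[names(sums)] <- sums
  }
  total <- sum(tot)
  if (total == 0) {
    return(list(rlt = stats::setNames(rep(NA_real_, length(tot)), names(tot)),
                total_in_aoi = 0, flagged = TRUE))
  }
  list(rlt = tot / total, total_in_aoi = total, flagged = FALSE)
}

#' Looking proportion of the affect-congruent cue
#'
#' The affect-congruent cue is the high-value (75%) cue of the L/H compound
#' for positively induced participants and the low-value (25%) cue for
#' negatively induced ones. Under `denominator = "all_cues"` the proportion
#' is relative to all cue AoIs on screen; under `"within_compound"` it is
#' renormalized to the time spent on the L/H compound's two cues.
#'
#' @param rlt Named per-cue looking proportions (from
#'   [relative_looking_time()]).
#' @param condition Affect code, +1 or -1 (neutral has no congruent cue).
#' @param trial The trial (must contain an L/H compound).
#' @param cues Cue set.
#' @param denominator `"all_cues"` or `"within_compound"`.
#' @return Proportion in [0, 1].
#' @export
affect_congruent_rlt <- function(rlt, condition, trial, cues,
                                 denominator = c("all_cues", "within_compound")) {
  denominator <- match.arg(denominator)
  if (!condition %in% c(-1, 1)) {
    stop("no affect-congruent cue is defined for the neutral condition")
  }
  cls <- stats::setNames(cues$value_class, cues$cue_id)
  side <- lh_side(as.data.frame(trial, stringsAsFactors = FALSE), cues)
  if (is.na(side)) stop("trial contains no L/H compound")
  comp <- stim_cues(trial[[paste0(side, "_cues")]])
  congruent <- comp[cls[comp] == if (condition > 0) "H" else "L"]
  if (denominator == "all_cues") {
    unname(rlt[congruent])
  } else {
    unname(rlt[congruent] / sum(rlt[comp]))
  }
}

#' Eye-tracking quality-control exclusions
#'
#' Flags participants whose metric exceeds Q3 + 1.5 * IQR of the cohort
#' distribution, applied to each metric column independently (e.g.
#' rater-disagreement pixels, percentage of fixations outside any valid
#' AoI). Realized thresholds are reported.
#'
#' @param metrics Data.frame with `participant_id` and one or more numeric
#'   metric columns.
#' @return Data.frame of per-metric flags plus `excluded`; realized
#'   thresholds in attribute `"thresholds"`.
#' @export
qc_exclusions <- function(metrics) {
  cols <- setdiff(names(metrics), "participant_id")
  if (nrow(metrics) < 4) stop("need >= 4 participants to estimate IQR thresholds")
  out <- metrics["participant_id"]
  thr <- stats::setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    q <- stats::quantile(metrics[[cl]], c(0.25, 0.75))
    thr[cl] <- q[2] + 1.5 * (q[2] - q[1])
    out[[paste0("flag_", cl)]] <- metrics[[cl]] > thr[cl]
  }
  out$excluded <- Reduce(`|`, out[grepl("^flag_", names(out))])
  attr(out, "thresholds") <- thr
  out
}

#' Simulate a pre-choice fixation stream for a trial
#'
#' Fixture generator for the gaze pipeline: emits alternating fixation
#' segments whose expected per-cue dwell-time shares equal the supplied
#' attention weights, with a configurable probability of off-AoI segments
#' (landing on the central fixation cross). Segment durations are
#' gamma-distributed (shape 4) with the given mean, roughly matching the
#' unimodal spread of human fixation durations.
#'
#' @param trial One trial (with at least one cue on screen).
#' @param weights Named attention weights over the cues on screen (summing
#'   to 1).
#' @param total_dur Total stream duration (ms).
#' @param noise Probability that a segment falls outside every AoI.
#' @param geometry An [aoi_geometry()].
#' @param mean_fix_ms Mean fixation duration (ms).
#' @param seed Integer seed (optional).
#' @return Fixation data.frame: `onset`, `offset`, `x`, `y`, `target`
#'   (generating cue id or NA for off-AoI segments).
#' @export
simulate_fixations <- function(trial, weights, total_dur = 2000, noise = 0,
                               geometry = aoi_geometry(), mean_fix_ms = 250,
                               seed = NULL) {
  local_rng(seed)
  aois <- build_aois(trial, geometry)
  if (!nrow(aois)) stop("trial has no cue AoIs")
  if (is.null(names(weights)) || !setequal(names(weights), aois$cue_id)) {
    stop("weights must be named by the cues on screen")
  }
  # representative landing point inside each AoI: the centre for full
  # ellipses, the half-ellipse midpoint along the major axis otherwise
  land <- lapply(seq_len(nrow(aois)), function(i) {
    aoi <- aois[i, ]
    shift <- switch(aoi$half, none = 0, neg = -aoi$a / 2, pos = aoi$a / 2)
    th <- aoi$angle_deg * pi / 180
    c(aoi$cx + shift * sin(th), aoi$cy + shift * -cos(th))
  })
  names(land) <- aois$cue_id
  onsets <- c(); offsets <- c(); xs <- c(); ys <- c(); tg <- c()
  t <- 0
  while (t < total_dur) {
    dur <- stats::rgamma(1, shape = 4, rate = 4 / mean_fix_ms)
    dur <- min(dur, total_dur - t)
    if (stats::runif(1) < noise) {
      pt <- geometry$screen / 2  # fixation cross
      target <- NA_character_
    } else {
      target <- sample(names(weights), 1, prob = weights)
      pt <- land[[target]]
    }
    onsets <- c(onsets, t); offsets <- c(offsets, t + dur)
    xs <- c(xs, pt[1]); ys <- c(ys, pt[2]); tg <- c(tg, target)
    t <- t + dur
  }
  data.frame(onset = onsets, offset = offsets, x = xs, y = ys,
             target = tg, stringsAsFactors = FALSE)
}
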