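# Turn segmentation: cut the synchronized run at trajectory inflections.

#' Detect turn-switch times from the smoothed lateral trajectory
#'
#' Turn switches are the inflection instants of the lateral coordinate where
#' path curvature changes sign. The default method finds sign changes of the
#' second time-derivative of the filtered lateral coordinate (the trajectory
#' inflection); `"third_derivative"` uses the third derivative instead (on
#' quasi-sinusoidal paths its zeros fall at the turn apexes rather than the
#' switches, so it is offered for cross-checks, not as the boundary marker).
#'
#' Crossings are validated with a hysteresis band (the derivative must leave
#' the noise floor on both sides of the crossing) and crossings closer than
#' `min_turn_duration` to the previously accepted one are suppressed (first
#' in a cluster wins).
#'
#' @param synced A `synced_run` from [synchronize()], or a data.frame with
#'   columns `t` and `x` (filtered lateral coordinate).
#' @param method Switch detection method.
#' @param min_turn_duration Minimum plausible turn duration, s.
#' @param hysteresis_frac Hysteresis band as a fraction of the robust
#'   (98th-percentile) derivative magnitude.
#' @param min_amplitude Absolute floor on the derivative magnitude
#'   (m/s^2 for the curvature method): if the whole stream stays below it,
#'   the run is straight and no switches are reported.
#' @return Ordered numeric vector of switch times, s.
#' @export
detect_turn_switches <- function(synced,
                                 method = c("curvature_sign", "third_derivative"),
                                 min_turn_duration = 0.6,
                                 hysteresis_frac = 0.1,
                                 min_amplitude = 1e-3) {
  method <- match.arg(method)
  t <- synced$t
  x <- synced$x
  d <- finite_gradient(finite_gradient(x, t), t)
  if (method == "third_derivative") d <- finite_gradient(d, t)
  q <- stats::quantile(abs(d), 0.98, names = FALSE)
  if (q < min_amplitude) return(numeric(0))
  h <- max(hysteresis_frac * q, min_amplitude)
  excursion_crossings(t, d, hysteresis = h, min_gap = min_turn_duration)
}

# Zero crossings of y(t) validated by excursion: between consecutive
# crossings the signal must exceed the hysteresis band, on both sides of an
# accepted crossing. Crossing times linearly interpolated; crossings closer
# than min_gap to the previous accepted one are dropped (first wins).
excursion_crossings <- function(t, y, hysteresis = 0, min_gap = 0) {
  s <- sign(y)
  s[s == 0] <- 1
  idx <- which(s[-1] != s[-length(s)])
  if (!length(idx)) return(numeric(0))
  tc <- t[idx] - y[idx] * (t[idx + 1] - t[idx]) / (y[idx + 1] - y[idx])
  if (hysteresis > 0) {
    seg_bounds <- c(1, idx, length(y))
    seg_max <- vapply(seq_len(length(seg_bounds) - 1), function(i)
      max(abs(y[seg_bounds[i]:seg_bounds[i + 1]])), numeric(1))
    keep <- seg_max[-length(seg_max)] >= hysteresis &
            seg_max[-1] >= hysteresis
    tc <- tc[keep]
  }
  if (min_gap > 0 && length(tc) > 1) {
    out <- tc[1]
    for (v in tc[-1]) if (v - out[length(out)] >= min_gap) out <- c(out, v)
    tc <- out
  }
  tc
}

#' Select the analysis turns from detected switches
#'
#' Consecutive switch times delimit turns, numbered 1-based from the first
#' detected switch. The analysis window retains turns `first_turn` to
#' `last_turn` (default 3-16: the skier has attained speed by turn 3, and
#' turn 16 is the last before the finish approach on an 18-gate course).
#'
#' @param switches Ordered switch times from [detect_turn_switches()].
#' @param first_turn,last_turn Analysis window (inclusive).
#' @param section_map Section map used to label the retained turns, see
#'   [assign_section()].
#' @return A data.frame of turn boundaries: `turn_index, start_t, end_t,
#'   section`.
#' @export
select_analysis_turns <- function(switches, first_turn = 3L, last_turn = 16L,
                                  section_map = default_section_map()) {
  n_complete <- length(switches) - 1L
  if (n_complete < last_turn)
    stop("only ", n_complete, " complete turns detected; need at least ",
         last_turn, " for the analysis window ", first_turn, "-", last_turn)
  idx <- first_turn:last_turn
  data.frame(
    turn_index = idx,
    start_t = switches[idx],
    end_t = switches[idx + 1L],
    section = assign_section(idx, section_map))
}

#' Assign a course section to turn indices
#'
#' Maps turn indices to the course sections of the analysis design:
#' `speed` (gaining speed), `overspeed` (steep section, speed management),
#' `flat` (maintaining speed); indices outside the map are `excluded`.
#'
#' @param turn_index Integer vector of 1-based turn indices.
#' @param section_map Named list of turn-index vectors, see
#'   [default_section_map()].
#' @return Factor with levels `speed, overspeed, flat, excluded`.
#' @export
#' @examples
#' assign_section(c(2, 4, 8, 12))
assign_section <- function(turn_index, section_map = default_section_map()) {
  lv <- c("speed", "overspeed", "flat", "excluded")
  out <- rep("excluded", length(turn_index))
  for (nm in names(section_map))
    out[turn_index %in% section_map[[nm]]] <- nm
  factor(out, levels = lv)
}
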