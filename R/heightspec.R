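#' Detect diffusion events in a height-spectroscopy trace
#'
#' Thresholds a fixed-position height-time trace at
#' \eqn{H_T = mean + k\sigma} of the baseline height distribution
#' (default k = 5). The baseline mean and sigma are re-estimated iteratively
#' on sub-threshold samples until the event set converges, so that the events
#' themselves do not contaminate the baseline. Contiguous super-threshold
#' runs separated by fewer than `merge_gap` samples are merged (tip ringing).
#'
#' @param trace A [gen_height_trace()] object, or a numeric vector of heights
#'   (nm) with `rate` supplied.
#' @param k_sigma Threshold in baseline sigmas above the mean (default 5).
#' @param rate Sampling rate (samples/s) when `trace` is a bare vector.
#' @param merge_gap Merge super-threshold runs separated by gaps shorter
#'   than this many samples (default 2).
#' @param max_iter Baseline re-estimation iterations.
#' @return Object of class `diffusion_events`: data.frame with `start`,
#'   `end` (sample indices), `samples`, `dwell_s`, `peak_nm`; attributes
#'   `threshold` (nm), `baseline` (mean, sd), `rate`, `n_samples`,
#'   `total_s`, `event_time_s`.
#' @examples
#' tr <- gen_height_trace(0.59, 830, rate = 1e5, duration = 0.05, seed = 1)
#' ev <- detect_events(tr)
#' @export
detect_events <- function(trace, k_sigma = 5, rate = NULL, merge_gap = 2,
                          max_iter = 20) {
  if (inherits(trace, "height_trace")) {
    z <- trace$z; rate <- trace$rate
  } else {
    z <- as.numeric(trace)
    if (is.null(rate)) stop("rate must be given for a bare trace", call. = FALSE)
  }
  n <- length(z)
  # robust initialization (median + MAD) so that frequent tall events cannot
  # inflate the first baseline estimate; subsequent iterations use the plain
  # mean + k*sd of sub-threshold samples
  mad0 <- stats::mad(z)
  base <- if (mad0 > 0) z <= stats::median(z) + k_sigma * mad0 else rep(TRUE, n)
  if (!any(base)) base <- rep(TRUE, n)
  thr <- Inf
  for (it in seq_len(max_iter)) {
    if (!any(base)) stop("baseline estimation failed: no sub-threshold samples", call. = FALSE)
    m <- mean(z[base]); s <- stats::sd(z[base])
    if (!is.finite(s) || s <= 0) stop("baseline estimation failed: zero spread", call. = FALSE)
    new_thr <- m + k_sigma * s
    new_base <- z <= new_thr
    if (isTRUE(all.equal(new_thr, thr)) || identical(new_base, base)) {
      thr <- new_thr; base <- new_base
      break
    }
    thr <- new_thr; base <- new_base
  }
  above <- !base
  # merge short gaps
  if (merge_gap > 0 && any(above)) {
    r <- rle(above)
    gap <- !r$values & r$lengths < merge_gap
    # do not merge across the trace ends
    gap[c(1, length(gap))] <- FALSE
    r$values[gap] <- TRUE
    above <- inverse.rle(r)
  }
  ev <- if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values)
    data.frame(start = starts[keep], end = ends[keep],
               samples = r$lengths[keep])
  } else {
    data.frame(start = integer(), end = integer(), samples = integer())
  }
  ev$dwell_s <- ev$samples / rate
  ev$peak_nm <- vapply(seq_len(nrow(ev)),
                       function(k) max(z[ev$start[k]:ev$end[k]]), 0)
  attr(ev, "threshold") <- thr
  attr(ev, "baseline") <- c(mean = mean(z[base]), sd = stats::sd(z[base]))
  attr(ev, "rate") <- rate
  attr(ev, "n_samples") <- n
  attr(ev, "total_s") <- n / rate
  attr(ev, "event_time_s") <- sum(ev$samples) / rate
  class(ev) <- c("diffusion_events", "data.frame")
  ev
}

#' Effective detection width of the tip over a protein
#'
#' The protein cross-section dilated by the tip radius, expressed as a
#' diameter: \eqn{w = 2(\sqrt{A/\pi} + r_{tip})}.
#'
#' @param a_protein Protein cross-section area, nm^2.
#' @param tip_radius Tip radius, nm (default 1).
#' @return Detection width w, nm.
#' @examples
#' detection_width(45.125, 1) # 9.58 nm
#' @export
detection_width <- function(a_protein, tip_radius = 1) {
  stopifnot(a_protein > 0, tip_radius >= 0)
  2 * (sqrt(a_protein / pi) + tip_radius)
}

#' Diffusion coefficient from the event dwell time
#'
#' Inverts the crossing-time relation \eqn{\tau_D = w^2 / (4 D_U)}:
#' \eqn{D_U = w^2/(4\tau_D)}.
#'
#' @param tau_d Characteristic event dwell time, s.
#' @param w Detection width, nm.
#' @return Diffusion coefficient, um^2/s.
#' @examples
#' diffusion_coefficient(39e-6, 9.58) # ~0.59 um^2/s
#' @export
diffusion_coefficient <- function(tau_d, w) {
  stopifnot(tau_d > 0, w > 0)
  (w * 1e-3)^2 / (4 * tau_d)
}

#' Characteristic dwell time of detected events
#'
#' Two estimators of \eqn{\tau_D} from a [detect_events()] set: the fitted
#' decay constant of the dwell-time distribution tail (exponential fit to
#' dwells above the `tail_quantile`, robust to truncation of very short
#' events; the default estimator) and the plain mean dwell.
#'
#' @param events A `diffusion_events` table.
#' @param method `"tail_fit"` (default) or `"mean"`.
#' @param tail_quantile Tail start for the fit (default 0.5 = median).
#' @return tau_D in seconds.
#' @export
event_dwell_time <- function(events, method = c("tail_fit", "mean"),
                             tail_quantile = 0.5) {
  method <- match.arg(method)
  if (nrow(events) == 0) stop("no events", call. = FALSE)
  d <- events$dwell_s
  if (method == "mean") return(mean(d))
  t0 <- stats::quantile(d, tail_quantile, names = FALSE)
  tail <- d[d >= t0]
  # MLE of a shifted exponential: decay constant = mean excess over t0
  mean(tail - t0) + 1 / attr(events, "rate") / 2
}

#' Unbound 2D concentration from the event time fraction
#'
#' \eqn{C_U = (t_{z>H_T} / t_{total}) / A_{protein}}: the fraction of time
#' the tip detects a molecule, divided by the area one molecule occludes.
#'
#' @param events A `diffusion_events` table.
#' @param a_protein Protein cross-section area, nm^2.
#' @return Concentration, molecules/um^2.
#' @examples
#' tr <- gen_height_trace(0.59, 830, rate = 1e5, duration = 0.05, seed = 1)
#' unbound_concentration(detect_events(tr))
#' @export
unbound_concentration <- function(events, a_protein = AQPZ_FOOTPRINT_NM2) {
  stopifnot(a_protein > 0)
  frac <- attr(events, "event_time_s") / attr(events, "total_s")
  frac / (a_protein * 1e-6)
}

#' Full height-spectroscopy analysis of one trace
#'
#' Detects events and reports the diffusion coefficient and unbound
#' concentration estimates with the detection geometry used.
#'
#' @inheritParams detect_events
#' @param a_protein Protein cross-section area, nm^2.
#' @param tip_radius Tip radius, nm.
#' @param tau_method Dwell-time estimator, see [event_dwell_time()].
#' @return List of class `diffusion_estimate`: `d_u` (um^2/s), `c_u`
#'   (molecules/um^2), `tau_d` (s), `w` (nm), `n_events`, threshold info.
#' @export
analyze_height_trace <- function(trace, a_protein = AQPZ_FOOTPRINT_NM2,
                                 tip_radius = 1, k_sigma = 5,
                                 tau_method = "tail_fit", merge_gap = 2) {
  ev <- detect_events(trace, k_sigma = k_sigma, merge_gap = merge_gap)
  w <- detection_width(a_protein, tip_radius)
  tau_d <- if (nrow(ev)) event_dwell_time(ev, method = tau_method) else NA_real_
  structure(list(
    d_u = if (is.na(tau_d)) NA_real_ else diffusion_coefficient(tau_d, w),
    c_u = unbound_concentration(ev, a_protein),
    tau_d = tau_d, w = w, a_protein = a_protein, tip_radius = tip_radius,
    n_events = nrow(ev), threshold = attr(ev, "threshold"),
    events = ev), class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf(
    "diffusion_estimate: %d events, tau_D = %.3g s, w = %.2f nm -> D_U = %.3g um^2/s, C_U = %.0f /um^2\n",
    x$n_events, x$tau_d, x$w, x$d_u, x$c_u))
  invisible(x)
}
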