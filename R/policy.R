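#' Vital-sign schedule window policy
#'
#' Bundles every schedule parameter used when scoring an episode against
#' the four-interval observation schedule. All durations are minutes,
#' matching the grain of the schedule itself. Defaults encode the hospital
#' policy the package audits against:
#' baseline observations from one hour before initiation up to 5 minutes
#' after; a 15-minute observation at 15 min with a +/- 5 min grace; hourly
#' observations with a +/- 20 min grace, anchored at either the start or a
#' 15-minute observation; and a post observation within one hour of
#' completion. Interval bounds are closed on both ends.
#'
#' @param baseline_before_min minutes before initiation the baseline
#'   window opens (default 60).
#' @param baseline_after_min minutes after initiation the baseline window
#'   closes (default 5).
#' @param t15_nominal_min nominal offset of the 15-minute observation
#'   (default 15).
#' @param t15_grace_min grace either side of the 15-minute mark
#'   (default 5).
#' @param hourly_grace_min grace either side of each hourly mark
#'   (default 20).
#' @param hourly_max_subintervals maximum number of hourly subintervals
#'   assessed (default 3, matching a maximum three-hour transfusion for
#'   monitoring purposes).
#' @param post_window_min minutes after completion in which the post
#'   observation must fall (default 60).
#' @param consent_lookback_min how far before initiation a consent record
#'   remains valid (default 1440, i.e. 24 h; the standard does not state a
#'   window, see the methods vignette).
#' @param open_episode_policy how to treat episodes with no completion
#'   record when deciding which hourly subintervals are required:
#'   `"ASSUME_MAX"` (all subintervals required; the audit default — a
#'   missing completion must not excuse missing observations) or
#'   `"CENSOR"` (require a subinterval only if the episode's documentation
#'   demonstrably extends past it).
#' @param match_product_type if `TRUE`, a Complete record may only close
#'   an Initiate carrying the same blood-product type. Off by default:
#'   matching is by encounter and time only.
#' @return an object of class `window_policy`.
#' @export
window_policy <- function(baseline_before_min = 60,
                          baseline_after_min = 5,
                          t15_nominal_min = 15,
                          t15_grace_min = 5,
                          hourly_grace_min = 20,
                          hourly_max_subintervals = 3,
                          post_window_min = 60,
                          consent_lookback_min = 1440,
                          open_episode_policy = c("ASSUME_MAX", "CENSOR"),
                          match_product_type = FALSE) {
  open_episode_policy <- match.arg(open_episode_policy)
  p <- list(
    baseline_before_min = baseline_before_min,
    baseline_after_min = baseline_after_min,
    t15_nominal_min = t15_nominal_min,
    t15_grace_min = t15_grace_min,
    hourly_grace_min = hourly_grace_min,
    hourly_max_subintervals = hourly_max_subintervals,
    post_window_min = post_window_min,
    consent_lookback_min = consent_lookback_min,
    open_episode_policy = open_episode_policy,
    match_product_type = isTRUE(match_product_type)
  )
  durs <- c("baseline_before_min", "baseline_after_min", "t15_nominal_min",
            "t15_grace_min", "hourly_grace_min", "post_window_min",
            "consent_lookback_min")
  for (d in durs) {
    v <- p[[d]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 ||
        v != round(v)) {
      stop(sprintf("window_policy: '%s' must be a positive whole number of minutes", d),
           call. = FALSE)
    }
    p[[d]] <- as.integer(v)
  }
  k <- p$hourly_max_subintervals
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != round(k)) {
    stop("window_policy: 'hourly_max_subintervals' must be a whole number >= 1",
         call. = FALSE)
  }
  p$hourly_max_subintervals <- as.integer(k)
  structure(p, class = "window_policy")
}

#' @export
print.window_policy <- function(x, ...) {
  cat("<window_policy>\n")
  cat(sprintf("  baseline  [start - %d, start + %d] min\n",
              x$baseline_before_min, x$baseline_after_min))
  cat(sprintf("  15-minute [start + %d, start + %d] min\n",
              x$t15_nominal_min - x$t15_grace_min,
              x$t15_nominal_min + x$t15_grace_min))
  cat(sprintf("  hourly    60k +/- %d min, k = 1..%d, anchored at start and 15-min obs\n",
              x$hourly_grace_min, x$hourly_max_subintervals))
  cat(sprintf("  post      [end, end + %d] min\n", x$post_window_min))
  cat(sprintf("  consent lookback %d min; open episodes: %s; product matching: %s\n",
              x$consent_lookback_min, x$open_episode_policy,
              if (x$match_product_type) "on" else "off"))
  invisible(x)
}

#' Default compliance measures and their 80% target
#'
#' The seven measures tracked by the warehouse. The default target of 0.80
#' applies to every measure and can be overridden per measure.
#'
#' @param target default target proportion applied to each measure.
#' @param overrides optional named numeric vector of per-measure targets.
#' @return named numeric vector over the seven measures.
#' @export
measure_targets <- function(target = 0.80, overrides = NULL) {
  tg <- setNames(rep(target, length(cdw_measures())), cdw_measures())
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), cdw_measures())
    if (length(bad)) {
      stop("unknown measure(s) in target overrides: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tg[names(overrides)] <- overrides
  }
  if (any(tg < 0 | tg > 1)) stop("targets must lie in [0, 1]", call. = FALSE)
  tg
}

#' @rdname measure_targets
#' @export
cdw_measures <- function() {
  c("consent", "compatibility", "completion",
    "baseline", "min15", "hourly", "post")
}
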