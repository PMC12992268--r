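# Channel quality rejection and separation of each recording's channels
# into activated / suppressive / channel-averaging responses.

#' Channel quality assessment and rejection
#'
#' Screens every channel of a recording against three rules and flags
#' failures: low photon counts (counts-based series only; median gated
#' counts per frame below a floor, typical of dead or decoupled optodes),
#' baseline instability (coefficient of variation over the pre-task rest
#' above a cap, or a whole-recording linear drift exceeding a fraction of
#' the signal level), and burst contamination (fraction of frames with
#' robust z-score beyond a cutoff). Thresholds are configurable;
#' decisions are deterministic given thresholds.
#'
#' @param x A `gated_series` (counts-based screening, using the summed
#'   counts across gates), an `hbo_series`, or a plain channel x frame
#'   matrix.
#' @param protocol A [task_protocol()]; its pre-task rest is the baseline.
#' @param min_counts Low-count floor (median counts/frame; counts input
#'   only).
#' @param max_baseline_cv Baseline coefficient-of-variation cap.
#' @param max_drift Cap on |linear slope| x duration relative to the median
#'   absolute signal level.
#' @param max_burst_frac Cap on the fraction of burst frames.
#' @param burst_z Robust z cutoff defining a burst frame.
#' @param burst_rel Minimum burst magnitude as a fraction of the median
#'   signal level (keeps sub-noise-floor curvature residuals of smooth
#'   responses from counting as bursts at very high photon counts).
#' @return An object of class `channel_quality`: data.frame `metrics`
#'   (per-channel metrics and reasons), logical `retained`, and
#'   `n_rejected`. Samples where every channel fails are flagged
#'   `all_rejected`.
#' @export
reject_channels <- function(x, protocol,
                            min_counts = 100,
                            max_baseline_cv = 0.15,
                            max_drift = 0.10,
                            max_burst_frac = 0.05,
                            burst_z = 5, burst_rel = 0.05) {
  counts_mode <- inherits(x, "gated_series")
  if (counts_mode) {
    nch <- length(x$channels)
    nf <- length(x$frame_times_s)
    # total counts across gates at the first wavelength: coupling proxy
    m <- matrix(NA_real_, nch, nf)
    for (ch in seq_len(nch))
      m[ch, ] <- colSums(matrix(x$values[ch, 1, , ], nrow = 3))
    channels <- x$channels
    ft <- x$frame_times_s
  } else if (inherits(x, "hbo_series")) {
    m <- x$values; channels <- x$channels; ft <- x$frame_times_s
  } else {
    m <- as.matrix(x); channels <- seq_len(nrow(m))
    ft <- protocol$frame_times_s
  }
  bl <- which(ft >= 0 & ft < protocol$rest_pre_s)
  nch <- nrow(m)
  met <- data.frame(channel = channels,
                    median_level = NA_real_, baseline_cv = NA_real_,
                    drift = NA_real_, burst_frac = NA_real_,
                    retained = TRUE, reasons = "",
                    stringsAsFactors = FALSE)
  for (ch in seq_len(nch)) {
    v <- m[ch, ]
    ok <- is.finite(v)
    reasons <- character(0)
    met$median_level[ch] <- stats::median(v[ok])
    if (!any(ok)) {
      reasons <- "low counts"
    } else {
      if (counts_mode && met$median_level[ch] < min_counts)
        reasons <- c(reasons, "low counts")
      vb <- v[intersect(which(ok), bl)]
      if (length(vb) >= 2 && mean(vb) != 0) {
        met$baseline_cv[ch] <- stats::sd(vb) / abs(mean(vb))
      } else met$baseline_cv[ch] <- Inf
      lev <- max(abs(met$median_level[ch]), 1e-12)
      fit <- stats::lm.fit(cbind(1, ft[ok]), v[ok])
      met$drift[ch] <- abs(fit$coefficients[2]) * diff(range(ft)) / lev
      if (met$baseline_cv[ch] > max_baseline_cv ||
          met$drift[ch] > max_drift)
        reasons <- c(reasons, "baseline instability")
      # bursts are isolated spikes off a running-median smooth that are
      # both many noise-sds large and a sizable fraction of the signal
      # level; the smooth hemodynamic deflection passes through the filter
      # and its tiny curvature residuals never clear the relative floor
      resid <- v[ok] - stats::runmed(v[ok], 5)
      s <- stats::mad(resid)
      met$burst_frac[ch] <- if (s > 0)
        mean(abs(resid) / s > burst_z &
               abs(resid) > burst_rel * max(abs(met$median_level[ch]),
                                            1e-12)) else 0
      if (met$burst_frac[ch] > max_burst_frac)
        reasons <- c(reasons, "saturation/burst")
    }
    if (length(reasons)) {
      met$retained[ch] <- FALSE
      met$reasons[ch] <- paste(reasons, collapse = "; ")
    }
  }
  structure(list(metrics = met, retained = met$retained,
                 n_rejected = sum(!met$retained),
                 all_rejected = all(!met$retained)),
            class = "channel_quality")
}

#' @export
print.channel_quality <- function(x, ...) {
  cat(sprintf("Channel quality: %d/%d rejected (%.0f%%)\n",
              x$n_rejected, nrow(x$metrics),
              100 * x$n_rejected / nrow(x$metrics)))
  bad <- x$metrics[!x$metrics$retained, c("channel", "reasons")]
  if (nrow(bad)) print(bad, row.names = FALSE)
  invisible(x)
}

#' Summarize channel rejection across recordings
#'
#' Aggregates rejection counts over a set of [reject_channels()] results
#' the way multi-session studies report coupling losses: mean and sd of
#' rejected channels per recording and the corresponding percentage of the
#' channel count.
#'
#' @param qualities List of `channel_quality` objects.
#' @param n_channels Channels per recording.
#' @return List with `mean_rejected`, `sd_rejected`, `percent_rejected`
#'   (rounded to the nearest percent) and `percent_sd`.
#' @examples
#' rejection_summary(list(), n_channels = 22, counts = c(7, 8))
#' @export
rejection_summary <- function(qualities, n_channels,
                              counts = vapply(qualities, `[[`, numeric(1),
                                              "n_rejected")) {
  m <- mean(counts); s <- stats::sd(counts)
  list(mean_rejected = m, sd_rejected = s,
       percent_rejected = round(100 * m / n_channels),
       percent_sd = round(100 * s / n_channels))
}

#' Classify one channel's response as activated or suppressive
#'
#' A channel is activated when its mean deflection from the rest reference
#' over the task window is positive, and suppressive otherwise (a response
#' at or below the reference is a non-positive deflection, so ties resolve
#' to suppressive). Missing frames are ignored; channels missing more than
#' half their task-window frames are unclassifiable.
#'
#' @param values Numeric vector, one channel's series on the protocol grid.
#' @param protocol A [task_protocol()].
#' @param reference Rest reference level: 1 for ratio series, 0 for
#'   concentration-change series.
#' @return `"activated"`, `"suppressive"`, or `NA_character_` when more than
#'   50% of task frames are missing.
#' @export
classify_channel_response <- function(values, protocol, reference = 1) {
  tv <- values[protocol$task_frames]
  if (mean(!is.finite(tv)) > 0.5) return(NA_character_)
  if (mean(tv[is.finite(tv)] - reference) > 0) "activated" else "suppressive"
}

#' Separate a recording into its three response curves
#'
#' Builds the activated-mean, suppressive-mean and channel-averaging
#' response curves from the retained channels of one recording. Retained
#' channels are partitioned by [classify_channel_response()]; class means
#' and the overall average ignore missing frames pointwise
#' (pairwise-available averaging, no interpolation). An empty class yields
#' a constant reference curve and an `empty_class` flag so downstream
#' features can be marked missing.
#'
#' @param series An `hbo_series` or channel x frame matrix.
#' @param quality A [reject_channels()] result (optional; all channels
#'   retained if omitted).
#' @param protocol A [task_protocol()].
#' @param reference Rest reference level (1 for ratios, 0 for changes).
#' @return An object of class `response_triplet`: curves `activated_mean`,
#'   `suppressive_mean`, `channel_avg`; `channel_class` per retained
#'   channel; class `counts`; `empty_class` flags; the `reference`.
#' @export
build_response_triplet <- function(series, quality = NULL, protocol,
                                   reference = 1) {
  m <- if (inherits(series, "hbo_series")) series$values else as.matrix(series)
  retained <- if (is.null(quality)) rep(TRUE, nrow(m)) else quality$retained
  if (inherits(series, "hbo_series") && length(series$unusable))
    retained <- retained & !(series$channels %in% series$unusable)
  if (!any(retained)) stop("no retained channels; sample is invalid")
  mr <- m[retained, , drop = FALSE]
  cls <- vapply(seq_len(nrow(mr)), function(i)
    classify_channel_response(mr[i, ], protocol, reference), character(1))
  usable <- !is.na(cls)
  mr <- mr[usable, , drop = FALSE]; cls <- cls[usable]
  if (!length(cls)) stop("no classifiable channels; sample is invalid")
  class_mean <- function(sel) {
    if (!any(sel)) return(rep(reference, ncol(mr)))
    colMeans(mr[sel, , drop = FALSE], na.rm = TRUE)
  }
  act <- class_mean(cls == "activated")
  sup <- class_mean(cls == "suppressive")
  avg <- colMeans(mr, na.rm = TRUE)
  structure(list(
    activated_mean = act, suppressive_mean = sup, channel_avg = avg,
    channel_class = cls,
    counts = c(activated = sum(cls == "activated"),
               suppressive = sum(cls == "suppressive")),
    empty_class = c(activated = !any(cls == "activated"),
                    suppressive = !any(cls == "suppressive")),
    reference = reference, frame_times_s = protocol$frame_times_s),
    class = "response_triplet")
}

#' @export
print.response_triplet <- function(x, ...) {
  cat(sprintf("Response triplet: %d activated, %d suppressive channels\n",
              x$counts["activated"], x$counts["suppressive"]))
  invisible(x)
}

#' Export response triplets as tidy long-format data
#'
#' @param triplets Named list of `response_triplet` objects (names used as
#'   the family label).
#' @param sample_id Sample identifier recorded in each row.
#' @return data.frame with columns sample_id, family, class, frame_time,
#'   value.
#' @export
triplet_long <- function(triplets, sample_id = "sample") {
  rows <- lapply(names(triplets), function(fam) {
    tr <- triplets[[fam]]
    data.frame(sample_id = sample_id, family = fam,
               class = rep(c("activated", "suppressive", "channel_avg"),
                           each = length(tr$frame_times_s)),
               frame_time = rep(tr$frame_times_s, 3),
               value = c(tr$activated_mean, tr$suppressive_mean,
                         tr$channel_avg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
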