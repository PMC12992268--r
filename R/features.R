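# Integral and centroid features of the separated responses, canonical
# F1..F12 feature table construction, t-test feature selection, and
# test-retest session comparison.

#' Integral feature of a response curve
#'
#' Signed trapezoidal area of the deflection from the rest reference over
#' the task window only: a proxy for the intensity of the hemodynamic
#' response. Suppressive responses yield negative integrals; missing frames
#' are dropped before integration.
#'
#' @param curve Numeric vector on the protocol grid (or a
#'   `response_triplet` curve).
#' @param protocol A [task_protocol()].
#' @param reference Rest reference level (1 for ratio series, 0 for
#'   concentration changes).
#' @return Signed area (curve units x s), or `NA` if fewer than 2 finite
#'   task-window frames.
#' @examples
#' p <- task_protocol()
#' box <- rep(1, p$n_frames); box[p$task_frames] <- 1.5
#' integral_feature(box, p)  # 0.5 * 60 within one trapezoid edge
#' @export
integral_feature <- function(curve, protocol, reference = 1) {
  idx <- protocol$task_frames
  t <- protocol$frame_times_s[idx]
  y <- curve[idx] - reference
  ok <- is.finite(y)
  if (sum(ok) < 2) return(NA_real_)
  t <- t[ok]; y <- y[ok]
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

#' Centroid feature of a response curve
#'
#' Magnitude-weighted mean time of the deflection over the task window,
#' reported relative to task onset: a proxy for response timing. Weights
#' are the absolute deviation from the reference so that suppressive
#' responses carry a meaningful timing.
#'
#' @inheritParams integral_feature
#' @return Centroid time in seconds since task onset, within
#'   `[0, task_s]`; `NA` when the total weight is zero or the curve is
#'   all-missing.
#' @export
centroid_feature <- function(curve, protocol, reference = 1) {
  idx <- protocol$task_frames
  t <- protocol$frame_times_s[idx] - protocol$task_window[1]
  w <- abs(curve[idx] - reference)
  ok <- is.finite(w)
  if (sum(ok) < 2 || sum(w[ok]) <= 0) return(NA_real_)
  sum(t[ok] * w[ok]) / sum(w[ok])
}

# canonical feature naming -------------------------------------------------

.RESPONSES <- c("activated", "suppressive", "channel_avg")
.VARIABLES <- c("integral", "centroid")

#' Canonical feature index
#'
#' The canonical F1..F12 index over the two task-rest ratio families:
#' within each family (RHbO1 then RHbO2) features run activated, then
#' suppressive, then channel-averaging response, integral before centroid
#' (F3 = integral of suppressive RHbO1, F7 = integral of activated RHbO2,
#' F12 = centroid of channel-averaging RHbO2). Concentration-change
#' families use the same ordering under names D1..D18.
#'
#' @return data.frame mapping feature name to family, response and
#'   variable.
#' @examples
#' subset(feature_index(), name %in% c("F3", "F7", "F12"))
#' @export
feature_index <- function() {
  fams <- c("RHbO1", "RHbO2", "dHbO1", "dHbO2", "dHbO3")
  out <- list()
  for (fi in seq_along(fams)) {
    prefix <- if (startsWith(fams[fi], "RHbO")) "F" else "D"
    base <- if (prefix == "F") (fi - 1) * 6 else (fi - 3) * 6
    k <- 0
    for (resp in .RESPONSES) for (var in .VARIABLES) {
      k <- k + 1
      out[[length(out) + 1]] <- data.frame(
        name = paste0(prefix, base + k), family = fams[fi],
        response = resp, variable = var, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Extract the feature vector of one sample
#'
#' Runs channel rejection, response separation and integral/centroid
#' extraction on each parameter family of a sample and returns the named
#' feature vector. Features of empty response classes are `NA`.
#'
#' @param families Named list of channel x frame matrices (or `hbo_series`)
#'   per parameter family (`RHbO1`, `RHbO2`, `dHbO1..3`).
#' @param protocol A [task_protocol()].
#' @param quality Optional precomputed [reject_channels()] result applied
#'   to every family; by default quality is assessed per family.
#' @param ... Threshold overrides passed to [reject_channels()].
#' @return Named numeric vector over the [feature_index()] names present in
#'   `families`, plus attribute `n_rejected` (per family).
#' @export
sample_features <- function(families, protocol, quality = NULL, ...) {
  fidx <- feature_index()
  out <- c(); nrej <- c()
  for (fam in names(families)) {
    x <- families[[fam]]
    ref <- if (startsWith(fam, "RHbO")) 1 else 0
    q <- if (is.null(quality)) reject_channels(x, protocol, ...) else quality
    nrej[fam] <- q$n_rejected
    rows <- fidx[fidx$family == fam, ]
    if (q$all_rejected) {
      v <- rep(NA_real_, nrow(rows)); names(v) <- rows$name
      out <- c(out, v); next
    }
    tr <- build_response_triplet(x, q, protocol, reference = ref)
    curves <- list(activated = tr$activated_mean,
                   suppressive = tr$suppressive_mean,
                   channel_avg = tr$channel_avg)
    for (i in seq_len(nrow(rows))) {
      resp <- rows$response[i]
      empty <- resp != "channel_avg" && tr$empty_class[[resp]]
      val <- if (empty) NA_real_ else if (rows$variable[i] == "integral")
        integral_feature(curves[[resp]], protocol, ref)
      else centroid_feature(curves[[resp]], protocol, ref)
      out[rows$name[i]] <- val
    }
  }
  attr(out, "n_rejected") <- nrej
  out
}

#' Build the cohort feature table
#'
#' Applies the full per-sample pipeline (rejection, response separation,
#' feature extraction) to every sample of a cohort and assembles the
#' samples x features table with ids and group labels. TPSF-mode samples
#' are first gated and inverted to the five hemodynamic families through
#' the physics layer.
#'
#' @param cohort A [generate_cohort()] result, or a list of samples each
#'   with `families` matrices.
#' @param ... Threshold overrides passed to [reject_channels()].
#' @return data.frame: sample_id, subject_id, group, session,
#'   n_rejected (mean over families), then one column per feature.
#' @export
build_feature_table <- function(cohort, ...) {
  samples <- if (inherits(cohort, "tdnirs_cohort")) cohort$samples else cohort
  spec <- if (inherits(cohort, "tdnirs_cohort")) cohort$spec else NULL
  rows <- lapply(samples, function(s) {
    fams <- s$families
    protocol <- if (!is.null(spec)) spec$protocol else s$protocol
    if (is.null(fams)) {
      gated <- gate_tpsf(s$tpsf, spec$gates)
      quality <- reject_channels(gated, spec$protocol, ...)
      fams <- hbo_families(gated, spec$protocol, spec$props, spec$ext)
    } else {
      # one quality decision per recording, taken on a ratio-scale family
      # (baseline level 1): concentration-change series are zero-mean at
      # baseline, where a coefficient of variation is meaningless
      ratio_fam <- grep("^RHbO", names(fams), value = TRUE)
      qsrc <- if (length(ratio_fam)) fams[[ratio_fam[1]]] else fams[[1]]
      quality <- reject_channels(qsrc, protocol, ...)
    }
    fv <- sample_features(fams, protocol, quality = quality, ...)
    cbind(data.frame(sample_id = s$sample_id, subject_id = s$subject_id,
                     group = s$group, session = s$session,
                     n_rejected = mean(attr(fv, "n_rejected")),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Two-sample t-test feature selection
#'
#' Compares every feature column between the two groups with a two-tailed
#' two-sample t-test (Welch by default) and selects features significant at
#' `alpha`. No multiplicity correction is applied by default, matching the
#' raw per-feature reporting convention of small fNIRS studies;
#' Benjamini-Hochberg adjustment is available behind `adjust`.
#'
#' @param table A [build_feature_table()] result.
#' @param features Feature column names (default: all canonical names
#'   present).
#' @param group_col,alpha Group label column and significance level.
#' @param var_equal Use the pooled-variance (Student) test instead of
#'   Welch.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `selection_report`: data.frame with per
#'   feature the group means, t statistic, degrees of freedom, two-tailed
#'   p, and the `selected` flag.
#' @export
select_features <- function(table, features = NULL, group_col = "group",
                            alpha = 0.05, var_equal = FALSE,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(features))
    features <- intersect(feature_index()$name, names(table))
  g <- factor(table[[group_col]])
  stopifnot(nlevels(g) == 2)
  lv <- levels(g)
  rows <- lapply(features, function(f) {
    x <- table[[f]][g == lv[1]]; y <- table[[f]][g == lv[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(feature = f, mean_1 = NA, mean_2 = NA, t = NA,
                        df = NA, p = NA, degenerate = TRUE))
    degen <- stats::sd(x) == 0 && stats::sd(y) == 0
    if (degen) {
      p <- if (mean(x) == mean(y)) 1 else 0
      tt <- list(statistic = if (p == 1) 0 else Inf, parameter = NA_real_,
                 p.value = p)
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
    }
    data.frame(feature = f, mean_1 = mean(x), mean_2 = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  names(rep)[2:3] <- paste0("mean_", lv)
  if (adjust == "BH") rep$p_adj <- stats::p.adjust(rep$p, "BH")
  crit <- if (adjust == "BH") rep$p_adj else rep$p
  rep$selected <- !is.na(crit) & crit <= alpha
  structure(rep, class = c("selection_report", "data.frame"),
            alpha = alpha, groups = lv)
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Feature selection (alpha = %g): %d of %d selected\n",
              attr(x, "alpha"), sum(x$selected), nrow(x)))
  print.data.frame(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}

#' Test-retest session comparison
#'
#' Paired two-tailed t-test of each feature between session 1 and session 2
#' across subjects, the standard check that repeated task sessions yield
#' statistically indistinguishable features. Subjects lacking either
#' session are excluded. When every within-subject difference is exactly
#' zero the feature is maximally stable and p is reported as 1.
#'
#' @param table A [build_feature_table()] result with a `session` column.
#' @param features Feature column names (default: all canonical names).
#' @return data.frame per feature: n pairs, mean session difference, t, p.
#' @export
test_retest_compare <- function(table, features = NULL) {
  if (is.null(features))
    features <- intersect(feature_index()$name, names(table))
  s1 <- table[table$session == 1, ]
  s2 <- table[table$session == 2, ]
  common <- intersect(s1$subject_id, s2$subject_id)
  s1 <- s1[match(common, s1$subject_id), ]
  s2 <- s2[match(common, s2$subject_id), ]
  rows <- lapply(features, function(f) {
    d <- s2[[f]] - s1[[f]]
    d <- d[is.finite(d)]
    if (length(d) < 2)
      return(data.frame(feature = f, n = length(d), mean_diff = NA,
                        t = NA, p = NA))
    if (all(d == 0) || stats::sd(d) == 0) {
      p <- if (mean(d) == 0) 1 else 0
      return(data.frame(feature = f, n = length(d), mean_diff = mean(d),
                        t = 0, p = p))
    }
    tt <- stats::t.test(d)
    data.frame(feature = f, n = length(d), mean_diff = mean(d),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
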