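# Synthetic verbal-fluency-task cohort generator. Emulates the statistical
# structure the downstream analysis assumes -- block-design activated and
# suppressive channel responses, group effect directions (depressed group:
# stronger suppression in the shallow-delay ratio, stronger and earlier
# activation in the deep-delay ratio), Poisson photon noise at TPSF level,
# and corrupted channels -- so every pipeline stage is testable without any
# subject recording.

#' Block-design task protocol
#'
#' Rest-task-rest timing of one recording and the acquisition frame rate.
#' Defaults follow a typical verbal-fluency block design: 30 s pre-task
#' rest, 60 s task, 70 s post-task rest at 1 Hz.
#'
#' @param rest_pre_s,task_s,rest_post_s Block durations (s), all > 0.
#' @param fs_hz Frame rate (Hz), > 0.
#' @return An object of class `task_protocol` with derived fields
#'   `frame_times_s`, `n_frames`, `task_window` (`[onset, offset)` in s)
#'   and `task_frames` (indices).
#' @examples
#' task_protocol()
#' @export
task_protocol <- function(rest_pre_s = 30, task_s = 60, rest_post_s = 70,
                          fs_hz = 1) {
  if (any(c(rest_pre_s, task_s, rest_post_s, fs_hz) <= 0))
    stop("durations and frame rate must be > 0")
  total <- rest_pre_s + task_s + rest_post_s
  n <- floor(total * fs_hz)
  ft <- (seq_len(n) - 1) / fs_hz
  tw <- c(rest_pre_s, rest_pre_s + task_s)
  structure(list(rest_pre_s = rest_pre_s, task_s = task_s,
                 rest_post_s = rest_post_s, fs_hz = fs_hz,
                 frame_times_s = ft, n_frames = n, task_window = tw,
                 task_frames = which(ft >= tw[1] & ft < tw[2])),
            class = "task_protocol")
}

#' @export
print.task_protocol <- function(x, ...) {
  cat(sprintf("Task protocol: %gs rest | %gs task | %gs rest @ %g Hz (%d frames)\n",
              x$rest_pre_s, x$task_s, x$rest_post_s, x$fs_hz, x$n_frames))
  invisible(x)
}

#' Canonical hemodynamic response curve on the ratio scale
#'
#' Deterministic unit response used by the cohort generator: exactly 1
#' (baseline) until task onset plus latency, then a gamma-difference
#' deflection peaking `peak_s` seconds after response onset and relaxing
#' toward baseline after the task, with a small late undershoot. Activated
#' curves deflect above 1, suppressive curves mirror below 1; the extreme
#' deflection equals `amplitude` exactly.
#'
#' @param class `"activated"` or `"suppressive"`.
#' @param amplitude Peak deflection from baseline (ratio units, >= 0).
#' @param latency_s Response onset after task onset (s); must be smaller
#'   than the task duration.
#' @param peak_s Time from response onset to peak (s), > 0.
#' @param protocol A [task_protocol()].
#' @param undershoot Relative amplitude of the post-peak undershoot lobe.
#' @param shape Gamma shape parameter controlling rise steepness.
#' @return Numeric vector of length `protocol$n_frames` (ratio scale).
#' @examples
#' p <- task_protocol()
#' a <- hrf_curve("activated", 0.05, latency_s = 5, peak_s = 20, protocol = p)
#' max(a) - 1  # == 0.05
#' @export
hrf_curve <- function(class = c("activated", "suppressive"), amplitude,
                      latency_s, peak_s, protocol,
                      undershoot = 0.08, shape = 3) {
  class <- match.arg(class)
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  if (latency_s >= protocol$task_s)
    stop("'latency_s' must be smaller than the task duration")
  if (peak_s <= 0) stop("'peak_s' must be > 0")
  s <- protocol$frame_times_s - (protocol$task_window[1] + latency_s)
  gshape <- function(s, p) {
    g <- rep(0, length(s))
    pos <- s > 0
    g[pos] <- (s[pos] / p)^shape * exp(shape * (1 - s[pos] / p))
    g
  }
  g <- gshape(s, peak_s) - undershoot * gshape(s, 2.2 * peak_s)
  if (amplitude > 0 && max(g) > 0) g <- g / max(g)
  dir <- if (class == "activated") 1 else -1
  1 + dir * amplitude * g
}

#' Group effect specification for the cohort generator
#'
#' Population-level response parameters per group (healthy controls `HC`
#' and the depressed group `MDD`) and response class, plus between-subject
#' variability. The defaults encode the effect directions the analysis is
#' designed to detect: the depressed group has a more pronounced
#' suppressive response, and a stronger, earlier activated response, with
#' timing shifts that also pull the channel-averaging centroid earlier. A
#' zero session effect encodes test-retest stability.
#'
#' Per-family amplitude scalings express depth sensitivity: suppressive
#' (largely extracerebral) components load on early delays, activated
#' cortical components on late delays.
#'
#' @param act_amp,sup_amp Named length-2 vectors (`HC`, `MDD`): population
#'   peak deflection of activated / suppressive responses (ratio units).
#' @param act_latency_s,sup_latency_s Response onset after task onset (s).
#' @param act_peak_s,sup_peak_s Onset-to-peak time (s).
#' @param sup_frac Fraction of channels following the suppressive class.
#' @param amp_sdlog Between-subject lognormal sd on amplitudes.
#' @param latency_sd_s,peak_sd_s Between-subject normal sd on timings (s).
#' @param session_effect Additive session-2 amplitude shift (ratio units);
#'   0 encodes test-retest stability.
#' @param family_scales Named list of `c(act, sup)` amplitude multipliers
#'   per parameter family.
#' @return An object of class `group_effect_spec`.
#' @export
group_effect_spec <- function(act_amp = c(HC = 0.040, MDD = 0.053),
                              sup_amp = c(HC = 0.020, MDD = 0.027),
                              act_latency_s = c(HC = 9, MDD = 6.5),
                              sup_latency_s = c(HC = 9, MDD = 9),
                              act_peak_s = c(HC = 27, MDD = 23),
                              sup_peak_s = c(HC = 25, MDD = 25),
                              sup_frac = c(HC = 0.4, MDD = 0.4),
                              amp_sdlog = 0.40,
                              latency_sd_s = 3.5,
                              peak_sd_s = 5,
                              session_effect = 0,
                              family_scales = list(
                                RHbO1 = c(act = 0.6, sup = 1.0),
                                RHbO2 = c(act = 1.0, sup = 0.6),
                                dHbO1 = c(act = 0.5, sup = 1.0),
                                dHbO2 = c(act = 0.75, sup = 0.8),
                                dHbO3 = c(act = 1.0, sup = 0.6))) {
  stopifnot(all(act_amp >= 0), all(sup_amp >= 0),
            all(sup_frac >= 0 & sup_frac <= 1))
  structure(list(act_amp = act_amp, sup_amp = sup_amp,
                 act_latency_s = act_latency_s,
                 sup_latency_s = sup_latency_s,
                 act_peak_s = act_peak_s, sup_peak_s = sup_peak_s,
                 sup_frac = sup_frac, amp_sdlog = amp_sdlog,
                 latency_sd_s = latency_sd_s, peak_sd_s = peak_sd_s,
                 session_effect = session_effect,
                 family_scales = family_scales),
            class = "group_effect_spec")
}

#' Cohort design specification
#'
#' Study-level design of a synthetic cohort. Defaults mirror the target
#' study design: 27 subjects per group, two sessions each (108 samples),
#' 22 channels, and a 34% channel corruption probability.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param sessions_per_subject Sessions per subject.
#' @param n_channels Channels per recording.
#' @param corruption_probability Per-channel probability of a corruption
#'   artifact, in `[0, 1)`.
#' @param photon_budget Expected photon counts per frame and channel (TPSF
#'   mode).
#' @param seed Integer seed; all randomness derives from it via a
#'   counter-based per-subject scheme, so enlarging the cohort never
#'   reshuffles existing subjects.
#' @param effects A [group_effect_spec()].
#' @param protocol A [task_protocol()].
#' @param mode `"HBO_DIRECT"` (generate hemodynamic series directly) or
#'   `"TPSF"` (generate photon histograms through the diffusion forward
#'   model).
#' @param noise_sd Additive frame noise on the ratio scale (HBO_DIRECT).
#' @param channel_amp_sdlog Channel-to-channel lognormal amplitude spread.
#' @param hbo_rest_uM,hbr_rest_uM Rest-state concentrations driving the
#'   TPSF-mode absorption (uM).
#' @param props,ext,gates Optical properties, extinction table and gate set
#'   for TPSF mode.
#' @param families Families to generate in HBO_DIRECT mode.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 27, sessions_per_subject = 2,
                        n_channels = 22, corruption_probability = 0.34,
                        photon_budget = 1e6, seed = 1,
                        effects = group_effect_spec(),
                        protocol = task_protocol(),
                        mode = c("HBO_DIRECT", "TPSF"),
                        noise_sd = 0.012, channel_amp_sdlog = 0.25,
                        hbo_rest_uM = 50, hbr_rest_uM = 20,
                        props = optical_properties(),
                        ext = extinction_table(),
                        gates = gate_set(),
                        families = c("RHbO1", "RHbO2", "dHbO1", "dHbO2",
                                     "dHbO3")) {
  mode <- match.arg(mode)
  if (n_per_group < 2) stop("'n_per_group' must be >= 2")
  if (corruption_probability < 0 || corruption_probability >= 1)
    stop("'corruption_probability' must be in [0, 1)")
  if (photon_budget <= 0) stop("'photon_budget' must be > 0")
  structure(list(n_per_group = as.integer(n_per_group),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 n_channels = as.integer(n_channels),
                 corruption_probability = corruption_probability,
                 photon_budget = photon_budget, seed = as.integer(seed),
                 effects = effects, protocol = protocol, mode = mode,
                 noise_sd = noise_sd,
                 channel_amp_sdlog = channel_amp_sdlog,
                 hbo_rest_uM = hbo_rest_uM, hbr_rest_uM = hbr_rest_uM,
                 props = props, ext = ext, gates = gates,
                 families = families),
            class = "cohort_spec")
}

# counter-based seed derivation: independent substreams per (subject,
# session, purpose) so cohorts are extensible without reshuffling
.sub_seed <- function(seed, subject, session = 0L, purpose = 0L) {
  (as.numeric(seed) * 2654435761 + subject * 97561 + session * 7919 +
     purpose * 131) %% 2147483629
}

# draw one subject's latent response parameters (shared across sessions)
.draw_subject <- function(spec, subject_idx, group) {
  set.seed(.sub_seed(spec$seed, subject_idx))
  eff <- spec$effects
  nch <- spec$n_channels
  list(
    act_amp = stats::rlnorm(1, log(eff$act_amp[[group]]), eff$amp_sdlog),
    sup_amp = stats::rlnorm(1, log(eff$sup_amp[[group]]), eff$amp_sdlog),
    act_latency = max(0, stats::rnorm(1, eff$act_latency_s[[group]],
                                      eff$latency_sd_s)),
    sup_latency = max(0, stats::rnorm(1, eff$sup_latency_s[[group]],
                                      eff$latency_sd_s)),
    act_peak = max(5, stats::rnorm(1, eff$act_peak_s[[group]],
                                   eff$peak_sd_s)),
    sup_peak = max(5, stats::rnorm(1, eff$sup_peak_s[[group]],
                                   eff$peak_sd_s)),
    channel_class = ifelse(
      stats::runif(nch) < eff$sup_frac[[group]], "suppressive", "activated"),
    channel_gain = stats::rlnorm(nch, 0, spec$channel_amp_sdlog),
    corrupted = stats::runif(nch) < spec$corruption_probability,
    archetype = sample(c("dead", "drift", "burst"), nch, replace = TRUE)
  )
}

# clean per-channel latent ratio trajectories for one sample (no noise)
.channel_ratio_curves <- function(spec, subj, session, act_scale = 1,
                                  sup_scale = 1) {
  p <- spec$protocol
  shift <- spec$effects$session_effect * (session - 1)
  act <- hrf_curve("activated", max(0, subj$act_amp * act_scale + shift),
                   min(subj$act_latency, p$task_s - 1), subj$act_peak, p)
  sup <- hrf_curve("suppressive", max(0, subj$sup_amp * sup_scale + shift),
                   min(subj$sup_latency, p$task_s - 1), subj$sup_peak, p)
  base <- rbind(activated = act, suppressive = sup)
  m <- base[subj$channel_class, , drop = FALSE]
  1 + (m - 1) * subj$channel_gain   # channel-specific response gain
}

# corruption artifacts applied on the ratio scale (HBO_DIRECT mode)
.corrupt_ratio <- function(vals, subj, spec) {
  nf <- ncol(vals)
  tt <- seq_len(nf) / nf
  for (ch in which(subj$corrupted)) {
    vals[ch, ] <- switch(
      subj$archetype[ch],
      dead = 1 + stats::rnorm(nf, 0, 0.5),
      drift = vals[ch, ] + 0.45 * (tt - 0.5) * sample(c(-1, 1), 1),
      burst = {
        v <- vals[ch, ]
        hit <- stats::runif(nf) < 0.10
        v[hit] <- v[hit] + sample(c(-1, 1), sum(hit), TRUE) *
          stats::runif(sum(hit), 0.3, 0.8)
        v
      })
  }
  vals
}

#' Generate a synthetic TD-fNIRS cohort
#'
#' Produces a reproducible cohort of verbal-fluency-task recordings with
#' known ground truth. In `HBO_DIRECT` mode each sample carries the five
#' hemodynamic parameter families directly (task-rest ratios on the ratio
#' scale, concentration changes in uM), with per-family depth scalings,
#' channel noise and corruption artifacts. In `TPSF` mode each sample
#' carries photon time-of-flight histograms: the programmed HbO trajectory
#' drives the absorption coefficient through the extinction table, expected
#' bin counts follow the semi-infinite diffusion reflectance scaled to the
#' photon budget, and observed counts are Poisson draws; corrupted channels
#' receive count-level artifacts (collapsed gain, drifting gain, count
#' bursts).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `tdnirs_cohort`: list with `samples` (each a
#'   list with ids plus `families` matrices or `tpsf` records), `manifest`
#'   (sample_id, subject_id, group, session), `truth` (per sample-channel
#'   ground truth: class, corruption, archetype, subject parameters), and
#'   the `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_per_group = 2, seed = 7))
#' coh$manifest
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(c("HC", "MDD"), each = spec$n_per_group)
  n_subj <- length(groups)
  samples <- list(); manifest <- list(); truth <- list()
  k <- 0L
  for (si in seq_len(n_subj)) {
    subj <- .draw_subject(spec, si, groups[si])
    for (se in seq_len(spec$sessions_per_subject)) {
      k <- k + 1L
      sid <- sprintf("S%03d_%d", si, se)
      set.seed(.sub_seed(spec$seed, si, se, purpose = 1L))
      sample <- list(sample_id = sid, subject_id = sprintf("S%03d", si),
                     group = groups[si], session = se)
      if (spec$mode == "HBO_DIRECT") {
        fams <- list()
        for (fam in spec$families) {
          sc <- spec$effects$family_scales[[fam]]
          vals <- .channel_ratio_curves(spec, subj, se,
                                        act_scale = sc[["act"]],
                                        sup_scale = sc[["sup"]])
          vals <- vals +
            matrix(stats::rnorm(length(vals), 0, spec$noise_sd),
                   nrow = nrow(vals))
          vals <- .corrupt_ratio(vals, subj, spec)
          if (startsWith(fam, "dHbO"))
            vals <- spec$hbo_rest_uM * (vals - 1)
          rownames(vals) <- seq_len(spec$n_channels)
          fams[[fam]] <- vals
        }
        sample$families <- fams
      } else {
        sample$tpsf <- .sample_tpsf(spec, subj, se)
      }
      samples[[k]] <- sample
      manifest[[k]] <- data.frame(sample_id = sid,
                                  subject_id = sample$subject_id,
                                  group = groups[si], session = se,
                                  stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        sample_id = sid, channel = seq_len(spec$n_channels),
        group = groups[si], session = se, class = subj$channel_class,
        corrupted = subj$corrupted, archetype = ifelse(
          subj$corrupted, subj$archetype, "none"),
        act_amp = subj$act_amp, sup_amp = subj$sup_amp,
        act_latency = subj$act_latency, act_peak = subj$act_peak,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(samples = samples, manifest = do.call(rbind, manifest),
                 truth = do.call(rbind, truth), spec = spec),
            class = "tdnirs_cohort")
}

# TPSF-mode sample: photon histograms through the diffusion forward model
.sample_tpsf <- function(spec, subj, session,
                         bin_edges_ps = seq(0, 4000, by = 25)) {
  p <- spec$protocol
  nf <- p$n_frames
  centers <- (bin_edges_ps[-1] + bin_edges_ps[-length(bin_edges_ps)]) / 2
  ratio <- .channel_ratio_curves(spec, subj, session)   # uniform depth
  hbr <- spec$hbr_rest_uM
  em <- spec$ext$matrix
  v <- .C_MM_PS / spec$props$n_tissue
  # mua-free reflectance shape over bins, shared across frames/channels
  m_free <- semi_infinite_reflectance(pmax(centers, 1), spec$props,
                                      mua_free = TRUE)
  records <- vector("list", spec$n_channels * 2L)
  r <- 0L
  for (ch in seq_len(spec$n_channels)) {
    hbo_t <- spec$hbo_rest_uM * ratio[ch, ]             # uM over frames
    for (wi in 1:2) {
      wl <- spec$ext$wavelengths_nm[wi]
      mua_t <- em[wi, "HbO"] * hbo_t + em[wi, "HbR"] * hbr
      # expected counts (frames x bins): bin shape modulated per-frame by
      # the absorption trajectory
      lam <- exp(-outer(mua_t, centers * v)) *
        matrix(m_free, nf, length(centers), byrow = TRUE)
      # normalize so total expected counts at rest mua equal the budget
      mua0 <- em[wi, "HbO"] * spec$hbo_rest_uM + em[wi, "HbR"] * hbr
      norm0 <- sum(m_free * exp(-v * centers * mua0))
      lam <- lam * (spec$photon_budget / norm0)
      gain <- rep(1, nf)
      if (subj$corrupted[ch]) {
        gain <- switch(subj$archetype[ch],
                       dead = rep(1e-4, nf),
                       drift = seq(1, 0.25, length.out = nf),
                       burst = {
                         g <- rep(1, nf)
                         hit <- stats::runif(nf) < 0.10
                         g[hit] <- stats::runif(sum(hit), 5, 20)
                         g
                       })
      }
      counts <- matrix(stats::rpois(length(lam), lam * gain), nrow = nf)
      records[[r <- r + 1L]] <- tpsf_record(ch, wl, bin_edges_ps, counts,
                                            p$frame_times_s)
    }
  }
  # feasibility: expected counts in the latest gate at rest absorption
  g3 <- spec$gates
  in_g3 <- centers >= g3$starts_ps[3] & centers < g3$ends_ps[3]
  mua0 <- em[1, "HbO"] * spec$hbo_rest_uM + em[1, "HbR"] * hbr
  lam3 <- sum(m_free[in_g3] * exp(-v * centers[in_g3] * mua0)) *
    spec$photon_budget / sum(m_free * exp(-v * centers * mua0))
  if (lam3 < 1)
    warning(sprintf(
      "photon budget %g gives expected gate-3 counts %.3g (< 1) per frame",
      spec$photon_budget, lam3))
  records
}

#' @export
print.tdnirs_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TD-fNIRS cohort: %d samples (%s mode), %d channels\n",
              length(x$samples), x$spec$mode, x$spec$n_channels))
  print(table(x$manifest$group, x$manifest$session,
              dnn = c("group", "session")))
  invisible(x)
}
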