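# Channel rejection and activated/suppressive response separation.

test_that("clean fixtures pass rejection and targeted defects are caught with the right reasons", {
  proto <- task_protocol()
  set.seed(3)
  nch <- 6
  m <- 1 + matrix(rnorm(nch * proto$n_frames, 0, 0.01), nch)
  m[2, ] <- hrf_curve("activated", 0.06, 5, 20, proto) +
    rnorm(proto$n_frames, 0, 0.01)
  q <- reject_channels(m, proto)
  expect_identical(q$n_rejected, 0L)
  # huge baseline variance -> baseline instability
  m_cv <- m; m_cv[3, ] <- 1 + rnorm(proto$n_frames, 0, 0.5)
  expect_match(reject_channels(m_cv, proto)$metrics$reasons[3],
               "baseline instability")
  # slow drift -> baseline instability
  m_dr <- m; m_dr[4, ] <- m_dr[4, ] + seq(0, 0.4, length.out = proto$n_frames)
  expect_match(reject_channels(m_dr, proto)$metrics$reasons[4],
               "baseline instability")
  # spikes -> saturation/burst
  m_b <- m; idx <- seq(5, 155, by = 10)
  m_b[5, idx] <- m_b[5, idx] + 0.6
  qb <- reject_channels(m_b, proto)
  expect_match(qb$metrics$reasons[5], "saturation/burst")
  expect_identical(which(!qb$metrics$retained), 5L)
  # dead channel in a counts-based series -> low counts
  spec <- cohort_spec(n_per_group = 2, sessions_per_subject = 1,
                      n_channels = 3, corruption_probability = 0,
                      mode = "TPSF", seed = 8)
  coh <- generate_cohort(spec)
  g <- gate_tpsf(coh$samples[[1]]$tpsf, spec$gates)
  g$values[2, , , ] <- 0
  qg <- reject_channels(g, spec$protocol)
  expect_match(qg$metrics$reasons[2], "low counts")
  expect_true(all(qg$metrics$retained[-2]))
})

test_that("rejection rate matches the programmed corruption rate across cohorts", {
  hits <- c(); programmed <- c()
  for (r in 1:50) {
    spec <- cohort_spec(n_per_group = 2, sessions_per_subject = 1,
                        corruption_probability = 0.34, seed = 300 + r,
                        families = "RHbO1")
    coh <- generate_cohort(spec)
    for (s in coh$samples) {
      q <- reject_channels(s$families$RHbO1, spec$protocol)
      hits <- c(hits, q$n_rejected)
      truth <- coh$truth[coh$truth$sample_id == s$sample_id, ]
      programmed <- c(programmed, sum(truth$corrupted))
    }
  }
  n <- length(hits) * 22
  phat <- sum(hits) / n
  ci <- 0.34 + c(-1, 1) * 3 * sqrt(0.34 * 0.66 / n)
  expect_gt(phat, ci[1] - 0.02)
  expect_lt(phat, ci[2] + 0.02)
  # rejection tracks the per-sample programmed corruption closely
  expect_gt(cor(hits, programmed), 0.9)
  # zero corruption -> zero rejections at default thresholds
  spec0 <- cohort_spec(n_per_group = 2, sessions_per_subject = 1,
                       corruption_probability = 0, seed = 12,
                       families = "RHbO1")
  coh0 <- generate_cohort(spec0)
  rej0 <- vapply(coh0$samples, function(s)
    reject_channels(s$families$RHbO1, spec0$protocol)$n_rejected,
    integer(1))
  expect_identical(sum(rej0), 0L)
})

test_that("channel response classification follows the task-window mean sign with suppressive ties", {
  proto <- task_protocol()
  # constant series at the reference -> suppressive by the tie rule
  expect_identical(classify_channel_response(rep(1, proto$n_frames), proto, 1),
                   "suppressive")
  # programmed curves classify as programmed
  expect_identical(classify_channel_response(
    hrf_curve("activated", 0.05, 5, 20, proto), proto, 1), "activated")
  expect_identical(classify_channel_response(
    hrf_curve("suppressive", 0.05, 5, 20, proto), proto, 1), "suppressive")
  # oracle equivalence on pure-noise channels
  set.seed(99)
  agree <- vapply(1:1000, function(i) {
    v <- 1 + rnorm(proto$n_frames, 0, 0.05)
    oracle <- if (mean(v[proto$task_frames] - 1) > 0) "activated"
    else "suppressive"
    identical(classify_channel_response(v, proto, 1), oracle)
  }, logical(1))
  expect_true(all(agree))
  # mostly-missing task window is unclassifiable
  v <- rep(1.05, proto$n_frames)
  v[proto$task_frames[1:40]] <- NA
  expect_true(is.na(classify_channel_response(v, proto, 1)))
})

test_that("response triplet separates classes, conserves the overall mean, and flags empty classes", {
  proto <- task_protocol()
  a <- hrf_curve("activated", 0.06, 5, 20, proto)
  b <- hrf_curve("activated", 0.03, 8, 25, proto)
  s <- hrf_curve("suppressive", 0.04, 6, 22, proto)
  tr <- build_response_triplet(rbind(a, b, s), protocol = proto)
  expect_equal(unname(tr$activated_mean), unname((a + b) / 2))
  expect_equal(unname(tr$suppressive_mean), unname(s))
  expect_equal(unname(tr$channel_avg), unname((a + b + s) / 3))
  expect_identical(unname(tr$counts), c(2L, 1L))
  # conservation: channel_avg is the class-size-weighted mean of the class
  # means at every frame
  expect_equal(tr$channel_avg,
               (2 * tr$activated_mean + 1 * tr$suppressive_mean) / 3)
  # permuting channels leaves the triplet unchanged
  tr2 <- build_response_triplet(rbind(s, b, a), protocol = proto)
  expect_equal(tr2$activated_mean, tr$activated_mean)
  expect_equal(tr2$channel_avg, tr$channel_avg)
  # all-activated input: suppressive mean pinned at reference and flagged
  tr3 <- build_response_triplet(rbind(a, b), protocol = proto)
  expect_true(tr3$empty_class["suppressive"])
  expect_equal(unname(tr3$suppressive_mean), rep(1, proto$n_frames))
  # missing frames averaged pairwise
  a_na <- a; a_na[50] <- NA
  tr4 <- build_response_triplet(rbind(a_na, b), protocol = proto)
  expect_equal(unname(tr4$activated_mean[50]), unname(b[50]))
  # random fixture equals brute-force recomputation
  set.seed(17)
  m <- 1 + matrix(rnorm(5 * proto$n_frames, 0, 0.05), 5)
  trr <- build_response_triplet(m, protocol = proto)
  cls <- apply(m, 1, function(v)
    if (mean(v[proto$task_frames] - 1) > 0) "activated" else "suppressive")
  for (f in c(1, 80, 160)) {
    expect_equal(unname(trr$channel_avg[f]), mean(m[, f]))
    if (any(cls == "activated"))
      expect_equal(unname(trr$activated_mean[f]),
                   mean(m[cls == "activated", f]))
  }
  # all channels rejected -> invalid sample
  qbad <- structure(list(retained = rep(FALSE, 2)), class = "channel_quality")
  expect_error(build_response_triplet(m[1:2, ], qbad, proto),
               "no retained channels")
})

test_that("triplet long export is tidy and complete", {
  proto <- short_protocol()
  m <- 1 + matrix(rnorm(3 * proto$n_frames, 0, 0.01), 3)
  tr <- build_response_triplet(m, protocol = proto)
  long <- triplet_long(list(RHbO1 = tr), sample_id = "S001_1")
  expect_identical(nrow(long), 3L * as.integer(proto$n_frames))
  expect_setequal(unique(long$class),
                  c("activated", "suppressive", "channel_avg"))
  expect_identical(long$value[long$class == "channel_avg"],
                   unname(tr$channel_avg))
})
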