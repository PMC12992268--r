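# Diffusion forward model and the two inverse computations.

test_that("reflectance is positive, monotone in absorption, and obeys the late-time slope identity", {
  p1 <- optical_properties(mua = 0.01, musp = 1.0, n_tissue = 1.4, rho = 30)
  p2 <- optical_properties(mua = 0.02, musp = 1.0, n_tissue = 1.4, rho = 30)
  t <- c(200, 500, 1000, 2000, 4000)
  expect_true(all(semi_infinite_reflectance(t, p1) > 0))
  expect_true(all(semi_infinite_reflectance(t, p2) <
                    semi_infinite_reflectance(t, p1)))
  # applying a mua change shifts the late-time log-slope by -dmua * v * dt
  t1 <- 6000; t2 <- 6400
  dslope <- (log(semi_infinite_reflectance(t2, p2)) -
               log(semi_infinite_reflectance(t1, p2))) -
    (log(semi_infinite_reflectance(t2, p1)) -
       log(semi_infinite_reflectance(t1, p1)))
  v <- 0.299792458 / 1.4
  expect_equal(dslope, -0.01 * v * (t2 - t1), tolerance = 1e-10)
  # asymptotically d ln R / dt -> -(mua v + 5/(2t)); the remaining
  # rho^2/(4 D v t^2) correction is ~6e-4 of the slope at this t
  tm <- 50000
  num <- (log(semi_infinite_reflectance(tm + 1, p1)) -
            log(semi_infinite_reflectance(tm - 1, p1))) / 2
  expect_equal(num, -(p1$mua * v + 5 / (2 * tm)), tolerance = 2e-3)
  expect_error(semi_infinite_reflectance(-5, p1), "t_ps > 0")
  expect_error(optical_properties(mua = -1), "mua")
})

test_that("reflectance matches an independently coded evaluation of the closed form", {
  # oracle: literal extrapolated-boundary image-source formula written out
  # from scratch
  oracle <- function(t, mua, musp, n, rho) {
    c0 <- 0.299792458
    v <- c0 / n
    D <- 1 / (3 * musp)
    rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
    A <- (1 + rd) / (1 - rd)
    z0 <- 1 / musp
    zb <- 2 * A * D
    0.5 * (4 * pi * D * v)^(-3 / 2) * t^(-5 / 2) * exp(-mua * v * t) *
      exp(-rho^2 / (4 * D * v * t)) *
      (z0 * exp(-z0^2 / (4 * D * v * t)) +
         (z0 + 2 * zb) * exp(-(z0 + 2 * zb)^2 / (4 * D * v * t)))
  }
  p <- optical_properties(mua = 0.01, musp = 1.0, n_tissue = 1.4, rho = 30)
  for (t in c(300, 1500, 5000))
    expect_equal(semi_infinite_reflectance(t, p),
                 oracle(t, 0.01, 1.0, 1.4, 30), tolerance = 1e-12)
  # zero-boundary variant drops the second image source
  pz <- semi_infinite_reflectance(1500, p, boundary = "zero")
  expect_gt(abs(pz / semi_infinite_reflectance(1500, p) - 1), 0.1)
})

test_that("gate_tpsf sums whole bins inside each window and matches a brute-force loop", {
  edges <- seq(0, 4000, by = 100)
  nf <- 4
  gates <- gate_set(c(500, 1500, 2500), c(1000, 2000, 3000))
  # all-zero counts -> all-zero gated values
  rec0 <- tpsf_record(1, 760, edges, matrix(0, nf, 40), 0:3)
  expect_true(all(gate_tpsf(rec0, gates)$values == 0))
  # unit counts: gated value equals the number of whole bins in the window
  rec1 <- tpsf_record(1, 760, edges, matrix(1, nf, 40), 0:3)
  expect_true(all(gate_tpsf(rec1, gates)$values == 5))
  # random histogram vs brute-force loop over bins
  set.seed(42)
  cnt <- matrix(rpois(4 * 40, 20), nf, 40)
  rec <- tpsf_record(1, 760, edges, cnt, 0:3)
  g <- gate_tpsf(rec, gates)
  centers <- (edges[-1] + edges[-41]) / 2
  for (gi in 1:3) for (f in 1:nf) {
    brute <- 0
    for (b in 1:40)
      if (centers[b] >= gates$starts_ps[gi] && centers[b] < gates$ends_ps[gi])
        brute <- brute + cnt[f, b]
    expect_identical(unname(g$values[1, 1, gi, f]), as.numeric(brute))
  }
  expect_error(gate_tpsf(rec, gate_set(c(500, 1500, 3900), c(1000, 2000, 4400))),
               "outside the histogram support")
})

test_that("MBLL inversion is a machine-precision round trip and linear", {
  proto <- task_protocol()
  ext <- extinction_table()
  gates <- gate_set()
  n_t <- 1.4
  v <- 0.299792458 / n_t
  L <- v * gates$centers_ps
  set.seed(7)
  dhbo_true <- 0.4 * (hrf_curve("activated", 0.05, 5, 20, proto) - 1) * 100
  dhbr_true <- -0.3 * dhbo_true
  nf <- proto$n_frames
  vals <- array(NA_real_, c(1, 2, 3, nf),
                dimnames = list(channel = 1, wavelength = c(760, 850),
                                gate = 1:3, frame = NULL))
  for (wi in 1:2) for (g in 1:3) {
    dod <- (ext$matrix[wi, "HbO"] * dhbo_true +
              ext$matrix[wi, "HbR"] * dhbr_true) * L[g]
    vals[1, wi, g, ] <- 1000 * exp(-dod)      # forward MBLL from I0 = 1000
  }
  gs <- structure(list(values = vals, channels = 1L,
                       wavelengths = c(760, 850), gate_set = gates,
                       frame_times_s = proto$frame_times_s),
                  class = "gated_series")
  out <- mbll_delta_hbo(gs, c(0, proto$rest_pre_s), ext, n_tissue = n_t)
  for (g in 1:3) {
    expect_equal(out[[g]]$values[1, ], dhbo_true, tolerance = 1e-10)
    expect_equal(mean(out[[g]]$values[1, 1:proto$rest_pre_s]), 0,
                 tolerance = 1e-10)
  }
  # identity case: constant intensity gives identically zero changes
  vals0 <- vals; vals0[] <- rep(1000, length(vals0))
  gs0 <- gs; gs0$values <- vals0
  out0 <- mbll_delta_hbo(gs0, c(0, 30), ext, n_tissue = n_t)
  expect_true(all(abs(out0[[2]]$values) < 1e-12))
  # doubling both wavelengths' OD doubles the recovered change
  gs2 <- gs
  gs2$values <- 1000 * (vals / 1000)^2
  out2 <- mbll_delta_hbo(gs2, c(0, 30), ext, n_tissue = n_t)
  expect_equal(out2[[1]]$values[1, ], 2 * dhbo_true, tolerance = 1e-9)
  # channel with nonpositive baseline intensity is flagged unusable
  gsb <- gs; gsb$values[1, 1, 1, 3] <- 0
  outb <- mbll_delta_hbo(gsb, c(0, 30), ext, n_tissue = n_t)
  expect_identical(outb[[1]]$unusable, 1L)
  expect_length(outb[[2]]$unusable, 0)
})

test_that("delay-pair absorption estimate inverts the forward model within 2% and degrades smoothly with gate width", {
  p <- optical_properties(mua = 0.013, musp = 1.1, n_tissue = 1.4, rho = 30)
  g <- forward_gated(rep(p$mua, 3), p)
  for (pr in 1:2) {
    mua <- estimate_mua_from_pair(g, pr, p)
    expect_lt(abs(mua[1, 1, 1] - p$mua) / p$mua, 0.02)
  }
  # midpoint variant: error grows monotonically with gate width
  widths <- c(100, 300, 500)
  errs <- vapply(widths, function(w) {
    gts <- gate_set(c(500, 1500, 2500), c(500, 1500, 2500) + w)
    gw <- forward_gated(rep(p$mua, 2), p, gates = gts)
    mua <- estimate_mua_from_pair(gw, 1, p, method = "midpoint")
    abs(mua[1, 1, 1] - p$mua) / p$mua
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[1], 0.02)   # narrow gates: near-exact inverse
  # monotonicity: raising the later gate's intensity lowers the estimate
  g_hi <- g; g_hi$values[1, 1, 2, ] <- g_hi$values[1, 1, 2, ] * 1.2
  expect_lt(suppressWarnings(estimate_mua_from_pair(g_hi, 1, p))[1, 1, 1],
            estimate_mua_from_pair(g, 1, p)[1, 1, 1])
  # degenerate input whose ratio lies below the zero-absorption bound:
  # floored and flagged
  g0 <- forward_gated(rep(1e-9, 2), p)    # effectively absorption-free
  g_eq <- g0; g_eq$values[1, 1, 2, ] <- g_eq$values[1, 1, 2, ] * 2
  expect_warning(m_eq <- estimate_mua_from_pair(g_eq, 1, p), "floor")
  expect_equal(unname(m_eq[1, 1, 1]), 1e-5)
  expect_gt(attr(m_eq, "n_floored"), 0)
  # nonpositive intensities are flagged missing
  g_na <- g; g_na$values[1, 1, 1, 2] <- 0
  m_na <- estimate_mua_from_pair(g_na, 1, p)
  expect_true(is.na(m_na[1, 1, 2]))
  expect_identical(attr(m_na, "n_missing"), 1L)
})

test_that("task-rest ratio reproduces a programmed trajectory and cancels gains", {
  p <- optical_properties(mua = 0.012, musp = 1.0)
  proto <- task_protocol()
  ext <- extinction_table()
  ratio <- hrf_curve("activated", 0.06, 6, 22, proto)
  g <- forward_gated_2wl(50 * ratio, 20, p, ext,
                         frame_times = proto$frame_times_s)
  bw <- c(0, proto$rest_pre_s)
  for (pr in 1:2) {
    mua <- estimate_mua_from_pair(g, pr, p)
    r <- rhbo_series(mua, ext, bw, proto$frame_times_s, pr)
    expect_lt(max(abs(r$values[1, ] / ratio - 1)), 0.03)
    expect_equal(mean(r$values[1, 1:proto$rest_pre_s]), 1, tolerance = 1e-9)
    expect_true(all(r$values > 0))
  }
  # identical task and rest state -> ratio identically 1
  g0 <- forward_gated_2wl(rep(50, proto$n_frames), 20, p, ext,
                          frame_times = proto$frame_times_s)
  r0 <- rhbo_series(estimate_mua_from_pair(g0, 1, p), ext, bw,
                    proto$frame_times_s)
  expect_equal(unname(r0$values[1, ]), rep(1, proto$n_frames),
               tolerance = 1e-12)
  # per-channel multiplicative gain cancels end to end
  g_gain <- g; g_gain$values <- g_gain$values * 3.7
  r1 <- rhbo_series(estimate_mua_from_pair(g, 2, p), ext, bw,
                    proto$frame_times_s)
  r2 <- rhbo_series(estimate_mua_from_pair(g_gain, 2, p), ext, bw,
                    proto$frame_times_s)
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})

test_that("extinction table validates and loads from CSV", {
  expect_error(extinction_table(eps_hbo = c(1e-4, 1e-4),
                                eps_hbr = c(2e-4, 2e-4)), "singular")
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = c(760, 850),
                       eps_HbO = c(1.3e-4, 2.4e-4),
                       eps_HbR = c(3.6e-4, 1.6e-4)), path,
            row.names = FALSE)
  ext <- read_extinction_csv(path)
  expect_s3_class(ext, "extinction_table")
  expect_equal(ext$matrix["760", "HbR"], 3.6e-4)
})
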