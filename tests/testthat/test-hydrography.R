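test_that("preprocessing drops pressure reversals and density spikes", {
  # smooth, strictly increasing profile passes through unchanged
  p <- density_profile(1:10, 1025 + 0.01 * (1:10))
  out <- preprocess_profile(p)
  expect_equal(out$depth, p$depth)
  expect_equal(out$sigma, p$sigma)

  # repeated depth (pressure reversal): second occurrence dropped
  raw <- density_profile(c(1, 2, 3, 3, 4, 5, 6),
                         1025 + 0.01 * c(1, 2, 3, 3.1, 4, 5, 6),
                         strict = FALSE)
  out <- preprocess_profile(raw)
  expect_equal(nrow(out), 6L)
  expect_true(all(diff(out$depth) > 0))

  # single-point spike 10x the noise threshold above its neighbours
  sig <- 1025 + 0.001 * (1:11)
  sig[6] <- sig[6] + 10 * 0.002
  raw <- density_profile(1:11, sig, strict = FALSE)
  out <- preprocess_profile(raw)
  expect_equal(nrow(out), 10L)
  expect_false(any(abs(out$sigma - stats::median(out$sigma)) > 0.02))

  # degenerate profile after cleaning
  expect_error(preprocess_profile(
    density_profile(c(1, 1, 1, 1), c(1025, 1025, 1025, 1025),
                    strict = FALSE)), "degenerate")
})

test_that("Thorpe displacements match the worked example and sum to zero", {
  p <- density_profile(1:5, c(1025.0, 1025.3, 1025.1, 1025.2, 1025.4))
  d <- thorpe_displacements(p)
  expect_equal(d$displacement, c(0, 2, -1, -1, 0))

  # already-stable profile: all zero
  st <- density_profile(1:6, 1025 + 0.01 * (1:6))
  expect_equal(thorpe_displacements(st)$displacement, rep(0, 6))

  # two-sample inversion is antisymmetric
  p2 <- density_profile(1:3, c(1025.0, 1025.6, 1025.3))
  expect_equal(thorpe_displacements(p2)$displacement, c(0, 1, -1))

  # ties produce zero displacement (stable sort, index-order tie-break)
  pt <- density_profile(1:4, c(1025, 1025.2, 1025.2, 1025.4))
  expect_equal(thorpe_displacements(pt)$displacement, rep(0, 4))
})

test_that("displacements equal a brute-force stable-sort oracle", {
  set.seed(11)
  for (rep in 1:200) {
    p <- random_permuted_profile(sample(10:50, 1))
    d <- thorpe_displacements(p)
    expect_equal(d$displacement, oracle_displacements(p$depth, p$sigma),
                 tolerance = 0)
    expect_equal(sum(d$displacement), 0, tolerance = 1e-9)
  }
})

test_that("overturn detection finds the worked patch and rejects noise", {
  pars <- mixing_params()
  # stable profile: no patches
  st <- density_profile(1:10, 1025 + 0.01 * (1:10))
  expect_equal(nrow(detect_overturns(thorpe_displacements(st), st, pars)), 0L)

  # 5-point worked example: one patch spanning samples 2-4
  p <- density_profile(1:5, c(1025.0, 1025.3, 1025.1, 1025.2, 1025.4))
  s <- detect_overturns(thorpe_displacements(p), p, pars)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start_depth, 2)
  expect_equal(s$end_depth, 4)
  expect_equal(s$L_T, sqrt((4 + 1 + 1) / 3))

  # sub-threshold inversion rejected as sensor noise
  tiny <- density_profile(1:5, c(1025, 1025.0006, 1025.0002, 1025.0004,
                                 1025.001))
  expect_equal(nrow(detect_overturns(thorpe_displacements(tiny), tiny, pars)),
               0L)
})

test_that("patch K_z follows the closed form Gamma a^2 L_T^2 N", {
  pars <- mixing_params()
  # build an inversion whose sorted gradient yields a chosen N
  n_target <- 5e-3
  dz <- 1
  dsig <- n_target^2 * pars$rho0 / pars$g * dz  # per metre
  depth <- 1:7
  sigma <- 1025 + dsig * depth
  sigma[3:5] <- rev(sigma[3:5])  # full inversion of a 2-m segment
  p <- density_profile(depth, sigma)
  s <- detect_overturns(thorpe_displacements(p), p,
                        mixing_params(noise_threshold = dsig / 10))
  expect_equal(nrow(s), 1L)
  expect_equal(s$N, n_target, tolerance = 1e-10)
  expect_equal(s$K_z, pars$gamma * pars$ozmidov_ratio^2 * s$L_T^2 * s$N,
               tolerance = 1e-12)
  # worked magnitude: L_T = 1 m, N = 5e-3 -> K_z = 6.4e-4
  expect_equal(pars$gamma * pars$ozmidov_ratio^2 * 1^2 * 5e-3, 6.4e-4)
})

test_that("cast K_z profiles map patches onto bins with weighted means", {
  pars <- mixing_params()
  bins <- seq(0, 20, by = 1)
  empty <- detect_overturns(
    thorpe_displacements(density_profile(1:5, 1025 + 0.01 * (1:5))),
    density_profile(1:5, 1025 + 0.01 * (1:5)), pars)
  prof <- cast_kz_profile(empty, bins, pars)
  expect_equal(prof$kz, rep(pars$background_kz, 20))

  seg <- data.frame(start_depth = 5, end_depth = 8, n_samples = 6L,
                    L_T = 1, N = 5e-3, epsilon = 1e-7, K_z = 1e-4,
                    sum_abs_disp = 4)
  prof <- cast_kz_profile(seg, bins, pars)
  expect_equal(prof$kz[6:8], rep(1e-4, 3))  # bins 5-6,6-7,7-8
  expect_equal(prof$kz[-(6:8)], rep(1e-6, 17))

  # two overlapping patches: displacement-weighted mean
  segs <- rbind(seg, data.frame(start_depth = 7, end_depth = 9,
                                n_samples = 4L, L_T = 0.5, N = 5e-3,
                                epsilon = 1e-8, K_z = 4e-4,
                                sum_abs_disp = 12))
  prof <- cast_kz_profile(segs, bins, pars)
  expect_equal(prof$kz[8], (1e-4 * 4 + 4e-4 * 12) / 16)
})

test_that("cross-cast averaging is a per-bin geometric mean", {
  mk <- function(kz) data.frame(depth_top = 0:4, depth_bottom = 1:5, kz = kz)
  one <- average_kz(list(mk(rep(1e-5, 5))))
  expect_equal(one$kz_geomean, rep(1e-5, 5))
  expect_equal(one$n_casts, rep(1L, 5))

  two <- average_kz(list(mk(rep(1e-6, 5)), mk(rep(1e-4, 5))))
  expect_equal(two$kz_geomean, rep(1e-5, 5))

  # AM-GM: geometric mean never exceeds the arithmetic mean
  set.seed(21)
  vals <- replicate(14, 10^runif(5, -6, -4))
  gm <- average_kz(apply(vals, 2, mk, simplify = FALSE))$kz_geomean
  expect_true(all(gm <= rowMeans(vals) + 1e-15))

  expect_error(average_kz(list()), "no cast profiles")
})

test_that("an inverted linearly stratified segment recovers its Thorpe scale", {
  # full inversion of an h-metre segment: L_T should match the rms
  # displacement of the brute-force sorted profile (h/sqrt(3) scaling)
  pars <- mixing_params()
  for (h in c(6, 8, 16)) {
    depth <- seq(1, 60, by = 0.5)
    sigma <- 1024 + 0.01 * depth
    idx <- which(depth >= 30 - h / 2 & depth <= 30 + h / 2)
    sigma[idx] <- rev(sigma[idx])
    p <- density_profile(depth, sigma)
    d <- thorpe_displacements(p)
    s <- detect_overturns(d, p, pars)
    expect_equal(nrow(s), 1L)
    lt_oracle <- sqrt(mean(oracle_displacements(p$depth, p$sigma)[idx]^2))
    expect_lt(abs(s$L_T - lt_oracle) / lt_oracle, 0.10)
    # and the oracle rms itself follows the h/sqrt(3) scaling
    expect_equal(lt_oracle, h / sqrt(3), tolerance = 0.1)
  }
})
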