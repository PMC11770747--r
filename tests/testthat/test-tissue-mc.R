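# Voxel Monte Carlo: conservation, limiting cases against closed forms,
# convergence scaling, diffusion-theory slope, similarity relation.

test_that("a pure absorber reproduces Beer-Lambert attenuation", {
  model <- tissue_model(mu_a_per_cm = 1, mu_s_prime_per_cm = 0)
  map <- run_mc(model, beam_model(), n_packets = 2e5, seed = 21)
  prof <- depth_profile(map, 0, half_width_mm = 3)
  sel <- prof$depth_mm <= 30
  expected <- exp(-prof$depth_mm[sel] / 10)
  expected <- expected / expected[1]
  observed <- prof$relative_density[sel] / prof$relative_density[1]
  expect_lt(max(abs(observed / expected - 1)), 0.02)
  # no scattering build-up: profile decreases monotonically
  expect_true(all(diff(prof$relative_density) < 0))
})

test_that("packet weight is conserved exactly", {
  map <- run_mc(tissue_model(), beam_model(), n_packets = 5e4, seed = 2)
  expect_lt(conservation_residual(map), 1e-6)
  # non-absorbing medium: every launched packet escapes
  map0 <- run_mc(tissue_model(mu_a_per_cm = 0), beam_model(),
                 n_packets = 2e4, seed = 3)
  expect_lt(abs(map0$tallies$escaped - map0$tallies$launched) /
              map0$tallies$launched, 1e-6)
  expect_equal(map0$tallies$absorbed, 0)
})

test_that("runs are bit-reproducible under a seed", {
  m1 <- run_mc(tissue_model(), beam_model(), n_packets = 2e4, seed = 9)
  m2 <- run_mc(tissue_model(), beam_model(), n_packets = 2e4, seed = 9)
  expect_identical(m1$values, m2$values)
  m3 <- run_mc(tissue_model(), beam_model(), n_packets = 2e4, seed = 10)
  expect_false(identical(m1$values, m3$values))
})

test_that("the fluence map is left-right symmetric up to MC noise", {
  map <- get_benchmark_map(1e6)
  layer <- map$values[, , 10]  # 1 cm depth
  nx <- dim(layer)[1]
  left <- mean(layer[1:(nx / 2), ])
  right <- mean(layer[(nx / 2 + 1):nx, ])
  expect_equal(left, right, tolerance = 0.05)
})

test_that("MC error scales as one over the square root of packet count", {
  read10 <- function(n, seed) {
    m <- run_mc(tissue_model(), beam_model(), n_packets = n, seed = seed)
    p <- depth_profile(m, 0)
    p$relative_density[which.min(abs(p$depth_mm - 10))]
  }
  sd_small <- sd(vapply(1:6, function(s) read10(2e4, 100 + s), numeric(1)))
  sd_large <- sd(vapply(1:6, function(s) read10(8e4, 200 + s), numeric(1)))
  # 4x packets -> 2x lower standard error, within the noise of 6 replicates
  expect_gt(sd_small / sd_large, 1.2)
  expect_lt(sd_small / sd_large, 3.4)
})

test_that("deep decay matches the diffusion-theory attenuation", {
  # broad beam puts the axis in the planar regime where the on-axis slope
  # approaches mu_eff = sqrt(3 mu_a (mu_a + mu_s')) = 1.11 /cm
  map <- run_mc(tissue_model(), beam_model(diameter_cm = 6),
                n_packets = 2e5, seed = 31)
  prof <- depth_profile(map, 0)
  sel <- prof$depth_mm >= 10 & prof$depth_mm <= 30
  slope <- -unname(coef(lm(log(prof$relative_density[sel]) ~
                             I(prof$depth_mm[sel] / 10)))[2])
  mu_eff <- sqrt(3 * 0.035 * (0.035 + 11.7))
  expect_lt(abs(slope - mu_eff) / mu_eff, 0.15)
})

test_that("isotropic similarity agrees with Henyey-Greenstein at depth", {
  iso <- run_mc(tissue_model(), beam_model(), n_packets = 3e5, seed = 41)
  hg <- run_mc(tissue_model(anisotropy_g = 0.9), beam_model(),
               n_packets = 3e5, seed = 42)
  p_iso <- depth_profile(iso, 0)
  p_hg <- depth_profile(hg, 0)
  a_iso <- p_iso$relative_density * iso$surface_dose_raw
  a_hg <- p_hg$relative_density * hg$surface_dose_raw
  # band chosen so MC noise at this packet count stays below the
  # similarity tolerance
  sel <- p_iso$depth_mm >= 5 & p_iso$depth_mm <= 20
  expect_lt(max(abs(a_hg[sel] / a_iso[sel] - 1)), 0.10)
})

test_that("depth profiles and power scaling behave as documented", {
  map <- get_benchmark_map(1e6)
  # axial symmetry of preset offsets: band averages are well defined
  for (off in c(0, 4.8, 5.9, 11)) {
    prof <- depth_profile(map, off)
    expect_equal(nrow(prof), 50)
    expect_true(all(prof$relative_density >= 0))
  }
  expect_error(depth_profile(map, 1e3), "outside the grid")
  # linearity in surface power density
  p1 <- power_at_depth(map, 1, c(0, 10, 20))
  p3 <- power_at_depth(map, 3, c(0, 10, 20))
  expect_equal(p3, 3 * p1, tolerance = 1e-12)
  # surface power equals delivered power density x beam area
  expect_equal(p1[1], 1 * map$beam$area_cm2 *
                 depth_profile(map, 0)$relative_density[1],
               tolerance = 0.05)
  # beyond the slab nothing arrives
  expect_equal(power_at_depth(map, 1, 52), 0)
})

test_that("fluence maps serialize and restore faithfully", {
  map <- run_mc(tissue_model(), beam_model(), n_packets = 2e4, seed = 5)
  path <- file.path(tempdir(), "map_roundtrip.csv")
  write_fluence_map(map, path)
  back <- read_fluence_map(path)
  expect_equal(back$values, map$values, tolerance = 1e-12)
  expect_equal(back$tallies$escaped, map$tallies$escaped)
  expect_equal(back$model$mu_s_prime_per_cm, 11.7)
})

test_that("model validation rejects unphysical configurations", {
  expect_error(tissue_model(mu_a_per_cm = -1), "mu_a")
  expect_error(tissue_model(anisotropy_g = 1.5), "anisotropy_g")
  expect_error(run_mc(tissue_model(), beam_model(), n_packets = 100),
               "n_packets")
})
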