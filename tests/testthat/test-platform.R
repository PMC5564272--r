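test_that("droplet generation honours the configured size and composition", {
  cfg <- platform_config(n_droplets = 40, init_radius_cv = 0,
                         composition = list(
                           list(fraction = 0.5,
                                concentrations_M = c(monomer = 0.05)),
                           list(fraction = 0.5,
                                concentrations_M = c(monomer = 0))
                         ))
  set.seed(1)
  pop <- generate_droplets(cfg)
  # cv = 0: exactly monodisperse
  expect_true(all(pop$droplets$radius_um == 30))
  expect_identical(polydispersity(pop$droplets$radius_um)$s_over_d, 0)
  # two exactly equal composition classes
  pi_i <- osmolarity(pop)$osmolarity_M
  expect_equal(sum(pi_i > 0.049), 20)
  expect_equal(sum(pi_i == 0), 20)
  # determinism under a fixed seed
  cfg2 <- platform_config(n_droplets = 40, init_radius_cv = 0.1)
  set.seed(99); a <- generate_droplets(cfg2)
  set.seed(99); b <- generate_droplets(cfg2)
  expect_identical(a$droplets, b$droplets)
})

test_that("size sorting partitions the population at the threshold", {
  sp <- species("s", 100)
  d <- new_droplets(3, c(20, 25, 30), species = sp) # diameters 40, 50, 60
  pop <- droplet_population(d, sp)
  srt <- sort_by_size(pop, f = 50, mode = "individual")
  expect_setequal(2 * srt$selected$droplets$radius_um, c(50, 60))
  expect_equal(2 * srt$discarded$droplets$radius_um, 40)
  # f = 0 keeps everything; f above the maximum discards everything
  expect_equal(nrow(sort_by_size(pop, 0)$selected$droplets), 3)
  expect_equal(nrow(sort_by_size(pop, 100)$selected$droplets), 0)
  # partition property: union = input, intersection empty
  set.seed(11)
  d2 <- new_droplets(50, runif(50, 10, 50), species = sp)
  pop2 <- droplet_population(d2, sp)
  for (mode in c("individual", "subpopulation")) {
    s2 <- sort_by_size(pop2, 55, mode = mode, bins = 4)
    expect_setequal(c(s2$selected$droplets$id, s2$discarded$droplets$id),
                    pop2$droplets$id)
    expect_length(intersect(s2$selected$droplets$id,
                            s2$discarded$droplets$id), 0)
  }
  expect_error(sort_by_size(droplet_population(d[0, ], sp), 50), "empty")
})

test_that("subpopulation sorting keeps whole bins by mean diameter", {
  sp <- species("s", 100)
  # diameters 20,22 | 40,42 | 60,62 | 80,82 in four equal-width bins
  d <- new_droplets(8, c(10, 11, 20, 21, 30, 31, 40, 41), species = sp)
  pop <- droplet_population(d, sp)
  srt <- sort_by_size(pop, f = 50, mode = "subpopulation", bins = 4)
  expect_setequal(2 * srt$selected$droplets$radius_um, c(60, 62, 80, 82))
  # a bin with mean below f is discarded wholesale even if one member passes f
  srt2 <- sort_by_size(pop, f = 41.5, mode = "subpopulation", bins = 4)
  expect_false(42 %in% (2 * srt2$selected$droplets$radius_um))
})

test_that("fusion is strictly additive in volume and amounts", {
  sp <- species("s", 100)
  d <- new_droplets(2, 30, species = sp)
  d$s <- c(1e-12, 2e-12)
  fused <- fuse_droplets(d[1, ], d[2, ], sp)
  expect_equal(fused$radius_um, 30 * 2^(1 / 3), tolerance = 1e-12)
  expect_equal(fused$radius_um, 37.798, tolerance = 1e-4)
  expect_identical(fused$s, 3e-12)
  expect_setequal(fused$parent_ids[[1]], c("d0001", "d0002"))
  # fusing with a floor-sized water droplet leaves amounts unchanged
  tiny <- new_droplets(1, 0.5, species = sp, id_prefix = "t")
  fused2 <- fuse_droplets(d[1, ], tiny, sp)
  expect_identical(fused2$s, d$s[1])
  expect_lt(fused2$radius_um / d$radius_um[1] - 1, 1e-5)
})

test_that("splitting conserves volume and amounts exactly", {
  sp <- species(c("a", "b"), c(100, 500))
  d <- new_droplets(1, 30, species = sp)
  d$a <- 4e-12; d$b <- 7e-13
  # symmetric noiseless split: identical halves
  kids <- split_droplet(d, sp, fraction = 0.5, noise_sd = 0)
  expect_equal(kids$radius_um[1], kids$radius_um[2])
  expect_equal(kids$a[1], kids$a[2])
  expect_equal(kids$generation, c(1L, 1L))
  # conservation under arbitrary fraction and noise (property)
  set.seed(21)
  for (i in 1:25) {
    phi <- runif(1, 0.05, 0.95)
    kids <- split_droplet(d, sp, fraction = phi, noise_sd = 0.3)
    expect_identical(kids$a[1] + kids$a[2], d$a)
    expect_identical(kids$b[1] + kids$b[2], d$b)
    expect_true(all(kids$a >= 0) && all(kids$b >= 0))
    v <- (4 / 3) * pi * d$radius_um^3
    expect_equal(sum((4 / 3) * pi * kids$radius_um^3), v, tolerance = 1e-12)
    expect_equal((4 / 3) * pi * kids$radius_um[1]^3, phi * v,
                 tolerance = 1e-12)
  }
  # determinism of the noisy partition under a fixed seed
  set.seed(5); k1 <- split_droplet(d, sp, noise_sd = 0.1)
  set.seed(5); k2 <- split_droplet(d, sp, noise_sd = 0.1)
  expect_identical(k1, k2)
})

test_that("one generation wires selection, fitness and offspring correctly", {
  cfg <- platform_config(n_droplets = 30, incubation_time_s = 2000,
                         dt_s = 20, size_threshold_um = 0.1)
  set.seed(2)
  pop <- generate_droplets(cfg)
  res <- run_generation(pop, cfg, generation = 0L)
  rec <- res$record
  # f below all diameters: every parent survives, offspring pool subsampled
  expect_equal(rec$n_survivors, 30)
  expect_equal(rec$n_fresh, 0)
  expect_equal(sum(rec$parents$w), 30)
  expect_true(all(rec$parents$w %in% 0:2))
  expect_equal(nrow(res$population$droplets), 30)
  # offspring table is consistent with fitness counts
  expect_equal(nrow(rec$offspring), sum(rec$parents$w))
  # f above all diameters: all fitness zero, next generation all fresh
  cfg_hi <- platform_config(n_droplets = 30, incubation_time_s = 2000,
                            dt_s = 20, size_threshold_um = 500)
  set.seed(2)
  pop <- generate_droplets(cfg_hi)
  expect_warning(res_hi <- run_generation(pop, cfg_hi, 0L), "threshold")
  expect_true(all(res_hi$record$parents$w == 0))
  expect_equal(res_hi$record$n_fresh, 30)
  expect_equal(nrow(res_hi$population$droplets), 30)
})

test_that("threshold selection forces a non-negative selection differential", {
  cfg <- platform_config(n_droplets = 50, incubation_time_s = 2000, dt_s = 20)
  set.seed(4)
  pop <- generate_droplets(cfg)
  res <- run_generation(pop, cfg, 0L)
  rec <- res$record
  sel <- rec$parents$z_um[rec$parents$w > 0]
  dis <- rec$parents$z_um[rec$parents$w == 0]
  if (length(sel) && length(dis)) expect_gte(mean(sel), mean(dis))
  expect_lte(sum(rec$parents$w), cfg$n_droplets)
})

test_that("the recursion is reproducible and the neutral control is flat", {
  cfg <- platform_config(n_droplets = 20, n_generations = 3,
                         incubation_time_s = 2000, dt_s = 20, seed = 17)
  r1 <- run_recursion(cfg)
  r2 <- run_recursion(cfg)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$droplets, r2$droplets)
  # neutral control: no chemistry, no partition noise, monodisperse input
  cfg_n <- platform_config(
    n_droplets = 20, n_generations = 5, incubation_time_s = 2000,
    dt_s = 20, init_radius_cv = 0, partition_noise_sd = 0,
    chemistry = default_chemistry(k_init = 0, k_auto = 0), seed = 3
  )
  rn <- suppressWarnings(run_recursion(cfg_n))
  z <- tidy(rn)$z_bar_um
  expect_lt(max(z) - min(z), 1e-9)
  tr <- evolution_trend(z)
  expect_false(tr$evolving)
})
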