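test_that("osmolarity reproduces known concentrations", {
  sp <- species("glycylglycine", 132.12, exchangeable = FALSE)
  # any radius initialised at 50 mM reads back 50 mM
  for (r in c(10, 30, 80)) {
    d <- new_droplets(1, r, c(glycylglycine = 0.05), sp)
    pop <- droplet_population(d, sp)
    expect_equal(osmolarity(pop)$osmolarity_M, 0.05, tolerance = 1e-12)
  }
  # pure water droplet: empty sum
  d <- new_droplets(1, 30, species = sp)
  expect_identical(osmolarity(droplet_population(d, sp))$osmolarity_M, 0)
  # hand-computed: V = (4/3)*pi*30^3 um^3 = 1.1309734e-10 L
  d <- new_droplets(1, 30, species = sp)
  d$glycylglycine <- 5.654867e-12
  expect_equal(osmolarity(droplet_population(d, sp))$osmolarity_M,
               0.0500, tolerance = 1e-6)
})

test_that("invalid droplets are rejected", {
  sp <- species("s", 100)
  d <- new_droplets(1, 30, species = sp)
  d$radius_um <- -1
  expect_error(droplet_population(d, sp), "positive")
  d$radius_um <- 30
  d$s <- -1e-12
  expect_error(droplet_population(d, sp), "non-negative")
})

test_that("water exchange follows the area-weighted mean-field law", {
  # identical droplets: all rates exactly zero
  sp <- species("glycylglycine", 132.12, exchangeable = FALSE)
  d_eq <- new_droplets(5, 30, c(glycylglycine = 0.05), sp)
  expect_identical(
    water_exchange_rates(droplet_population(d_eq, sp))$dV_dt_um3_s,
    rep(0, 5))
  # equal concentrations at different radii: zero up to amount round-off
  d <- new_droplets(5, c(10, 20, 30, 40, 50), c(glycylglycine = 0.05), sp)
  pop <- droplet_population(d, sp)
  w <- water_exchange_rates(pop)$dV_dt_um3_s
  scale_flux <- 0.01 * 4 * pi * 50^2 * 0.05
  expect_lt(max(abs(w)), 1e-12 * scale_flux)
  # single droplet: mean equals itself
  pop1 <- droplet_population(d[1, ], sp)
  expect_identical(water_exchange_rates(pop1)$dV_dt_um3_s, 0)
  # two 30 um droplets, Pi = {0.05, 0}, k_w = 1:
  # A = 4*pi*900, Pi_bar = 0.025, dV/dt = A * 0.025 = 282.743 um^3/s
  pop2 <- two_droplet_pop(k_w = 1)
  rates <- water_exchange_rates(pop2)$dV_dt_um3_s
  expect_equal(rates, c(282.7433, -282.7433), tolerance = 1e-6)
  # flux balance on an arbitrary polydisperse population
  set.seed(42)
  d3 <- new_droplets(20, runif(20, 10, 50), c(glycylglycine = 0.05), sp)
  d3$glycylglycine <- d3$glycylglycine * runif(20)
  r3 <- water_exchange_rates(droplet_population(d3, sp))$dV_dt_um3_s
  expect_lt(abs(sum(r3)), 1e-9 * sum(abs(r3)))
})

test_that("solute exchange is inverse in molecular weight and conservative", {
  sp <- species(c("light", "heavy", "trapped"),
                molecular_weight = c(100, 200, 100),
                exchangeable = c(TRUE, TRUE, FALSE))
  set.seed(7)
  d <- new_droplets(3, c(20, 30, 40), species = sp)
  v_l <- (4 / 3) * pi * d$radius_um^3 * 1e-15
  conc <- runif(3, 0, 0.05)
  d$light <- conc * v_l
  d$heavy <- conc * v_l # same concentration profile as light
  d$trapped <- runif(3) * 1e-12
  pop <- droplet_population(d, sp)
  rates <- solute_exchange_rates(pop)
  rl <- rates$dn_dt_mol_s[rates$species == "light"]
  rh <- rates$dn_dt_mol_s[rates$species == "heavy"]
  rt <- rates$dn_dt_mol_s[rates$species == "trapped"]
  # trapped species never moves
  expect_identical(rt, rep(0, 3))
  # doubling MW halves every rate at identical concentration fields
  expect_equal(rh, rl / 2, tolerance = 1e-12)
  # per-species flux balance
  expect_lt(abs(sum(rl)), 1e-9 * sum(abs(rl)))
  # equal concentrations: exactly zero
  d$light <- 0.02 * v_l
  pop_eq <- droplet_population(d, sp)
  req <- solute_exchange_rates(pop_eq)
  expect_identical(req$dn_dt_mol_s[req$species == "light"], rep(0, 3))
})

test_that("reaction rates match hand-evaluated mass-action kinetics", {
  chem <- default_chemistry(k_init = 1e-5, k_auto = 2e-3)
  d <- new_droplets(1, 30, species = chem$species)
  v_l <- (4 / 3) * pi * 30^3 * 1e-15
  cm <- 0.04; cp <- 0.002
  d$monomer <- cm * v_l
  d$polymer <- cp * v_l
  pop <- droplet_population(d, chem$species, chem$reactions)
  rates <- reaction_rates(pop)
  # independent hand evaluation of the two rate laws
  rate_init <- 1e-5 * cm^2          # mol/L/s
  rate_auto <- 2e-3 * cm * cp
  exp_m <- -10 * (rate_init + rate_auto) * v_l
  exp_p <- (rate_init + rate_auto) * v_l
  expect_equal(rates$dn_dt_mol_s[rates$species == "monomer"], exp_m,
               tolerance = 1e-12)
  expect_equal(rates$dn_dt_mol_s[rates$species == "polymer"], exp_p,
               tolerance = 1e-12)
  # monomer-equivalent mass change is zero
  expect_equal(exp_m * 132 + exp_p * 1320, 0, tolerance = 1e-25)
  # zero rate constants and zero catalyst concentration give zero rates
  chem0 <- default_chemistry(k_init = 0, k_auto = 0)
  pop0 <- droplet_population(d, chem0$species, chem0$reactions)
  expect_true(all(reaction_rates(pop0)$dn_dt_mol_s == 0))
  d$polymer <- 0 # purely catalytic channel shut off
  chem_cat <- default_chemistry(k_init = 0, k_auto = 2e-3)
  pop_cat <- droplet_population(d, chem_cat$species, chem_cat$reactions)
  expect_true(all(reaction_rates(pop_cat)$dn_dt_mol_s == 0))
})

test_that("reactions referencing unknown species fail at assembly", {
  sp <- species("monomer", 132)
  rx <- list(reaction(c(monomer = 10), c(ghost = 1), 1e-5))
  d <- new_droplets(2, 30, species = sp)
  expect_error(droplet_population(d, sp, rx), "ghost")
  expect_error(reaction(c(a = 2), c(b = 1), 1) |>
                 validate_reaction(species(c("a", "b"), c(100, 150))),
               "mass balanced")
})

test_that("a uniform zero-rate population is an exact fixed point of step", {
  sp <- species("glycylglycine", 132.12, exchangeable = FALSE)
  d <- new_droplets(4, 25, c(glycylglycine = 0.05), sp)
  pop <- droplet_population(d, sp)
  out <- step_dynamics(pop, 10)
  expect_identical(out$droplets$radius_um, pop$droplets$radius_um)
  expect_identical(out$droplets$glycylglycine, pop$droplets$glycylglycine)
  expect_equal(out$time, 10)
})

test_that("step rejects time steps above the stability bound", {
  pop <- two_droplet_pop()
  expect_error(step_dynamics(pop, 2 * stable_dt(pop)), "stability")
})

test_that("halving dt changes radius trajectories by far less than 1%", {
  pop <- mixed_reacting_pop(n = 20, seed = 3)
  horizon <- 4000
  r1 <- incubate(pop, horizon, dt = 40)$population$droplets$radius_um
  r2 <- incubate(pop, horizon, dt = 20)$population$droplets$radius_um
  expect_lt(max(abs(r1 - r2) / r2), 0.01)
})

test_that("two-droplet system transfers all water to the solute droplet", {
  pop <- two_droplet_pop()
  v_total <- total_volume(pop)
  run <- incubate(pop, duration = 2e5, dt = 20, sample_every = 1e4)
  # solute droplet ends with the combined volume (water droplet extinct)
  expect_equal(nrow(run$population$droplets), 1)
  expect_equal(run$population$droplets$id, "d0001")
  expect_equal(total_volume(run$population) / v_total, 1, tolerance = 0.01)
  expect_equal(nrow(run$population$log$extinctions), 1)
  # solute droplet radius trajectory is monotone non-decreasing
  traj <- run$trajectory[run$trajectory$droplet_id == "d0001", ]
  expect_true(all(diff(traj$radius_um) >= 0))
  # agrees with a dt/10 reference integration
  ref <- incubate(pop, duration = 2e5, dt = 2, sample_every = 1e4)
  expect_equal(run$population$droplets$radius_um,
               ref$population$droplets$radius_um, tolerance = 1e-3)
})

test_that("incubation conserves volume, solute totals and monomer mass", {
  pop <- mixed_reacting_pop(n = 30, seed = 5)
  v0 <- total_volume(pop)
  m0 <- monomer_equiv_mass(pop)
  tr0 <- sum(pop$droplets$tracer)
  run <- incubate(pop, duration = 5000, dt = 5)
  fin <- run$population
  expect_equal(nrow(fin$log$extinctions), 0)
  expect_lt(abs(total_volume(fin) / v0 - 1), 1e-7)
  expect_lt(abs(monomer_equiv_mass(fin) / m0 - 1), 1e-7)
  expect_lt(abs(sum(fin$droplets$tracer) / tr0 - 1), 1e-9)
  expect_gt(sum(fin$droplets$polymer), 0) # chemistry actually ran
})

test_that("mixed populations coarsen monotonically; controls do not", {
  mixed <- glygly_population(n = 20)
  run <- incubate(mixed, duration = 7500, dt = 10, sample_every = 500)
  sd_series <- run$summary$s_over_d
  expect_true(all(diff(sd_series) >= 0))
  expect_gt(sd_series[length(sd_series)], sd_series[1])
  # unmixed controls: composition identical, zero exchange at every step
  for (mix in c("glycylglycine", "water")) {
    ctrl <- glygly_population(n = 20, mix = mix)
    crun <- incubate(ctrl, duration = 7500, dt = 10, sample_every = 2500)
    expect_lt(max(abs(crun$summary$s_over_d - crun$summary$s_over_d[1])),
              1e-10)
    expect_identical(water_exchange_rates(crun$population)$dV_dt_um3_s,
                     rep(0, 20))
  }
})

test_that("incubation sampling covers start and end states", {
  pop <- two_droplet_pop()
  run <- incubate(pop, duration = 10, dt = 10)
  expect_equal(nrow(run$summary), 2) # one dt: start + end samples
  expect_equal(run$summary$time_s, c(0, 10))
  expect_equal(unique(run$trajectory$time_s), c(0, 10))
})
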