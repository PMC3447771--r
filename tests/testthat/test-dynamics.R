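test_that("holling2 has the stated limits and arithmetic", {
  expect_equal(holling2(1, 1, 1), 0.5)
  expect_equal(holling2(2, 1, 0), 0)
  # N -> Inf approaches the maximum predation rate 1/g
  expect_lt(abs(holling2(1, 2, 1e9) - 0.5), 1e-6)
  # monotone non-decreasing in N
  N <- seq(0, 50, length.out = 200)
  f <- holling2(1.7, 0.8, N)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f < 1 / 0.8))
  expect_error(holling2(1, 0, 1), "g")
  expect_error(holling2(1, -2, 1), "g")
  expect_error(holling2(-1, 1, 1), "c")
})

test_that("beetle growth replaces both stages from time-t values", {
  p <- model_params()
  st <- random_state(5, 5, seed = 2)
  st$scales[] <- 0
  out <- beetle_growth(st, p)
  expect_true(all(out$adults == 0))
  expect_true(all(out$larvae == 0))

  # decoupled stages: larvae alone produce adults only
  st <- random_state(3, 3, seed = 3)
  st$scales[] <- 0.5; st$larvae[] <- 1; st$adults[] <- 0
  out <- beetle_growth(st, p)
  expect_true(all(out$larvae == 0))
  expect_equal(out$adults[1, 1], p$e * holling2(p$c_L, p$g, 0.5),
               tolerance = 1e-12)

  # ants suppress adult consumption, so larval recruitment is lower there
  st <- random_state(3, 3, seed = 4)
  st$scales[] <- 0.6; st$adults[] <- 1; st$larvae[] <- 0
  st$ants[] <- 0; st$ants[1, 1] <- 1
  out <- beetle_growth(st, p)
  expect_lt(out$larvae[1, 1], out$larvae[2, 2])
})

test_that("ant mortality follows the clamped linear form", {
  # deterministic checks on the probability itself
  p <- update_params(model_params(), d0 = 0.2, d1 = 0.3)
  expect_equal(antscape:::ant_death_prob(p, 1), 0)     # clamp(-0.1) = 0
  expect_equal(antscape:::ant_death_prob(p, 0.5), 0.05)
  p85 <- update_params(model_params(), d0 = 0.85, d1 = 0)
  expect_equal(antscape:::ant_death_prob(p85, 0.7), 0.85)

  # stochastic realization at N = 1 with d0=0.2, d1=0.3: nests never die
  g <- lattice_geometry(50, 40)
  st <- init_state(g, init_spec(p_ant = 1), seed = 9)
  st$scales[] <- 1
  set.seed(10)
  out <- ant_mortality(st, p)
  expect_true(all(out$ants == 1))

  # empirical death frequency matches the linear probability
  st$scales[] <- 0.5
  set.seed(11)
  out <- ant_mortality(st, p)
  deaths <- sum(st$ants) - sum(out$ants)
  bounds <- qbinom(c(0.0005, 0.9995), 2000, 0.05)
  expect_gte(deaths, bounds[1])
  expect_lte(deaths, bounds[2])
})

test_that("ant expansion is a clamped linear function of occupied neighbors", {
  # a0 = 0 and no occupied neighbors: no local colonization, ever
  p <- update_params(model_params(), a0 = 0, a1 = 0.1, m_ant = 0)
  g <- lattice_geometry(10, 10)
  st <- init_state(g, init_spec(p_ant = 0), seed = 1)
  set.seed(2)
  out <- ant_expansion(st, p)
  expect_true(all(out$ants == 0))
  expect_equal(antscape:::ant_birth_prob(p, 8), 0.8)
  expect_equal(antscape:::ant_birth_prob(update_params(p, a0 = 0, a1 = 0.05), 8),
               0.4)

  # supercritical expansion advances one Moore shell per step, deterministically
  p1 <- update_params(model_params(), a0 = 0, a1 = 1, m_ant = 0)
  g5 <- lattice_geometry(5, 5)
  st <- init_state(g5, init_spec(p_ant = 0), seed = 1)
  st$ants[3, 3] <- 1
  set.seed(3)
  st <- ant_expansion(st, p1)
  expect_equal(sum(st$ants), 9)
  expect_true(all(st$ants[2:4, 2:4] == 1))
  set.seed(4)
  st <- ant_expansion(st, p1)
  expect_equal(sum(st$ants), 25)
})

test_that("propagule rain colonizes empty cells independently", {
  g <- lattice_geometry(120, 90)
  st <- init_state(g, init_spec(p_ant = 0), seed = 1)
  p0 <- update_params(model_params(), m_ant = 0)
  set.seed(5)
  expect_equal(ant_propagule_rain(st, p0)$ants, st$ants)
  p1 <- update_params(model_params(), m_ant = 1)
  set.seed(6)
  expect_true(all(ant_propagule_rain(st, p1)$ants == 1))

  # pooled colonization count across replicates is binomially plausible
  pm <- update_params(model_params(), m_ant = 0.001)
  set.seed(7)
  total <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) total <- total + sum(ant_propagule_rain(st, pm)$ants)
  bounds <- qbinom(c(0.005, 0.995), n_rep * 10800, 0.001)
  expect_gte(total, bounds[1])
  expect_lte(total, bounds[2])
})

test_that("local migration conserves mass and honors its parameters", {
  set.seed(20)
  pop <- matrix(runif(12 * 10, 0, 2), 10, 12)
  # mu = 0 is the identity
  out <- local_migration(pop, k_loc = 0.5, mu_loc = 0)
  expect_equal(unclass(out)[, ], pop, ignore_attr = TRUE)

  # conservation at 1e-9 relative tolerance over many random draws
  for (i in 1:50) {
    k <- runif(1, 0, 2); mu <- runif(1)
    out <- local_migration(pop, k, mu)
    expect_lt(abs(sum(out) - sum(pop)), 1e-9 * sum(pop))
    expect_true(all(out >= -1e-15))
  }
  expect_error(local_migration(pop, -1, 0.5), "k_loc")
  expect_error(local_migration(pop, 1, 2), "mu_loc")
})

test_that("local migration drains a lone occupied cell as hand-computed", {
  # single occupied cell on a 3x3 torus: every other cell neighbors it,
  # so all 8 fire (k_loc * S >= 1) and each takes mu_loc of it, rescaled
  pop <- matrix(0, 3, 3)
  pop[2, 2] <- 1
  mu <- 0.3  # demand 8 * 0.3 = 2.4 > 1, so outflows rescale to drain it fully
  set.seed(21)
  out <- local_migration(pop, k_loc = 10, mu_loc = mu)
  expect_equal(out[2, 2], 0, tolerance = 1e-12)
  expect_equal(as.vector(out)[-5], rep(1 / 8, 8), tolerance = 1e-12)

  # sub-saturated demand: each neighbor receives exactly mu_loc of the source
  mu <- 0.1
  set.seed(22)
  out <- local_migration(pop, k_loc = 10, mu_loc = mu)
  expect_equal(out[2, 2], 1 - 8 * mu, tolerance = 1e-12)
  expect_equal(as.vector(out)[-5], rep(mu, 8), tolerance = 1e-12)
})

test_that("global migration redistributes the stated pool", {
  set.seed(23)
  pop <- matrix(runif(9, 0, 2), 3, 3)
  ants <- matrix(0, 3, 3); ants[1, 2] <- 1

  out <- global_migration(pop, ants, 0.5, 0.5, mu_glob = 0)
  expect_equal(unclass(out)[, ], pop, ignore_attr = TRUE)

  # ant-only reception: the whole pool lands on the single nest cell
  set.seed(24)
  out <- global_migration(pop, ants, 1, 0, mu_glob = 0.4)
  pool <- 0.4 * sum(pop)
  expect_equal(out[1, 2], pop[1, 2] * 0.6 + pool, tolerance = 1e-12)
  expect_equal(out[2, 2], pop[2, 2] * 0.6, tolerance = 1e-12)
  expect_equal(sum(out), sum(pop), tolerance = 1e-12)

  # all cells chosen with a uniform start stays uniform
  popu <- matrix(0.7, 4, 5)
  set.seed(25)
  out <- global_migration(popu, matrix(0, 4, 5), 1, 1, mu_glob = 0.5)
  expect_true(all(abs(out - 0.7) < 1e-12))

  # conservation even when nobody is chosen
  set.seed(26)
  out <- global_migration(pop, ants, 0, 0, mu_glob = 0.9)
  expect_equal(sum(out), sum(pop), tolerance = 1e-12)
  expect_error(global_migration(pop, ants, 1.2, 0.5, 0.1), "probabilities")
})

test_that("scale growth follows the Rosenzweig-MacArthur form", {
  p <- update_params(model_params(), r_ant = 0.5, r_noant = 0.4)
  st <- random_state(3, 3, seed = 30)
  st$ants[] <- 1
  st$larvae[] <- 0; st$adults[] <- 0

  st$scales[] <- 0
  expect_true(all(scale_growth(st, p)$scales == 0))  # absorbing zero

  st$scales[] <- 1
  expect_true(all(abs(scale_growth(st, p)$scales - 1) < 1e-12))  # K fixed point

  st$scales[] <- 0.5
  expect_equal(scale_growth(st, p)$scales[1, 1], 0.625, tolerance = 1e-12)

  # heavy predation floors the density at zero
  st$scales[] <- 0.1; st$larvae[] <- 50; st$adults[] <- 50
  expect_true(all(scale_growth(st, p)$scales == 0))
})

test_that("beetle survival thins by habitat", {
  p <- model_params()
  st <- random_state(4, 4, seed = 31)
  p1 <- update_params(p, s_A_ant = 0.999999, s_A_noant = 1, s_L_ant = 1,
                      s_L_noant = 0.999999)
  out <- beetle_survival(st, p1)
  expect_equal(out$adults, st$adults, tolerance = 1e-5)

  p0 <- update_params(p, s_A_ant = 0, s_A_noant = 1e-12, s_L_ant = 1e-12,
                      s_L_noant = 0)
  out <- beetle_survival(st, p0)
  expect_lt(sum(out$adults) + sum(out$larvae), 1e-10)

  # 4:1 larval survival ratio between an ant and an ant-free cell
  p2 <- update_params(p, s_L_ant = 0.8, s_L_noant = 0.2)
  st$ants[] <- 0; st$ants[1, 1] <- 1
  st$larvae[] <- 1
  out <- beetle_survival(st, p2)
  expect_equal(out$larvae[1, 1] / out$larvae[2, 2], 4, tolerance = 1e-12)
})

test_that("a full step leaves the empty state fixed and is deterministic", {
  p <- update_params(model_params(), m_ant = 0)
  g <- lattice_geometry(8, 6)
  st <- init_state(g, init_spec(p_ant = 0, scale_max = 0, larva_max = 0,
                                adult_max = 0), seed = 1)
  set.seed(40)
  out <- model_step(st, p)
  expect_equal(out$state$ants, st$ants)
  expect_true(all(out$state$scales == 0))
  expect_true(all(out$state$larvae == 0))
  expect_true(all(out$state$adults == 0))
  expect_equal(out$state$t, st$t + 1L)

  st2 <- random_state(6, 7, seed = 50)
  p2 <- random_params(51)
  set.seed(52); a <- model_step(st2, p2)$state
  set.seed(52); b <- model_step(st2, p2)$state
  expect_identical(a, b)
})

test_that("adult recruitment respects the saturation bound", {
  # total adults after a step cannot exceed e * (1/g) * total larvae before
  for (seed in 1:10) {
    st <- random_state(5, 5, seed = seed)
    p <- random_params(seed + 100)
    tot_L <- sum(st$larvae)
    set.seed(seed)
    out <- model_step(st, p)$state
    expect_lte(sum(out$adults), p$e * (1 / p$g) * tot_L + 1e-9)
  }
})

test_that("run_model composes steps and records the requested trace", {
  st <- random_state(6, 6, seed = 60)
  p <- random_params(61)
  run0 <- run_model(st, p, n_steps = 0, seed = 62)
  expect_equal(nrow(run0$trace), 1L)
  expect_equal(run0$state$t, 0L)

  run2 <- run_model(st, p, n_steps = 2, seed = 63)
  set.seed(63)
  manual <- model_step(model_step(st, p)$state, p)$state
  expect_identical(run2$state, manual)

  run10 <- run_model(st, p, n_steps = 10, record_every = 3, seed = 64)
  expect_equal(run10$trace$t, c(0, 3, 6, 9, 10))
  expect_true(all(run10$trace$n_nests <= 36))
  expect_true(all(run10$trace[, -1] >= 0))
})
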