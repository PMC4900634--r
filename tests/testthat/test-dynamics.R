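test_that("EEF forces are charge x field with exact masking", {
  st <- make_atoms(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0)),
                   charge = c(1, -0.5, 0), radius = 0)
  f <- eef_forces(st, c(0, 0, 0.2), mask = c(1, 2))
  expect_equal(f$fz[1], 0.2 * 23.0609)
  expect_equal(f$fz[2], -0.5 * 0.2 * 23.0609)
  expect_equal(unlist(f[3, ]), c(fx = 0, fy = 0, fz = 0)) # zero charge
  g <- eef_forces(st, c(0, 0, 0.2), mask = 1)
  expect_identical(unlist(g[2, ]), c(fx = 0, fy = 0, fz = 0)) # outside mask
  # linearity in charge and field
  with_seed(2, {
    for (i in 1:20) {
      q <- rnorm(1); E <- rnorm(3, sd = 0.1); a <- runif(1, 0.5, 3)
      stq <- make_atoms(c(0, 0, 0), charge = q)
      f1 <- unlist(eef_forces(stq, E, 1)[1, ])
      f2 <- unlist(eef_forces(stq, a * E, 1)[1, ])
      sta <- make_atoms(c(0, 0, 0), charge = a * q)
      f3 <- unlist(eef_forces(sta, E, 1)[1, ])
      expect_equal(f2, a * f1, tolerance = 1e-12)
      expect_equal(f3, a * f1, tolerance = 1e-12)
    }
  })
})

test_that("potential energy terms match their closed forms", {
  two <- make_atoms(rbind(c(0, 0, 0), c(1, 0, 0)), charge = 1, radius = 0)
  expect_equal(potential_energy(two)$coulomb, 332.0636)
  # restraint convention E = k d^2: 1 A at k = 20 gives 20 kcal/mol
  one <- make_atoms(c(1, 0, 0))
  ffr <- forcefield(restraints = tibble::tibble(atom = 1, x0 = 0, y0 = 0,
                                                z0 = 0, k = 20))
  expect_equal(potential_energy(one, ffr)$restraint, 20)
  # WCA is exactly zero beyond contact
  apart <- make_atoms(rbind(c(0, 0, 0), c(4.001, 0, 0)), radius = 2)
  expect_identical(potential_energy(apart)$wca, 0)
  touching <- make_atoms(rbind(c(0, 0, 0), c(3.0, 0, 0)), radius = 2)
  expect_gt(potential_energy(touching)$wca, 0)
  # coincident charges are an error
  coin <- make_atoms(rbind(c(0, 0, 0), c(0, 0, 0)), charge = 1)
  expect_error(potential_energy(coin), "diverges")
})

test_that("analytic forces are exact negative gradients (finite differences)", {
  with_seed(7, {
    for (rep in 1:5) {
      n <- 6
      st <- make_atoms(matrix(runif(3 * n, 0, 8), n, 3),
                       charge = rnorm(n), radius = runif(n, 0.5, 1.5),
                       resnum = seq_len(n) * 10) # no exclusions
      ff <- forcefield(eef_field = rnorm(3, sd = 0.05), eef_mask = 1:3,
                       restraints = tibble::tibble(atom = 1, x0 = 0, y0 = 0,
                                                   z0 = 0, k = 5))
      f_ana <- ff_forces(st, ff)
      h <- 1e-5
      for (i in sample(n, 3)) {
        for (d in 1:3) {
          xp <- coords(st); xp[i, d] <- xp[i, d] + h
          xm <- coords(st); xm[i, d] <- xm[i, d] - h
          ep <- potential_energy(set_coords(st, xp), ff)$total
          em <- potential_energy(set_coords(st, xm), ff)$total
          f_num <- -(ep - em) / (2 * h)
          expect_equal(f_ana[i, d], f_num,
                       tolerance = 1e-5 * max(1, abs(f_num)))
        }
      }
    }
  })
})

test_that("zero-temperature dynamics without forces is stationary", {
  st <- make_atoms(rbind(c(0, 0, 0), c(10, 0, 0)))
  cfg <- dynamics_config(n_steps = 200, temperature = 0, save_interval = 0.1,
                         mobile = c(1, 2), rigid_ligand = FALSE)
  tr <- run_dynamics(st, forcefield(), cfg)
  for (fr in tr$frames) expect_identical(fr, unname(coords(st)))
})

test_that("constant force gives the Langevin terminal drift F/(m gamma)", {
  st <- make_atoms(c(0, 0, 0), charge = 1, radius = 0, resname = "LIG")
  ff <- forcefield(eef_field = c(0, 0, 0.2), eef_mask = 1)
  gamma <- 5
  cfg <- dynamics_config(n_steps = 4000, temperature = 0, friction = gamma,
                         save_interval = 4, mobile = 1, rigid_ligand = FALSE)
  tr <- run_dynamics(st, ff, cfg)
  m <- permeakit:::structure_masses(st)
  v_th <- 0.2 * 23.0609 * 418.4 / (m * gamma)
  zs <- vapply(tr$frames, function(fr) fr[1, 3], numeric(1))
  v_obs <- (zs[length(zs)] - zs[length(zs) - 1]) / diff(utils::tail(tr$times, 2))
  expect_equal(v_obs, v_th, tolerance = 0.01)
})

test_that("a harmonic well at 300 K equipartitions (k d^2 convention)", {
  st <- make_atoms(c(0, 0, 0))
  k <- 10
  ff <- forcefield(restraints = tibble::tibble(atom = 1, x0 = 0, y0 = 0,
                                               z0 = 0, k = k))
  cfg <- dynamics_config(n_steps = 120000, temperature = 300,
                         save_interval = 0.1, mobile = 1,
                         rigid_ligand = FALSE, rng_seed = 3)
  tr <- run_dynamics(st, ff, cfg)
  xyz <- t(vapply(tr$frames, function(fr) fr[1, ], numeric(3)))
  v_emp <- mean(apply(xyz, 2, stats::var))
  expect_equal(v_emp, 0.0019872041 * 300 / (2 * k), tolerance = 0.05)
})

test_that("trajectories are bitwise reproducible per seed", {
  st <- make_atoms(matrix(c(0, 0, 0, 6, 0, 0), 2, 3, byrow = TRUE),
                   charge = c(1, -1), radius = 1)
  cfg <- dynamics_config(n_steps = 300, save_interval = 0.5, mobile = 1:2,
                         rigid_ligand = FALSE, rng_seed = 42)
  t1 <- run_dynamics(st, forcefield(), cfg)
  t2 <- run_dynamics(st, forcefield(), cfg)
  expect_identical(t1$frames, t2$frames)
  cfg$rng_seed <- 43L
  t3 <- run_dynamics(st, forcefield(), cfg)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("restraint schedules run phase by phase and are logged", {
  st <- make_atoms(c(3, 0, 0))
  ff <- forcefield(restraints = tibble::tibble(atom = 1, x0 = 0, y0 = 0,
                                               z0 = 0, k = 20))
  phases <- tibble::tibble(n_steps = c(200, 200), k_scale = c(1, 0.05))
  cfg <- dynamics_config(temperature = 0, save_interval = 0.1, mobile = 1,
                         rigid_ligand = FALSE, phases = phases)
  tr <- run_dynamics(st, ff, cfg)
  log <- attr(tr, "log")
  expect_equal(nrow(log), 2L)
  expect_equal(log$t_start_ps, c(0, 2))
  expect_equal(log$k_scale, c(1, 0.05))
  # the restrained bead relaxes toward the reference in phase 1
  mid <- tr$frames[[which.min(abs(tr$times - 2))]][1, 1]
  expect_lt(abs(mid), 0.5)
})

test_that("steric blockage prevents passage through a closed constriction", {
  closed <- build_system(
    channel = channel_spec(pore_constriction_radius = 1.0),
    bath = NULL)
  cfg <- dynamics_config(n_steps = 3000, save_interval = 4)
  res <- run_permeation_protocol(closed, 0, seeds = 1, config = cfg)
  expect_identical(res$n_down, 0L)
  expect_identical(res$first_passage_ps, Inf)
})

test_that("protocol runs are deterministic per seed and distinct across seeds", {
  sysb <- build_system(bath = NULL)
  cfg <- dynamics_config(n_steps = 1500, save_interval = 4)
  r1 <- run_permeation_protocol(sysb, 0.2, seeds = c(1, 2), config = cfg,
                                keep_trajectories = TRUE)
  r2 <- run_permeation_protocol(sysb, 0.2, seeds = 1, config = cfg,
                                keep_trajectories = TRUE)
  expect_identical(r1$trajectory[[1]]$frames, r2$trajectory[[1]]$frames)
  expect_false(identical(r1$trajectory[[1]]$frames, r1$trajectory[[2]]$frames))
})
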