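test_that("kabsch fit recovers constructed rigid motions", {
  with_seed(3, {
    pts <- matrix(rnorm(30), 10, 3)
    tr0 <- kabsch_fit(pts, pts)
    expect_equal(tr0$rotation, diag(3), tolerance = 1e-12)
    expect_equal(tr0$translation, c(0, 0, 0), tolerance = 1e-12)
    expect_equal(tr0$rmsd, 0, tolerance = 1e-12)
    for (i in 1:20) {
      ax <- rnorm(3)
      R <- rotation_from_axis_angle(ax, 72)
      mob <- sweep(pts %*% t(R), 2, rnorm(3, sd = 5), "+")
      fit <- kabsch_fit(mob, pts)
      aa <- axis_angle(fit$rotation)
      expect_equal(aa$angle, 72, tolerance = 1e-8)
      expect_lt(fit$rmsd, 1e-10)
      expect_equal(apply_transform(fit, mob), pts, tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("kabsch enforces proper rotations on mirrored sets", {
  with_seed(4, {
    pts <- matrix(rnorm(24), 8, 3)
    mirrored <- pts
    mirrored[, 3] <- -mirrored[, 3]
    fit <- kabsch_fit(mirrored, pts)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
    expect_equal(max(abs(t(fit$rotation) %*% fit$rotation - diag(3))), 0,
                 tolerance = 1e-10)
    expect_gt(fit$rmsd, 0.1)
  })
  expect_error(kabsch_fit(matrix(0, 2, 3), matrix(0, 2, 3)), "n >= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line), "degenerate")
})

test_that("kabsch residual is a minimum under random perturbations", {
  with_seed(5, {
    pts <- matrix(rnorm(30), 10, 3)
    mob <- sweep(pts %*% t(rotation_from_axis_angle(c(1, 1, 0), 40)),
                 2, c(2, 0, -1), "+") + matrix(rnorm(30, sd = 0.3), 10, 3)
    w <- runif(10)
    fit <- kabsch_fit(mob, pts, weights = w)
    wn <- w / sum(w)
    resid <- function(R, t) {
      moved <- sweep(mob %*% t(R), 2, t, "+")
      sqrt(sum(wn * rowSums((moved - pts)^2)))
    }
    base <- resid(fit$rotation, fit$translation)
    expect_equal(base, fit$rmsd, tolerance = 1e-12)
    for (i in 1:100) {
      dR <- rotation_from_axis_angle(rnorm(3), runif(1, 0.01, 2))
      dt <- rnorm(3, sd = 0.05)
      expect_gte(resid(dR %*% fit$rotation, fit$translation + dt),
                 base - 1e-12)
    }
  })
})

test_that("axis-angle conversion round-trips and handles branches", {
  id <- axis_angle(diag(3))
  expect_equal(id$angle, 0)
  expect_equal(id$axis, c(0, 0, 1)) # convention for the identity
  z27 <- axis_angle(rotation_from_axis_angle(c(0, 0, 1), 27.5))
  expect_equal(z27$angle, 27.5, tolerance = 1e-10)
  expect_equal(z27$axis, c(0, 0, 1), tolerance = 1e-10)
  with_seed(6, {
    for (i in 1:1000) {
      u <- permeakit:::normalize(rnorm(3))
      th <- runif(1, 1e-3, 180 - 1e-3)
      aa <- axis_angle(rotation_from_axis_angle(u, th))
      expect_equal(aa$angle, th, tolerance = 1e-8)
      k <- which.max(abs(aa$axis))
      uu <- if (u[k] < 0) -u else u # axis sign convention
      expect_equal(aa$axis, uu, tolerance = 1e-6)
    }
  })
  near180 <- axis_angle(rotation_from_axis_angle(c(1, 2, -1), 179.9999))
  expect_equal(near180$angle, 179.9999, tolerance = 1e-3)
  expect_error(axis_angle(matrix(2 * diag(3), 3, 3)), "orthogonal")
})

test_that("two-selection RMSD follows the fit-then-measure protocol", {
  st <- build_pentamer(channel_spec())
  xyz <- coords(st)
  # a rigid translation of the whole frame is removed by the fit
  moved <- set_coords(st, sweep(xyz, 2, c(5, -3, 11), "+"))
  r0 <- rmsd_two_selection(moved, st, "name CA", "name CB")
  expect_lt(r0$rmsd_A, 1e-9)
  # fit = measure equals the classic fitted RMSD
  with_seed(8, {
    jitter <- set_coords(st, xyz + matrix(rnorm(length(xyz), sd = 0.4),
                                          ncol = 3))
    fi <- resolve_selection(st, "name CA")
    fit <- kabsch_fit(coords(jitter)[fi, ], xyz[fi, ])
    classic <- sqrt(mean(rowSums(
      (apply_transform(fit, coords(jitter)[fi, ]) - xyz[fi, ])^2)))
    r1 <- rmsd_two_selection(jitter, st, "name CA", "name CA")
    expect_equal(r1$rmsd_A, classic, tolerance = 1e-12)
  })
  # a 2 A domain displacement after a global fit on the rest
  dom <- resolve_selection(st, "monomer 0 and resnum 110:130 and name CA")
  rest <- setdiff(resolve_selection(st, "name CA"), dom)
  x2 <- xyz
  x2[dom, 3] <- x2[dom, 3] + 2
  disp <- set_coords(st, x2)
  r2 <- rmsd_two_selection(disp, st, rest,
                           "monomer 0 and resnum 110:130 and name CA")
  expect_equal(r2$rmsd_A, 2, tolerance = 1e-9)
  r3 <- rmsd_two_selection(disp, st, rest,
                           "monomer 1 and resnum 110:130 and name CA")
  expect_lt(r3$rmsd_A, 1e-9)
  expect_error(rmsd_two_selection(disp, st, "name CA", "resname NOPE"),
               "empty")
})

test_that("per-helix rotation recovers a constructed corkscrew", {
  st <- build_pentamer(channel_spec())
  hsel <- list(S1 = "monomer 0 and resnum 1:12 and name CA",
               TM1 = "monomer 0 and resnum 15:45 and name CA",
               TM2 = "monomer 0 and resnum 76:105 and name CA",
               C = "monomer 0 and resnum 110:130 and name CA")
  same <- helix_rotation(st, st, hsel)
  expect_equal(same$angle_deg, rep(0, 4), tolerance = 1e-4)
  # corkscrew TM1 about its own axis by the mid-transition magnitude
  xyz <- coords(st)
  idx <- resolve_selection(st, hsel$TM1)
  u <- permeakit:::normalize(c(0.05, 0, 0.9987))
  ctr <- colMeans(xyz[idx, ])
  Rc <- rotation_from_axis_angle(u, 16.3)
  x2 <- xyz
  x2[idx, ] <- sweep(sweep(xyz[idx, ], 2, ctr) %*% t(Rc), 2, ctr, "+")
  rot <- helix_rotation(set_coords(st, x2), st, hsel)
  expect_equal(rot$angle_deg[rot$helix == "TM1"], 16.3, tolerance = 1e-6)
  expect_equal(rot$angle_deg[rot$helix != "TM1"], rep(0, 3),
               tolerance = 1e-4)
  # handedness: an axis pointing toward -Z reads as clockwise from +Z
  x3 <- xyz
  Rd <- rotation_from_axis_angle(-u, 16.3)
  x3[idx, ] <- sweep(sweep(xyz[idx, ], 2, ctr) %*% t(Rd), 2, ctr, "+")
  rot3 <- helix_rotation(set_coords(st, x3), st, hsel)
  expect_true(rot3$clockwise_from_periplasm[rot3$helix == "TM1"])
})

test_that("a global rigid rotation shifts every per-helix angle consistently", {
  st <- build_pentamer(channel_spec())
  hsel <- list(TM1 = "monomer 0 and resnum 15:45 and name CA",
               TM2 = "monomer 0 and resnum 76:105 and name CA")
  G <- rotation_from_axis_angle(c(0, 0, 1), 30)
  rotated <- set_coords(st, coords(st) %*% t(G))
  rot <- helix_rotation(rotated, st, hsel) # no global pre-fit by default
  # brute-force oracle: each helix's fitted rotation should equal G exactly
  for (nm in names(hsel)) {
    idx <- resolve_selection(st, hsel[[nm]])
    fit <- kabsch_fit(coords(rotated)[idx, ], coords(st)[idx, ])
    expect_equal(axis_angle(fit$rotation)$angle,
                 rot$angle_deg[rot$helix == nm], tolerance = 1e-9)
    expect_equal(rot$angle_deg[rot$helix == nm], 30, tolerance = 1e-6)
  }
  # with the global pre-fit enabled the common motion is removed
  rot2 <- helix_rotation(rotated, st, hsel, global_prefit = TRUE)
  expect_equal(rot2$angle_deg, rep(0, 2), tolerance = 1e-4)
})

test_that("pore profiling matches analytic ring fixtures", {
  ring <- ring_structure(n = 12, circle_radius = 5, vdw = 1.5, z0 = 0)
  pp <- pore_profile(ring, z_range = c(0, 0), step = 1, r_max = 8)
  expect_equal(pp$radius_A, 3.5, tolerance = 0.05)
  # dense-grid oracle
  xyz <- coords(ring)
  g <- as.matrix(expand.grid(x = seq(-2, 2, 0.1), y = seq(-2, 2, 0.1)))
  oracle <- max(apply(g, 1, function(c2) {
    min(sqrt((c2[1] - xyz[, 1])^2 + (c2[2] - xyz[, 2])^2) - 1.5)
  }))
  expect_equal(pp$radius_A, oracle, tolerance = 0.05)
})

test_that("bottleneck detection counts constructed constrictions", {
  stack <- function(radii, zs) {
    do.call(rbind, lapply(seq_along(zs), function(i)
      coords(ring_structure(12, radii[i], 1.5, zs[i]))))
  }
  # hourglass: wide-narrow-wide -> exactly one bottleneck at the narrow ring
  hour <- make_atoms(stack(c(8, 4, 8), c(-4, 0, 4)), radius = 1.5)
  ph <- pore_profile(hour, z_range = c(-4, 4), step = 1, r_max = 10)
  bh <- bottlenecks(ph)
  expect_equal(nrow(bh), 1L)
  expect_lte(abs(bh$z_A), 1) # within one step of the narrow ring
  # double constriction: the W-shaped profile has exactly two bottlenecks
  w <- make_atoms(stack(c(8, 4, 8, 4.5, 8), c(-20, -15, -8, -2, 4)),
                  radius = 1.5)
  pw <- pore_profile(w, z_range = c(-20, 4), step = 1, r_max = 10)
  bw <- bottlenecks(pw)
  expect_equal(nrow(bw), 2L)
  expect_lte(abs(bw$z_A[1] - (-15)), 1)
  expect_lte(abs(bw$z_A[2] - (-2)), 1)
  # dense-scan oracle for the two minima
  for (i in 1:2) {
    z0 <- c(-15, -2)[i]
    xyz <- coords(w)
    rads <- w$vdw_radius
    g <- as.matrix(expand.grid(x = seq(-1, 1, 0.1), y = seq(-1, 1, 0.1)))
    oracle <- max(apply(g, 1, function(c2) {
      min(sqrt((c2[1] - xyz[, 1])^2 + (c2[2] - xyz[, 2])^2 +
                 (z0 - xyz[, 3])^2) - rads)
    }))
    expect_equal(bw$radius_A[i], oracle, tolerance = 0.05)
  }
})

test_that("pore profiles respect monotonicity and cylinder invariance", {
  cyl <- make_atoms(do.call(rbind, lapply(seq(-6, 6, 1.5), function(z)
    coords(ring_structure(10, 6, 1.5, z)))), radius = 1.5)
  pc <- pore_profile(cyl, z_range = c(-4, 4), step = 1, r_max = 10)
  expect_lt(max(pc$radius_A) - min(pc$radius_A), 0.2) # constant within tol
  # growing one atom's radius can only shrink the profile
  bigger <- cyl
  bigger$vdw_radius[25] <- 2.8
  pb <- pore_profile(bigger, z_range = c(-4, 4), step = 1, r_max = 10)
  expect_true(all(pb$radius_A <= pc$radius_A + 1e-6))
  # empty slab: radius capped at r_max and flagged
  pe <- pore_profile(cyl, z_range = c(100, 100), step = 1, r_max = 10)
  expect_equal(pe$radius_A, 10)
  expect_true(pe$capped)
})

test_that("membrane thickness is the leaflet marker-plane separation", {
  flat <- make_atoms(rbind(c(0, 0, 9), c(5, 0, 9), c(0, 0, -9), c(5, 0, -9)),
                     name = c("PU", "PU", "PL", "PL"), resname = "PC")
  expect_equal(membrane_thickness(flat), 18)
  single <- make_atoms(rbind(c(0, 0, 9), c(0, 0, -9)),
                       name = c("PU", "PL"), resname = "PC")
  expect_identical(membrane_thickness(single), 18)
  with_seed(10, {
    n <- 200
    noisy <- make_atoms(cbind(rnorm(2 * n), rnorm(2 * n),
                              c(9 + runif(n, -0.5, 0.5),
                                -9 + runif(n, -0.5, 0.5))),
                        name = rep(c("PU", "PL"), each = n), resname = "PC")
    expect_equal(membrane_thickness(noisy), 18, tolerance = 0.1)
  })
  expect_error(membrane_thickness(flat, "name NOPE", "name PL"), "empty")
})
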