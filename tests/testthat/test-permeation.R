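# independent crossing oracle: symbolize the series (H >= upper, L <= lower,
# M between), drop the M's, collapse runs, count adjacent H->L / L->H pairs
oracle_crossing_counts <- function(v, upper, lower) {
  s <- ifelse(v >= upper, "H", ifelse(v <= lower, "L", "M"))
  s <- s[s != "M"]
  if (length(s) == 0) return(c(down = 0L, up = 0L))
  r <- rle(s)$values
  c(down = sum(r[-length(r)] == "H" & r[-1] == "L"),
    up = sum(r[-length(r)] == "L" & r[-1] == "H"))
}

test_that("geometric center is the unweighted mean with equivariance", {
  expect_equal(geometric_center(c(1, 2, 3)), c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(geometric_center(rbind(c(1, 0, 0), c(-1, 0, 0))), c(0, 0, 0),
               ignore_attr = TRUE)
  with_seed(1, {
    pts <- matrix(rnorm(30), 10, 3)
    v <- c(3, -2, 7)
    expect_equal(geometric_center(sweep(pts, 2, v, "+")),
                 geometric_center(pts) + v, ignore_attr = TRUE)
  })
  expect_error(geometric_center(matrix(0, 0, 3)), "empty")
})

test_that("delta_z matches its definition, sign convention and oracle", {
  top <- make_atoms(matrix(0, 8, 3), resname = c(rep("LIG", 3), rep("LYS", 5)),
                    name = c(rep("B", 3), rep("CA", 5)),
                    resnum = c(1, 1, 1, 2:6))
  ring_xy <- cbind(5 * cos(2 * pi * (1:5) / 5), 5 * sin(2 * pi * (1:5) / 5), 0)
  mk_frame <- function(lig_z) rbind(matrix(c(0, 0, lig_z), 3, 3, byrow = TRUE),
                                    ring_xy)
  tr <- make_traj(top, list(mk_frame(0), mk_frame(25), mk_frame(-8)))
  dz <- delta_z(tr, "resname LIG", "resname LYS")
  # in the ring plane, 25 A above (an intermediate-state-scale height), below
  expect_equal(dz$delta_z_A, c(0, 25, -8))
  # random-frame brute-force oracle
  with_seed(9, {
    frames <- lapply(1:50, function(k) matrix(rnorm(24, sd = 10), 8, 3))
    tr2 <- make_traj(top, frames)
    dz2 <- delta_z(tr2, "resname LIG", "resname LYS")
    oracle <- vapply(frames, function(fr) {
      s1 <- 0; for (i in 1:3) s1 <- s1 + fr[i, 3]
      s2 <- 0; for (i in 4:8) s2 <- s2 + fr[i, 3]
      s1 / 3 - s2 / 5
    }, numeric(1))
    expect_lt(max(abs(dz2$delta_z_A - oracle)), 1e-9)
    # rigid translation invariance and z-mirror antisymmetry
    shift <- lapply(frames, function(fr) sweep(fr, 2, c(4, -1, 13), "+"))
    dz3 <- delta_z(make_traj(top, shift), "resname LIG", "resname LYS")
    expect_equal(dz3$delta_z_A, dz2$delta_z_A, tolerance = 1e-9)
    mirror <- lapply(frames, function(fr) { fr[, 3] <- -fr[, 3]; fr })
    dz4 <- delta_z(make_traj(top, mirror), "resname LIG", "resname LYS")
    expect_equal(dz4$delta_z_A, -dz2$delta_z_A, tolerance = 1e-9)
  })
  expect_error(delta_z(tr, "resname NOPE", "resname LYS"), "empty")
})

test_that("crossing detection is a hysteresis state machine", {
  mk <- function(v) tibble::tibble(time_ps = seq_along(v) - 1, delta_z_A = v)
  # monotone descent: one downward event
  ev <- detect_crossings(mk(seq(30, -10, by = -2)), 10, -5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "down")
  # t_start is the last sample at/above the upper threshold
  expect_equal(ev$t_start, which(seq(30, -10, by = -2) >= 10)[
    sum(seq(30, -10, by = -2) >= 10)] - 1)
  # four full oscillations: four downward events (and three upward returns)
  osc <- rep(c(30, -10), 4)
  ev2 <- detect_crossings(mk(osc), 10, -5)
  expect_equal(sum(ev2$direction == "down"), 4L)
  expect_equal(sum(ev2$direction == "up"), 3L)
  # a dip that stops short of the lower threshold is not an event
  dip <- c(30, 20, -4.9, 20, 30)
  expect_equal(nrow(detect_crossings(mk(dip), 10, -5)), 0L)
  expect_error(detect_crossings(mk(c(1)), 10, -5), "2 samples")
  expect_error(detect_crossings(mk(osc), -5, 10), "z_upper")
})

test_that("crossing counts agree with an independent automaton on 1000 series", {
  with_seed(21, {
    for (i in 1:1000) {
      v <- cumsum(rnorm(60, sd = 8))
      ev <- detect_crossings(tibble::tibble(time_ps = seq_along(v),
                                            delta_z_A = v), 10, -5)
      oc <- oracle_crossing_counts(v, 10, -5)
      expect_identical(sum(ev$direction == "down"), as.integer(oc["down"]),
                       label = sprintf("series %d down", i))
      expect_identical(sum(ev$direction == "up"), as.integer(oc["up"]),
                       label = sprintf("series %d up", i))
    }
  })
})

test_that("stage segmentation recovers constructed plateaus exactly", {
  dt <- 4 # ps between samples
  dwell_frames <- c(175, 2200, 200, 100) # 0.7, 8.8, 0.8, 0.4 ns at 4 ps
  plateaus <- c(40, 25, 0, -15)
  v <- rep(plateaus, dwell_frames)
  tt <- (seq_along(v) - 1) * dt
  series <- tibble::tibble(time_ps = tt, delta_z_A = v)
  st <- segment_stages(series, bands = c(30, 10, -5))
  expect_equal(nrow(st), 4L)
  expect_equal(st$n_frames, dwell_frames) # run-length oracle
  expect_equal(st$mean_dz, plateaus)
  # the stages partition the window exactly
  expect_equal(st$t_start[1], tt[1])
  expect_equal(st$t_end[4], tt[length(tt)])
  expect_equal(sum(st$dwell_ps), tt[length(tt)] - tt[1])
  expect_equal(st$t_start[-1], st$t_end[-4])
  # constant series: a single stage
  const <- tibble::tibble(time_ps = tt[1:50], delta_z_A = rep(5, 50))
  expect_equal(nrow(segment_stages(const, bands = c(10, 0))), 1L)
  # a one-frame blip is absorbed when min_dwell exceeds the frame spacing
  blip <- v
  blip[500] <- -20
  st2 <- segment_stages(tibble::tibble(time_ps = tt, delta_z_A = blip),
                        bands = c(30, 10, -5), min_dwell = 10)
  expect_equal(nrow(st2), 4L)
  expect_equal(st2$n_frames, dwell_frames)
  expect_error(segment_stages(series, bands = numeric(0)), "empty")
  expect_error(segment_stages(series, bands = c(1, 2)), "decreasing")
})

test_that("stage means annotate per-frame energies when given", {
  v <- rep(c(30, 0), c(10, 10))
  en <- rep(c(-100, -250), c(10, 10))
  st <- segment_stages(tibble::tibble(time_ps = 4 * (0:19), delta_z_A = v),
                       energies = en, bands = 15)
  expect_equal(st$mean_energy, c(-100, -250))
})

test_that("ion displacement matches endpoint and mean conventions", {
  top <- make_atoms(matrix(0, 4, 3), resname = "K", name = "K", element = "K",
                    resnum = 1:4)
  static <- make_traj(top, replicate(3, matrix(1, 4, 3), simplify = FALSE))
  d0 <- ion_displacement(static, "resname K")
  expect_equal(d0$dz_A, rep(0, 4))
  shifted <- make_traj(top, list(matrix(1, 4, 3),
                                 cbind(rep(1, 4), 1, 1 - 6))) # all ions -6 A
  d1 <- ion_displacement(shifted, "resname K")
  expect_equal(attr(d1, "mean_dz"), -6)
  with_seed(13, {
    frames <- lapply(1:20, function(k) matrix(rnorm(12), 4, 3))
    tr <- make_traj(top, frames)
    d2 <- ion_displacement(tr, "resname K")
    expect_equal(d2$dz_A, frames[[20]][, 3] - frames[[1]][, 3])
    d3 <- ion_displacement(tr, "resname K", mode = "mean")
    zmat <- sapply(frames, function(fr) fr[, 3])
    expect_equal(d3$dz_A, rowMeans(zmat) - frames[[1]][, 3])
    # window validation
    expect_error(ion_displacement(tr, "resname K", window = c(1, 50)),
                 "window")
  })
})

test_that("contact numbers use an inclusive threshold and match brute force", {
  # one target residue per 'monomer', hydrophobic lipid residues around it
  top <- pk_structure(tibble::tibble(
    atom_name = c("CB", "CB", "C2", "C2", "C3"),
    residue_name = c("ASN", "ASN", "PA", "PA", "OL"),
    residue_number = c(103L, 239L, 500L, 501L, 502L),
    monomer_index = c(0L, 1L, -1L, -1L, -1L),
    element = "C", x = 0, y = 0, z = 0, charge = 0, vdw_radius = 2))
  mk <- function(d1) rbind(c(0, 0, 0), c(50, 0, 0),
                           c(d1, 0, 0), c(20, 0, 0), c(50, 6.5, 0))
  tr <- make_traj(top, list(mk(6.5), mk(6.500001)))
  cn <- contact_number(tr, target_resnum = 103, threshold = 6.5)
  c103 <- cn[cn$monomer == 0, ]
  expect_equal(c103$count, c(1L, 0L)) # exactly-at-threshold counts; beyond not
  c239 <- cn[cn$monomer == 1, ]
  expect_equal(c239$count, c(1L, 1L)) # the OL residue at exactly 6.5
  # no flagged residues is an error
  bare <- pk_structure(tibble::as_tibble(top)[1:2, ])
  expect_error(contact_number(make_traj(bare, list(matrix(0, 2, 3))), 103),
               "hydrophobic")
})

test_that("contact numbers equal an O(n^2) oracle on random frames", {
  with_seed(31, {
    n_lip <- 30
    top <- pk_structure(tibble::tibble(
      atom_name = c(rep("CB", 2), rep("C2", n_lip)),
      residue_name = c("ASN", "ASN", rep(c("PA", "OL"), n_lip / 2)),
      residue_number = c(103L, 239L, 500L + seq_len(n_lip)),
      monomer_index = c(0L, 1L, rep(-1L, n_lip)),
      element = "C", x = 0, y = 0, z = 0, charge = 0, vdw_radius = 2))
    frames <- lapply(1:100, function(k) matrix(rnorm(3 * (n_lip + 2), sd = 6),
                                               n_lip + 2, 3))
    tr <- make_traj(top, frames)
    cn <- contact_number(tr, 103, threshold = 6.5)
    for (k in c(1, 17, 50, 100)) {
      fr <- frames[[k]]
      for (m in 0:1) {
        cnt <- 0L
        for (j in 3:(n_lip + 2)) {
          d <- sqrt(sum((fr[m + 1, ] - fr[j, ])^2))
          if (d <= 6.5) cnt <- cnt + 1L
        }
        expect_identical(cn$count[cn$frame == k & cn$monomer == m], cnt)
      }
    }
    # monotone non-decreasing in the threshold
    cn_small <- contact_number(tr, 103, threshold = 5)
    cn_large <- contact_number(tr, 103, threshold = 8)
    expect_true(all(cn_small$count <= cn$count))
    expect_true(all(cn$count <= cn_large$count))
    # frame-average agreement with direct recomputation
    g <- glance(cn)
    man <- mean(vapply(seq_along(frames), function(k) {
      fr <- frames[[k]]
      sum(sqrt(colSums((t(fr[3:(n_lip + 2), ]) - fr[1, ])^2)) <= 6.5)
    }, numeric(1)))
    expect_equal(g$mean_count[g$monomer == 0], man, tolerance = 1e-12)
  })
})

test_that("permeation reports bundle series, events and stages", {
  top <- make_atoms(matrix(0, 8, 3), resname = c(rep("LIG", 3), rep("LYS", 5)),
                    name = c(rep("B", 3), rep("CA", 5)),
                    resnum = c(1, 1, 1, 2:6))
  zpath <- c(30, 28, 25, 20, 10, 0, -8, -12)
  frames <- lapply(zpath, function(z) rbind(matrix(c(0, 0, z), 3, 3,
                                                   byrow = TRUE),
                                            cbind(rep(1, 5), 1, 0)))
  tr <- make_traj(top, frames)
  rep <- permeation_report(tr, "resname LIG", "resname LYS",
                           z_upper = 10, z_lower = -5, bands = c(15, 5))
  expect_equal(glance(rep)$n_down, 1L)
  expect_equal(rep$first_passage_ps, 6)
  expect_equal(nrow(rep$stages), 3L)
})
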