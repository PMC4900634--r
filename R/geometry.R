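#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) squared deviation of `mobile` onto `reference`. Reflections
#' are corrected, so the returned rotation always has determinant +1.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3,
#'   non-degenerate.
#' @param weights Optional non-negative per-point weights.
#' @return A `pk_rigid_transform`: list with `rotation` (3 x 3),
#'   `translation` (3-vector) and `rmsd` (the residual, A).
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  mobile <- rbind(mobile)
  reference <- rbind(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n) {
    abort("kabsch_fit needs matching point sets with n >= 3")
  }
  w <- if (is.null(weights)) rep(1, n) else weights
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    abort("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  if (sv$d[2] < 1e-12) abort("degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd),
            class = "pk_rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform A `pk_rigid_transform`.
#' @param xyz n x 3 coordinates.
#' @return Transformed n x 3 coordinates.
#' @export
apply_transform <- function(transform, xyz) {
  sweep(rbind(xyz) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' @export
tidy.pk_rigid_transform <- function(x, ...) {
  aa <- axis_angle(x$rotation)
  tibble(angle_deg = aa$angle, axis_x = aa$axis[1], axis_y = aa$axis[2],
         axis_z = aa$axis[3], tx = x$translation[1], ty = x$translation[2],
         tz = x$translation[3], rmsd = x$rmsd)
}

#' Axis-angle representation of a rotation matrix
#'
#' Angle in degrees in \[0, 180\] from `acos((trace - 1)/2)`; the axis comes
#' from the antisymmetric part away from the branch points, from the
#' symmetric part near 180 deg, and is reported as (0, 0, 1) by convention
#' for the identity. The axis sign is fixed so its largest-magnitude
#' component is positive.
#'
#' @param rotation A 3 x 3 proper orthogonal matrix.
#' @param tol Orthogonality tolerance.
#' @return A list: `axis` (unit 3-vector), `angle` (degrees).
#' @export
axis_angle <- function(rotation, tol = 1e-6) {
  R <- rotation
  if (max(abs(t(R) %*% R - diag(3))) > tol || abs(det(R) - 1) > tol) {
    abort("input is not a proper orthogonal matrix within tolerance")
  }
  ctheta <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  theta <- acos(ctheta)
  if (theta < 1e-8) {
    return(list(axis = c(0, 0, 1), angle = 0))
  }
  if (pi - theta > 1e-4) {
    a <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(theta))
  } else {
    # near 180 deg: axis from the symmetric part R ~ 2aa^T - I
    S <- (R + diag(3)) / 2
    a <- sqrt(pmax(diag(S), 0))
    k <- which.max(a)
    if (a[k] > 0) {
      for (j in seq_len(3)[-k]) a[j] <- S[k, j] / a[k]
    }
  }
  a <- a / sqrt(sum(a^2))
  k <- which.max(abs(a))
  if (a[k] < 0) a <- -a
  list(axis = as.numeric(a), angle = theta * 180 / pi)
}

#' Build a rotation matrix from an axis and angle
#' @param axis 3-vector (normalized internally).
#' @param angle_deg Angle in degrees.
#' @return A 3 x 3 rotation matrix (Rodrigues formula).
#' @export
rotation_from_axis_angle <- function(axis, angle_deg) {
  u <- normalize(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Two-selection RMSD (fit on one set, measure on another)
#'
#' Each frame is superposed on the reference using `fit_sel` only (a global
#' alpha-carbon fit, typically); the RMSD is then computed over
#' `measure_sel` directly, without re-fitting. With
#' `measure_sel = fit_sel` this reduces to the classic fitted RMSD.
#'
#' @param x A [pk_trajectory()] or [pk_structure()] (single frame).
#' @param reference A [pk_structure()].
#' @param fit_sel Selection used for the superposition.
#' @param measure_sel Selection over which the RMSD is measured.
#' @return A tibble: `frame`, `time_ps`, `rmsd_A` (one row for a single
#'   structure).
#' @export
rmsd_two_selection <- function(x, reference, fit_sel, measure_sel) {
  if (inherits(x, "pk_structure")) {
    x <- pk_trajectory(x, list(coords(x)), times = 0)
  }
  top <- x$topology
  fi <- resolve_selection(top, fit_sel, allow_empty = FALSE)
  mi <- resolve_selection(top, measure_sel, allow_empty = FALSE)
  fr <- resolve_selection(reference, fit_sel, allow_empty = FALSE)
  mr <- resolve_selection(reference, measure_sel, allow_empty = FALSE)
  if (length(fi) != length(fr) || length(mi) != length(mr)) {
    abort("selection sizes differ between frame and reference")
  }
  ref_xyz <- coords(reference)
  vals <- vapply(x$frames, function(frm) {
    tr <- kabsch_fit(frm[fi, , drop = FALSE], ref_xyz[fr, , drop = FALSE])
    moved <- apply_transform(tr, frm[mi, , drop = FALSE])
    sqrt(mean(rowSums((moved - ref_xyz[mr, , drop = FALSE])^2)))
  }, numeric(1))
  tibble(frame = seq_along(vals), time_ps = x$times, rmsd_A = vals)
}

#' Per-helix rotation relative to a reference conformation
#'
#' For each named helix selection, fits the conformation's helix directly
#' onto the reference's (no global pre-alignment) and reports the rotation
#' as an axis-angle pair, plus the handedness attribute
#' `clockwise_from_periplasm`: with +Z periplasmic, a rotation whose
#' (unnormalized) axis points toward -Z appears clockwise when viewed from
#' the periplasmic side. The handedness comes from the raw antisymmetric
#' part of the rotation, since the reported axis is sign-normalized.
#'
#' @param conformation,reference [pk_structure()]s with identical helix
#'   selections.
#' @param helix_selections Named list of selections (e.g. TM1 alpha-carbons
#'   of one monomer).
#' @param global_prefit If `TRUE`, superpose the whole conformation on the
#'   reference (using all helix atoms) before the per-helix fits. Off by
#'   default: per-helix direct fits.
#' @return A tibble: `helix`, `angle_deg`, `axis_x/y/z`, `rmsd_A`,
#'   `clockwise_from_periplasm`.
#' @export
helix_rotation <- function(conformation, reference, helix_selections,
                           global_prefit = FALSE) {
  conf_xyz <- coords(conformation)
  ref_xyz <- coords(reference)
  if (global_prefit) {
    all_c <- sort(unique(unlist(lapply(helix_selections, function(s)
      resolve_selection(conformation, s, allow_empty = FALSE)))))
    all_r <- sort(unique(unlist(lapply(helix_selections, function(s)
      resolve_selection(reference, s, allow_empty = FALSE)))))
    tr <- kabsch_fit(conf_xyz[all_c, , drop = FALSE],
                     ref_xyz[all_r, , drop = FALSE])
    conf_xyz <- apply_transform(tr, conf_xyz)
  }
  purrr::map_dfr(names(helix_selections), function(nm) {
    ci <- resolve_selection(conformation, helix_selections[[nm]],
                            allow_empty = FALSE)
    ri <- resolve_selection(reference, helix_selections[[nm]],
                            allow_empty = FALSE)
    if (length(ci) != length(ri)) {
      abort(sprintf("helix '%s' resolves to different sizes", nm))
    }
    tr <- kabsch_fit(conf_xyz[ci, , drop = FALSE],
                     ref_xyz[ri, , drop = FALSE])
    aa <- axis_angle(tr$rotation)
    # handedness of the physical motion (reference -> conformation), which
    # is the inverse of the fitted mobile->reference rotation; taken from
    # the raw antisymmetric part because axis_angle() sign-normalizes the
    # reported axis, which would erase the sense of rotation
    motion_axis_z <- t(tr$rotation)[2, 1] - t(tr$rotation)[1, 2]
    tibble(helix = nm, angle_deg = aa$angle, axis_x = aa$axis[1],
           axis_y = aa$axis[2], axis_z = aa$axis[3], rmsd_A = tr$rmsd,
           clockwise_from_periplasm = motion_axis_z < 0 & aa$angle > 1e-9)
  })
}

#' Pore-radius profile along the channel axis
#'
#' At each sampled z, the pore radius is the radius of the largest sphere
#' whose center lies in the slice plane near the axis and which touches no
#' atom's van der Waals sphere: `max over (cx, cy) of min_i(|c - x_i| -
#' r_i)`, found from a deterministic seed grid in XY refined by
#' Nelder-Mead descent, and capped at `r_max`. Unlike full HOLE-style
#' profiling, the center is constrained to the slice plane and to within
#' `center_max_offset` of the axis, which keeps the search deterministic
#' for near-axial pores. Bottlenecks are strict local minima of the sampled
#' profile (leftmost sample of a flat minimum) below
#' `bottleneck_max_radius`.
#'
#' @param structure A [pk_structure()] with vdW radii.
#' @param z_range `c(zmin, zmax)` (A).
#' @param step Sampling step along z (A), > 0.
#' @param r_max Radius cap (A).
#' @param center_max_offset Maximum distance of the sphere center from the
#'   Z axis (A).
#' @param seed_extent,seed_step Seed-grid half-width and spacing in XY (A).
#' @param bottleneck_max_radius Only minima below this radius are reported
#'   as bottlenecks.
#' @return A `pk_pore_profile` tibble: `z_A`, `radius_A`, `capped`;
#'   attribute `bottlenecks` is a tibble `z_A`, `radius_A`.
#' @export
pore_profile <- function(structure, z_range = c(-60, 0), step = 1,
                         r_max = 10, center_max_offset = 5,
                         seed_extent = 3, seed_step = 1.5,
                         bottleneck_max_radius = r_max) {
  if (step <= 0) abort("step must be > 0")
  zs <- seq(z_range[1], z_range[2], by = step)
  xyz <- coords(structure)
  rad <- structure$vdw_radius
  seeds <- as.matrix(expand.grid(
    cx = seq(-seed_extent, seed_extent, by = seed_step),
    cy = seq(-seed_extent, seed_extent, by = seed_step)))
  max_r <- max(rad)
  res <- purrr::map_dfr(zs, function(z) {
    near <- which(abs(xyz[, 3] - z) <= r_max + max_r)
    if (length(near) == 0L) {
      return(tibble(z_A = z, radius_A = r_max, capped = TRUE))
    }
    ax <- xyz[near, 1]; ay <- xyz[near, 2]
    adz2 <- (xyz[near, 3] - z)^2
    ar <- rad[near]
    obj <- function(c2) {
      if (sum(c2^2) > center_max_offset^2) return(1e6) # outside search disc
      -min(sqrt((c2[1] - ax)^2 + (c2[2] - ay)^2 + adz2) - ar)
    }
    best <- -Inf
    for (s in seq_len(nrow(seeds))) {
      v0 <- -obj(seeds[s, ])
      if (v0 <= -1e5) next
      opt <- stats::optim(seeds[s, ], obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 400))
      if (-opt$value > best) best <- -opt$value
      if (v0 > best) best <- v0
    }
    r <- max(best, 0)
    tibble(z_A = z, radius_A = min(r, r_max), capped = r >= r_max)
  })
  rr <- rle(res$radius_A)
  starts <- cumsum(rr$lengths) - rr$lengths + 1L
  bn <- list()
  for (k in seq_along(rr$values)) {
    if (k == 1L || k == length(rr$values)) next
    if (rr$values[k] < rr$values[k - 1L] && rr$values[k] < rr$values[k + 1L] &&
        rr$values[k] < bottleneck_max_radius) {
      i <- starts[k] # leftmost sample of a flat minimum
      bn[[length(bn) + 1L]] <- tibble(z_A = res$z_A[i],
                                      radius_A = res$radius_A[i])
    }
  }
  out <- res
  class(out) <- c("pk_pore_profile", class(out))
  attr(out, "bottlenecks") <- if (length(bn) > 0) bind_rows(bn) else
    tibble(z_A = numeric(0), radius_A = numeric(0))
  out
}

#' Bottlenecks of a pore profile
#' @param profile A `pk_pore_profile`.
#' @return Tibble `z_A`, `radius_A` of the detected local minima.
#' @export
bottlenecks <- function(profile) {
  attr(profile, "bottlenecks", exact = TRUE)
}

#' @export
glance.pk_pore_profile <- function(x, ...) {
  bn <- bottlenecks(x)
  tibble(min_radius_A = min(x$radius_A),
         z_at_min_A = x$z_A[which.min(x$radius_A)],
         n_bottlenecks = nrow(bn))
}

#' Membrane thickness from leaflet marker atoms
#'
#' Mean z of the upper markers minus mean z of the lower markers — the
#' simple estimator behind an implicit-slab thickness setting (an 18-A slab
#' stands in for a phospholipid bilayer whose leaflet-marker separation
#' averages about 18 A in all-atom practice).
#'
#' @param structure A [pk_structure()].
#' @param upper_sel,lower_sel Selections of the upper/lower leaflet marker
#'   atoms (defaults match the synthetic lipids' `PU`/`PL` head markers).
#' @return Thickness (A).
#' @export
membrane_thickness <- function(structure, upper_sel = "name PU",
                               lower_sel = "name PL") {
  ui <- resolve_selection(structure, upper_sel, allow_empty = FALSE)
  li <- resolve_selection(structure, lower_sel, allow_empty = FALSE)
  mean(structure$z[ui]) - mean(structure$z[li])
}
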