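#' Implicit-membrane slab dielectric specification
#'
#' Dielectric environment for the finite-difference Poisson solve: solute
#' interior `eps_solute` (inside any atom's vdW sphere), a membrane slab of
#' `eps_membrane` of the given `thickness` centered `z_offset` above the
#' solute geometric center, and `eps_water` elsewhere. The standard values
#' for a membrane protein are 80 (water) and 4 (membrane) with an 18-A
#' slab; the per-conformation `z_offset` (the "mctrdz" grid-center shift)
#' aligns the slab with the membrane center when the solute center and the
#' membrane center differ — see [compute_mctrdz()]. `thickness = 0` turns
#' the slab off (uniform solvent).
#'
#' @param eps_water,eps_membrane,eps_solute Dielectric constants (> 0).
#' @param thickness Slab thickness (A); 0 for no slab.
#' @param z_offset Slab center relative to the solute geometric center (A).
#' @return A `pk_slab_spec` list.
#' @export
slab_dielectric_spec <- function(eps_water = 80, eps_membrane = 4,
                                 eps_solute = 1, thickness = 18,
                                 z_offset = 0) {
  if (any(c(eps_water, eps_membrane, eps_solute) <= 0)) {
    abort("dielectric constants must be > 0")
  }
  if (thickness < 0) abort("thickness must be >= 0")
  structure(list(eps_water = eps_water, eps_membrane = eps_membrane,
                 eps_solute = eps_solute, thickness = thickness,
                 z_offset = z_offset),
            class = "pk_slab_spec")
}

#' Membrane-center grid offset (mctrdz)
#'
#' The Z offset between the membrane center and the solute geometric
#' center: `z(gc(membrane markers)) - z(gc(solute))`. Computed per
#' conformation and used to shift the dielectric slab (equivalently, the
#' grid center) so it tracks the membrane rather than the solute.
#'
#' @param structure A [pk_structure()].
#' @param membrane_marker_sel Selection of membrane marker atoms (default:
#'   both leaflet head markers of the synthetic lipids).
#' @param solute_sel Selection defining the solute center (default: protein
#'   plus ligand).
#' @return Offset (A).
#' @export
compute_mctrdz <- function(structure,
                           membrane_marker_sel = "name PU or name PL",
                           solute_sel = "monomer 0:100 or resname LIG") {
  mi <- resolve_selection(structure, membrane_marker_sel, allow_empty = FALSE)
  si <- resolve_selection(structure, solute_sel, allow_empty = FALSE)
  mean(structure$z[mi]) - mean(structure$z[si])
}

#' Build the finite-difference grid and dielectric map
#'
#' A regular grid enclosing the structure plus `buffer` on all sides. Node
#' dielectrics are `eps_solute` inside any solute sphere, `eps_membrane`
#' in the slab, `eps_water` elsewhere; the solver uses harmonic-mean edge
#' dielectrics between adjacent nodes. Atom charges are spread onto the
#' grid trilinearly.
#'
#' @param structure A [pk_structure()] with charges and radii.
#' @param spec A [slab_dielectric_spec()].
#' @param spacing Grid spacing (A).
#' @param buffer Clearance between the structure and the grid edge (A).
#' @return A `pk_pb_grid`: list with `origin`, `spacing`, `dims`, `eps`
#'   (node dielectrics), `charge` (node charges, e), `slab_z` and the atom
#'   table used.
#' @export
build_dielectric_map <- function(structure, spec = slab_dielectric_spec(),
                                 spacing = 0.5, buffer = 10) {
  if (spacing <= 0) abort("spacing must be > 0")
  xyz <- coords(structure)
  lo <- apply(xyz - structure$vdw_radius, 2, min) - buffer
  hi <- apply(xyz + structure$vdw_radius, 2, max) + buffer
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  if (any(dims < 8L)) abort("grid too small; increase buffer or reduce spacing")
  origin <- lo
  slab_z <- if (spec$thickness > 0) {
    ctr <- mean(xyz[, 3]) + spec$z_offset
    c(ctr - spec$thickness / 2, ctr + spec$thickness / 2)
  } else c(1, -1) # empty slab
  eps <- eps_node_map_cpp(dims, origin, spacing, xyz, structure$vdw_radius,
                          spec$eps_solute, spec$eps_membrane, spec$eps_water,
                          slab_z[1], slab_z[2])
  qn <- spread_charges(structure, origin, spacing, dims)
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 eps = eps, charge = qn, slab_z = slab_z,
                 atoms = structure, spec = spec),
            class = "pk_pb_grid")
}

spread_charges <- function(structure, origin, spacing, dims) {
  qn <- numeric(prod(dims))
  idx <- which(structure$charge != 0)
  for (a in idx) {
    g <- (c(structure$x[a], structure$y[a], structure$z[a]) - origin) / spacing
    i0 <- pmin(pmax(floor(g), 0), dims - 2)
    f <- g - i0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) f[1] else 1 - f[1]) *
           (if (dj) f[2] else 1 - f[2]) *
           (if (dk) f[3] else 1 - f[3])
      p <- (i0[1] + di) + dims[1] * ((i0[2] + dj) + dims[2] * (i0[3] + dk))
      qn[p + 1] <- qn[p + 1] + w * structure$charge[a]
    }
  }
  qn
}

#' Solve the finite-difference Poisson equation on a grid
#'
#' 7-point stencil with harmonic-mean edge dielectrics and
#' Jacobi-preconditioned conjugate gradients; the Dirichlet boundary is the
#' analytic Coulomb potential in a uniform dielectric `eps_boundary`.
#' Zero ionic strength (pure Poisson).
#'
#' @param grid A `pk_pb_grid` from [build_dielectric_map()].
#' @param eps_boundary Uniform dielectric for the analytic boundary
#'   condition (defaults to the water dielectric of the grid's spec).
#' @param tol Relative residual tolerance.
#' @param maxit Maximum CG iterations.
#' @return The grid with `$phi` (node potentials, kcal/(mol*e)) and
#'   `$iterations` added.
#' @export
solve_poisson <- function(grid, eps_boundary = NULL, tol = 1e-8,
                          maxit = 5000L) {
  kc <- pk_constants()$coulomb
  if (is.null(eps_boundary)) eps_boundary <- grid$spec$eps_water
  xyz <- coords(grid$atoms)
  phi0 <- boundary_phi_cpp(grid$dims, grid$origin, grid$spacing, xyz,
                           grid$atoms$charge, kc, eps_boundary)
  b <- 4 * pi * kc * grid$charge / grid$spacing
  sol <- pb_solve_cpp(grid$dims, grid$eps, b, phi0, tol, as.integer(maxit))
  if (!sol$converged) {
    abort(paste0("Poisson solver did not converge; residual history: ",
                 paste(utils::tail(signif(sol$history, 3), 8), collapse = ", ")))
  }
  grid$phi <- sol$phi
  grid$iterations <- sol$iterations
  grid
}

#' Trilinear interpolation of the grid potential
#' @param grid A solved `pk_pb_grid` (with `$phi`).
#' @param points n x 3 matrix of positions (A).
#' @return Potential at each point (kcal/(mol*e)).
#' @export
interpolate_potential <- function(grid, points) {
  if (is.null(grid$phi)) abort("grid has no potential; run solve_poisson()")
  points <- rbind(points)
  dims <- grid$dims
  out <- numeric(nrow(points))
  for (n in seq_len(nrow(points))) {
    g <- (points[n, ] - grid$origin) / grid$spacing
    i0 <- pmin(pmax(floor(g), 0), dims - 2)
    f <- g - i0
    val <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) f[1] else 1 - f[1]) *
           (if (dj) f[2] else 1 - f[2]) *
           (if (dk) f[3] else 1 - f[3])
      p <- (i0[1] + di) + dims[1] * ((i0[2] + dj) + dims[2] * (i0[3] + dk))
      val <- val + w * grid$phi[p + 1]
    }
    out[n] <- val
  }
  out
}

#' Polar (reaction-field) solvation energy
#'
#' Two finite-difference solves on the same grid: one with the
#' slab-plus-solute dielectric environment and one with the uniform solute
#' dielectric. The energy is `1/2 * sum q_i (phi_env(r_i) - phi_ref(r_i))`;
#' the grid self-energy of the spread charges cancels in the difference.
#'
#' @param structure A [pk_structure()] with charges and radii.
#' @param spec A [slab_dielectric_spec()].
#' @param spacing,buffer Grid parameters (see [build_dielectric_map()]).
#' @param tol,maxit Solver parameters.
#' @return `E_PB` (kcal/mol), with the two solved grids attached as
#'   attributes `grid_env` and `grid_ref`.
#' @export
pb_energy <- function(structure, spec = slab_dielectric_spec(),
                      spacing = 0.5, buffer = 10, tol = 1e-8, maxit = 5000L) {
  if (all(structure$charge == 0)) return(structure(0, grid_env = NULL,
                                                   grid_ref = NULL))
  grid_env <- build_dielectric_map(structure, spec, spacing, buffer)
  grid_env <- solve_poisson(grid_env, eps_boundary = spec$eps_water,
                            tol = tol, maxit = maxit)
  ref_spec <- spec
  ref_spec$thickness <- 0
  ref_spec$eps_water <- spec$eps_solute
  ref_spec$eps_membrane <- spec$eps_solute
  grid_ref <- build_dielectric_map(structure, ref_spec, spacing, buffer)
  grid_ref <- solve_poisson(grid_ref, eps_boundary = spec$eps_solute,
                            tol = tol, maxit = maxit)
  pts <- coords(structure)[structure$charge != 0, , drop = FALSE]
  qs <- structure$charge[structure$charge != 0]
  dphi <- interpolate_potential(grid_env, pts) -
    interpolate_potential(grid_ref, pts)
  e <- 0.5 * sum(qs * dphi)
  structure(e, grid_env = grid_env, grid_ref = grid_ref)
}

#' Total MM-PB energy
#'
#' The molecular-mechanics energy (Coulomb + WCA + restraints; the EEF
#' driving term is excluded) plus the polar solvation energy from the
#' finite-difference Poisson solve. No nonpolar surface-area term is
#' included.
#'
#' @param structure A [pk_structure()].
#' @param ff A [forcefield()].
#' @param spec A [slab_dielectric_spec()].
#' @param ... Grid/solver parameters passed to [pb_energy()].
#' @return A one-row tibble: `e_mm`, `e_pb`, `total` (kcal/mol).
#' @export
mm_pb_total <- function(structure, ff = forcefield(),
                        spec = slab_dielectric_spec(), ...) {
  pe <- potential_energy(structure, ff)
  e_mm <- pe$coulomb + pe$wca + pe$restraint
  e_pb <- as.numeric(pb_energy(structure, spec, ...))
  tibble(e_mm = e_mm, e_pb = e_pb, total = e_mm + e_pb)
}

#' Per-frame MM-PB energies of a trajectory
#'
#' Evaluates [mm_pb_total()] on a (sub)system extracted from each selected
#' frame; the dielectric slab follows each frame's membrane center when
#' `mctrdz` is `TRUE` and the topology has leaflet markers.
#'
#' @param trajectory A [pk_trajectory()].
#' @param subsystem_sel Selection of atoms to include in the energy
#'   evaluation (default: protein plus ligand).
#' @param frames Frame indices to evaluate (default: all).
#' @param ff A [forcefield()].
#' @param spec A [slab_dielectric_spec()].
#' @param mctrdz Recompute the slab offset per frame from the lipid
#'   markers.
#' @param ... Grid/solver parameters passed to [pb_energy()].
#' @return A tibble: `frame`, `time_ps`, `e_mm`, `e_pb`, `total`.
#' @export
mm_pb_series <- function(trajectory,
                         subsystem_sel = "monomer 0:100 or resname LIG",
                         frames = NULL, ff = forcefield(),
                         spec = slab_dielectric_spec(), mctrdz = TRUE, ...) {
  top <- trajectory$topology
  idx <- resolve_selection(top, subsystem_sel, allow_empty = FALSE)
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))
  has_markers <- any(top$atom_name %in% c("PU", "PL"))
  purrr::map_dfr(frames, function(k) {
    st <- frame_structure(trajectory, k)
    sub <- pk_structure(as_tibble(st)[idx, ], monomer_offset = monomer_offset(top))
    fr_spec <- spec
    if (mctrdz && has_markers) {
      mi <- which(top$atom_name %in% c("PU", "PL"))
      fr_spec$z_offset <- mean(trajectory$frames[[k]][mi, 3]) -
        mean(trajectory$frames[[k]][idx, 3])
    }
    e <- mm_pb_total(sub, ff, fr_spec, ...)
    tibble(frame = k, time_ps = trajectory$times[k],
           e_mm = e$e_mm, e_pb = e$e_pb, total = e$total)
  })
}
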