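#' Channel, ligand and bath specifications
#'
#' `channel_spec()` describes an idealized n-fold symmetric channel built
#' from two pseudo-atoms per residue (a backbone CA and a side-chain CB):
#' ideal alpha-helical segments (rise 1.5 A/residue, 100 deg/residue twist,
#' wrap radius 2.3 A) for the named secondary-structure domains (S1, TM1,
#' TM2, C), straight-coil interpolation elsewhere. The membrane normal is
#' +Z, the periplasmic side is +Z and the cytoplasm is -Z; the ligand exits
#' toward -Z. Pore-lining TM1 side chains place a "gasket" ring at
#' `constriction_z` whose clearance equals `pore_constriction_radius`
#' exactly, so the built pore's minimum radius is a controlled ground truth.
#'
#' `ligand_spec()` describes a rigid polycationic bead-cluster surrogate for
#' a ~10-A, +3-charged aminoglycoside: `n_beads` collinear beads along Z
#' whose cloud diameter (max bead-center separation plus two bead radii)
#' equals `diameter`, with the total charge split uniformly.
#'
#' `bath_spec()` describes the solvent stand-ins: counts of monatomic
#' cations/anions placed by rejection sampling outside the membrane slab
#' and the protein/ligand volume, plus three-residue surrogate lipids
#' (one polar PC residue at each slab face carrying a leaflet marker atom,
#' and two hydrophobic residues, PA and OL, inside the slab).
#'
#' @param n_monomers Number of subunits (>= 3).
#' @param residues_per_monomer Residues per subunit.
#' @param helices Named list of residue ranges for S1, TM1, TM2, C.
#' @param pore_constriction_radius Minimum pore radius of the build (A).
#' @param constriction_z Z position of the constriction (A).
#' @param lysine_ring_resnum Per-monomer residue number of the cytoplasmic
#'   lysine ring (LYS).
#' @param asn_resnum Per-monomer residue number of the lipid-facing
#'   asparagine used for contact statistics (ASN).
#' @param monomer_offset Residue-numbering offset between monomers.
#' @param rng_seed Seed for any stochastic placement.
#' @return A spec list of the corresponding class.
#' @export
channel_spec <- function(n_monomers = 5L,
                         residues_per_monomer = 136L,
                         helices = list(S1 = 1:12, TM1 = 15:45,
                                        TM2 = 76:105, C = 110:130),
                         pore_constriction_radius = 2.5,
                         constriction_z = -5,
                         lysine_ring_resnum = 106L,
                         asn_resnum = 103L,
                         monomer_offset = residues_per_monomer,
                         rng_seed = 1L) {
  if (n_monomers < 3L) abort("n_monomers must be >= 3")
  if (pore_constriction_radius <= 0) abort("pore_constriction_radius must be > 0")
  resn <- unlist(helices)
  if (anyDuplicated(resn) > 0L) abort("helix residue ranges must be disjoint")
  if (any(resn < 1L | resn > residues_per_monomer)) {
    abort("helix residues outside 1..residues_per_monomer")
  }
  structure(list(n_monomers = as.integer(n_monomers),
                 residues_per_monomer = as.integer(residues_per_monomer),
                 helices = helices,
                 pore_constriction_radius = pore_constriction_radius,
                 constriction_z = constriction_z,
                 lysine_ring_resnum = as.integer(lysine_ring_resnum),
                 asn_resnum = as.integer(asn_resnum),
                 monomer_offset = as.integer(monomer_offset),
                 rng_seed = as.integer(rng_seed)),
            class = "pk_channel_spec")
}

#' @rdname channel_spec
#' @param n_beads Number of ligand beads (>= 1).
#' @param total_charge Total ligand charge (e).
#' @param diameter Ligand cloud diameter (A).
#' @param bead_radius Van der Waals radius of each bead (A).
#' @param bead_mass Mass of each bead (amu); the default makes a 3-bead
#'   cluster weigh 583.5 amu, the molecular weight of dihydrostreptomycin.
#' @export
ligand_spec <- function(n_beads = 3L, total_charge = 3, diameter = 10,
                        bead_radius = 2.0, bead_mass = 194.5) {
  if (n_beads < 1L) abort("n_beads must be >= 1")
  structure(list(n_beads = as.integer(n_beads), total_charge = total_charge,
                 diameter = diameter, bead_radius = bead_radius,
                 bead_mass = bead_mass),
            class = "pk_ligand_spec")
}

#' @rdname channel_spec
#' @param n_cations,n_anions Ion counts.
#' @param n_lipids Number of surrogate lipids scattered in the slab.
#' @param slab_z Membrane slab z-bounds, `c(lower, upper)` (A).
#' @param box Placement box lengths `c(Lx, Ly, Lz)` (A), centered on the
#'   origin.
#' @param min_separation Minimum ion-ion separation (A).
#' @param ion_exclusion_radius Ions are kept outside this cylindrical
#'   radius around the channel axis: with no explicit water, a bare ion
#'   parked in the permeation pathway would exert an unscreened Coulomb
#'   force on the ligand that solvated baths do not.
#' @export
bath_spec <- function(n_cations = 95L, n_anions = 95L, n_lipids = 230L,
                      slab_z = c(-9, 9), box = c(80, 80, 140),
                      min_separation = 3, ion_exclusion_radius = 20,
                      rng_seed = 1L) {
  if (n_cations < 0L || n_anions < 0L || n_lipids < 0L) abort("counts must be >= 0")
  if (slab_z[1] >= slab_z[2]) abort("slab z-bounds must be ordered")
  structure(list(n_cations = as.integer(n_cations),
                 n_anions = as.integer(n_anions),
                 n_lipids = as.integer(n_lipids),
                 slab_z = slab_z, box = box,
                 min_separation = min_separation,
                 ion_exclusion_radius = ion_exclusion_radius,
                 rng_seed = as.integer(rng_seed)),
            class = "pk_bath_spec")
}

# geometry templates for the named helices, in the monomer-0 frame
# (x is the radial direction of monomer 0): start point and axis direction
helix_geometry <- function(name) {
  switch(name,
    S1  = list(p0 = c(26, -15, -17), u = c(-0.866, 0.5, 0.03)),
    TM1 = list(p0 = c(7.5, 0, -16),  u = c(0.05, 0, 0.9987)),
    TM2 = list(p0 = c(16.5, 4, 24),  u = c(0.03, -0.03, -0.999)),
    C   = list(p0 = c(7.5, 1, -26),  u = c(0.03, 0, -0.9995)),
    list(p0 = c(10, 0, 0), u = c(0, 0, 1))
  )
}

normalize <- function(v) v / sqrt(sum(v^2))

# CA positions of an ideal helix: rise 1.5 A/residue, 100 deg/residue,
# wrap radius 2.3 A about the axis p0 + t*u
helix_ca <- function(p0, u, n) {
  u <- normalize(u)
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- normalize(pracma_cross(u, a))
  e2 <- pracma_cross(u, e1)
  k <- seq_len(n) - 1
  phase <- k * 100 * pi / 180
  axis_pts <- outer(k * 1.5, u)
  sweep(axis_pts, 2, p0, "+") +
    2.3 * (outer(cos(phase), e1) + outer(sin(phase), e2))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# template CA coordinates for monomer 0, one row per residue
monomer_template_ca <- function(spec) {
  R <- spec$residues_per_monomer
  ca <- matrix(NA_real_, R, 3)
  seg_axis <- vector("list", length(spec$helices))
  names(seg_axis) <- names(spec$helices)
  ord <- order(vapply(spec$helices, min, 0L))
  helices <- spec$helices[ord]
  for (nm in names(helices)) {
    res <- helices[[nm]]
    geo <- helix_geometry(nm)
    ca[res, ] <- helix_ca(geo$p0, geo$u, length(res))
    seg_axis[[nm]] <- list(res = res, u = normalize(geo$u), p0 = geo$p0)
  }
  # coil residues: placed along an arc between the flanking helix anchors
  # whose length matches an extended-chain spacing, so loops never fold
  # onto themselves; extended extrapolation at the chain termini
  known <- which(!is.na(ca[, 1]))
  if (length(known) == 0L) abort("at least one helix must be defined")
  gaps <- split(seq_len(R)[-known],
                findInterval(seq_len(R)[-known], known))
  for (g in gaps) {
    before <- known[known < min(g)]
    after <- known[known > max(g)]
    if (length(before) == 0L) {
      a <- ca[after[1], ]
      b <- ca[after[min(2, length(after))], ]
      dirv <- if (all(a == b)) c(0, 0, 1) else normalize(a - b)
      for (r in g) ca[r, ] <- a + dirv * 2.5 * (after[1] - r)
    } else if (length(after) == 0L) {
      a <- ca[before[length(before)], ]
      b <- ca[before[max(1, length(before) - 1)], ]
      dirv <- if (all(a == b)) c(0, 0, -1) else normalize(a - b)
      for (r in g) ca[r, ] <- a + dirv * 2.5 * (r - before[length(before)])
    } else {
      anchor_a <- ca[before[length(before)], ]
      anchor_b <- ca[after[1], ]
      ca[g, ] <- coil_arc(anchor_a, anchor_b, length(g))
    }
  }
  list(ca = ca, seg_axis = seg_axis)
}

# m interior points between anchors a and b at roughly `spacing` A per
# step; when the chord is too short the path bulges outward (away from the
# channel axis and the membrane center) along a quadratic Bezier whose
# length matches the required contour length
coil_arc <- function(a, b, m, spacing = 2.5) {
  need <- spacing * (m + 1)
  chord <- sqrt(sum((b - a)^2))
  if (chord >= 0.99 * need) {
    w <- seq_len(m) / (m + 1)
    return(outer(1 - w, a) + outer(w, b))
  }
  mid <- (a + b) / 2
  radial <- c(mid[1], mid[2], 0)
  radial <- if (sqrt(sum(radial^2)) < 1e-9) c(1, 0, 0) else normalize(radial)
  dirv <- normalize(radial + c(0, 0, 0.3 * sign(mid[3] + 1e-12)))
  bez_len <- function(h) {
    ctrl <- mid + h * dirv
    t <- seq(0, 1, length.out = 201)
    p <- outer((1 - t)^2, a) + outer(2 * t * (1 - t), ctrl) + outer(t^2, b)
    sum(sqrt(rowSums(diff(p)^2)))
  }
  h <- stats::uniroot(function(h) bez_len(h) - need, c(0, 200))$root
  ctrl <- mid + h * dirv
  tfine <- seq(0, 1, length.out = 400)
  p <- outer((1 - tfine)^2, a) + outer(2 * tfine * (1 - tfine), ctrl) +
    outer(tfine^2, b)
  cl <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  targets <- cl[length(cl)] * seq_len(m) / (m + 1)
  idx <- vapply(targets, function(s) which.min(abs(cl - s)), 0L)
  p[idx, , drop = FALSE]
}

#' Build an idealized symmetric channel pentamer
#'
#' Places `n_monomers` copies of a two-pseudo-atom-per-residue monomer with
#' exact n-fold symmetry about Z. Residue `lysine_ring_resnum` is LYS (the
#' cytoplasmic ring used as the permeation-coordinate reference), residue
#' `asn_resnum` is ASN (the lipid-facing contact target); all other residues
#' are ALA. The TM1 side chain nearest `constriction_z` is placed as an
#' exact ring whose clearance from the axis equals
#' `pore_constriction_radius`, and the builder verifies that no other atom
#' narrows the pore below that value (otherwise it errors: the requested
#' constriction would not be the profile minimum).
#'
#' @param spec A [channel_spec()].
#' @return A [pk_structure()] of the apo channel.
#' @export
build_pentamer <- function(spec) {
  tmpl <- monomer_template_ca(spec)
  ca <- tmpl$ca
  R <- spec$residues_per_monomer
  # side chains: 1.8 A from CA. Near-vertical (transmembrane/bundle)
  # helices point them radially outward from the channel axis, so the
  # backbone wrap (not stray side chains) sets the pore envelope and the
  # gasket ring below is the unique constriction; in-plane helices point
  # them away from their own axis; coil side chains point azimuthally so
  # they clear the outward-arcing loop backbone.
  cb <- matrix(NA_real_, R, 3)
  vertical <- rep(FALSE, R)
  for (seg in tmpl$seg_axis) {
    if (abs(seg$u[3]) > 0.7) {
      vertical[seg$res] <- TRUE
    } else {
      for (r in seg$res) {
        t_proj <- sum((ca[r, ] - seg$p0) * seg$u)
        dirv <- ca[r, ] - (seg$p0 + t_proj * seg$u)
        nr <- sqrt(sum(dirv^2))
        dirv <- if (nr < 1e-9) c(0, 0, 1) else dirv / nr
        cb[r, ] <- ca[r, ] + 1.8 * dirv
      }
    }
  }
  for (r in which(vertical)) {
    dirv <- c(ca[r, 1], ca[r, 2], 0)
    nr <- sqrt(sum(dirv^2))
    dirv <- if (nr < 1e-9) c(1, 0, 0) else dirv / nr
    cb[r, ] <- ca[r, ] + 1.8 * dirv
  }
  for (r in which(is.na(cb[, 1]))) { # coil
    dirv <- c(-ca[r, 2], ca[r, 1], 0)
    nr <- sqrt(sum(dirv^2))
    dirv <- if (nr < 1e-9) c(1, 0, 0) else dirv / nr
    cb[r, ] <- ca[r, ] + 1.8 * dirv
  }
  # the constriction gasket: TM1 side chain nearest constriction_z becomes
  # an exact ring at radius (pore radius + side-chain vdW radius)
  sc_radius <- 2.0
  if (!"TM1" %in% names(spec$helices)) abort("spec must define a TM1 helix")
  tm1 <- spec$helices$TM1
  gasket_res <- tm1[which.min(abs(ca[tm1, 3] - spec$constriction_z))]
  r_gasket <- spec$pore_constriction_radius + sc_radius
  az <- atan2(ca[gasket_res, 2], ca[gasket_res, 1])
  cb[gasket_res, ] <- c(r_gasket * cos(az), r_gasket * sin(az),
                        spec$constriction_z)
  resname <- rep("ALA", R)
  resname[spec$lysine_ring_resnum] <- "LYS"
  resname[spec$asn_resnum] <- "ASN"
  one <- tibble(
    atom_name = rep(c("CA", "CB"), R),
    residue_name = rep(resname, each = 2),
    residue_canonical = rep(seq_len(R), each = 2),
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3]))
  )
  monos <- purrr::map_dfr(seq_len(spec$n_monomers) - 1L, function(m) {
    Rm <- rot_z(360 * m / spec$n_monomers)
    xyz <- as.matrix(one[, c("x", "y", "z")]) %*% t(Rm)
    tibble(atom_name = one$atom_name,
           residue_name = one$residue_name,
           residue_number = one$residue_canonical + spec$monomer_offset * m,
           monomer_index = m,
           element = "C",
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
           charge = 0, vdw_radius = 2.0)
  })
  st <- pk_structure(monos, monomer_offset = spec$monomer_offset)
  # feasibility: on-axis clearance at the constriction from everything but
  # the gasket ring must exceed the requested radius
  gasket_idx <- which(st$atom_name == "CB" &
                        sel_canonical_resnum(st) == gasket_res)
  others <- setdiff(seq_len(nrow(st)), gasket_idx)
  d <- sqrt(st$x[others]^2 + st$y[others]^2 +
              (st$z[others] - spec$constriction_z)^2) - st$vdw_radius[others]
  if (min(d) <= spec$pore_constriction_radius) {
    abort(sprintf(paste0("infeasible geometry: requested constriction radius ",
                         "%.2f A exceeds the surrounding pore clearance %.2f A"),
                  spec$pore_constriction_radius, min(d)))
  }
  attr(st, "channel_spec") <- spec
  st
}

#' Append a rigid ligand surrogate to a system
#'
#' Appends `n_beads` collinear beads (along Z) centered at
#' `initial_position`, with the total charge split uniformly over the beads
#' and the bead-center span chosen so the cloud diameter (span + 2 radii)
#' equals `diameter`. The cluster carries `monomer_index = -1`, residue name
#' `LIG` and atom names `B1`, `B2`, ...
#'
#' @param structure A [pk_structure()] (the channel so far).
#' @param spec A [ligand_spec()].
#' @param initial_position 3-vector: the ligand geometric center (A).
#' @return The structure with the ligand appended.
#' @export
place_ligand <- function(structure, spec, initial_position = c(0, 0, 5)) {
  n <- spec$n_beads
  span <- max(spec$diameter - 2 * spec$bead_radius, 0)
  zoff <- if (n == 1L) 0 else seq(-span / 2, span / 2, length.out = n)
  lig <- tibble(
    atom_name = paste0("B", seq_len(n)),
    residue_name = "LIG",
    residue_number = max(structure$residue_number) + 1L,
    monomer_index = -1L,
    element = "C",
    x = initial_position[1],
    y = initial_position[2],
    z = initial_position[3] + zoff,
    charge = spec$total_charge / n,
    vdw_radius = spec$bead_radius
  )
  out <- pk_structure(bind_rows(structure, lig),
                      monomer_offset = monomer_offset(structure))
  attr(out, "channel_spec") <- attr(structure, "channel_spec", exact = TRUE)
  attr(out, "ligand_spec") <- spec
  out
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Add ion baths, surrogate lipids and the membrane slab
#'
#' Ions (resnames `K` and `CL`) are placed by rejection sampling: uniform in
#' the box, outside the membrane slab, clear of every existing atom's vdW
#' sphere, and at least `min_separation` from each other. Surrogate lipids
#' (three single-atom residues each: polar `PC` at the slab face, with atom
#' name `PU`/`PL` marking the upper/lower leaflet, and hydrophobic `PA` and
#' `OL` inside the slab) are scattered around the protein. Placement is
#' deterministic given `spec$rng_seed`. The slab bounds and box are stored
#' as attributes (`slab_z`, `box`) and a build log (seed, counts, net
#' charge) as attribute `build_log`.
#'
#' @param structure A [pk_structure()].
#' @param spec A [bath_spec()].
#' @param max_attempts Rejection-sampling attempt cap per particle.
#' @return The structure with ions and lipids appended.
#' @export
place_ions_and_slab <- function(structure, spec, max_attempts = 2000L) {
  with_preserved_seed(spec$rng_seed, {
    box <- spec$box
    half <- box / 2
    ex <- coords(structure)
    ex_r <- structure$vdw_radius
    next_res <- max(structure$residue_number) + 1L
    rows <- list()
    placed <- matrix(numeric(0), 0, 3)
    sample_ion <- function(radius) {
      for (a in seq_len(max_attempts)) {
        p <- c(stats::runif(1, -half[1], half[1]),
               stats::runif(1, -half[2], half[2]),
               stats::runif(1, -half[3], half[3]))
        if (p[3] >= spec$slab_z[1] && p[3] <= spec$slab_z[2]) next
        if (p[1]^2 + p[2]^2 < spec$ion_exclusion_radius^2) next
        d_ex <- sqrt(colSums((t(ex) - p)^2))
        if (any(d_ex < ex_r + radius)) next
        if (nrow(placed) > 0L) {
          d_pl <- sqrt(colSums((t(placed) - p)^2))
          if (any(d_pl < spec$min_separation)) next
        }
        return(p)
      }
      abort("ion placement failed after max attempts; use a larger box")
    }
    # lipid surrogates first (ions must clear them too): heads at the slab
    # faces, tails pointing inward
    if (spec$n_lipids > 0L) {
      in_slab <- structure$z > spec$slab_z[1] & structure$z < spec$slab_z[2]
      prot_clear <- if (any(in_slab)) {
        max(sqrt(structure$x[in_slab]^2 + structure$y[in_slab]^2) +
              structure$vdw_radius[in_slab]) + 2
      } else 0
      heads <- list(upper = matrix(numeric(0), 0, 2),
                    lower = matrix(numeric(0), 0, 2))
      slab_h <- spec$slab_z[2] - spec$slab_z[1]
      for (i in seq_len(spec$n_lipids)) {
        upper <- i %% 2L == 1L
        leaflet <- if (upper) "upper" else "lower"
        ok <- FALSE
        for (a in seq_len(max_attempts)) {
          p <- c(stats::runif(1, -half[1], half[1]),
                 stats::runif(1, -half[2], half[2]))
          if (sqrt(sum(p^2)) < prot_clear) next
          if (nrow(heads[[leaflet]]) > 0L) {
            d <- sqrt(colSums((t(heads[[leaflet]]) - p)^2))
            if (any(d < 4)) next
          }
          ok <- TRUE
          break
        }
        if (!ok) abort("lipid placement failed after max attempts; use a larger box")
        heads[[leaflet]] <- rbind(heads[[leaflet]], p)
        face_z <- if (upper) spec$slab_z[2] else spec$slab_z[1]
        sgn <- if (upper) -1 else 1
        zs <- face_z + sgn * c(0, 0.2 * slab_h, 0.38 * slab_h)
        marker <- if (upper) "PU" else "PL"
        rows[[length(rows) + 1L]] <- tibble(
          atom_name = c(marker, "C2", "C3"),
          residue_name = c("PC", "PA", "OL"),
          residue_number = next_res + 0:2,
          monomer_index = -1L, element = c("P", "C", "C"),
          x = p[1] + c(0, 0.5, -0.5), y = p[2] + c(0, -0.5, 0.5), z = zs,
          charge = 0, vdw_radius = 3.0)
        next_res <- next_res + 3L
      }
      lip <- bind_rows(rows)
      ex <- rbind(ex, cbind(lip$x, lip$y, lip$z))
      ex_r <- c(ex_r, lip$vdw_radius)
    }
    ion_specs <- rbind(
      if (spec$n_cations > 0L)
        data.frame(name = "K", res = "K", q = 1, r = 1.52, el = "K",
                   count = spec$n_cations),
      if (spec$n_anions > 0L)
        data.frame(name = "CL", res = "CL", q = -1, r = 1.81, el = "Cl",
                   count = spec$n_anions)
    )
    if (!is.null(ion_specs)) {
      for (j in seq_len(nrow(ion_specs))) {
        isp <- ion_specs[j, ]
        for (i in seq_len(isp$count)) {
          p <- sample_ion(isp$r)
          placed <- rbind(placed, p)
          rows[[length(rows) + 1L]] <- tibble(
            atom_name = isp$name, residue_name = isp$res,
            residue_number = next_res, monomer_index = -1L, element = isp$el,
            x = p[1], y = p[2], z = p[3], charge = isp$q, vdw_radius = isp$r)
          next_res <- next_res + 1L
        }
      }
    }
    added <- bind_rows(rows)
    out <- pk_structure(bind_rows(structure, added),
                        monomer_offset = monomer_offset(structure))
    attr(out, "channel_spec") <- attr(structure, "channel_spec", exact = TRUE)
    attr(out, "ligand_spec") <- attr(structure, "ligand_spec", exact = TRUE)
    attr(out, "slab_z") <- spec$slab_z
    attr(out, "box") <- spec$box
    attr(out, "build_log") <- list(
      rng_seed = spec$rng_seed,
      n_cations = spec$n_cations, n_anions = spec$n_anions,
      n_lipids = spec$n_lipids,
      net_charge = sum(out$charge))
    out
  })
}

#' Build a complete synthetic channel system
#'
#' Convenience wrapper: [build_pentamer()], then [place_ligand()], then
#' [place_ions_and_slab()].
#'
#' @param channel A [channel_spec()].
#' @param ligand A [ligand_spec()], or `NULL` to skip the ligand.
#' @param bath A [bath_spec()], or `NULL` to skip ions/lipids.
#' @param ligand_position Initial ligand center.
#' @return A [pk_structure()].
#' @export
build_system <- function(channel = channel_spec(), ligand = ligand_spec(),
                         bath = bath_spec(), ligand_position = c(0, 0, 5)) {
  st <- build_pentamer(channel)
  if (!is.null(ligand)) st <- place_ligand(st, ligand, ligand_position)
  if (!is.null(bath)) st <- place_ions_and_slab(st, bath)
  st
}
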