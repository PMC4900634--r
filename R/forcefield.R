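#' Coarse-grained force field
#'
#' The toy energy model used by the Langevin engine and the
#' molecular-mechanics part of the MM-PB energy:
#'
#' * Coulomb: `332.0636 * q_i q_j / r_ij` over all pairs, no cutoff;
#' * WCA repulsion: purely repulsive Lennard-Jones, shifted to zero at its
#'   minimum, with the pair contact distance `r_i + r_j` (the term is exactly
#'   zero beyond contact);
#' * harmonic positional restraints with energy `k * d^2` (note: no 1/2 —
#'   the convention of the engine family whose force constants, 20..1
#'   kcal/mol/A^2, this model inherits);
#' * an external-electric-field (EEF) term applied only to a masked atom
#'   subset: force `f_i = c_i * EEF` per component, with the field in V/A
#'   converted by 23.0609 kcal/(mol*A) per e*(V/A).
#'
#' @param eef_field 3-vector, electric field in V/A.
#' @param eef_mask Selection (expression, `pk_selection` or indices) of the
#'   atoms that feel the field; `NULL` for none.
#' @param restraints Tibble with columns `atom`, `x0`, `y0`, `z0`, `k`
#'   (kcal/mol/A^2), or `NULL`.
#' @param wca_eps WCA well depth epsilon (kcal/mol).
#' @return A `pk_forcefield` list.
#' @export
forcefield <- function(eef_field = c(0, 0, 0), eef_mask = NULL,
                       restraints = NULL, wca_eps = 0.2) {
  if (length(eef_field) != 3L || any(!is.finite(eef_field))) {
    abort("eef_field must be a finite 3-vector (V/A)")
  }
  if (!is.null(restraints)) {
    need <- c("atom", "x0", "y0", "z0", "k")
    if (!all(need %in% names(restraints))) {
      abort("restraints needs columns atom, x0, y0, z0, k")
    }
  }
  structure(list(eef_field = as.numeric(eef_field), eef_mask = eef_mask,
                 restraints = restraints, wca_eps = wca_eps,
                 kc = pk_constants()$coulomb),
            class = "pk_forcefield")
}

#' Molecule grouping used for non-bonded exclusions
#'
#' Assigns each atom a molecule id and an "exclude all internal pairs"
#' flag: protein atoms group by monomer (with adjacent-residue exclusions
#' handled pairwise), ligand beads form one rigid molecule, each surrogate
#' lipid (a PC head starting a PC/PA/OL trio) forms one molecule, and every
#' other non-protein residue (ions) is its own molecule.
#'
#' @param structure A [pk_structure()].
#' @return A list: `molid` (integer per atom), `exclall` (logical per
#'   atom).
#' @keywords internal
molecule_ids <- function(structure) {
  n <- nrow(structure)
  molid <- integer(n)
  exclall <- logical(n)
  prot <- structure$monomer_index >= 0L
  molid[prot] <- structure$monomer_index[prot] + 1L
  next_id <- max(c(0L, molid)) + 1L
  het <- which(!prot)
  lipid_set <- c("PC", "PA", "OL")
  cur_res <- NA_integer_
  cur_id <- NA_integer_
  in_lipid <- FALSE
  for (i in het) {
    rn <- structure$residue_name[i]
    res <- structure$residue_number[i]
    new_mol <- if (rn == "PC") TRUE
      else if (rn %in% lipid_set) !in_lipid
      else !identical(res, cur_res) || in_lipid
    if (new_mol) {
      cur_id <- next_id
      next_id <- next_id + 1L
      in_lipid <- rn %in% lipid_set
    }
    cur_res <- res
    molid[i] <- cur_id
    exclall[i] <- rn == "LIG" || rn %in% lipid_set
  }
  list(molid = molid, exclall = exclall)
}

ff_eval_args <- function(structure, ff) {
  n <- nrow(structure)
  mask <- rep(FALSE, n)
  if (!is.null(ff$eef_mask)) {
    mask[resolve_selection(structure, ff$eef_mask)] <- TRUE
  }
  eef <- ff$eef_field * pk_constants()$ev_per_volt_angstrom
  if (is.null(ff$restraints)) {
    ratom <- integer(0)
    rref <- matrix(numeric(0), 0, 3)
    rk <- numeric(0)
  } else {
    ratom <- as.integer(ff$restraints$atom) - 1L
    rref <- cbind(ff$restraints$x0, ff$restraints$y0, ff$restraints$z0)
    rk <- ff$restraints$k
  }
  mol <- molecule_ids(structure)
  list(mask = mask, eef = eef, ratom = ratom, rref = rref, rk = rk,
       mono = structure$monomer_index, resno = structure$residue_number,
       molid = mol$molid, exclall = mol$exclall)
}

#' External-electric-field forces
#'
#' The per-atom force due to a uniform external electric field applied to a
#' masked atom subset: `f_i = c_i * EEF` componentwise for masked atoms (with
#' `c_i` the partial charge in e and the field in V/A, converted to
#' kcal/(mol*A) by the factor 23.0609), and exactly zero for every atom
#' outside the mask.
#'
#' @param structure A [pk_structure()].
#' @param field 3-vector, field in V/A.
#' @param mask Selection of atoms that feel the field.
#' @return A tibble with one row per atom: `fx`, `fy`, `fz` (kcal/(mol*A)).
#' @export
eef_forces <- function(structure, field, mask) {
  if (length(field) != 3L || any(!is.finite(field))) {
    abort("field must be a finite 3-vector (V/A)")
  }
  idx <- resolve_selection(structure, mask)
  conv <- pk_constants()$ev_per_volt_angstrom
  f <- matrix(0, nrow(structure), 3)
  if (length(idx) > 0L) {
    f[idx, ] <- structure$charge[idx] %o% (field * conv)
  }
  tibble(fx = f[, 1], fy = f[, 2], fz = f[, 3])
}

#' Potential energy with per-term breakdown
#'
#' Evaluates the full force-field energy of a configuration: Coulomb, WCA
#' repulsion, positional restraints (`k*d^2`) and the EEF term
#' (`-sum q_i E.x_i` over masked atoms). The analytic forces are attached as
#' attribute `"forces"` (an n x 3 matrix) and are exact negative gradients
#' of the returned energy.
#'
#' @param structure A [pk_structure()].
#' @param ff A [forcefield()].
#' @return A one-row tibble `coulomb`, `wca`, `restraint`, `eef`, `total`
#'   (kcal/mol) with attribute `forces`.
#' @export
potential_energy <- function(structure, ff = forcefield()) {
  a <- ff_eval_args(structure, ff)
  res <- energy_forces_cpp(coords(structure), structure$charge,
                           structure$vdw_radius, a$mono, a$resno,
                           a$molid, a$exclall, a$eef, a$mask,
                           a$ratom, a$rref, a$rk, ff$kc, ff$wca_eps)
  out <- tibble(coulomb = res$coulomb, wca = res$wca,
                restraint = res$restraint, eef = res$eef,
                total = res$coulomb + res$wca + res$restraint + res$eef)
  attr(out, "forces") <- res$forces
  out
}

#' Analytic forces of the force field
#'
#' @param structure A [pk_structure()].
#' @param ff A [forcefield()].
#' @return An n x 3 matrix of forces (kcal/(mol*A)).
#' @export
ff_forces <- function(structure, ff = forcefield()) {
  attr(potential_energy(structure, ff), "forces")
}
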