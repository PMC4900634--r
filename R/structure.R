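#' Construct a molecular structure table
#'
#' A structure is a tibble with one row per atom and the columns
#' `atom_name`, `residue_name`, `residue_number`, `monomer_index`, `element`,
#' `x`, `y`, `z` (A), `charge` (e) and `vdw_radius` (A). `monomer_index` is
#' 0-based for protein subunits and `-1` for everything that is not part of
#' the protein (ligand, ions, lipid surrogates). Residue numbering follows
#' the concatenated-subunit convention: a residue with per-monomer number n
#' in monomer m carries the number `n + offset * m` (offset 136 by default),
#' so the lysine-ring
#' residue 106 appears as 106, 242, 378, 514 and 650 in a pentamer.
#'
#' @param atoms A data frame with the columns above (missing `charge`,
#'   `vdw_radius`, `element` are filled with 0, 1.7 and "C").
#' @param monomer_offset The residue-numbering offset between consecutive
#'   monomers. Stored as an attribute and used by the selection language to
#'   translate per-monomer residue numbers.
#' @return A `pk_structure` tibble.
#' @export
pk_structure <- function(atoms, monomer_offset = 136L) {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0L) abort("structure must contain at least one atom")
  defaults <- list(charge = 0, vdw_radius = 1.7, element = "C")
  for (col in names(defaults)) {
    if (!col %in% names(atoms)) atoms[[col]] <- defaults[[col]]
  }
  required <- c("atom_name", "residue_name", "residue_number", "monomer_index",
                "element", "x", "y", "z", "charge", "vdw_radius")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L) {
    abort(paste0("structure is missing columns: ", paste(missing, collapse = ", ")))
  }
  atoms <- atoms[, required]
  atoms$residue_number <- as.integer(atoms$residue_number)
  atoms$monomer_index <- as.integer(atoms$monomer_index)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom positions must be finite")
  }
  if (any(atoms$vdw_radius < 0)) abort("vdw_radius must be >= 0")
  if (any(atoms$monomer_index < -1L)) abort("monomer_index must be >= -1")
  structure(atoms,
            class = c("pk_structure", class(tibble())),
            monomer_offset = as.integer(monomer_offset))
}

#' @export
print.pk_structure <- function(x, ...) {
  cat(sprintf("# A structure: %d atoms, %d protein monomer(s), offset %d\n",
              nrow(x), length(unique(x$monomer_index[x$monomer_index >= 0])),
              monomer_offset(x)))
  NextMethod()
}

#' Residue-numbering offset of a structure
#' @param structure A `pk_structure`.
#' @return Integer offset (136 unless overridden at construction).
#' @export
monomer_offset <- function(structure) {
  off <- attr(structure, "monomer_offset", exact = TRUE)
  if (is.null(off)) 136L else as.integer(off)
}

#' Atom coordinates as a matrix
#' @param structure A `pk_structure`.
#' @return An n x 3 numeric matrix of coordinates (A).
#' @export
coords <- function(structure) {
  cbind(x = structure$x, y = structure$y, z = structure$z)
}

#' Replace the coordinates of a structure
#' @param structure A `pk_structure`.
#' @param xyz n x 3 matrix of new coordinates.
#' @return The structure with updated coordinates.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure), ncol(xyz) == 3L)
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

#' Construct a trajectory
#'
#' A trajectory couples a fixed topology (a [pk_structure()]) with an ordered
#' list of coordinate frames and strictly increasing timestamps.
#'
#' @param topology A `pk_structure` describing every frame's atoms.
#' @param frames A list of n_atoms x 3 coordinate matrices (A).
#' @param times Numeric vector of frame times (ps), strictly increasing.
#' @param box Optional 3-vector of orthorhombic box lengths (A).
#' @return A `pk_trajectory` object.
#' @export
pk_trajectory <- function(topology, frames, times = NULL, box = NULL) {
  if (!inherits(topology, "pk_structure")) abort("topology must be a pk_structure")
  if (length(frames) == 0L) abort("trajectory must contain at least one frame")
  n <- nrow(topology)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (!is.matrix(fr) || ncol(fr) != 3L) abort(sprintf("frame %d is not an n x 3 matrix", k))
    if (nrow(fr) != n) {
      abort(sprintf("frame %d has %d atoms but the topology has %d", k, nrow(fr), n))
    }
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames)) abort("times must match the number of frames")
  if (any(diff(times) <= 0)) abort("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames,
                 times = as.numeric(times), box = box),
            class = "pk_trajectory")
}

#' @export
print.pk_trajectory <- function(x, ...) {
  cat(sprintf("# A trajectory: %d frames x %d atoms, t = %g..%g ps\n",
              length(x$frames), nrow(x$topology),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `pk_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Extract one frame of a trajectory as a structure
#' @param trajectory A `pk_trajectory`.
#' @param i Frame index (1-based).
#' @return A `pk_structure` with that frame's coordinates.
#' @export
frame_structure <- function(trajectory, i) {
  if (i < 1L || i > n_frames(trajectory)) abort("frame index out of range")
  set_coords(trajectory$topology, trajectory$frames[[i]])
}

#' @export
tidy.pk_trajectory <- function(x, ...) {
  top <- x$topology
  purrr::map2_dfr(x$frames, seq_along(x$frames), function(fr, k) {
    tibble(frame = k, time_ps = x$times[k], atom = seq_len(nrow(fr)),
           atom_name = top$atom_name, residue_number = top$residue_number,
           monomer_index = top$monomer_index,
           x = fr[, 1], y = fr[, 2], z = fr[, 3])
  })
}

#' @export
glance.pk_trajectory <- function(x, ...) {
  tibble(n_frames = n_frames(x), n_atoms = nrow(x$topology),
         t_start_ps = x$times[1], t_end_ps = x$times[length(x$times)])
}
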