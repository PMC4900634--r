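# small structures and systems shared across test files; everything is
# generated in code, nothing is read from disk

# a bare structure from coordinate rows
make_atoms <- function(xyz, charge = 0, radius = 0, name = "X",
                       resname = "X", resnum = NULL, monomer = -1L,
                       element = "C", offset = 136L) {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  pk_structure(tibble::tibble(
    atom_name = rep_len(name, n),
    residue_name = rep_len(resname, n),
    residue_number = if (is.null(resnum)) seq_len(n) else rep_len(resnum, n),
    monomer_index = rep_len(as.integer(monomer), n),
    element = rep_len(element, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n),
    vdw_radius = rep_len(radius, n)
  ), monomer_offset = offset)
}

# a small channel spec that builds fast (20 residues/monomer)
tiny_channel_spec <- function(...) {
  channel_spec(residues_per_monomer = 20L,
               helices = list(TM1 = 2:12, TM2 = 14:19),
               lysine_ring_resnum = 13L, asn_resnum = 15L,
               pore_constriction_radius = 2.5, constriction_z = -5,
               ...)
}

# a ring of atoms in the z = z0 plane
ring_structure <- function(n = 12, circle_radius = 5, vdw = 1.5, z0 = 0) {
  th <- 2 * pi * seq_len(n) / n
  make_atoms(cbind(circle_radius * cos(th), circle_radius * sin(th), z0),
             radius = vdw, name = "O", resname = "RNG", element = "O")
}

# a trajectory with given per-frame coordinates for one topology
make_traj <- function(topology, frames, times = NULL) {
  pk_trajectory(topology, frames, times = times)
}

# deterministic RNG scope for tests
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
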