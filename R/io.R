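#' Default per-atom charge and van der Waals radius lookup
#'
#' PDB files carry no partial charges, so charges and radii are filled from a
#' lookup table when a structure is read. A row matches an atom by
#' `residue_name` and `atom_name`; `"*"` is a wildcard. The first matching
#' row wins, searched in the order: exact (residue, atom), then
#' (`"*"`, atom), then (residue, `"*"`), then the (`"*"`, `"*"`) fallback.
#'
#' The defaults cover the synthetic system: neutral 2.0-A pseudo-atoms for
#' protein residues, +1/-1 monatomic ions, +1 ligand beads and neutral 3.0-A
#' lipid-residue centers. Override by passing your own table (same columns)
#' to [read_pdb()].
#'
#' @return A tibble with columns `residue_name`, `atom_name`, `charge`,
#'   `vdw_radius`.
#' @export
default_charge_table <- function() {
  tibble(
    residue_name = c("K",  "CL",  "LIG", "PA",  "PC",  "OL",  "*",  "*",  "*"),
    atom_name    = c("K",  "CL",  "*",   "*",   "*",   "*",   "CA", "CB", "*"),
    charge       = c(1,    -1,    1,     0,     0,     0,     0,    0,    0),
    vdw_radius   = c(1.52, 1.81,  2.0,   3.0,   3.0,   3.0,   2.0,  2.0,  1.7)
  )
}

lookup_charges <- function(atoms, table) {
  charge <- numeric(nrow(atoms))
  radius <- numeric(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    rn <- atoms$residue_name[i]
    an <- atoms$atom_name[i]
    hit <- which(table$residue_name == rn & table$atom_name == an)
    if (length(hit) == 0L) hit <- which(table$residue_name == "*" & table$atom_name == an)
    if (length(hit) == 0L) hit <- which(table$residue_name == rn & table$atom_name == "*")
    if (length(hit) == 0L) hit <- which(table$residue_name == "*" & table$atom_name == "*")
    if (length(hit) == 0L) {
      charge[i] <- 0
      radius[i] <- 1.7
    } else {
      charge[i] <- table$charge[hit[1]]
      radius[i] <- table$vdw_radius[hit[1]]
    }
  }
  atoms$charge <- charge
  atoms$vdw_radius <- radius
  atoms
}

pdb_prescan <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  coord_rows <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in coord_rows) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(sprintf("PDB parse error in '%s' at line %d: coordinate fields truncated",
                    path, i))
    }
    for (rng in list(c(31, 38), c(39, 46), c(47, 54))) {
      fld <- trimws(substr(ln, rng[1], rng[2]))
      if (fld == "" || is.na(suppressWarnings(as.numeric(fld)))) {
        abort(sprintf("PDB parse error in '%s' at line %d: malformed coordinate field '%s'",
                      path, i, fld))
      }
    }
  }
  serials <- suppressWarnings(as.integer(trimws(substr(lines[coord_rows], 7, 11))))
  dup <- serials[!is.na(serials)][duplicated(serials[!is.na(serials)])]
  if (length(dup) > 0L) {
    warn(sprintf("duplicate atom serial(s) in '%s': %s (keeping all records)",
                 path, paste(unique(dup), collapse = ", ")))
  }
  invisible(coord_rows)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into a [pk_structure()]. Protein
#' chains are mapped to `monomer_index` 0, 1, ... in order of first
#' appearance; HETATM records get `monomer_index = -1`. Charges and radii
#' are filled from `charge_csv` (a sidecar written by [write_charge_csv()],
#' matched per atom by index) when given, otherwise from the
#' (residue, atom)-keyed `charge_table`.
#'
#' Files with more than one MODEL are trajectories; use [read_trajectory()].
#'
#' @param path Path to a PDB file.
#' @param charge_table Lookup table as in [default_charge_table()].
#' @param charge_csv Optional sidecar CSV with columns
#'   `index`, `charge`, `vdw_radius` (per-atom, row order = atom order).
#' @param monomer_offset Residue-numbering offset stored on the structure.
#' @return A `pk_structure`.
#' @export
read_pdb <- function(path, charge_table = default_charge_table(),
                     charge_csv = NULL, monomer_offset = 136L) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  n_models <- sum(substr(lines, 1, 6) == "MODEL ")
  if (n_models > 1L) {
    abort(sprintf("'%s' has %d MODEL records; use read_trajectory()", path, n_models))
  }
  pdb_prescan(lines, path)
  # the pre-scan above already reports duplicates/malformed fields with
  # line numbers; silence bio3d's overlapping warnings
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  is_protein <- at$type == "ATOM"
  chains <- unique(at$chain[is_protein])
  mono <- rep(-1L, nrow(at))
  mono[is_protein] <- match(at$chain[is_protein], chains) - 1L
  elem <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                 trimws(at$elesy), substr(trimws(at$elety), 1, 1))
  atoms <- tibble(
    atom_name = trimws(at$elety),
    residue_name = trimws(at$resid),
    residue_number = as.integer(at$resno),
    monomer_index = mono,
    element = elem,
    x = at$x, y = at$y, z = at$z
  )
  if (!is.null(charge_csv)) {
    side <- readr::read_csv(charge_csv, show_col_types = FALSE)
    if (nrow(side) != nrow(atoms)) {
      abort("charge sidecar row count does not match atom count")
    }
    atoms$charge <- side$charge
    atoms$vdw_radius <- side$vdw_radius
  } else {
    atoms <- lookup_charges(atoms, charge_table)
  }
  pk_structure(atoms, monomer_offset = monomer_offset)
}

#' Write a structure to a PDB file
#'
#' Protein atoms (monomer_index >= 0) are written as ATOM records with
#' chains A, B, ...; everything else as HETATM with chain X. Coordinates are
#' written at 3 decimals (the PDB fixed-column precision).
#'
#' @param structure A [pk_structure()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pdb <- function(structure, path) {
  n <- nrow(structure)
  chain <- ifelse(structure$monomer_index >= 0L,
                  LETTERS[structure$monomer_index + 1L], "X")
  type <- ifelse(structure$monomer_index >= 0L, "ATOM", "HETATM")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(structure))),
                   type = type,
                   resno = structure$residue_number,
                   resid = structure$residue_name,
                   eleno = seq_len(n),
                   elety = structure$atom_name,
                   chain = chain,
                   elesy = structure$element)
  invisible(path)
}

#' Write / read a per-atom charge sidecar CSV
#'
#' The sidecar carries the two per-atom quantities a PDB file cannot:
#' partial charge (e) and van der Waals radius (A), one row per atom in
#' atom order.
#'
#' @param structure A [pk_structure()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_charge_csv <- function(structure, path) {
  df <- tibble(index = seq_len(nrow(structure)),
               charge = structure$charge,
               vdw_radius = structure$vdw_radius)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a trajectory from a multi-model PDB or XYZ file
#'
#' The topology (atom identities, charges, radii) comes from `topology`;
#' the file supplies coordinate frames only. XYZ comment lines may carry
#' `t=<ps>`; otherwise frames are stamped 0, 1, 2, ... ps. Multi-model PDB
#' frames are delimited by MODEL/ENDMDL.
#'
#' @param path Path to the trajectory file.
#' @param topology A [pk_structure()] with the same atom count as each frame.
#' @param format `"xyz"` or `"pdb"`; guessed from the file extension when
#'   `NULL`.
#' @return A [pk_trajectory()].
#' @export
read_trajectory <- function(path, topology, format = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  if (is.null(format)) {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  switch(format,
         xyz = read_xyz_frames(path, topology),
         pdb = read_multimodel_pdb(path, topology),
         abort(sprintf("unknown trajectory format '%s'", format)))
}

read_xyz_frames <- function(path, topology) {
  lines <- readLines(path, warn = FALSE)
  n_top <- nrow(topology)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    k <- k + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort(sprintf("XYZ parse error at line %d: expected atom count", i))
    if (n != n_top) {
      abort(sprintf("frame %d has %d atoms but the topology has %d", k, n, n_top))
    }
    if (i + 1L + n > length(lines)) {
      abort(sprintf("frame %d is truncated", k))
    }
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("t=([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2]) else k - 1)
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, 0L) < 4L)
    if (length(bad) > 0L) {
      abort(sprintf("XYZ parse error in frame %d at line %d", k, i + 1L + bad[1]))
    }
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      abort(sprintf("XYZ parse error in frame %d: non-numeric coordinate", k))
    }
    frames[[k]] <- unname(xyz)
    i <- i + 2L + n
  }
  if (k == 0L) abort("no frames found")
  pk_trajectory(topology, frames, times = times)
}

read_multimodel_pdb <- function(path, topology) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  n_top <- nrow(topology)
  if (length(model_starts) == 0L) {
    pdb_prescan(lines, path)
    st <- read_pdb(path, monomer_offset = monomer_offset(topology))
    if (nrow(st) != n_top) {
      abort(sprintf("frame 1 has %d atoms but the topology has %d", nrow(st), n_top))
    }
    return(pk_trajectory(topology, list(coords(st)), times = 0))
  }
  ends <- c(model_starts[-1] - 1L, length(lines))
  frames <- vector("list", length(model_starts))
  for (k in seq_along(model_starts)) {
    blk <- lines[model_starts[k]:ends[k]]
    rows <- which(substr(blk, 1, 6) %in% c("ATOM  ", "HETATM"))
    if (length(rows) != n_top) {
      abort(sprintf("frame %d has %d atoms but the topology has %d",
                    k, length(rows), n_top))
    }
    ln <- blk[rows]
    xyz <- cbind(as.numeric(substr(ln, 31, 38)),
                 as.numeric(substr(ln, 39, 46)),
                 as.numeric(substr(ln, 47, 54)))
    if (any(!is.finite(xyz))) {
      abort(sprintf("PDB parse error in frame %d: malformed coordinate field", k))
    }
    frames[[k]] <- xyz
  }
  pk_trajectory(topology, frames, times = seq_along(frames) - 1)
}

#' Write a trajectory as XYZ
#'
#' One frame per block: atom count, comment line `t=<ps>`, then
#' `element x y z` at 6 decimals.
#'
#' @param trajectory A [pk_trajectory()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_xyz <- function(trajectory, path) {
  top <- trajectory$topology
  n <- nrow(top)
  out <- character(0)
  for (k in seq_len(n_frames(trajectory))) {
    fr <- trajectory$frames[[k]]
    out <- c(out,
             as.character(n),
             sprintf("t=%g", trajectory$times[k]),
             sprintf("%s %.6f %.6f %.6f", top$element, fr[, 1], fr[, 2], fr[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

format_csv_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(abs(x - round(x)) < .Machine$double.eps * 4 & abs(x) < 1e15,
                as.character(round(x)), formatC(x, digits = 6, format = "g")))
}

write_numeric_csv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) format_csv_num(col) else as.character(col)
  })
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(paste(names(df), collapse = ","), body), path)
  invisible(path)
}

#' Write a time series to CSV
#'
#' Fixed column order as supplied; numeric values at 6 significant digits.
#' An empty series is an error.
#'
#' @param series A data frame (e.g. a ΔZ series: `time_ps`, `delta_z_A`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (is.null(series) || nrow(series) == 0L) abort("empty series")
  write_numeric_csv(series, path)
}

#' Write a pore profile to CSV
#'
#' Columns `z_A`, `radius_A` (6 significant digits); an empty profile is an
#' error.
#'
#' @param profile A pore profile tibble (see [pore_profile()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  if (is.null(profile) || nrow(profile) == 0L) abort("empty series")
  write_numeric_csv(profile[, c("z_A", "radius_A")], path)
}
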