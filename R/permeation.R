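#' Geometric center of a set of points
#'
#' The unweighted componentwise mean (not the center of mass).
#'
#' @param xyz An n x 3 coordinate matrix (n >= 1).
#' @return A 3-vector.
#' @export
geometric_center <- function(xyz) {
  xyz <- rbind(xyz)
  if (nrow(xyz) == 0L) abort("geometric center of an empty point set")
  colMeans(xyz)
}

#' Permeation coordinate: ligand-to-ring Z difference
#'
#' Per frame, `delta_z = z(gc(ligand)) - z(gc(reference))` where `gc` is the
#' unweighted geometric center. With the cytoplasmic lysine ring as the
#' reference, the coordinate is >= 0 while the ligand sits in or above the
#' ring plane and < 0 once it has moved below (toward the cytoplasmic exit).
#'
#' @param trajectory A [pk_trajectory()].
#' @param ligand_sel Selection of the ligand atoms.
#' @param ref_sel Selection of the reference ring (default: the lysine-ring
#'   alpha-carbons).
#' @return A `pk_deltaz` tibble: `time_ps`, `delta_z_A`.
#' @export
delta_z <- function(trajectory, ligand_sel = "resname LIG",
                    ref_sel = "resnum 106 and name CA") {
  top <- trajectory$topology
  li <- resolve_selection(top, ligand_sel, allow_empty = FALSE)
  ri <- resolve_selection(top, ref_sel, allow_empty = FALSE)
  vals <- vapply(trajectory$frames, function(fr) {
    mean(fr[li, 3]) - mean(fr[ri, 3])
  }, numeric(1))
  out <- tibble(time_ps = trajectory$times, delta_z_A = vals)
  class(out) <- c("pk_deltaz", class(out))
  out
}

#' Detect permeation crossings with hysteresis
#'
#' A downward passage is recorded when the series, having most recently
#' been at or above `z_upper`, first reaches `z_lower` or below; `t_end` is
#' that sample and `t_start` the last sample at or above `z_upper`. Upward
#' passages are symmetric. Excursions that do not reach the far threshold
#' are ignored (hysteresis), so noise around a single threshold cannot
#' create events.
#'
#' @param series A `pk_deltaz` tibble (or any tibble with `time_ps` and
#'   `delta_z_A`).
#' @param z_upper,z_lower Thresholds (A), `z_upper > z_lower`.
#' @return A tibble of events: `t_start`, `t_end`, `direction`
#'   (`"down"`/`"up"`), time-ordered.
#' @export
detect_crossings <- function(series, z_upper = 10, z_lower = -5) {
  if (z_upper <= z_lower) abort("z_upper must be > z_lower")
  v <- series$delta_z_A
  tt <- series$time_ps
  if (length(v) < 2L) abort("series must have at least 2 samples")
  state <- "none"
  last_high <- NA_integer_
  last_low <- NA_integer_
  events <- list()
  for (i in seq_along(v)) {
    if (v[i] >= z_upper) {
      if (state == "low") {
        events[[length(events) + 1L]] <-
          tibble(t_start = tt[last_low], t_end = tt[i], direction = "up")
      }
      state <- "high"
      last_high <- i
    } else if (v[i] <= z_lower) {
      if (state == "high") {
        events[[length(events) + 1L]] <-
          tibble(t_start = tt[last_high], t_end = tt[i], direction = "down")
      }
      state <- "low"
      last_low <- i
    }
  }
  if (length(events) == 0L) {
    return(tibble(t_start = numeric(0), t_end = numeric(0),
                  direction = character(0)))
  }
  bind_rows(events)
}

#' Segment a permeation series into stages
#'
#' Frames are labeled by the band their permeation-coordinate value falls
#' in (`bands` are strictly decreasing break values: band 1 is above
#' `bands[1]`, band k+1 between `bands[k]` and `bands[k+1]`, ...).
#' Contiguous runs whose dwell (frame count times the sampling interval) is
#' shorter than `min_dwell` are merged into the longer neighboring run,
#' shortest first. Stage boundaries are placed midway between adjacent
#' frames of different stages, so the stages partition the analyzed window
#' exactly.
#'
#' @param series A `pk_deltaz` tibble.
#' @param energies Optional per-frame energies (kcal/mol) to average per
#'   stage.
#' @param bands Strictly decreasing break values (A).
#' @param min_dwell Minimum stage dwell (ps).
#' @return A tibble: `stage`, `band`, `t_start`, `t_end`, `dwell_ps`,
#'   `n_frames`, `mean_dz`, and `mean_energy` when energies are given.
#' @export
segment_stages <- function(series, energies = NULL, bands, min_dwell = 0) {
  if (length(bands) == 0L) abort("band set must not be empty")
  if (any(diff(bands) >= 0)) abort("bands must be strictly decreasing")
  if (min_dwell < 0) abort("min_dwell must be >= 0")
  v <- series$delta_z_A
  tt <- series$time_ps
  if (!is.null(energies) && length(energies) != length(v)) {
    abort("energies must have one value per frame")
  }
  dt <- if (length(tt) > 1L) stats::median(diff(tt)) else 1
  lab <- findInterval(-v, -c(Inf, bands)) # band 1 = above bands[1]
  runs <- function(l) {
    r <- rle(l)
    ends <- cumsum(r$lengths)
    tibble(band = r$values, start = ends - r$lengths + 1L, end = ends,
           len = r$lengths)
  }
  rr <- runs(lab)
  while (nrow(rr) > 1L) {
    dwell <- rr$len * dt
    short <- which(dwell < min_dwell)
    if (length(short) == 0L) break
    s <- short[order(rr$len[short], rr$start[short])][1]
    nb <- c(if (s > 1L) s - 1L, if (s < nrow(rr)) s + 1L)
    target <- nb[which.max(rr$len[nb])]
    lab[rr$start[s]:rr$end[s]] <- rr$band[target]
    rr <- runs(lab)
  }
  n <- length(v)
  bounds <- c(tt[1], (tt[rr$end[-nrow(rr)]] + tt[rr$end[-nrow(rr)] + 1L]) / 2,
              tt[n])
  out <- tibble(
    stage = seq_len(nrow(rr)),
    band = rr$band,
    t_start = bounds[-length(bounds)],
    t_end = bounds[-1],
    dwell_ps = diff(bounds),
    n_frames = rr$len,
    mean_dz = vapply(seq_len(nrow(rr)),
                     function(k) mean(v[rr$start[k]:rr$end[k]]), numeric(1))
  )
  if (!is.null(energies)) {
    out$mean_energy <- vapply(seq_len(nrow(rr)), function(k) {
      mean(energies[rr$start[k]:rr$end[k]])
    }, numeric(1))
  }
  out
}

#' Ion displacement along Z
#'
#' Per ion, the Z shift over the analyzed window: either the endpoint
#' difference `z(last) - z(first)` (default) or the window-mean minus the
#' initial value (`mode = "mean"`). Negative values mean motion toward -Z,
#' the cytoplasmic/outward exit side in the build convention.
#'
#' @param trajectory A [pk_trajectory()].
#' @param ion_sel Selection of the ions (e.g. `"resname K"`).
#' @param window Frame index range `c(first, last)`; default whole
#'   trajectory.
#' @param mode `"endpoint"` or `"mean"`.
#' @return A tibble with one row per ion: `atom`, `dz_A`; attribute
#'   `mean_dz` and a [glance()] method reporting it.
#' @export
ion_displacement <- function(trajectory, ion_sel = "resname K",
                             window = NULL, mode = c("endpoint", "mean")) {
  mode <- match.arg(mode)
  idx <- resolve_selection(trajectory$topology, ion_sel, allow_empty = FALSE)
  nf <- n_frames(trajectory)
  if (is.null(window)) window <- c(1L, nf)
  if (window[1] < 1L || window[2] > nf || window[1] > window[2]) {
    abort("window outside trajectory")
  }
  z0 <- trajectory$frames[[window[1]]][idx, 3]
  dz <- if (mode == "endpoint") {
    trajectory$frames[[window[2]]][idx, 3] - z0
  } else {
    zmat <- vapply(trajectory$frames[window[1]:window[2]],
                   function(fr) fr[idx, 3], numeric(length(idx)))
    rowMeans(rbind(zmat)) - z0
  }
  out <- tibble(atom = idx, dz_A = dz)
  class(out) <- c("pk_ion_disp", class(out))
  attr(out, "mean_dz") <- mean(dz)
  attr(out, "mode") <- mode
  out
}

#' @export
glance.pk_ion_disp <- function(x, ...) {
  tibble(n_ions = nrow(x), mean_dz_A = attr(x, "mean_dz", exact = TRUE),
         mode = attr(x, "mode", exact = TRUE))
}

#' Lipid-contact numbers of a residue and its counterparts
#'
#' For each monomer's copy of the target residue (per-monomer residue
#' number `target_resnum`, e.g. 103 with counterparts 239/375/511/647 under
#' the 136 offset), counts per frame the hydrophobic lipid residues whose
#' geometric center lies within `threshold` (inclusive) of the target
#' residue's geometric center. Lipid residues are identified by residue
#' name (`PA` and `OL` are the hydrophobic residues of the surrogate
#' lipids).
#'
#' @param trajectory A [pk_trajectory()].
#' @param target_resnum Per-monomer residue number of the target.
#' @param threshold Contact distance threshold (A), inclusive.
#' @param hydrophobic_resnames Lipid residue names that count as
#'   hydrophobic.
#' @return A `pk_contacts` tibble: `frame`, `time_ps`, `target` (global
#'   residue number), `monomer`, `count`.
#' @export
contact_number <- function(trajectory, target_resnum = 103, threshold = 6.5,
                           hydrophobic_resnames = c("PA", "OL")) {
  top <- trajectory$topology
  lipid_rows <- which(top$residue_name %in% hydrophobic_resnames)
  if (length(lipid_rows) == 0L) {
    abort("no flagged hydrophobic lipid residues in the topology")
  }
  lipid_groups <- split(lipid_rows, top$residue_number[lipid_rows])
  canon <- sel_canonical_resnum(top)
  monomers <- sort(unique(top$monomer_index[top$monomer_index >= 0L]))
  targets <- lapply(monomers, function(m) {
    which(top$monomer_index == m & canon == target_resnum)
  })
  keep <- lengths(targets) > 0L
  monomers <- monomers[keep]
  targets <- targets[keep]
  if (length(targets) == 0L) abort("target residue not found in any monomer")
  rows <- purrr::map_dfr(seq_len(n_frames(trajectory)), function(k) {
    fr <- trajectory$frames[[k]]
    lip_centers <- t(vapply(lipid_groups,
                            function(g) geometric_center(fr[g, , drop = FALSE]),
                            numeric(3)))
    purrr::map_dfr(seq_along(targets), function(ti) {
      gc_t <- geometric_center(fr[targets[[ti]], , drop = FALSE])
      d <- sqrt(colSums((t(lip_centers) - gc_t)^2))
      tibble(frame = k, time_ps = trajectory$times[k],
             target = top$residue_number[targets[[ti]][1]],
             monomer = monomers[ti],
             count = sum(d <= threshold))
    })
  })
  class(rows) <- c("pk_contacts", class(rows))
  attr(rows, "threshold") <- threshold
  rows
}

#' @export
glance.pk_contacts <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(as_tibble(x), .data$target, .data$monomer),
                   mean_count = mean(.data$count), .groups = "drop")
}

#' Assemble a permeation report
#'
#' Bundles the permeation-coordinate series, crossing events, stage
#' segmentation and first-passage time of one trajectory.
#'
#' @param trajectory A [pk_trajectory()].
#' @param ligand_sel,ref_sel Selections for [delta_z()].
#' @param z_upper,z_lower Crossing thresholds for [detect_crossings()].
#' @param bands,min_dwell Stage parameters for [segment_stages()];
#'   `bands = NULL` skips segmentation.
#' @param energies Optional per-frame energies for the stage table.
#' @return A `pk_permeation_report` list: `series`, `events`, `stages`,
#'   `first_passage_ps`.
#' @export
permeation_report <- function(trajectory, ligand_sel = "resname LIG",
                              ref_sel = "resnum 106 and name CA",
                              z_upper = 10, z_lower = -5,
                              bands = NULL, min_dwell = 0, energies = NULL) {
  series <- delta_z(trajectory, ligand_sel, ref_sel)
  events <- detect_crossings(series, z_upper, z_lower)
  stages <- if (!is.null(bands)) {
    segment_stages(series, energies = energies, bands = bands,
                   min_dwell = min_dwell)
  } else NULL
  down <- events[events$direction == "down", , drop = FALSE]
  structure(list(series = series, events = events, stages = stages,
                 first_passage_ps = if (nrow(down) > 0) down$t_end[1] else Inf),
            class = "pk_permeation_report")
}

#' @export
print.pk_permeation_report <- function(x, ...) {
  cat(sprintf("# Permeation report: %d crossing event(s), first passage %s\n",
              nrow(x$events),
              if (is.finite(x$first_passage_ps))
                sprintf("%g ps", x$first_passage_ps) else "none"))
  invisible(x)
}

#' @export
tidy.pk_permeation_report <- function(x, ...) x$events

#' @export
glance.pk_permeation_report <- function(x, ...) {
  tibble(n_events = nrow(x$events),
         n_down = sum(x$events$direction == "down"),
         n_up = sum(x$events$direction == "up"),
         n_stages = if (is.null(x$stages)) NA_integer_ else nrow(x$stages),
         first_passage_ps = x$first_passage_ps)
}
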