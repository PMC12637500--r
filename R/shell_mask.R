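#' @name shell_mask
#' @title Distance-banded solvent-shell masks
#' @description
#' The comparison universe is the set of voxels whose distance to the
#' nearest reference RNA heavy atom falls in a half-open band
#' `[r_min, r_max)` (default 1.8-3.2 \enc{Å}{A}, covering directly coordinated
#' water and ions). Each voxel carries its distance and the residue of its
#' nearest atom; voxels nearest to an excluded (poorly resolved) residue
#' are dropped, not reassigned. Distances are always measured on the
#' reference structure, never on model frames, because the mask addresses
#' the experimental map.
NULL

# distance-to-RNA and nearest residue for every voxel of a lattice; this is
# the expensive part shared by all band selections, so it is computed once.
shell_distance_field <- function(ref, lattice) {
  at <- ref$atoms[is_heavy(ref$atoms), , drop = FALSE]
  if (nrow(at) == 0L) stop("reference structure has no heavy atoms")
  md <- cpp_min_dist(voxel_centers(lattice), atom_coords(at))
  # nearest-atom ties resolved inside the scan by first (lowest) index; map
  # to residues so the lowest residue index wins on exact ties
  list(dist = md$dist, residue = at$residue_index[md$nearest])
}

new_shell_mask <- function(indices, dist, residue, band, lattice) {
  structure(list(indices = indices, distance = dist, nearest_residue = residue,
                 band = band, origin = lattice$origin, spacing = lattice$spacing,
                 dim = lattice$dim,
                 mask_id = sprintf("%gx%gx%g@%.4g[%g,%g)", lattice$dim[1],
                                   lattice$dim[2], lattice$dim[3],
                                   lattice$spacing[1], band[1], band[2])),
            class = "shell_mask")
}

#' @export
print.shell_mask <- function(x, ...) {
  cat(sprintf("<shell_mask> [%g, %g) A: %d voxels, %d residue(s)\n",
              x$band[1], x$band[2], length(x$indices),
              length(unique(x$nearest_residue))))
  invisible(x)
}

#' Compute a solvent-shell mask on a lattice
#'
#' Selects voxels with `r_min <= d < r_max`, where d is the distance from
#' the voxel centre to the nearest reference RNA heavy atom, dropping
#' voxels whose nearest residue is excluded.
#'
#' @param ref a `reference_structure` (its `excluded_residues` are applied
#'   unless overridden).
#' @param lattice a `density_grid` defining the lattice.
#' @param r_min,r_max band limits in \enc{Å}{A}, half-open `[r_min, r_max)`.
#' @param excluded_residues override of the reference's exclusion list.
#' @param field optionally a precomputed distance field (internal reuse).
#' @return a `shell_mask`.
#' @export
compute_shell <- function(ref, lattice, r_min = 1.8, r_max = 3.2,
                          excluded_residues = NULL, field = NULL) {
  if (r_min > r_max) stop("r_min must not exceed r_max")
  if (is.null(excluded_residues)) excluded_residues <- ref$excluded_residues
  if (is.null(field)) field <- shell_distance_field(ref, lattice)
  sel <- field$dist >= r_min & field$dist < r_max &
    !(field$residue %in% excluded_residues)
  new_shell_mask(which(sel), field$dist[sel], field$residue[sel],
                 c(r_min, r_max), lattice)
}

#' Growing solvent shells
#'
#' Bands `[1.8, 1.9), [1.8, 2.0), ..., [1.8, 5.0)` in 0.1 \enc{Å}{A} steps: 32
#' nested masks of increasing outer radius.
#'
#' @inheritParams compute_shell
#' @param r_min inner radius, \enc{Å}{A}.
#' @param r_max_seq outer radii sequence.
#' @return list of `shell_mask`, inner-nested in order.
#' @export
growing_shells <- function(ref, lattice, r_min = 1.8,
                           r_max_seq = seq(1.9, 5.0, by = 0.1),
                           excluded_residues = NULL) {
  field <- shell_distance_field(ref, lattice)
  lapply(r_max_seq, function(r_max)
    compute_shell(ref, lattice, r_min, r_max, excluded_residues, field = field))
}

#' Sliding 1 A distance windows
#'
#' Bands `[1.8, 2.8), [1.9, 2.9), ..., [4.0, 5.0)`: 23 overlapping windows
#' whose union is `[1.8, 5.0)`.
#'
#' @inheritParams compute_shell
#' @param starts window start radii, \enc{Å}{A}.
#' @param width window width, \enc{Å}{A}.
#' @return list of `shell_mask`.
#' @export
distance_windows <- function(ref, lattice, starts = seq(1.8, 4.0, by = 0.1),
                             width = 1.0, excluded_residues = NULL) {
  field <- shell_distance_field(ref, lattice)
  lapply(starts, function(s)
    compute_shell(ref, lattice, s, s + width, excluded_residues, field = field))
}

#' Partition a shell mask by nearest residue
#'
#' @param mask a `shell_mask`.
#' @param min_voxels regions smaller than this are flagged (mutual
#'   information is skipped for them downstream).
#' @return named list (residue index as name) of `shell_mask` regions; each
#'   has attribute `too_small` when below `min_voxels`.
#' @export
per_residue_regions <- function(mask, min_voxels = cryoshell_config()$min_voxels_mi) {
  lattice <- list(origin = mask$origin, spacing = mask$spacing, dim = mask$dim)
  groups <- split(seq_along(mask$indices), mask$nearest_residue)
  out <- lapply(groups, function(ii) {
    m <- new_shell_mask(mask$indices[ii], mask$distance[ii],
                        mask$nearest_residue[ii], mask$band, lattice)
    attr(m, "too_small") <- length(ii) < min_voxels
    m
  })
  out
}

#' Extract the masked values of a density grid as a vector
#'
#' @param grid a `density_grid` on the mask's lattice.
#' @param mask a `shell_mask`.
#' @return numeric vector, one value per mask voxel, with the mask id as
#'   attribute.
#' @export
mask_values <- function(grid, mask) {
  if (!identical(as.integer(grid$dim), as.integer(mask$dim)) ||
      max(abs(grid$origin - mask$origin)) > 1e-6)
    stop("grid and mask are on different lattices; resample first")
  v <- as.numeric(grid$values)[mask$indices]
  attr(v, "mask_id") <- mask$mask_id
  v
}

#' Export a shell mask as a CSV voxel table or binary MRC mask
#'
#' @param mask a `shell_mask`.
#' @param path output path; `.csv` writes a voxel table (index, centre
#'   coordinates, distance, nearest residue), `.mrc` a 0/1 map.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  lattice <- density_grid(mask$origin, mask$spacing, mask$dim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    ijk <- arrayInd(mask$indices, mask$dim)
    xyz <- sweep(sweep(ijk - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
    df <- data.frame(index = mask$indices, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     distance = mask$distance, nearest_residue = mask$nearest_residue)
    write.csv(df, path, row.names = FALSE)
  } else {
    v <- array(0, mask$dim)
    v[mask$indices] <- 1
    write_mrc(density_grid(mask$origin, mask$spacing, mask$dim, v, "mask"), path)
  }
  invisible(path)
}
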