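#' @name density_builder
#' @title Rendering solvent clouds as density grids and stitching maps
#' @description
#' Two renderers are provided. The scattering-factor density places, at each
#' atom, the real-space profile obtained by Fourier transforming the
#' 5-Gaussian fit of the neutral-atom electron scattering factor
#' \eqn{f(s) = \sum_i a_i e^{-b_i s^2}} (s = \eqn{\sin\theta/\lambda}),
#' giving \eqn{\rho(r) = \sum_i a_i (4\pi/b_i)^{3/2} e^{-4\pi^2 r^2 / b_i}},
#' truncated at a cutoff radius (4 \enc{Å}{A} by default, inclusive). The
#' probability density simply counts atoms in the voxel containing them.
#' Both are additive over atoms and normalized per model, so ensembles of
#' different sizes are directly comparable. Local per-residue grids are
#' stitched into the full map by per-voxel weighted averaging with weights
#' 1/r to the region's centre residue.
NULL

#' Create an empty density grid
#'
#' Voxel centres lie at `origin + (i-1)*spacing` per axis; values are stored
#' in a 3-D array with the x index fastest.
#'
#' @param origin length-3 numeric, \enc{Å}{A} (centre of the first voxel).
#' @param spacing length-1 or length-3 numeric, \enc{Å}{A}.
#' @param dim length-3 integer.
#' @param values optional array of matching dim (default zeros).
#' @param species species label ("water", "Mg2+", ..., "RNA" or "total").
#' @return a `density_grid`.
#' @export
density_grid <- function(origin, spacing, dim, values = NULL, species = "total") {
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  dim <- as.integer(rep_len(dim, 3L))
  if (is.null(values)) values <- array(0, dim = dim)
  stopifnot(identical(as.integer(base::dim(values)), dim))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dim = dim, values = values, species = species),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> [%s] %dx%dx%d @ %.3g A, origin (%.2f, %.2f, %.2f), range [%.4g, %.4g]\n",
              x$species, x$dim[1], x$dim[2], x$dim[3], x$spacing[1],
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# voxel centres of a grid (or a sub-range of indices) as an n x 3 matrix
voxel_centers <- function(grid, ix = seq_len(grid$dim[1]),
                          iy = seq_len(grid$dim[2]), iz = seq_len(grid$dim[3])) {
  g <- expand.grid(x = grid$origin[1] + (ix - 1) * grid$spacing[1],
                   y = grid$origin[2] + (iy - 1) * grid$spacing[2],
                   z = grid$origin[3] + (iz - 1) * grid$spacing[3],
                   KEEP.OUT.ATTRS = FALSE)
  unname(as.matrix(g))
}

#' Default output lattice for a reference structure
#'
#' Axis-aligned lattice covering the reference RNA bounding box padded by
#' `pad` \enc{Å}{A}, with the origin snapped down to a multiple of the spacing so
#' lattices of nested computations align.
#'
#' @param ref a `reference_structure` (or atom table).
#' @param spacing voxel spacing, \enc{Å}{A}.
#' @param pad padding, \enc{Å}{A}.
#' @return a zero-valued `density_grid` defining the lattice.
#' @export
default_lattice <- function(ref, spacing = 0.82, pad = 6.0) {
  at <- if (inherits(ref, "reference_structure")) ref$atoms else ref
  xyz <- atom_coords(at)
  lo <- floor((apply(xyz, 2, min) - pad) / spacing) * spacing
  hi <- apply(xyz, 2, max) + pad
  dim <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  density_grid(lo, spacing, dim)
}

# Peng et al. neutral-atom 5-Gaussian electron scattering coefficients
# (International Tables for Crystallography Vol. C, table 4.3.2.2);
# a_i in A, b_i in A^2, f(s) = sum a_i exp(-b_i s^2).
.scattering_coefficients <- local({
  m <- rbind(
    H  = c(0.0349, 0.1201, 0.1970, 0.0573, 0.1195, 0.5347, 3.5867, 12.3471, 18.9525, 38.6269),
    C  = c(0.0893, 0.2563, 0.7570, 1.0487, 0.3575, 0.2465, 1.7100, 6.4094, 18.6113, 50.2523),
    N  = c(0.1022, 0.3219, 0.7982, 0.8197, 0.1715, 0.2451, 1.7481, 6.1925, 17.3894, 48.1431),
    O  = c(0.0974, 0.2921, 0.6910, 0.6990, 0.2039, 0.2067, 1.3815, 4.6943, 12.7105, 32.4726),
    Na = c(0.2142, 0.6853, 0.7692, 1.6589, 1.4482, 0.3334, 2.3446, 10.0830, 48.3037, 138.2700),
    Mg = c(0.2314, 0.6866, 0.9677, 2.1882, 1.1339, 0.3278, 2.2720, 10.9241, 39.2898, 101.9748),
    P  = c(0.2548, 0.6106, 1.4541, 2.3204, 0.8477, 0.2908, 1.8740, 8.5176, 24.3434, 63.2996),
    Cl = c(0.2443, 0.5397, 1.3919, 2.0197, 0.6621, 0.2468, 1.5242, 6.1537, 16.6687, 42.3086),
    K  = c(0.4115, 1.4031, 2.2784, 2.6742, 2.2162, 0.3703, 3.3874, 13.1029, 68.9592, 194.4329)
  )
  colnames(m) <- c(paste0("a", 1:5), paste0("b", 1:5))
  m
})

#' Electron scattering factor table
#'
#' 5-Gaussian fits of neutral-atom electron scattering factors (Peng et al.
#' parameterization, as tabulated in International Tables for
#' Crystallography Vol. C): amplitudes `a1..a5` (\enc{Å}{A}) and widths `b1..b5`
#' (\enc{Å}{A}^2) per element, plus the truncation radius.
#'
#' @param cutoff_radius \enc{Å}{A}; atom signal is truncated beyond this (default 4,
#'   inclusive at exactly the cutoff).
#' @return list with `coefficients` (matrix, rownames = elements) and
#'   `cutoff_radius`.
#' @export
scattering_table <- function(cutoff_radius = 4.0) {
  list(coefficients = .scattering_coefficients, cutoff_radius = cutoff_radius)
}

#' Scattering-factor density of a set of atoms
#'
#' Sums the per-atom real-space Gaussian profiles (see
#' \link{density_builder}) on the lattice of `grid_spec`, truncated at the
#' table's cutoff radius, and divides by `n_models` so values are per-model
#' averages.
#'
#' @param atoms atom table (needs `element` and coordinates), or an n x 3
#'   coordinate matrix together with `elements`.
#' @param grid_spec a `density_grid` defining the output lattice.
#' @param table from [scattering_table()].
#' @param n_models ensemble size used for normalization.
#' @param elements element symbols when `atoms` is a bare matrix.
#' @param species species label for the result.
#' @return a `density_grid`.
#' @export
scattering_density <- function(atoms, grid_spec, table = scattering_table(),
                               n_models = 1L, elements = NULL, species = "total") {
  if (is.matrix(atoms)) {
    xyz <- atoms
  } else {
    xyz <- atom_coords(atoms)
    elements <- atoms$element
  }
  out <- grid_spec
  out$species <- species
  out$values <- array(0, dim = grid_spec$dim)
  if (nrow(xyz) == 0L) return(out)
  elements <- normalize_element(elements)
  known <- rownames(table$coefficients)
  if (any(!elements %in% known))
    stop("no scattering coefficients for element(s): ",
         paste(unique(setdiff(elements, known)), collapse = ", "))
  co <- table$coefficients[elements, , drop = FALSE]
  a <- co[, 1:5, drop = FALSE]
  b <- co[, 6:10, drop = FALSE]
  pref <- a * (4 * pi / b)^1.5
  expo <- 4 * pi^2 / b
  v <- cpp_scatter_density(xyz, pref, expo, grid_spec$origin, grid_spec$spacing,
                           grid_spec$dim, table$cutoff_radius)
  out$values <- array(v / n_models, dim = grid_spec$dim)
  out
}

#' Probability density (per-voxel occupancy counts) of a set of atoms
#'
#' Each atom increments the count of the voxel containing its position
#' (voxel `i` covers centres within half a spacing); counts are divided by
#' `n_models`. Atoms outside the grid are counted in no voxel; their number
#' is reported in `attr(, "n_outside")`.
#'
#' @inheritParams scattering_density
#' @return a `density_grid` of counts per model per voxel.
#' @export
probability_density <- function(atoms, grid_spec, n_models = 1L, species = "total") {
  xyz <- if (is.matrix(atoms)) atoms else atom_coords(atoms)
  out <- grid_spec
  out$species <- species
  out$values <- array(0, dim = grid_spec$dim)
  if (nrow(xyz) == 0L) { attr(out, "n_outside") <- 0L; return(out) }
  idx <- sweep(sweep(xyz, 2, grid_spec$origin), 2, grid_spec$spacing, "/")
  idx <- round(idx) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= grid_spec$dim[1] &
    idx[, 2] >= 1 & idx[, 2] <= grid_spec$dim[2] &
    idx[, 3] >= 1 & idx[, 3] <= grid_spec$dim[3]
  idx <- idx[inside, , drop = FALSE]
  lin <- (idx[, 3] - 1) * grid_spec$dim[1] * grid_spec$dim[2] +
    (idx[, 2] - 1) * grid_spec$dim[1] + idx[, 1]
  counts <- tabulate(lin, nbins = prod(grid_spec$dim))
  out$values <- array(counts / n_models, dim = grid_spec$dim)
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Stitch local density grids into one map by 1/r-weighted averaging
#'
#' Every output voxel covered by one or more local grids (by bounding box)
#' is the weighted average of those grids' values there, with weight
#' \eqn{1/\max(r, r_{floor})} where r is the minimum distance from the
#' voxel centre to any atom of the region's centre residue on the reference.
#' Voxels covered by no region are 0.
#'
#' @param local_grids list of `list(grid = density_grid, center_residue = i)`;
#'   each grid must lie on a sublattice of `lattice`.
#' @param ref the `reference_structure` (provides centre-residue atoms).
#' @param lattice output `density_grid` lattice.
#' @param r_floor \enc{Å}{A}; cap on the 1/r weight (default one voxel spacing).
#' @param species species label of the output.
#' @param weights optional list of precomputed weight arrays, parallel to
#'   `local_grids` (internal reuse across species, which share regions).
#' @return a `density_grid` on `lattice`.
#' @export
stitch <- function(local_grids, ref, lattice, r_floor = lattice$spacing[1],
                   species = "total", weights = NULL) {
  num <- array(0, dim = lattice$dim)
  den <- array(0, dim = lattice$dim)
  at <- ref$atoms
  for (gi in seq_along(local_grids)) {
    lg <- local_grids[[gi]]
    g <- lg$grid
    off <- (g$origin - lattice$origin) / lattice$spacing
    if (max(abs(off - round(off))) > 1e-6 || max(abs(g$spacing - lattice$spacing)) > 1e-9)
      stop("local grid is not on a sublattice of the output lattice")
    off <- as.integer(round(off))
    ix <- off[1] + seq_len(g$dim[1]); iy <- off[2] + seq_len(g$dim[2])
    iz <- off[3] + seq_len(g$dim[3])
    if (min(ix) < 1 || min(iy) < 1 || min(iz) < 1 ||
        max(ix) > lattice$dim[1] || max(iy) > lattice$dim[2] || max(iz) > lattice$dim[3])
      stop("local grid extends beyond the output lattice")
    w <- if (!is.null(weights)) weights[[gi]] else {
      ctr <- at[at$residue_index == lg$center_residue & is_heavy(at), , drop = FALSE]
      r <- cpp_min_dist(voxel_centers(g), atom_coords(ctr))$dist
      array(1 / pmax(r, r_floor), dim = g$dim)
    }
    num[ix, iy, iz] <- num[ix, iy, iz] + w * g$values
    den[ix, iy, iz] <- den[ix, iy, iz] + w
  }
  vals <- num
  nz <- den > 0
  vals[nz] <- num[nz] / den[nz]
  density_grid(lattice$origin, lattice$spacing, lattice$dim, vals, species)
}

#' Trilinear interpolation of a density grid at arbitrary points
#'
#' Standard 8-corner blend. Points outside the hull of voxel centres are an
#' error; use [resample_onto()] for lattice-to-lattice transfer with
#' out-of-hull zero fill.
#'
#' @param grid a `density_grid`.
#' @param points n x 3 matrix (or length-3 vector), \enc{Å}{A}.
#' @return numeric vector of interpolated values.
#' @export
trilinear <- function(grid, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  as.numeric(trilinear_impl(grid, points, outside_error = TRUE))
}

trilinear_impl <- function(grid, points, outside_error = FALSE) {
  f <- sweep(sweep(points, 2, grid$origin), 2, grid$spacing, "/") + 1
  inside <- f[, 1] >= 1 & f[, 1] <= grid$dim[1] &
    f[, 2] >= 1 & f[, 2] <= grid$dim[2] & f[, 3] >= 1 & f[, 3] <= grid$dim[3]
  if (outside_error && any(!inside))
    stop(sum(!inside), " point(s) outside the grid hull")
  out <- numeric(nrow(points))
  if (!any(inside)) {
    attr(out, "n_outside") <- sum(!inside)
    return(out)
  }
  f <- f[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(f), 1), matrix(grid$dim - 1L, nrow(f), 3, byrow = TRUE))
  fr <- f - i0
  d <- grid$dim
  lin <- function(ix, iy, iz) (iz - 1) * d[1] * d[2] + (iy - 1) * d[1] + ix
  vals <- grid$values
  acc <- numeric(nrow(f))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) fr[, 1] else 1 - fr[, 1]) *
      (if (dy == 1) fr[, 2] else 1 - fr[, 2]) *
      (if (dz == 1) fr[, 3] else 1 - fr[, 3])
    acc <- acc + w * vals[lin(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out[inside] <- acc
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Resample a density grid onto another lattice
#'
#' Each target voxel centre receives the trilinear value from the source
#' grid; target voxels outside the source hull are set to 0 and counted in
#' `attr(, "n_outside")`.
#'
#' @param source a `density_grid`.
#' @param target_lattice a `density_grid` defining the target lattice.
#' @return a `density_grid` on the target lattice.
#' @export
resample_onto <- function(source, target_lattice) {
  v <- trilinear_impl(source, voxel_centers(target_lattice))
  out <- density_grid(target_lattice$origin, target_lattice$spacing,
                      target_lattice$dim, array(v, target_lattice$dim),
                      species = source$species)
  attr(out, "n_outside") <- attr(v, "n_outside")
  out
}

#' Convert a solvation ensemble to per-species density maps
#'
#' Runs the full rendering pipeline: build neighbourhoods on the reference,
#' locally align each model's solvent ([extract_local_solvent()]), render
#' each neighbourhood's pooled solvent per species (scattering or
#' probability method, per-model normalized), and stitch the local grids
#' with 1/r weights. Species maps are additive: their sum is the returned
#' total map.
#'
#' @param ensemble a standardized, trimmed `solvent_ensemble`.
#' @param ref a `reference_structure`.
#' @param config a [cryoshell_config()] list.
#' @param lattice output lattice; defaults to [default_lattice()] of the
#'   reference (pass the reference map's grid to adopt its lattice).
#' @param neighborhoods optionally precomputed [build_neighborhoods()].
#' @return list with `total` (a `density_grid`), `species` (named list of
#'   per-species grids), and `skipped` (alignment failures).
#' @export
ensemble_to_map <- function(ensemble, ref, config = cryoshell_config(),
                            lattice = NULL, neighborhoods = NULL) {
  if (is.null(lattice))
    lattice <- default_lattice(ref, config$voxel_spacing, config$pad)
  if (is.null(neighborhoods))
    neighborhoods <- build_neighborhoods(ref, config$neighborhood_radius,
                                         config$atom_selection)
  clouds <- extract_local_solvent(ensemble, neighborhoods, ref, config)
  n_models <- length(ensemble$models)
  table <- scattering_table(config$scattering_cutoff)
  pad <- config$solvent_capture_radius + config$scattering_cutoff

  # pool transformed atoms across models, per neighbourhood
  by_center <- split(clouds, vapply(clouds, function(cl) cl$center_residue, numeric(1)))
  species_present <- setdiff(.species_levels, "RNA")
  if (config$include_rna) species_present <- c(species_present, "RNA")
  local_by_species <- setNames(lapply(species_present, function(s) list()), species_present)

  ref_at <- ref$atoms
  for (ctr_chr in names(by_center)) {
    ctr <- as.numeric(ctr_chr)
    cls <- by_center[[ctr_chr]]
    pooled <- do.call(rbind, lapply(cls, function(cl) cl$atoms))
    if (config$include_rna) {
      # aligned member-residue RNA of each model, rendered like solvent
      nb <- neighborhoods[[which(vapply(neighborhoods, function(n) n$center, numeric(1)) == ctr)]]
      rna_rows <- lapply(seq_along(cls), function(i) {
        m <- cls[[i]]$model_index
        at <- ensemble$models[[m]]
        r <- at[at$species == "RNA" & at$residue_index %in% nb$members, , drop = FALSE]
        xyz <- apply_transform(atom_coords(r), cls[[i]]$transform)
        r$x <- xyz[, 1]; r$y <- xyz[, 2]; r$z <- xyz[, 3]
        r
      })
      pooled <- rbind(pooled, do.call(rbind, rna_rows))
    }
    # local sublattice: centre-residue capture zone + scattering cutoff
    ctr_xyz <- atom_coords(ref_at[ref_at$residue_index == ctr & is_heavy(ref_at), , drop = FALSE])
    lo_i <- pmax(1L, as.integer(floor((apply(ctr_xyz, 2, min) - pad - lattice$origin) / lattice$spacing)) + 1L)
    hi_i <- pmin(lattice$dim, as.integer(ceiling((apply(ctr_xyz, 2, max) + pad - lattice$origin) / lattice$spacing)) + 1L)
    sub <- density_grid(lattice$origin + (lo_i - 1) * lattice$spacing,
                        lattice$spacing, hi_i - lo_i + 1L)
    for (s in species_present) {
      at_s <- pooled[pooled$species == s, , drop = FALSE]
      g <- if (config$density_method == "scat") {
        scattering_density(at_s, sub, table, n_models = n_models, species = s)
      } else {
        probability_density(at_s, sub, n_models = n_models, species = s)
      }
      local_by_species[[s]][[length(local_by_species[[s]]) + 1L]] <-
        list(grid = g, center_residue = ctr)
    }
  }
  # the 1/r weight field of a region is species-independent; compute once
  region_w <- lapply(local_by_species[[1]], function(lg) {
    ctr <- ref_at[ref_at$residue_index == lg$center_residue & is_heavy(ref_at), , drop = FALSE]
    r <- cpp_min_dist(voxel_centers(lg$grid), atom_coords(ctr))$dist
    array(1 / pmax(r, config$r_floor), dim = lg$grid$dim)
  })
  species_maps <- lapply(species_present, function(s)
    stitch(local_by_species[[s]], ref, lattice, r_floor = config$r_floor,
           species = s, weights = region_w))
  names(species_maps) <- species_present
  total <- density_grid(lattice$origin, lattice$spacing, lattice$dim,
                        Reduce(`+`, lapply(species_maps, `[[`, "values")), "total")
  list(total = total, species = species_maps, skipped = attr(clouds, "skipped"))
}
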