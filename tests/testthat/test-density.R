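test_that("scattering density peaks at the atom and vanishes past the cutoff", {
  grid <- density_grid(c(-4.92, -4.92, -4.92), 0.82, c(13, 13, 13))
  g <- scattering_density(matrix(0, 1, 3), grid, elements = "O")
  expect_equal(which.max(g$values), (7 - 1) * 13 * 13 + (7 - 1) * 13 + 7)
  centers <- expand.grid(x = grid$origin[1] + (seq_len(13) - 1) * 0.82,
                         y = grid$origin[2] + (seq_len(13) - 1) * 0.82,
                         z = grid$origin[3] + (seq_len(13) - 1) * 0.82)
  r <- sqrt(rowSums(centers^2))
  expect_true(all(g$values[r > 4.0] == 0))
  expect_true(all(g$values[r <= 4.0] > 0))
})

test_that("both density methods are additive over atom sets", {
  grid <- density_grid(c(-4, -4, -4), 0.82, c(11, 11, 11))
  set.seed(3)
  xyz <- matrix(runif(12, -2, 2), ncol = 3)
  el <- c("O", "Mg", "P", "N")
  whole <- scattering_density(xyz, grid, elements = el)
  parts <- lapply(seq_len(4), function(i)
    scattering_density(xyz[i, , drop = FALSE], grid, elements = el[i]))
  expect_lt(max(abs(whole$values - Reduce(`+`, lapply(parts, `[[`, "values")))), 1e-12)
  pw <- probability_density(xyz, grid)
  pp <- lapply(seq_len(4), function(i) probability_density(xyz[i, , drop = FALSE], grid))
  expect_lt(max(abs(pw$values - Reduce(`+`, lapply(pp, `[[`, "values")))), 1e-12)
})

test_that("scattering density matches the naive double-loop oracle", {
  grid <- density_grid(c(-3.2, -3.0, -2.8), c(0.82, 0.9, 0.75), c(8, 7, 9))
  set.seed(8)
  xyz <- matrix(runif(60, -3, 3), ncol = 3)
  el <- sample(c("O", "N", "C", "P", "Mg", "Na", "Cl", "K", "H"), 20, replace = TRUE)
  g <- scattering_density(xyz, grid, elements = el, n_models = 2)
  oracle <- naive_scatter(xyz, el, grid) / 2
  expect_lt(max(abs(g$values - oracle)) / max(oracle), 1e-9)
  expect_error(scattering_density(xyz, grid, elements = rep("Xx", 20)), "Xx")
})

test_that("probability density counts voxel occupancy and conserves atoms", {
  grid <- density_grid(c(0, 0, 0), 1, c(5, 5, 5))
  one <- probability_density(matrix(c(2.2, 1.9, 3.1), 1, 3), grid)
  expect_equal(sum(one$values != 0), 1L)
  expect_equal(max(one$values), 1)
  # atom (2.2, 1.9, 3.1) falls in voxel (3, 3, 4): centres at integers 0..4
  expect_equal(which(one$values != 0), (4 - 1) * 25 + (3 - 1) * 5 + 3)
  set.seed(5)
  xyz <- matrix(runif(90, 0, 4), ncol = 3)
  g <- probability_density(xyz, grid, n_models = 6)
  expect_equal(sum(g$values) * 6, 30)
  # shifting the lattice by half a voxel conserves counts, moves positions
  grid2 <- density_grid(c(0.5, 0.5, 0.5), 1, c(5, 5, 5))
  g2 <- probability_density(xyz, grid2, n_models = 6)
  expect_equal(sum(g2$values) * 6, 30)
  recount <- array(0, c(5, 5, 5))
  idx <- round(sweep(xyz, 2, c(0.5, 0.5, 0.5))) + 1
  for (i in seq_len(30)) recount[idx[i, 1], idx[i, 2], idx[i, 3]] <-
    recount[idx[i, 1], idx[i, 2], idx[i, 3]] + 1
  expect_equal(g2$values, recount / 6)
  # out-of-grid atoms are counted nowhere and reported
  out <- probability_density(matrix(c(99, 0, 0), 1, 3), grid)
  expect_equal(sum(out$values), 0)
  expect_equal(attr(out, "n_outside"), 1L)
})

test_that("stitching reproduces the closed-form 1/r weighted averages", {
  lattice <- density_grid(c(0, 0, 0), 1, c(1, 1, 1))
  mk <- function(v) list(grid = density_grid(c(0, 0, 0), 1, c(1, 1, 1),
                                             array(v, c(1, 1, 1))),
                         center_residue = NA)
  ref2 <- point_reference(rbind(c(1, 0, 0), c(3, 0, 0)))
  # single region: output equals its value
  g1 <- mk(7); g1$center_residue <- 1
  expect_equal(as.numeric(stitch(list(g1), ref2, lattice, r_floor = 0.5)$values), 7)
  # equal distances: arithmetic mean
  refsym <- point_reference(rbind(c(2, 0, 0), c(-2, 0, 0)))
  a <- mk(2); a$center_residue <- 1
  b <- mk(10); b$center_residue <- 2
  expect_equal(as.numeric(stitch(list(a, b), refsym, lattice, r_floor = 0.5)$values), 6)
  # r = 1 and r = 3 with values a, b -> (3a + b) / 4
  a <- mk(2); a$center_residue <- 1
  b <- mk(10); b$center_residue <- 2
  expect_equal(as.numeric(stitch(list(a, b), ref2, lattice, r_floor = 0.5)$values),
               (3 * 2 + 10) / 4)
  # voxels covered by no region are zero
  lat3 <- density_grid(c(0, 0, 0), 1, c(3, 1, 1))
  g <- list(grid = density_grid(c(0, 0, 0), 1, c(1, 1, 1), array(5, c(1, 1, 1))),
            center_residue = 1)
  out <- stitch(list(g), ref2, lat3, r_floor = 0.5)
  expect_equal(as.numeric(out$values), c(5, 0, 0))
})

test_that("stitched values stay within the range of contributing regions", {
  lattice <- density_grid(c(0, 0, 0), 1, c(4, 4, 4))
  ref2 <- point_reference(rbind(c(0, 0, 0), c(3, 3, 3)))
  set.seed(13)
  mkg <- function(ctr) list(
    grid = density_grid(c(0, 0, 0), 1, c(4, 4, 4), array(runif(64), c(4, 4, 4))),
    center_residue = ctr)
  regions <- list(mkg(1), mkg(2))
  out <- stitch(regions, ref2, lattice)
  lo <- pmin(regions[[1]]$grid$values, regions[[2]]$grid$values)
  hi <- pmax(regions[[1]]$grid$values, regions[[2]]$grid$values)
  expect_true(all(out$values >= lo - 1e-12 & out$values <= hi + 1e-12))
})

test_that("trilinear interpolation matches the 8-corner formula", {
  set.seed(17)
  grid <- density_grid(c(-1, 2, 0.5), c(0.7, 0.9, 1.1), c(6, 5, 7),
                       array(rnorm(210), c(6, 5, 7)))
  ctr <- c(grid$origin[1] + 2 * 0.7, grid$origin[2] + 3 * 0.9, grid$origin[3] + 1.1)
  expect_equal(trilinear(grid, ctr), grid$values[3, 4, 2])
  mid <- ctr + c(0.35, 0, 0)
  expect_equal(trilinear(grid, mid), (grid$values[3, 4, 2] + grid$values[4, 4, 2]) / 2)
  pts <- cbind(runif(40, grid$origin[1], grid$origin[1] + 5 * 0.7),
               runif(40, grid$origin[2], grid$origin[2] + 4 * 0.9),
               runif(40, grid$origin[3], grid$origin[3] + 6 * 1.1))
  oracle <- vapply(seq_len(40), function(k) {
    f <- (pts[k, ] - grid$origin) / grid$spacing
    i0 <- pmin(floor(f), grid$dim - 2); fr <- f - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
      acc <- acc + prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr)) *
        grid$values[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    acc
  }, numeric(1))
  expect_lt(max(abs(trilinear(grid, pts) - oracle)), 1e-12)
  expect_error(trilinear(grid, c(99, 0, 0)), "outside")
})

test_that("resampling onto another lattice uses trilinear values and zero fill", {
  set.seed(19)
  src <- density_grid(c(0, 0, 0), 1, c(6, 6, 6), array(rnorm(216), c(6, 6, 6)))
  same <- resample_onto(src, src)
  expect_equal(same$values, src$values)
  const <- density_grid(c(0, 0, 0), 1, c(6, 6, 6), array(3.5, c(6, 6, 6)))
  tgt <- density_grid(c(0.3, 0.4, 0.2), c(1.7, 1.7, 1.7), c(3, 3, 3))
  expect_true(all(abs(resample_onto(const, tgt)$values - 3.5) < 1e-12))
  down <- density_grid(c(0.5, 0.5, 0.5), 2, c(3, 3, 3))
  out <- resample_onto(src, down)
  centers <- as.matrix(expand.grid(x = 0.5 + 2 * (0:2), y = 0.5 + 2 * (0:2),
                                   z = 0.5 + 2 * (0:2)))
  expect_equal(as.numeric(out$values), unname(trilinear(src, centers)))
  far <- density_grid(c(90, 90, 90), 1, c(2, 2, 2))
  zf <- resample_onto(src, far)
  expect_true(all(zf$values == 0))
  expect_equal(attr(zf, "n_outside"), 8L)
})

test_that("ensemble maps average models, decompose by species, ignore B-factors", {
  ref <- make_toy_rna(4, seed = 5)
  spec <- fixture_spec(n_models = 1, n_sites = 20, occupancy_range = c(1, 1),
                       n_bulk_waters = 3, seed = 8)
  one <- make_solvent_ensemble(ref, spec)
  five <- one
  five$models <- rep(one$models, 5)
  m1 <- ensemble_to_map(one, ref)
  m5 <- ensemble_to_map(five, ref)
  expect_lt(max(abs(m5$total$values - m1$total$values)), 1e-9)
  # species decomposition sums to the total
  expect_lt(max(abs(m1$total$values -
                      Reduce(`+`, lapply(m1$species, `[[`, "values")))), 1e-9)
  # B-factors never influence densities
  jb <- one
  jb$models <- lapply(jb$models, function(at) { at$b_factor <- runif(nrow(at), 0, 99); at })
  expect_identical(ensemble_to_map(jb, ref)$total$values, m1$total$values)
  # peaks sit on the planted sites (argmax within one voxel)
  sites <- attr(one, "sites")
  tot <- m1$total
  for (k in head(order(-sites$occupancy), 3)) {
    p <- as.numeric(sites[k, c("x", "y", "z")])
    idx <- round((p - tot$origin) / tot$spacing) + 1
    box <- tot$values[pmax(1, idx[1] - 1):pmin(tot$dim[1], idx[1] + 1),
                      pmax(1, idx[2] - 1):pmin(tot$dim[2], idx[2] + 1),
                      pmax(1, idx[3] - 1):pmin(tot$dim[3], idx[3] + 1)]
    expect_gte(max(box), 0.5 * max(tot$values[idx[1], idx[2], idx[3]]))
    expect_gt(tot$values[idx[1], idx[2], idx[3]], 0)
  }
})

test_that("probability maps from larger ensembles converge on the distribution", {
  ref <- make_toy_rna(3, seed = 5)
  cfg <- cryoshell_config(density_method = "prob")
  sites <- default_sites(ref, n_sites = 40, seed = 30)
  build <- function(n, seed) {
    spec <- fixture_spec(n_models = n, sites = sites, n_bulk_waters = 0, seed = seed)
    ensemble_to_map(make_solvent_ensemble(ref, spec), ref, cfg)$total$values
  }
  rms <- function(a, b) sqrt(mean((a - b)^2))
  d_small <- mean(c(rms(build(40, 31), build(40, 32)),
                    rms(build(40, 35), build(40, 36))))
  d_large <- mean(c(rms(build(160, 33), build(160, 34)),
                    rms(build(160, 37), build(160, 38))))
  expect_gt(d_small, 1.4 * d_large)  # ~ 1/sqrt(n) shrinkage
})
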