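test_that("neighbourhood membership matches a brute-force all-pairs scan", {
  ref <- make_toy_rna(10, seed = 2)
  at <- ref$atoms[toupper(ref$atoms$element) != "H", ]
  res <- sort(unique(at$residue_index))
  brute <- function(radius) {
    sapply(res, function(i) sapply(res, function(j) {
      xi <- coords_of(at[at$residue_index == i, ])
      xj <- coords_of(at[at$residue_index == j, ])
      d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
      min(sqrt(pmax(d2, 0))) <= radius
    }))
  }
  for (radius in c(6, 10)) {
    nb <- build_neighborhoods(ref, radius)
    m <- brute(radius)
    for (i in seq_along(res)) {
      expect_setequal(nb[[i]]$members, res[m[, i]])
      expect_true(nb[[i]]$center %in% nb[[i]]$members)
    }
    # symmetry of the membership relation
    for (i in seq_along(res)) for (j in seq_along(res))
      expect_equal(res[j] %in% nb[[i]]$members, res[i] %in% nb[[j]]$members)
  }
})

test_that("neighbourhoods are monotone in radius and handle isolated residues", {
  ref <- make_toy_rna(10, seed = 2)
  nbs <- lapply(c(6, 10, 12), function(r) build_neighborhoods(ref, r))
  for (i in seq_along(nbs[[1]])) {
    expect_true(all(nbs[[1]][[i]]$members %in% nbs[[2]][[i]]$members))
    expect_true(all(nbs[[2]][[i]]$members %in% nbs[[3]][[i]]$members))
  }
  iso <- point_reference(rbind(c(0, 0, 0), c(40, 0, 0)))
  nb <- build_neighborhoods(iso, 10)
  expect_equal(nb[[1]]$members, 1L)
  expect_equal(nb[[2]]$members, 2L)
  expect_error(build_neighborhoods(ref, 0), "positive")
})

test_that("the Kabsch fit recovers exact rigid motions", {
  set.seed(4)
  pts <- matrix(rnorm(30), ncol = 3)
  id <- kabsch(pts, pts)
  expect_lt(max(abs(id$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
  expect_lt(id$rmsd, 1e-9)
  Q <- rotation_about(c(1, 2, 3), 0.7)
  tr <- c(4, -2, 1)
  fit <- kabsch(pts, sweep(pts %*% t(Q), 2, -tr))
  expect_lt(max(abs(fit$rotation - Q)), 1e-9)
  expect_lt(max(abs(fit$translation - tr)), 1e-9)
  expect_lt(fit$rmsd, 1e-9)
  moved <- apply_transform(pts, fit)
  expect_lt(max(abs(moved - sweep(pts %*% t(Q), 2, -tr))), 1e-9)
})

test_that("Kabsch RMSD matches the quaternion-method oracle on random clouds", {
  set.seed(11)
  for (rep in 1:20) {
    a <- matrix(rnorm(30), ncol = 3)
    b <- matrix(rnorm(30), ncol = 3)
    fit <- kabsch(a, b)
    expect_lt(abs(fit$rmsd - quaternion_rmsd(a, b)), 1e-9)
    expect_lt(abs(det(fit$rotation) - 1), 1e-9)
    expect_lt(max(abs(crossprod(fit$rotation) - diag(3))), 1e-9)
    # alignment never increases the RMSD
    expect_lte(fit$rmsd, sqrt(mean(rowSums((a - b)^2))) + 1e-12)
  }
})

test_that("reflections are excluded and degenerate point sets rejected", {
  set.seed(12)
  pts <- matrix(rnorm(24), ncol = 3)
  mirror <- pts %*% diag(c(-1, 1, 1))
  fit <- kabsch(pts, mirror)
  expect_gt(det(fit$rotation), 0)
  expect_gt(fit$rmsd, 0)  # a mirror image cannot be reached by rotation
  line <- cbind(seq_len(5), 0, 0)
  expect_error(kabsch(line, line), "collinear")
  expect_error(kabsch(pts[1:2, ], pts[1:2, ]), "at least 3")
})

test_that("alignment atom selections follow residue type and intersect sides", {
  ref <- make_toy_rna(8, seed = 1)
  at <- ref$atoms
  g_res <- at$residue_index[match("G", at$residue_name)]
  u_res <- at$residue_index[match("U", at$residue_name)]
  sel5 <- select_alignment_atoms(at, at, g_res, "five_atom")
  expect_equal(sel5$n, 5L)
  sel3 <- select_alignment_atoms(at, at, u_res, "three_atom")
  expect_equal(sel3$n, 3L)
  expect_identical(sel5$mobile, sel5$target)
  # atom names actually selected
  gat <- at[at$residue_index == g_res, ]
  expect_setequal(
    gat$atom_name[apply(coords_of(gat), 1, function(p)
      any(colSums(abs(t(sel5$target) - p)) < 1e-9))],
    c("P", "C4'", "C2", "N9", "C6"))
  # a model missing its P drops the atom from both sides
  model <- at[!(at$residue_index == g_res & at$atom_name == "P"), ]
  sel4 <- select_alignment_atoms(model, at, g_res, "five_atom")
  expect_equal(sel4$n, 4L)
  expect_equal(nrow(sel4$mobile), nrow(sel4$target))
  # fewer than 3 common atoms is an alignment-impossible error
  model2 <- at[at$residue_index == g_res & at$atom_name %in% c("P", "C4'"), ]
  expect_error(select_alignment_atoms(model2, at, g_res, "five_atom"),
               class = "cryoshell_undefined_metric")
  # backbone selection uses the configurable atom list
  selb <- select_alignment_atoms(at, at, g_res, "backbone",
                                 backbone_atoms = c("P", "C4'", "C1'"))
  expect_equal(selb$n, 3L)
})

test_that("local solvent extraction is exact for identity and rigid motion", {
  ref <- make_toy_rna(6, seed = 9)
  spec <- fixture_spec(n_models = 3, n_sites = 12, occupancy_range = c(1, 1),
                       n_bulk_waters = 0, seed = 4)
  ens <- make_solvent_ensemble(ref, spec)
  nbh <- build_neighborhoods(ref, 10)
  clouds <- extract_local_solvent(ens, nbh, ref)
  for (cl in clouds) {
    expect_lt(cl$rmsd, 1e-9)
    expect_lt(max(abs(cl$transform$rotation - diag(3))), 1e-6)
  }
  # apply a distinct global rigid motion to every model: clouds must agree
  set.seed(21)
  moved <- ens
  moved$models <- lapply(ens$models, function(at) {
    R <- rotation_about(rnorm(3), runif(1, 0.3, 2))
    xyz <- sweep(coords_of(at) %*% t(R), 2, -rnorm(3, 0, 15))
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    at
  })
  clouds2 <- extract_local_solvent(moved, nbh, ref)
  key <- vapply(clouds2, function(cl) cl$center_residue, numeric(1))
  for (ctr in unique(key)) {
    grp <- clouds2[key == ctr]
    xyz <- lapply(grp, function(cl) coords_of(cl$atoms))
    for (m in seq_along(xyz)[-1]) {
      expect_equal(nrow(xyz[[m]]), nrow(xyz[[1]]))
      expect_lt(max(abs(xyz[[m]] - xyz[[1]])), 1e-6)
    }
  }
})

test_that("hinge motion yields small local but large global RMSD", {
  ref <- make_toy_rna(8, seed = 1)
  spec <- fixture_spec(n_models = 5, n_sites = 10, n_bulk_waters = 0,
                       hinge = list(residues = 5:8, angle_sd = 12), seed = 6)
  ens <- make_solvent_ensemble(ref, spec)
  global_rmsd <- vapply(ens$models, function(at) {
    a <- at[at$species == "RNA", ]
    sqrt(mean(rowSums((coords_of(a) - coords_of(ref$atoms))^2)))
  }, numeric(1))
  clouds <- extract_local_solvent(ens, build_neighborhoods(ref, 6), ref)
  local_rmsd <- vapply(clouds, function(cl) cl$rmsd, numeric(1))
  expect_gt(mean(global_rmsd), 4 * mean(local_rmsd))
})
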