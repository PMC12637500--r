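# Shared fixtures and independent oracles for the test suite.

coords_of <- function(at) unname(as.matrix(at[, c("x", "y", "z")]))

# small cached fixture system used by several files (8-residue helix,
# default hydration-layer spec)
fixture_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- make_toy_rna(8, seed = 1)
      spec <- fixture_spec(seed = 3)
      rmap <- make_reference_map(ref, spec, seed = 11)
      mask <- compute_shell(ref, rmap)
      cache <<- list(ref = ref, spec = spec, rmap = rmap, mask = mask,
                     sites = attr(make_solvent_ensemble(ref, spec), "sites"))
    }
    cache
  }
})

# Horn's quaternion method for least-squares rigid superposition: an
# independent oracle for the minimized RMSD of a Kabsch fit.
quaternion_rmsd <- function(mobile, target) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sq <- (sum(A^2) + sum(B^2) - 2 * lambda) / nrow(A)
  sqrt(max(sq, 0))
}

# rotation matrix about a given axis (unit) by angle (radians)
rotation_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# naive per-voxel double-loop scattering density oracle
naive_scatter <- function(xyz, elements, grid, table = scattering_table()) {
  co <- table$coefficients[elements, , drop = FALSE]
  out <- array(0, grid$dim)
  for (k in seq_len(grid$dim[3])) for (j in seq_len(grid$dim[2]))
    for (i in seq_len(grid$dim[1])) {
      v <- grid$origin + (c(i, j, k) - 1) * grid$spacing
      acc <- 0
      for (a in seq_len(nrow(xyz))) {
        r2 <- sum((v - xyz[a, ])^2)
        if (r2 > table$cutoff_radius^2) next
        aa <- co[a, 1:5]; bb <- co[a, 6:10]
        acc <- acc + sum(aa * (4 * pi / bb)^1.5 * exp(-4 * pi^2 * r2 / bb))
      }
      out[i, j, k] <- acc
    }
  out
}

# brute-force precision-recall enumeration over all distinct thresholds
naive_pr <- function(x, labels) {
  thr <- sort(unique(x), decreasing = TRUE)
  P <- sum(labels)
  prec <- rec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    call <- x >= thr[i]
    tp <- sum(call & labels)
    prec[i] <- tp / sum(call)
    rec[i] <- tp / P
  }
  auc <- sum(diff(c(0, rec)) * prec)
  list(thresholds = thr, precision = prec, recall = rec, auc_pr = auc)
}

# write an ensemble as a minimal mmCIF atom_site loop (test serialization
# independent of the package's PDB writer)
write_cif_fixture <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_fixture", "loop_",
               paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                       "label_atom_id", "label_alt_id",
                                       "label_comp_id", "label_asym_id",
                                       "label_seq_id", "pdbx_PDB_ins_code",
                                       "Cartn_x", "Cartn_y", "Cartn_z",
                                       "occupancy", "B_iso_or_equiv",
                                       "auth_seq_id", "auth_asym_id",
                                       "pdbx_PDB_model_num"))), con)
  for (m in seq_along(ensemble$models)) {
    at <- ensemble$models[[m]]
    rec <- ifelse(!is.na(at$species) & at$species != "RNA", "HETATM", "ATOM")
    writeLines(sprintf("%s %d %s \"%s\" . %s A %d ? %.3f %.3f %.3f 1.00 %.2f %d A %d",
                       rec, seq_len(nrow(at)), at$element, at$atom_name,
                       at$residue_name, at$residue_index, at$x, at$y, at$z,
                       at$b_factor, at$residue_index, m), con)
  }
  invisible(path)
}

# tiny hand-built reference: n single-phosphorus residues at given coords
point_reference <- function(xyz, excluded = integer()) {
  at <- data.frame(element = "P", atom_name = "P", residue_name = "G",
                   residue_index = seq_len(nrow(xyz)), chain_id = "A",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   species = "RNA", b_factor = 0, stringsAsFactors = FALSE)
  reference_structure(at, excluded)
}
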