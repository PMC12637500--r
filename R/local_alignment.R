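#' @name local_alignment
#' @title Per-residue neighbourhoods and local Kabsch superposition
#' @description
#' Global superposition of an ensemble would let RNA conformational drift
#' blur the solvent signal, so the solvent around each residue is aligned
#' locally: the residue's neighbourhood (all residues with any heavy atom
#' within a radius of it on the reference) defines the RNA atoms used for a
#' rigid Kabsch fit of each model onto the reference, and the model's local
#' solvent is carried through that transform into the reference frame.
NULL

.purines <- c("A", "G", "RA", "RG", "ADE", "GUA", "A3", "A5", "G3", "G5")

#' Build per-residue alignment neighbourhoods on the reference RNA
#'
#' Residue `j` belongs to the neighbourhood of residue `i` iff some heavy
#' atom of `j` lies within `radius` of some heavy atom of `i` in the
#' reference structure; the relation is symmetric and every neighbourhood
#' contains its centre.
#'
#' @param ref a `reference_structure`.
#' @param radius \enc{Å}{A} (default 10; 6, 12 and 20 are the standard
#'   alternatives for studying neighbourhood-size effects).
#' @param selection atom selection later used for the fit: `"all_heavy"`,
#'   `"backbone"`, `"five_atom"` or `"three_atom"`.
#' @return list of neighbourhoods: `list(center, members, radius, selection)`.
#' @export
build_neighborhoods <- function(ref, radius = 10,
                                selection = c("all_heavy", "backbone",
                                              "five_atom", "three_atom")) {
  selection <- match.arg(selection)
  if (radius <= 0) stop("radius must be positive")
  at <- ref$atoms[is_heavy(ref$atoms), , drop = FALSE]
  res <- sort(unique(at$residue_index))
  xyz <- lapply(res, function(r) atom_coords(at[at$residue_index == r, , drop = FALSE]))
  cent <- t(vapply(xyz, colMeans, numeric(3)))
  rad <- vapply(seq_along(xyz), function(i)
    sqrt(max(rowSums(sweep(xyz[[i]], 2, cent[i, ])^2))), numeric(1))
  n <- length(res)
  members <- vector("list", n)
  for (i in seq_len(n)) members[[i]] <- i
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    # bounding-sphere prefilter before the exact min atom-pair distance
    dc <- sqrt(sum((cent[i, ] - cent[j, ])^2))
    if (dc - rad[i] - rad[j] > radius) next
    dmin <- min(cpp_min_dist(xyz[[i]], xyz[[j]])$dist)
    if (dmin <= radius) {
      members[[i]] <- c(members[[i]], j)
      members[[j]] <- c(members[[j]], i)
    }
  }
  lapply(seq_len(n), function(i)
    list(center = res[i], members = res[sort(members[[i]])],
         radius = radius, selection = selection))
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Returns the rotation and translation minimizing the RMSD of
#' `mobile %*% t(R) + t` to `target` over proper rotations (reflections are
#' excluded by the determinant sign correction).
#'
#' @param mobile,target n x 3 matrices of corresponded points, n >= 3,
#'   non-collinear.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` of the fit.
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stop("point sets differ in length")
  if (nrow(mobile) < 3L) stop("need at least 3 corresponded points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  s <- svd(crossprod(A, B))      # H = A^T B = U d V^T
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("degenerate (collinear) point set: rotation is not determined")
  sgn <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, sgn)) %*% t(s$u)
  tr <- as.numeric(ct - R %*% cm)
  fit <- A %*% t(R) - B
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums(fit^2))))
}

#' Apply a rigid transform to points
#'
#' @param xyz n x 3 matrix.
#' @param tf list with `rotation` and `translation` (as from [kabsch()]).
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tf) {
  sweep(as.matrix(xyz) %*% t(tf$rotation), 2, -tf$translation)
}

# identity transform, used for degenerate compositions
identity_transform <- function() list(rotation = diag(3), translation = rep(0, 3))

#' Select corresponded alignment atoms for a set of residues
#'
#' Filters both model and reference atoms of the given residues to the
#' requested selection, keeps only atoms present on both sides (matched by
#' residue index and atom name), and returns them in the same order.
#' Selections: all heavy atoms; the backbone atom list; the 5-atom set P,
#' C4', C2 plus N9/C6 for purines or N1/C4 for pyrimidines; the 3-atom set
#' P, C4' plus N9 (purines) or N1 (pyrimidines).
#'
#' @param model_atoms,ref_atoms atom tables sharing residue indices.
#' @param residues residue indices to use.
#' @param selection one of `"all_heavy"`, `"backbone"`, `"five_atom"`,
#'   `"three_atom"`.
#' @param backbone_atoms atom-name set for the backbone selection.
#' @return list with matrices `mobile` (model) and `target` (reference) and
#'   the common atom count `n`; fewer than 3 common atoms is an error.
#' @export
select_alignment_atoms <- function(model_atoms, ref_atoms, residues,
                                   selection = "all_heavy",
                                   backbone_atoms = cryoshell_config()$backbone_atoms) {
  pick <- function(at) {
    at <- at[at$residue_index %in% residues & is_heavy(at), , drop = FALSE]
    if (!anyNA(at$species)) at <- at[at$species == "RNA", , drop = FALSE]
    if (selection == "all_heavy") return(at)
    if (selection == "backbone")
      return(at[at$atom_name %in% backbone_atoms, , drop = FALSE])
    pur <- at$residue_name %in% .purines
    keep <- if (selection == "five_atom") {
      (at$atom_name %in% c("P", "C4'", "C2")) |
        (pur & at$atom_name %in% c("N9", "C6")) |
        (!pur & at$atom_name %in% c("N1", "C4"))
    } else { # three_atom
      (at$atom_name %in% c("P", "C4'")) |
        (pur & at$atom_name == "N9") | (!pur & at$atom_name == "N1")
    }
    at[keep, , drop = FALSE]
  }
  m <- pick(model_atoms); r <- pick(ref_atoms)
  mk <- paste(m$residue_index, m$atom_name)
  rk <- paste(r$residue_index, r$atom_name)
  common <- intersect(mk, rk)
  if (length(common) < 3L)
    undefined_metric("alignment_impossible",
                     sprintf("only %d common alignment atoms", length(common)))
  common <- common[order(as.integer(sub(" .*", "", common)), sub("^[^ ]+ ", "", common))]
  list(mobile = atom_coords(m[match(common, mk), , drop = FALSE]),
       target = atom_coords(r[match(common, rk), , drop = FALSE]),
       n = length(common))
}

#' Extract locally aligned solvent clouds from an ensemble
#'
#' For every (model, neighbourhood) pair: fit the model's selected RNA atoms
#' of the member residues onto the reference with [kabsch()], collect the
#' model's solvent atoms within `capture_radius` of the member-residue RNA
#' heavy atoms (distances in the model frame, before the transform), and
#' map them into the reference frame. Neighbourhoods whose alignment is
#' impossible (too few common atoms, degenerate geometry) are skipped and
#' recorded, never aborting the run.
#'
#' @param ensemble a standardized, trimmed `solvent_ensemble`.
#' @param neighborhoods from [build_neighborhoods()].
#' @param ref the `reference_structure`.
#' @param config a [cryoshell_config()] list (capture radius, selection,
#'   backbone set).
#' @return list of clouds `list(center_residue, model_index, atoms, rmsd,
#'   transform)`; skipped (model, centre) pairs in `attr(, "skipped")`.
#' @export
extract_local_solvent <- function(ensemble, neighborhoods, ref,
                                  config = cryoshell_config()) {
  clouds <- list()
  skipped <- list()
  ref_at <- ref$atoms
  for (m in seq_along(ensemble$models)) {
    at <- ensemble$models[[m]]
    if (anyNA(at$species)) stop("ensemble must be standardized first")
    rna <- at[at$species == "RNA", , drop = FALSE]
    solv <- at[at$species != "RNA", , drop = FALSE]
    solv_xyz <- atom_coords(solv)
    for (nb in neighborhoods) {
      tf <- tryCatch({
        sel <- select_alignment_atoms(rna, ref_at, nb$members, nb$selection,
                                      config$backbone_atoms)
        kabsch(sel$mobile, sel$target)
      }, error = function(e) e)
      if (inherits(tf, "error")) {
        skipped[[length(skipped) + 1L]] <-
          list(model = m, center = nb$center, reason = conditionMessage(tf))
        next
      }
      memb <- rna[rna$residue_index %in% nb$members & is_heavy(rna), , drop = FALSE]
      cl_atoms <- solv[0, , drop = FALSE]
      if (nrow(solv) && nrow(memb)) {
        d <- cpp_min_dist(solv_xyz, atom_coords(memb))$dist
        sel_idx <- which(d <= config$solvent_capture_radius)
        if (length(sel_idx)) {
          cl_atoms <- solv[sel_idx, , drop = FALSE]
          new_xyz <- apply_transform(atom_coords(cl_atoms), tf)
          cl_atoms$x <- new_xyz[, 1]; cl_atoms$y <- new_xyz[, 2]; cl_atoms$z <- new_xyz[, 3]
        }
      }
      clouds[[length(clouds) + 1L]] <- list(
        center_residue = nb$center, model_index = m,
        atoms = cl_atoms, rmsd = tf$rmsd, transform = tf)
    }
  }
  attr(clouds, "skipped") <- skipped
  clouds
}
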