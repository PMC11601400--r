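## Rigid-body deformation geometry of the strained ternary complex.
##
## The clash between the partner and the effector-bound switch resolves
## through global strain: the partner pivots from its clashing design
## position to its strained position about a located axis.  We recover that
## pivot as the screw (Chasles) decomposition of the rigid transform
## mapping the clashing partner onto the switch-aligned strained partner,
## and measure its orientation against the interface binder helix.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets, via SVD of the cross-covariance matrix with the
#' reflection branch excluded.
#'
#' @param moving n x 3 coordinate matrix to be moved, Angstrom.
#' @param fixed n x 3 target coordinates, paired row-by-row with `moving`.
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3; the transform is `x %*% t(R) + t`), and `rmsd` (Angstrom).
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!identical(dim(moving), dim(fixed)) || ncol(moving) != 3L ||
      nrow(moving) < 3L)
    stop("need paired n x 3 coordinate sets with n >= 3", call. = FALSE)
  cm <- colMeans(moving); cf <- colMeans(fixed)
  a <- sweep(moving, 2, cm); b <- sweep(fixed, 2, cf)
  h <- crossprod(a, b)                    # 3x3 cross-covariance
  sv <- svd(h)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) coordinate set: rotation ill-defined",
         call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))        # exclude reflections
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cf - as.vector(r %*% cm)
  moved <- moving %*% t(r) + matrix(trans, nrow(moving), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  list(rotation = r, translation = trans, rmsd = rmsd)
}

apply_rigid <- function(coords, rotation, translation) {
  as.matrix(coords) %*% t(rotation) +
    matrix(translation, nrow(coords), 3, byrow = TRUE)
}

## principal-axis line fit through a Calpha trace; direction oriented
## N- to C-terminal
principal_axis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L)
    stop("need >= 3 points for an axis fit", call. = FALSE)
  cen <- colMeans(coords)
  sv <- svd(sweep(coords, 2, cen))
  ax <- sv$v[, 1]
  if (sum(ax * (coords[nrow(coords), ] - coords[1, ])) < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}

#' Paired structure container for deformation analysis
#'
#' Holds Calpha coordinates of the reference (clashing design model) and
#' strained (predicted ternary complex) structures, split into the host
#' switch region used for alignment and the partner whose pivot is
#' measured.  Rows correspond across paired sets by residue index.  The
#' interface binder helix — part of the host fusion and structurally
#' identical across variants — is addressed by a residue range into the
#' reference host coordinates and supplies the helix axis against which
#' deformation perpendicularity is measured.
#'
#' @param switch_coords_ref,switch_coords_strained n x 3 Calpha matrices of
#'   the switch region, Angstrom.
#' @param partner_coords_clash,partner_coords_strained m x 3 Calpha
#'   matrices of the partner.
#' @param helix_axis_residues integer range (>= 7 residues, two helical
#'   turns) indexing the binder helix rows within the reference host
#'   coordinates.
#' @return An object of class `"structure_pair"`.
#' @export
structure_pair <- function(switch_coords_ref, switch_coords_strained,
                           partner_coords_clash, partner_coords_strained,
                           helix_axis_residues) {
  sr <- as.matrix(switch_coords_ref); ss <- as.matrix(switch_coords_strained)
  pc <- as.matrix(partner_coords_clash)
  ps <- as.matrix(partner_coords_strained)
  if (!identical(dim(sr), dim(ss)) || !identical(dim(pc), dim(ps)))
    stop("paired coordinate sets must have matching dimensions",
         call. = FALSE)
  if (nrow(sr) < 3L || nrow(pc) < 3L)
    stop("coordinate sets must have >= 3 residues", call. = FALSE)
  helix_axis_residues <- as.integer(helix_axis_residues)
  if (length(helix_axis_residues) < 7L)
    stop("helix range must span >= 7 residues (two turns)", call. = FALSE)
  if (any(helix_axis_residues < 1L) || any(helix_axis_residues > nrow(sr)))
    stop("helix range outside the reference host coordinates",
         call. = FALSE)
  structure(list(switch_coords_ref = sr, switch_coords_strained = ss,
                 partner_coords_clash = pc, partner_coords_strained = ps,
                 helix_axis_residues = helix_axis_residues),
            class = "structure_pair")
}

#' @export
print.structure_pair <- function(x, ...) {
  cat(sprintf(
    "structure pair: switch %d residues, partner %d residues, helix %d-%d\n",
    nrow(x$switch_coords_ref), nrow(x$partner_coords_clash),
    min(x$helix_axis_residues), max(x$helix_axis_residues)))
  invisible(x)
}

## screw (Chasles) decomposition of x -> R x + t:
## rotation angle, unit axis, point on the axis (perpendicular to the axis,
## minimising screw translation), and residual translation along the axis.
screw_decompose <- function(rotation, translation, theta_tol = 1e-6) {
  tr <- sum(diag(rotation))
  theta <- acos(min(max((tr - 1) / 2, -1), 1))
  if (theta < theta_tol)
    return(list(theta = theta, axis = NULL, point = NULL,
                translation_residual = sqrt(sum(translation^2)),
                degenerate = TRUE))
  if (pi - theta < 1e-7) {
    ## near-180 degrees: axis from the dominant column of R + I
    m <- rotation + diag(3)
    j <- which.max(colSums(m^2))
    axis <- m[, j] / sqrt(sum(m[, j]^2))
  } else {
    axis <- c(rotation[3, 2] - rotation[2, 3],
              rotation[1, 3] - rotation[3, 1],
              rotation[2, 1] - rotation[1, 2]) / (2 * sin(theta))
    axis <- axis / sqrt(sum(axis^2))
  }
  d_along <- sum(translation * axis)       # screw translation along axis
  t_perp <- translation - d_along * axis
  ## axis point p solves (I - R) p = t_perp with p perpendicular to axis;
  ## least-squares via pseudoinverse handles the singular direction
  m <- diag(3) - rotation
  sv <- svd(m)
  dinv <- ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
  p <- sv$v %*% (dinv * crossprod(sv$u, t_perp))
  p <- as.vector(p - sum(p * axis) * axis)
  list(theta = theta, axis = axis, point = p,
       translation_residual = d_along, degenerate = FALSE)
}

#' Pivot-axis decomposition of the clash-to-strained deformation
#'
#' Measures how the partner relaxes from its clashing design position to
#' its strained position in the ternary complex: (1) the strained complex
#' is superposed onto the reference via the switch coordinates; (2) the
#' rigid transform carrying the clashing partner onto the switch-aligned
#' strained partner is computed; (3) that transform is decomposed into
#' screw form, giving the pivot angle `theta` (the deformation angle
#' theta - theta0), the located pivot axis, and the residual translation
#' along it; (4) the interface binder helix axis is obtained by a
#' principal-component line fit over the declared residue range; (5) `phi`
#' is the angle between pivot and helix axes folded to [0, pi/2], and
#' `sin_phi` its sine — the "perpendicularity" of the deformation to the
#' secondary structure.
#'
#' @param pair a [structure_pair].
#' @param theta_tol rotation angle below which the pivot is degenerate
#'   (axis undefined).
#' @return An object of class `"deformation_geometry"` with elements
#'   `theta` (radians), `pivot_axis`, `pivot_point` (Angstrom),
#'   `helix_axis`, `phi`, `sin_phi`, `translation_residual` (Angstrom),
#'   `switch_rmsd` and `degenerate`.
#' @export
pivot_decomposition <- function(pair, theta_tol = 1e-6) {
  stopifnot(inherits(pair, "structure_pair"))
  ## (1) align the strained complex onto the reference frame via the switch
  al <- superpose(pair$switch_coords_strained, pair$switch_coords_ref)
  partner_strained <- apply_rigid(pair$partner_coords_strained,
                                  al$rotation, al$translation)
  ## (2) clash -> strained partner transform
  tp <- superpose(pair$partner_coords_clash, partner_strained)
  ## (3) screw decomposition
  sc <- screw_decompose(tp$rotation, tp$translation, theta_tol = theta_tol)
  ## (4) helix axis from the reference host
  helix <- principal_axis(
    pair$switch_coords_ref[pair$helix_axis_residues, , drop = FALSE])
  if (sc$degenerate) {
    geom <- list(theta = sc$theta, pivot_axis = NULL, pivot_point = NULL,
                 helix_axis = helix, phi = NA_real_, sin_phi = NA_real_,
                 translation_residual = sc$translation_residual,
                 partner_rmsd = tp$rmsd, switch_rmsd = al$rmsd,
                 degenerate = TRUE)
    return(structure(geom, class = "deformation_geometry"))
  }
  ## (5) perpendicularity: fold phi to [0, pi/2] (sign-free)
  cosphi <- abs(sum(sc$axis * helix))
  phi <- acos(min(max(cosphi, 0), 1))
  structure(list(theta = sc$theta, pivot_axis = sc$axis,
                 pivot_point = sc$point, helix_axis = helix,
                 phi = phi, sin_phi = sin(phi),
                 translation_residual = sc$translation_residual,
                 partner_rmsd = tp$rmsd, switch_rmsd = al$rmsd,
                 degenerate = FALSE),
            class = "deformation_geometry")
}

#' @export
print.deformation_geometry <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf(
      "deformation geometry: degenerate (theta = %.3g rad, axis undefined)\n",
      x$theta))
    return(invisible(x))
  }
  cat("deformation geometry:\n")
  cat(sprintf("  pivot angle theta - theta0 = %.6g rad (%.3f deg)\n",
              x$theta, x$theta * 180 / pi))
  cat(sprintf("  pivot axis  [%s], point [%s] A\n",
              paste(sprintf("%.4f", x$pivot_axis), collapse = ", "),
              paste(sprintf("%.2f", x$pivot_point), collapse = ", ")))
  cat(sprintf("  helix angle phi = %.4g rad, sin(phi) = %.4f\n",
              x$phi, x$sin_phi))
  cat(sprintf("  screw translation along axis = %.4g A\n",
              x$translation_residual))
  invisible(x)
}

#' Build a structure pair from PDB files
#'
#' Convenience reader extracting Calpha coordinates for the switch and
#' partner chains of a clashing design model and a strained ternary-complex
#' model.  Requires the bio3d package.
#'
#' @param pdb_ref,pdb_strained paths to PDB files of the reference
#'   (clashing) and strained models.
#' @param switch_chain,partner_chain chain identifiers in both files.
#' @param helix_axis_residues residue range (indices within the switch
#'   chain's Calpha trace) of the interface binder helix.
#' @return A [structure_pair].
#' @export
structure_pair_from_pdb <- function(pdb_ref, pdb_strained,
                                    switch_chain = "A", partner_chain = "B",
                                    helix_axis_residues) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("structure_pair_from_pdb requires the bio3d package",
         call. = FALSE)
  ca <- function(path, chain) {
    pdb <- bio3d::read.pdb(path)
    sel <- bio3d::atom.select(pdb, chain = chain, elety = "CA")
    matrix(pdb$xyz[sel$xyz], ncol = 3, byrow = TRUE)
  }
  structure_pair(ca(pdb_ref, switch_chain), ca(pdb_strained, switch_chain),
                 ca(pdb_ref, partner_chain), ca(pdb_strained, partner_chain),
                 helix_axis_residues)
}
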