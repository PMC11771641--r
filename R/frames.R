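# Reference frames for bases, base pairs and G-tetrads.
#
# A frame is the local coordinate system of the standard-reference-frame
# (Tsukuba) convention: x points toward the major groove, y toward the
# backbone of the sequence-first strand, z along the local helix advance.
# Frames are stored as origin + 3x3 matrix whose ROWS are the axes in
# global coordinates (so the matrix maps global displacements into frame
# coordinates by left multiplication).

#' Construct a reference frame
#'
#' @param origin numeric length-3, angstrom.
#' @param axes 3x3 orthonormal right-handed matrix; rows are the x, y, z
#'   axes expressed in global coordinates.
#' @return object of class `ref_frame`.
#' @export
ref_frame <- function(origin, axes) {
  axes <- as.matrix(axes)
  if (max(abs(axes %*% t(axes) - diag(3))) > 1e-8) {
    stop("frame axes must be orthonormal")
  }
  if (det(axes) < 0) stop("frame axes must be right-handed")
  structure(list(origin = as.numeric(origin), axes = axes), class = "ref_frame")
}

#' @export
print.ref_frame <- function(x, ...) {
  cat("<ref_frame> origin:", sprintf("%.3f", x$origin), "\n")
  print(round(x$axes, 4))
  invisible(x)
}

# Rotation matrix with frame axes as columns (frame -> global).
frame_rotation <- function(f) t(f$axes)

frame_from_rotation <- function(R, origin) ref_frame(origin, t(R))

# Express global points (rows) in frame coordinates.
to_frame <- function(f, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1, 3)
  sweep(pts, 2, f$origin) %*% t(f$axes)
}

# Flip a base frame for the complementary-strand base of a pair: y and z
# axes are negated so paired frames become comparable (a 180 deg rotation
# about x, keeping the frame right-handed).
flip_frame <- function(f) ref_frame(f$origin, diag(c(1, -1, -1)) %*% f$axes)

apply_rigid_frame <- function(f, R, t = c(0, 0, 0)) {
  ref_frame(as.numeric(R %*% f$origin) + t, f$axes %*% t(R))
}

#' Fit the standard reference frame to an observed base
#'
#' Least-squares rigid superposition (Kabsch) of the embedded standard base
#' template onto the observed ring heavy atoms. The returned frame carries
#' the fit RMSD as attribute `"fit_rmsd"` — a quality flag for deformed or
#' flipped-out bases, which are fitted, never dropped.
#'
#' @param coords named coordinate source: a matrix with atom-name rownames
#'   covering the canonical ring atoms (purine: N1,C2,N3,C4,C5,C6,N7,C8,N9;
#'   pyrimidine: N1,C2,N3,C4,C5,C6).
#' @param base residue type, one of A/C/G/T (or DA/DC/DG/DT).
#' @return a [ref_frame()] with attribute `fit_rmsd` (angstrom).
#' @export
base_frame <- function(coords, base) {
  tmpl <- base_template(base)
  ring <- ring_atom_names(base)
  have <- rownames(coords)
  miss <- setdiff(ring, have)
  if (length(miss)) {
    stop("base ", base, " is missing ring atom(s): ", paste(miss, collapse = ", "))
  }
  obs <- coords[ring, , drop = FALSE]
  fit <- kabsch(tmpl[ring, , drop = FALSE], obs)
  f <- frame_from_rotation(fit$R, fit$t)
  attr(f, "fit_rmsd") <- fit$rmsd
  f
}

# Halfway rotation between two rotation matrices (slerp at 1/2 via
# axis-angle of the relative rotation).
halfway_rotation <- function(R1, R2) {
  Rrel <- t(R1) %*% R2
  tr <- (sum(diag(Rrel)) - 1) / 2
  ang <- acos(max(-1, min(1, tr)))
  if (ang < 1e-6) return(R1)  # acos is ill-conditioned near identity
  ax <- c(Rrel[3, 2] - Rrel[2, 3], Rrel[1, 3] - Rrel[3, 1], Rrel[2, 1] - Rrel[1, 2])
  if (vnorm(ax) < 1e-12) stop("halfway rotation undefined for a 180-degree relative rotation")
  R1 %*% rotation_about(ax, ang / 2)
}

#' Mid-frame of a base pair
#'
#' Origin is the midpoint of the two base-frame origins; axes are the
#' halfway rotation between the two frames (the complementary frame must
#' already be flipped, see [flip_frame()]).
#'
#' @param f1 frame of the reference-strand base.
#' @param f2_flipped flipped frame of the complementary base.
#' @param check if `TRUE`, require the two z-axes to be within 65 degrees
#'   (the pairing precondition used by automatic pair detection).
#' @return a [ref_frame()].
#' @export
pair_frame <- function(f1, f2_flipped, check = FALSE) {
  if (check) {
    cosz <- sum(f1$axes[3, ] * f2_flipped$axes[3, ])
    if (cosz < cos(65 * pi / 180)) {
      stop("frames do not satisfy the pairing precondition (z-axes > 65 deg apart)")
    }
  }
  Rm <- halfway_rotation(frame_rotation(f1), frame_rotation(f2_flipped))
  # re-orthonormalize against accumulated numerical drift
  sv <- svd(Rm)
  Rm <- sv$u %*% t(sv$v)
  frame_from_rotation(Rm, (f1$origin + f2_flipped$origin) / 2)
}

#' Glycosidic torsion and anti/syn state
#'
#' chi is the signed dihedral O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2
#' for pyrimidines. The state is `anti` iff chi mod 360 lies in [90, 270)
#' (boundary assigned to anti), `syn` otherwise.
#'
#' @param coords coordinate matrix with atom-name rownames for one
#'   nucleotide (needs O4', C1' and the two base atoms).
#' @param base residue type (A/C/G/T).
#' @return list with `chi` (degrees, in (-180, 180]) and `state`.
#' @export
chi_state <- function(coords, base) {
  atoms <- if (is_purine(base)) c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
  miss <- setdiff(atoms, rownames(coords))
  if (length(miss)) {
    stop("chi for base ", base, " needs atom(s): ", paste(miss, collapse = ", "))
  }
  chi <- dihedral_deg(coords[atoms[1], ], coords[atoms[2], ],
                      coords[atoms[3], ], coords[atoms[4], ])
  chi360 <- chi %% 360
  state <- if (chi360 >= 90 && chi360 < 270) "anti" else "syn"
  list(chi = chi, state = state)
}

#' Reference frame of a G-tetrad
#'
#' Origin is the mean of the four guanine base-frame origins; z is the
#' total-least-squares normal of the plane through the four origins,
#' oriented toward the declared solvent-exposed side; x is the in-plane
#' projection of the vector from the origin to the N9 atom of the first
#' guanine.
#'
#' @param guanine_coords list of four coordinate matrices (atom-name
#'   rownames), one per guanine, in tetrad order.
#' @param side_reference a global point on the solvent-exposed side toward
#'   which +z must point (e.g. the centroid of the flanking tetrad negated,
#'   or a 5'/3' marker atom).
#' @return a [ref_frame()].
#' @export
tetrad_frame <- function(guanine_coords, side_reference = NULL) {
  if (length(guanine_coords) != 4) stop("a tetrad needs exactly four guanines")
  frames <- lapply(guanine_coords, base_frame, base = "G")
  origins <- do.call(rbind, lapply(frames, `[[`, "origin"))
  ctr <- colMeans(origins)
  dev <- sweep(origins, 2, ctr)
  sv <- svd(dev)
  z <- sv$v[, 3]
  # near-degenerate plane fit (4 nearly coplanar points): average base
  # normals as tie-breaker orientation
  mean_normal <- colMeans(do.call(rbind, lapply(frames, function(f) f$axes[3, ])))
  if (sum(z * mean_normal) < 0) z <- -z
  if (!is.null(side_reference)) {
    if (sum(z * (side_reference - ctr)) < 0) z <- -z
  }
  n9 <- guanine_coords[[1]]["N9", ]
  xr <- n9 - ctr
  xr <- xr - sum(xr * z) * z
  x <- unit(xr)
  y <- cross3(z, x)
  ref_frame(ctr, rbind(x, y, z))
}
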