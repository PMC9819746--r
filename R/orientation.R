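# The (Z, alpha, beta) state triad: membrane-referenced centre-of-mass height
# plus tilt and rotation angles built on the beta-sheet reference vectors of
# the three-finger fold.
#
# A runs from the beta-structural core ("head") to the tip of the central
# loop (II); B runs from loop III to loop I; both lie in the beta-sheet plane.
# alpha = 90 deg - angle(A, z): positive when the head dips toward the
# membrane, negative when the central loop does. beta is assembled from
# angle(B, z) by a three-branch rule switched on the signs of B_z and F_z,
# where F disambiguates the hemisphere; the default F is the sheet normal
# (unit A x B), the only completion that makes the branch rule cover the full
# circle (see the methods vignette).

mass_com <- function(xyz, idx, mass) {
  w <- mass[idx]
  colSums(xyz[idx, , drop = FALSE] * w) / sum(w)
}

#' Assign bilayer leaflets from phosphorus atoms
#'
#' Lipid residues bearing a phosphorus atom are split into upper and lower
#' leaflets by comparing each P z-coordinate with the bilayer midplane (the
#' mean z of all lipid P atoms) in the supplied frame. The assignment is
#' frozen: downstream per-frame analysis reuses it, so transient z-crossings
#' do not flip lipids between leaflets. Phosphorus-free lipids (cholesterol)
#' are excluded.
#'
#' @param topology an `lu_topology`.
#' @param xyz `natoms x 3` coordinates (nm) of the assignment frame.
#' @return object of class `lu_leaflets`: atom indices and lipid residue
#'   numbers per leaflet, plus the midplane z (nm).
#' @export
assign_leaflets <- function(topology, xyz) {
  at <- topology$atoms
  p_idx <- which(at$moiety == "lipid" & at$elem == "P")
  if (length(p_idx) < 2) {
    stop("need at least two phosphorus-bearing lipids to define leaflets")
  }
  z <- xyz[p_idx, 3]
  if (diff(range(z)) < 1e-9) {
    stop("degenerate bilayer: all lipid phosphorus atoms at identical z")
  }
  mid <- mean(z)
  up <- z > mid
  structure(list(
    upper_p_atoms = p_idx[up],
    lower_p_atoms = p_idx[!up],
    upper_lipids = unique(at$resno[p_idx[up]]),
    lower_lipids = unique(at$resno[p_idx[!up]]),
    midplane_z = mid
  ), class = "lu_leaflets")
}

#' Protein centre-of-mass height above the upper phosphate plane
#'
#' Z is the z-component of the mass-weighted centre of mass of the selected
#' amino-acid atoms minus the mean z of the upper-leaflet phosphorus atoms in
#' the same frame. Negative values (protein below the phosphate plane) are
#' returned unclamped.
#'
#' @param xyz `natoms x 3` frame coordinates (nm).
#' @param protein_sel atom indices of the protein's amino-acid atoms.
#' @param leaflets an `lu_leaflets` assignment.
#' @param topology the `lu_topology` (for masses and the amino-acid check).
#' @return Z in nm.
#' @export
com_height <- function(xyz, protein_sel, leaflets, topology) {
  if (!length(protein_sel)) stop("empty protein selection")
  moi <- topology$atoms$moiety[protein_sel]
  if (any(moi != "amino-acid")) {
    stop("protein selection for the COM height must contain amino-acid atoms only")
  }
  com_z <- mass_com(xyz, protein_sel, topology$atoms$mass)[3]
  unname(com_z - mean(xyz[leaflets$upper_p_atoms, 3]))
}

#' Reference vectors of the three-finger fold
#'
#' A: head-group COM to loop-II-tip COM. B: loop-III-tip COM to loop-I-tip
#' COM. F: the hemisphere-disambiguation vector for the rotation angle;
#' by default the beta-sheet normal `unit(A x B)`.
#'
#' @param xyz frame coordinates (nm).
#' @param groups an `lu_groups` residue-group configuration.
#' @param topology the `lu_topology`.
#' @param f_vector `"sheet_normal"` (default), `"a"`, or `"custom"` with
#'   `f_from`/`f_to` residue-number groups.
#' @param f_from,f_to residue groups defining a custom F (COM to COM).
#' @return object of class `lu_refvec` with unit-independent vectors `A`,
#'   `B`, `F` (nm) and the membrane `normal` (0, 0, 1).
#' @export
reference_vectors <- function(xyz, groups, topology,
                              f_vector = c("sheet_normal", "a", "custom"),
                              f_from = NULL, f_to = NULL) {
  f_vector <- match.arg(f_vector)
  at <- topology$atoms
  gcom <- function(resnos, what) {
    idx <- which(at$resno %in% resnos & at$moiety == "amino-acid")
    if (!length(idx)) stop("residue group '", what, "' resolves to no atoms")
    mass_com(xyz, idx, at$mass)
  }
  head_com <- gcom(groups$head, "head")
  l1 <- gcom(groups$loop1_tip, "loop1_tip")
  l2 <- gcom(groups$loop2_tip, "loop2_tip")
  l3 <- gcom(groups$loop3_tip, "loop3_tip")
  A <- l2 - head_com
  B <- l1 - l3
  if (vec_norm(A) == 0 || vec_norm(B) == 0) stop("degenerate reference vectors")
  FF <- switch(f_vector,
    sheet_normal = {
      cr <- c(A[2] * B[3] - A[3] * B[2],
              A[3] * B[1] - A[1] * B[3],
              A[1] * B[2] - A[2] * B[1])
      if (vec_norm(cr) == 0) stop("A and B are parallel; sheet normal undefined")
      unit_vec(cr)
    },
    a = A,
    custom = {
      if (is.null(f_from) || is.null(f_to)) stop("custom F needs f_from and f_to")
      gcom(f_to, "f_to") - gcom(f_from, "f_from")
    })
  structure(list(A = A, B = B, F = FF, normal = c(0, 0, 1)),
            class = "lu_refvec")
}

#' Tilt angle of the central loop
#'
#' `alpha = 90 - angle(A, z)` in degrees, in `[-90, 90]`. Positive alpha:
#' the head is tilted toward the membrane; negative: the central loop is;
#' zero: the head-to-loop-II axis is parallel to the membrane plane.
#'
#' @param v an `lu_refvec` (or a list with element `A`).
#' @return alpha in degrees.
#' @export
tilt_angle <- function(v) {
  a <- unit_vec(v$A)
  90 - acos_deg(sum(a * v$normal %||% c(0, 0, 1)))
}

#' Rotation angle about the head-to-central-loop axis
#'
#' Three-branch rule on `angle(B, z)` switched by the signs of `B_z` and
#' `F_z`:
#' `beta = 90 - angle(B, z)` if `F_z >= 0`;
#' `beta = 90 + angle(B, z)` if `B_z >= 0` and `F_z < 0`;
#' `beta = -270 + angle(B, z)` if `B_z < 0` and `F_z < 0`;
#' mapped into `(-180, 180]`. beta of about -90 means loop I faces the
#' membrane, +90 loop III, 0 the ventral side, +-180 the dorsal side.
#'
#' @param v an `lu_refvec` (elements `B` and `F`).
#' @return beta in degrees in `(-180, 180]`.
#' @export
rotation_angle <- function(v) {
  b <- unit_vec(v$B)
  f <- v$F
  if (vec_norm(f) == 0) stop("zero-length F vector")
  ang <- acos_deg(b[3])
  beta <- if (f[3] >= 0) {
    90 - ang
  } else if (b[3] >= 0) {
    90 + ang
  } else {
    -270 + ang
  }
  wrap_angle(beta)
}

#' Per-frame orientation series (Z, alpha, beta)
#'
#' Runs the full triad over a trajectory: the protein is unwrapped across
#' periodic boundaries (membrane atoms stay wrapped), leaflets are taken from
#' the supplied (or first-frame) assignment, and one `(time, Z, alpha, beta)`
#' record is produced per frame.
#'
#' @param traj an `lu_trajectory`.
#' @param groups an `lu_groups` configuration.
#' @param leaflets optional `lu_leaflets`; defaults to [assign_leaflets()] on
#'   frame 1.
#' @param f_vector,f_from,f_to passed to [reference_vectors()].
#' @param unwrap unwrap the protein before COM/vector computation (default
#'   TRUE; meaningless COMs result from wrapped molecules straddling the box).
#' @return data frame of class `lu_orient_series` with columns `time_ps`,
#'   `Z_nm`, `alpha_deg`, `beta_deg`.
#' @export
orientation_series <- function(traj, groups, leaflets = NULL,
                               f_vector = "sheet_normal",
                               f_from = NULL, f_to = NULL, unwrap = TRUE) {
  stopifnot(inherits(traj, "lu_trajectory"), inherits(groups, "lu_groups"))
  top <- traj$topology
  if (is.null(leaflets)) leaflets <- assign_leaflets(top, frame_coords(traj, 1))
  psel <- select_atoms(top, resno = groups$protein_all, moiety = "amino-acid")
  nf <- traj$nframes
  Z <- alpha <- beta <- numeric(nf)
  for (k in seq_len(nf)) {
    xyz <- frame_coords(traj, k)
    if (unwrap) xyz <- unwrap_group(xyz, psel, traj$box[k, ])
    Z[k] <- com_height(xyz, psel, leaflets, top)
    v <- reference_vectors(xyz, groups, top, f_vector = f_vector,
                           f_from = f_from, f_to = f_to)
    alpha[k] <- tilt_angle(v)
    beta[k] <- rotation_angle(v)
  }
  out <- data.frame(time_ps = traj$time_ps, Z_nm = Z,
                    alpha_deg = alpha, beta_deg = beta)
  class(out) <- c("lu_orient_series", "data.frame")
  attr(out, "label") <- groups$label
  out
}

#' @export
summary.lu_orient_series <- function(object, ...) {
  obs <- c("Z_nm", "alpha_deg", "beta_deg")
  s <- t(vapply(obs, function(v) {
    x <- object[[v]]
    c(min = min(x), median = stats::median(x), max = max(x), sd = stats::sd(x))
  }, numeric(4)))
  structure(list(label = attr(object, "label"), n_frames = nrow(object),
                 stats = s),
            class = "summary.lu_orient_series")
}

#' @export
print.summary.lu_orient_series <- function(x, ...) {
  cat("Orientation series:", x$label, "-", x$n_frames, "frames\n")
  print(round(x$stats, 3))
  invisible(x)
}

#' Write an orientation series to a TSV file
#' @param series an `lu_orient_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
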