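# Backbone PCA after xy-only superposition. The superposition mirrors the
# trjconv "rotxy+transxy" semantics: each frame is fitted to the reference by
# the least-squares rotation about the z-axis plus an x/y translation
# (a 2D Procrustes problem solved from the 2x2 cross-covariance SVD); z passes
# through untouched, so rise/pitch/roll-like motions relative to the membrane
# normal survive the fit. The covariance is not mass-weighted.

#' Superpose frames on a reference in the xy-plane only
#'
#' @param traj an `lu_trajectory`.
#' @param reference `natoms x 3` reference coordinates (nm), e.g. frame 1.
#' @param sel atom indices (>= 3) on which the fit is computed.
#' @return array like `traj$coords` with every frame aligned (all atoms are
#'   transformed; the fit itself uses `sel`).
#' @export
fit_xy <- function(traj, reference, sel) {
  stopifnot(inherits(traj, "lu_trajectory"))
  if (length(sel) < 3) stop("need at least 3 atoms in the fit selection")
  ref <- reference[sel, 1:2, drop = FALSE]
  ref_c <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_c)
  out <- traj$coords
  for (k in seq_len(traj$nframes)) {
    P <- out[sel, 1:2, k, drop = TRUE]
    p_c <- colMeans(P)
    P0 <- sweep(P, 2, p_c)
    M <- crossprod(P0, ref0)            # 2x2 cross-covariance
    sv <- svd(M)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)  # proper rotation about z
    xy <- out[, 1:2, k, drop = TRUE]
    xy <- sweep(xy, 2, p_c)
    out[, 1:2, k] <- sweep(xy %*% t(R), 2, ref_c, `+`)
  }
  out
}

#' Principal component analysis of backbone coordinates
#'
#' Covariance of the 3N coordinate vector of the selected atoms about its
#' time mean, eigendecomposed; per-frame projections on each component are
#' returned. Run on [fit_xy()]-aligned coordinates to reproduce the
#' rise/pitch/roll motion decomposition.
#'
#' @param aligned coordinate array `natoms x 3 x nframes` (nm).
#' @param sel backbone atom indices.
#' @return object of class `lu_pca`: `mean` (N x 3 mean structure),
#'   `values` (eigenvalues, nm^2, descending), `vectors` (3N x k orthonormal
#'   columns, xyz-interleaved per atom), `projections` (nframes x k, nm),
#'   `total_variance`.
#' @export
pca_backbone <- function(aligned, sel) {
  nf <- dim(aligned)[3]
  if (is.na(nf) || nf < 2) stop("PCA needs at least 2 frames")
  X <- t(apply(aligned[sel, , , drop = FALSE], 3, function(m) as.numeric(t(m))))
  # rows: frames; columns: x1 y1 z1 x2 y2 z2 ...
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nf - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  structure(list(mean = matrix(mu, ncol = 3, byrow = TRUE),
                 values = vals, vectors = e$vectors,
                 projections = Xc %*% e$vectors,
                 total_variance = sum(diag(C)), n_frames = nf),
            class = "lu_pca")
}

#' @export
print.lu_pca <- function(x, ...) {
  k <- min(5, length(x$values))
  cat("Backbone PCA:", x$n_frames, "frames,",
      length(x$values) / 3, "atoms\n")
  cat("  top eigenvalues (nm^2):", signif(x$values[seq_len(k)], 4), "\n")
  cat("  variance explained:",
      paste0(round(100 * x$values[seq_len(k)] / sum(x$values), 1), "%"), "\n")
  invisible(x)
}

#' Frames with extreme projections on a component
#'
#' @param result an `lu_pca`.
#' @param component component index (1-based).
#' @return named integer vector `c(min = ..., max = ...)` of frame indices;
#'   ties are broken toward the lowest frame index.
#' @export
extreme_projections <- function(result, component = 1) {
  if (component < 1 || component > ncol(result$projections)) {
    stop("component out of range")
  }
  p <- result$projections[, component]
  c(min = which.min(p), max = which.max(p))
}
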