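# Synthetic fixture generator: a planar two-leaflet pseudo-lipid patch plus a
# rigid mock three-finger protein posed at prescribed (Z, alpha, beta) paths,
# with exact ground truth, and optional planted residue-lipid contacts.
#
# Geometry of the legal pose domain: writing unit body axes a (along A),
# b (along B), n = a x b, the angle definitions force a_z = sin(alpha) and
# (in every branch of the rotation rule) b_z = sin(beta); orthonormality then
# requires sin^2(alpha) + sin^2(beta) <= 1. Poses outside that domain do not
# exist for any rigid orientation and are rejected.

#' Rigid mock three-finger protein template
#'
#' Marker residues define the reference-vector groups in a canonical pose
#' (A along +x, B along +y, sheet normal along +z): a four-residue head
#' cluster around the origin, loop tips I/II/III, and off-plane backbone
#' filler atoms that give the body three-dimensional extent. Separate probe
#' residues (LYS 51, TYR 52, ASP 53, LEU 54, SER 55) carry the atoms used by
#' [plant_contacts()]; they are excluded from the `protein_all` group so that
#' planting does not disturb the orientation ground truth.
#'
#' @return list with `atoms` (data frame), `xyz` (canonical coordinates, nm),
#'   and `groups` (an `lu_groups`).
#' @export
three_finger_template <- function() {
  mk <- function(name, resname, resno, x, y, z) {
    data.frame(name = name, resname = resname, resno = resno,
               x = x, y = y, z = z, stringsAsFactors = FALSE)
  }
  at <- rbind(
    # head cluster, COM at origin
    mk("CA", "GLY", 1, -0.15, -0.15, 0),
    mk("CA", "GLY", 2, -0.15,  0.15, 0),
    mk("CA", "GLY", 3,  0.15,  0.15, 0),
    mk("CA", "GLY", 4,  0.15, -0.15, 0),
    # loop I tip (COM 0.45, 0.45, 0)
    mk("CA", "GLY", 11, 0.40, 0.45, 0),
    mk("CA", "GLY", 11, 0.50, 0.45, 0),
    # loop II (central) tip (COM 0.80, 0, 0)
    mk("CA", "GLY", 21, 0.80, -0.05, 0),
    mk("CA", "GLY", 21, 0.80,  0.05, 0),
    # loop III tip (COM 0.45, -0.45, 0)
    mk("CA", "GLY", 31, 0.40, -0.45, 0),
    mk("CA", "GLY", 31, 0.50, -0.45, 0),
    # backbone filler, off-plane
    mk("CA", "ALA", 5, 0.10,  0.20,  0.15),
    mk("CA", "ALA", 6, 0.30, -0.10, -0.15),
    mk("CA", "ALA", 7, 0.55,  0.10,  0.10),
    mk("CA", "ALA", 8, 0.20,  0.00, -0.20),
    mk("CA", "ALA", 9, 0.60, -0.20,  0.05),
    # contact probe residues (moved by plant_contacts, rigid otherwise)
    mk("NZ",  "LYS", 51, 0.00, 0.30, 0.25),
    mk("OH",  "TYR", 52, 0.10, -0.30, 0.25),
    mk("HH",  "TYR", 52, 0.10, -0.30, 0.35),
    mk("CG",  "TYR", 52, 0.24, -0.30, 0.25),
    mk("CD1", "TYR", 52, 0.31, -0.42, 0.25),
    mk("CD2", "TYR", 52, 0.31, -0.18, 0.25),
    mk("CE1", "TYR", 52, 0.45, -0.42, 0.25),
    mk("CE2", "TYR", 52, 0.45, -0.18, 0.25),
    mk("CZ",  "TYR", 52, 0.52, -0.30, 0.25),
    mk("OD1", "ASP", 53, -0.20, 0.00, 0.30),
    mk("CD1", "LEU", 54, -0.10, -0.20, 0.30),
    mk("CD2", "LEU", 54, -0.10, -0.30, 0.30),
    mk("OG",  "SER", 55, -0.25, 0.20, 0.30),
    mk("HG1", "SER", 55, -0.25, 0.20, 0.40)
  )
  xyz <- as.matrix(at[, c("x", "y", "z")])
  atoms <- at[, c("name", "resname", "resno")]
  atoms$elem <- guess_element(atoms$name)
  atoms$mass <- element_mass(atoms$elem)
  atoms$chain <- "A"
  groups <- residue_groups(head = 1:4, loop1_tip = 11, loop2_tip = 21,
                           loop3_tip = 31, backbone = c(1:9, 11, 21, 31),
                           protein_all = c(1:9, 11, 21, 31),
                           label = "mock3f")
  list(atoms = atoms, xyz = xyz, groups = groups,
       probe_residues = c(LYS = 51L, TYR = 52L, ASP = 53L, LEU = 54L,
                          SER = 55L))
}

# Body-frame rotation realising (alpha, beta) with azimuth phi about z.
pose_rotation <- function(alpha, beta, phi) {
  ar <- deg2rad(alpha)
  br <- deg2rad(beta)
  sa <- sin(ar); ca <- cos(ar)
  sb <- sin(br)
  if (sa^2 + sb^2 > 1 + 1e-12) {
    stop(sprintf(
      "pose (alpha=%.3f, beta=%.3f) is geometrically infeasible: sin^2(alpha) + sin^2(beta) must be <= 1",
      alpha, beta))
  }
  # unit a with azimuth phi and a_z = sin(alpha)
  a <- c(ca * cos(phi), ca * sin(phi), sa)
  # horizontal and meridional unit vectors spanning the plane normal to a
  u <- c(-sin(phi), cos(phi), 0)
  v <- c(-sa * cos(phi), -sa * sin(phi), ca)
  # b = cos(psi) u + sin(psi) v with sin(psi) = sin(beta)/cos(alpha);
  # sign(cos(psi)) = sign(n_z) picks the hemisphere: n_z >= 0 iff |beta| <= 90
  sp <- if (ca < 1e-12) 0 else sb / ca
  sp <- pmin(1, pmax(-1, sp))
  cp <- sqrt(max(0, 1 - sp^2))
  if (abs(beta) > 90) cp <- -cp
  b <- cp * u + sp * v
  n <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cbind(a, b, n)  # maps body x->a, y->b, z->n
}

#' Pose the rigid template at a prescribed (Z, alpha, beta)
#'
#' Rotates the canonical template so that measuring the posed coordinates
#' with [tilt_angle()] / [rotation_angle()] (F = sheet normal) returns exactly
#' `(alpha, beta)`, and translates it so that [com_height()] over the core
#' `protein_all` group returns exactly `Z` relative to `plane_z`. The residual
#' symmetry (rotation about the membrane normal) is set by `phi`.
#'
#' @param template output of [three_finger_template()].
#' @param Z target COM height (nm) above the phosphate plane.
#' @param alpha,beta target angles (degrees); must satisfy `|alpha| <= 90`,
#'   `beta` in `(-180, 180]` and `sin^2(alpha) + sin^2(beta) <= 1`.
#' @param phi azimuth about the membrane normal (radians); `NULL` = random.
#' @param plane_z z of the upper phosphate plane (nm).
#' @param xy in-plane position of the protein COM (length 2, nm).
#' @return `natoms x 3` posed coordinates (nm).
#' @export
pose_protein <- function(template, Z, alpha, beta, phi = NULL,
                         plane_z = 0, xy = c(0, 0)) {
  if (abs(alpha) > 90) stop("|alpha| must be <= 90")
  if (beta <= -180 || beta > 180) stop("beta must lie in (-180, 180]")
  if (is.null(phi)) phi <- stats::runif(1, 0, 2 * pi)
  R <- pose_rotation(alpha, beta, phi)
  xyz <- template$xyz %*% t(R)
  # translate: core amino-acid COM to (xy, plane_z + Z)
  core <- which(template$atoms$resno %in% template$groups$protein_all)
  com <- colSums(xyz[core, , drop = FALSE] * template$atoms$mass[core]) /
    sum(template$atoms$mass[core])
  sweep(xyz, 2, com - c(xy, plane_z + Z))
}

#' Synthetic system specification
#'
#' Defines the lipid patch and the stochastic orientation processes. Each
#' observable (Z, alpha, beta) follows a mixture-of-Gaussians target realised
#' as an Ornstein-Uhlenbeck process that relaxes toward the mean of a
#' currently occupied mode; mode occupancy switches by a seeded Markov chain
#' whose stationary distribution equals the mixture weights, which yields
#' autocorrelated series resembling MD without simulating physics.
#'
#' Defaults emulate the reported behaviour of Lynx1: unimodal COM height
#' 1.43 +- 0.21 nm, tilt -31.5 +- 8.7 deg with a low-population mode at
#' 0.7 +- 6.5 deg, and two rotation modes -121.6 +- 8.6 / -47.9 +- 7.2 deg.
#'
#' @param nx,ny lipids per leaflet row/column (>= 2).
#' @param spacing lipid lattice spacing (nm).
#' @param leaflet_sep distance between upper and lower phosphate planes (nm).
#' @param Z,alpha,beta per-observable process: `list(means, sds, weights)`.
#' @param n_frames number of frames (>= 1).
#' @param dt_ps time step between frames (ps).
#' @param tau_ps OU relaxation time (ps).
#' @param switch_prob per-frame probability of redrawing the occupied mode.
#' @param headgroup_jitter_sd per-frame Gaussian z-jitter of lipid headgroup
#'   beads (nm); the patch is otherwise static.
#' @return object of class `lu_synth_spec`.
#' @export
synthetic_spec <- function(nx = 6, ny = 6, spacing = 0.8, leaflet_sep = 4,
                           Z = list(means = 1.43, sds = 0.21, weights = 1),
                           alpha = list(means = c(-31.5, 0.7),
                                        sds = c(8.7, 6.5),
                                        weights = c(0.8, 0.2)),
                           beta = list(means = c(-121.6, -47.9),
                                       sds = c(8.6, 7.2),
                                       weights = c(0.5, 0.5)),
                           n_frames = 1000, dt_ps = 1000, tau_ps = 5000,
                           switch_prob = 0.005,
                           headgroup_jitter_sd = 0.05) {
  chk <- function(p, nm) {
    if (length(p$means) != length(p$sds) || length(p$means) != length(p$weights))
      stop("process '", nm, "': means/sds/weights lengths differ")
    if (any(p$sds <= 0)) stop("process '", nm, "': SDs must be > 0")
    if (abs(sum(p$weights) - 1) > 1e-9)
      stop("process '", nm, "': weights must sum to 1")
    p
  }
  if (nx < 2 || ny < 2) stop("nx and ny must be >= 2")
  if (n_frames < 1) stop("n_frames must be >= 1")
  structure(list(nx = nx, ny = ny, spacing = spacing, leaflet_sep = leaflet_sep,
                 Z = chk(Z, "Z"), alpha = chk(alpha, "alpha"),
                 beta = chk(beta, "beta"),
                 n_frames = as.integer(n_frames), dt_ps = dt_ps,
                 tau_ps = tau_ps, switch_prob = switch_prob,
                 headgroup_jitter_sd = headgroup_jitter_sd),
            class = "lu_synth_spec")
}

# Build the patch topology rows and canonical bead offsets for one lipid.
# Beads: P (phosphate, charge -1), OA (polar acceptor), N4 (choline-like
# cation), C1/C2 (hydrophobic tail). Offsets are laterally separated so that
# planting one contact type cannot satisfy another criterion by accident.
.lipid_beads <- function() {
  data.frame(
    name = c("P", "OA", "N4", "C1", "C2"),
    dx = c(0, 0.25, -0.25, 0, 0),
    dy = c(0, 0.25, -0.25, 0, 0),
    dz = c(0, 0.10, 0.20, -0.60, -1.20),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic trajectory with exact ground truth
#'
#' Builds the patch + mock protein topology and a trajectory whose per-frame
#' `(Z, alpha, beta)` are draws from the spec's switching-OU processes.
#' `beta` is propagated on the circle; draws falling outside the joint legal
#' domain `sin^2(alpha) + sin^2(beta) <= 1` have `|sin(beta)|` shrunk onto the
#' boundary, and `|alpha|` is clamped to 89.9 deg away from the gimbal poles.
#' The ground truth records the values actually used, so measurement
#' round-trips are exact. Identical spec + seed gives identical output.
#'
#' @param spec an `lu_synth_spec`.
#' @param seed integer RNG seed.
#' @param dir optional directory; when given, writes `system.pdb` (topology +
#'   frame 1), `traj.dcd`, and `ground_truth.tsv` there.
#' @return list with `trajectory` (`lu_trajectory`), `topology`, `groups`,
#'   `ground_truth` (data frame: frame, time_ps, Z_nm, alpha_deg, beta_deg),
#'   `template`, and file paths when `dir` was given.
#' @export
generate_trajectory <- function(spec, seed = 1, dir = NULL) {
  stopifnot(inherits(spec, "lu_synth_spec"))
  set.seed(as.integer(seed))
  nf <- spec$n_frames

  draw_series <- function(p, circular = FALSE) {
    k <- length(p$weights)
    state <- sample.int(k, 1, prob = p$weights)
    x <- stats::rnorm(1, p$means[state], p$sds[state])
    lambda <- exp(-spec$dt_ps / spec$tau_ps)
    out <- numeric(nf)
    out[1] <- x
    if (nf > 1) for (t in 2:nf) {
      if (stats::runif(1) < spec$switch_prob) {
        state <- sample.int(k, 1, prob = p$weights)
      }
      mu <- p$means[state]
      dev <- x - mu
      if (circular) dev <- wrap_angle(dev)
      dev <- dev * lambda +
        p$sds[state] * sqrt(1 - lambda^2) * stats::rnorm(1)
      x <- mu + dev
      if (circular) x <- wrap_angle(x)
      out[t] <- x
    }
    out
  }

  Z <- draw_series(spec$Z)
  alpha <- draw_series(spec$alpha)
  beta <- draw_series(spec$beta, circular = TRUE)
  # clamp away from the gimbal poles, then project onto the joint domain
  alpha <- pmin(89.9, pmax(-89.9, alpha))
  sa2 <- sin(deg2rad(alpha))^2
  sb <- sin(deg2rad(beta))
  lim <- sqrt(pmax(0, 1 - sa2)) * (1 - 1e-9)
  over <- abs(sb) > lim
  if (any(over)) {
    # replace beta by the boundary angle with the same sign and hemisphere
    new_abs <- rad2deg(asin(lim[over]))
    hemi <- abs(beta[over]) > 90
    ab <- ifelse(hemi, 180 - new_abs, new_abs)
    beta[over] <- wrap_angle(sign(sb[over]) * ab)
  }

  tpl <- three_finger_template()
  beads <- .lipid_beads()
  nlip_leaf <- spec$nx * spec$ny
  lip_rows <- function(first_resno, z0) {
    idx <- 0
    rows <- vector("list", nlip_leaf)
    for (ix in seq_len(spec$nx)) for (iy in seq_len(spec$ny)) {
      idx <- idx + 1
      rows[[idx]] <- data.frame(
        name = beads$name, resname = "LIP",
        resno = first_resno + idx - 1,
        x = (ix - 0.5) * spec$spacing + beads$dx,
        y = (iy - 0.5) * spec$spacing + beads$dy,
        z = z0 + beads$dz, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  z_upper <- spec$leaflet_sep
  upper <- lip_rows(101, z_upper)
  lower <- lip_rows(101 + nlip_leaf, 0)
  lower$z <- 0 - (lower$z - 0)          # mirror tails upward
  lip <- rbind(upper, lower)
  lip_atoms <- lip[, c("name", "resname", "resno")]
  lip_atoms$elem <- guess_element(lip_atoms$name)
  lip_atoms$elem[lip_atoms$name == "OA"] <- "O"
  lip_atoms$elem[lip_atoms$name == "N4"] <- "N"
  lip_atoms$mass <- element_mass(lip_atoms$elem)
  lip_atoms$chain <- "L"

  atoms <- rbind(tpl$atoms, lip_atoms)
  atoms$moiety <- classify_moiety(atoms$resname, default_moiety_rules())
  top <- new_topology(atoms)
  npro <- nrow(tpl$atoms)
  lip_xyz <- as.matrix(lip[, c("x", "y", "z")])
  head_beads <- which(lip$name %in% c("P", "OA", "N4"))
  lip_ids <- sort(unique(lip$resno))
  head_lip <- match(lip$resno[head_beads], lip_ids)

  box <- c(spec$nx * spec$spacing, spec$ny * spec$spacing,
           z_upper + 6)
  centre <- box[1:2] / 2
  coords <- array(0, c(top$natoms, 3, nf))
  phi <- stats::runif(nf, 0, 2 * pi)
  # one z-jitter per lipid per frame: the headgroup moves as a unit, so the
  # relative bead geometry inside each headgroup is exact in every frame
  jit <- matrix(stats::rnorm(nf * length(lip_ids), 0,
                             spec$headgroup_jitter_sd),
                nf, length(lip_ids))
  for (k in seq_len(nf)) {
    lz <- lip_xyz
    lz[head_beads, 3] <- lz[head_beads, 3] + jit[k, head_lip]
    # reference plane = mean z of upper-leaflet P beads this frame
    upP <- which(lip$name == "P" & lip$resno <= 100 + nlip_leaf)
    plane <- mean(lz[upP, 3])
    pro <- pose_protein(tpl, Z[k], alpha[k], beta[k], phi = phi[k],
                        plane_z = plane, xy = centre)
    coords[seq_len(npro), , k] <- pro
    coords[npro + seq_len(nrow(lip)), , k] <- lz
  }
  traj <- trajectory(top, coords, time_ps = (seq_len(nf) - 1) * spec$dt_ps,
                     box = box)
  gt <- data.frame(frame = seq_len(nf), time_ps = traj$time_ps,
                   Z_nm = Z, alpha_deg = alpha, beta_deg = beta)
  out <- list(trajectory = traj, topology = top, groups = tpl$groups,
              ground_truth = gt, template = tpl)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$files <- c(
      pdb = write_pdb_topology(top, coords[, , 1], file.path(dir, "system.pdb")),
      dcd = write_dcd(traj, file.path(dir, "traj.dcd")),
      ground_truth = {
        p <- file.path(dir, "ground_truth.tsv")
        utils::write.table(gt, p, sep = "\t", row.names = FALSE, quote = FALSE)
        p
      })
  }
  out
}

#' Plant residue-lipid contacts at prescribed time fractions
#'
#' Moves the probe residues of a generated synthetic system so that, in
#' exactly `ceiling(fraction * n_frames)` seeded-random frames, the probe
#' satisfies the named contact criterion against a chosen upper-leaflet
#' lipid, and in all other frames sits far above the membrane (beyond every
#' cutoff plus a 0.2 nm margin). Supported types and probes:
#' `ionic` (LYS 51 NZ vs the lipid P bead), `hbond` (a hydroxyl probe, SER 55
#' OG/HG1 or TYR 52 OH/HH, vs the OA bead), `pication` (TYR 52 ring vs the N4
#' bead), `hydrophobic` (LEU 54 CD1/CD2 vs the C1 tail bead; note this plants
#' two simultaneous atom pairs, so the detected lifetime is twice the planted
#' fraction while the ground-truth `lifetime` column stores the per-frame
#' presence fraction).
#'
#' @param sim output of [generate_trajectory()].
#' @param plan data frame with columns `resno`, `type`, `fraction` (and
#'   optionally `lipid` resno); fractions in `[0, 1]`.
#' @param criteria an `lu_contact_criteria` (cutoffs used for placement).
#' @param seed RNG seed for the frame subsets.
#' @return `sim` with modified trajectory and a `planted` ground-truth table
#'   (resno, type, lipid, fraction, n_frames_on, frames as list column).
#' @export
plant_contacts <- function(sim, plan, criteria = contact_criteria(), seed = 1) {
  stopifnot(is.data.frame(plan), all(c("resno", "type", "fraction") %in% names(plan)))
  if (any(plan$fraction < 0 | plan$fraction > 1)) stop("fractions must be in [0, 1]")
  set.seed(as.integer(seed))
  top <- sim$topology
  at <- top$atoms
  traj <- sim$trajectory
  nf <- traj$nframes
  # upper-leaflet lipid resnos, deterministic order
  leaf <- assign_leaflets(top, frame_coords(traj, 1))
  upper <- sort(leaf$upper_lipids)
  ann <- annotate_atoms(top)
  probe_sign <- vapply(seq_len(nrow(plan)), function(i) {
    idx <- which(at$resno == plan$resno[i] & at$moiety == "amino-acid")
    ch <- ann$charge[idx]
    if (any(ch != 0)) sign(ch[ch != 0][1]) else 1
  }, numeric(1))
  park_z <- sim$trajectory$box[1, 3] - 1  # far above everything
  planted <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    resno <- plan$resno[i]
    type <- plan$type[i]
    frac <- plan$fraction[i]
    lipid <- if ("lipid" %in% names(plan) && !is.na(plan$lipid[i])) {
      plan$lipid[i]
    } else {
      upper[(i - 1) %% length(upper) + 1]
    }
    pidx <- which(at$resno == resno & at$moiety == "amino-acid")
    if (!length(pidx)) stop("plan residue ", resno, " not found in topology")
    n_on <- as.integer(ceiling(frac * nf - 1e-9))
    on_frames <- if (n_on > 0) sort(sample.int(nf, n_on)) else integer(0)
    lat <- function(nm) which(at$resno == lipid & at$name == nm)
    place <- function(k, on) {
      xyz <- traj$coords[, , k]
      if (!on) {
        # park high above the membrane, laterally spread by plan row
        base <- c(0.5 + 0.6 * i, 0.5, park_z)
        off <- sweep(sim$template$xyz[pidx, , drop = FALSE], 2,
                     sim$template$xyz[pidx[1], ])
        xyz[pidx, ] <- sweep(off, 2, base, `+`)
      } else if (type == "ionic") {
        # cationic probes pair with the phosphate bead, anionic probes with
        # the choline-like cation bead
        bead <- if (probe_sign[i] >= 0) "P" else "N4"
        target <- xyz[lat(bead), ]
        d <- criteria$ionic_dist - 0.05
        xyz[pidx[1], ] <- target + c(0, 0, d)
      } else if (type == "hbond") {
        target <- xyz[lat("OA"), ]
        oh <- pidx[at$elem[pidx] == "O"][1]
        hh <- pidx[at$elem[pidx] == "H"]
        if (is.na(oh)) stop("residue ", resno, " has no oxygen donor to plant")
        xyz[oh, ] <- target + c(0, 0, 0.30)
        if (length(hh)) xyz[hh[1], ] <- target + c(0, 0, 0.20)
        hh <- hh[1][!is.na(hh[1])]
        others <- setdiff(pidx, c(oh, hh))
        if (length(others)) {
          # keep the rest of the residue away from the membrane
          off <- sweep(sim$template$xyz[others, , drop = FALSE], 2,
                       sim$template$xyz[others[1], ])
          xyz[others, ] <- sweep(off, 2, target + c(0.9, 0.9, 1.2), `+`)
        }
      } else if (type == "pication") {
        target <- xyz[lat("N4"), ]
        ring <- which(at$resno == resno &
                        at$name %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
        cen <- target + c(0, 0, criteria$pication_dist - 0.15)
        ang <- seq(0, 2 * pi, length.out = 7)[1:6]
        xyz[ring, ] <- cbind(cen[1] + 0.14 * cos(ang),
                             cen[2] + 0.14 * sin(ang),
                             rep(cen[3], 6))
        others <- setdiff(pidx, ring)
        if (length(others)) {
          off <- sweep(sim$template$xyz[others, , drop = FALSE], 2,
                       sim$template$xyz[others[1], ])
          xyz[others, ] <- sweep(off, 2, target + c(0.9, 0.9, 1.5), `+`)
        }
      } else if (type == "hydrophobic") {
        target <- xyz[lat("C1"), ]
        cd1 <- which(at$resno == resno & at$name == "CD1")
        cd2 <- which(at$resno == resno & at$name == "CD2")
        d <- criteria$hydrophobic_dist - 0.08
        xyz[cd1, ] <- target + c(0, 0, d)
        xyz[cd2, ] <- target + c(0.05, 0, d)
      } else {
        stop("unsupported planted contact type: ", type)
      }
      traj$coords[, , k] <<- xyz
    }
    on <- logical(nf)
    on[on_frames] <- TRUE
    for (k in seq_len(nf)) place(k, on[k])
    planted[[i]] <- data.frame(resno = resno, type = type, lipid = lipid,
                               fraction = frac, n_frames_on = n_on,
                               lifetime = n_on / nf)
    planted[[i]]$frames <- list(on_frames)
  }
  sim$trajectory <- traj
  sim$planted <- do.call(rbind, planted)
  sim
}
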