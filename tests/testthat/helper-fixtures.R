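# Fixture builders shared across test files. Everything is generated in code;
# no stored binary data.

# Build an lu_topology directly from atom fields (test-only shortcut around
# the file readers).
fix_topology <- function(name, resname, resno, xyz = NULL, chain = "A",
                         moiety = NULL) {
  atoms <- data.frame(name = name, resname = resname, resno = resno,
                      stringsAsFactors = FALSE)
  atoms$elem <- luorient:::guess_element(atoms$name)
  atoms$mass <- luorient:::element_mass(atoms$elem)
  atoms$chain <- chain
  atoms$moiety <- if (is.null(moiety)) {
    luorient:::classify_moiety(atoms$resname, default_moiety_rules())
  } else moiety
  top <- luorient:::new_topology(atoms)
  if (!is.null(xyz)) attr(top, "xyz_nm") <- xyz
  top
}

# A flat 36-lipid patch (two leaflets of 18) with P atoms at z = hi / lo, as
# bare phosphorus-bearing pseudo-POPC.
fix_bilayer_topology <- function(hi = 4, lo = 0, resname = "POPC") {
  n <- 18
  name <- rep("P", 2 * n)
  resno <- 101:(100 + 2 * n)
  xyz <- cbind(rep(seq(0.5, by = 0.8, length.out = 6), 6),
               rep(seq(0.5, by = 0.8, length.out = 6), each = 6),
               c(rep(hi, n), rep(lo, n)))
  fix_topology(name, rep(resname, 2 * n), resno, xyz = xyz, chain = "L")
}

# Reference-vector object for direct angle tests.
fix_refvec <- function(A, B, F, normal = c(0, 0, 1)) {
  structure(list(A = A, B = B, F = F, normal = normal), class = "lu_refvec")
}

# Sample a (Z, alpha, beta) triple uniformly from the legal pose domain
# sin^2(alpha) + sin^2(beta) <= 1, away from the poles.
sample_pose_triple <- function(alpha_max = 89) {
  a <- stats::runif(1, -alpha_max, alpha_max)
  lim <- sqrt(max(0, 1 - sin(a * pi / 180)^2)) * 0.999
  bmax <- asin(lim) * 180 / pi
  b <- if (stats::runif(1) < 0.5) {
    stats::runif(1, -bmax, bmax)
  } else {
    sample(c(-1, 1), 1) * stats::runif(1, 180 - bmax, 180)
  }
  c(Z = stats::runif(1, 0.5, 3), alpha = a, beta = b)
}

# Mock-protein topology with all template atoms marked amino-acid.
fix_template_topology <- function(tpl = three_finger_template()) {
  atoms <- tpl$atoms
  atoms$moiety <- "amino-acid"
  luorient:::new_topology(atoms)
}

# Measure (Z, alpha, beta) of posed coordinates against a phosphate plane at
# plane_z, using the package's own measurement path.
measure_pose <- function(xyz, tpl, top, plane_z = 0) {
  v <- reference_vectors(xyz, tpl$groups, top)
  core <- which(top$atoms$resno %in% tpl$groups$protein_all)
  comz <- sum(xyz[core, 3] * top$atoms$mass[core]) / sum(top$atoms$mass[core])
  c(Z = unname(comz - plane_z), alpha = tilt_angle(v), beta = rotation_angle(v))
}

# Smallest circular difference in degrees.
circ_diff <- function(a, b) {
  d <- abs(luorient::wrap_angle(a - b))
  pmin(d, 360 - d)
}

# Low-noise synthetic spec for contact fixtures: protein held high and level
# so only planted contacts can occur.
fix_contact_spec <- function(n_frames) {
  synthetic_spec(n_frames = n_frames,
                 Z = list(means = 2.0, sds = 0.01, weights = 1),
                 alpha = list(means = 0, sds = 1, weights = 1),
                 beta = list(means = 0, sds = 1, weights = 1))
}

# Encode the published Lynx1 contact rows as a timeline fixture: four ionic
# residues (two strong), eleven hydrogen-bond residues (three strong), three
# GPI entries in the ionic column, one glycan-free hydrophobic set.
fix_lynx1_timelines <- function() {
  ion <- c(D31 = 0.2, R38 = 0.2, R57 = 0.6, K59 = 0.6)
  hb <- c(Y28 = 0.2, N29 = 0.2, G30 = 0.2, N32 = 0.6, C33 = 0.2, F34 = 0.2,
          N35 = 0.6, Y53 = 0.6, T54 = 0.2, T56 = 0.2, Y76 = 0.2)
  gpi_ion <- c("DSPI-1" = 0.6, "GlcN-2" = 0.2, "PEtN-Man-3" = 0.6)
  hyd <- c(C26 = 2.5, A27 = 2.5, P36 = 2.5, P55 = 2.5)
  rows <- list()
  for (l in names(ion)) rows[[length(rows) + 1]] <-
    contact_timeline(l, "amino-acid", "ion_ion", ion[[l]])
  for (l in names(hb)) rows[[length(rows) + 1]] <-
    contact_timeline(l, "amino-acid", "hbond", hb[[l]])
  for (l in names(gpi_ion)) rows[[length(rows) + 1]] <-
    contact_timeline(l, "gpi", "ion_ion", gpi_ion[[l]])
  for (l in names(hyd)) rows[[length(rows) + 1]] <-
    contact_timeline(l, "amino-acid", "hydrophobic", hyd[[l]],
                     max_simultaneous = 3)
  # residues listed under hydrogen bonds also form sub-threshold ionic
  # contacts; and the strong ionic residues also hydrogen-bond (they must
  # appear in the ionic column only)
  rows[[length(rows) + 1]] <- contact_timeline("R57", "amino-acid", "hbond", 0.3)
  rows[[length(rows) + 1]] <- contact_timeline("K59", "amino-acid", "hbond", 0.2)
  do.call(rbind, rows)
}
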