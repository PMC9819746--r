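# Rule-based physico-chemical annotation of atoms from residue + atom names:
# formal charge groups, hydrogen-bond donors/acceptors, aromatic rings,
# cation groups for pi-cation geometry, and the sign of the atomic
# lipophilicity constant used for hydrophobic (molecular hydrophobic
# potential, MHP) contacts. The tables cover the twenty amino acids (CHARMM
# naming, His deprotonated/neutral), common CHARMM lipid headgroups, sugar
# residues, GPI-anchor residues, and the synthetic generator's bead lipid.
# All tables are plain R data and swappable via the `annotations` argument of
# the detection functions.

# --- amino-acid side-chain tables (backbone N donor / O acceptor added in code)
.aa_charged <- list(
  LYS = list(atoms = "NZ", sign = +1),
  ARG = list(atoms = c("NE", "NH1", "NH2", "CZ"), sign = +1),
  ASP = list(atoms = c("OD1", "OD2"), sign = -1),
  GLU = list(atoms = c("OE1", "OE2"), sign = -1)
)

.aa_donors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", TRP = "NE1",
  ASN = "ND2", GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  HIS = "NE2", HSD = "ND1", HSE = "NE2"
)

.aa_acceptors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", MET = "SD",
  ASN = "OD1", GLN = "OE1", ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  HIS = "ND1", HSD = "NE2", HSE = "ND1"
)

.aa_rings <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HSD = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HSE = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# side-chain carbons with polar/charged neighbours: excluded from MHP+
.aa_polar_carbons <- list(
  ARG = "CZ", ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD", TYR = "CZ",
  SER = "CB", THR = "CB", CYS = "CB"
)

.lipid_class_table <- c(
  CHL1 = "cholesterol",
  PSM = "sphingomyelin", SSM = "sphingomyelin", NSM = "sphingomyelin",
  LSM = "sphingomyelin",
  POPC = "phosphatidylcholine", DPPC = "phosphatidylcholine",
  DOPC = "phosphatidylcholine", DSPC = "phosphatidylcholine",
  POPE = "phosphatidylethanolamine", DOPE = "phosphatidylethanolamine",
  POPS = "other", POPI = "phosphatidylinositol",
  DSPI = "phosphatidylinositol", SAPI = "phosphatidylinositol",
  LIP = "other"
)

#' Lipid class of a residue name
#' @param resname lipid residue name(s).
#' @return class label: cholesterol, sphingomyelin, phosphatidylcholine,
#'   phosphatidylethanolamine, phosphatidylinositol, or other.
#' @export
lipid_class <- function(resname) {
  cl <- .lipid_class_table[toupper(resname)]
  cl[is.na(cl)] <- "other"
  unname(cl)
}

# Annotate every atom of a topology. Returns a list of per-atom vectors plus
# group structures used by the detectors.
annotate_atoms <- function(topology) {
  at <- topology$atoms
  n <- nrow(at)
  charge <- numeric(n)
  donor <- acceptor <- mhp_pos <- logical(n)
  polar <- at$elem %in% c("O", "N")
  res <- toupper(at$resname)
  nm <- toupper(at$name)
  aa <- at$moiety == "amino-acid"

  # backbone polar atoms of amino acids
  donor[aa & nm == "N"] <- TRUE
  acceptor[aa & nm == "O"] <- TRUE

  for (r in names(.aa_charged)) {
    sel <- aa & res == r & nm %in% .aa_charged[[r]]$atoms
    charge[sel] <- .aa_charged[[r]]$sign
  }
  for (r in names(.aa_donors)) donor[aa & res == r & nm %in% .aa_donors[[r]]] <- TRUE
  for (r in names(.aa_acceptors)) acceptor[aa & res == r & nm %in% .aa_acceptors[[r]]] <- TRUE

  # MHP sign: carbons are lipophilic unless bonded to polar/charged groups
  is_c <- at$elem == "C"
  mhp_pos[is_c] <- TRUE
  mhp_pos[aa & nm %in% c("C", "CA")] <- FALSE      # carbonyl and Calpha
  for (r in names(.aa_polar_carbons)) {
    mhp_pos[aa & res == r & nm %in% .aa_polar_carbons[[r]]] <- FALSE
  }

  lip <- at$moiety == "lipid"
  if (any(lip)) {
    # CHARMM lipid headgroups: phosphate (P, O11-O14) anionic, ester oxygens
    # acceptors, choline N cationic, tail carbons C2x/C3x (and sphingosine
    # chain) lipophilic
    phosO <- lip & grepl("^O1[1-4]$", nm)
    acceptor[phosO] <- TRUE
    charge[lip & nm %in% c("O13", "O14")] <- -1
    charge[lip & nm == "P"] <- -1
    charge[lip & nm == "N"] <- +1
    mhp_pos[lip & nm %in% c("N", "P")] <- FALSE
    mhp_pos[lip & grepl("^C1[3-5]$", nm)] <- FALSE   # choline methyls stay near N
    acceptor[lip & nm == "O3" & res == "CHL1"] <- TRUE
    donor[lip & nm == "O3" & res == "CHL1"] <- TRUE
    # synthetic bead lipid
    bead <- lip & res == "LIP"
    charge[bead] <- 0
    charge[bead & nm == "P"] <- -1
    charge[bead & nm == "N4"] <- +1
    acceptor[bead] <- FALSE
    acceptor[bead & nm == "OA"] <- TRUE
    donor[bead] <- FALSE
    polar[bead] <- FALSE
    polar[bead & nm == "OA"] <- TRUE
    mhp_pos[bead] <- FALSE
    mhp_pos[bead & nm %in% c("C1", "C2")] <- TRUE
  }

  # glycans / GPI: hydroxyl oxygens donate and accept; ring carbons are not
  # lipophilic; GlcN amine is a donor; PEtN phosphate anionic
  gly <- at$moiety %in% c("glycan", "gpi")
  if (any(gly)) {
    ox <- gly & at$elem == "O"
    donor[ox] <- TRUE
    acceptor[ox] <- TRUE
    donor[gly & res == "GLCN" & nm == "N2"] <- TRUE
    charge[gly & nm %in% c("O13", "O14")] <- -1
    mhp_pos[gly] <- FALSE
    # GPI lipid tails (DSPI/SAPI acyl chains) are lipophilic
    mhp_pos[gly & res %in% c("DSPI", "SAPI") & grepl("^C[23][0-9]", nm)] <- TRUE
  }

  # cation groups for pi-cation geometry: Lys NZ, Arg guanidinium centroid,
  # lipid choline N
  cation_groups <- list()
  add_cg <- function(idx, label) {
    if (length(idx)) cation_groups[[length(cation_groups) + 1]] <<-
        list(idx = idx, label = label)
  }
  for (rn in unique(at$resno[aa & res == "LYS"])) {
    add_cg(which(aa & at$resno == rn & nm == "NZ"), paste0("LYS", rn))
  }
  for (rn in unique(at$resno[aa & res == "ARG"])) {
    add_cg(which(aa & at$resno == rn & nm %in% c("NE", "NH1", "NH2", "CZ")),
           paste0("ARG", rn))
  }
  for (rn in unique(at$resno[lip & nm == "N"])) {
    add_cg(which(lip & at$resno == rn & nm == "N"), paste0("LIPN", rn))
  }
  for (rn in unique(at$resno[lip & nm == "N4"])) {
    add_cg(which(lip & at$resno == rn & nm == "N4"), paste0("LIPN4", rn))
  }

  rings <- list()
  for (r in names(.aa_rings)) {
    for (rn in unique(at$resno[aa & res == r])) {
      idx <- which(aa & at$resno == rn & nm %in% .aa_rings[[r]])
      if (length(idx) >= 3) {
        rings[[length(rings) + 1]] <- list(idx = idx, resno = rn, resname = r)
      }
    }
  }

  list(charge = charge, donor = donor, acceptor = acceptor, polar = polar,
       mhp_pos = mhp_pos, cation_groups = cation_groups, rings = rings)
}

#' Contact criteria configuration
#'
#' Geometric criteria for contact classification. The source analysis tool's
#' exact numeric criteria are not published with it; these defaults are the
#' standard MD-analysis conventions and every value is overridable.
#'
#' @param hbond_dist donor-acceptor heavy-atom max distance (nm).
#' @param hbond_angle max H-donor-acceptor angle (degrees).
#' @param ionic_dist max distance between atoms of oppositely charged groups
#'   (nm).
#' @param ion_dipole_dist max charged-atom to polar-heavy-atom distance (nm).
#' @param pication_dist max cation to ring-centroid distance (nm).
#' @param pication_angle max angle between the cation-centroid axis and the
#'   ring normal (degrees).
#' @param hydrophobic_dist max distance between two positive-MHP atoms (nm).
#' @return object of class `lu_contact_criteria`.
#' @export
contact_criteria <- function(hbond_dist = 0.35, hbond_angle = 30,
                             ionic_dist = 0.45, ion_dipole_dist = 0.40,
                             pication_dist = 0.60, pication_angle = 45,
                             hydrophobic_dist = 0.45) {
  vals <- c(hbond_dist, ionic_dist, ion_dipole_dist, pication_dist,
            hydrophobic_dist)
  if (any(vals <= 0)) stop("all distance cutoffs must be > 0")
  if (hbond_angle <= 0 || hbond_angle > 180 ||
      pication_angle <= 0 || pication_angle > 180) {
    stop("angles must lie in (0, 180]")
  }
  structure(list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 ionic_dist = ionic_dist, ion_dipole_dist = ion_dipole_dist,
                 pication_dist = pication_dist,
                 pication_angle = pication_angle,
                 hydrophobic_dist = hydrophobic_dist),
            class = "lu_contact_criteria")
}
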