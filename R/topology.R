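# Topology container and readers (PDB via bio3d, GRO parsed here).
# Internal length unit is nm throughout the package; PDB/DCD input (Angstrom)
# is converted at the boundary.

# Standard atomic masses (amu), keyed by element symbol.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, F = 18.998, CL = 35.45, "NA" = 22.990, K = 39.098,
  MG = 24.305, CA = 40.078, ZN = 65.38, FE = 55.845, BR = 79.904, I = 126.904
)

.amino_acids3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  # CHARMM histidine tautomer names
  "HSD", "HSE", "HSP"
)

.aa_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", HSD = "H", HSE = "H", HSP = "H",
  ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Default residue-name to moiety-class rules
#'
#' Maps residue names onto the moiety classes used for group bookkeeping:
#' `amino-acid`, `glycan`, `gpi`, `lipid`, `solvent`, `ion`. The table covers
#' the twenty amino acids (plus CHARMM histidine tautomers), common CHARMM
#' membrane lipids, sugar residues of N-/O-glycans, the GPI-anchor residues
#' (DSPI, SAPI, GlcN, PEtN), waters and monatomic ions, and the bead residues
#' written by the synthetic generator (`LIP`).
#'
#' Glycosidic mannose (`MAN`/`BMA`) defaults to `glycan`; when a system's GPI
#' core mannoses share that residue name, override the rule (or renumber) to
#' classify them as `gpi`.
#'
#' @return named character vector, `names()` are residue names, values are
#'   moiety classes.
#' @export
default_moiety_rules <- function() {
  aa <- stats::setNames(rep("amino-acid", length(.amino_acids3)), .amino_acids3)
  lipids <- stats::setNames(rep("lipid", 14), c(
    "POPC", "DPPC", "DOPC", "DSPC", "PSM", "SSM", "NSM", "LSM",
    "CHL1", "POPE", "DOPE", "POPS", "POPI", "LIP"
  ))
  glycans <- stats::setNames(rep("glycan", 8), c(
    "NAG", "BMA", "MAN", "GAL", "FUC", "SIA", "NGA", "GLC"
  ))
  gpi <- stats::setNames(rep("gpi", 4), c("DSPI", "SAPI", "GLCN", "PETN"))
  solvent <- stats::setNames(rep("solvent", 4), c("TIP3", "HOH", "SOL", "WAT"))
  ions <- stats::setNames(rep("ion", 6), c("SOD", "CLA", "POT", "MG", "CAL", "CES"))
  c(aa, lipids, glycans, gpi, solvent, ions)
}

# Guess an element symbol from a PDB/GRO atom name.
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "NA", "MG", "FE", "ZN") &
                  nchar(nm) == 2,
                two, substr(nm, 1, 1))
  # CHARMM ion names
  out[nm == "SOD"] <- "NA"
  out[nm == "CLA"] <- "CL"
  out[nm == "POT"] <- "K"
  out
}

element_mass <- function(elem) {
  m <- .element_masses[toupper(elem)]
  bad <- is.na(m)
  if (any(bad)) {
    stop("no mass for element(s): ",
         paste(unique(toupper(elem)[bad]), collapse = ", "), call. = FALSE)
  }
  unname(m)
}

new_topology <- function(atoms, bonds = NULL) {
  stopifnot(is.data.frame(atoms))
  needed <- c("name", "elem", "mass", "resname", "resno", "chain", "moiety")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (any(atoms$mass <= 0)) stop("all atom masses must be > 0")
  atoms$index <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, bonds = bonds, natoms = nrow(atoms)),
            class = "lu_topology")
}

classify_moiety <- function(resname, rules) {
  m <- rules[toupper(resname)]
  bad <- is.na(m)
  if (any(bad)) {
    stop("unclassifiable residue name(s): ",
         paste(sort(unique(resname[bad])), collapse = ", "),
         "; extend the moiety rules to cover them", call. = FALSE)
  }
  unname(m)
}

#' Load a topology from a PDB or GRO file
#'
#' Atoms are classified into moiety classes by residue name using
#' `moiety_rules`; any residue name without a rule is an error that lists the
#' offending names. Masses are assigned from the (guessed) element.
#'
#' @param path path to a `.pdb` or `.gro` file.
#' @param moiety_rules named character vector mapping residue name to moiety
#'   class; see [default_moiety_rules()].
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return an object of class `lu_topology` with an `atoms` data frame
#'   (index, name, elem, mass, resname, resno, chain, moiety) and, as
#'   attribute `"xyz_nm"`, the coordinates of the file's (first) frame in nm.
#' @export
load_topology <- function(path, moiety_rules = default_moiety_rules(),
                          format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- pdb$atom
    elem <- at$elesy
    if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
      elem <- guess_element(at$elety)
    } else {
      elem[is.na(elem) | elem == ""] <- guess_element(at$elety[is.na(elem) | elem == ""])
    }
    atoms <- data.frame(
      name = at$elety, elem = toupper(elem),
      mass = element_mass(elem),
      resname = at$resid, resno = at$resno,
      chain = ifelse(is.na(at$chain), "", at$chain),
      stringsAsFactors = FALSE
    )
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10  # Angstrom -> nm
  } else {
    g <- parse_gro(path)
    atoms <- g$atoms
    atoms$elem <- guess_element(atoms$name)
    atoms$mass <- element_mass(atoms$elem)
    atoms$chain <- ""
    xyz <- g$xyz  # already nm
  }
  atoms$moiety <- classify_moiety(atoms$resname, moiety_rules)
  top <- new_topology(atoms)
  attr(top, "xyz_nm") <- xyz
  top
}

# GRO fixed-column parser (coordinates are nm natively). No installed R
# package reads GRO, hence the hand parser.
parse_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("not a GRO file (too short): ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop("bad atom count line in GRO file: ", path)
  if (length(lines) < 2 + natoms + 1) stop("truncated GRO file: ", path)
  rec <- lines[3:(2 + natoms)]
  resno <- as.integer(substr(rec, 1, 5))
  resname <- trimws(substr(rec, 6, 10))
  name <- trimws(substr(rec, 11, 15))
  x <- as.numeric(substr(rec, 21, 28))
  y <- as.numeric(substr(rec, 29, 36))
  z <- as.numeric(substr(rec, 37, 44))
  if (anyNA(c(x, y, z))) stop("unparseable coordinates in GRO file: ", path)
  box <- as.numeric(strsplit(trimws(lines[2 + natoms + 1]), "\\s+")[[1]])[1:3]
  list(atoms = data.frame(name = name, resname = resname, resno = resno,
                          stringsAsFactors = FALSE),
       xyz = unname(cbind(x, y, z)), box = box)
}

#' @export
print.lu_topology <- function(x, ...) {
  cat("lu_topology:", x$natoms, "atoms,",
      length(unique(paste(x$atoms$resno, x$atoms$resname))), "residues\n")
  print(table(x$atoms$moiety))
  invisible(x)
}

#' Select atoms from a topology
#'
#' Deterministic rule-based atom selection. All supplied filters are
#' intersected; the result is an ascending, duplicate-free atom index vector,
#' so identical arguments on an identical topology always return the same
#' selection.
#'
#' @param topology an `lu_topology`.
#' @param name,resname,resno,moiety,elem optional filters (vectors; an atom
#'   must match every filter that is non-NULL).
#' @param allow_empty if `FALSE` (default) an empty selection is an error.
#' @return integer vector of atom indices (1-based, ascending).
#' @export
select_atoms <- function(topology, name = NULL, resname = NULL, resno = NULL,
                         moiety = NULL, elem = NULL, allow_empty = FALSE) {
  stopifnot(inherits(topology, "lu_topology"))
  at <- topology$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(name))    keep <- keep & at$name %in% name
  if (!is.null(resname)) keep <- keep & at$resname %in% resname
  if (!is.null(resno))   keep <- keep & at$resno %in% resno
  if (!is.null(moiety))  keep <- keep & at$moiety %in% moiety
  if (!is.null(elem))    keep <- keep & at$elem %in% toupper(elem)
  idx <- which(keep)
  if (!length(idx) && !allow_empty) {
    stop("selection matched no atoms (set allow_empty = TRUE to permit)",
         call. = FALSE)
  }
  sort(idx)
}

#' Residue groups configuration
#'
#' Names the residue-number groups that define the orientation reference
#' vectors: the beta-structural core (`head`), the three loop tips, the
#' backbone selection for PCA, and the full amino-acid selection used for the
#' centre-of-mass height.
#'
#' @param head,loop1_tip,loop2_tip,loop3_tip,backbone,protein_all integer
#'   residue-number vectors (source-file numbering, no renumbering).
#' @param label protein label carried through outputs.
#' @param topology optional `lu_topology`; when given, membership of every
#'   residue number is validated against it.
#' @return object of class `lu_groups`.
#' @export
residue_groups <- function(head, loop1_tip, loop2_tip, loop3_tip,
                           backbone, protein_all, label = "protein",
                           topology = NULL) {
  g <- list(head = as.integer(head), loop1_tip = as.integer(loop1_tip),
            loop2_tip = as.integer(loop2_tip), loop3_tip = as.integer(loop3_tip),
            backbone = as.integer(backbone), protein_all = as.integer(protein_all),
            label = label)
  for (nm in c("head", "loop1_tip", "loop2_tip", "loop3_tip", "backbone",
               "protein_all")) {
    if (!length(g[[nm]])) stop("residue group '", nm, "' is empty")
  }
  tips <- list(g$loop1_tip, g$loop2_tip, g$loop3_tip)
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(tips[[i]], tips[[j]]))) {
      stop("loop tip groups must be pairwise disjoint")
    }
  }
  if (!is.null(topology)) {
    known <- unique(topology$atoms$resno)
    for (nm in c("head", "loop1_tip", "loop2_tip", "loop3_tip", "backbone",
                 "protein_all")) {
      miss <- setdiff(g[[nm]], known)
      if (length(miss)) {
        stop("group '", nm, "' names residue number(s) absent from topology: ",
             paste(miss, collapse = ", "))
      }
    }
  }
  structure(g, class = "lu_groups")
}

#' Read a residue-groups configuration from a YAML file
#'
#' Expects keys `head`, `loop1_tip`, `loop2_tip`, `loop3_tip`, `backbone`,
#' `protein_all` (residue-number lists) and optionally `label`.
#'
#' @param path YAML file path.
#' @param topology optional topology for validation.
#' @return an `lu_groups` object.
#' @export
read_groups <- function(path, topology = NULL) {
  y <- yaml::read_yaml(path)
  residue_groups(head = y$head, loop1_tip = y$loop1_tip,
                 loop2_tip = y$loop2_tip, loop3_tip = y$loop3_tip,
                 backbone = y$backbone, protein_all = y$protein_all,
                 label = y$label %||% "protein", topology = topology)
}
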