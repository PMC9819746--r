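# Protein-moiety <-> lipid contact detection, relative lifetimes, and the
# tiered residue report.
#
# Relative lifetime of a (residue, lipid class, contact type) key is the sum
# of per-frame contact counts divided by the number of analysed frames: 0 is
# no contact, 1 is one contact present in every frame, and values above 1
# mean several simultaneous contacts of that key.

pair_dists <- function(xyz, idx_a, idx_b) {
  A <- xyz[idx_a, , drop = FALSE]
  B <- xyz[idx_b, , drop = FALSE]
  da <- rowSums(A^2)
  db <- rowSums(B^2)
  d2 <- outer(da, db, `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

residue_label <- function(resname, resno, moiety) {
  one <- .aa_one[toupper(resname)]
  ifelse(moiety == "amino-acid" & !is.na(one),
         paste0(one, resno),
         paste0(resname, "-", resno))
}

# group protein-side atoms by residue entity
.protein_entities <- function(at) {
  sel <- which(at$moiety %in% c("amino-acid", "glycan", "gpi"))
  if (!length(sel)) stop("no protein-moiety atoms in topology")
  key <- paste(at$moiety[sel], at$resno[sel], at$resname[sel], sep = "|")
  split(sel, key)
}

#' Detect typed contacts in one frame
#'
#' Classifies protein-moiety (amino-acid, glycan, GPI) to lipid contacts of
#' five types: `ion_ion` (opposite formal-charge groups), `ion_dipole`
#' (charged group vs uncharged polar heavy atom, either direction), `hbond`
#' (donor-acceptor distance, plus the H-donor-acceptor angle when hydrogens
#' are present; distance-only for hydrogen-free topologies), `pication`
#' (cation within distance of an aromatic ring centroid and within an angle
#' of the ring normal), and `hydrophobic` (atom pairs with positive atomic
#' lipophilicity). Counts are per qualifying group pair (atom pair for
#' hydrophobic contacts).
#'
#' @param xyz `natoms x 3` frame coordinates (nm).
#' @param topology an `lu_topology`.
#' @param criteria an `lu_contact_criteria`.
#' @param ann optional precomputed [annotate_atoms()] result (recomputed when
#'   NULL).
#' @return data frame: resno, resname, moiety, label, lipid_resno,
#'   lipid_class, type, count.
#' @export
detect_contacts <- function(xyz, topology, criteria = contact_criteria(),
                            ann = NULL) {
  at <- topology$atoms
  if (is.null(ann)) ann <- annotate_atoms(topology)
  lip_atoms <- which(at$moiety == "lipid")
  pro_atoms <- which(at$moiety %in% c("amino-acid", "glycan", "gpi"))
  rows <- list()
  emit <- function(p_idx, lipid_resno, type, count) {
    if (count <= 0) return()
    i <- p_idx[1]
    rows[[length(rows) + 1]] <<- data.frame(
      resno = at$resno[i], resname = at$resname[i], moiety = at$moiety[i],
      label = residue_label(at$resname[i], at$resno[i], at$moiety[i]),
      lipid_resno = lipid_resno,
      lipid_class = lipid_class(at$resname[at$resno == lipid_resno &
                                             at$moiety == "lipid"][1]),
      type = type, count = count, stringsAsFactors = FALSE)
  }

  # charged groups, by side
  grp_by <- function(idx) {
    ch <- ann$charge[idx]
    keep <- idx[ch != 0]
    if (!length(keep)) return(list())
    key <- paste(at$resno[keep], sign(ann$charge[keep]), sep = "|")
    split(keep, key)
  }
  pro_charged <- grp_by(pro_atoms)
  lip_charged <- grp_by(lip_atoms)
  lip_polar0 <- lip_atoms[ann$polar[lip_atoms] & ann$charge[lip_atoms] == 0]
  pro_polar0 <- pro_atoms[ann$polar[pro_atoms] & ann$charge[pro_atoms] == 0]

  for (pg in pro_charged) {
    ps <- sign(ann$charge[pg[1]])
    # ion-ion: one contact per opposite-sign group pair in range
    for (lg in lip_charged) {
      if (sign(ann$charge[lg[1]]) == ps) next
      if (min(pair_dists(xyz, pg, lg)) <= criteria$ionic_dist) {
        emit(pg, at$resno[lg[1]], "ion_ion", 1)
      }
    }
    # ion-dipole: charged protein group vs uncharged lipid polar atoms
    if (length(lip_polar0)) {
      d <- pair_dists(xyz, pg, lip_polar0)
      hit <- which(apply(d, 2, min) <= criteria$ion_dipole_dist)
      if (length(hit)) {
        for (lr in unique(at$resno[lip_polar0[hit]])) {
          emit(pg, lr, "ion_dipole",
               sum(at$resno[lip_polar0[hit]] == lr))
        }
      }
    }
  }
  # ion-dipole, lipid charged group vs protein polar atoms
  for (lg in lip_charged) {
    if (!length(pro_polar0)) break
    d <- pair_dists(xyz, lg, pro_polar0)
    hit <- which(apply(d, 2, min) <= criteria$ion_dipole_dist)
    for (ai in pro_polar0[hit]) {
      emit(ai, at$resno[lg[1]], "ion_dipole", 1)
    }
  }

  # hydrogen bonds (both directions)
  hydrogens <- which(at$elem == "H")
  donor_h <- function(d_idx) {
    hs <- hydrogens[at$resno[hydrogens] == at$resno[d_idx]]
    if (!length(hs)) return(integer(0))
    hs[pair_dists(xyz, d_idx, hs)[1, ] <= 0.12]
  }
  hb_pairs <- function(donors, acceptors) {
    if (!length(donors) || !length(acceptors)) return(NULL)
    d <- pair_dists(xyz, donors, acceptors)
    hits <- which(d <= criteria$hbond_dist, arr.ind = TRUE)
    if (!nrow(hits)) return(NULL)
    ok <- logical(nrow(hits))
    for (r in seq_len(nrow(hits))) {
      D <- donors[hits[r, 1]]; A <- acceptors[hits[r, 2]]
      hs <- donor_h(D)
      if (!length(hs)) { ok[r] <- TRUE; next }  # hydrogen-free fallback
      for (h in hs) {
        v1 <- xyz[h, ] - xyz[D, ]
        v2 <- xyz[A, ] - xyz[D, ]
        ang <- acos_deg(sum(v1 * v2) / (vec_norm(v1) * vec_norm(v2)))
        if (ang <= criteria$hbond_angle) { ok[r] <- TRUE; break }
      }
    }
    hits[ok, , drop = FALSE]
  }
  pro_don <- pro_atoms[ann$donor[pro_atoms]]
  pro_acc <- pro_atoms[ann$acceptor[pro_atoms]]
  lip_don <- lip_atoms[ann$donor[lip_atoms]]
  lip_acc <- lip_atoms[ann$acceptor[lip_atoms]]
  h1 <- hb_pairs(pro_don, lip_acc)
  if (!is.null(h1)) for (r in seq_len(nrow(h1))) {
    emit(pro_don[h1[r, 1]], at$resno[lip_acc[h1[r, 2]]], "hbond", 1)
  }
  h2 <- hb_pairs(lip_don, pro_acc)
  if (!is.null(h2)) for (r in seq_len(nrow(h2))) {
    emit(pro_acc[h2[r, 2]], at$resno[lip_don[h2[r, 1]]], "hbond", 1)
  }

  # pi-cation: lipid cations vs protein aromatic rings
  lip_cations <- Filter(function(g) all(g$idx %in% lip_atoms), ann$cation_groups)
  for (ring in ann$rings) {
    R <- xyz[ring$idx, , drop = FALSE]
    cen <- colMeans(R)
    Rc <- sweep(R, 2, cen)
    nrm <- svd(Rc, nu = 0, nv = 3)$v[, 3]
    for (cg in lip_cations) {
      cat_pos <- colMeans(xyz[cg$idx, , drop = FALSE])
      v <- cat_pos - cen
      dist <- vec_norm(v)
      if (dist > criteria$pication_dist || dist == 0) next
      ang <- acos_deg(abs(sum(v / dist * nrm)))  # fold: normal sign arbitrary
      if (ang <= criteria$pication_angle) {
        emit(which(at$resno == ring$resno & at$moiety == "amino-acid"),
             at$resno[cg$idx[1]], "pication", 1)
      }
    }
  }

  # hydrophobic: positive-MHP atom pairs
  pro_mhp <- pro_atoms[ann$mhp_pos[pro_atoms]]
  lip_mhp <- lip_atoms[ann$mhp_pos[lip_atoms]]
  if (length(pro_mhp) && length(lip_mhp)) {
    d <- pair_dists(xyz, pro_mhp, lip_mhp)
    hits <- which(d <= criteria$hydrophobic_dist, arr.ind = TRUE)
    if (nrow(hits)) {
      key <- paste(at$resno[pro_mhp[hits[, 1]]],
                   at$resno[lip_mhp[hits[, 2]]], sep = "|")
      tab <- table(key)
      for (kk in names(tab)) {
        parts <- strsplit(kk, "|", fixed = TRUE)[[1]]
        emit(which(at$resno == as.integer(parts[1]) &
                     at$moiety %in% c("amino-acid", "glycan", "gpi")),
             as.integer(parts[2]), "hydrophobic", as.integer(tab[[kk]]))
      }
    }
  }

  if (!length(rows)) {
    return(data.frame(resno = integer(0), resname = character(0),
                      moiety = character(0), label = character(0),
                      lipid_resno = integer(0), lipid_class = character(0),
                      type = character(0), count = integer(0)))
  }
  out <- do.call(rbind, rows)
  # collapse duplicate keys within the frame
  agg <- stats::aggregate(count ~ resno + resname + moiety + label +
                            lipid_resno + lipid_class + type,
                          data = out, FUN = sum)
  agg
}

#' Relative lifetimes from per-frame contact counts
#'
#' @param frame_counts data frame of per-frame [detect_contacts()] rows with
#'   an added `frame` column.
#' @param nframes number of analysed frames.
#' @return data frame of class `lu_contact_timelines`: one row per (residue,
#'   lipid class, type) and per (residue, "all", type), with `lifetime`
#'   (sum of counts / nframes; may exceed 1) and `max_simultaneous` (largest
#'   per-frame total count of the key).
#' @export
lifetimes <- function(frame_counts, nframes) {
  if (nframes < 1) stop("nframes must be >= 1")
  empty <- data.frame(resno = integer(0), resname = character(0),
                      moiety = character(0), label = character(0),
                      type = character(0), lipid_class = character(0),
                      lifetime = numeric(0), max_simultaneous = numeric(0))
  if (is.null(frame_counts) || !nrow(frame_counts)) {
    return(structure(empty, class = c("lu_contact_timelines", "data.frame")))
  }
  fc <- frame_counts
  per_scope <- function(scope_col) {
    key <- paste(fc$resno, fc$moiety, fc$resname, fc$type, fc[[scope_col]],
                 sep = "|")
    tot <- tapply(fc$count, key, sum)
    # max simultaneous: counts summed within key and frame first
    fkey <- paste(key, fc$frame, sep = "@")
    perframe <- tapply(fc$count, fkey, sum)
    base <- sub("@.*$", "", names(perframe))
    mx <- tapply(perframe, base, max)
    info <- do.call(rbind, strsplit(names(tot), "|", fixed = TRUE))
    data.frame(resno = as.integer(info[, 1]), moiety = info[, 2],
               resname = info[, 3],
               label = residue_label(info[, 3], as.integer(info[, 1]),
                                     info[, 2]),
               type = info[, 4], lipid_class = info[, 5],
               lifetime = as.numeric(tot) / nframes,
               max_simultaneous = as.numeric(mx[names(tot)]),
               stringsAsFactors = FALSE)
  }
  by_class <- per_scope("lipid_class")
  fc$all_scope <- "all"
  total <- per_scope("all_scope")
  out <- rbind(total, by_class)
  rownames(out) <- NULL
  structure(out, class = c("lu_contact_timelines", "data.frame"))
}

#' Contact timelines over a trajectory
#'
#' Runs [detect_contacts()] on every `stride`-th frame and accumulates
#' relative lifetimes per (residue, lipid class, contact type) and per
#' residue totals (`lipid_class == "all"`).
#'
#' @param traj an `lu_trajectory`.
#' @param criteria an `lu_contact_criteria`.
#' @param stride analyse every `stride`-th frame.
#' @return an `lu_contact_timelines` data frame (see [lifetimes()]).
#' @export
contact_timelines <- function(traj, criteria = contact_criteria(),
                              stride = 1L) {
  stopifnot(inherits(traj, "lu_trajectory"))
  ann <- annotate_atoms(traj$topology)
  frames <- seq(1, traj$nframes, by = as.integer(stride))
  acc <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fc <- detect_contacts(frame_coords(traj, frames[i]), traj$topology,
                          criteria, ann)
    if (nrow(fc)) {
      fc$frame <- frames[i]
      acc[[i]] <- fc
    }
  }
  lifetimes(do.call(rbind, acc), length(frames))
}

#' Build a contact-timeline fixture row set by hand
#'
#' Convenience constructor for encoding published contact tables as timeline
#' fixtures (e.g. to test report rendering).
#'
#' @param label residue label (e.g. `"R57"`, `"GlcN-2"`).
#' @param moiety moiety class of the residue.
#' @param type contact type (`ion_ion`, `ion_dipole`, `hbond`, `pication`,
#'   `hydrophobic`).
#' @param lifetime relative lifetime.
#' @param max_simultaneous largest per-frame simultaneous count.
#' @param resno residue number (parsed from `label` when omitted).
#' @return an `lu_contact_timelines` row.
#' @export
contact_timeline <- function(label, moiety, type, lifetime,
                             max_simultaneous = 1,
                             resno = NULL) {
  if (is.null(resno)) {
    resno <- suppressWarnings(as.integer(gsub("[^0-9]", "", label)))
    if (is.na(resno)) resno <- 0L
  }
  structure(data.frame(resno = resno, moiety = moiety, resname = label,
                       label = label, type = type, lipid_class = "all",
                       lifetime = lifetime,
                       max_simultaneous = max_simultaneous,
                       stringsAsFactors = FALSE),
            class = c("lu_contact_timelines", "data.frame"))
}

#' Report thresholds
#'
#' Inclusion and emphasis thresholds for the contact report: polar contacts
#' (ionic/ion-dipole and hydrogen bonds) enter at >= 10% relative lifetime,
#' pi-cation at >= 5%, and hydrophobic entries require at least two
#' simultaneous contacts and a total lifetime above 200%. Polar entries are
#' emphasised at >= 50% (bold tier) and >= 75% (bold+underline tier).
#'
#' @param polar_min,pication_min,hydrophobic_min_lifetime numeric thresholds.
#' @param hydrophobic_min_simultaneous integer threshold.
#' @param bold,underline emphasis tier thresholds.
#' @return a list of thresholds.
#' @export
report_thresholds <- function(polar_min = 0.10, pication_min = 0.05,
                              hydrophobic_min_lifetime = 2.0,
                              hydrophobic_min_simultaneous = 2,
                              bold = 0.50, underline = 0.75) {
  list(polar_min = polar_min, pication_min = pication_min,
       hydrophobic_min_lifetime = hydrophobic_min_lifetime,
       hydrophobic_min_simultaneous = hydrophobic_min_simultaneous,
       bold = bold, underline = underline)
}

#' Render the tiered contact report
#'
#' Four columns per protein: ionic + ion-dipole, hydrogen bonds, pi-cation,
#' hydrophobic. Residues that form both ionic contacts and hydrogen bonds are
#' listed in the ionic column only; the pi-cation column is independent (a
#' residue may appear there and in the hydrogen-bond column); the hydrophobic
#' column lists only residues absent from all other columns. Polar entries
#' carry an emphasis tier: `plain`, `bold` (lifetime >= 0.5), or `underline`
#' (>= 0.75, rendered bold+underlined).
#'
#' @param timelines an `lu_contact_timelines` (rows with
#'   `lipid_class == "all"` are used).
#' @param thresholds see [report_thresholds()].
#' @return object of class `lu_contact_report`: a list of four data frames
#'   (`ionic`, `hbond`, `pication`, `hydrophobic`) with label, moiety,
#'   lifetime and tier.
#' @export
contact_report <- function(timelines, thresholds = report_thresholds()) {
  tl <- as.data.frame(timelines)
  tl <- tl[tl$lipid_class == "all", , drop = FALSE]
  key <- function(d) paste(d$label, d$moiety)
  coltab <- function(types, min_lt) {
    sel <- tl[tl$type %in% types, , drop = FALSE]
    if (!nrow(sel)) {
      return(data.frame(label = character(0), moiety = character(0),
                        lifetime = numeric(0), max_simultaneous = numeric(0)))
    }
    k <- key(sel)
    lt <- tapply(sel$lifetime, k, sum)
    mx <- tapply(sel$max_simultaneous, k, max)
    first <- !duplicated(k)
    d <- data.frame(label = sel$label[first], moiety = sel$moiety[first],
                    stringsAsFactors = FALSE)
    d$lifetime <- as.numeric(lt[key(d)])
    d$max_simultaneous <- as.numeric(mx[key(d)])
    d[d$lifetime >= min_lt | is.na(min_lt), , drop = FALSE]
  }
  tier <- function(lt) {
    ifelse(lt >= thresholds$underline, "underline",
           ifelse(lt >= thresholds$bold, "bold", "plain"))
  }
  ionic <- coltab(c("ion_ion", "ion_dipole"), thresholds$polar_min)
  hbond <- coltab("hbond", thresholds$polar_min)
  pication <- coltab("pication", thresholds$pication_min)
  hydroph <- coltab("hydrophobic", NA)
  hydroph <- hydroph[hydroph$lifetime > thresholds$hydrophobic_min_lifetime &
                       hydroph$max_simultaneous >=
                       thresholds$hydrophobic_min_simultaneous, , drop = FALSE]
  # precedence
  hbond <- hbond[!(key(hbond) %in% key(ionic)), , drop = FALSE]
  excl <- c(key(ionic), key(hbond), key(pication))
  hydroph <- hydroph[!(key(hydroph) %in% excl), , drop = FALSE]
  ionic$tier <- tier(ionic$lifetime)
  hbond$tier <- tier(hbond$lifetime)
  pication$tier <- rep("plain", nrow(pication))
  hydroph$tier <- rep("plain", nrow(hydroph))
  structure(list(ionic = ionic, hbond = hbond, pication = pication,
                 hydrophobic = hydroph, thresholds = thresholds),
            class = "lu_contact_report")
}

#' @export
print.lu_contact_report <- function(x, ...) {
  deco <- function(d) {
    if (!nrow(d)) return("-")
    lab <- d$label
    lab[d$tier == "bold"] <- paste0("**", lab[d$tier == "bold"], "**")
    lab[d$tier == "underline"] <- paste0("__**", lab[d$tier == "underline"],
                                         "**__")
    paste(lab, collapse = ", ")
  }
  cat("Ionic/ion-dipole:", deco(x$ionic), "\n")
  cat("Hydrogen bonds:  ", deco(x$hbond), "\n")
  cat("Pi-cation:       ", deco(x$pication), "\n")
  cat("Hydrophobic:     ", deco(x$hydrophobic), "\n")
  invisible(x)
}

#' Count distinct polar-contact residues of a moiety class
#'
#' Number of distinct residues of the given moiety class appearing in the
#' ionic/ion-dipole or hydrogen-bond columns of a contact report.
#'
#' @param report an `lu_contact_report`.
#' @param moiety moiety class to count (default amino acids, i.e. GPI and
#'   glycan entries are excluded).
#' @return integer count.
#' @export
count_polar_residues <- function(report, moiety = "amino-acid") {
  labs <- c(report$ionic$label[report$ionic$moiety == moiety],
            report$hbond$label[report$hbond$moiety == moiety])
  length(unique(labs))
}
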