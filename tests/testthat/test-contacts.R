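# Contact detection geometry, lifetimes, report semantics.

test_that("single-frame geometric classification matches the criteria", {
  # Lys NZ 0.30 nm from a phosphate oxygen: one ionic contact
  top <- fix_topology(c("NZ", "P", "O13"), c("LYS", "POPC", "POPC"),
                      c(1, 101, 101),
                      xyz = rbind(c(0, 0, 0.30), c(0, 0.2, -0.05), c(0, 0, 0)))
  fc <- detect_contacts(attr(top, "xyz_nm"), top)
  expect_equal(sum(fc$count[fc$type == "ion_ion"]), 1)

  # Tyr OH donor at D-A 0.30 nm, H-D-A angle 10 degrees: one hydrogen bond
  hda <- 10 * pi / 180
  top2 <- fix_topology(c("OH", "HH", "O12"), c("TYR", "TYR", "POPC"),
                       c(1, 1, 101),
                       xyz = rbind(c(0, 0, 0),
                                   0.1 * c(sin(hda), 0, cos(hda)),
                                   c(0, 0, 0.30)))
  fc2 <- detect_contacts(attr(top2, "xyz_nm"), top2)
  expect_equal(sum(fc2$count[fc2$type == "hbond"]), 1)
  # same geometry with the hydrogen swung past the 30-degree cutoff: no bond
  top3 <- top2
  xyz3 <- attr(top2, "xyz_nm")
  hda2 <- 50 * pi / 180
  xyz3[2, ] <- 0.1 * c(sin(hda2), 0, cos(hda2))
  fc3 <- detect_contacts(xyz3, top3)
  expect_equal(sum(fc3$count[fc3$type == "hbond"]), 0)

  # everything at 0.9 nm: no contacts of any type
  top4 <- fix_topology(c("CZ", "NH1", "NH2", "NE", "P", "O13", "C28"),
                       c("ARG", "ARG", "ARG", "ARG", "POPC", "POPC", "POPC"),
                       c(1, 1, 1, 1, 101, 101, 101),
                       xyz = rbind(c(0, 0, 0.9), c(0.05, 0, 0.95),
                                   c(-0.05, 0, 0.95), c(0, 0.05, 0.95),
                                   c(0, 0, 0), c(0.05, 0.05, 0),
                                   c(0.2, 0, 0)))
  fc4 <- detect_contacts(attr(top4, "xyz_nm"), top4)
  expect_equal(nrow(fc4), 0)

  # pi-cation: choline N on the ring axis at 0.45 nm
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring <- cbind(0.14 * cos(ang), 0.14 * sin(ang), 0)
  top5 <- fix_topology(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "N"),
                       c(rep("PHE", 6), "POPC"), c(rep(1, 6), 101),
                       xyz = rbind(ring, c(0, 0, 0.45)))
  fc5 <- detect_contacts(attr(top5, "xyz_nm"), top5)
  expect_equal(sum(fc5$count[fc5$type == "pication"]), 1)
  # same distance but in the ring plane: rejected by the axis angle
  xyz6 <- attr(top5, "xyz_nm")
  xyz6[7, ] <- c(0.45, 0, 0)
  expect_equal(sum(detect_contacts(xyz6, top5)$count[
    detect_contacts(xyz6, top5)$type == "pication"]), 0)

  # hydrophobic pairs are counted per qualifying atom pair
  top7 <- fix_topology(c("CD1", "CD2", "C28", "C29"),
                       c("LEU", "LEU", "POPC", "POPC"),
                       c(1, 1, 101, 101),
                       xyz = rbind(c(0, 0, 0.4), c(0.1, 0, 0.4),
                                   c(0, 0, 0), c(0.1, 0, 0)))
  fc7 <- detect_contacts(attr(top7, "xyz_nm"), top7)
  expect_equal(sum(fc7$count[fc7$type == "hydrophobic"]), 4)
})

test_that("relative lifetimes accumulate counts over frames and may exceed 1", {
  fc <- data.frame(resno = 1, resname = "LYS", moiety = "amino-acid",
                   label = "K1", lipid_resno = 101,
                   lipid_class = "phosphatidylcholine", type = "ion_ion",
                   count = 1, frame = 1:300)
  tl <- lifetimes(fc, 1000)
  expect_equal(tl$lifetime[tl$lipid_class == "all"], 0.30)
  # two simultaneous contacts in every frame: lifetime 2
  fc2 <- rbind(fc, transform(fc, lipid_resno = 102))
  fc2$frame <- rep(1:300, 2)
  tl2 <- lifetimes(fc2, 300)
  expect_equal(tl2$lifetime[tl2$lipid_class == "all"], 2.0)
  expect_equal(tl2$max_simultaneous[tl2$lipid_class == "all"], 2)
  # no contacts
  tl0 <- lifetimes(NULL, 100)
  expect_equal(nrow(tl0), 0)
})

test_that("per-lipid-class lifetimes are reported alongside the total", {
  fc <- rbind(
    data.frame(resno = 1, resname = "LYS", moiety = "amino-acid", label = "K1",
               lipid_resno = 101, lipid_class = "phosphatidylcholine",
               type = "ion_ion", count = 1, frame = 1:60),
    data.frame(resno = 1, resname = "LYS", moiety = "amino-acid", label = "K1",
               lipid_resno = 201, lipid_class = "sphingomyelin",
               type = "ion_ion", count = 1, frame = 41:100))
  tl <- lifetimes(fc, 100)
  expect_equal(tl$lifetime[tl$lipid_class == "phosphatidylcholine"], 0.6)
  expect_equal(tl$lifetime[tl$lipid_class == "sphingomyelin"], 0.6)
  expect_equal(tl$lifetime[tl$lipid_class == "all"], 1.2)
  expect_equal(tl$max_simultaneous[tl$lipid_class == "all"], 2)
})

test_that("cutoff enlargement never decreases lifetimes", {
  sim <- generate_trajectory(fix_contact_spec(60), seed = 21)
  plan <- data.frame(resno = c(51, 55), type = c("ionic", "hbond"),
                     fraction = c(0.5, 0.3))
  sim2 <- plant_contacts(sim, plan, seed = 2)
  base <- contact_timelines(sim2$trajectory)
  wide <- contact_timelines(sim2$trajectory,
                            contact_criteria(hbond_dist = 0.45,
                                             ionic_dist = 0.60,
                                             ion_dipole_dist = 0.55,
                                             pication_dist = 0.8,
                                             hydrophobic_dist = 0.6))
  for (i in seq_len(nrow(base))) {
    match_row <- wide$lifetime[wide$resno == base$resno[i] &
                                 wide$type == base$type[i] &
                                 wide$lipid_class == base$lipid_class[i]]
    expect_true(length(match_row) == 1 && match_row >= base$lifetime[i])
  }
})

test_that("report columns follow precedence, thresholds, and emphasis tiers", {
  tl <- rbind(
    contact_timeline("R10", "amino-acid", "ion_ion", 0.6),
    contact_timeline("R10", "amino-acid", "hbond", 0.3),
    contact_timeline("Y20", "amino-acid", "pication", 0.06),
    contact_timeline("L30", "amino-acid", "hydrophobic", 1.5,
                     max_simultaneous = 3),
    contact_timeline("V40", "amino-acid", "hydrophobic", 2.5,
                     max_simultaneous = 2),
    contact_timeline("S50", "amino-acid", "hbond", 0.8),
    contact_timeline("E60", "amino-acid", "ion_dipole", 0.08),
    contact_timeline("W70", "amino-acid", "hbond", 0.2),
    contact_timeline("W70", "amino-acid", "pication", 0.1))
  rep <- contact_report(tl)
  expect_equal(rep$ionic$label, "R10")      # listed once, ionic column only
  expect_equal(rep$ionic$tier, "bold")      # 0.6 + 0.3 is not summed across columns
  expect_false("R10" %in% rep$hbond$label)
  expect_equal(rep$pication$label, c("Y20", "W70"))  # 0.06 >= 5%, plain
  expect_true(all(rep$pication$tier == "plain"))
  expect_false("L30" %in% rep$hydrophobic$label)  # 1.5 <= 200%: omitted
  expect_equal(rep$hydrophobic$label, "V40")
  expect_equal(rep$hbond$label[rep$hbond$tier == "underline"], "S50")
  expect_false("E60" %in% rep$ionic$label)  # below the 10% polar threshold
  # hydrogen-bond and pi-cation columns may share a residue
  expect_true("W70" %in% rep$hbond$label && "W70" %in% rep$pication$label)
})

test_that("no residue appears in both polar columns or leaks into hydrophobic", {
  set.seed(33)
  types <- c("ion_ion", "ion_dipole", "hbond", "pication", "hydrophobic")
  for (r in 1:20) {
    n <- sample(5:25, 1)
    rows <- lapply(seq_len(n), function(i) {
      contact_timeline(paste0("R", sample(1:12, 1)), "amino-acid",
                       sample(types, 1), stats::runif(1, 0, 3),
                       max_simultaneous = sample(1:4, 1))
    })
    rep <- contact_report(do.call(rbind, rows))
    expect_length(intersect(rep$ionic$label, rep$hbond$label), 0)
    expect_length(intersect(rep$hydrophobic$label,
                            c(rep$ionic$label, rep$hbond$label,
                              rep$pication$label)), 0)
  }
})

test_that("the encoded Lynx1 table yields 15 polar amino-acid residues", {
  tl <- fix_lynx1_timelines()
  rep <- contact_report(tl)
  expect_equal(count_polar_residues(rep), 15)
  # GPI entries stay out of the amino-acid polar count but are reported
  expect_true(all(c("DSPI-1", "GlcN-2", "PEtN-Man-3") %in% rep$ionic$label))
  expect_equal(count_polar_residues(contact_report(
    contact_timeline("GlcN-2", "gpi", "ion_ion", 0.9))), 0)
  empty <- contact_report(fix_lynx1_timelines()[0, ])
  expect_equal(count_polar_residues(empty), 0)
  # strong ionic residues are bold and not duplicated in the hbond column
  expect_setequal(rep$ionic$label[rep$ionic$tier != "plain"],
                  c("R57", "K59", "DSPI-1", "PEtN-Man-3"))
  expect_false(any(c("R57", "K59") %in% rep$hbond$label))
})

test_that("reports are deterministic for identical trajectories and criteria", {
  sim <- generate_trajectory(fix_contact_spec(40), seed = 8)
  plan <- data.frame(resno = 51, type = "ionic", fraction = 0.4)
  s1 <- plant_contacts(sim, plan, seed = 3)
  t1 <- contact_timelines(s1$trajectory)
  t2 <- contact_timelines(s1$trajectory)
  expect_identical(t1, t2)
})
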