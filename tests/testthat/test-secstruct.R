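# Dihedrals, Ramachandran classification, secondary-structure assignment.

test_that("backbone dihedrals reproduce the builder's internal coordinates", {
  fr <- build_ideal_backbone(paste(rep("A", 12), collapse = ""), -57, -47)
  dh <- backbone_dihedrals(fr, "A")
  expect_true(all(abs(dh$phi[2:12] - (-57)) < 1))
  expect_true(all(abs(dh$psi[1:11] - (-47)) < 1))
  expect_false(dh$phi_defined[1])
  expect_false(dh$psi_defined[12])
  fr2 <- build_ideal_backbone("AAAAAA", -120, 120)
  dh2 <- backbone_dihedrals(fr2, "A")
  expect_true(all(abs(dh2$phi[2:6] - (-120)) < 1))
  # two-residue chain: no phi for residue 1, flagged not dropped
  fr3 <- build_ideal_backbone("AA", -57, -47)
  dh3 <- backbone_dihedrals(fr3, "A")
  expect_equal(nrow(dh3), 2L)
  expect_false(dh3$phi_defined[1])
  # collinear points are an explicit error
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 0, 0)), "collinear")
})

test_that("Ramachandran regions classify canonical points and ensembles", {
  recs <- data.frame(chain = "A", resid = 1:4,
                     resname = c("ALA", "ALA", "GLY", "PRO"),
                     phi = c(-60, 60, 60, -60),
                     psi = c(-45, 180, 180, -30),
                     phi_defined = TRUE, psi_defined = TRUE)
  cls <- ramachandran_classify(recs)
  expect_equal(cls$labels$region[1], "core")        # canonical helix
  expect_equal(cls$labels$region[2], "disallowed")  # non-Gly (60, 180)
  expect_false(cls$labels$region[3] == "disallowed")  # Gly exemption
  expect_equal(cls$labels$region[4], "core")        # Pro helical
  # an all-helix chain scores a favored fraction of 1
  fr <- build_ideal_backbone(paste(rep("A", 15), collapse = ""), -57, -47)
  all_h <- ramachandran_classify(backbone_dihedrals(fr, "A"))
  expect_equal(all_h$favored_fraction, 1)
  # favored fraction counts core + allowed over the defined residues
  expect_equal(cls$favored_fraction, 3 / 4)  # only (60, 180) non-Gly fails
  # undefined dihedrals leave the denominator
  recs$phi_defined[2] <- FALSE
  cls2 <- ramachandran_classify(recs)
  expect_equal(cls2$favored_fraction, 1)
  # the ensemble summary equals the mean of per-frame summaries when every
  # frame defines the same dihedral set (rigid-motion ensemble)
  set.seed(41)
  frt <- dimerlens:::.jd_fold(dimerlens:::.jd_sequence())
  frames <- lapply(1:6, function(f) {
    structure_frame(frt$atoms,
                    sweep(frt$coords %*% rand_rotation(), 2, rnorm(3), "+"))
  })
  per_frame <- vapply(frames, function(fr) {
    ramachandran_classify(backbone_dihedrals(fr, "A"))$favored_fraction
  }, numeric(1))
  pooled <- ramachandran_classify(do.call(rbind, lapply(frames,
    backbone_dihedrals, chain = "A")))
  expect_equal(pooled$favored_fraction, mean(per_frame), tolerance = 1e-12)
})

test_that("the assigner finds helices, sheets and coil where they were
           built", {
  frh <- build_ideal_backbone(paste(rep("A", 12), collapse = ""), -57, -47)
  ssh <- assign_secondary_structure(frh)
  expect_true(all(ssh$ss[3:9] == "H"))
  hp <- build_ideal_hairpin(8)
  ssp <- assign_secondary_structure(hp)
  expect_true(all(ssp$ss[4:6] == "E"))   # strand 1 core
  expect_true(all(ssp$ss[12:14] == "E")) # strand 2 core
  # fully extended isolated chain: no partners, all coil
  fre <- build_ideal_backbone(paste(rep("A", 10), collapse = ""), -120, 120)
  expect_true(all(assign_secondary_structure(fre)$ss == "C"))
  # rigid motion leaves the assignment unchanged
  set.seed(42)
  moved <- structure_frame(frh$atoms,
                           sweep(frh$coords %*% rand_rotation(), 2,
                                 rnorm(3), "+"))
  expect_identical(assign_secondary_structure(moved)$ss, ssh$ss)
  # too-short chains are all coil, with a warning
  tiny <- build_ideal_backbone("AAAA", -57, -47)
  expect_warning(sst <- assign_secondary_structure(tiny), "fewer than 5")
  expect_true(all(sst$ss == "C"))
})

test_that("secondary-structure occupancies recover the planted helix-coil
           switching exactly", {
  gen <- generate_dimer_trajectory(default_plant_spec(
    "single", seed = 43, n_frames = 40, rmsf_plan = NULL,
    ss_plan = list(first = 84L, last = 87L, coil_fraction = 0.35)))
  prof <- ss_profile(gen$trajectory, "A")
  expect_s3_class(prof, "ss_profile")
  expect_equal(prof$helix + prof$sheet + prof$coil, rep(1, nrow(prof)))
  blk <- prof[prof$resid %in% 84:87, ]
  planted <- mean(gen$truth$frames$ss_state == "coil")
  expect_equal(planted, 0.35)  # exact-count schedule at 40 frames
  expect_equal(blk$coil, rep(planted, 4), tolerance = 1e-12)
  expect_equal(blk$helix, rep(1 - planted, 4), tolerance = 1e-12)
  # a static helix trajectory has helix fraction 1 in its core
  frh <- build_ideal_backbone(paste(rep("A", 12), collapse = ""), -57, -47)
  trh <- trajectory(frh$atoms, array(rep(frh$coords, 3), c(nrow(frh$coords), 3, 3)),
                    times = 1:3)
  profh <- ss_profile(trh, "A")
  expect_true(all(profh$helix[3:9] == 1))
})

test_that("helix-loss differences isolate the toggled region", {
  gen_ref <- generate_dimer_trajectory(default_plant_spec(
    "single", seed = 44, n_frames = 20, rmsf_plan = NULL))
  gen_sw <- generate_dimer_trajectory(default_plant_spec(
    "single", seed = 44, n_frames = 20, rmsf_plan = NULL,
    ss_plan = list(first = 84L, last = 87L, coil_fraction = 0.35)))
  pa <- ss_profile(gen_ref$trajectory, "A")
  pb <- ss_profile(gen_sw$trajectory, "A")
  reg <- region_spec("alpha4", "A", 84, 87)
  loss <- helix_loss_fraction(pa, pb, reg)
  expect_equal(loss$delta_helix, rep(-0.35, 4), tolerance = 0.01)
  # identical profiles: zero everywhere
  zero <- helix_loss_fraction(pa, pa, reg)
  expect_true(all(zero$delta_helix == 0))
  # residues outside the region are untouched by the toggle
  other <- helix_loss_fraction(pa, pb, region_spec("a1", "A", 8, 23))
  expect_lt(max(abs(other$delta_helix)), 1e-12)
  expect_error(helix_loss_fraction(pa[pa$resid != 85, ], pb, reg),
               "different residue")
})

test_that("assignments agree with a reference implementation on ideal
           builds", {
  # spot check; the full 50-case comparison runs with the acceptance suite
  tmp <- withr::local_tempdir()
  cases <- list(build_ideal_backbone(paste(rep("A", 16), collapse = ""),
                                     -57, -47),
                build_ideal_hairpin(10))
  ours <- character(0); files <- character(0)
  for (i in seq_along(cases)) {
    f <- file.path(tmp, sprintf("case%d.pdb", i))
    write_multimodel_pdb(trajectory(cases[[i]]$atoms, cases[[i]]$coords), f)
    ours <- c(ours, paste(assign_secondary_structure(cases[[i]])$ss,
                          collapse = ""))
    files <- c(files, f)
  }
  ref <- system2("python", c("-c", shQuote(paste0(
    "import mdtraj as md, sys\n",
    "for f in sys.argv[1:]:\n",
    "    print(''.join(md.compute_dssp(md.load(f), simplified=True)[0]))")),
    files), stdout = TRUE)
  total <- sum(nchar(ours))
  agree <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }, ours, ref))
  expect_gte(agree / total, 0.9)
})
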