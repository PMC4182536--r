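# Contact probability / maps / interface table, SAS and contact surface.

test_that("residue minimum distance equals the exhaustive oracle", {
  set.seed(201)
  # two single-atom residues 0.30 nm apart
  fr <- point_frame(rbind(c(0, 0, 0), c(0.3, 0, 0)),
                    chain = c("A", "B"), resid = c(1, 1))
  expect_equal(residue_min_distance(fr, list(chain = "A", resid = 1),
                                    list(chain = "B", resid = 1)), 0.3)
  # identical coordinates -> 0
  fr0 <- point_frame(rbind(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)),
                     chain = c("A", "B"), resid = c(1, 1))
  expect_equal(residue_min_distance(fr0, list(chain = "A", resid = 1),
                                    list(chain = "B", resid = 1)), 0)
  # random multi-atom residues against a double loop
  for (i in 1:25) {
    xa <- matrix(runif(12), 4, 3); xb <- matrix(runif(9), 3, 3)
    fr2 <- point_frame(rbind(xa, xb), chain = rep(c("A", "B"), c(4, 3)),
                       resid = rep(1, 7))
    want <- min(sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                       2 * xa %*% t(xb)))
    brute <- Inf
    for (p in 1:4) for (q in 1:3) {
      brute <- min(brute, sqrt(sum((xa[p, ] - xb[q, ])^2)))
    }
    got <- residue_min_distance(fr2, list(chain = "A", resid = 1),
                                list(chain = "B", resid = 1))
    expect_equal(got, brute, tolerance = 1e-12)
  }
  expect_error(residue_min_distance(fr, list(chain = "A", resid = 9),
                                    list(chain = "B", resid = 1)),
               "zero selected atoms")
})

test_that("contact probability counts snapshots exactly, with an inclusive
           threshold", {
  # one residue pair at exactly the cutoff in every frame: p = 1 for both
  at <- atom_table(1:2, c("CA", "CA"), c("ALA", "ALA"), c(1, 1), c("A", "B"))
  coords <- array(0, c(2, 3, 4))
  coords[2, 1, ] <- 0.28
  tr <- trajectory(at, coords, times = 1:4)
  cp <- contact_probability(tr, "A", "B", cutoff = 0.28)
  expect_equal(cp$a$probability, 1)
  expect_equal(cp$b$probability, 1)
  # infinitesimally beyond: 0
  coords[2, 1, ] <- 0.28 + 1e-9
  cp2 <- contact_probability(trajectory(at, coords, times = 1:4), "A", "B")
  expect_equal(cp2$a$probability, 0)
  # far-apart chains: all zero
  gen <- generate_dimer_trajectory(default_plant_spec(
    "bound", seed = 31, n_frames = 6,
    contact_plan = data.frame(resid_a = 101, resid_b = 57, p = 0)))
  cp3 <- contact_probability(gen$trajectory, "A", "B")
  expect_true(all(cp3$a$probability == 0))
  expect_true(all(cp3$b$probability == 0))
  expect_error(contact_probability(tr, "A", "A"), "differ")
})

test_that("planted contact schedules are recovered as exact rationals", {
  gen <- generate_dimer_trajectory(default_plant_spec("bound", seed = 32,
                                                      n_frames = 40))
  cp <- contact_probability(gen$trajectory, "A", "B")
  truth <- gen$truth$contacts
  for (i in seq_len(nrow(truth))) {
    expect_identical(cp$a$probability[cp$a$resid == truth$resid_a[i]],
                     truth$probability[i])
    expect_identical(cp$b$probability[cp$b$resid == truth$resid_b[i]],
                     truth$probability[i])
  }
  # counts are integers over n_frames
  expect_true(all(cp$a$probability * cp$n_frames ==
                    round(cp$a$probability * cp$n_frames)))
  # no residue outside the plan is ever in contact
  expect_true(all(cp$a$probability[!cp$a$resid %in% truth$resid_a] == 0))
})

test_that("contact probability equals brute force on random tiny systems,
           is cutoff-monotone and rigid-motion invariant", {
  set.seed(202)
  for (i in 1:100) {
    tr <- random_tiny_system()
    cutoff <- runif(1, 0.05, 0.5)
    ours <- contact_probability(tr, "A", "B", cutoff = cutoff)
    brute <- brute_contact_probability(tr, "A", "B", cutoff)
    expect_identical(ours$a$probability, brute$a)
    expect_identical(ours$b$probability, brute$b)
    # monotone in the cutoff
    wider <- contact_probability(tr, "A", "B", cutoff = cutoff * 1.5)
    expect_true(all(wider$a$probability >= ours$a$probability))
    # invariant under per-frame rigid motion of the whole complex and
    # under frame order
    moved <- apply_rigid(tr, rand_rotation(), rnorm(3))
    expect_equal(contact_probability(moved, "A", "B",
                                     cutoff = cutoff)$a$probability,
                 ours$a$probability, tolerance = 1e-9)
  }
  tr <- random_tiny_system(nf = 4)
  perm <- trajectory(tr$topology, tr$coords[, , c(3, 1, 4, 2)], times = 1:4)
  expect_identical(contact_probability(perm, "A", "B", 0.3)$a$probability,
                   contact_probability(tr, "A", "B", 0.3)$a$probability)
})

test_that("contact map rows never exceed the any-partner profile", {
  set.seed(203)
  for (i in 1:20) {
    tr <- random_tiny_system()
    cutoff <- runif(1, 0.1, 0.4)
    cp <- contact_probability(tr, "A", "B", cutoff = cutoff)
    cm <- contact_map(tr, "A", "B", cutoff = cutoff)
    expect_true(all(cm$freq >= 0 & cm$freq <= 1))
    expect_true(all(cp$a$probability >= apply(cm$freq, 1, max) - 1e-12))
    expect_true(all(cp$b$probability >= apply(cm$freq, 2, max) - 1e-12))
  }
  # single planted pair in all frames: one entry 1, rest 0
  at <- atom_table(1:4, rep("CA", 4), rep("ALA", 4), c(1, 2, 1, 2),
                   c("A", "A", "B", "B"))
  coords <- array(0, c(4, 3, 3))
  coords[2, , ] <- 5      # A res 2 far away
  coords[3, 1, ] <- 0.2   # B res 1 near A res 1
  coords[4, , ] <- -5     # B res 2 far away
  cm <- contact_map(trajectory(at, coords, times = 1:3), "A", "B", 0.28)
  expect_equal(sum(cm$freq), 1)
  expect_equal(cm$freq["1", "1"], 1)
})

test_that("interface table ranks contacts and classes their chemistry", {
  gen <- generate_dimer_trajectory(default_plant_spec("bound", seed = 33,
                                                      n_frames = 20))
  cp <- contact_probability(gen$trajectory, "A", "B")
  cm <- contact_map(gen$trajectory, "A", "B")
  tab <- interface_table(cp, cm, threshold = 0.25)
  # the planted Arg101-Asp57 salt bridge tops the table, classed charged
  expect_equal(tab$resid[1:2], c(57L, 101L))  # equal p: ties by resid
  arg <- tab[tab$chain == "A" & tab$resid == 101, ]
  expect_equal(arg$partner_resid, 57L)
  expect_equal(arg$polarity, "charged")
  expect_equal(arg$partner_polarity, "charged")
  expect_true(all(diff(tab$probability) <= 1e-12))
  # all-zero profiles give an empty table
  empty <- interface_table(
    contact_probability(random_tiny_system(), "A", "B", cutoff = 1e-6),
    contact_map(random_tiny_system(), "A", "B", cutoff = 1e-6),
    threshold = 0.25)
  expect_equal(nrow(empty), 0L)
})

test_that("Shrake-Rupley areas match analytic spheres and caps", {
  # isolated sphere: exact quadrature
  fr <- point_frame(matrix(0, 1, 3), element = "S", name = "S")
  sas <- shrake_rupley_sas(fr, probe = 0.14)
  expect_equal(sas$total, 4 * pi * (0.18 + 0.14)^2, tolerance = 1e-9)
  # two far-apart atoms: sum of isolated spheres
  fr2 <- point_frame(rbind(c(0, 0, 0), c(5, 0, 0)), element = "C",
                     resid = c(1, 2))
  expect_equal(shrake_rupley_sas(fr2)$total,
               2 * 4 * pi * (0.17 + 0.14)^2, tolerance = 1e-9)
  # overlapping equal spheres against the spherical-cap closed form
  R <- 0.17 + 0.14
  for (d in c(0.25, 0.4, 0.55)) {
    fr3 <- point_frame(rbind(c(0, 0, 0), c(d, 0, 0)), element = "C",
                       resid = c(1, 2))
    got <- shrake_rupley_sas(fr3, n_points = 960)$total
    want <- two_sphere_sas(R, R, d)
    expect_lt(abs(got - want) / want, 0.02)
  }
  # unequal radii
  frm <- point_frame(rbind(c(0, 0, 0), c(0.3, 0, 0)),
                     element = c("C", "O"), resid = c(1, 2),
                     name = c("C", "O"))
  got <- shrake_rupley_sas(frm, n_points = 960)$total
  want <- two_sphere_sas(0.17 + 0.14, 0.152 + 0.14, 0.3)
  expect_lt(abs(got - want) / want, 0.02)
  # per-atom areas are non-negative and sum to the total
  expect_equal(sum(shrake_rupley_sas(frm)$area), shrake_rupley_sas(frm)$total)
  # an element with no tabulated radius names the offending atom
  frx <- point_frame(matrix(0, 1, 3), element = "FE", name = "FE1")
  expect_error(shrake_rupley_sas(frx), "FE1")
})

test_that("SAS is deterministic and decreases when surroundings are added", {
  set.seed(204)
  xyz <- matrix(runif(30, 0, 0.5), 10, 3)
  fr <- point_frame(xyz, resid = 1:10)
  a1 <- shrake_rupley_sas(fr, selection = 1:5)
  a2 <- shrake_rupley_sas(fr, selection = 1:10)
  expect_identical(shrake_rupley_sas(fr, selection = 1:5)$area, a1$area)
  # atoms 1..5 can only lose area when 6..10 are present
  expect_true(all(a2$area[1:5] <= a1$area + 1e-12))
})

test_that("contact surface halves the buried area, symmetrically", {
  # far-apart chains: zero up to quadrature noise
  fr <- point_frame(rbind(c(0, 0, 0), c(5, 0, 0)), chain = c("A", "B"),
                    resid = c(1, 1))
  expect_equal(contact_surface_area(fr, "A", "B"), 0, tolerance = 1e-9)
  # two-atom chains with known overlap: analytic buried area / 2
  d <- 0.35; R <- 0.17 + 0.14
  fr2 <- point_frame(rbind(c(0, 0, 0), c(d, 0, 0)), chain = c("A", "B"),
                     resid = c(1, 1))
  buried <- (2 * 4 * pi * R^2 - two_sphere_sas(R, R, d))
  got <- contact_surface_area(fr2, "A", "B")
  expect_lt(abs(got - buried / 2) / (buried / 2), 0.02)
  expect_equal(contact_surface_area(fr2, "A", "B"),
               contact_surface_area(fr2, "B", "A"))
  expect_equal(contact_surface_area(fr2, "A", "B", halve = FALSE), 2 * got)
  expect_error(contact_surface_area(fr2, "A", "Q"), "chains")
})
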