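test_that("donor/acceptor identification finds backbone polar atoms and excludes water", {
  fx <- make_topology(small_spec())
  da <- identify_donors_acceptors(fx$topology, fx$folded)
  # 6 residues, each with one backbone N-H donor; N and O acceptors
  expect_equal(nrow(da$donors), 6L)
  expect_equal(length(da$acceptors), 12L)
  a <- fx$topology$atoms
  expect_true(all(a$name[da$donors$heavy + 1L] == "N"))
  expect_true(all(a$element[da$donors$hydrogen + 1L] == "H"))
  expect_false(any(a$is_water[da$acceptors + 1L]))
})

test_that("polar-free topologies give empty lists and H-less polar ones an error", {
  carbons <- new_topology(data.frame(name = c("C1", "C2", "C3"), resid = c(0, 0, 0),
                                     resname = "UNK"))
  frame <- new_frame(matrix(rnorm(9), 3, 3))
  da <- identify_donors_acceptors(carbons, frame)
  expect_equal(nrow(da$donors), 0L)
  expect_length(da$acceptors, 0L)

  polar_no_h <- new_topology(data.frame(name = c("N", "CA", "O"), resid = c(0, 0, 0),
                                        resname = "ALA"))
  expect_error(identify_donors_acceptors(polar_no_h, frame), "hydrogens")
})

test_that("water competition is additive over waters and zero in vacuum", {
  # one protein N, two waters at controlled distances
  top <- new_topology(data.frame(
    name = c("N", "H", "OW", "HW1", "HW2", "OW", "HW1", "HW2"),
    resid = c(0, 0, 1, 1, 1, 2, 2, 2),
    resname = c("ALA", "ALA", rep("SOL", 6))))
  p <- water_switch_params()
  place <- function(r1, r2) new_frame(rbind(
    c(0, 0, 0), c(0, 0, 1),
    c(r1, 0, 0), c(r1 + 0.96, 0, 0), c(r1 - 0.24, 0.93, 0),
    c(0, r2, 0), c(0.96, r2, 0), c(-0.24, r2 + 0.93, 0)))
  # two waters at equal distance: exactly twice one switch
  f <- place(2.9, 2.9)
  expect_equal(water_competition(0, f, top, p),
               2 * rational_switch(2.9, p), tolerance = 1e-12)
  # additivity at unequal distances, against the independent oracle
  f2 <- place(2.5, 4.0)
  expect_equal(water_competition(0, f2, top, p),
               rational_oracle(2.5, p) + rational_oracle(4.0, p), tolerance = 1e-9)
  # far waters (beyond d_max): exactly zero
  f3 <- place(25, 30)
  expect_identical(water_competition(0, f3, top, p), 0)
  # vacuum
  vac <- new_topology(data.frame(name = c("N", "H"), resid = 0, resname = "ALA"))
  expect_identical(water_competition(0, new_frame(rbind(c(0, 0, 0), c(0, 0, 1))), vac,
                                     p), 0)
})

test_that("hydrogen-bond features compose switch, angle and competition as documented", {
  fx <- make_topology(small_spec())
  top <- fx$topology
  a <- top$atoms
  row0 <- function(r, nm) which(a$resid == r & a$name == nm) - 1L
  f <- hbond_feature(top, row0(4, "N"), row0(4, "H"), row0(0, "O"))

  # planted ideal geometry: value equals the composed oracles (no competitors,
  # waters far enough that only the weak slab tail contributes)
  d <- sqrt(sum((fx$folded$xyz[f$donor + 1, ] - fx$folded$xyz[f$acceptor + 1, ])^2))
  v <- evaluate_hbond_feature(f, fx$folded, top)
  expected <- rational_oracle(d, f$dist_switch) -
    water_competition(f$donor, fx$folded, top, f$water_switch) -
    water_competition(f$acceptor, fx$folded, top, f$water_switch)
  expect_equal(v, expected, tolerance = 1e-9)
  expect_gt(v, 0.6)
  expect_lte(v, 1)

  # broken in the misfolded frame
  expect_lt(abs(evaluate_hbond_feature(f, fx$misfolded, top)), 0.1)
})

test_that("a water seizing a far-separated native pair drives the feature to -1", {
  # donor residue 0, acceptor residue 2, placed far apart; one water almost
  # touching the donor so its switch saturates
  top <- new_topology(data.frame(
    name = c("N", "H", "CA", "N", "CA", "O", "OW", "HW1", "HW2"),
    resid = c(0, 0, 0, 1, 1, 2, 3, 3, 3),
    resname = c(rep("ALA", 6), rep("SOL", 3))))
  xyz <- rbind(
    c(0, 0, 0), c(0, 0, 1), c(1.46, 0, 0),
    c(10, 10, 0), c(11.5, 10, 0), c(30, 30, 0),
    c(0.4, 0, 0), c(1.36, 0, 0), c(0.16, 0.93, 0))
  f <- hbond_feature(top, 0L, 1L, 5L)
  v <- evaluate_hbond_feature(f, new_frame(xyz), top)
  expect_equal(v, -1, tolerance = 0.01)
  # with the competition ablated the same geometry is just "no contact"
  f0 <- hbond_feature(top, 0L, 1L, 5L, lambda_w = 0, lambda_p = 0)
  expect_equal(evaluate_hbond_feature(f0, new_frame(xyz), top), 0, tolerance = 1e-6)
})

test_that("hydrogen-bond features are invariant under rigid motion, water relabeling and box shifts", {
  set.seed(31)
  spec <- small_spec(bridging_waters = list(list(residue = 0L, atom = "O")))
  fx <- make_topology(spec)
  top <- fx$topology
  a <- top$atoms
  row0 <- function(r, nm) which(a$resid == r & a$name == nm) - 1L
  f <- hbond_feature(top, row0(4, "N"), row0(4, "H"), row0(0, "O"),
                     competitors = row0(2, "O"))
  for (frame in list(fx$folded, fx$misfolded)) {
    v0 <- evaluate_hbond_feature(f, frame, top)
    expect_gt(abs(v0), 1e-6)  # non-trivial value (bridging water in range)
    # rotation + translation
    vr <- evaluate_hbond_feature(f, rotate_frame(frame, random_rotation(), c(1.3, -2.1, 0.7)), top)
    expect_equal(vr, v0, tolerance = 1e-9)
    # whole-box translation wraps back through minimum image
    shifted <- new_frame(sweep(frame$xyz, 2, frame$box, `+`), box = frame$box)
    expect_equal(evaluate_hbond_feature(f, shifted, top), v0, tolerance = 1e-9)
    # single water translated by a full box vector
    wo <- which(a$is_water)[1:3]
    xyz <- frame$xyz; xyz[wo, ] <- sweep(xyz[wo, ], 2, frame$box, `+`)
    expect_equal(evaluate_hbond_feature(f, new_frame(xyz, box = frame$box), top),
                 v0, tolerance = 1e-9)
    # water relabeling
    expect_equal(evaluate_hbond_feature(f, swap_waters(frame, top, 1, 4), top),
                 v0, tolerance = 1e-12)
  }
})

test_that("hydrogen-bond feature construction enforces its invariants", {
  fx <- make_topology(small_spec())
  top <- fx$topology
  a <- top$atoms
  row0 <- function(r, nm) which(a$resid == r & a$name == nm) - 1L
  # adjacent residues violate the sequence-separation floor
  expect_error(hbond_feature(top, row0(1, "N"), row0(1, "H"), row0(0, "O")), "separation")
  # water atoms cannot anchor a protein hydrogen bond
  wo <- which(a$is_water & a$element == "O")[1] - 1L
  expect_error(hbond_feature(top, row0(4, "N"), row0(4, "H"), wo), "protein")
  expect_error(hbond_feature(top, 10000L, 1L, 2L), "range")
  f <- hbond_feature(top, row0(4, "N"), row0(4, "H"), row0(0, "O"))
  small <- make_topology(fixture_spec(n_waters = 0L))
  expect_error(evaluate_hbond_feature(f, new_frame(matrix(0, 2, 3)), top), "atoms")
})
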