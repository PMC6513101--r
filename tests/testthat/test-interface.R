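test_that("isolated-atom SASA matches the sphere area analytically", {
  for (el in c("C", "N", "O", "S")) {
    atoms <- data.frame(chain = "H", resno = 1L, ins = "", aa3 = "ALA",
                        atom = "CA", element = el, x = 0, y = 0, z = 0,
                        stringsAsFactors = FALSE)
    cx <- new_complex(atoms, roles = c(H = "heavy"))
    s <- compute_sasa(cx)
    r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)[[el]] + 1.4
    expect_equal(attr(s, "total"), 4 * pi * r^2, tolerance = 0.01)
  }
})

test_that("occluded-pair SASA matches the two-sphere closed form", {
  # exact analytic value for two intersecting probe-expanded spheres
  cases <- list(c("C", "C", 2.5), c("C", "N", 3.0), c("O", "S", 2.0),
                c("C", "O", 4.0))
  for (cs in cases) {
    d <- as.numeric(cs[3])
    cx <- two_atom_complex(cs[1], cs[2], d)
    got <- attr(compute_sasa(cx, n_points = 2000), "total")
    radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
    want <- oracle_two_sphere_sasa(radii[[cs[1]]] + 1.4, radii[[cs[2]]] + 1.4, d)
    expect_equal(got, want, tolerance = 0.02)
  }
})

test_that("compute_sasa names the offending atom for unknown elements", {
  atoms <- data.frame(chain = "H", resno = 7L, ins = "", aa3 = "ALA",
                      atom = "ZZ1", element = "Zz", x = 0, y = 0, z = 0,
                      stringsAsFactors = FALSE)
  cx <- new_complex(atoms)
  expect_error(compute_sasa(cx), "ZZ1.*H:7")
})

test_that("buried surface is positive for the complex, ~zero when separated", {
  fx <- default_fixture()
  bsa <- buried_surface(fx$complex, n_points = 480)
  expect_gt(bsa, 50)
  apart <- transform_apply(fx$complex, c("H", "L"),
                           rigid_transform(diag(3), c(0, -500, 0)))
  expect_equal(buried_surface(apart, n_points = 480), 0, tolerance = 1e-6)
})

test_that("interfacial_residues matches a brute-force census", {
  fx <- default_fixture()
  got <- interfacial_residues(fx$complex, cutoff = 5.0)
  a <- fx$complex$atoms
  keys <- paste0(a$chain, ":", a$resno)
  binder_keys <- unique(keys[a$chain %in% c("H", "L")])
  oracle_b <- character(0)
  txyz <- cbind(a$x, a$y, a$z)[a$chain == "A", , drop = FALSE]
  for (k in binder_keys) {
    bxyz <- cbind(a$x, a$y, a$z)[keys == k, , drop = FALSE]
    if (oracle_min_cross_dist(bxyz, txyz) <= 5.0) oracle_b <- c(oracle_b, k)
  }
  expect_setequal(got$binder, oracle_b)
})

test_that("planted interactions are detected with exact geometry", {
  fx <- default_fixture()
  recs <- detect_interactions(fx$complex)
  expect_equal(nrow(recs), 4)
  expect_setequal(recs$kind, c("salt_bridge", "hbond", "pi_cation", "hydrophobic"))
  sb <- recs[recs$kind == "salt_bridge", ]
  expect_equal(sb$binder_chain, "H"); expect_equal(sb$binder_pos, "4")
  expect_equal(sb$distance, 3.0, tolerance = 0.05)
  pc <- recs[recs$kind == "pi_cation", ]
  expect_equal(pc$distance, 4.9, tolerance = 0.05)
  expect_equal(pc$angle, 28.5, tolerance = 2)
  hp <- recs[recs$kind == "hydrophobic", ]
  expect_equal(hp$distance, 4.0, tolerance = 0.05)
})

test_that("salt-bridge atom pairs are never double counted as hydrogen bonds", {
  spec <- fixture_spec(planted = data.frame(
    kind = "salt_bridge", binder_chain = "H", binder_pos = 4L,
    antigen_pos = 4L, distance = 3.0, angle = NA, stringsAsFactors = FALSE),
    retained_positions = character(0))
  fx <- make_toy_complex(spec)
  recs <- detect_interactions(fx$complex)
  expect_equal(recs$kind, "salt_bridge")
  expect_equal(nrow(recs), 1)
})

test_that("both published pi-cation geometries pass the default cutoffs", {
  for (geom in list(c(4.9, 28.5), c(5.7, 51.5))) {
    spec <- fixture_spec(planted = data.frame(
      kind = "pi_cation", binder_chain = "L", binder_pos = 4L,
      antigen_pos = 4L, distance = geom[1], angle = geom[2],
      stringsAsFactors = FALSE), retained_positions = character(0))
    fx <- make_toy_complex(spec)
    recs <- detect_interactions(fx$complex)
    pc <- recs[recs$kind == "pi_cation", ]
    expect_equal(nrow(pc), 1)
    expect_equal(pc$distance, geom[1], tolerance = 0.05)
    expect_equal(pc$angle, geom[2], tolerance = 2)
  }
})

test_that("pi-cation candidates outside the cutoffs are rejected", {
  over_angle <- make_toy_complex(fixture_spec(planted = data.frame(
    kind = "pi_cation", binder_chain = "L", binder_pos = 4L,
    antigen_pos = 4L, distance = 4.9, angle = 75,
    stringsAsFactors = FALSE), retained_positions = character(0)))
  recs <- detect_interactions(over_angle$complex)
  expect_false("pi_cation" %in% recs$kind)
  expect_error(fixture_spec(planted = data.frame(
    kind = "pi_cation", binder_chain = "L", binder_pos = 4L,
    antigen_pos = 4L, distance = 6.4, angle = 20, stringsAsFactors = FALSE)),
    "exceeds its class cutoff")
})

test_that("interaction records honour cutoff boundaries", {
  # hand-built Ser OG ... OG pair at a controlled separation
  ser_pair <- function(d) {
    atoms <- data.frame(
      chain = c("H", "A"), resno = 1L, ins = "", aa3 = "SER",
      atom = "OG", element = "O", x = 0, y = c(0, d), z = 0,
      stringsAsFactors = FALSE)
    new_complex(atoms, roles = c(H = "heavy", A = "antigen"))
  }
  expect_equal(detect_interactions(ser_pair(3.45))$kind, "hbond")
  expect_equal(nrow(detect_interactions(ser_pair(3.55))), 0)
})

test_that("detect_interactions restricted to one binder residue is a subset", {
  fx <- default_fixture()
  all_recs <- detect_interactions(fx$complex)
  one <- detect_interactions(fx$complex, binder_residue = "H:4")
  expect_equal(one, all_recs[all_recs$binder_chain == "H" &
                               all_recs$binder_pos == "4", ],
               ignore_attr = TRUE)
})

test_that("interaction_profile aggregates per residue and kind", {
  fx <- default_fixture()
  prof <- interaction_profile(fx$complex, pose_id = 17)
  expect_s3_class(prof, "interface_profile")
  expect_equal(prof$total, 4)
  expect_setequal(prof$counts$residue, c("H:4", "H:8", "L:11", "L:2"))
  expect_true(all(prof$counts$n == 1))
  expect_equal(prof$pose_id, 17)
})
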