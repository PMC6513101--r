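test_that("phenotype tables validate labels and notation", {
  expect_error(phenotype_table(c("H:K4A" = "weird")), "unknown phenotype")
  expect_error(phenotype_table(c("K4A" = "retained")), "cannot parse")
  ok <- phenotype_table(c("H:K4A" = "non_binding", "L:L2A" = "reduced"))
  expect_named(ok, c("H:K4A", "L:L2A"))
})

test_that("read_phenotypes errors name the file for empty/malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("mutation,label", path)   # header only, zero rows
  expect_error(read_phenotypes(path), path, fixed = TRUE)
  writeLines("foo,bar\n1,2", path)
  expect_error(read_phenotypes(path), path, fixed = TRUE)
  expect_error(read_phenotypes(file.path(tempdir(), "nope.csv")), "not found")
  writeLines("mutation,label\nH:K4A,non_binding", path)
  expect_equal(read_phenotypes(path), c("H:K4A" = "non_binding"))
})

test_that("consistency_filter applies both rules with exhaustive violations", {
  m <- rbind(
    good = c("H:Y1A" = 0.5, "H:R2A" = 0.1, "L:Y3A" = 0.2),
    bad1 = c(-0.01, 0.3, 0.2),    # deleterious below 0
    bad2 = c(1.0, 0.0, 0.51))     # retained above 0.5
  colnames(m) <- c("H:Y1A", "H:R2A", "L:Y3A")
  ph <- c("H:Y1A" = "non_binding", "H:R2A" = "reduced", "L:Y3A" = "retained")
  out <- consistency_filter(m, ph)
  expect_equal(out$passing, "good")
  expect_equal(out$violations$bad1$mutation, "H:Y1A")
  expect_match(out$violations$bad1$rule, "deleterious ddE -0.01 < 0.00")
  expect_equal(out$violations$bad2$mutation, "L:Y3A")
  expect_match(out$violations$bad2$rule, "retained ddE 0.51 > 0.50")
  # boundary values pass: >= for deleterious, <= for retained
  mb <- m["good", , drop = FALSE]; mb[1, ] <- c(0.0, 0.0, 0.5)
  expect_equal(consistency_filter(mb, ph)$passing, "good")
})

test_that("consistency_filter names missing mutations and NA cells", {
  m <- matrix(0, 1, 1, dimnames = list("p1", "H:Y1A"))
  ph <- c("H:Y1A" = "retained", "H:R2A" = "reduced")
  expect_error(consistency_filter(m, ph), "H:R2A")
  m2 <- matrix(NA_real_, 1, 1, dimnames = list("p7", "H:Y1A"))
  expect_error(consistency_filter(m2, c("H:Y1A" = "retained")), "pose p7.*H:Y1A")
})

test_that("consistency_filter matches exhaustive enumeration on random matrices", {
  set.seed(2024)
  for (rep in 1:25) {
    n_pose <- sample(3:12, 1); n_mut <- sample(3:8, 1)
    muts <- paste0("H:Y", seq_len(n_mut), "A")
    labels <- stats::setNames(
      sample(c("non_binding", "reduced", "retained"), n_mut, replace = TRUE),
      muts)
    m <- matrix(round(rnorm(n_pose * n_mut, 0.2, 1), 2), n_pose, n_mut,
                dimnames = list(paste0("pose", seq_len(n_pose)), muts))
    got <- consistency_filter(m, labels)
    want <- oracle_consistency(m, labels)
    expect_equal(got$passing, want$passing)
    for (pid in rownames(m)) {
      expect_equal(sort(got$violations[[pid]]$mutation), want$violations[[pid]])
    }
  }
})

test_that("rank_partial_knockout orders by margin with strict front group", {
  m <- rbind(
    p1 = c(red = 0.3, d1 = 1.0, d2 = 2.0),   # strict: 0.3 < 1.0, margin -0.7
    p2 = c(red = 0.9, d1 = 1.0, d2 = 2.0),   # strict, margin -0.1
    p3 = c(red = 1.5, d1 = 1.0, d2 = 2.0),   # not strict, margin 0.5
    p4 = c(red = 0.3, d1 = 1.0, d2 = 2.0))   # tie with p1 -> pose id order
  colnames(m) <- c("L:L2A", "H:K4A", "H:S8A")
  out <- rank_partial_knockout(c("p3", "p4", "p2", "p1"), m,
                               "L:L2A", c("H:K4A", "H:S8A"))
  expect_equal(as.character(out), c("p1", "p4", "p2", "p3"))
  expect_equal(attr(out, "margin"), c(-0.7, -0.7, -0.1, 0.5))
  expect_equal(attr(out, "strict_partial"), c(TRUE, TRUE, TRUE, FALSE))
  expect_error(rank_partial_knockout(character(0), m, "L:L2A", "H:K4A"),
               "no passing poses")
  # empty reduced set: input order preserved, NA margins
  none <- rank_partial_knockout(c("p2", "p1"), m, character(0), "H:K4A")
  expect_equal(as.character(none), c("p2", "p1"))
  expect_true(all(is.na(attr(none, "margin"))))
})

test_that("interaction_loss_score counts lost contacts at hotspots", {
  fx <- default_fixture()
  out <- interaction_loss_score(fx$complex, c("H:4", "H:8", "L:11"))
  # each hotspot has exactly one planted interaction, all lost on truncation
  expect_equal(out$total, 3)
  expect_equal(out$explained, 3)
  # a non-contact position contributes nothing
  out2 <- interaction_loss_score(fx$complex, "H:11")
  expect_equal(out2$total, 0)
  expect_equal(out2$explained, 0)
})

test_that("scan_pose_matrix returns poses x mutations with pose-id rownames", {
  fx <- default_fixture()
  ps <- make_decoy_set(fx, n_decoys = 3, seed = 4)
  m <- scan_pose_matrix(ps, fx$truth$scan_positions)
  expect_equal(nrow(m), 4)
  expect_equal(sort(as.integer(rownames(m))), c(0, sort(setdiff(as.integer(rownames(m)), 0))))
  expect_true(all(c("H:K4A", "L:L2A") %in% colnames(m)))
  expect_equal(m["0", "H:K4A"], 2.0)
})

test_that("design_validation_panel implements all four selection rules", {
  # constructed scan matrix over 6 eligible positions and 3 poses
  pos <- c("H:1", "H:2", "H:3", "H:4", "L:1", "L:2")
  m <- rbind(
    a = c(2.0, 0.0, 1.0, 0.0, 1.2, 0.01),
    b = c(0.1, 0.0, 2.5, 0.02, 0.1, -0.01),
    c = c(0.1, 0.0, 0.2, 0.01, 2.4, 0.0))
  colnames(m) <- pos
  # profiles: H:1 appears in exactly one pose's interface profile
  prof <- function(id, residues) {
    structure(list(pose_id = id,
                   counts = data.frame(residue = residues, kind = "hbond",
                                       n = 1L, stringsAsFactors = FALSE),
                   total = length(residues)),
              class = "interface_profile")
  }
  profiles <- list(prof("a", c("H:1", "H:3")), prof("b", c("H:3", "L:1")),
                   prof("c", c("H:3", "L:1")))
  # an annotated complex covering the positions (toy: all CDR/Vernier
  # except H:4 and L:2 framework is NOT the point here, keep all eligible)
  atoms <- do.call(rbind, lapply(list(c("H", 6), c("L", 6)), function(cl) {
    data.frame(chain = cl[1], resno = seq_len(as.integer(cl[2])), ins = "",
               aa3 = "TYR", atom = "CA", element = "C",
               x = 3.8 * seq_len(as.integer(cl[2])), y = 0,
               z = ifelse(cl[1] == "H", 0, 8), stringsAsFactors = FALSE)
  }))
  cx <- new_complex(atoms, roles = c(H = "heavy", L = "light"))
  map <- data.frame(chain_id = atoms$chain, author_pos = atoms$resno,
                    imgt_label = atoms$resno,
                    annotation = "CDRH1", stringsAsFactors = FALSE)
  map$annotation[map$chain_id == "L"] <- "CDRL1"
  cx <- annotate_complex(cx, map)

  panel <- design_validation_panel(m, profiles, cx,
                                   discrimination_delta = 0.5,
                                   min_discordant_poses = 2, n_triples = 1)
  unique_rows <- panel[panel$category == "unique", ]
  expect_equal(unique_rows$positions, "H:1")
  singles <- panel[panel$category == "single", ]
  # H:3 (spread 1.0/2.3), L:1 (1.1/2.3) discriminate vs >= 2 poses; H:1 is
  # already unique; H:2, H:4, L:2 are flat
  expect_setequal(strsplit(paste(singles$positions, collapse = ","), ",")[[1]],
                  c("H:3", "L:1"))
  ctrl <- panel[panel$category == "control", ]
  expect_setequal(ctrl$positions, c("H:2", "L:2"))
  # mutations carry the wild type from the complex (all TYR here)
  expect_equal(unique_rows$mutations, "H:Y1A")
  # triples need >= 3 singles; with 2 singles none are emitted
  expect_false("triple" %in% panel$category)
})

test_that("design_validation_panel triples maximise worst-case discrimination", {
  pos <- paste0("H:", 1:5)
  set.seed(5)
  m <- matrix(rnorm(4 * 5, 1, 1.2), 4, 5, dimnames = list(paste0("p", 1:4), pos))
  profiles <- lapply(paste0("p", 1:4), function(id) {
    structure(list(pose_id = id, counts = data.frame(
      residue = character(0), kind = character(0), n = integer(0)),
      total = 0L), class = "interface_profile")
  })
  atoms <- data.frame(chain = "H", resno = 1:5, ins = "", aa3 = "SER",
                      atom = "CA", element = "C", x = 3.8 * (1:5), y = 0, z = 0,
                      stringsAsFactors = FALSE)
  cx <- annotate_complex(
    new_complex(atoms, roles = c(H = "heavy")),
    data.frame(chain_id = "H", author_pos = 1:5, imgt_label = 1:5,
               annotation = "CDRH2", stringsAsFactors = FALSE))
  panel <- suppressWarnings(   # no flat control position exists by design
    design_validation_panel(m, profiles, cx, discrimination_delta = 0.1,
                            min_discordant_poses = 2, n_triples = 2))
  trips <- panel[panel$category == "triple", ]
  singles_all <- sort(unlist(strsplit(
    panel$positions[panel$category == "single"], ",")))
  if (length(singles_all) >= 3 && nrow(trips)) {
    combos <- utils::combn(singles_all, 3, simplify = FALSE)
    score <- vapply(combos, function(tr) {
      min(stats::dist(rowSums(m[, tr, drop = FALSE])))
    }, 0)
    best <- max(score)
    got_first <- strsplit(trips$positions[1], ",")[[1]]
    got_score <- min(stats::dist(rowSums(m[, got_first, drop = FALSE])))
    expect_equal(got_score, best)
  }
})

test_that("design_validation_panel warns when a chain has no control", {
  pos <- c("H:1", "H:2")
  m <- rbind(a = c(2, 1), b = c(0.2, 0.3))
  colnames(m) <- pos
  profiles <- list(
    structure(list(pose_id = "a", counts = data.frame(
      residue = "H:1", kind = "hbond", n = 1L), total = 1L),
      class = "interface_profile"),
    structure(list(pose_id = "b", counts = data.frame(
      residue = "H:1", kind = "hbond", n = 1L), total = 1L),
      class = "interface_profile"))
  atoms <- data.frame(chain = "H", resno = 1:2, ins = "", aa3 = "SER",
                      atom = "CA", element = "C", x = c(0, 3.8), y = 0, z = 0,
                      stringsAsFactors = FALSE)
  cx <- annotate_complex(
    new_complex(atoms, roles = c(H = "heavy")),
    data.frame(chain_id = "H", author_pos = 1:2, imgt_label = 1:2,
               annotation = "CDRH1", stringsAsFactors = FALSE))
  expect_warning(
    design_validation_panel(m, profiles, cx),
    "no qualifying control position on chain H")
})
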