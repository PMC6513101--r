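# Seeded synthetic-structure generator: idealised extended chains with
# heavy-atom side-chain templates installed only at planted interaction
# sites, alanine elsewhere. Planted terminal groups are positioned
# analytically so each specified interaction geometry is exact; side chains
# at planted sites are extended atom lines bridging the backbone gap (the
# toy emulates interface geometry, not folding).

CA_SPACING <- 3.8
FIXTURE_GAP <- 14     # binder-backbone to antigen-backbone separation (y, A)
CHAIN_Z <- c(H = 0, L = 8, A = 4)

#' Specification of a synthetic antibody-antigen fixture
#'
#' @param seed integer seed (controls nothing in the deterministic builder
#'   itself but is recorded and used for downstream decoy sampling).
#' @param binder_lengths named residue counts for the heavy/light chains.
#' @param antigen_length antigen residue count.
#' @param planted data.frame with columns `kind` (salt_bridge, hbond,
#'   pi_cation, hydrophobic, pi_pi), `binder_chain`, `binder_pos`,
#'   `antigen_pos`, `distance` (A) and `angle` (deg, pi-cation only).
#' @param retained_positions `"chain:pos"` keys of non-interface positions
#'   included in the phenotype panel as retained binders.
#' @param decoys default decoy count for [make_decoy_set()].
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1,
                         binder_lengths = c(H = 12, L = 12),
                         antigen_length = 16,
                         planted = default_planted(),
                         retained_positions = c("H:11", "L:6"),
                         decoys = 199) {
  kinds <- c("salt_bridge", "hbond", "pi_cation", "hydrophobic", "pi_pi")
  if (!all(planted$kind %in% kinds)) {
    stop("unknown planted interaction kind(s): ",
         paste(setdiff(planted$kind, kinds), collapse = ", "))
  }
  gp <- geometry_params()
  cutoffs <- c(salt_bridge = gp$salt_bridge_dist, hbond = gp$hbond_dist,
               pi_cation = gp$pi_cation_dist, hydrophobic = gp$hydrophobic_dist,
               pi_pi = gp$pi_pi_dist)
  over <- planted$distance > cutoffs[planted$kind]
  if (any(over)) {
    i <- which(over)[1]
    stop("unsatisfiable planted interaction: ", planted$kind[i], " at ",
         planted$distance[i], " A exceeds its class cutoff ",
         cutoffs[planted$kind[i]], " A")
  }
  if (any(planted$binder_pos > binder_lengths[planted$binder_chain]) ||
      any(planted$antigen_pos > antigen_length)) {
    stop("planted position outside chain length")
  }
  ap <- sort(planted$antigen_pos)
  if (length(ap) > 1 && any(diff(ap) < 2)) {
    stop("unsatisfiable planted set: antigen positions ",
         paste(ap[which(diff(ap) < 2)[1] + 0:1], collapse = " and "),
         " are too close to keep interaction groups independent")
  }
  structure(list(seed = seed, binder_lengths = binder_lengths,
                 antigen_length = antigen_length, planted = planted,
                 retained_positions = retained_positions, decoys = decoys),
            class = "fixture_spec")
}

#' Default planted-interaction layout
#'
#' Three strong hotspots (salt bridge, hydrogen bond, pi-cation at the
#' canonical 4.9 A / 28.5 degree geometry) and one weak hydrophobic site.
#' @export
default_planted <- function() {
  data.frame(
    kind = c("salt_bridge", "hbond", "pi_cation", "hydrophobic"),
    binder_chain = c("H", "H", "L", "L"),
    binder_pos = c(4L, 8L, 11L, 2L),
    antigen_pos = c(4L, 8L, 11L, 2L),
    distance = c(3.0, 3.0, 4.9, 4.0),
    angle = c(NA, NA, 28.5, NA),
    stringsAsFactors = FALSE
  )
}

fixture_atom <- function(chain, resno, aa3, atom, element, xyz) {
  data.frame(chain = chain, resno = resno, ins = "", aa3 = aa3, atom = atom,
             element = element, x = xyz[1], y = xyz[2], z = xyz[3],
             stringsAsFactors = FALSE)
}

backbone_rows <- function(chain, resno, aa3, ca) {
  rbind(
    fixture_atom(chain, resno, aa3, "N", "N", ca + c(-1.25, 0, 0.45)),
    fixture_atom(chain, resno, aa3, "CA", "C", ca),
    fixture_atom(chain, resno, aa3, "C", "C", ca + c(1.25, 0, 0.45)),
    fixture_atom(chain, resno, aa3, "O", "O", ca + c(1.25, 0, 1.68))
  )
}

# Evenly spaced atom line from CA towards `terminal`; first atom (CB) at
# 1.53 A, last atom exactly at `terminal`.
line_side_chain <- function(chain, resno, aa3, ca, terminal, names) {
  u <- unit_vec(terminal - ca)
  reach <- vnorm(terminal - ca)
  n <- length(names)
  pos <- if (n == 1) reach else c(1.53, 1.53 + (reach - 1.53) *
                                    seq_len(n - 1) / (n - 1))
  do.call(rbind, lapply(seq_len(n), function(k) {
    el <- substr(gsub("[0-9]", "", names[k]), 1, 1)
    fixture_atom(chain, resno, aa3, names[k], el, ca + pos[k] * u)
  }))
}

hexagon_ring <- function(chain, resno, aa3, centroid, radius = 1.39) {
  names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  do.call(rbind, lapply(1:6, function(k) {
    a <- (k - 1) * pi / 3
    el <- "C"
    fixture_atom(chain, resno, aa3, names[k], el,
                 centroid + radius * c(cos(a), 0, sin(a)))
  }))
}

#' Build a toy antibody-antigen complex with planted interactions
#'
#' Constructs idealised extended chains (C-alpha spacing 3.8 A) for two
#' binder chains and one antigen chain, installs full heavy-atom side-chain
#' groups only at planted positions (alanine elsewhere) and places every
#' planted interaction at its specified distance/angle exactly. The output
#' complex is the "true pose"; the binder and antigen are also returned
#' separately for redocking.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, writes `binder.pdb`,
#'   `antigen.pdb`, `complex.pdb`, `truth.json`, `numbering_map.tsv` and
#'   `phenotypes.csv` there.
#' @return list with `complex` (posed, roles set), `binder`, `antigen`,
#'   `truth` (ground-truth list: planted table, hotspot keys, weak keys,
#'   scan positions, true transform) and `paths` (when `dir` given).
#' @export
make_toy_complex <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  planted <- spec$planted
  chains <- c(names(spec$binder_lengths), "A")
  lengths <- c(spec$binder_lengths, A = spec$antigen_length)
  ca_of <- function(chain, i) {
    # slight antigen zigzag keeps its C-alpha trace non-collinear, which
    # downstream superposition (receptor-blockade mapping) requires
    zig <- if (chain == "A") 0.6 * (i %% 2) else 0
    c(CA_SPACING * (i - 1),
      if (chain == "A") FIXTURE_GAP else 0,
      CHAIN_Z[[chain]] + zig)
  }
  s_dir <- function(chain) if (chain == "A") c(0, -1, 0) else c(0, 1, 0)

  atoms <- list()
  add <- function(df) atoms[[length(atoms) + 1L]] <<- df

  # antigen-side groups first: their terminal positions anchor the binder's
  antigen_terminal <- list()
  for (k in seq_len(nrow(planted))) {
    p <- planted[k, ]
    ca <- ca_of("A", p$antigen_pos)
    s <- s_dir("A")
    key <- as.character(k)
    if (p$kind == "salt_bridge") {
      od1 <- ca + 4.2 * s
      add(line_side_chain("A", p$antigen_pos, "ASP", ca, od1, c("CB", "CG", "OD1")))
      add(fixture_atom("A", p$antigen_pos, "ASP", "OD2", "O", od1 + c(1.2, 0, 0)))
      antigen_terminal[[key]] <- od1
    } else if (p$kind == "hbond") {
      og <- ca + 3.0 * s
      add(line_side_chain("A", p$antigen_pos, "SER", ca, og, c("CB", "OG")))
      antigen_terminal[[key]] <- og
    } else if (p$kind == "pi_cation") {
      centroid <- ca + 5.5 * s
      add(fixture_atom("A", p$antigen_pos, "TYR", "CB", "C", ca + 1.53 * s))
      add(hexagon_ring("A", p$antigen_pos, "TYR", centroid))
      antigen_terminal[[key]] <- centroid
    } else if (p$kind == "hydrophobic") {
      cd1 <- ca + 4.0 * s
      add(line_side_chain("A", p$antigen_pos, "LEU", ca, cd1, c("CB", "CG", "CD1")))
      add(fixture_atom("A", p$antigen_pos, "LEU", "CD2", "C", cd1 + c(1.3, 0, 0)))
      antigen_terminal[[key]] <- cd1
    } else if (p$kind == "pi_pi") {
      centroid <- ca + 5.0 * s
      add(fixture_atom("A", p$antigen_pos, "PHE", "CB", "C", ca + 1.53 * s))
      add(hexagon_ring("A", p$antigen_pos, "PHE", centroid))
      antigen_terminal[[key]] <- centroid
    }
  }

  # binder-side groups, placed relative to the antigen terminals
  binder_side <- list(); binder_aa3 <- list()
  for (k in seq_len(nrow(planted))) {
    p <- planted[k, ]
    ca <- ca_of(p$binder_chain, p$binder_pos)
    anchor <- antigen_terminal[[as.character(k)]]
    rk <- residue_key(p$binder_chain, p$binder_pos)
    toward_binder <- c(0, -1, 0)   # from the antigen towards the binder rows
    if (p$kind == "salt_bridge") {
      nz <- anchor + p$distance * toward_binder
      binder_side[[rk]] <- line_side_chain(p$binder_chain, p$binder_pos, "LYS",
                                           ca, nz, c("CB", "CG", "CD", "CE", "NZ"))
      binder_aa3[[rk]] <- "LYS"
    } else if (p$kind == "hbond") {
      og <- anchor + p$distance * toward_binder
      binder_side[[rk]] <- line_side_chain(p$binder_chain, p$binder_pos, "SER",
                                           ca, og, c("CB", "OG"))
      binder_aa3[[rk]] <- "SER"
    } else if (p$kind == "pi_cation") {
      th <- p$angle * pi / 180
      centre <- anchor + p$distance * (cos(th) * toward_binder + sin(th) * c(1, 0, 0))
      grp <- rbind(
        fixture_atom(p$binder_chain, p$binder_pos, "ARG", "CZ", "C", centre),
        do.call(rbind, lapply(0:2, function(j) {
          a <- pi / 6 + j * 2 * pi / 3
          nm <- c("NE", "NH1", "NH2")[j + 1]
          fixture_atom(p$binder_chain, p$binder_pos, "ARG", nm, "N",
                       centre + 1.2 * c(cos(a), 0, sin(a)))
        }))
      )
      stem <- line_side_chain(p$binder_chain, p$binder_pos, "ARG", ca,
                              centre - 1.8 * unit_vec(centre - ca),
                              c("CB", "CG", "CD"))
      binder_side[[rk]] <- rbind(stem, grp)
      binder_aa3[[rk]] <- "ARG"
    } else if (p$kind == "hydrophobic") {
      cd1 <- anchor + p$distance * toward_binder
      sc <- rbind(
        line_side_chain(p$binder_chain, p$binder_pos, "LEU", ca, cd1,
                        c("CB", "CG", "CD1")),
        fixture_atom(p$binder_chain, p$binder_pos, "LEU", "CD2", "C",
                     cd1 + c(1.3, 0, 0))
      )
      binder_side[[rk]] <- sc
      binder_aa3[[rk]] <- "LEU"
    } else if (p$kind == "pi_pi") {
      centre <- anchor + p$distance * toward_binder
      binder_side[[rk]] <- rbind(
        fixture_atom(p$binder_chain, p$binder_pos, "PHE", "CB", "C",
                     ca + 1.53 * unit_vec(centre - ca)),
        hexagon_ring(p$binder_chain, p$binder_pos, "PHE", centre)
      )
      binder_aa3[[rk]] <- "PHE"
    }
  }

  build_chain <- function(chain) {
    rows <- list()
    for (i in seq_len(lengths[[chain]])) {
      rk <- residue_key(chain, i)
      aa3 <- binder_aa3[[rk]] %||% "ALA"
      if (chain == "A") {
        sel <- planted$antigen_pos == i
        aa3 <- if (any(sel)) {
          switch(planted$kind[which(sel)[1]], salt_bridge = "ASP",
                 hbond = "SER", pi_cation = "TYR", hydrophobic = "LEU",
                 pi_pi = "PHE")
        } else "ALA"
      }
      ca <- ca_of(chain, i)
      rows[[length(rows) + 1L]] <- backbone_rows(chain, i, aa3, ca)
      side <- if (chain != "A") binder_side[[rk]] else NULL
      if (!is.null(side)) {
        rows[[length(rows) + 1L]] <- side
      } else if (aa3 == "ALA") {
        rows[[length(rows) + 1L]] <-
          fixture_atom(chain, i, "ALA", "CB", "C", ca + 1.53 * s_dir(chain))
      }
    }
    do.call(rbind, rows)
  }

  binder_atoms <- do.call(rbind, lapply(names(spec$binder_lengths), build_chain))
  antigen_bb <- build_chain("A")
  antigen_atoms <- rbind(antigen_bb, do.call(rbind, atoms))
  # keep antigen atoms grouped by residue and ordered by position
  antigen_atoms <- antigen_atoms[order(antigen_atoms$resno,
                                       !antigen_atoms$atom %in% BACKBONE_ATOMS), ,
                                 drop = FALSE]

  roles_b <- stats::setNames(c("heavy", "light"), names(spec$binder_lengths))
  binder <- new_complex(binder_atoms, roles = roles_b)
  antigen <- new_complex(antigen_atoms, roles = c(A = "antigen"))
  cx <- combine_binder_target(binder, antigen)

  hot <- planted$kind %in% c("salt_bridge", "hbond", "pi_cation", "pi_pi")
  hotspot <- residue_key(planted$binder_chain[hot], planted$binder_pos[hot])
  weak <- residue_key(planted$binder_chain[!hot], planted$binder_pos[!hot])
  truth <- list(
    seed = spec$seed,
    true_transform = rigid_transform(),
    planted = planted,
    hotspot_positions = hotspot,
    weak_positions = weak,
    scan_positions = c(hotspot, weak, spec$retained_positions),
    true_pose_id = NA
  )
  out <- list(complex = cx, binder = binder, antigen = antigen, truth = truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      binder = file.path(dir, "binder.pdb"),
      antigen = file.path(dir, "antigen.pdb"),
      complex = file.path(dir, "complex.pdb"),
      truth = file.path(dir, "truth.json"),
      numbering_map = file.path(dir, "numbering_map.tsv"),
      phenotypes = file.path(dir, "phenotypes.csv")
    )
    write_pdb_file(binder, paths$binder)
    write_pdb_file(antigen, paths$antigen)
    write_pdb_file(cx, paths$complex)
    tr <- truth; tr$true_transform <- list(rotation = truth$true_transform$rotation,
                                           translation = truth$true_transform$translation)
    jsonlite::write_json(tr, paths$truth, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    utils::write.table(fixture_numbering_map(spec), paths$numbering_map,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ph <- simulate_phenotypes(truth, cx)
    utils::write.table(data.frame(mutation = names(ph), label = unname(ph)),
                       paths$phenotypes, sep = ",", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

# CDR/Vernier annotation for the toy antibody: planted/weak positions carry
# CDR labels, retained controls are Vernier, everything else framework.
fixture_numbering_map <- function(spec) {
  rows <- list()
  cdr_of <- c(H = "CDRH1", L = "CDRL1")
  planted_keys <- residue_key(spec$planted$binder_chain, spec$planted$binder_pos)
  for (ch in names(spec$binder_lengths)) {
    for (i in seq_len(spec$binder_lengths[[ch]])) {
      key <- residue_key(ch, i)
      ann <- if (key %in% planted_keys) cdr_of[[ch]]
      else if (key %in% spec$retained_positions) "Vernier"
      else "FR"
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = ch, author_pos = i, imgt_label = i, annotation = ann,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Phenotype labels implied by the planted ground truth
#'
#' Alanine mutation at a position with at least one strong planted
#' interaction (salt bridge, hydrogen bond, pi-cation, pi-pi) is
#' `non_binding`; a position with only weak (hydrophobic) contacts is
#' `reduced`; scan positions with no planted interaction are `retained`.
#'
#' @param truth ground-truth list from [make_toy_complex()].
#' @param complex the fixture complex (for wild-type amino-acid lookup).
#' @return a [phenotype_table()].
#' @export
simulate_phenotypes <- function(truth, complex) {
  label_of <- function(key) {
    if (key %in% truth$hotspot_positions) "non_binding"
    else if (key %in% truth$weak_positions) "reduced"
    else "retained"
  }
  muts <- vapply(truth$scan_positions, function(key) {
    ch <- sub(":.*", "", key); pos <- sub(".*:", "", key)
    i <- resolve_residue(complex, ch, pos)
    wt <- unname(aa_three_to_one[complex$residues$aa3[i]])
    paste0(ch, ":", wt, pos, "A")
  }, "")
  phenotype_table(stats::setNames(
    vapply(truth$scan_positions, label_of, ""), unname(muts)))
}

#' True pose plus clash-free random decoys
#'
#' Returns a `pose_set` containing the fixture's true pose (pose id 0,
#' identity transform) followed by `n_decoys` random clash-free poses from
#' [generate_poses()]. Decoy poses skip the buried-surface computation
#' (`contact_sasa` = NA); the triage pipeline does not consume it.
#'
#' @param fixture result of [make_toy_complex()].
#' @param n_decoys decoy count (>= 0).
#' @param seed RNG seed for the decoy sampler.
#' @param params from [energy_params()].
#' @return a `pose_set`; the true pose id is also recorded in
#'   `attr(, "true_pose_id")`.
#' @export
make_decoy_set <- function(fixture, n_decoys, seed, params = energy_params()) {
  true_cx <- fixture$complex
  true_score <- binding_energy(true_cx, params)
  if (n_decoys >= 1) {
    ps <- generate_poses(fixture$binder, fixture$antigen, n_decoys, seed,
                         params = params, compute_sasa = FALSE)
  } else {
    cx <- combine_binder_target(fixture$binder, fixture$antigen)
    ps <- structure(list(
      poses = data.frame(pose_id = integer(0), score = numeric(0),
                         contact_sasa = numeric(0), cluster = integer(0),
                         rank = integer(0)),
      transforms = list(), complex = cx,
      binder_chains = binder_chains(cx), target_chains = target_chains(cx)
    ), class = "pose_set")
  }
  poses <- rbind(
    data.frame(pose_id = 0L, score = true_score, contact_sasa = NA_real_,
               cluster = NA_integer_, rank = NA_integer_,
               stringsAsFactors = FALSE),
    ps$poses
  )
  ps$transforms[["0"]] <- rigid_transform()
  ord <- order(poses$score, poses$pose_id)
  poses <- poses[ord, , drop = FALSE]
  poses$rank <- seq_len(nrow(poses))
  rownames(poses) <- NULL
  ps$poses <- poses
  attr(ps, "true_pose_id") <- 0L
  ps
}
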