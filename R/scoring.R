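# Transparent residue-contact stand-in energy and point-mutation modelling.
#
# The energy is a weighted count of classified cross-interface interactions
# plus a steric clash penalty, in arbitrary units (AU) calibrated so that a
# single salt bridge contributes about 2 AU. Stabilising contributions are
# negative. Mutants are modelled deterministically: truncation at C-beta for
# alanine (C-alpha for glycine) and a single pseudo-side-chain centroid with
# residue chemotypes for all other substitutions; there is no rotamer
# repacking or minimisation.

#' Stand-in energy parameters
#'
#' @param weights named favourable interaction weights (AU, all <= 0).
#' @param clash_distance heavy-atom distance (A) below which a pair counts
#'   as a steric clash.
#' @param clash_penalty penalty per clashing pair (AU, >= 0).
#' @param pseudo_sidechain_slack cutoff slack (A) for pseudo-side-chain
#'   centroids of modelled mutants.
#' @export
energy_params <- function(weights = c(salt_bridge = -2.0, hbond = -1.0,
                                      pi_cation = -1.25, pi_pi = -0.75,
                                      hydrophobic = -0.25),
                          clash_distance = 2.4, clash_penalty = 5.0,
                          pseudo_sidechain_slack = 1.0) {
  stopifnot(all(weights <= 0), clash_penalty >= 0, clash_distance > 0)
  list(weights = weights, clash_distance = clash_distance,
       clash_penalty = clash_penalty,
       pseudo_sidechain_slack = pseudo_sidechain_slack)
}

geometry_from_energy <- function(params) {
  geometry_params(pseudo_slack = params$pseudo_sidechain_slack)
}

count_cross_clashes <- function(complex, clash_distance,
                                binder_residue = NULL) {
  ba <- side_atoms(complex, "binder")
  if (!is.null(binder_residue)) {
    ba <- ba[atom_res_key(ba) == binder_residue, , drop = FALSE]
  }
  ta <- side_atoms(complex, "target")
  if (!nrow(ba) || !nrow(ta)) return(0L)
  sum(cross_dist(coords(ba), coords(ta)) < clash_distance)
}

#' Cross-interface binding energy (AU)
#'
#' Sum of interaction weights over [detect_interactions()] plus
#' `clash_penalty` for every cross-interface heavy-atom pair closer than
#' `clash_distance`. Deterministic; more negative is better.
#'
#' @param complex an `ab_complex` with roles assigned.
#' @param params from [energy_params()].
#' @param interactions optional precomputed record table.
#' @export
binding_energy <- function(complex, params = energy_params(),
                           interactions = NULL) {
  recs <- interactions %||% detect_interactions(complex, geometry_from_energy(params))
  e <- if (nrow(recs)) sum(params$weights[recs$kind]) else 0
  e + params$clash_penalty * count_cross_clashes(complex, params$clash_distance)
}

# ---------------------------------------------------------------------------
# Mutations

#' Parse mutation notation
#'
#' Parses the `"H:S28R"` notation (chain, wild-type amino acid, position,
#' substituted amino acid). Positions may carry an insertion code.
#'
#' @param x character vector of mutation strings.
#' @return data.frame with columns `chain`, `wt`, `pos`, `mut`.
#' @export
parse_mutation <- function(x) {
  if (!length(x)) {
    return(data.frame(chain = character(0), wt = character(0),
                      pos = character(0), mut = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- regmatches(x, regexec("^([A-Za-z]):([A-Z])([0-9]+[A-Z]?)([A-Z])$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("cannot parse mutation notation: ", x[bad][1])
  out <- do.call(rbind, lapply(m, function(p) {
    data.frame(chain = p[2], wt = p[3], pos = p[4], mut = p[5],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Format mutations back into `"H:S28R"` notation
#' @param m data.frame from [parse_mutation()] (or with those columns).
#' @export
format_mutation <- function(m) paste0(m$chain, ":", m$wt, m$pos, m$mut)

# mean C-alpha to side-chain-centroid reach (A) per residue type; fixed
# deterministic constants used to place pseudo-side-chain centroids
SIDECHAIN_REACH <- c(
  G = 0.0, A = 1.5, S = 1.9, C = 2.1, P = 1.9, T = 1.9, V = 2.0,
  I = 2.3, L = 2.6, D = 2.5, N = 2.5, M = 2.9, E = 3.1, Q = 3.1,
  K = 3.5, H = 3.2, F = 3.4, R = 4.1, Y = 3.8, W = 3.9
)

# Ideal C-beta from backbone N, CA, C (tetrahedral construction).
construct_cb <- function(n, ca, c) {
  b1 <- unit_vec(n - ca); b2 <- unit_vec(c - ca)
  if (vnorm(b1 + b2) < 1e-8) {
    stop("cannot construct C-beta: backbone N-CA-C is collinear")
  }
  bisector <- -unit_vec(b1 + b2)
  perp <- unit_vec(pracma_cross(b1, b2))
  ca + 1.53 * unit_vec(sqrt(2 / 3) * bisector + sqrt(1 / 3) * perp)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Model a point mutation
#'
#' Mutations to alanine/glycine truncate the side chain at C-beta/C-alpha.
#' All other substitutions replace the side chain with a single
#' pseudo-side-chain centroid placed along the C-alpha to C-beta direction at
#' a residue-specific reach, carrying the residue's chemotypes (cationic,
#' anionic, aromatic, donor/acceptor, apolar). Self-mutations return the
#' structure unchanged.
#'
#' @param complex an `ab_complex`.
#' @param m one-row data.frame from [parse_mutation()], or a mutation string.
#' @return mutated `ab_complex` (input is not modified).
#' @export
apply_mutation <- function(complex, m) {
  if (is.character(m)) m <- parse_mutation(m)
  stopifnot(nrow(m) == 1L)
  i <- resolve_residue(complex, m$chain, m$pos)
  res <- complex$residues[i, ]
  wt1 <- unname(aa_three_to_one[res$aa3])
  if (is.na(wt1) || wt1 != m$wt) {
    stop("wild-type mismatch at ", m$chain, ":", m$pos, " (structure has ",
         res$aa3, ", mutation says ", m$wt, ")")
  }
  if (m$mut == m$wt) return(complex)
  sel <- complex$atoms$chain == res$chain & complex$atoms$resno == res$resno &
    complex$atoms$ins == res$ins
  ra <- complex$atoms[sel, , drop = FALSE]
  keep_names <- c(BACKBONE_ATOMS, "OXT")
  bb <- ra[ra$atom %in% keep_names, , drop = FALSE]
  get_atom <- function(nm) {
    j <- which(ra$atom == nm)
    if (!length(j)) return(NULL)
    as.numeric(ra[j[1], c("x", "y", "z")])
  }
  ca <- get_atom("CA")
  if (is.null(ca)) stop("residue ", m$chain, ":", m$pos, " lacks a CA atom")
  new_atoms <- bb
  if (m$mut != "G") {
    cb <- get_atom("CB")
    if (is.null(cb)) {
      n <- get_atom("N"); c_ <- get_atom("C")
      if (is.null(n) || is.null(c_)) {
        stop("cannot construct C-beta at ", m$chain, ":", m$pos,
             ": backbone incomplete")
      }
      cb <- construct_cb(n, ca, c_)
    }
    cb_row <- bb[1, , drop = FALSE]
    cb_row$atom <- "CB"; cb_row$element <- "C"; cb_row$backbone <- FALSE
    cb_row[, c("x", "y", "z")] <- as.list(cb)
    new_atoms <- rbind(new_atoms, cb_row)
    if (m$mut != "A") {
      reach <- SIDECHAIN_REACH[[m$mut]]
      psc <- ca + reach * unit_vec(cb - ca)
      ps_row <- cb_row
      ps_row$atom <- PSEUDO_ATOM; ps_row$element <- "C"
      ps_row[, c("x", "y", "z")] <- as.list(psc)
      new_atoms <- rbind(new_atoms, ps_row)
    }
  }
  new_aa3 <- aa_one_to_three[[m$mut]]
  new_atoms$aa3 <- new_aa3
  atoms <- complex$atoms
  before <- atoms[seq_len(nrow(atoms)) < which(sel)[1], , drop = FALSE]
  after <- atoms[seq_len(nrow(atoms)) > which(sel)[length(which(sel))], , drop = FALSE]
  out <- complex
  out$atoms <- rbind(before, new_atoms, after)
  rownames(out$atoms) <- NULL
  out$residues$aa3[i] <- new_aa3
  out
}

# ---------------------------------------------------------------------------
# ddE

same_molecule_chains <- function(complex, chain) {
  b <- binder_chains(complex)
  if (chain %in% b) b else {
    t <- target_chains(complex)
    if (chain %in% t) t else chain
  }
}

# Count intramolecular clashes of a residue's side-chain atoms against its
# own molecule, excluding same-residue atoms and backbone atoms of sequence
# neighbours. `ignore_sidechains_of`: residue keys whose side-chain atoms are
# exempt (tolerant accommodation mode).
count_intra_clashes <- function(complex, rkey, clash_distance,
                                ignore_sidechains_of = character(0)) {
  atoms <- complex$atoms[toupper(complex$atoms$element) != "H", , drop = FALSE]
  keys <- atom_res_key(atoms)
  sel <- keys == rkey
  side <- atoms[sel & !atoms$backbone & atoms$atom != "OXT", , drop = FALSE]
  if (!nrow(side)) return(0L)
  chain <- side$chain[1]; resno <- side$resno[1]
  mol <- same_molecule_chains(complex, chain)
  other <- atoms[atoms$chain %in% mol & keys != rkey, , drop = FALSE]
  okeys <- atom_res_key(other)
  adjacent_bb <- other$chain == chain & abs(other$resno - resno) == 1 &
    other$backbone
  other <- other[!adjacent_bb, , drop = FALSE]
  okeys <- okeys[!adjacent_bb]
  if (length(ignore_sidechains_of)) {
    drop <- okeys %in% ignore_sidechains_of & !other$backbone
    other <- other[!drop, , drop = FALSE]
  }
  if (!nrow(other)) return(0L)
  sum(cross_dist(coords(side), coords(other)) < clash_distance)
}

# Residues of the same molecule with any heavy atom within `radius` of any
# heavy atom of residue `rkey` (the tolerant-mode accommodation shell).
neighbour_residues <- function(complex, rkey, radius = 5.0) {
  atoms <- complex$atoms[toupper(complex$atoms$element) != "H", , drop = FALSE]
  keys <- atom_res_key(atoms)
  sel <- keys == rkey
  if (!any(sel)) return(character(0))
  chain <- atoms$chain[sel][1]
  mol <- same_molecule_chains(complex, chain)
  cand <- atoms$chain %in% mol & keys != rkey
  if (!any(cand)) return(character(0))
  d <- cross_dist(coords(atoms[cand, , drop = FALSE]),
                  coords(atoms[sel, , drop = FALSE]))
  unique(keys[cand][apply(d, 1, min) <= radius])
}

local_binding_terms <- function(complex, rkey, params) {
  recs <- detect_interactions(complex, geometry_from_energy(params),
                              binder_residue = rkey)
  e <- if (nrow(recs)) sum(params$weights[recs$kind]) else 0
  e + params$clash_penalty *
    count_cross_clashes(complex, params$clash_distance, binder_residue = rkey)
}

#' Mutation effect on binding and stability (AU)
#'
#' `ddE_binding` is the change in cross-interface energy upon the mutation;
#' `ddE_stability` is the change in intramolecular clash count times the
#' clash penalty (side chain of the mutated residue against its own
#' molecule; same-residue and sequence-adjacent backbone contacts excluded).
#' In `tolerant` mode, new clashes against side chains of residues within
#' `tolerant_radius` of the mutated site are forgiven (backbone clashes
#' always count), emulating local side-chain accommodation.
#'
#' @param complex an `ab_complex` with roles assigned.
#' @param m mutation (string or one-row parse table).
#' @param mode `"rigid"` or `"tolerant"`.
#' @param params from [energy_params()].
#' @param pose_id optional identifier copied into the result.
#' @param tolerant_radius accommodation shell radius (A).
#' @return one-row data.frame: `pose_id`, `mutation`, `mode`, `ddE_binding`,
#'   `ddE_stability`.
#' @export
ddE <- function(complex, m, mode = c("rigid", "tolerant"),
                params = energy_params(), pose_id = NA,
                tolerant_radius = 5.0) {
  mode <- match.arg(mode)
  if (is.character(m)) m <- parse_mutation(m)
  mstr <- format_mutation(m)
  i <- resolve_residue(complex, m$chain, m$pos)
  res <- complex$residues[i, ]
  rkey <- residue_key(res$chain, res$resno, res$ins)
  if (m$mut == m$wt) {
    # self-mutation: structure unchanged by construction
    return(data.frame(pose_id = pose_id, mutation = mstr, mode = mode,
                      ddE_binding = 0, ddE_stability = 0,
                      stringsAsFactors = FALSE))
  }
  mut_cx <- apply_mutation(complex, m)
  on_binder <- res$chain %in% binder_chains(complex)
  if (on_binder) {
    e_wt <- local_binding_terms(complex, rkey, params)
    e_mut <- local_binding_terms(mut_cx, rkey, params)
  } else {
    # target-side mutation: swap role of the restriction by full recompute
    e_wt <- binding_energy(complex, params)
    e_mut <- binding_energy(mut_cx, params)
  }
  ignore <- character(0)
  if (mode == "tolerant") {
    ignore <- neighbour_residues(complex, rkey, tolerant_radius)
  }
  n_wt <- count_intra_clashes(complex, rkey, params$clash_distance)
  n_mut <- count_intra_clashes(mut_cx, rkey, params$clash_distance,
                               ignore_sidechains_of = ignore)
  data.frame(pose_id = pose_id, mutation = mstr, mode = mode,
             ddE_binding = e_mut - e_wt,
             ddE_stability = (n_mut - n_wt) * params$clash_penalty,
             stringsAsFactors = FALSE)
}

scan_position_table <- function(complex, positions) {
  if (is.character(positions)) {
    sp <- strsplit(positions, ":", fixed = TRUE)
    positions <- data.frame(chain = vapply(sp, `[`, "", 1),
                            pos = vapply(sp, `[`, "", 2),
                            stringsAsFactors = FALSE)
  }
  positions$pos <- as.character(positions$pos)
  positions
}

#' Alanine scan over antibody positions
#'
#' One rigid-mode [ddE()] per position; glycine and alanine positions are
#' scanned as no-ops with both energies zero. Results are ordered by chain
#' then position.
#'
#' @param complex an `ab_complex`.
#' @param positions character vector of `"chain:pos"` keys or a data.frame
#'   with `chain` and `pos` columns. Positions must lie on antibody chains.
#' @param params from [energy_params()].
#' @param pose_id optional identifier.
#' @return data.frame with one row per position.
#' @export
alanine_scan <- function(complex, positions, params = energy_params(),
                         pose_id = NA) {
  positions <- scan_position_table(complex, positions)
  b <- binder_chains(complex)
  if (!all(positions$chain %in% b)) {
    stop("alanine scan positions must lie on antibody (heavy/light) chains")
  }
  rows <- lapply(seq_len(nrow(positions)), function(k) {
    ch <- positions$chain[k]; pos <- positions$pos[k]
    i <- resolve_residue(complex, ch, pos)
    wt <- aa_three_to_one[[complex$residues$aa3[i]]]
    m <- data.frame(chain = ch, wt = wt, pos = pos, mut = "A",
                    stringsAsFactors = FALSE)
    if (wt %in% c("A", "G")) {
      data.frame(pose_id = pose_id, mutation = format_mutation(m),
                 mode = "rigid", ddE_binding = 0, ddE_stability = 0,
                 stringsAsFactors = FALSE)
    } else {
      ddE(complex, m, mode = "rigid", params = params, pose_id = pose_id)
    }
  })
  out <- do.call(rbind, rows)
  pm <- parse_mutation(out$mutation)
  ord <- order(pm$chain, suppressWarnings(as.numeric(gsub("[A-Z]", "", pm$pos))),
               pm$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species-switch check: simultaneous antigen substitutions
#'
#' Applies all substitutions to the antigen at once and returns
#' `E(mutant complex) - E(wild-type complex)` in AU. A pose is
#' "specificity-consistent" when the value is at or above `threshold`.
#'
#' @param complex an `ab_complex`.
#' @param substitutions mutation strings or parse table; all must lie on the
#'   antigen chain.
#' @param params from [energy_params()].
#' @param threshold consistency threshold (AU, default 0).
#' @return numeric total ddE_binding with attribute `specificity_consistent`.
#' @export
species_switch <- function(complex, substitutions, params = energy_params(),
                           threshold = 0.0) {
  if (is.character(substitutions)) substitutions <- parse_mutation(substitutions)
  if (!nrow(substitutions)) {
    out <- 0
    attr(out, "specificity_consistent") <- out >= threshold
    return(out)
  }
  tc <- target_chains(complex)
  if (!all(substitutions$chain %in% tc)) {
    bad <- which(!substitutions$chain %in% tc)[1]
    stop("species-switch substitution not on the antigen chain: ",
         format_mutation(substitutions[bad, , drop = FALSE]))
  }
  mut_cx <- complex
  for (k in seq_len(nrow(substitutions))) {
    mut_cx <- apply_mutation(mut_cx, substitutions[k, , drop = FALSE])
  }
  out <- binding_energy(mut_cx, params) - binding_energy(complex, params)
  attr(out, "specificity_consistent") <- out >= threshold
  out
}

#' Saturation mutagenesis over designable positions
#'
#' Mutates every designable position to all 20 genetically encoded amino
#' acids (self-mutations included, both energies zero) in both accommodation
#' modes, giving `|positions| x 20 x 2` rows.
#'
#' @param complex an `ab_complex`.
#' @param designable positions as in [alanine_scan()].
#' @param params from [energy_params()].
#' @param pose_id optional identifier.
#' @return data.frame of [ddE()] rows.
#' @export
saturation_scan <- function(complex, designable, params = energy_params(),
                            pose_id = NA) {
  designable <- scan_position_table(complex, designable)
  if (!nrow(designable)) stop("designable position set is empty")
  aas <- names(aa_one_to_three)
  rows <- list()
  for (k in seq_len(nrow(designable))) {
    ch <- designable$chain[k]; pos <- designable$pos[k]
    i <- resolve_residue(complex, ch, pos)
    wt <- aa_three_to_one[[complex$residues$aa3[i]]]
    for (aa in aas) {
      m <- data.frame(chain = ch, wt = wt, pos = pos, mut = aa,
                      stringsAsFactors = FALSE)
      for (mode in c("rigid", "tolerant")) {
        rows[[length(rows) + 1L]] <-
          ddE(complex, m, mode = mode, params = params, pose_id = pose_id)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
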