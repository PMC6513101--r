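# Rigid-body pose generation with interface constraints, ranking, greedy
# RMSD clustering and receptor-blockade filtering against a surrogate
# receptor-ligand complex.
#
# The sampler draws uniform random orientations and approach directions,
# slides the binder onto the target until first contact and keeps
# constraint-satisfying, clash-free placements. It replaces FFT grid-search
# docking: the triage logic downstream, not docking efficiency, is the point.

#' Pose-generation constraints
#'
#' @param blocked_residues binder residue keys (`"chain:pos"`) that must NOT
#'   be interfacial (at `interfacial_cutoff`) in an accepted pose.
#' @param required_residues binder residue keys that must have an atom
#'   within `required_distance` of the target.
#' @param required_distance distance for required residues (A, default 10).
#' @param touch_distance minimum cross heavy-atom distance at placement
#'   (A, default 4).
#' @param interfacial_cutoff cutoff for the blocked-residue test (A).
#' @export
pose_constraints <- function(blocked_residues = character(0),
                             required_residues = character(0),
                             required_distance = 10.0,
                             touch_distance = 4.0,
                             interfacial_cutoff = 5.0) {
  if (length(intersect(blocked_residues, required_residues))) {
    stop("blocked and required residue sets must be disjoint")
  }
  list(blocked_residues = blocked_residues,
       required_residues = required_residues,
       required_distance = required_distance,
       touch_distance = touch_distance,
       interfacial_cutoff = interfacial_cutoff)
}

combine_binder_target <- function(binder, target) {
  clash <- intersect(names(binder$roles), names(target$roles))
  if (length(clash)) {
    stop("binder and target share chain id(s): ", paste(clash, collapse = ", "))
  }
  atoms <- rbind(binder$atoms, target$atoms)
  cx <- new_complex(atoms)
  cx$roles[names(binder$roles)] <- binder$roles
  cx$roles[names(target$roles)] <- target$roles
  cx$residues <- rbind(binder$residues, target$residues)
  rownames(cx$residues) <- NULL
  cx
}

# Slide the binder (already rotated, centred at origin) along `dir` towards
# the target until the minimum cross distance equals `touch` exactly.
# Binder atom i at offset t sits at bxyz_i + tc + t*dir; each atom pair's
# distance is a quadratic in t, so first contact (approaching from t = +Inf)
# is the largest real root of d_ij(t) = touch over all pairs. Returns the
# binder-centroid offset, or NULL when the approach ray misses the target.
slide_to_touch <- function(bxyz, txyz, dir, touch) {
  tc <- colMeans(txyz)
  bt <- sweep(bxyz, 2, tc, "+")
  w_dot <- outer(as.numeric(bt %*% dir), as.numeric(txyz %*% dir), "-")
  w2 <- cross_dist(bt, txyz)^2
  disc <- w_dot^2 - (w2 - touch^2)
  real <- disc >= 0
  if (!any(real)) return(NULL)
  t_star <- max(-w_dot[real] + sqrt(disc[real]))
  tc + t_star * dir
}

#' Generate rigid-body docked poses
#'
#' Seeded rejection sampler: each trial draws a uniform random rotation of
#' the binder about its centroid and a random approach direction, places the
#' binder in first contact with the target (minimum cross heavy-atom
#' distance = `touch_distance`) and accepts the pose iff it is clash-free,
#' every required residue is within `required_distance` of the target and no
#' blocked residue is interfacial. Accepted poses are scored with
#' [binding_energy()] and returned sorted by score (more negative first,
#' ties by pose id).
#'
#' @param binder,target `ab_complex` objects (disjoint chain ids); binder
#'   chains should carry heavy/light roles, target chains the antigen role.
#' @param n number of accepted poses to return.
#' @param seed integer RNG seed.
#' @param constraints from [pose_constraints()].
#' @param params from [energy_params()].
#' @param max_trials sampling budget (default `50 * n + 200`).
#' @param compute_sasa also record per-pose buried surface (A^2); slower.
#' @param sasa_points quadrature points for the buried-surface calculation.
#' @return object of class `pose_set`: list with `poses` (data.frame
#'   `pose_id`, `score`, `contact_sasa`, `cluster`, `rank`, flag columns),
#'   `transforms` (list of [rigid_transform()] keyed by pose id), `complex`
#'   (the combined unposed complex) and the binder/target chain ids.
#' @export
generate_poses <- function(binder, target, n, seed,
                           constraints = pose_constraints(),
                           params = energy_params(),
                           max_trials = 50 * n + 200,
                           compute_sasa = TRUE, sasa_points = 240) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  cx <- combine_binder_target(binder, target)
  bch <- binder_chains(cx); tch <- target_chains(cx)
  if (!length(bch) || !length(tch)) stop("binder/target roles incomplete")
  heavy <- cx$atoms[toupper(cx$atoms$element) != "H", , drop = FALSE]
  bxyz0 <- coords(heavy[heavy$chain %in% bch, , drop = FALSE])
  txyz <- coords(heavy[heavy$chain %in% tch, , drop = FALSE])
  bc <- colMeans(bxyz0)
  bcent <- sweep(bxyz0, 2, bc)

  accepted <- list()
  trial <- 0L
  while (length(accepted) < n && trial < max_trials) {
    trial <- trial + 1L
    R <- random_rotation()
    dir <- random_unit_vector()
    brot <- bcent %*% t(R)
    pos <- slide_to_touch(brot, txyz, dir, constraints$touch_distance)
    if (is.null(pos)) next
    tf <- rigid_transform(R, pos - as.numeric(R %*% bc))
    posed <- transform_apply(cx, bch, tf)
    pb <- coords(posed$atoms[posed$atoms$chain %in% bch &
                               toupper(posed$atoms$element) != "H", , drop = FALSE])
    if (min_cross_dist(pb, txyz) < params$clash_distance) next
    ok <- TRUE
    if (length(constraints$required_residues)) {
      keys <- atom_res_key(posed$atoms)
      for (rk in constraints$required_residues) {
        sel <- keys == rk & posed$atoms$chain %in% bch
        if (!any(sel)) stop("required residue not found on binder: ", rk)
        dmin <- min_cross_dist(coords(posed$atoms[sel, , drop = FALSE]), txyz)
        if (dmin > constraints$required_distance) { ok <- FALSE; break }
      }
    }
    if (ok && length(constraints$blocked_residues)) {
      ifr <- interfacial_residues(posed, constraints$interfacial_cutoff)
      if (length(intersect(constraints$blocked_residues, ifr$binder))) ok <- FALSE
    }
    if (!ok) next
    score <- binding_energy(posed, params)
    csasa <- if (compute_sasa) {
      buried_surface(posed, n_points = sasa_points)
    } else NA_real_
    accepted[[length(accepted) + 1L]] <- list(tf = tf, score = score,
                                              contact_sasa = csasa)
  }
  if (length(accepted) < n) {
    stop("pose sampling accepted ", length(accepted), "/", n, " poses in ",
         max_trials, " trials; consider loosening the constraints ",
         "(blocked/required residues or distances)")
  }
  poses <- data.frame(
    pose_id = seq_along(accepted),
    score = vapply(accepted, `[[`, 0, "score"),
    contact_sasa = vapply(accepted, `[[`, 0, "contact_sasa"),
    cluster = NA_integer_,
    stringsAsFactors = FALSE
  )
  ord <- order(poses$score, poses$pose_id)
  poses <- poses[ord, , drop = FALSE]
  poses$rank <- seq_len(nrow(poses))
  rownames(poses) <- NULL
  structure(list(
    poses = poses,
    transforms = stats::setNames(lapply(accepted, `[[`, "tf"),
                                 as.character(seq_along(accepted))),
    complex = cx, binder_chains = bch, target_chains = tch
  ), class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat("<pose_set> ", nrow(x$poses), " pose(s); binder chains ",
      paste(x$binder_chains, collapse = ","), " onto ",
      paste(x$target_chains, collapse = ","), "\n", sep = "")
  print(utils::head(x$poses, 10))
  invisible(x)
}

#' Realise one pose as a complex
#'
#' @param pose_set a `pose_set`.
#' @param pose_id pose identifier.
#' @export
pose_complex <- function(pose_set, pose_id) {
  tf <- pose_set$transforms[[as.character(pose_id)]]
  if (is.null(tf)) stop("unknown pose id: ", pose_id)
  transform_apply(pose_set$complex, pose_set$binder_chains, tf)
}

binder_ca_coords <- function(pose_set, pose_id) {
  cx <- pose_set$complex
  sel <- cx$atoms$chain %in% pose_set$binder_chains & cx$atoms$atom == "CA"
  xyz <- coords(cx$atoms[sel, , drop = FALSE])
  apply_transform_xyz(xyz, pose_set$transforms[[as.character(pose_id)]])
}

#' Greedy leader clustering of poses by binder C-alpha RMSD
#'
#' Walks the poses in rank order (they must be sorted by score); a pose
#' joins the first leader within `rmsd_threshold` of it, else founds a new
#' cluster. RMSD is computed in the fixed target frame without
#' re-superposition. Cluster labels are the leaders' ranks.
#'
#' @param pose_set a `pose_set` (poses sorted by score).
#' @param rmsd_threshold join threshold in Angstrom (default 5).
#' @return the `pose_set` with the `cluster` column filled.
#' @export
cluster_poses <- function(pose_set, rmsd_threshold = 5.0) {
  poses <- pose_set$poses
  if (!nrow(poses)) return(pose_set)
  if (is.unsorted(poses$score)) stop("poses must be sorted by score")
  cas <- lapply(poses$pose_id, function(id) binder_ca_coords(pose_set, id))
  leaders <- integer(0)
  labels <- integer(nrow(poses))
  for (i in seq_len(nrow(poses))) {
    assigned <- FALSE
    for (l in leaders) {
      r <- sqrt(mean(rowSums((cas[[i]] - cas[[l]])^2)))
      if (r <= rmsd_threshold) { labels[i] <- l; assigned <- TRUE; break }
    }
    if (!assigned) { leaders <- c(leaders, i); labels[i] <- i }
  }
  pose_set$poses$cluster <- labels
  pose_set
}

#' Receptor-blockade filter against a surrogate complex
#'
#' Superposes each pose's antigen C-alpha trace onto the surrogate ligand
#' via the given residue pairs, carries the antibody along and counts
#' antibody-receptor heavy-atom contacts closer than `overlap_distance`.
#' A pose is flagged `blocking` iff the count reaches
#' `clash_count_threshold`, i.e. the antibody occupies the receptor-bound
#' ligand site.
#'
#' @param pose_set a `pose_set`.
#' @param surrogate `ab_complex` with `receptor` and `surrogate_ligand`
#'   roles.
#' @param antigen_to_ligand_pairs data.frame with columns `antigen_pos` and
#'   `ligand_pos` (>= 3 rows) mapping antigen residues to surrogate-ligand
#'   residues.
#' @param clash_count_threshold minimum overlapping-pair count (default 25).
#' @param overlap_distance contact distance (A, default 2.5).
#' @return the `pose_set` with a logical `blocking` column and an
#'   `overlap_count` column.
#' @export
blockade_filter <- function(pose_set, surrogate, antigen_to_ligand_pairs,
                            clash_count_threshold = 25,
                            overlap_distance = 2.5) {
  pairs <- antigen_to_ligand_pairs
  if (nrow(pairs) < 3) stop("need at least 3 antigen-to-ligand residue pairs")
  rec_ch <- chains_with_role(surrogate, "receptor")
  lig_ch <- chains_with_role(surrogate, "surrogate_ligand")
  if (!length(rec_ch) || !length(lig_ch)) {
    stop("surrogate complex needs receptor and surrogate_ligand roles")
  }
  cx <- pose_set$complex
  ant_ca <- function(pos) {
    sel <- cx$atoms$chain %in% pose_set$target_chains & cx$atoms$atom == "CA" &
      cx$atoms$resno == pos
    if (!any(sel)) stop("antigen residue not found for pair mapping: ", pos)
    coords(cx$atoms[sel, , drop = FALSE])[1, ]
  }
  lig_ca <- function(pos) {
    sel <- surrogate$atoms$chain %in% lig_ch & surrogate$atoms$atom == "CA" &
      surrogate$atoms$resno == pos
    if (!any(sel)) stop("surrogate-ligand residue not found for pair mapping: ", pos)
    coords(surrogate$atoms[sel, , drop = FALSE])[1, ]
  }
  moving <- do.call(rbind, lapply(pairs$antigen_pos, ant_ca))
  fixed <- do.call(rbind, lapply(pairs$ligand_pos, lig_ca))
  sup <- kabsch_superpose(moving, fixed)
  rec_xyz <- coords(surrogate$atoms[surrogate$atoms$chain %in% rec_ch &
                                      toupper(surrogate$atoms$element) != "H", ,
                                    drop = FALSE])
  counts <- vapply(pose_set$poses$pose_id, function(id) {
    ab <- binder_heavy_coords(pose_set, id)
    ab_in_surrogate <- apply_transform_xyz(ab, sup$transform)
    sum(cross_dist(ab_in_surrogate, rec_xyz) < overlap_distance)
  }, 0)
  pose_set$poses$overlap_count <- counts
  pose_set$poses$blocking <- counts >= clash_count_threshold
  pose_set
}

binder_heavy_coords <- function(pose_set, pose_id) {
  cx <- pose_set$complex
  sel <- cx$atoms$chain %in% pose_set$binder_chains &
    toupper(cx$atoms$element) != "H"
  apply_transform_xyz(coords(cx$atoms[sel, , drop = FALSE]),
                      pose_set$transforms[[as.character(pose_id)]])
}
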