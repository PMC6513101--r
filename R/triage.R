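# Experimentally guided pose triage: filter poses by consistency between
# per-pose alanine-scan ddE profiles and experimental mutant phenotypes,
# rank by partial-knockout agreement, score interaction-loss correlation
# and design the validation variant panel.

#' Read an experimental phenotype table
#'
#' Comma-separated `mutation,label` with labels `non_binding`, `reduced` or
#' `retained`.
#'
#' @param path file path.
#' @return named character vector label per mutation string.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mutation", "label") %in% names(p)) || !nrow(p)) {
    stop("phenotype file must have non-empty mutation,label columns: ", path)
  }
  phenotype_table(stats::setNames(p$label, p$mutation))
}

#' Validate a phenotype table
#' @param x named character vector mapping mutation strings to labels.
#' @export
phenotype_table <- function(x) {
  bad <- setdiff(unique(x), c("non_binding", "reduced", "retained"))
  if (length(bad)) stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(x))) stop("duplicate mutation in phenotype table")
  parse_mutation(names(x))  # validates notation
  x
}

#' Triage thresholds
#'
#' @param deleterious_min minimum ddE_binding (AU) a deleterious
#'   (non-binding or reduced) mutation must reach (default 0.00).
#' @param neutral_max maximum ddE_binding (AU) a retained mutation may show
#'   (default 0.50).
#' @export
triage_criteria <- function(deleterious_min = 0.00, neutral_max = 0.50) {
  stopifnot(is.finite(deleterious_min), is.finite(neutral_max))
  list(deleterious_min = deleterious_min, neutral_max = neutral_max)
}

#' Filter poses by consistency with experimental phenotypes
#'
#' A pose passes iff every non-binding and reduced mutation has
#' `ddE >= deleterious_min` AND every retained mutation has
#' `ddE <= neutral_max`. Violations are reported exhaustively.
#'
#' @param ddE_matrix numeric matrix, rows = poses (rownames = pose ids),
#'   columns = mutation strings.
#' @param phenotypes a [phenotype_table()].
#' @param criteria from [triage_criteria()].
#' @return list with `passing` (character pose ids) and `violations` (named
#'   list of data.frames `mutation`, `value`, `rule`).
#' @export
consistency_filter <- function(ddE_matrix, phenotypes,
                               criteria = triage_criteria()) {
  phenotypes <- phenotype_table(phenotypes)
  muts <- names(phenotypes)
  missing <- setdiff(muts, colnames(ddE_matrix))
  if (length(missing)) {
    stop("ddE matrix lacks phenotyped mutation(s): ",
         paste(missing, collapse = ", "))
  }
  deleterious <- muts[phenotypes %in% c("non_binding", "reduced")]
  retained <- muts[phenotypes == "retained"]
  pose_ids <- rownames(ddE_matrix) %||% as.character(seq_len(nrow(ddE_matrix)))
  violations <- vector("list", length(pose_ids))
  names(violations) <- pose_ids
  for (i in seq_along(pose_ids)) {
    v <- ddE_matrix[i, muts]
    if (anyNA(v)) {
      stop("missing ddE value for pose ", pose_ids[i], ", mutation ",
           muts[which(is.na(v))[1]])
    }
    rows <- list()
    for (m in deleterious) {
      if (v[[m]] < criteria$deleterious_min) {
        rows[[length(rows) + 1L]] <- data.frame(
          mutation = m, value = v[[m]],
          rule = sprintf("deleterious ddE %.2f < %.2f", v[[m]],
                         criteria$deleterious_min),
          stringsAsFactors = FALSE)
      }
    }
    for (m in retained) {
      if (v[[m]] > criteria$neutral_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          mutation = m, value = v[[m]],
          rule = sprintf("retained ddE %.2f > %.2f", v[[m]],
                         criteria$neutral_max),
          stringsAsFactors = FALSE)
      }
    }
    violations[[i]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(mutation = character(0), value = numeric(0),
                 rule = character(0), stringsAsFactors = FALSE)
  }
  n_viol <- vapply(violations, nrow, 0L)
  list(passing = pose_ids[n_viol == 0L], violations = violations)
}

#' Rank passing poses by partial-knockout agreement
#'
#' A reduced-binding (partial-knockout) mutation should perturb binding less
#' than the full-knockout mutations. Poses are ordered by
#' `margin = mean over reduced of (ddE(reduced) - min over full-knockout ddE)`
#' ascending; poses in which every reduced ddE is strictly below every
#' full-knockout ddE rank before all others. Ties break by pose id.
#'
#' @param passing character pose ids (non-empty).
#' @param ddE_matrix as in [consistency_filter()].
#' @param reduced_mutations,deleterious_mutations mutation strings; the
#'   deleterious set is the full-knockout (non-binding) set.
#' @return ordered character pose ids, with the margins in attribute
#'   `margin`.
#' @export
rank_partial_knockout <- function(passing, ddE_matrix, reduced_mutations,
                                  deleterious_mutations) {
  if (!length(passing)) stop("no passing poses to rank")
  if (!length(reduced_mutations)) {
    attr(passing, "margin") <- rep(NA_real_, length(passing))
    return(passing)
  }
  need <- c(reduced_mutations, deleterious_mutations)
  missing <- setdiff(need, colnames(ddE_matrix))
  if (length(missing)) stop("ddE matrix lacks mutation(s): ",
                            paste(missing, collapse = ", "))
  sub <- ddE_matrix[passing, , drop = FALSE]
  margin <- vapply(seq_along(passing), function(i) {
    mean(sub[i, reduced_mutations] - min(sub[i, deleterious_mutations]))
  }, 0)
  strict <- vapply(seq_along(passing), function(i) {
    max(sub[i, reduced_mutations]) < min(sub[i, deleterious_mutations])
  }, TRUE)
  ord <- order(!strict, margin, suppressWarnings(as.numeric(passing)), passing)
  out <- passing[ord]
  attr(out, "margin") <- margin[ord]
  attr(out, "strict_partial") <- strict[ord]
  out
}

#' Interaction-loss agreement of a pose with deleterious positions
#'
#' Counts, over the given deleterious antibody positions, how many
#' cross-interface interactions involving each position disappear under
#' rigid alanine truncation.
#'
#' @param complex a posed `ab_complex`.
#' @param deleterious_positions `"chain:pos"` keys on the antibody.
#' @param params from [energy_params()].
#' @return list with `explained` (lost-interaction count) and `total`
#'   (wild-type interaction count at those positions).
#' @export
interaction_loss_score <- function(complex, deleterious_positions,
                                   params = energy_params()) {
  gp <- geometry_from_energy(params)
  positions <- scan_position_table(complex, deleterious_positions)
  explained <- 0L; total <- 0L
  for (k in seq_len(nrow(positions))) {
    ch <- positions$chain[k]; pos <- positions$pos[k]
    i <- resolve_residue(complex, ch, pos)
    res <- complex$residues[i, ]
    rkey <- residue_key(res$chain, res$resno, res$ins)
    wt_recs <- detect_interactions(complex, gp, binder_residue = rkey)
    total <- total + nrow(wt_recs)
    wt1 <- unname(aa_three_to_one[res$aa3])
    if (wt1 %in% c("A", "G")) next
    m <- data.frame(chain = ch, wt = wt1, pos = pos, mut = "A",
                    stringsAsFactors = FALSE)
    mut_recs <- detect_interactions(apply_mutation(complex, m), gp,
                                    binder_residue = rkey)
    explained <- explained + (nrow(wt_recs) - nrow(mut_recs))
  }
  list(explained = explained, total = total)
}

#' Alanine-scan ddE matrix across a pose set
#'
#' @param pose_set a `pose_set`.
#' @param positions scan positions as in [alanine_scan()].
#' @param params from [energy_params()].
#' @return numeric matrix poses x mutations (rownames = pose ids).
#' @export
scan_pose_matrix <- function(pose_set, positions, params = energy_params()) {
  ids <- pose_set$poses$pose_id
  rows <- lapply(ids, function(id) {
    alanine_scan(pose_complex(pose_set, id), positions, params = params,
                 pose_id = id)
  })
  muts <- rows[[1]]$mutation
  m <- do.call(rbind, lapply(rows, function(r) r$ddE_binding[match(muts, r$mutation)]))
  dimnames(m) <- list(as.character(ids), muts)
  m
}

#' Design the experimental validation panel
#'
#' Implements the three selection criteria for validation variants plus
#' negative controls:
#' * `unique`: CDR/Vernier positions whose interaction (any kind) appears in
#'   exactly one pose's interface profile;
#' * `single`: CDR/Vernier positions where some pose's alanine ddE differs
#'   by at least `discrimination_delta` from at least `min_discordant_poses`
#'   other poses (positions already emitted as `unique` are not repeated);
#' * `triple`: `n_triples` greedy combinations of three singles maximising
#'   the minimum pairwise separation of the summed per-pose ddE values;
#' * `control`: one position per antibody chain with `|ddE| <= control
#'   epsilon` in every pose.
#'
#' @param scan_matrix numeric matrix poses x positions of alanine ddE values
#'   (colnames `"chain:pos"`, rownames pose ids).
#' @param profiles list of `interface_profile` objects, one per pose (same
#'   order as the matrix rows).
#' @param complex a wild-type `ab_complex` carrying IMGT/CDR annotations
#'   (see [annotate_complex()]); used for eligibility and wild-type lookup.
#' @param discrimination_delta AU difference defining "significant" (0.5).
#' @param min_discordant_poses minimum number of discordant poses (2).
#' @param control_epsilon max |ddE| for a control (0.05 AU).
#' @param n_triples number of triple combinations (5).
#' @return object of class `variant_panel`: data.frame `category`,
#'   `mutations` (comma-joined for triples), `positions`.
#' @export
design_validation_panel <- function(scan_matrix, profiles, complex,
                                    discrimination_delta = 0.5,
                                    min_discordant_poses = 2,
                                    control_epsilon = 0.05, n_triples = 5) {
  if (nrow(scan_matrix) < 2) stop("panel design needs at least 2 poses")
  res <- complex$residues
  keys <- residue_key(res$chain, res$resno, res$ins)
  elig <- keys[!is.na(res$annotation) &
                 grepl("^(CDR[HL][123]|Vernier)$", res$annotation)]
  cols <- intersect(colnames(scan_matrix), elig)
  ala_mut <- function(key) {
    i <- resolve_residue(complex, sub(":.*", "", key), sub(".*:", "", key))
    wt <- unname(aa_three_to_one[res$aa3[i]])
    paste0(res$chain[i], ":", wt, sub(".*:", "", key), "A")
  }

  # criterion 2: unique explicit interaction
  n_poses_with <- vapply(cols, function(key) {
    sum(vapply(profiles, function(p) key %in% p$counts$residue, TRUE))
  }, 0L)
  unique_pos <- cols[n_poses_with == 1L]

  # criterion 3: discriminating alanine ddE
  is_single <- vapply(cols, function(key) {
    v <- scan_matrix[, key]
    any(vapply(seq_along(v), function(i) {
      sum(abs(v[i] - v[-i]) >= discrimination_delta) >= min_discordant_poses
    }, TRUE))
  }, TRUE)
  single_pos <- setdiff(cols[is_single], unique_pos)

  # triples: maximise the worst pairwise pose discrimination of summed ddE
  triples <- list()
  if (length(single_pos) >= 3 && n_triples > 0) {
    combos <- utils::combn(sort(single_pos), 3, simplify = FALSE)
    score <- vapply(combos, function(trip) {
      s <- rowSums(scan_matrix[, trip, drop = FALSE])
      min(stats::dist(s))
    }, 0)
    ord <- order(-score, vapply(combos, paste, "", collapse = ","))
    triples <- combos[ord[seq_len(min(n_triples, length(combos)))]]
  }

  # controls: flat ddE in every pose, one per antibody chain
  ctrl_ok <- cols[apply(abs(scan_matrix[, cols, drop = FALSE]), 2, max) <=
                    control_epsilon]
  ctrl_ok <- setdiff(ctrl_ok, c(unique_pos, single_pos))
  controls <- character(0)
  for (ch in sort(unique(sub(":.*", "", cols)))) {
    cand <- ctrl_ok[startsWith(ctrl_ok, paste0(ch, ":"))]
    if (length(cand)) {
      controls <- c(controls, sort(cand)[1])
    } else {
      warning("no qualifying control position on chain ", ch)
    }
  }

  rows <- list()
  add <- function(category, positions) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category,
      mutations = paste(vapply(positions, ala_mut, ""), collapse = ","),
      positions = paste(positions, collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (p in sort(unique_pos)) add("unique", p)
  for (trip in triples) add("triple", trip)
  for (p in sort(single_pos)) add("single", p)
  for (p in controls) add("control", p)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(0), mutations = character(0),
               positions = character(0), stringsAsFactors = FALSE)
  class(out) <- c("variant_panel", class(out))
  out
}
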