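# Affinity-maturation candidate handling: threshold filtering, dual
# accommodation-mode consensus, multi-method pooling with deduplication and
# diversity-constrained panel selection.

#' Build a candidate table
#'
#' @param mutation mutation strings (`"H:S28R"` notation).
#' @param method_tag method identifier per row.
#' @param mode accommodation mode per row (`rigid`/`tolerant`).
#' @param ddE_binding,ddE_stability AU values per row.
#' @return data.frame of class `candidate_table`; `(mutation, method_tag,
#'   mode)` must be unique.
#' @export
candidate_table <- function(mutation, method_tag, mode, ddE_binding,
                            ddE_stability) {
  out <- data.frame(mutation = mutation, method_tag = method_tag, mode = mode,
                    ddE_binding = ddE_binding, ddE_stability = ddE_stability,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("mutation", "method_tag", "mode")])) {
    stop("duplicate (mutation, method_tag, mode) rows in candidate table")
  }
  parse_mutation(out$mutation)
  class(out) <- c("candidate_table", class(out))
  out
}

#' Filter candidates on binding and stability thresholds
#'
#' Keeps rows with `ddE_binding <= binding_max` and
#' `ddE_stability <= stability_max`. The default `binding_max = -1` requires
#' at least 1 AU of predicted stabilisation (stabilising values are
#' negative), while `stability_max = +0.5` discards destabilising mutants.
#'
#' @param table a [candidate_table()] (or compatible data.frame).
#' @param binding_max,stability_max AU thresholds.
#' @export
filter_candidates <- function(table, binding_max = -1.0, stability_max = 0.5) {
  stopifnot(is.finite(binding_max), is.finite(stability_max))
  keep <- table$ddE_binding <= binding_max & table$ddE_stability <= stability_max
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

mutation_site_key <- function(mutation) {
  p <- parse_mutation(mutation)
  paste(p$chain, p$pos, p$mut, sep = ":")
}

#' Consensus of the two accommodation modes
#'
#' Exact set intersection keyed by (chain, position, substituted amino
#' acid).
#'
#' @param rigid_accepted,tolerant_accepted mutation-string vectors.
#' @return mutation strings present in both (rigid spelling, sorted).
#' @export
dual_mode_consensus <- function(rigid_accepted, tolerant_accepted) {
  if (!length(rigid_accepted) || !length(tolerant_accepted)) return(character(0))
  rk <- mutation_site_key(rigid_accepted)
  tk <- mutation_site_key(tolerant_accepted)
  sort(unique(rigid_accepted[rk %in% tk]))
}

#' Pool method candidate sets and count duplicates
#'
#' @param method_sets named list of mutation-string vectors, one per method.
#' @return list with `pooled_count` (sum of set sizes), `duplicate_count`
#'   (extra occurrences beyond the union) and `unique` (data.frame
#'   `mutation`, `methods` with comma-joined provenance).
#' @export
pool_dedupe <- function(method_sets) {
  if (!length(method_sets)) stop("need at least one method set")
  if (is.null(names(method_sets)) || any(!nzchar(names(method_sets)))) {
    names(method_sets) <- paste0("method", seq_along(method_sets))
  }
  method_sets <- lapply(method_sets, unique)
  pooled <- sum(lengths(method_sets))
  all_m <- unlist(method_sets, use.names = FALSE)
  tags <- rep(names(method_sets), lengths(method_sets))
  uniq <- sort(unique(all_m))
  provenance <- vapply(uniq, function(m) {
    paste(tags[all_m == m], collapse = ",")
  }, "")
  list(
    pooled_count = pooled,
    duplicate_count = pooled - length(uniq),
    unique = data.frame(mutation = uniq, methods = unname(provenance),
                        stringsAsFactors = FALSE)
  )
}

#' Select a diversity-constrained mutation panel
#'
#' Greedy selection in ascending `ddE_binding` order (most stabilising
#' first), subject to a per-position cap and, optionally, round-robin
#' spreading across method tags. Optionally appends one neutral control
#' mutation whose |ddE_binding| is within `control_epsilon` under every
#' method.
#'
#' @param candidates a [candidate_table()] of filtered candidates.
#' @param n panel size including the control (default 20).
#' @param max_per_position max substitutions kept at one (chain, position)
#'   (default 2).
#' @param include_control append a neutral control (default TRUE).
#' @param spread_methods round-robin across method tags (default TRUE).
#' @param control_pool optional candidate-table rows searched for the
#'   control (defaults to `candidates`); the control must appear under every
#'   method tag of the pool with `|ddE_binding| <= control_epsilon`.
#' @param control_epsilon AU tolerance for the control (default 0.05).
#' @return `variant_panel` data.frame with categories `design` and
#'   `control`, plus the provenance columns of the winning rows.
#' @export
select_panel <- function(candidates, n = 20, max_per_position = 2,
                         include_control = TRUE, spread_methods = TRUE,
                         control_pool = NULL, control_epsilon = 0.05) {
  n_design <- n - as.integer(include_control)
  p <- parse_mutation(candidates$mutation)
  pos_key <- paste(p$chain, p$pos, sep = ":")
  ord <- order(candidates$ddE_binding, candidates$mutation)
  cand <- candidates[ord, , drop = FALSE]
  pos_key <- pos_key[ord]

  chosen <- integer(0)
  pos_count <- integer(0)
  take <- function(i) {
    pk <- pos_key[i]
    cnt <- pos_count[pk]
    if (is.na(cnt)) cnt <- 0L
    if (cnt >= max_per_position) return(FALSE)
    if (cand$mutation[i] %in% cand$mutation[chosen]) return(FALSE)
    chosen <<- c(chosen, i)
    pos_count[pk] <<- cnt + 1L
    TRUE
  }
  if (spread_methods) {
    tags <- sort(unique(cand$method_tag))
    queues <- lapply(tags, function(tg) which(cand$method_tag == tg))
    heads <- rep(1L, length(queues))
    repeat {
      progressed <- FALSE
      for (qi in seq_along(queues)) {
        if (length(chosen) >= n_design) break
        while (heads[qi] <= length(queues[[qi]])) {
          i <- queues[[qi]][heads[qi]]
          heads[qi] <- heads[qi] + 1L
          if (take(i)) { progressed <- TRUE; break }
        }
      }
      if (length(chosen) >= n_design || !progressed) break
    }
  } else {
    for (i in seq_len(nrow(cand))) {
      if (length(chosen) >= n_design) break
      take(i)
    }
  }
  if (length(chosen) < n_design && n_design > nrow(cand)) {
    stop("infeasible panel: requested ", n_design, " design mutations but ",
         "only ", nrow(cand), " candidates are available under the ",
         "max_per_position = ", max_per_position, " constraint")
  }
  sel <- cand[sort(chosen), , drop = FALSE]
  sel <- sel[order(sel$ddE_binding, sel$mutation), , drop = FALSE]
  sel$category <- "design"

  if (include_control) {
    pool <- control_pool %||% candidates
    tags <- unique(pool$method_tag)
    by_mut <- split(pool, pool$mutation)
    ok <- vapply(by_mut, function(rows) {
      all(tags %in% rows$method_tag) &&
        all(abs(rows$ddE_binding) <= control_epsilon)
    }, TRUE)
    if (!any(ok)) {
      warning("no qualifying neutral control mutation; panel has none")
    } else {
      mut <- sort(names(by_mut)[ok])[1]
      ctrl <- by_mut[[mut]][1, , drop = FALSE]
      ctrl$category <- "control"
      sel <- rbind(sel, ctrl)
    }
  }
  rownames(sel) <- NULL
  class(sel) <- c("variant_panel", setdiff(class(sel), "variant_panel"))
  sel
}
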