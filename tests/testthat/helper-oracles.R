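# Independent brute-force oracles used across the test files. These
# deliberately re-derive results with the most naive formulation available
# so they share no code path with the package implementations.

# all heavy-atom coordinates of a complex as a matrix
heavy_xyz <- function(complex, chains = NULL) {
  a <- complex$atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  a <- a[toupper(a$element) != "H", , drop = FALSE]
  cbind(a$x, a$y, a$z)
}

# naive minimum distance between two point sets (double loop via dist())
oracle_min_cross_dist <- function(a, b) {
  full <- as.matrix(stats::dist(rbind(a, b)))
  min(full[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b))])
}

oracle_count_within <- function(a, b, cutoff) {
  full <- as.matrix(stats::dist(rbind(a, b)))
  sum(full[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b)), drop = FALSE] < cutoff)
}

# exhaustive consistency-filter enumeration (rule-by-rule double loop)
oracle_consistency <- function(m, labels, del_min = 0, neu_max = 0.5) {
  deleterious <- names(labels)[labels %in% c("non_binding", "reduced")]
  retained <- names(labels)[labels == "retained"]
  passing <- character(0)
  violations <- list()
  for (pid in rownames(m)) {
    v <- character(0)
    for (mu in deleterious) if (m[pid, mu] < del_min) v <- c(v, mu)
    for (mu in retained) if (m[pid, mu] > neu_max) v <- c(v, mu)
    violations[[pid]] <- sort(v)
    if (!length(v)) passing <- c(passing, pid)
  }
  list(passing = passing, violations = violations)
}

# reference greedy leader clustering over a list of coordinate matrices,
# written as the textbook double loop
oracle_leader_cluster <- function(coord_list, threshold) {
  labels <- integer(length(coord_list))
  leaders <- integer(0)
  for (i in seq_along(coord_list)) {
    labels[i] <- 0L
    for (l in leaders) {
      rmsd <- sqrt(mean(rowSums((coord_list[[i]] - coord_list[[l]])^2)))
      if (rmsd <= threshold) { labels[i] <- l; break }
    }
    if (labels[i] == 0L) { leaders <- c(leaders, i); labels[i] <- i }
  }
  labels
}

# analytic SASA of two intersecting spheres (radii already probe-expanded):
# each sphere loses the spherical cap cut off by the radical plane
oracle_two_sphere_sasa <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  cap <- function(ra, rb) {
    x <- (d^2 + ra^2 - rb^2) / (2 * d)
    2 * pi * ra * (ra - x)
  }
  4 * pi * r1^2 - cap(r1, r2) + 4 * pi * r2^2 - cap(r2, r1)
}

# minimal two-atom complex for SASA tests
two_atom_complex <- function(el1, el2, d) {
  atoms <- data.frame(
    chain = c("H", "H"), resno = c(1L, 2L), ins = "", aa3 = "ALA",
    atom = c("CA", "CA"), element = c(el1, el2),
    x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE)
  new_complex(atoms, roles = c(H = "heavy"))
}

# shared default fixture (built once per test file)
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_complex()
    cache
  }
})

# naive full-recompute ddE oracle: energy difference of complete complexes
oracle_ddE_binding <- function(complex, mutation_str, params = energy_params()) {
  mut <- parse_mutation(mutation_str)
  binding_energy(apply_mutation(complex, mut), params) -
    binding_energy(complex, params)
}

# independent Rodrigues rotation (test-side reimplementation)
rotation_about_axis_test <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * ux + (1 - cos(theta)) * (ux %*% ux)
}

apply_transform_xyz_test <- function(m, tf) {
  t(tf$rotation %*% t(m) + tf$translation)
}

expect_identical_files <- function(a, b) {
  expect_identical(readLines(a), readLines(b))
}
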