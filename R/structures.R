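# Structure data model: a Complex is a flat heavy-atom table plus a residue
# table and per-chain role assignments. Bio3d-style list-of-data.frames, kept
# deliberately small: only what interface geometry and mutation modelling need.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")
CHAIN_ROLES <- c("heavy", "light", "antigen", "receptor", "surrogate_ligand")

#' Construct a complex from atom records
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer author
#'   position), `ins` (insertion code, "" when absent), `aa3` (3-letter
#'   residue code), `atom` (atom name), `element`, `x`, `y`, `z`.
#' @param roles named character vector mapping chain id to one of
#'   `r paste(CHAIN_ROLES, collapse = ", ")`. May be `NA` for chains whose
#'   role is assigned later with [set_roles()].
#' @return An object of class `ab_complex`: list with elements `atoms`,
#'   `residues` (one row per residue, with optional `imgt` and `annotation`
#'   columns filled by [annotate_complex()]) and `roles`.
#' @export
new_complex <- function(atoms, roles = NULL) {
  required <- c("chain", "resno", "ins", "aa3", "atom", "element", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms$chain <- as.character(atoms$chain)
  atoms$ins <- as.character(atoms$ins)
  atoms$backbone <- atoms$atom %in% BACKBONE_ATOMS
  if (any(!nzchar(atoms$element))) stop("atoms with empty element symbol")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atomic coordinates")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
  first <- !duplicated(key)
  residues <- data.frame(
    chain = atoms$chain[first], resno = atoms$resno[first],
    ins = atoms$ins[first], aa3 = atoms$aa3[first],
    imgt = NA_character_, annotation = NA_character_,
    stringsAsFactors = FALSE
  )
  chains <- unique(atoms$chain)
  r <- stats::setNames(rep(NA_character_, length(chains)), chains)
  if (!is.null(roles)) {
    bad <- setdiff(stats::na.omit(unname(roles)), CHAIN_ROLES)
    if (length(bad)) stop("unknown chain role(s): ", paste(bad, collapse = ", "))
    r[names(roles)] <- roles
  }
  structure(list(atoms = atoms, residues = residues, roles = r),
            class = "ab_complex")
}

#' @export
print.ab_complex <- function(x, ...) {
  cat("<ab_complex> ", nrow(x$residues), " residues / ", nrow(x$atoms),
      " atoms in ", length(x$roles), " chain(s)\n", sep = "")
  for (ch in names(x$roles)) {
    n <- sum(x$residues$chain == ch)
    cat("  chain ", ch, ": ", n, " residues (",
        ifelse(is.na(x$roles[[ch]]), "role unset", x$roles[[ch]]), ")\n", sep = "")
  }
  invisible(x)
}

#' Assign chain roles
#'
#' @param complex an `ab_complex`.
#' @param ... named arguments `chain = "role"`, e.g. `H = "heavy"`.
#' @export
set_roles <- function(complex, ...) {
  r <- c(...)
  bad <- setdiff(unname(r), CHAIN_ROLES)
  if (length(bad)) stop("unknown chain role(s): ", paste(bad, collapse = ", "))
  unknown <- setdiff(names(r), names(complex$roles))
  if (length(unknown)) stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
  complex$roles[names(r)] <- r
  complex
}

chains_with_role <- function(complex, roles) {
  names(complex$roles)[complex$roles %in% roles & !is.na(complex$roles)]
}

binder_chains <- function(complex) chains_with_role(complex, c("heavy", "light"))
target_chains <- function(complex) chains_with_role(complex, "antigen")

coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])

residue_key <- function(chain, resno, ins = "") {
  paste0(chain, ":", resno, ifelse(nzchar(ins), ins, ""))
}

atom_res_key <- function(atoms) residue_key(atoms$chain, atoms$resno, atoms$ins)

subset_chains <- function(complex, chains) {
  keep <- complex$atoms$chain %in% chains
  cx <- new_complex(complex$atoms[keep, , drop = FALSE])
  cx$roles[] <- complex$roles[names(cx$roles)]
  res_keep <- complex$residues$chain %in% chains
  cx$residues <- complex$residues[res_keep, , drop = FALSE]
  rownames(cx$residues) <- NULL
  cx
}

# ---------------------------------------------------------------------------
# PDB I/O: fixed-column ATOM/TER/END subset. Hydrogens dropped by default
# (all downstream geometry is heavy-atom only); for duplicated alternate
# locations the first-listed record wins.

#' Parse a PDB-format string into a complex
#'
#' Reads the fixed-column `ATOM` record subset (plus `TER`/`END`). HETATM and
#' all other records are ignored.
#'
#' @param text a single PDB-format string, or a character vector of lines.
#' @param roles optional named chain-role vector, see [new_complex()].
#' @param drop_hydrogens drop hydrogen atoms (default `TRUE`).
#' @return an `ab_complex`.
#' @export
load_pdb <- function(text, roles = NULL, drop_hydrogens = TRUE) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (!length(text) || !any(startsWith(text, "ATOM"))) {
    stop("PDB input contains no ATOM records")
  }
  idx <- which(startsWith(text, "ATOM"))
  lines <- text[idx]
  num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & nzchar(trimws(s))
    bad <- bad | !nzchar(trimws(s))
    if (any(bad)) {
      stop("malformed ATOM record (bad ", what, ") at line ",
           lineno[which(bad)[1]])
    }
    v
  }
  name <- trimws(substr(lines, 13, 16))
  alt <- trimws(substr(lines, 17, 17))
  aa3 <- trimws(substr(lines, 18, 20))
  chain <- trimws(substr(lines, 22, 22))
  resno <- num(substr(lines, 23, 26), "residue number", idx)
  ins <- trimws(substr(lines, 27, 27))
  x <- num(substr(lines, 31, 38), "x coordinate", idx)
  y <- num(substr(lines, 39, 46), "y coordinate", idx)
  z <- num(substr(lines, 47, 54), "z coordinate", idx)
  element <- trimws(substr(lines, 77, 78))
  guess <- toupper(substr(gsub("[0-9]", "", name), 1, 1))
  element <- ifelse(nzchar(element), element, guess)
  if (any(!nzchar(chain))) {
    stop("malformed ATOM record (missing chain id) at line ",
         idx[which(!nzchar(chain))[1]])
  }
  atoms <- data.frame(
    chain = chain, resno = as.integer(resno), ins = ins, aa3 = aa3,
    atom = name, element = element, x = x, y = y, z = z,
    stringsAsFactors = FALSE
  )
  if (drop_hydrogens) atoms <- atoms[toupper(atoms$element) != "H", , drop = FALSE]
  # altloc rule: keep the first-listed location of each atom
  dup <- duplicated(paste(atoms$chain, atoms$resno, atoms$ins, atoms$atom, sep = "|"))
  atoms <- atoms[!dup, , drop = FALSE]
  rownames(atoms) <- NULL
  new_complex(atoms, roles = roles)
}

#' Read a PDB file
#' @inheritParams load_pdb
#' @param path file path.
#' @export
read_pdb_file <- function(path, roles = NULL, drop_hydrogens = TRUE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  load_pdb(readLines(path, warn = FALSE), roles = roles,
           drop_hydrogens = drop_hydrogens)
}

#' Serialise a complex to a PDB-format string
#'
#' Writes fixed-column ATOM records (coordinates to 3 decimals), a TER line
#' after each chain and a terminal END.
#'
#' @param complex an `ab_complex`.
#' @return a single string.
#' @export
save_pdb <- function(complex) {
  atoms <- complex$atoms
  if (!nrow(atoms)) stop("cannot write an empty complex")
  if (any(nchar(atoms$chain) != 1L)) {
    stop("PDB chain ids must be a single character")
  }
  out <- character(0)
  serial <- 0L
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$atom[i]
      nm4 <- if (nchar(nm) < 4L) formatC(paste0(" ", nm), width = -4) else substr(nm, 1, 4)
      out <- c(out, sprintf(
        "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm4, a$aa3[i], ch, a$resno[i],
        ifelse(nzchar(a$ins[i]), a$ins[i], " "),
        a$x[i], a$y[i], a$z[i], 1, 0, toupper(a$element[i])
      ))
    }
    serial <- serial + 1L
    last <- a[nrow(a), ]
    out <- c(out, sprintf("TER   %5d      %-3s %1s%4d", serial, last$aa3,
                          ch, last$resno))
  }
  paste0(paste(c(out, "END"), collapse = "\n"), "\n")
}

#' Write a complex to a PDB file
#' @inheritParams save_pdb
#' @param path output path.
#' @export
write_pdb_file <- function(complex, path) {
  writeLines(sub("\n$", "", save_pdb(complex)), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Rigid transforms

#' Create a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation 3-vector (Angstrom).
#' @return object of class `rigid_transform`; maps `x` to `R x + t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation matrix is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-8) stop("rotation determinant must be +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Compose two rigid transforms
#'
#' `compose_transform(t2, t1)` is the transform equivalent to applying `t1`
#' first and `t2` second.
#' @param t2,t1 `rigid_transform` objects.
#' @export
compose_transform <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

apply_transform_xyz <- function(m, tf) {
  sweep(m %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Apply a rigid transform to selected chains
#'
#' @param complex an `ab_complex`.
#' @param chains chain ids to move.
#' @param tf a `rigid_transform`.
#' @return a new complex; the input is not modified.
#' @export
transform_apply <- function(complex, chains, tf) {
  unknown <- setdiff(chains, names(complex$roles))
  if (length(unknown)) stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
  sel <- complex$atoms$chain %in% chains
  xyz <- apply_transform_xyz(coords(complex$atoms[sel, , drop = FALSE]), tf)
  complex$atoms$x[sel] <- xyz[, 1]
  complex$atoms$y[sel] <- xyz[, 2]
  complex$atoms$z[sel] <- xyz[, 3]
  complex
}

#' Least-squares superposition (Kabsch)
#'
#' Finds the rigid transform minimising the RMSD of `moving` onto `fixed`.
#'
#' @param moving,fixed n x 3 coordinate matrices, n >= 3, matched row-wise.
#' @return list with `transform` (a [rigid_transform()]) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("point sets differ in length")
  if (nrow(moving) < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  if (svd(P)$d[2] < 1e-8 * max(1, svd(P)$d[1])) {
    stop("degenerate input: points are collinear")
  }
  s <- svd(crossprod(P, Q))            # H = P^T Q ; R = V diag(1,1,d) U^T
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tf <- rigid_transform(R, cf - as.numeric(R %*% cm))
  moved <- apply_transform_xyz(moving, tf)
  list(transform = tf, rmsd = sqrt(mean(rowSums((moved - fixed)^2))))
}

# ---------------------------------------------------------------------------
# Antibody numbering map

#' Read an antibody numbering map
#'
#' Tab-separated columns `chain_id`, `author_pos`, `imgt_label`, `annotation`
#' with annotations in CDRH1..CDRL3, Vernier or FR.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_numbering_map <- function(path) {
  if (!file.exists(path)) stop("numbering map not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chain_id", "author_pos", "imgt_label", "annotation")
  missing <- setdiff(required, names(m))
  if (length(missing)) stop("numbering map lacks columns: ", paste(missing, collapse = ", "))
  ok <- grepl("^(CDR[HL][123]|Vernier|FR)$", m$annotation)
  if (any(!ok)) stop("unknown annotation(s): ", paste(unique(m$annotation[!ok]), collapse = ", "))
  m
}

#' Attach IMGT labels and CDR/Vernier annotations to a complex
#'
#' @param complex an `ab_complex`.
#' @param map data.frame from [read_numbering_map()].
#' @export
annotate_complex <- function(complex, map) {
  key <- paste(map$chain_id, map$author_pos)
  if (anyDuplicated(paste(map$chain_id, map$imgt_label))) {
    stop("IMGT labels must be unique within a chain")
  }
  rkey <- paste(complex$residues$chain, complex$residues$resno)
  hit <- match(rkey, key)
  # labels may be written either bare ("55") or chain-qualified ("H:55")
  imgt <- sub("^[A-Za-z]:", "", as.character(map$imgt_label))
  complex$residues$imgt <- ifelse(is.na(hit), NA_character_, imgt[hit])
  complex$residues$annotation <- ifelse(is.na(hit), NA_character_, map$annotation[hit])
  complex
}

# Resolve a residue position label (author number, or IMGT label when
# annotated) to a row of the residue table. Returns the row index.
resolve_residue <- function(complex, chain, pos) {
  res <- complex$residues
  pos <- as.character(pos)
  i <- which(res$chain == chain & !is.na(res$imgt) & res$imgt == pos)
  if (!length(i)) {
    i <- which(res$chain == chain &
                 paste0(res$resno, ifelse(nzchar(res$ins), res$ins, "")) == pos)
  }
  if (!length(i)) stop("no residue at position ", chain, ":", pos)
  i[1]
}
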