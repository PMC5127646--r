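#' Construct a structure ensemble
#'
#' Ordered models sharing one atom inventory: an atom table (chain, residue
#' number, atom name) plus one coordinate matrix per model.
#'
#' @param atoms `data.frame` with columns `chain`, `resno`, `atom`.
#' @param xyz list of numeric n x 3 matrices (Angstrom), one per model.
#' @return Object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "atom") %in% names(atoms)))
  if (!is.list(xyz)) xyz <- list(xyz)
  for (m in xyz)
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != nrow(atoms))
      stop("each model must be an n x 3 matrix matching the atom table",
           call. = FALSE)
  structure(list(atoms = atoms, xyz = xyz), class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("Structure ensemble: %d model(s), %d atoms, chains %s, residues %d-%d\n",
              length(x$xyz), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ","),
              min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ens a [structure_ensemble()].
#' @return Integer model count.
#' @export
n_models <- function(ens) length(ens$xyz)

#' Read a PDB structure ensemble
#'
#' Reads a (possibly multi-model NMR) PDB file; models are kept in file
#' order. Alternate locations are resolved to the highest-occupancy copy;
#' insertion codes are rejected.
#'
#' @param file PDB path.
#' @return A [structure_ensemble()].
#' @export
read_ensemble <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  at$row <- seq_len(nrow(at))
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported", call. = FALSE)
  alt <- !is.na(at$alt) & nzchar(at$alt)
  if (any(alt)) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ)
    at <- at[ord, ][!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(at$row), , drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, atom = at$elety,
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  models <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)[at$row, , drop = FALSE]
    colnames(m) <- c("x", "y", "z")
    m
  })
  structure_ensemble(atoms, models)
}

#' Write a structure ensemble to PDB
#'
#' Multi-model output with MODEL/ENDMDL records; all residues are written
#' as ALA (the package only tracks backbone geometry, not side chains).
#'
#' @param ens a [structure_ensemble()].
#' @param file output path.
#' @export
write_ensemble_pdb <- function(ens, file) {
  con <- file(file, "w")
  on.exit(close(con))
  multi <- n_models(ens) > 1
  for (k in seq_len(n_models(ens))) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    m <- ens$xyz[[k]]
    writeLines(sprintf(
      "ATOM  %5d %-4s ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(m)),
      ifelse(nchar(ens$atoms$atom) < 4, paste0(" ", ens$atoms$atom),
             ens$atoms$atom),
      ens$atoms$chain, ens$atoms$resno, m[, 1], m[, 2], m[, 3]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

# Atom-selection index into the shared atom table. atoms = "backbone"
# (N, CA, C), "heavy" (all non-hydrogen) or an explicit name vector.
select_atoms <- function(ens, chain = NULL, range = NULL,
                         atoms = c("backbone", "heavy")) {
  tab <- ens$atoms
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(chain)) keep <- keep & tab$chain %in% chain
  if (!is.null(range)) keep <- keep & tab$resno >= range[1] & tab$resno <= range[2]
  if (is.character(atoms) && length(atoms) == 1 &&
      atoms %in% c("backbone", "heavy")) {
    names_want <- if (atoms == "backbone") c("N", "CA", "C") else NULL
  } else names_want <- atoms
  if (!is.null(names_want)) keep <- keep & tab$atom %in% names_want
  else keep <- keep & !grepl("^H", tab$atom)           # heavy atoms
  idx <- which(keep)
  if (identical(names_want, c("N", "CA", "C"))) {
    res <- unique(tab$resno[keep])
    cnt <- table(tab$resno[keep])
    incomplete <- names(cnt)[cnt < 3]
    if (length(incomplete))
      stop("missing backbone atoms for residue(s): ",
           paste(incomplete, collapse = ", "), call. = FALSE)
  }
  if (length(idx) == 0) stop("atom selection is empty", call. = FALSE)
  idx
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Signed torsion p1-p2-p3-p4 in degrees, IUPAC sign convention (positive =
# clockwise rotation of the far bond viewed from p2 towards p3).
dihedral_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- (p3 - p2); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  atan2(sum(cross3(b1, v) * w), sum(v * w)) * 180 / pi
}

#' Backbone dihedral angles of one model
#'
#' Standard IUPAC definitions: phi is the C'(i-1)-N(i)-CA(i)-C'(i) torsion,
#' psi the N(i)-CA(i)-C'(i)-N(i+1) torsion. Angles are reported in degrees
#' in (-180, 180]; termini and residues with missing neighbours get `NA`.
#'
#' @param ens a [structure_ensemble()].
#' @param chain chain identifier (default: first chain present).
#' @param range optional `c(first, last)` residue range.
#' @param model model index.
#' @return `data.frame` of class `dihedral_set`: `resno`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(ens, chain = NULL, range = NULL, model = 1) {
  if (is.null(chain)) chain <- ens$atoms$chain[1]
  tab <- ens$atoms
  xyz <- ens$xyz[[model]]
  sel <- tab$chain == chain
  if (!is.null(range)) sel <- sel & tab$resno >= range[1] & tab$resno <= range[2]
  resnos <- sort(unique(tab$resno[sel]))
  get_atom <- function(resno, name) {
    i <- which(tab$chain == chain & tab$resno == resno & tab$atom == name)
    if (length(i) != 1) return(NULL)
    xyz[i, ]
  }
  phi <- psi <- rep(NA_real_, length(resnos))
  for (k in seq_along(resnos)) {
    r <- resnos[k]
    N <- get_atom(r, "N"); CA <- get_atom(r, "CA"); C <- get_atom(r, "C")
    Cprev <- get_atom(r - 1, "C")
    Nnext <- get_atom(r + 1, "N")
    if (!is.null(Cprev) && !is.null(N) && !is.null(CA) && !is.null(C))
      phi[k] <- dihedral_angle(Cprev, N, CA, C)
    if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Nnext))
      psi[k] <- dihedral_angle(N, CA, C, Nnext)
  }
  structure(data.frame(resno = resnos, phi = phi, psi = psi),
            chain = chain, model = model,
            class = c("dihedral_set", "data.frame"))
}

circular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Classify residues as polyproline-II
#'
#' A residue is flagged PPII when both backbone angles lie within a
#' circular tolerance of the canonical PPII geometry, phi = -75 deg,
#' psi = +145 deg (the extended left-handed helix with ~3 residues per
#' turn). Residues with undefined angles are flagged `FALSE` with the
#' reason recorded.
#'
#' @param dihedrals a [backbone_dihedrals()] table.
#' @param tolerance circular half-width (degrees), > 0.
#' @param phi0,psi0 reference angles (degrees).
#' @return The input with added columns `ppii` (logical) and `reason`.
#' @export
classify_ppii <- function(dihedrals, tolerance = 30,
                          phi0 = -75, psi0 = 145) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  undef <- is.na(dihedrals$phi) | is.na(dihedrals$psi)
  ok <- !undef &
    circular_distance(dihedrals$phi, phi0) <= tolerance &
    circular_distance(dihedrals$psi, psi0) <= tolerance
  dihedrals$ppii <- ok
  dihedrals$reason <- ifelse(undef, "undefined angle",
                             ifelse(ok, "within tolerance", "outside tolerance"))
  dihedrals
}

#' Kabsch superposition of two coordinate sets
#'
#' Least-squares rigid-body superposition of matched atom sets: both sets
#' are centred, the optimal proper rotation is obtained from the SVD of the
#' covariance matrix (with the reflection corrected via the sign of the
#' determinant), and the residual RMSD is reported.
#'
#' @param xyz_mobile,xyz_ref matched n x 3 coordinate matrices, n >= 3.
#' @return Object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (applied after rotation), `rmsd` (Angstrom),
#'   `atom_count`.
#' @export
superpose <- function(xyz_mobile, xyz_ref) {
  A <- as.matrix(xyz_mobile); B <- as.matrix(xyz_ref)
  if (nrow(A) != nrow(B) || ncol(A) != 3 || ncol(B) != 3)
    stop("coordinate sets must be matched n x 3 matrices", call. = FALSE)
  if (nrow(A) < 3) stop("need at least 3 atoms to superpose", call. = FALSE)
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  sv <- svd(crossprod(A0, B0))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) geometry: rotation not uniquely defined",
         call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitA <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitA - B0)^2)))
  structure(list(rotation = R,
                 translation = cB - as.numeric(R %*% cA),
                 rmsd = rmsd, atom_count = nrow(A)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Kabsch superposition: %d atoms, rmsd %.4f A\n",
              x$atom_count, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup a [superpose()] result.
#' @param xyz n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, xyz) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' Coordinate RMSD between matched atom sets
#'
#' @param xyz_a,xyz_b matched n x 3 matrices.
#' @param fit superpose first (default) or compute the RMSD in place.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(xyz_a, xyz_b, fit = TRUE) {
  if (fit) return(superpose(xyz_a, xyz_b)$rmsd)
  sqrt(mean(rowSums((as.matrix(xyz_a) - as.matrix(xyz_b))^2)))
}

#' Pairwise RMSD of an NMR ensemble
#'
#' Precision statistic of a structure ensemble: mean and SD of the
#' superposed RMSD over all unordered model pairs, for a chosen residue
#' range and atom set.
#'
#' @param ens a [structure_ensemble()] with >= 2 models.
#' @param chain chain identifier (default: all chains).
#' @param range residue range `c(first, last)`.
#' @param atoms `"backbone"` (N, CA, C'), `"heavy"`, or explicit atom names.
#' @return List of class `ensemble_rmsd`: `mean`, `sd`, `pairwise` (vector
#'   over pairs), `n_models`, `atom_count`, `convention` (text record of
#'   range/atom-set used).
#' @export
ensemble_pairwise_rmsd <- function(ens, chain = NULL, range = NULL,
                                   atoms = "backbone") {
  if (n_models(ens) < 2) stop("need >= 2 models", call. = FALSE)
  idx <- select_atoms(ens, chain, range, atoms)
  pairs <- utils::combn(n_models(ens), 2)
  r <- apply(pairs, 2, function(p)
    coord_rmsd(ens$xyz[[p[1]]][idx, ], ens$xyz[[p[2]]][idx, ]))
  structure(list(mean = mean(r), sd = stats::sd(r), pairwise = r,
                 n_models = n_models(ens), atom_count = length(idx),
                 convention = rmsd_convention(chain, range, atoms)),
            class = "ensemble_rmsd")
}

rmsd_convention <- function(chain, range, atoms) {
  sprintf("chain %s, residues %s, atoms %s",
          if (is.null(chain)) "all" else paste(chain, collapse = ","),
          if (is.null(range)) "all" else paste(range, collapse = "-"),
          paste(atoms, collapse = ","))
}

#' @export
print.ensemble_rmsd <- function(x, ...) {
  cat(sprintf("Ensemble pairwise rmsd: %.3f +/- %.3f A (%d models, %d atoms; %s)\n",
              x$mean, if (is.na(x$sd)) 0 else x$sd,
              x$n_models, x$atom_count, x$convention))
  invisible(x)
}

medoid_model <- function(ens, idx) {
  k <- n_models(ens)
  if (k == 1) return(1L)
  d <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d[i, j] <- d[j, i] <- coord_rmsd(ens$xyz[[i]][idx, ], ens$xyz[[j]][idx, ])
  }
  which.min(rowSums(d))
}

#' Backbone RMSD between two ensembles
#'
#' Compares a representative model of each ensemble (model 1 by default, or
#' the medoid — the model with minimal summed RMSD to its ensemble mates)
#' after Kabsch superposition over the shared residue range, e.g. the
#' free-versus-bound comparison of a domain. The convention used (range,
#' atom set, representative) is recorded in the result because reported
#' RMSDs depend on it.
#'
#' @param ens_a,ens_b [structure_ensemble()] objects.
#' @param chain_a,chain_b chain in each ensemble.
#' @param range shared residue range `c(first, last)`.
#' @param atoms atom set as in [ensemble_pairwise_rmsd()].
#' @param representative `"first"` or `"medoid"`.
#' @return List of class `cross_rmsd`: `rmsd`, `convention`,
#'   `representatives`.
#' @export
cross_rmsd <- function(ens_a, ens_b, chain_a = NULL, chain_b = NULL,
                       range = NULL, atoms = "backbone",
                       representative = c("first", "medoid")) {
  representative <- match.arg(representative)
  ia <- select_atoms(ens_a, chain_a, range, atoms)
  ib <- select_atoms(ens_b, chain_b, range, atoms)
  key_a <- paste(ens_a$atoms$resno[ia], ens_a$atoms$atom[ia])
  key_b <- paste(ens_b$atoms$resno[ib], ens_b$atoms$atom[ib])
  common <- intersect(key_a, key_b)
  if (length(common) < 3)
    stop("residue range does not resolve matched atoms in both ensembles",
         call. = FALSE)
  ia <- ia[match(common, key_a)]
  ib <- ib[match(common, key_b)]
  ra <- if (representative == "first") 1L else medoid_model(ens_a, ia)
  rb <- if (representative == "first") 1L else medoid_model(ens_b, ib)
  structure(list(
    rmsd = coord_rmsd(ens_a$xyz[[ra]][ia, ], ens_b$xyz[[rb]][ib, ]),
    convention = paste0(rmsd_convention(NULL, range, atoms),
                        "; representative = ", representative),
    representatives = c(ra, rb)),
    class = "cross_rmsd")
}

#' @export
print.cross_rmsd <- function(x, ...) {
  cat(sprintf("Cross-ensemble rmsd: %.3f A (models %d vs %d; %s)\n",
              x$rmsd, x$representatives[1], x$representatives[2],
              x$convention))
  invisible(x)
}
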