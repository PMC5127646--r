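# Seeded generators for every input type the analysis modules consume, each
# returning its ground truth so recovery tests never re-derive it. Defaults
# mirror the reference experimental conditions: 200 uM labelled protein
# titrated to 10-fold peptide excess (NMR), 100 uM cell / 1 mM syringe with
# one 0.4 ul pre-injection plus 38 x 1 ul injections (ITC).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

default_ddmax <- function() {
  c(`470` = 0.8, `471` = 0.6, `479` = 0.9, `481` = 0.5,
    `483` = 0.4, `490` = 0.3, `495` = 1.0)
}

#' Generate a fast-exchange NMR titration series
#'
#' Simulates HSQC peak positions along a ligand-concentration ladder under
#' the 1:1 fast-exchange model: each residue's combined shift perturbation
#' at point i is \eqn{\Delta\delta_{max}(r) f_{bound}(P_i, L_i, K_D)},
#' decomposed into 1H and 15N components along a per-residue direction that
#' is fixed by the seed and recorded in the ground truth. Gaussian read
#' noise of SD `noise_sd` (on the combined-ppm scale) is added to the
#' weighted 1H and to the 15N component independently.
#'
#' @param kd ground-truth dissociation constant (uM).
#' @param ddmax named vector of maximal combined shifts (ppm); names are
#'   residue numbers.
#' @param protein_conc labelled protein concentration (uM).
#' @param ratios ligand:protein molar ratios of the ladder (first must
#'   be 0, the apo point).
#' @param noise_sd Gaussian read noise SD (combined-ppm units).
#' @param seed integer seed; identical parameters and seed reproduce the
#'   series exactly.
#' @param weight_H proton weighting of the combined-CSP convention.
#' @return A [titration_series()] with attribute `truth` (list: `kd`,
#'   `ddmax`, `directions`, `noise_sd`, `seed`).
#' @export
gen_titration <- function(kd = 41, ddmax = default_ddmax(),
                          protein_conc = 200,
                          ratios = c(0, 0.5, 1, 2, 4, 6, 8, 10),
                          noise_sd = 0, seed = 1, weight_H = 10) {
  stopifnot(kd > 0, length(ratios) >= 2, ratios[1] == 0)
  res_no <- as.integer(names(ddmax))
  with_seed(seed, {
    # apo peak positions and per-residue perturbation directions
    apo_H <- stats::runif(length(ddmax), 7.5, 9.5)
    apo_N <- stats::runif(length(ddmax), 108, 128)
    theta <- stats::runif(length(ddmax), 0, 2 * pi)
    pts <- lapply(ratios, function(rat) {
      L <- rat * protein_conc
      f <- fraction_bound(protein_conc, L, kd)
      dd <- as.numeric(ddmax) * f
      dH <- dd * cos(theta) / weight_H
      dN <- dd * sin(theta)
      if (noise_sd > 0) {
        dH <- dH + stats::rnorm(length(dd), 0, noise_sd) / weight_H
        dN <- dN + stats::rnorm(length(dd), 0, noise_sd)
      }
      titration_point(protein_conc, L,
                      peak_list(paste0("X", res_no), apo_H + dH, apo_N + dN))
    })
    out <- titration_series(pts, ligand_name = "synthetic peptide")
    attr(out, "truth") <- list(kd = kd, ddmax = ddmax, directions = theta,
                               noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Generate a one-site ITC thermogram
#'
#' Delegates to [simulate_itc()] on the reference injection design and
#' appends seeded Gaussian noise.
#'
#' @param kd,dh,n ground-truth one-site parameters (uM, kcal/mol, sites).
#' @param design an [itc_experiment()] giving the injection schedule.
#' @param noise_sd Gaussian heat noise SD (ucal).
#' @param seed integer seed.
#' @return An [itc_experiment()] with heats and attribute `truth`.
#' @export
gen_itc <- function(kd = 41, dh = -10, n = 1,
                    design = itc_experiment(100, 1000),
                    noise_sd = 0, seed = 1) {
  simulate_itc(kd, dh, n, design, noise_sd = noise_sd,
               seed = if (noise_sd > 0) seed else NULL)
}

build_motif <- function(consensus, run = consensus$max_prolines) {
  phi <- consensus$phi_set[1]
  paste0("R", strrep("P", run), "G", phi, "R")
}

#' Generate random sequences with planted proline-rich motifs
#'
#' Background residues are drawn uniformly from the canonical alphabet
#' excluding P and R (so no spurious motifs can arise); strict-consensus
#' motifs are planted at recorded positions with at least `spacer`
#' background residues between them and to the sequence ends.
#'
#' @param n_motifs number of motifs to plant, >= 0.
#' @param length total sequence length.
#' @param consensus a [consensus_definition()]; the planted motif uses its
#'   maximal proline run and first phi residue.
#' @param spacer minimum background residues between planted motifs.
#' @param seed integer seed.
#' @return Named list: `sequence` (string) and `truth` (`motif_hits`-style
#'   data frame of planted positions).
#' @export
gen_sequences <- function(n_motifs = 6, length = 300,
                          consensus = consensus_definition(),
                          spacer = 5, seed = 1) {
  stopifnot(n_motifs >= 0)
  motif <- build_motif(consensus)
  mlen <- nchar(motif)
  need <- n_motifs * mlen + (n_motifs + 1) * spacer
  if (need > length)
    stop(sprintf("%d motifs of length %d with spacer %d need %d residues, have %d",
                 n_motifs, mlen, spacer, need, length), call. = FALSE)
  bg_alpha <- setdiff(AA_ALPHABET, c("P", "R", "X"))
  with_seed(seed, {
    chars <- sample(bg_alpha, length, replace = TRUE)
    starts <- integer(0)
    if (n_motifs > 0) {
      # distribute the slack uniformly between consecutive motifs
      slack <- length - need
      gaps <- if (slack > 0) {
        cuts <- sort(sample.int(slack + n_motifs, n_motifs))
        diff(c(0, cuts)) - 1L
      } else rep(0L, n_motifs)
      pos <- spacer + 1L
      for (i in seq_len(n_motifs)) {
        pos <- pos + gaps[i]
        starts[i] <- pos
        chars[pos:(pos + mlen - 1L)] <- strsplit(motif, "")[[1]]
        pos <- pos + mlen + spacer
      }
    }
    truth <- data.frame(seq_id = rep("synth", n_motifs), start = starts,
                        end = starts + mlen - 1L,
                        mode = rep("strict", n_motifs),
                        proline_run = rep(consensus$max_prolines, n_motifs),
                        matched_text = rep(motif, n_motifs),
                        stringsAsFactors = FALSE)
    list(sequence = paste(chars, collapse = ""), truth = truth)
  })
}

# Ideal peptide-backbone covalent geometry (Engh-Huber averages).
BOND_N_CA <- 1.458; BOND_CA_C <- 1.525; BOND_C_N <- 1.329
ANGLE_N_CA_C <- 111.2; ANGLE_CA_C_N <- 116.2; ANGLE_C_N_CA <- 121.7

# Place atom D given A-B-C, |CD|, angle BCD (deg) and torsion ABCD (deg)
# (natural-extension reference frame).
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Generate an ideal helical peptide backbone
#'
#' Builds an N-CA-C' backbone with ideal bond lengths and angles and
#' uniform backbone torsions, so [backbone_dihedrals()] recovers the set
#' angles exactly (to numerical precision). Defaults give a polyproline-II
#' helix (phi = -75, psi = +145, omega = 180); pass phi = -57, psi = -47
#' for an ideal alpha helix.
#'
#' @param n_residues chain length, >= 2.
#' @param phi,psi,omega backbone torsions (degrees) applied to every
#'   residue.
#' @param chain chain identifier.
#' @return A single-model [structure_ensemble()] of residues 1..n.
#' @export
gen_helix_coordinates <- function(n_residues, phi = -75, psi = 145,
                                  omega = 180, chain = "A") {
  stopifnot(n_residues >= 2)
  coords <- matrix(NA_real_, 3 * n_residues, 3)
  rownames <- NULL
  a <- ANGLE_N_CA_C * pi / 180
  N1 <- c(0, 0, 0)
  CA1 <- c(BOND_N_CA, 0, 0)
  C1 <- CA1 + BOND_CA_C * c(cos(pi - a), sin(pi - a), 0)
  coords[1, ] <- N1; coords[2, ] <- CA1; coords[3, ] <- C1
  for (i in seq_len(n_residues - 1)) {
    N_i <- coords[3 * i - 2, ]; CA_i <- coords[3 * i - 1, ]
    C_i <- coords[3 * i, ]
    N_next <- place_atom(N_i, CA_i, C_i, BOND_C_N, ANGLE_CA_C_N, psi)
    CA_next <- place_atom(CA_i, C_i, N_next, BOND_N_CA, ANGLE_C_N_CA, omega)
    C_next <- place_atom(C_i, N_next, CA_next, BOND_CA_C, ANGLE_N_CA_C, phi)
    coords[3 * i + 1, ] <- N_next
    coords[3 * i + 2, ] <- CA_next
    coords[3 * i + 3, ] <- C_next
  }
  colnames(coords) <- c("x", "y", "z")
  atoms <- data.frame(chain = chain,
                      resno = rep(seq_len(n_residues), each = 3),
                      atom = rep(c("N", "CA", "C"), n_residues),
                      stringsAsFactors = FALSE)
  structure_ensemble(atoms, list(coords))
}

#' Generate an ideal polyproline-II backbone
#'
#' @param n_residues chain length, >= 3.
#' @return A single-model [structure_ensemble()] with PPII torsions
#'   (phi = -75, psi = +145).
#' @export
gen_ppii_coordinates <- function(n_residues) {
  stopifnot(n_residues >= 3)
  gen_helix_coordinates(n_residues, phi = -75, psi = 145, omega = 180)
}

#' Generate a jittered structure ensemble
#'
#' Copies of a base model with seeded isotropic Gaussian coordinate noise;
#' a controllable toy for RMSD statistics.
#'
#' @param base a single-model [structure_ensemble()].
#' @param n_models number of models.
#' @param jitter_sd per-coordinate noise SD (Angstrom).
#' @param seed integer seed.
#' @return A [structure_ensemble()] of `n_models` models.
#' @export
gen_jittered_ensemble <- function(base, n_models = 10, jitter_sd = 0.3,
                                  seed = 1) {
  stopifnot(inherits(base, "structure_ensemble"))
  m0 <- base$xyz[[1]]
  with_seed(seed, {
    xyz <- lapply(seq_len(n_models), function(i)
      m0 + matrix(stats::rnorm(length(m0), 0, jitter_sd), nrow(m0), 3))
    structure_ensemble(base$atoms, xyz)
  })
}
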