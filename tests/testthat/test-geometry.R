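test_that("ideal helix generators reproduce their set dihedrals", {
  pp <- gen_ppii_coordinates(6)
  d <- backbone_dihedrals(pp)
  internal <- d[!is.na(d$phi) & !is.na(d$psi), ]
  expect_equal(nrow(internal), 4L)
  expect_true(all(abs(internal$phi - (-75)) < 0.5))
  expect_true(all(abs(internal$psi - 145) < 0.5))
  ah <- backbone_dihedrals(gen_helix_coordinates(8, phi = -57, psi = -47))
  ok <- !is.na(ah$phi) & !is.na(ah$psi)
  expect_true(all(abs(ah$phi[ok] + 57) < 0.5))
  expect_true(all(abs(ah$psi[ok] + 47) < 0.5))
  # two residues: no residue has both angles, and nothing crashes
  d2 <- backbone_dihedrals(gen_helix_coordinates(2))
  expect_true(all(is.na(d2$phi) | is.na(d2$psi)))
  # three residues: exactly one fully defined residue
  d3 <- backbone_dihedrals(gen_ppii_coordinates(3))
  expect_equal(sum(!is.na(d3$phi) & !is.na(d3$psi)), 1L)
})

test_that("package dihedrals agree with an independent torsion implementation", {
  pp <- gen_helix_coordinates(7, phi = -63, psi = 131)
  d <- backbone_dihedrals(pp)
  tor <- bio3d::torsion.xyz(as.numeric(t(pp$xyz[[1]])), atm.inc = 1)
  # bio3d returns successive 4-atom torsions along the N-CA-C chain with a
  # leading NA: psi(i) lands at index 3i-1, phi(i) at index 3i-2
  expect_equal(d$psi[2], tor[5], tolerance = 1e-6)
  expect_equal(d$phi[3], tor[7], tolerance = 1e-6)
})

test_that("PPII helix is left-handed with about three residues per turn", {
  pp <- gen_ppii_coordinates(13)
  ca <- pp$xyz[[1]][pp$atoms$atom == "CA", ]
  rot <- oracle_rotation_per_residue(ca)
  expect_lt(rot, 0)                       # left-handed
  expect_equal(rot, -120, tolerance = 8)  # ~3 residues per turn
})

test_that("PPII classification uses circular angle distance", {
  pp <- classify_ppii(backbone_dihedrals(gen_ppii_coordinates(6)))
  expect_true(all(pp$ppii[!is.na(pp$phi) & !is.na(pp$psi)]))
  expect_true(all(!pp$ppii[is.na(pp$phi) | is.na(pp$psi)]))
  expect_match(pp$reason[1], "undefined")
  # alpha-helical angles are rejected
  ah <- classify_ppii(backbone_dihedrals(gen_helix_coordinates(6, -57, -47)))
  expect_false(any(ah$ppii))
  # tolerance boundary: |145 - 179| = 34 degrees
  fake <- data.frame(resno = 1L, phi = -75, psi = 179)
  expect_false(classify_ppii(fake, tolerance = 30)$ppii)
  expect_true(classify_ppii(fake, tolerance = 40)$ppii)
  # wrap-around: psi = -175 is 40 degrees from +145 the short way
  wrap <- data.frame(resno = 1L, phi = -75, psi = -175)
  expect_true(classify_ppii(wrap, tolerance = 45)$ppii)
  expect_error(classify_ppii(fake, tolerance = 0), "tolerance")
})

test_that("Kabsch superposition is exact, proper and matches brute force", {
  A <- toy_coords(10)
  self <- superpose(A, A)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)
  # translation only
  expect_equal(superpose(A, sweep(A, 2, c(5, 0, 0), `+`))$rmsd, 0,
               tolerance = 1e-10)
  # arbitrary rigid transform
  B <- random_rigid_transform(A, seed = 3)
  sup <- superpose(A, B)
  expect_equal(sup$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_superposition(sup, A), B, tolerance = 1e-8)
  # single displaced atom among N: rmsd bounded by d/sqrt(N)
  C <- A; C[4, ] <- C[4, ] + c(1, 0, 0)
  expect_lte(superpose(A, C)$rmsd, 1 / sqrt(10) + 1e-12)
  # non-trivial pair against the Euler-angle brute force
  set.seed(41)
  D <- A + matrix(rnorm(30, sd = 0.5), 10, 3)
  expect_equal(superpose(A, D)$rmsd, oracle_min_rmsd(A, D), tolerance = 1e-5)
  # degenerate geometry rejected
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate|collinear")
})

test_that("RMSD is symmetric and rigid-motion invariant", {
  A <- toy_coords(8, seed = 5)
  set.seed(6)
  B <- A + matrix(rnorm(24, sd = 0.4), 8, 3)
  r <- coord_rmsd(A, B)
  expect_equal(r, coord_rmsd(B, A), tolerance = 1e-10)
  expect_equal(coord_rmsd(random_rigid_transform(A, 8), B), r,
               tolerance = 1e-8)
  expect_equal(coord_rmsd(A, random_rigid_transform(B, 9)), r,
               tolerance = 1e-8)
})

test_that("ensemble pairwise RMSD matches the brute-force pair loop", {
  base <- gen_ppii_coordinates(8)
  ens <- gen_jittered_ensemble(base, n_models = 4, jitter_sd = 0.4, seed = 2)
  out <- ensemble_pairwise_rmsd(ens, atoms = "backbone")
  # identical models: exactly zero spread
  same <- structure_ensemble(base$atoms,
                             list(base$xyz[[1]], base$xyz[[1]], base$xyz[[1]]))
  z <- ensemble_pairwise_rmsd(same)
  expect_equal(z$mean, 0, tolerance = 1e-10)
  expect_equal(z$sd, 0, tolerance = 1e-10)
  # two models: mean is the single pair, sd 0
  two <- structure_ensemble(base$atoms, ens$xyz[1:2])
  p2 <- ensemble_pairwise_rmsd(two)
  expect_equal(p2$mean, coord_rmsd(ens$xyz[[1]], ens$xyz[[2]]),
               tolerance = 1e-10)
  expect_true(is.na(p2$sd) || p2$sd == 0)
  # brute force over all unordered pairs
  pairs <- combn(4, 2)
  brute <- apply(pairs, 2, function(p)
    oracle_min_rmsd(ens$xyz[[p[1]]], ens$xyz[[p[2]]]))
  expect_equal(out$mean, mean(brute), tolerance = 1e-4)
  expect_equal(out$sd, sd(brute), tolerance = 1e-4)
  expect_gte(out$mean, 0)
  expect_match(out$convention, "backbone")
  expect_error(ensemble_pairwise_rmsd(base), ">= 2 models")
})

test_that("cross-ensemble RMSD honours representatives and conventions", {
  base <- gen_ppii_coordinates(10)
  ens <- gen_jittered_ensemble(base, n_models = 5, jitter_sd = 0.5, seed = 4)
  # an ensemble against itself is exactly zero under both rules
  expect_equal(cross_rmsd(ens, ens)$rmsd, 0, tolerance = 1e-10)
  expect_equal(cross_rmsd(ens, ens, representative = "medoid")$rmsd, 0,
               tolerance = 1e-10)
  # known offsets on a 4-atom toy: hand-computed in-place rmsd after
  # superposition equals the Kabsch result computed atom by atom
  other <- gen_jittered_ensemble(base, n_models = 5, jitter_sd = 0.5, seed = 9)
  cr <- cross_rmsd(ens, other, range = c(2, 9))
  idx <- which(base$atoms$resno >= 2 & base$atoms$resno <= 9)
  expect_equal(cr$rmsd,
               superpose(ens$xyz[[1]][idx, ], other$xyz[[1]][idx, ])$rmsd,
               tolerance = 1e-10)
  expect_match(cr$convention, "representative = first")
  expect_error(cross_rmsd(ens, other, range = c(100, 120)), "empty|matched")
})

test_that("hand-built toy cross RMSD matches the direct formula", {
  # square of side 2 vs the same square with one corner pulled out:
  # in-place rmsd with no fitting = sqrt(mean(per-atom squared shifts))
  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  sq2 <- sq; sq2[1, ] <- c(0, 0, 1)
  expect_equal(coord_rmsd(sq, sq2, fit = FALSE), sqrt(1 / 4), tolerance = 1e-12)
})

test_that("PDB ensemble IO round-trips models, atoms and coordinates", {
  dir <- withr::local_tempdir()
  base <- gen_ppii_coordinates(8)
  ens <- gen_jittered_ensemble(base, n_models = 10, jitter_sd = 0.3, seed = 7)
  f <- file.path(dir, "ens.pdb")
  write_ensemble_pdb(ens, f)
  back <- read_ensemble(f)
  expect_equal(n_models(back), 10L)
  expect_equal(back$atoms$atom, ens$atoms$atom)
  expect_equal(back$atoms$resno, ens$atoms$resno)
  expect_equal(back$xyz[[4]], ens$xyz[[4]], tolerance = 1e-3,
               ignore_attr = TRUE)
  # single model file
  write_ensemble_pdb(base, f)
  expect_equal(n_models(read_ensemble(f)), 1L)
  # analysis on the round-tripped ensemble matches the original
  expect_equal(ensemble_pairwise_rmsd(back)$mean,
               ensemble_pairwise_rmsd(ens)$mean, tolerance = 1e-3)
  # CA-only residues in a backbone selection raise a named error
  ca_only <- structure_ensemble(
    data.frame(chain = "A", resno = rep(1:4, each = 1), atom = "CA"),
    list(toy_coords(4)))
  expect_error(ensemble_pairwise_rmsd(
    structure_ensemble(ca_only$atoms, list(toy_coords(4), toy_coords(4, 8)))),
    "missing backbone")
})
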