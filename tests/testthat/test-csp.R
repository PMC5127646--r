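test_that("combined CSP reproduces hand-evaluated values and rejects bad input", {
  expect_equal(combined_csp(0, 0), 0)
  expect_equal(combined_csp(0.1, 1.0), sqrt(2), tolerance = 1e-12)
  expect_equal(combined_csp(0.02, 0.1), sqrt(0.05), tolerance = 1e-12)
  # configurable proton weight
  expect_equal(combined_csp(0.1, 0, weight_H = 1), 0.1)
  expect_error(combined_csp(NA, 0.1), "non-finite")
  expect_error(combined_csp(Inf, 0.1), "non-finite")
})

test_that("combined CSP is sign-invariant and monotone in both components", {
  set.seed(11)
  for (i in 1:25) {
    a <- rnorm(1, sd = 0.1); b <- rnorm(1)
    expect_equal(combined_csp(a, b), combined_csp(-a, -b))
    expect_equal(combined_csp(a, b), combined_csp(abs(a), abs(b)))
    # increasing either component magnitude never decreases the result
    expect_gte(combined_csp(abs(a) * 1.5, b), combined_csp(a, b))
    expect_gte(combined_csp(a, abs(b) * 1.5), combined_csp(a, b))
  }
})

test_that("CSP profile matches residues by number and reports the unmatched", {
  s <- manual_series()
  p_same <- csp_profile(s, 1, 1)
  expect_s3_class(p_same, "csp_profile")
  expect_true(all(p_same$dd == 0))

  # single residue moved by (0.05 ppm 1H, 0): combined CSP = 10 * 0.05
  apo <- titration_point(200, 0, peak_list(c("Y495", "D481"), c(8.9, 8.2),
                                           c(124, 119)))
  moved <- titration_point(200, 2000, peak_list(c("Y495", "D481"),
                                                c(8.95, 8.2), c(124, 119)))
  p <- csp_profile(titration_series(list(apo, moved)))
  expect_equal(p$dd[p$residue_number == 495], 0.5, tolerance = 1e-12)
  expect_equal(p$dd[p$residue_number == 481], 0)
  expect_true(all(p$dd >= 0))

  # residue present only in the apo point goes to the missing set, not zero
  apo2 <- titration_point(200, 0, peak_list(c("Y495", "G456"), c(8.9, 8.0),
                                            c(124, 110)))
  p2 <- csp_profile(titration_series(list(apo2, moved)))
  expect_equal(attr(p2, "missing")$ref_only, 456)
  expect_false(456 %in% p2$residue_number)

  # disjoint residue sets are an error
  other <- titration_point(200, 100, peak_list("A451", 8.0, 115))
  expect_error(csp_profile(titration_series(list(apo, other))), "common")
})

test_that("CSP score self-normalizes, scales linearly and names missing residues", {
  set.seed(4)
  dd <- runif(7, 0.1, 1)
  mk_profile <- function(scale) {
    apo <- titration_point(200, 0, peak_list(
      paste0("X", ocre_score_residues), rep(8.5, 7), rep(120, 7)))
    sat <- titration_point(200, 2000, peak_list(
      paste0("X", ocre_score_residues), 8.5 + scale * dd / 10, rep(120, 7)))
    csp_profile(titration_series(list(apo, sat)))
  }
  wt <- mk_profile(1)
  expect_equal(csp_score(wt, wt)$score, 1)
  expect_equal(csp_score(wt, mk_profile(0.5))$score, 0.5, tolerance = 1e-10)
  expect_equal(csp_score(wt, mk_profile(0))$score, 0)
  # invariance under common rescaling of both profiles
  s1 <- csp_score(mk_profile(2), mk_profile(1))$score
  s2 <- csp_score(mk_profile(6), mk_profile(3))$score
  expect_equal(s1, s2, tolerance = 1e-10)
  # zero wild-type sum is undefined, missing residues are named
  expect_error(csp_score(mk_profile(0), wt), "undefined")
  expect_error(csp_score(wt, wt, residues = c(470, 999)), "999")
})

test_that("significance rule flags only residues above mean + k SD", {
  mk <- function(dd_vec, resn = seq_along(dd_vec) + 460) {
    apo <- titration_point(200, 0, peak_list(paste0("X", resn),
                                             rep(8, length(resn)),
                                             rep(120, length(resn))))
    sat <- titration_point(200, 2000, peak_list(paste0("X", resn),
                                                8 + dd_vec / 10,
                                                rep(120, length(resn))))
    csp_profile(titration_series(list(apo, sat)))
  }
  expect_length(significant_residues(mk(rep(0, 10))), 0)
  # hand calculation: one residue at 1.0 among nine zeros:
  # mean 0.1, sd sqrt(0.1), cutoff 0.4162 -> only that residue
  p <- mk(c(1, rep(0, 9)), resn = c(470, 501:509))
  expect_equal(significant_residues(p), 470)
  # uniform profile: SD = 0 and the strict inequality excludes everything
  expect_length(significant_residues(mk(rep(0.5, 8))), 0)
  # absolute rule
  expect_equal(significant_residues(p, rule = "absolute", threshold = 0.9), 470)
})

test_that("peak-list and manifest round trip preserves the series", {
  dir <- withr::local_tempdir()
  s <- gen_titration(kd = 41, noise_sd = 0.01, seed = 9)
  files <- character(length(s$points))
  for (i in seq_along(s$points)) {
    files[i] <- file.path(dir, sprintf("point%02d.list", i))
    write_peak_list(s$points[[i]], files[i])
  }
  manifest <- file.path(dir, "series.manifest")
  writeLines(c("# synthetic titration", basename(files)), manifest)
  s2 <- read_titration(manifest)
  expect_length(s2$points, length(s$points))
  expect_equal(s2$points[[3]]$ligand_conc, s$points[[3]]$ligand_conc)
  expect_equal(s2$points[[3]]$peaks$delta_H, s$points[[3]]$peaks$delta_H,
               tolerance = 1e-5)
  p1 <- csp_profile(s); p2 <- csp_profile(s2)
  expect_equal(p1$dd, p2$dd, tolerance = 1e-4)
  # comma-separated rows parse too
  f <- file.path(dir, "commas.list")
  writeLines(c("# protein_conc_uM = 200", "# ligand_conc_uM = 0",
               "Y495,124.0,8.90", "Y470,120.0,8.10"), f)
  pt <- read_peak_list(f)
  expect_equal(pt$peaks$delta_N, c(124, 120))
  expect_equal(pt$peaks$residue_number, c(495L, 470L))
})
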