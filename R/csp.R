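#' Default OCRE residue set for the normalized CSP score
#'
#' The seven OCRE amides (author numbering) whose chemical-shift perturbations
#' are summed to score the relative binding of peptide variants: Y470, Y471,
#' Y479, D481, N483, S490 and Y495. These residues line the tyrosine-rich
#' binding surface of the domain and respond most strongly to proline-rich
#' peptide binding.
#'
#' @format Integer vector of length 7.
#' @export
ocre_score_residues <- c(470L, 471L, 479L, 481L, 483L, 490L, 495L)

#' Combined amide chemical-shift perturbation
#'
#' Collapses the proton and nitrogen components of an amide shift change into
#' a single scalar, \eqn{\Delta\delta = \sqrt{(w_H \Delta\delta_{HN})^2 +
#' (\Delta\delta_N)^2}} with the proton change up-weighted by `weight_H`
#' (default 10) to compensate for the narrower 1H shift dispersion.
#'
#' @param delta_H change in amide proton shift (ppm); vectorized.
#' @param delta_N change in amide nitrogen shift (ppm); recycled against
#'   `delta_H`.
#' @param weight_H multiplier applied to the proton term before squaring.
#' @return Non-negative combined perturbation (ppm), same length as the
#'   longer input.
#' @examples
#' combined_csp(0.1, 1.0)   # sqrt(1 + 1) = 1.414...
#' combined_csp(0.02, 0.1)  # sqrt(0.04 + 0.01)
#' @export
combined_csp <- function(delta_H, delta_N, weight_H = 10) {
  delta_H <- suppressWarnings(as.numeric(delta_H))
  delta_N <- suppressWarnings(as.numeric(delta_N))
  if (any(!is.finite(delta_H)) || any(!is.finite(delta_N)))
    stop("non-finite shift change supplied to combined_csp()", call. = FALSE)
  sqrt((weight_H * delta_H)^2 + delta_N^2)
}

residue_number_from_label <- function(label) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]*", "", label)))
  if (any(is.na(num)))
    stop("cannot parse residue number from label(s): ",
         paste(label[is.na(num)], collapse = ", "), call. = FALSE)
  num
}

#' Construct a residue peak table
#'
#' @param residue_label character labels like `"Y495"` (one-letter residue
#'   code followed by the author residue number).
#' @param delta_H amide 1H shifts (ppm).
#' @param delta_N amide 15N shifts (ppm).
#' @return A `data.frame` with columns `residue_label`, `residue_number`,
#'   `delta_H`, `delta_N`; residue numbers must be unique.
#' @export
peak_list <- function(residue_label, delta_H, delta_N) {
  residue_number <- residue_number_from_label(residue_label)
  if (anyDuplicated(residue_number))
    stop("duplicate residue numbers in peak list: ",
         paste(unique(residue_number[duplicated(residue_number)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(delta_H)) || any(!is.finite(delta_N)))
    stop("peak shifts must be finite", call. = FALSE)
  data.frame(residue_label = as.character(residue_label),
             residue_number = residue_number,
             delta_H = as.numeric(delta_H),
             delta_N = as.numeric(delta_N),
             stringsAsFactors = FALSE)
}

#' Construct a titration point
#'
#' @param protein_conc labelled protein concentration (uM), >= 0.
#' @param ligand_conc titrant concentration (uM), >= 0.
#' @param peaks a peak table from [peak_list()].
#' @return A list of class `titration_point`.
#' @export
titration_point <- function(protein_conc, ligand_conc, peaks) {
  if (protein_conc < 0 || ligand_conc < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  stopifnot(is.data.frame(peaks),
            all(c("residue_number", "delta_H", "delta_N") %in% names(peaks)))
  structure(list(protein_conc = protein_conc,
                 ligand_conc = ligand_conc,
                 peaks = peaks),
            class = "titration_point")
}

#' Assemble an NMR titration series
#'
#' An ordered set of titration points; the first point is the apo spectrum
#' (ligand concentration zero).
#'
#' @param points list of [titration_point()] objects, apo first.
#' @param ligand_name label for the titrant.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(points, ligand_name = "ligand") {
  if (length(points) < 2)
    stop("a titration series needs at least 2 points", call. = FALSE)
  if (!all(vapply(points, inherits, logical(1), "titration_point")))
    stop("all points must be titration_point objects", call. = FALSE)
  if (points[[1]]$ligand_conc != 0)
    stop("first titration point must be apo (ligand_conc = 0)", call. = FALSE)
  structure(list(points = points, ligand_name = ligand_name),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat("NMR titration series:", x$ligand_name, "\n")
  df <- data.frame(
    point = seq_along(x$points),
    protein_uM = vapply(x$points, `[[`, numeric(1), "protein_conc"),
    ligand_uM = vapply(x$points, `[[`, numeric(1), "ligand_conc"),
    n_peaks = vapply(x$points, function(p) nrow(p$peaks), integer(1)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read a titration peak list file
#'
#' The dialect is plain text: `#`-prefixed header lines carrying
#' `protein_conc_uM` and `ligand_conc_uM`, then one row per assigned amide
#' with columns `residue_label  w_N(ppm)  w_HN(ppm)`, whitespace- or
#' comma-separated.
#'
#' @param file path to one peak-list file (one titration point).
#' @return A [titration_point()].
#' @export
read_peak_list <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- lines[startsWith(trimws(lines), "#")]
  body <- lines[!startsWith(trimws(lines), "#")]
  get_meta <- function(key) {
    hit <- grep(key, hdr, value = TRUE)
    if (length(hit) == 0)
      stop("peak list ", file, " missing header field ", key, call. = FALSE)
    as.numeric(sub(paste0(".*", key, "[ =:]+([0-9.eE+-]+).*"), "\\1", hit[1]))
  }
  protein <- get_meta("protein_conc_uM")
  ligand <- get_meta("ligand_conc_uM")
  fields <- strsplit(trimws(body), "[,[:space:]]+")
  bad <- lengths(fields) < 3
  if (any(bad))
    stop("malformed peak rows in ", file, ": lines ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  lab <- vapply(fields, `[[`, character(1), 1)
  w_N <- as.numeric(vapply(fields, `[[`, character(1), 2))
  w_HN <- as.numeric(vapply(fields, `[[`, character(1), 3))
  titration_point(protein, ligand, peak_list(lab, w_HN, w_N))
}

#' Read a titration series via a manifest
#'
#' @param manifest path to a text file listing one peak-list file per line,
#'   in titration order (apo first); paths are resolved relative to the
#'   manifest's directory. `#` comment lines are ignored.
#' @param ligand_name label for the titrant.
#' @return A [titration_series()].
#' @export
read_titration <- function(manifest, ligand_name = "ligand") {
  lines <- trimws(readLines(manifest, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  dir <- dirname(manifest)
  paths <- ifelse(file.exists(lines), lines, file.path(dir, lines))
  titration_series(lapply(paths, read_peak_list), ligand_name = ligand_name)
}

#' Write a titration point to the peak-list dialect
#'
#' @param point a [titration_point()].
#' @param file output path.
#' @export
write_peak_list <- function(point, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# protein_conc_uM = %.6g", point$protein_conc),
               sprintf("# ligand_conc_uM = %.6g", point$ligand_conc),
               "# residue_label  w_N(ppm)  w_HN(ppm)"), con)
  with(point$peaks,
       writeLines(sprintf("%s  %.6f  %.6f", residue_label, delta_N, delta_H), con))
  invisible(file)
}

#' Per-residue chemical-shift-perturbation profile
#'
#' Computes combined CSPs between two points of a titration series. Residues
#' are matched by author residue number; residues present in only one of the
#' two points are reported in the `missing` attribute, never as zero.
#'
#' @param series a [titration_series()].
#' @param ref_index index of the reference point (default 1, the apo point).
#' @param cmp_index index of the comparison point (default the last point).
#' @param weight_H proton weighting passed to [combined_csp()].
#' @return An object of class `csp_profile`: a `data.frame` with columns
#'   `residue_number`, `dd` (combined Delta-delta, ppm), `dd_H`, `dd_N`
#'   (signed component changes), plus attributes `ref_index`, `cmp_index`
#'   and `missing`.
#' @export
csp_profile <- function(series, ref_index = 1,
                        cmp_index = length(series$points), weight_H = 10) {
  stopifnot(inherits(series, "titration_series"))
  np <- length(series$points)
  if (ref_index < 1 || ref_index > np || cmp_index < 1 || cmp_index > np)
    stop("point index out of range", call. = FALSE)
  ref <- series$points[[ref_index]]$peaks
  cmp <- series$points[[cmp_index]]$peaks
  common <- intersect(ref$residue_number, cmp$residue_number)
  if (length(common) == 0)
    stop("no residues in common between the two titration points", call. = FALSE)
  i <- match(common, ref$residue_number)
  j <- match(common, cmp$residue_number)
  dd_H <- cmp$delta_H[j] - ref$delta_H[i]
  dd_N <- cmp$delta_N[j] - ref$delta_N[i]
  out <- data.frame(residue_number = common,
                    dd = combined_csp(dd_H, dd_N, weight_H = weight_H),
                    dd_H = dd_H, dd_N = dd_N)
  out <- out[order(out$residue_number), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            ref_index = ref_index, cmp_index = cmp_index,
            weight_H = weight_H,
            missing = list(
              ref_only = setdiff(ref$residue_number, common),
              cmp_only = setdiff(cmp$residue_number, common)),
            class = c("csp_profile", "data.frame"))
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf("CSP profile (point %d vs %d), %d residues\n",
              attr(x, "cmp_index"), attr(x, "ref_index"), nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  miss <- attr(x, "missing")
  if (length(miss$ref_only) || length(miss$cmp_only))
    cat("unmatched residues - ref only:",
        paste(miss$ref_only, collapse = ","),
        "; cmp only:", paste(miss$cmp_only, collapse = ","), "\n")
  invisible(x)
}

profile_dd <- function(profile, residues) {
  idx <- match(residues, profile$residue_number)
  if (anyNA(idx))
    stop("profile is missing residue(s): ",
         paste(residues[is.na(idx)], collapse = ", "), call. = FALSE)
  profile$dd[idx]
}

#' Normalized multi-residue CSP score
#'
#' Sums combined CSPs over a fixed residue set for a variant-peptide
#' titration and normalizes by the corresponding wild-type sum. Both
#' profiles should be taken at the same molar ratio (the reference protocol
#' titrates peptide to 10x excess). The wild type scored against itself
#' gives exactly 1; smaller scores mean weaker perturbation, i.e. weaker
#' relative binding.
#'
#' @param wt_profile [csp_profile()] of the wild-type peptide titration.
#' @param variant_profile [csp_profile()] of the variant peptide.
#' @param residues residue set to sum over; defaults to
#'   [ocre_score_residues].
#' @return An object of class `csp_score`: list with `score`, `raw_sum`
#'   (variant, ppm), `wt_sum` (ppm) and `residues`.
#' @export
csp_score <- function(wt_profile, variant_profile,
                      residues = ocre_score_residues) {
  wt <- profile_dd(wt_profile, residues)
  var <- profile_dd(variant_profile, residues)
  wt_sum <- sum(wt)
  if (wt_sum <= 0)
    stop("wild-type CSP sum is zero; score undefined", call. = FALSE)
  structure(list(score = sum(var) / wt_sum,
                 raw_sum = sum(var), wt_sum = wt_sum,
                 residues = residues),
            class = "csp_score")
}

#' @export
print.csp_score <- function(x, ...) {
  cat(sprintf("CSP score %.4f (variant sum %.4f / WT sum %.4f ppm over %d residues)\n",
              x$score, x$raw_sum, x$wt_sum, length(x$residues)))
  invisible(x)
}

#' Residues with significant chemical-shift perturbation
#'
#' Default rule flags residues whose combined CSP strictly exceeds the
#' profile mean plus `k` standard deviations; used for mapping the binding
#' surface. A fixed ppm cutoff can be given instead.
#'
#' @param profile a [csp_profile()].
#' @param rule `"mean_sd"` (default) or `"absolute"`.
#' @param k number of standard deviations for the `"mean_sd"` rule.
#' @param threshold fixed Delta-delta cutoff (ppm) for the `"absolute"` rule.
#' @return Integer vector of residue numbers exceeding the threshold.
#' @export
significant_residues <- function(profile, rule = c("mean_sd", "absolute"),
                                 k = 1, threshold = NULL) {
  rule <- match.arg(rule)
  if (nrow(profile) == 0) stop("empty CSP profile", call. = FALSE)
  cut <- switch(rule,
    mean_sd = mean(profile$dd) + k * stats::sd(profile$dd),
    absolute = {
      if (is.null(threshold)) stop("absolute rule needs a threshold", call. = FALSE)
      threshold
    })
  if (is.na(cut)) cut <- Inf  # single-residue profile: SD undefined
  sort(profile$residue_number[profile$dd > cut])
}
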