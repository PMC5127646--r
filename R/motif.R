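AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y","X")

#' Define a proline-rich-motif consensus
#'
#' The OCRE-binding consensus is RPPP(P)G-phi-R: a run of three or four
#' prolines preceded by an arginine and followed by glycine, a hydrophobic
#' residue phi (Ile/Met/Val by default) and another arginine. The relaxed
#' rule only requires arginines within `arg_window` residues on either side
#' of the proline run.
#'
#' @param min_prolines,max_prolines allowed proline-run lengths.
#' @param phi_set admissible hydrophobic residues at the phi position;
#'   Leu/Phe can be added, they are chemically plausible but untested.
#' @param require_pre_arg,require_post_arg whether the relaxed rule demands
#'   an arginine before/after the run. The preceding arginine contributes
#'   more to binding than the following one, so dropping only the post-Arg
#'   requirement is the common relaxation.
#' @param arg_window search window (residues) for flanking arginines in
#'   relaxed mode.
#' @return A list of class `consensus_definition`.
#' @export
consensus_definition <- function(min_prolines = 3, max_prolines = 4,
                                 phi_set = c("I", "M", "V"),
                                 require_pre_arg = TRUE,
                                 require_post_arg = TRUE,
                                 arg_window = 3) {
  if (min_prolines < 1 || min_prolines > max_prolines)
    stop("need 1 <= min_prolines <= max_prolines", call. = FALSE)
  structure(list(min_prolines = as.integer(min_prolines),
                 max_prolines = as.integer(max_prolines),
                 phi_set = toupper(phi_set),
                 require_pre_arg = require_pre_arg,
                 require_post_arg = require_post_arg,
                 arg_window = as.integer(arg_window)),
            class = "consensus_definition")
}

validate_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    stop("invalid residue letter(s) at position(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  sequence
}

empty_hits <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             mode = character(0), proline_run = integer(0),
             pre_arg_pos = integer(0), post_arg_pos = integer(0),
             matched_text = character(0), stringsAsFactors = FALSE)
}

as_motif_hits <- function(df) {
  class(df) <- c("motif_hits", "data.frame")
  df
}

#' Scan a sequence for strict consensus motifs
#'
#' Finds non-overlapping, left-to-right matches of
#' `R P{min,max} G phi R` (greedy: the longest admissible proline run wins
#' at each anchor). Runs longer than `max_prolines` do not match.
#'
#' @param sequence one amino-acid string (upper case, 20 canonical letters
#'   plus X).
#' @param consensus a [consensus_definition()].
#' @param seq_id identifier carried into the hit table.
#' @return A `motif_hits` data frame: `seq_id`, 1-based inclusive `start`
#'   and `end` of the full match, `mode`, `proline_run`, flanking arginine
#'   positions and `matched_text`, sorted by `start`.
#' @export
scan_strict <- function(sequence, consensus = consensus_definition(),
                        seq_id = "seq") {
  sequence <- validate_sequence(sequence)
  pat <- sprintf("RP{%d,%d}G[%s]R", consensus$min_prolines,
                 consensus$max_prolines, paste(consensus$phi_set, collapse = ""))
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(as_motif_hits(empty_hits()))
  start <- as.integer(m)
  len <- attr(m, "match.length")
  end <- start + len - 1L
  text <- substring(sequence, start, end)
  as_motif_hits(data.frame(
    seq_id = seq_id, start = start, end = end, mode = "strict",
    proline_run = len - 4L,           # match is R + run + G + phi + R
    pre_arg_pos = start, post_arg_pos = end,
    matched_text = text, stringsAsFactors = FALSE))
}

#' Scan a sequence for relaxed proline-rich motifs
#'
#' Finds maximal proline runs of admissible length and accepts each run as
#' a hit if an arginine lies within `arg_window` residues before the run
#' (when `require_pre_arg`) and after it (when `require_post_arg`). The
#' reported hit spans from the pre-arginine (or run start) to the
#' post-arginine (or run end). Runs longer than `max_prolines` are reported
#' with a warning by default, or dropped with `long_runs = "drop"`.
#'
#' @inheritParams scan_strict
#' @param long_runs treatment of proline runs longer than `max_prolines`.
#' @return A `motif_hits` data frame (see [scan_strict()]).
#' @export
scan_relaxed <- function(sequence, consensus = consensus_definition(),
                         seq_id = "seq", long_runs = c("warn", "drop")) {
  long_runs <- match.arg(long_runs)
  sequence <- validate_sequence(sequence)
  m <- gregexpr("P+", sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(as_motif_hits(empty_hits()))
  run_start <- as.integer(m)
  run_len <- attr(m, "match.length")
  keep_len <- run_len >= consensus$min_prolines
  too_long <- run_len > consensus$max_prolines
  if (any(too_long & keep_len)) {
    if (long_runs == "drop") {
      keep_len <- keep_len & !too_long
    } else {
      warning(sprintf("%d proline run(s) longer than max_prolines = %d reported",
                      sum(too_long & keep_len), consensus$max_prolines),
              call. = FALSE)
    }
  }
  run_start <- run_start[keep_len]
  run_len <- run_len[keep_len]
  if (length(run_start) == 0) return(as_motif_hits(empty_hits()))

  chars <- strsplit(sequence, "")[[1]]
  w <- consensus$arg_window
  rows <- lapply(seq_along(run_start), function(i) {
    s <- run_start[i]; e <- s + run_len[i] - 1L
    pre_rng <- seq.int(max(1L, s - w), s - 1L)
    pre_rng <- pre_rng[pre_rng >= 1 & pre_rng < s]
    post_rng <- seq.int(e + 1L, min(length(chars), e + w))
    post_rng <- post_rng[post_rng > e & post_rng <= length(chars)]
    pre <- if (s > 1) pre_rng[chars[pre_rng] == "R"] else integer(0)
    post <- if (e < length(chars)) post_rng[chars[post_rng] == "R"] else integer(0)
    pre_arg <- if (length(pre)) max(pre) else NA_integer_   # nearest before
    post_arg <- if (length(post)) min(post) else NA_integer_ # nearest after
    if (consensus$require_pre_arg && is.na(pre_arg)) return(NULL)
    if (consensus$require_post_arg && is.na(post_arg)) return(NULL)
    h_start <- if (is.na(pre_arg)) s else pre_arg
    h_end <- if (is.na(post_arg)) e else post_arg
    data.frame(seq_id = seq_id, start = h_start, end = h_end,
               mode = "relaxed", proline_run = run_len[i],
               pre_arg_pos = pre_arg, post_arg_pos = post_arg,
               matched_text = substr(sequence, h_start, h_end),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(as_motif_hits(empty_hits()))
  out <- do.call(rbind, rows)
  as_motif_hits(out[order(out$start), , drop = FALSE])
}

#' Scan with a selectable mode
#'
#' @inheritParams scan_strict
#' @param mode `"strict"` or `"relaxed"`.
#' @param ... passed to the underlying scanner.
#' @return A `motif_hits` data frame.
#' @export
scan_prm <- function(sequence, consensus = consensus_definition(),
                     mode = c("strict", "relaxed"), seq_id = "seq", ...) {
  mode <- match.arg(mode)
  switch(mode,
         strict = scan_strict(sequence, consensus, seq_id),
         relaxed = scan_relaxed(sequence, consensus, seq_id, ...))
}

#' Count proline-rich motifs in a sequence
#'
#' @inheritParams scan_prm
#' @return Integer hit count.
#' @export
count_prms <- function(sequence, consensus = consensus_definition(),
                       mode = c("strict", "relaxed"), ...) {
  nrow(scan_prm(sequence, consensus, mode, ...))
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("%d proline-rich motif hit(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Scan every sequence of a FASTA file or named vector
#'
#' @param sequences path to a FASTA file, or a named character vector of
#'   sequences.
#' @inheritParams scan_prm
#' @return A `motif_hits` data frame over all sequences.
#' @export
scan_sequences <- function(sequences, consensus = consensus_definition(),
                           mode = c("strict", "relaxed"), ...) {
  mode <- match.arg(mode)
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- read_fasta(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  hits <- lapply(names(sequences), function(id)
    scan_prm(sequences[[id]], consensus, mode, seq_id = id, ...))
  as_motif_hits(do.call(rbind, c(hits, list(make.row.names = FALSE))))
}

#' Read protein sequences from FASTA
#'
#' @param file FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(file) {
  recs <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- toupper(vapply(recs, `[[`, character(1), 1))
  names(out) <- names(recs)
  out
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param file output path.
#' @export
write_fasta <- function(sequences, file) {
  seqinr::write.fasta(as.list(unname(sequences)), names = names(sequences),
                      file.out = file, as.string = TRUE)
  invisible(file)
}

#' Write motif hits as TSV
#'
#' Columns `seq_id, start, end, mode, proline_run, matched_text` with
#' 1-based inclusive coordinates.
#'
#' @param hits a `motif_hits` table.
#' @param file output path.
#' @export
write_hits_tsv <- function(hits, file) {
  utils::write.table(
    hits[, c("seq_id", "start", "end", "mode", "proline_run", "matched_text")],
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write motif hits as BED6
#'
#' Converts the 1-based inclusive hit coordinates to BED's 0-based
#' half-open convention; the score column carries the proline-run length.
#'
#' @param hits a `motif_hits` table.
#' @param file output path.
#' @export
write_hits_bed <- function(hits, file) {
  bed <- data.frame(chrom = hits$seq_id,
                    chromStart = hits$start - 1L,
                    chromEnd = hits$end,
                    name = paste0("PRM_", hits$mode),
                    score = hits$proline_run,
                    strand = ".")
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Count mismatches in an ungapped sequence comparison
#'
#' Position-by-position comparison of two equal-length sequences, e.g. the
#' SmN- and SmB-derived motif peptides that differ at the phi position only.
#'
#' @param a,b equal-length amino-acid strings.
#' @return Integer number of mismatching positions.
#' @export
count_mismatches <- function(a, b) {
  a <- validate_sequence(a); b <- validate_sequence(b)
  if (nchar(a) != nchar(b))
    stop("ungapped comparison needs equal-length sequences", call. = FALSE)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
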