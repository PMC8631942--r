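AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# consensus classes, Y at slot 3 of the 6-residue window
ITIM_REGEX <- "[SIVL].Y..[IVL]"
ITSM_REGEX <- "T.Y..[VI]"

#' Amino-acid molecular volumes
#'
#' Mean residue volumes (cubic Angstrom) of the 20 canonical amino acids
#' from the standard partial-volume compilation (Zamyatnin 1972), used for
#' the pY+1 size-dependence analysis.
#'
#' @return named numeric vector, one entry per residue (one-letter code).
#' @export
residue_volumes <- function() {
  c(G = 60.1, A = 88.6, S = 89.0, C = 108.5, D = 111.1, P = 112.7,
    N = 114.1, T = 116.1, E = 138.4, V = 140.0, Q = 143.8, H = 153.2,
    M = 162.9, I = 166.7, L = 166.7, K = 168.6, R = 173.4, F = 189.9,
    Y = 193.6, W = 227.8)
}

validate_sequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    stop_invalid("illegal character '", chars[bad[1]], "' at position ", bad[1])
  chars
}

#' Scan a protein sequence for ITIM and ITSM motifs
#'
#' Finds every window matching the inhibitory-motif consensus
#' `[SIVL]xYxx[IVL]` (ITIM) or the switch-motif consensus `TxYxx[VI]`
#' (ITSM), reporting tyrosine positions in full-protein numbering
#' (1-based; `offset` is the residue number of the first character of
#' `sequence`). Matches may overlap in sequence but each distinct tyrosine
#' is reported at most once per motif type. Windows matching both
#' consensus classes are reported under both.
#'
#' @param sequence amino-acid string (20-letter alphabet).
#' @param offset residue number of the first character (default 1).
#' @param protein label carried into the result.
#' @return data.frame `protein, motif, y_position, window, flank` where
#'   `window` is the 6-mer starting at pY-2 and `flank` the pY-2..pY+3
#'   context (identical here; kept as an explicit column).
#' @examples
#' scan_motifs("AAAVDYGELAAA", offset = 218)  # ITIM with Y at 223
#' @export
scan_motifs <- function(sequence, offset = 1, protein = "protein") {
  assert_that(offset >= 1, "offset must be >= 1")
  chars <- validate_sequence(sequence)
  seq_up <- paste(chars, collapse = "")
  hits <- lapply(c(ITIM = ITIM_REGEX, ITSM = ITSM_REGEX), function(rx) {
    m <- gregexpr(paste0("(?=(", rx, "))"), seq_up, perl = TRUE)[[1]]
    if (m[1] == -1) return(integer(0))
    as.integer(m)  # window start positions (1-based, overlapping allowed)
  })
  rows <- do.call(rbind, lapply(names(hits), function(type) {
    starts <- hits[[type]]
    if (!length(starts)) return(NULL)
    data.frame(protein = protein, motif = type,
               y_position = starts + 2L + (offset - 1L),
               window = vapply(starts, function(s) substr(seq_up, s, s + 5L), ""),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    return(data.frame(protein = character(0), motif = character(0),
                      y_position = integer(0), window = character(0),
                      flank = character(0)))
  rows <- rows[!duplicated(rows[c("motif", "y_position")]), , drop = FALSE]
  rows$flank <- rows$window
  rows <- rows[order(rows$y_position, rows$motif), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' ITIM-ITSM tyrosine spacing
#'
#' Number of residues separating the ITIM tyrosine from the ITSM tyrosine
#' (difference of their full-protein positions). In nearly all tandem
#' ITIM/ITSM receptors the ITIM lies N-terminal to the ITSM; the reversed
#' order is rejected.
#'
#' @param itim_hit,itsm_hit single rows from [scan_motifs()] output (or
#'   any list/data.frame with a `y_position` field).
#' @return integer residue count.
#' @examples
#' tyrosine_spacing(list(y_position = 223), list(y_position = 248))  # 25
#' @export
tyrosine_spacing <- function(itim_hit, itsm_hit) {
  y_itim <- itim_hit$y_position; y_itsm <- itsm_hit$y_position
  assert_that(length(y_itim) == 1 && length(y_itsm) == 1,
              "pass single motif hits")
  if (y_itsm <= y_itim)
    stop_invalid("orientation error: ITSM tyrosine (", y_itsm,
                 ") must lie C-terminal to ITIM tyrosine (", y_itim, ")")
  as.integer(y_itsm - y_itim)
}

#' Mismatches between two motif windows
#'
#' Position-wise mismatch count between two equal-length motif windows
#' aligned on their tyrosine (slot 3 of a 6-mer). Optionally excludes the
#' tyrosine slot so the count reflects only flanking residues.
#'
#' @param window_a,window_b character strings of equal length.
#' @param exclude_y drop slot 3 from the comparison (default FALSE).
#' @return integer mismatch count.
#' @examples
#' motif_hamming("VDYGEL", "IVYASL")  # 4
#' @export
motif_hamming <- function(window_a, window_b, exclude_y = FALSE) {
  a <- validate_sequence(window_a); b <- validate_sequence(window_b)
  if (length(a) != length(b)) stop_invalid("window lengths differ")
  idx <- seq_along(a)
  if (exclude_y) idx <- idx[idx != 3L]
  sum(a[idx] != b[idx])
}

#' Bell-shape analysis of pY+1 residue volume
#'
#' Least-squares quadratic of a recruitment readout (e.g. normalized
#' effector fluorescence) against the molecular volume of the residue at
#' the pY+1 position. A concave-down fit has a vertex (peak) volume; the
#' residues nearest the vertex are reported. A concave-up or degenerate
#' fit yields a no-peak result.
#'
#' @param variants data.frame with columns `residue` (one-letter code at
#'   pY+1) and `fi` (mean normalized readout); >= 4 distinct residues.
#' @param table named volume vector, default [residue_volumes()].
#' @return list: `coefficients` (intercept, linear, quadratic),
#'   `peak_volume` (NA if no peak), `peak_residues` (codes nearest the
#'   vertex, ties included), `concave_down`, `in_range` (vertex inside the
#'   data range), `fitted` data.frame.
#' @export
py1_volume_curve <- function(variants, table = residue_volumes()) {
  assert_that(all(c("residue", "fi") %in% names(variants)),
              "variants needs columns residue, fi")
  res <- toupper(variants$residue)
  assert_that(all(res %in% names(table)), "unknown residue code")
  assert_that(length(unique(res)) >= 4, "need >= 4 distinct residues")
  v <- unname(table[res]); fi <- variants$fi
  fit <- stats::lm(fi ~ v + I(v^2))
  co <- stats::coef(fit)
  quad <- unname(co[3])
  concave_down <- is.finite(quad) && quad < 0
  if (!concave_down) {
    warning("fit is not concave-down: no peak")
    return(list(coefficients = co, peak_volume = NA_real_,
                peak_residues = character(0), concave_down = FALSE,
                in_range = NA,
                fitted = data.frame(residue = res, volume = v,
                                    fi = fi, fitted = stats::fitted(fit))))
  }
  vertex <- -unname(co[2]) / (2 * quad)
  in_range <- vertex >= min(v) && vertex <= max(v)
  if (!in_range) warning("vertex lies outside the data range")
  d <- abs(table - vertex)
  peak <- names(table)[d <= min(d) + 1]  # ties within 1 A^3
  list(coefficients = co, peak_volume = vertex, peak_residues = sort(peak),
       concave_down = TRUE, in_range = in_range,
       fitted = data.frame(residue = res, volume = v, fi = fi,
                           fitted = stats::fitted(fit)))
}

#' Read protein sequences from FASTA
#'
#' Uses Biostrings when installed, otherwise a minimal internal reader.
#' A numeric `offset=<n>` token in a FASTA header is parsed into the
#' `offset` column (residue number of the sequence's first position),
#' defaulting to 1.
#'
#' @param path FASTA file.
#' @return data.frame `name, sequence, offset`.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    headers <- names(ss)
    seqs <- as.character(ss)
  } else {
    lines <- readLines(path)
    hdr_idx <- grep("^>", lines)
    headers <- sub("^>", "", lines[hdr_idx])
    bounds <- c(hdr_idx, length(lines) + 1L)
    seqs <- vapply(seq_along(hdr_idx), function(i)
      paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = ""), "")
  }
  off <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("offset=[0-9]+", h))
    if (length(m)) as.integer(sub("offset=", "", m)) else 1L
  }, 0L)
  data.frame(name = vapply(strsplit(headers, "\\s+"), `[[`, "", 1),
             sequence = unname(seqs), offset = unname(off),
             stringsAsFactors = FALSE)
}

#' Scan a FASTA file for ITIM/ITSM motifs
#'
#' @param path FASTA file (headers may carry `offset=<n>`).
#' @return combined [scan_motifs()] output for all records.
#' @export
scan_fasta <- function(path) {
  fa <- read_fasta(path)
  do.call(rbind, lapply(seq_len(nrow(fa)), function(i)
    scan_motifs(fa$sequence[i], offset = fa$offset[i], protein = fa$name[i])))
}
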