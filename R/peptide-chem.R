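## Peptide physicochemistry backing the mass-spectrometry tables:
## Kyte-Doolittle GRAVY, monoisotopic masses from elemental composition,
## modification mass deltas, m/z of charged ions, and ppm peak matching.

#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector of Kyte-Doolittle hydropathy values for the 20
#' standard residues (I 4.5 ... R -4.5), the scale underlying the GRAVY
#' index and the C-terminal hydrophobic-stretch rule of SHP annotation.
#'
#' @export
kyteDoolittle <- c(
  I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5,
  M =  1.9, A =  1.8, G = -0.4, T = -0.7, S = -0.8,
  W = -0.9, Y = -1.3, P = -1.6, H = -3.2, E = -3.5,
  Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

#' Monoisotopic atomic masses
#'
#' Monoisotopic masses (Da) of H, C, N, O, S plus the proton mass used
#' for m/z computation.
#'
#' @export
atomicMasses <- c(
  H = 1.0078250319, C = 12.0, N = 14.0030740052,
  O = 15.9949146221, S = 31.97207069
)

#' @rdname atomicMasses
#' @export
protonMass <- 1.00727646688

## residue (= amino acid minus water) elemental compositions, H C N O S
.residueFormulas <- local({
  f <- rbind(
    G = c(3, 2, 1, 1, 0),  A = c(5, 3, 1, 1, 0),  S = c(5, 3, 1, 2, 0),
    P = c(7, 5, 1, 1, 0),  V = c(9, 5, 1, 1, 0),  T = c(7, 4, 1, 2, 0),
    C = c(5, 3, 1, 1, 1),  L = c(11, 6, 1, 1, 0), I = c(11, 6, 1, 1, 0),
    N = c(6, 4, 2, 2, 0),  D = c(5, 4, 1, 3, 0),  Q = c(8, 5, 2, 2, 0),
    K = c(12, 6, 2, 1, 0), E = c(7, 5, 1, 3, 0),  M = c(9, 5, 1, 1, 1),
    H = c(7, 6, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(12, 6, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(10, 11, 2, 1, 0)
  )
  colnames(f) <- c("H", "C", "N", "O", "S")
  f
})

.residueMasses <- drop(.residueFormulas %*% atomicMasses[colnames(.residueFormulas)])
.waterMass <- 2 * atomicMasses[["H"]] + atomicMasses[["O"]]

.checkResidues <- function(peptide, allowed) {
  res <- strsplit(peptide, "")[[1]]
  bad <- which(!(res %in% allowed))
  if (length(bad))
    stop("non-standard residue(s) '", paste(res[bad], collapse = ","),
         "' at position(s) ", paste(bad, collapse = ","), call. = FALSE)
  res
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy values over the
#' residues of a peptide, as reported for mature SHP sequences.
#'
#' @param peptide character string over the 20 standard residues.
#' @return a single numeric GRAVY value.
#' @examples
#' gravy("DIIIIVGG")   # 2.2375
#' @export
gravy <- function(peptide) {
  res <- .checkResidues(peptide, names(kyteDoolittle))
  mean(kyteDoolittle[res])
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, derived from the
#' residue elemental compositions and the monoisotopic atomic masses.
#'
#' @param peptide character string over the 20 standard residues.
#' @return neutral monoisotopic mass in Da.
#' @export
monoisotopicMass <- function(peptide) {
  res <- .checkResidues(peptide, names(.residueMasses))
  sum(.residueMasses[res]) + .waterMass
}

#' Mass delta of a post-translational modification
#'
#' Converts an elemental loss formula (e.g. `"H2"`, `"H4"`, `"N2H2"`)
#' into a signed monoisotopic mass delta: the negative of the summed
#' masses of the lost atoms. These deltas correspond to the intramolecular
#' crosslinks of RaS-RiPPs (C-C and C-S bonds, Arg to N-methyl-ornithine).
#'
#' @param elementalLoss formula over H, C, N, O, S such as `"N2H2"`.
#' @return signed mass delta in Da (negative for a loss).
#' @examples
#' modificationDelta("H2")    # -2.01565 (streptide-type crosslink)
#' modificationDelta("N2H2")  # -30.0218 (enteropeptin-type)
#' @export
modificationDelta <- function(elementalLoss) {
  if (!grepl("^([HCNOS][0-9]*)+$", elementalLoss))
    stop("formula must be over elements H, C, N, O, S", call. = FALSE)
  m <- gregexpr("[HCNOS][0-9]*", elementalLoss)[[1]]
  parts <- regmatches(elementalLoss, list(m))[[1]]
  elems <- substr(parts, 1, 1)
  counts <- as.integer(sub("^[A-Z]", "", parts))
  counts[is.na(counts)] <- 1L
  -sum(atomicMasses[elems] * counts)
}

#' m/z of a (modified) peptide ion
#'
#' `(M + delta + z * proton) / z` for neutral monoisotopic mass M,
#' modification mass delta and charge z. The monocharged (z = 1) value
#' is the one used to extract ion chromatograms of mature SHPs.
#'
#' @param peptide character string over the 20 standard residues.
#' @param modification optional elemental loss formula as in
#'   [modificationDelta()], or a numeric mass delta in Da, or `NULL`.
#' @param charge positive integer charge state.
#' @return m/z value.
#' @export
mzValue <- function(peptide, modification = NULL, charge = 1L) {
  stopifnot(charge >= 1)
  delta <- 0
  if (!is.null(modification))
    delta <- if (is.numeric(modification)) modification
             else modificationDelta(modification)
  (monoisotopicMass(peptide) + delta + charge * protonMass) / charge
}

#' Match observed m/z peaks to candidate ions
#'
#' Assigns each observed m/z value to every candidate ion within a ppm
#' tolerance. Many-to-many assignments are allowed; observations matched
#' by more than one candidate are flagged ambiguous.
#'
#' @param observed numeric vector of observed m/z values.
#' @param candidates data.frame with columns `id` and `mz` (theoretical).
#' @param tolPpm tolerance in parts per million (default 10).
#' @return data.frame with columns `observed`, `candidate_id`, `mz_theoretical`,
#'   `ppm_error`, `ambiguous`; unmatched observations get `NA` candidate.
#' @export
matchPeaks <- function(observed, candidates, tolPpm = 10) {
  stopifnot(tolPpm > 0, all(c("id", "mz") %in% names(candidates)))
  out <- lapply(seq_along(observed), function(i) {
    ppm <- (observed[i] - candidates$mz) / candidates$mz * 1e6
    hit <- which(abs(ppm) <= tolPpm)
    if (!length(hit))
      return(data.frame(observed = observed[i], candidate_id = NA_character_,
                        mz_theoretical = NA_real_, ppm_error = NA_real_,
                        ambiguous = FALSE))
    data.frame(observed = observed[i],
               candidate_id = as.character(candidates$id[hit]),
               mz_theoretical = candidates$mz[hit],
               ppm_error = ppm[hit],
               ambiguous = length(hit) > 1L)
  })
  do.call(rbind, out)
}
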