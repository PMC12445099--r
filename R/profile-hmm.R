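## Generic RRNPP detection profile: build a profile HMM from a bait
## alignment, calibrate E-values on random sequences, search proteomes
## with the in-repo local Viterbi/forward-backward engine, filter hits
## and derive the consensus-filtered column mask.

#' Robinson-Robinson amino-acid background frequencies
#'
#' Standard background residue distribution used for match-emission
#' pseudocounts, insert emissions and E-value calibration sequences.
#'
#' @export
robinsonRobinson <- local({
  f <- c(A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
         G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
         M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
         S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)
  f / sum(f)
})

.encodeProtein <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], AA20)
  idx[is.na(idx)] <- 0L     # X and friends -> code -1 after shift
  as.integer(idx - 1L)
}

#' Read a bait multiple alignment
#'
#' Aligned FASTA whose headers carry `id family subfamily` separated by
#' whitespace (family one of Rgg, ComR, PlcR, PrgX).
#'
#' @param path aligned FASTA file.
#' @return data.frame with columns `bait_id`, `family`, `subfamily`,
#'   `aligned`.
#' @export
readBaitAlignment <- function(path) {
  recs <- readFasta(path, type = "AA")
  parts <- strsplit(names(recs), "\\s+")
  data.frame(
    bait_id = vapply(parts, `[`, character(1), 1),
    family = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                    character(1)),
    subfamily = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                       character(1)),
    aligned = unname(recs), stringsAsFactors = FALSE)
}

#' @rdname readBaitAlignment
#' @param baits data.frame as returned by `readBaitAlignment`.
#' @export
writeBaitAlignment <- function(baits, path) {
  headers <- paste(baits$bait_id, baits$family, baits$subfamily)
  writeFasta(stats::setNames(baits$aligned, headers), path, type = "AA")
}

#' Build a profile HMM from a bait alignment
#'
#' Match states are the alignment columns with gap fraction <= 0.5.
#' Match emissions are column residue frequencies blended with the
#' Robinson-Robinson background through `pseudocountWeight`; insert
#' emissions equal the background. Transitions are estimated from the
#' observed gap structure with Laplace (+1) smoothing.
#'
#' @param baits data.frame with at least the column `aligned` (equal-length
#'   gapped rows, gap character "-"); see [readBaitAlignment()].
#' @param pseudocountWeight total weight of the background pseudocount
#'   added to each match column (default 5, emulating the soft Dirichlet
#'   priors of standard profile builders; a small alignment with harsh
#'   pseudocounts over-penalizes mismatches and truncates local
#'   alignments of true homologs).
#' @param background length-20 background distribution.
#' @return a [ProfileHMM].
#' @export
buildProfile <- function(baits, pseudocountWeight = 5,
                         background = robinsonRobinson) {
  aln <- toupper(baits$aligned)
  if (length(aln) < 2L) stop("alignment needs at least 2 rows", call. = FALSE)
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned rows differ in length", call. = FALSE)
  chars <- do.call(rbind, strsplit(aln, ""))
  gapFrac <- colMeans(chars == "-")
  matchCols <- which(gapFrac <= 0.5)
  if (!length(matchCols))
    stop("no alignment column has gap fraction <= 0.5", call. = FALSE)
  M <- length(matchCols)
  bg <- background[AA20] / sum(background[AA20])
  em <- matrix(0, M, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(M)) {
    col <- chars[, matchCols[k]]
    cnt <- table(factor(col[col %in% AA20], levels = AA20))
    p <- as.numeric(cnt) + pseudocountWeight * bg
    em[k, ] <- p / sum(p)
  }
  ## transition counts per junction between consecutive match columns
  isMatch <- chars[, matchCols, drop = FALSE] != "-"
  cnt <- list(MM = rep(0, M - 1), MI = rep(0, M - 1), MD = rep(0, M - 1),
              IM = rep(0, M - 1), II = rep(0, M - 1),
              DM = rep(0, M - 1), DD = rep(0, M - 1))
  if (M > 1) {
    for (k in seq_len(M - 1)) {
      between <- if (matchCols[k + 1] - matchCols[k] > 1)
        chars[, (matchCols[k] + 1):(matchCols[k + 1] - 1), drop = FALSE]
        else NULL
      nIns <- if (is.null(between)) rep(0L, nrow(chars))
              else rowSums(between != "-")
      for (r in seq_len(nrow(chars))) {
        a <- isMatch[r, k]; b <- isMatch[r, k + 1]; ni <- nIns[r]
        if (ni > 0 && a) {
          cnt$MI[k] <- cnt$MI[k] + 1
          cnt$II[k] <- cnt$II[k] + (ni - 1)
          cnt$IM[k] <- cnt$IM[k] + 1
        } else if (a && b) cnt$MM[k] <- cnt$MM[k] + 1
        else if (a && !b) cnt$MD[k] <- cnt$MD[k] + 1
        else if (!a && b) cnt$DM[k] <- cnt$DM[k] + 1
        else cnt$DD[k] <- cnt$DD[k] + 1
      }
    }
  }
  trans <- list(
    MM = (cnt$MM + 1) / (cnt$MM + cnt$MI + cnt$MD + 3),
    MI = (cnt$MI + 1) / (cnt$MM + cnt$MI + cnt$MD + 3),
    MD = (cnt$MD + 1) / (cnt$MM + cnt$MI + cnt$MD + 3),
    IM = (cnt$IM + 1) / (cnt$IM + cnt$II + 2),
    II = (cnt$II + 1) / (cnt$IM + cnt$II + 2),
    DM = (cnt$DM + 1) / (cnt$DM + cnt$DD + 2),
    DD = (cnt$DD + 1) / (cnt$DM + cnt$DD + 2))
  methods::new("ProfileHMM",
    matchEmissions = em, insertEmissions = unname(bg),
    transitions = trans, matchColumnMap = as.integer(matchCols),
    background = unname(bg), calibration = NULL)
}

## log-space score model handed to the C++ engine
.scoreModel <- function(profile) {
  M <- profileLength(profile)
  bg <- profile@background
  mlo <- log(sweep(profile@matchEmissions, 2, bg, "/"))
  ilo <- log(profile@insertEmissions / bg)
  tr <- lapply(profile@transitions, log)
  k <- seq_len(M)
  entry <- log(2 * (M - k + 1) / (M * (M + 1)))
  list(mlo = unname(mlo), ilo = ilo, tr = tr, entry = entry, M = M)
}

.viterbiBits <- function(sm, seqs) {
  enc <- lapply(seqs, .encodeProtein)
  .hmm_viterbi_scores(enc, sm$mlo, sm$ilo, sm$tr, sm$entry) / log(2)
}

#' Calibrate profile E-values on random sequences
#'
#' Viterbi bit scores of `nRandom` i.i.d. background-composition
#' sequences are fitted to a Gumbel law by maximum likelihood. The
#' E-value of a bit score s against a database of D sequences is then
#' `D * exp(-lambda * (s - mu))`.
#'
#' @param profile a [ProfileHMM].
#' @param nRandom number of random sequences (>= 100, default 1000).
#' @param seed RNG seed recorded in the calibration.
#' @param lengths integer vector of lengths to sample target lengths
#'   from (default 300).
#' @param dbSize default database size for reported E-values.
#' @return the profile with its `calibration` slot set.
#' @export
calibrateEvalues <- function(profile, nRandom = 1000L, seed = 42L,
                             lengths = 300L, dbSize = 1L) {
  stopifnot(nRandom >= 100L)
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(seed)
  bg <- profile@background
  lens <- sample(rep(lengths, length.out = nRandom))
  seqs <- vapply(lens, function(L)
    paste(sample(AA20, L, replace = TRUE, prob = bg), collapse = ""),
    character(1))
  sm <- .scoreModel(profile)
  scores <- .viterbiBits(sm, seqs)
  if (stats::var(scores) < 1e-12)
    stop("degenerate score distribution; cannot calibrate", call. = FALSE)
  fit <- .gumbelFit(scores)
  calib <- methods::new("CalibrationParams",
    mu = fit$mu, lambda = 1 / fit$beta,
    nRandom = as.integer(nRandom), randomSeed = as.integer(seed),
    dbSize = as.integer(dbSize))
  profile@calibration <- calib
  profile
}

## Gumbel (max domain) maximum-likelihood fit
.gumbelFit <- function(x) {
  g <- function(beta) beta - mean(x) + sum(x * exp(-x / beta)) / sum(exp(-x / beta))
  s <- stats::sd(x)
  beta <- stats::uniroot(g, c(s / 100, s * 10), tol = 1e-10)$root
  mu <- -beta * log(mean(exp(-x / beta)))
  list(mu = mu, beta = beta)
}

#' E-value of a bit score
#'
#' @param bitScore numeric vector of bit scores.
#' @param calib a [CalibrationParams].
#' @param dbSize database size D (number of sequences searched).
#' @return E-values, monotone decreasing in the bit score and
#'   proportional to D.
#' @export
evalueOf <- function(bitScore, calib, dbSize = calib@dbSize) {
  dbSize * exp(-calib@lambda * (bitScore - calib@mu))
}

#' Search a proteome with a calibrated profile HMM
#'
#' Per target the best local Viterbi alignment over the profile state
#' graph is computed; per-match-state posteriors come from
#' forward-backward over the same graph. Hits with E-value below a
#' permissive reporting floor are returned.
#'
#' @param profile a calibrated [ProfileHMM].
#' @param proteome data.frame with columns `protein_id`, `genome_id`,
#'   `sequence` (see [extractProteome()]).
#' @param evalueFloor reporting floor (default 10).
#' @param dbSize database size for E-values; defaults to the number of
#'   proteins searched.
#' @return data.frame of hits: `protein_id`, `genome_id`, `bit_score`,
#'   `evalue`, `profile_start`, `profile_end`, `target_start`,
#'   `target_end`, `coverage`, `aligned_row` (length-M string over
#'   residues and "-"), plus a list column `posteriors` of M floats.
#' @export
searchProfile <- function(profile, proteome, evalueFloor = 10,
                          dbSize = nrow(proteome)) {
  calib <- calibration(profile)
  if (is.null(calib))
    stop("profile must be calibrated first (calibrateEvalues)", call. = FALSE)
  sm <- .scoreModel(profile)
  empty <- data.frame(protein_id = character(0), genome_id = character(0),
                      bit_score = numeric(0), evalue = numeric(0),
                      profile_start = integer(0), profile_end = integer(0),
                      target_start = integer(0), target_end = integer(0),
                      coverage = numeric(0), aligned_row = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(proteome) == 0L) { empty$posteriors <- list(); return(empty) }
  bits <- .viterbiBits(sm, proteome$sequence)
  ev <- evalueOf(bits, calib, dbSize)
  keep <- which(ev <= evalueFloor)
  if (!length(keep)) { empty$posteriors <- list(); return(empty) }
  rows <- lapply(keep, function(i) {
    enc <- .encodeProtein(proteome$sequence[i])
    vit <- .hmm_viterbi(enc, sm$mlo, sm$ilo, sm$tr, sm$entry, TRUE)
    fb <- .hmm_forward_backward(enc, sm$mlo, sm$ilo, sm$tr, sm$entry)
    row <- rep("-", sm$M)
    res <- strsplit(proteome$sequence[i], "")[[1]]
    mc <- vit$match_cols; mr <- vit$match_res
    row[mc[mr > 0]] <- res[mr[mr > 0]]
    ps <- vit$profile_start; pe <- vit$profile_end
    data.frame(protein_id = proteome$protein_id[i],
               genome_id = proteome$genome_id[i],
               bit_score = bits[i], evalue = ev[i],
               profile_start = ps, profile_end = pe,
               target_start = vit$target_start, target_end = vit$target_end,
               coverage = (pe - ps + 1) / sm$M,
               aligned_row = paste(row, collapse = ""),
               posteriors = I(list(fb$posteriors)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter reported hits
#'
#' Keeps statistically significant hits aligned to the entire or nearly
#' entire profile: E-value <= `evalueMax`, alignment starting from
#' profile position <= `profileStartMax`, and profile coverage >=
#' `coverageMin`. All three boundaries are inclusive. Idempotent and
#' order preserving.
#'
#' @param hits data.frame from [searchProfile()].
#' @param evalueMax maximum E-value (default 1e-5).
#' @param profileStartMax maximum profile start position (default 10).
#' @param coverageMin minimum profile coverage (default 0.90).
#' @return the filtered hits, original order preserved.
#' @export
filterHits <- function(hits, evalueMax = 1e-5, profileStartMax = 10L,
                       coverageMin = 0.90) {
  stopifnot(evalueMax > 0, profileStartMax > 0,
            coverageMin > 0, coverageMin <= 1)
  keep <- hits$evalue <= evalueMax &
    hits$profile_start <= profileStartMax &
    hits$coverage >= coverageMin
  hits[keep, , drop = FALSE]
}

#' Consensus-filtered column mask
#'
#' A profile column is retained iff the mean forward-backward posterior,
#' over the hits whose alignment spans the column, is at least
#' `ppThreshold`. If no column meets the threshold the single best
#' column is kept so the mask is never empty.
#'
#' @param hits filtered hits data.frame (>= 1 row) with `posteriors`.
#' @param ppThreshold mean-posterior threshold (default 0.85).
#' @return list with `mask` (logical over profile columns),
#'   `meanPosterior` and `ppThreshold`.
#' @export
retainedColumns <- function(hits, ppThreshold = 0.85) {
  stopifnot(nrow(hits) >= 1L)
  M <- nchar(hits$aligned_row[1])
  pp <- matrix(NA_real_, nrow(hits), M)
  for (i in seq_len(nrow(hits))) {
    span <- hits$profile_start[i]:hits$profile_end[i]
    pp[i, span] <- hits$posteriors[[i]][span]
  }
  mp <- colMeans(pp, na.rm = TRUE)
  mp[is.nan(mp)] <- 0
  mask <- mp >= ppThreshold
  if (!any(mask)) mask[which.max(mp)] <- TRUE
  list(mask = mask, meanPosterior = mp, ppThreshold = ppThreshold)
}

#' Hit alignment projected onto retained columns
#'
#' @param hits filtered hits data.frame.
#' @param mask logical column mask from [retainedColumns()] (its `mask`
#'   element), or `NULL` to keep all columns.
#' @return character matrix, rows named by `protein_id`, one column per
#'   retained match state, entries residues or "-".
#' @export
alignedHitMatrix <- function(hits, mask = NULL) {
  rows <- do.call(rbind, strsplit(hits$aligned_row, ""))
  rownames(rows) <- hits$protein_id
  if (!is.null(mask)) rows <- rows[, mask, drop = FALSE]
  rows
}

#' Serialize / read a profile HMM as text
#'
#' Documented plain-text round-trip format: emissions and transitions to
#' 6 decimals.
#'
#' @param profile a [ProfileHMM].
#' @param path file path.
#' @export
writeProfileHMM <- function(profile, path) {
  con <- file(path, "w"); on.exit(close(con))
  M <- profileLength(profile)
  writeLines(c("RRNPPminer-profile 1", paste("M", M),
               paste("ALPHABET", paste(AA20, collapse = " ")),
               paste("MAP", paste(profile@matchColumnMap, collapse = " ")),
               paste("BACKGROUND", paste(sprintf("%.6f", profile@background),
                                         collapse = " ")),
               paste("INSERT", paste(sprintf("%.6f", profile@insertEmissions),
                                     collapse = " "))), con)
  for (k in seq_len(M))
    writeLines(paste("MATCH", k, paste(sprintf("%.6f", profile@matchEmissions[k, ]),
                                       collapse = " ")), con)
  for (nm in names(profile@transitions))
    writeLines(paste("TRANS", nm,
                     paste(sprintf("%.6f", profile@transitions[[nm]]),
                           collapse = " ")), con)
  calib <- calibration(profile)
  if (!is.null(calib))
    writeLines(sprintf("CALIB %.6f %.6f %d %d %d", calib@mu, calib@lambda,
                       calib@nRandom, calib@randomSeed, calib@dbSize), con)
  invisible(path)
}

#' @rdname writeProfileHMM
#' @export
readProfileHMM <- function(path) {
  lines <- readLines(path)
  val <- function(tag) sub(paste0("^", tag, " "), "",
                           grep(paste0("^", tag, " "), lines, value = TRUE))
  nums <- function(x) as.numeric(strsplit(trimws(x), "\\s+")[[1]])
  M <- as.integer(val("M"))
  em <- do.call(rbind, lapply(val("MATCH"), function(l) nums(l)[-1]))
  em <- em / rowSums(em)
  colnames(em) <- AA20
  tl <- val("TRANS")
  trNames <- sub(" .*$", "", tl)
  trans <- stats::setNames(lapply(tl, function(l)
    nums(sub("^\\S+ ", "", l))), trNames)
  bg <- nums(val("BACKGROUND")); bg <- bg / sum(bg)
  ins <- nums(val("INSERT")); ins <- ins / sum(ins)
  p <- methods::new("ProfileHMM", matchEmissions = em,
    insertEmissions = ins, transitions = trans,
    matchColumnMap = as.integer(nums(val("MAP"))),
    background = bg, calibration = NULL)
  cl <- val("CALIB")
  if (length(cl)) {
    cv <- nums(cl)
    p@calibration <- methods::new("CalibrationParams", mu = cv[1],
      lambda = cv[2], nRandom = as.integer(cv[3]),
      randomSeed = as.integer(cv[4]), dbSize = as.integer(cv[5]))
  }
  p
}

## RNG bookkeeping so seeded internals do not disturb the caller's stream
.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
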