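## Short-CDS (7-60 aa) detection on both strands with a two-class
## sequence-composition model: a coding model (codon usage, or
## position-specific nucleotide distributions) against an order-k
## Markov background chain, combined through a coding prior into a
## posterior "confidence" per open reading frame. The minus strand is
## handled by scoring positive-strand predictions on the reverse
## complement with exactly the same model, so strand symmetry is exact.

.NT <- c("A", "C", "G", "T")

#' Detection configuration for short CDSs
#'
#' @param minLenAa minimum protein length (default 7; shorter
#'   predictions are discarded).
#' @param maxLenAa maximum protein length (default 60).
#' @param confidenceMin posterior confidence threshold (default 0.01).
#' @param startCodons,stopCodons codon sets.
#' @return list of detection parameters.
#' @export
detectionConfig <- function(minLenAa = 7L, maxLenAa = 60L,
                            confidenceMin = 0.01,
                            startCodons = c("ATG", "GTG", "TTG"),
                            stopCodons = c("TAA", "TAG", "TGA")) {
  stopifnot(minLenAa <= maxLenAa, confidenceMin > 0, confidenceMin < 1)
  list(minLenAa = as.integer(minLenAa), maxLenAa = as.integer(maxLenAa),
       confidenceMin = confidenceMin, startCodons = startCodons,
       stopCodons = stopCodons)
}

.SENSE_CODONS <- local({
  all <- as.vector(outer(outer(.NT, .NT, paste0), .NT, paste0))
  sort(setdiff(all, c("TAA", "TAG", "TGA")))
})

#' Train the short-CDS composition model
#'
#' Coding emissions are estimated from the codons of the annotated CDS
#' features of the training genomes (61 sense codons, Laplace
#' smoothed); the background is an order-`backgroundOrder` Markov chain
#' over nucleotides estimated from the full genome sequences.
#'
#' @param genomes list of [GenomeRecord] objects with annotated CDSs.
#' @param mode `"codon"` (61-codon usage, default) or `"positional"`
#'   (3 x 4 nucleotide-by-codon-position distributions).
#' @param backgroundOrder Markov order k of the background (default 2).
#' @param priorCoding prior probability of coding (default 0.5, so the
#'   confidence threshold is purely likelihood-ratio driven).
#' @return a [CdsCompositionModel].
#' @export
trainCdsModel <- function(genomes, mode = c("codon", "positional"),
                          backgroundOrder = 2L, priorCoding = 0.5) {
  mode <- match.arg(mode)
  if (methods::is(genomes, "GenomeRecord")) genomes <- list(genomes)
  codonCounts <- stats::setNames(rep(0, length(.SENSE_CODONS)), .SENSE_CODONS)
  posCounts <- matrix(0, 3, 4, dimnames = list(NULL, .NT))
  k <- as.integer(backgroundOrder)
  kmers <- .allKmers(k)
  transCounts <- matrix(0, length(kmers), 4, dimnames = list(kmers, .NT))
  initCounts <- stats::setNames(rep(0, length(kmers)), kmers)
  nCds <- 0L
  for (g in genomes) {
    ft <- featureTable(g)
    seqs <- as.character(contigs(g))
    for (i in seq_len(nrow(ft))) {
      cds <- substr(seqs[[ft$contig_id[i]]], ft$start[i] + 1L, ft$end[i])
      if (ft$strand[i] == "-") cds <- revcomp(cds)
      n <- nchar(cds)
      if (n < 6L || n %% 3L != 0L) next
      nCds <- nCds + 1L
      codons <- substring(cds, seq(1L, n - 3L, 3L), seq(3L, n - 3L, 3L))
      codons <- codons[codons %in% .SENSE_CODONS]
      tab <- table(codons)
      codonCounts[names(tab)] <- codonCounts[names(tab)] + as.numeric(tab)
      for (p in 1:3) {
        tabp <- table(factor(substr(codons, p, p), levels = .NT))
        posCounts[p, ] <- posCounts[p, ] + as.numeric(tabp)
      }
    }
    for (s in seqs) {
      enc <- .encodeDna(s)
      ok <- !is.na(enc)
      ctx <- .contextIndex(enc, k)
      valid <- which(!is.na(ctx) & ok & seq_along(enc) > k)
      t2 <- table(factor(ctx[valid], levels = seq_along(kmers)),
                  factor(enc[valid], levels = 1:4))
      transCounts <- transCounts + as.matrix(t2)
      iv <- ctx[!is.na(ctx)]
      ti <- table(factor(iv, levels = seq_along(kmers)))
      initCounts <- initCounts + as.numeric(ti)
    }
  }
  if (nCds == 0L)
    stop("no annotated CDS in the training genomes", call. = FALSE)
  codonUsage <- (codonCounts + 1) / sum(codonCounts + 1)
  posEm <- sweep(posCounts + 1, 1, rowSums(posCounts + 1), "/")
  transCounts <- matrix(as.numeric(transCounts), nrow(transCounts),
                        ncol(transCounts),
                        dimnames = dimnames(transCounts))
  trans <- sweep(transCounts + 1, 1, rowSums(transCounts + 1), "/")
  init <- (initCounts + 1) / sum(initCounts + 1)
  methods::new("CdsCompositionModel", mode = mode,
    codonUsage = codonUsage, positionalEmissions = posEm,
    backgroundOrder = k, backgroundTransitions = trans,
    backgroundInit = unname(init), priorCoding = priorCoding,
    trainingGenomeIds = vapply(genomes, genomeId, character(1)))
}

.allKmers <- function(k) {
  km <- .NT
  if (k > 1) for (i in 2:k) km <- as.vector(outer(km, .NT, paste0))
  sort(km)
}

.encodeDna <- function(seq) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  enc <- code[utf8ToInt(toupper(seq))]
  enc[enc == 0L] <- NA_integer_
  enc
}

## index of the k-mer ending at position i-1 (context for position i),
## NA where the context is incomplete or contains N
.contextIndex <- function(enc, k) {
  n <- length(enc)
  ctx <- rep(NA_real_, n)
  if (n <= k) return(ctx)
  acc <- rep(0, n)
  ok <- rep(TRUE, n)
  for (d in 1:k) {
    ## char d positions back contributes 4^(d-1): the oldest character
    ## (d = k) is the most significant digit of the k-mer index
    prev <- c(rep(NA_integer_, d), enc[seq_len(n - d)])
    acc <- acc + ifelse(is.na(prev), 0, (prev - 1)) * 4^(d - 1)
    ok <- ok & !is.na(prev)
  }
  ctx[ok] <- acc[ok] + 1
  ctx
}

## per-contig score preparation: cumulative background and coding terms
.prepScores <- function(seq, model) {
  enc <- .encodeDna(seq)
  n <- length(enc)
  k <- model@backgroundOrder
  ## marginal nucleotide distribution = init k-mer mass by last character
  kmers <- .allKmers(k)
  margNt <- as.numeric(tapply(model@backgroundInit,
                              substr(kmers, k, k), sum)[.NT])
  lmarg <- log(margNt)
  lpMarg <- ifelse(is.na(enc), log(0.25), lmarg[enc])
  ctx <- .contextIndex(enc, k)
  lpCond <- lpMarg
  has <- !is.na(ctx) & !is.na(enc)
  lpCond[has] <- log(model@backgroundTransitions[cbind(ctx[has], enc[has])])
  cumMarg <- cumsum(lpMarg)
  cumCond <- cumsum(lpCond)
  ## per-position coding log prob of the codon starting at i
  lcu <- rep(log(1 / 64), n)   # fallback for N-containing codons
  if (n >= 3L) {
    i <- seq_len(n - 2L)
    c1 <- enc[i]; c2 <- enc[i + 1L]; c3 <- enc[i + 2L]
    okc <- !is.na(c1) & !is.na(c2) & !is.na(c3)
    idx <- (c1 - 1L) * 16L + (c2 - 1L) * 4L + c3
    if (model@mode == "codon") {
      ## codon strings indexed by (c1-1)*16 + (c2-1)*4 + c3
      codonStrings <- paste0(rep(.NT, each = 16),
                             rep(rep(.NT, each = 4), 4),
                             rep(.NT, 16))
      lu <- log(ifelse(codonStrings %in% names(model@codonUsage),
                       model@codonUsage[codonStrings], NA))
      lu[is.na(lu)] <- -Inf           # stop codons cannot be coding-emitted
      lcu[i[okc]] <- lu[idx[okc]]
    } else {
      lp <- log(model@positionalEmissions)
      v <- rep(NA_real_, length(i))
      v[okc] <- lp[1, c1[okc]] + lp[2, c2[okc]] + lp[3, c3[okc]]
      lcu[i[okc]] <- v[okc]
    }
  }
  list(enc = enc, n = n, k = k, cumMarg = cumMarg, cumCond = cumCond,
       lcu = lcu)
}

.marginalWeights <- function(k) seq_len(4^k)

## background log-likelihood of the substring [s, e] (1-based inclusive):
## marginal for the first k positions, conditional afterwards
.bgLogLik <- function(prep, s, e) {
  kk <- pmin(prep$k, e - s + 1L)
  margPart <- prep$cumMarg[s + kk - 1L] - ifelse(s > 1L, prep$cumMarg[s - 1L], 0)
  condPart <- ifelse(e > s + kk - 1L,
                     prep$cumCond[e] - prep$cumCond[s + kk - 1L], 0)
  margPart + condPart
}

#' Enumerate candidate short ORFs on both strands
#'
#' Every span from an allowed start codon to the first in-frame stop
#' codon whose protein length lies in `[minLenAa, maxLenAa]`, on the
#' forward sequence and on the reverse complement; reverse-strand spans
#' are mapped back to forward-axis coordinates. Coordinates are 0-based
#' half-open with the stop codon included in the span.
#'
#' @param contigSeq DNA string.
#' @param cfg a [detectionConfig()].
#' @return data.frame with `start`, `end`, `strand`, `length_aa`.
#' @export
enumerateOrfs <- function(contigSeq, cfg = detectionConfig()) {
  fwd <- .enumerateStrand(toupper(contigSeq), cfg)
  L <- nchar(contigSeq)
  rc <- .enumerateStrand(revcomp(contigSeq), cfg)
  if (nrow(rc)) {
    newStart <- L - rc$end
    newEnd <- L - rc$start
    rc$start <- newStart; rc$end <- newEnd; rc$strand <- "-"
  }
  out <- rbind(fwd, rc)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

## positive-strand enumeration: 0-based half-open spans on the given seq
.enumerateStrand <- function(seq, cfg) {
  n <- nchar(seq)
  find <- function(pats) sort(unique(unlist(lapply(pats, function(p) {
    m <- gregexpr(p, seq, fixed = TRUE)[[1]]
    m[m > 0]
  }))))
  starts <- find(cfg$startCodons)
  stops <- find(cfg$stopCodons)
  rows <- list()
  for (f in 0:2) {
    sf <- starts[(starts - 1L) %% 3L == f]
    tf <- stops[(stops - 1L) %% 3L == f]
    if (!length(sf) || !length(tf)) next
    idx <- findInterval(sf, tf) + 1L
    ok <- idx <= length(tf)
    sf <- sf[ok]; q <- tf[idx[ok]]
    aa <- (q - sf) %/% 3L
    keep <- aa >= cfg$minLenAa & aa <= cfg$maxLenAa & q + 2L <= n
    if (any(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        start = sf[keep] - 1L, end = q[keep] + 2L, strand = "+",
        length_aa = aa[keep], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length_aa = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Posterior coding confidence of a span
#'
#' `confidence = pi * L_C / (pi * L_C + (1 - pi) * L_B)` where `L_C` is
#' the coding-model likelihood of the span's codons (stop codon
#' excluded), `L_B` the background-chain likelihood of the same
#' nucleotides, and `pi` the coding prior. Computed in log space;
#' monotone in the log-likelihood ratio.
#'
#' @param spanSequence nucleotide string, length divisible by 3; a
#'   trailing stop codon is excluded from scoring.
#' @param model a [CdsCompositionModel].
#' @return confidence in `[0, 1]`.
#' @export
scoreConfidence <- function(spanSequence, model) {
  spanSequence <- toupper(spanSequence)
  n <- nchar(spanSequence)
  if (n %% 3L != 0L) stop("span length must be divisible by 3", call. = FALSE)
  last <- substr(spanSequence, n - 2L, n)
  if (last %in% c("TAA", "TAG", "TGA")) {
    spanSequence <- substr(spanSequence, 1L, n - 3L)
    n <- n - 3L
  }
  prep <- .prepScores(spanSequence, model)
  codonStarts <- seq(1L, n - 2L, 3L)
  logLC <- sum(prep$lcu[codonStarts])
  logLB <- .bgLogLik(prep, 1L, n)
  .posterior(logLC, logLB, model@priorCoding)
}

.posterior <- function(logLC, logLB, prior) {
  d <- log(prior) + logLC - (log1p(-prior) + logLB)
  1 / (1 + exp(-d))
}

#' Predict short CDSs in a genome
#'
#' Enumerates candidate ORFs on both strands, scores each with the
#' composition model, deduplicates nested same-stop ORFs (keeping the
#' longest) and filters by the confidence threshold. Output order is
#' deterministic (contig, start, end, strand).
#'
#' @param genome a [GenomeRecord].
#' @param model a [CdsCompositionModel].
#' @param cfg a [detectionConfig()].
#' @return data.frame with `genome_id`, `contig_id`, `start`, `end`
#'   (0-based half-open, forward axis, stop codon included), `strand`,
#'   `length_aa`, `confidence`, `aa_sequence`.
#' @export
predictShortCds <- function(genome, model, cfg = detectionConfig()) {
  out <- list()
  for (ci in names(contigs(genome))) {
    seq <- as.character(contigs(genome)[[ci]])
    L <- nchar(seq)
    cand <- enumerateOrfs(seq, cfg)
    if (!nrow(cand)) next
    ## dedup nested same-stop ORFs: keep the longest
    stopKey <- ifelse(cand$strand == "+", cand$end, cand$start)
    key <- paste(cand$strand, stopKey)
    ord <- order(key, -(cand$end - cand$start))
    cand <- cand[ord, , drop = FALSE]
    cand <- cand[!duplicated(paste(cand$strand,
                                   ifelse(cand$strand == "+", cand$end,
                                          cand$start))), , drop = FALSE]
    prepF <- .prepScores(seq, model)
    rcSeq <- revcomp(seq)
    prepR <- .prepScores(rcSeq, model)
    conf <- numeric(nrow(cand))
    aaSeq <- character(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (cand$strand[i] == "+") {
        s <- cand$start[i] + 1L; e <- cand$end[i] - 3L  # coding part only
        codonStarts <- seq(s, e - 2L, 3L)
        logLC <- sum(prepF$lcu[codonStarts])
        logLB <- .bgLogLik(prepF, s, e)
        nt <- substr(seq, cand$start[i] + 1L, cand$end[i])
      } else {
        s <- L - cand$end[i] + 1L; e <- L - cand$start[i] - 3L
        codonStarts <- seq(s, e - 2L, 3L)
        logLC <- sum(prepR$lcu[codonStarts])
        logLB <- .bgLogLik(prepR, s, e)
        nt <- substr(rcSeq, s, L - cand$start[i])
      }
      conf[i] <- .posterior(logLC, logLB, model@priorCoding)
      aaSeq[i] <- translateCds(nt)
    }
    cand$confidence <- conf
    cand$aa_sequence <- aaSeq
    cand$contig_id <- ci
    out[[length(out) + 1L]] <- cand[cand$confidence >= cfg$confidenceMin, ,
                                    drop = FALSE]
  }
  if (!length(out))
    return(data.frame(genome_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length_aa = integer(0),
                      confidence = numeric(0), aa_sequence = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$genome_id <- genomeId(genome)
  res <- res[order(res$contig_id, res$start, res$end, res$strand),
             c("genome_id", "contig_id", "start", "end", "strand",
               "length_aa", "confidence", "aa_sequence")]
  rownames(res) <- NULL
  res
}

#' Restrict candidates to a regulator-gene neighborhood
#'
#' Keeps candidates whose span intersects the half-open window
#' `[hit_start - window, hit_end + window)` on the same contig, clamped
#' at the contig start.
#'
#' @param candidates data.frame from [predictShortCds()].
#' @param hitFeature one-row data.frame (or list) with `contig_id`,
#'   `start`, `end` (0-based half-open) of the regulator CDS.
#' @param window neighborhood size in bp (default 300).
#' @return the candidates inside the window, with added columns
#'   `regulator_id` (if present in `hitFeature`) and `signed_distance`
#'   (negative upstream of the regulator start, 0 if overlapping).
#' @export
neighborhoodScan <- function(candidates, hitFeature, window = 300L) {
  lo <- max(0L, hitFeature$start - window)
  hi <- hitFeature$end + window
  keep <- candidates$contig_id == hitFeature$contig_id &
    candidates$start < hi & candidates$end > lo
  out <- candidates[keep, , drop = FALSE]
  if (nrow(out)) {
    d <- ifelse(out$end <= hitFeature$start, out$end - hitFeature$start,
                ifelse(out$start >= hitFeature$end,
                       out$start - hitFeature$end + 1L, 0L))
    out$signed_distance <- as.integer(d)
    rid <- hitFeature[["feature_id"]]
    if (is.null(rid)) rid <- hitFeature[["protein_id"]]
    if (!is.null(rid)) out$regulator_id <- rid
  }
  out
}
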