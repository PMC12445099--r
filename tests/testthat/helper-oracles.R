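## Independent oracles and small fixtures shared across the test files.

## brute-force pairwise identity: explicit character loop
identityBrute <- function(a, b) {
  n <- 0L; m <- 0L
  for (i in seq_along(a)) {
    if (a[i] != "-" && b[i] != "-") {
      n <- n + 1L
      if (a[i] == b[i]) m <- m + 1L
    }
  }
  if (n == 0L) 0 else m / n
}

## O(n^3) transitive closure of an adjacency matrix -> partition labels
naiveClosure <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  labels <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      nxt <- nxt + 1L
      labels[reach[i, ]] <- nxt
    }
  }
  labels
}

## exhaustive enumeration of all local alignment paths through the
## profile state graph; must mirror the engine's score model exactly
bruteViterbi <- function(enc, sm) {
  L <- length(enc); M <- sm$M
  tr <- sm$tr
  best <- -Inf
  rec <- function(state, i, j, sc) {
    if (state == "M") best <<- max(best, sc)   # free exit from match
    if (state == "M") {
      if (j < M && i < L)
        rec("M", i + 1, j + 1, sc + tr$MM[j] + sm$mlo[j + 1, enc[i + 1] + 1])
      if (j < M && i < L)
        rec("I", i + 1, j, sc + tr$MI[j] + sm$ilo[enc[i + 1] + 1])
      if (j < M)
        rec("D", i, j + 1, sc + tr$MD[j])
    } else if (state == "I") {
      if (i < L)
        rec("I", i + 1, j, sc + tr$II[j] + sm$ilo[enc[i + 1] + 1])
      if (j < M && i < L)
        rec("M", i + 1, j + 1, sc + tr$IM[j] + sm$mlo[j + 1, enc[i + 1] + 1])
    } else {
      if (j < M)
        rec("D", i, j + 1, sc + tr$DD[j])
      if (j < M && i < L)
        rec("M", i + 1, j + 1, sc + tr$DM[j] + sm$mlo[j + 1, enc[i + 1] + 1])
    }
    invisible(NULL)
  }
  for (i in seq_len(L)) for (j in seq_len(M))
    rec("M", i, j, sm$entry[j] + sm$mlo[j, enc[i] + 1])
  best / log(2)
}

randomPeptide <- function(n) {
  paste(sample(names(RRNPPminer::robinsonRobinson), n, replace = TRUE,
               prob = RRNPPminer::robinsonRobinson), collapse = "")
}

## small bait set: mutants of one prototype (single family)
smallBaits <- function(n = 8L, len = 120L, family = "Rgg",
                       subfamily = "SHP/Rgg", identity = 0.8) {
  proto <- paste(c("M", sample(names(robinsonRobinson), len - 1L, TRUE,
                               robinsonRobinson)), collapse = "")
  data.frame(
    bait_id = paste0("b", seq_len(n)),
    family = family, subfamily = subfamily,
    aligned = vapply(seq_len(n), function(i)
      mutateProtein(proto, identity)$sequence, character(1)),
    stringsAsFactors = FALSE)
}

## down-scaled synthetic corpus for module tests (the acceptance file
## runs the full default-scale corpus)
smallCorpusConfig <- function(seed = 5L) {
  syntheticConfig(
    rngSeed = seed,
    nGenomesPerSpecies = c("S. thermophilus" = 2L, "S. salivarius" = 1L,
                           "S. vestibularis" = 1L),
    genomeLength = 40000L, nGenes = 20L, nClusters = 3L,
    presenceProbs = c(0.95, 0.8, 0.6))
}

adjustedRand <- function(a, b) {
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "adjusted.rand")
}
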