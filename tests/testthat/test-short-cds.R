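## build a tiny annotated genome from given codons for training tests
.trainGenome <- function(codons, nCodons = 1e4, bgLen = 2e4, seed = 1) {
  set.seed(seed)
  cds <- paste(c("ATG", sample(codons, nCodons, replace = TRUE), "TAA"),
               collapse = "")
  bg <- paste(sample(c("A", "C", "G", "T"), bgLen, replace = TRUE,
                     prob = c(.3, .2, .2, .3)), collapse = "")
  seq <- paste0(bg, cds, bg)
  ft <- data.frame(feature_id = "f1", contig_id = "c1",
                   start = nchar(bg), end = nchar(bg) + nchar(cds),
                   strand = "+", protein = "", product = "")
  makeGenomeRecord("train", "S. thermophilus", c(c1 = seq), ft)
}

test_that("training recovers degenerate codon composition", {
  g <- .trainGenome("GGC")
  m <- trainCdsModel(g, mode = "positional")
  expect_gte(m@positionalEmissions[3, "C"], 0.99)
  expect_true(all(abs(rowSums(m@backgroundTransitions) - 1) < 1e-9))
  g0 <- makeGenomeRecord("empty", "S. thermophilus", c(c1 = "ACGTACGT"))
  expect_error(trainCdsModel(g0), "no annotated CDS")
})

test_that("estimated parameters recover the generating distributions", {
  ## ~1e5 coding nucleotides from a known codon usage; known background
  usage <- RRNPPminer:::.defaultCodonUsage()
  set.seed(18)
  cds <- paste(c("ATG", sample(names(usage), 33000, TRUE, usage), "TAA"),
               collapse = "")
  bgChain <- RRNPPminer:::.defaultBackground(2L)
  enc <- RRNPPminer:::.sample_markov(60000L, 2L, 4L, bgChain$trans,
                                     bgChain$init)
  bg <- paste(c("A", "C", "G", "T")[enc + 1], collapse = "")
  ft <- data.frame(feature_id = "f1", contig_id = "c1", start = nchar(bg),
                   end = nchar(bg) + nchar(cds), strand = "+",
                   protein = "", product = "")
  g <- makeGenomeRecord("sim", "S. thermophilus",
                        c(c1 = paste0(bg, cds, bg)), ft)
  m <- trainCdsModel(g)
  expect_lt(sum(abs(m@codonUsage[names(usage)] - usage)), 0.05)
  expect_lt(max(abs(m@backgroundTransitions - bgChain$trans)), 0.05)
})

test_that("ORF enumeration applies the length window inclusively", {
  cfg <- detectionConfig()
  ## a 2-aa ORF is far below the 7-aa floor
  expect_equal(nrow(RRNPPminer:::.enumerateStrand("ATGAAATAA", cfg)), 0L)
  orf <- function(naa) paste(c("ATG", rep("AAA", naa - 1), "TAA"),
                             collapse = "")
  expect_equal(nrow(RRNPPminer:::.enumerateStrand(orf(6), cfg)), 0L)
  e7 <- RRNPPminer:::.enumerateStrand(orf(7), cfg)
  expect_equal(nrow(e7), 1L)
  expect_equal(e7$length_aa, 7L)
  expect_equal(nrow(RRNPPminer:::.enumerateStrand(orf(60), cfg)), 1L)
  expect_equal(nrow(RRNPPminer:::.enumerateStrand(orf(61), cfg)), 0L)
  ## GTG and TTG open ORFs too
  expect_equal(nrow(RRNPPminer:::.enumerateStrand(
    paste(c("GTG", rep("AAA", 9), "TGA"), collapse = ""), cfg)), 1L)
})

test_that("enumeration is strand symmetric", {
  set.seed(19)
  bg <- RRNPPminer:::.defaultBackground(2L)
  for (i in 1:5) {
    enc <- RRNPPminer:::.sample_markov(3000L, 2L, 4L, bg$trans, bg$init)
    seq <- paste(c("A", "C", "G", "T")[enc + 1], collapse = "")
    L <- nchar(seq)
    a <- enumerateOrfs(seq)
    b <- enumerateOrfs(revcomp(seq))
    bm <- data.frame(start = L - b$end, end = L - b$start,
                     strand = ifelse(b$strand == "+", "-", "+"),
                     length_aa = b$length_aa)
    key <- function(d) sort(paste(d$start, d$end, d$strand, d$length_aa))
    expect_equal(key(a), key(bm))
  }
})

test_that("confidence is a posterior: symmetric at equal likelihoods and
           monotone in the likelihood ratio", {
  post <- RRNPPminer:::.posterior
  expect_equal(post(-10, -10, 0.5), 0.5)
  lr <- seq(-5, 5, by = 0.5)
  p <- vapply(lr, function(d) post(d, 0, 0.5), numeric(1))
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("background spans score low, planted spans score high", {
  corp <- generateCorpus(smallCorpusConfig())
  m <- trainCdsModel(corp$genomes[1:2])
  ## spans drawn from the background chain: median confidence < 0.5
  set.seed(20)
  bg <- corp$config$background
  confs <- vapply(1:300, function(i) {
    L <- 3 * sample(7:60, 1)
    enc <- RRNPPminer:::.sample_markov(L, 2L, 4L, bg$trans, bg$init)
    scoreConfidence(paste(c("A", "C", "G", "T")[enc + 1], collapse = ""), m)
  }, numeric(1))
  expect_lt(median(confs), 0.5)
  ## planted AIP genes: >= 90% scored >= 0.01 with manifest coordinates
  aips <- corp$manifest$aips
  hitsOk <- 0L
  for (g in corp$genomes) {
    a <- aips[aips$genome_id == genomeId(g), , drop = FALSE]
    if (!nrow(a)) next
    cand <- predictShortCds(g, m)
    for (i in seq_len(nrow(a))) {
      sel <- cand$start == a$start[i] & cand$end == a$end[i] &
        cand$strand == a$strand[i] & cand$confidence >= 0.01
      if (any(sel)) hitsOk <- hitsOk + 1L
    }
  }
  expect_gte(hitsOk / nrow(aips), 0.9)
})

test_that("prediction is exactly mirror-symmetric on the reverse complement", {
  corp <- generateCorpus(smallCorpusConfig())
  m <- trainCdsModel(corp$genomes[1:2])
  g <- corp$genomes[[3]]
  seq <- as.character(contigs(g)[[1]])
  L <- nchar(seq)
  gr <- makeGenomeRecord("mirror", speciesLabel(g),
                         c(c1 = revcomp(seq)))
  a <- predictShortCds(g, m)
  b <- predictShortCds(gr, m)
  bm <- data.frame(start = L - b$end, end = L - b$start,
                   strand = ifelse(b$strand == "+", "-", "+"),
                   confidence = b$confidence)
  ord <- function(d) d[order(d$start, d$end, d$strand), ]
  a2 <- ord(data.frame(start = a$start, end = a$end, strand = a$strand,
                       confidence = a$confidence))
  b2 <- ord(bm)
  expect_equal(a2$start, b2$start)
  expect_equal(a2$strand, b2$strand)
  expect_equal(a2$confidence, b2$confidence, tolerance = 1e-9)
})

test_that("recall on planted genes dominates recall on decoy spans", {
  corp <- generateCorpus(smallCorpusConfig())
  m <- trainCdsModel(corp$genomes[1:2])
  aips <- corp$manifest$aips
  dec <- corp$manifest$decoys
  confOf <- function(rows) {
    out <- numeric(0)
    for (g in corp$genomes) {
      r <- rows[rows$genome_id == genomeId(g), , drop = FALSE]
      if (!nrow(r)) next
      cand <- predictShortCds(g, m, detectionConfig(confidenceMin = 1e-12))
      for (i in seq_len(nrow(r))) {
        sel <- cand$start == r$start[i] & cand$end == r$end[i] &
          cand$strand == r$strand[i]
        out <- c(out, if (any(sel)) max(cand$confidence[sel]) else 0)
      }
    }
    out
  }
  dec$genome_id <- sub("_c1$", "", dec$contig_id)
  cp <- confOf(aips); cd <- confOf(dec)
  for (thr in c(0.01, 0.1, 0.5))
    expect_gte(mean(cp >= thr), mean(cd >= thr))
})

test_that("neighborhood windows are half-open and brute-force checkable", {
  cand <- data.frame(genome_id = "g", contig_id = "c1",
                     start = c(100L, 699L, 700L, 1500L, 2199L, 2200L),
                     end = c(130L, 729L, 730L, 1530L, 2229L, 2230L),
                     strand = "+", length_aa = 9L, confidence = 1,
                     aa_sequence = "MKKKKKKKK", stringsAsFactors = FALSE)
  hit <- list(contig_id = "c1", start = 1000L, end = 1900L,
              feature_id = "reg1")
  nb <- neighborhoodScan(cand, hit, window = 300L)
  ## [700, 2200) window: span must intersect it
  expect_equal(nb$start, c(699L, 700L, 1500L, 2199L))
  ## candidate ending exactly at hit.start - 300 is excluded
  expect_false(130L %in% nb$end)
  ## brute-force interval check on random layouts
  set.seed(21)
  for (i in 1:100) {
    st <- sort(sample(0:5000, 2))
    hit2 <- list(contig_id = "c1", start = st[1], end = st[2],
                 feature_id = "r")
    cnd <- data.frame(genome_id = "g", contig_id = "c1",
                      start = sample(0:5000, 20), stringsAsFactors = FALSE)
    cnd$end <- cnd$start + sample(21:180, 20, replace = TRUE)
    cnd$strand <- "+"; cnd$length_aa <- 7L; cnd$confidence <- 1
    cnd$aa_sequence <- "MKKKKKK"
    lo <- max(0, st[1] - 300); hi <- st[2] + 300
    manual <- sum(cnd$start < hi & cnd$end > lo)
    expect_equal(nrow(neighborhoodScan(cnd, hit2)), manual)
  }
})
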