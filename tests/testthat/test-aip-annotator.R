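test_that("SHP feature flags match the published precursor description", {
  ## 26-aa precursor with N-terminal Lys, C-terminal Gly, central Asp
  r <- scoreShpLikeness("MKKVIAIFLFIQTVVVIDIIIFPPFG")
  expect_true(r$flags[["length_in_range"]])
  expect_true(r$flags[["n_term_lys"]])
  expect_true(r$flags[["c_term_gly"]])
  expect_true(r$flags[["central_acidic"]])
  expect_gte(r$score, 3)
  ## short homopolymer scores at most 1
  r2 <- scoreShpLikeness("AAAAAAA")
  expect_false(r2$flags[["length_in_range"]])
  expect_lte(r2$score, 1)
  ## every published SHP precursor passes the score >= 3 call
  published <- c("MKKVIAIFLFIQTVVVIDIIIFPPFG", "MSDLKFCKLLFLLTLFEILIIVGGG",
                 "MKKFLKYSLVILANVIIIVGG", "MEKVSKILPILILVMDIIIIVGG",
                 "MKLLKIIVLLTCIYIIVGGV", "MNISIKRFLMILLEIIIIIAL",
                 "MNKKALFSLLFVILEGIIVIGVG", "MNKESFLAILLLIFESIIVIAVG",
                 "MKKQILLTLLLVVFEGIIVIVVG", "MKKQKLLLLVVLVCEGIIVILVG")
  for (p in published)
    expect_gte(scoreShpLikeness(p)$score, 3)
})

test_that("flags agree with an independent character scan", {
  set.seed(22)
  kd <- kyteDoolittle
  for (i in 1:500) {
    pep <- randomPeptide(sample(7:40, 1))
    res <- strsplit(pep, "")[[1]]; n <- length(res)
    got <- scoreShpLikeness(pep)$flags
    expect_equal(got[["length_in_range"]], n >= 20 && n <= 26)
    expect_equal(got[["n_term_lys"]], "K" %in% res[1:min(3, n)])
    expect_equal(got[["c_term_gly"]], res[n] == "G")
    ## hydrophobic suffix run
    run <- 0
    for (j in n:1) {
      if (kd[res[j]] > 0 || res[j] == "G") run <- run + 1 else break
    }
    expect_equal(got[["c_term_hydrophobic_stretch"]], run >= 5)
    half <- res[seq(floor(n / 2) + 1, n)]
    half <- half[-length(half)]
    expect_equal(got[["central_acidic"]], any(half %in% c("D", "E")))
  }
})

test_that("the cleavage rule reproduces the published mature SHPs", {
  pairs <- c(
    MKKVIAIFLFIQTVVVIDIIIFPPFG = "DIIIFPPFG",
    MEKVSKILPILILVMDIIIIVGG = "DIIIIVGG",
    MNKKALFSLLFVILEGIIVIGVG = "EGIIVIGVG",
    MNKESFLAILLLIFESIIVIAVG = "ESIIVIAVG",
    MKKQILLTLLLVVFEGIIVIVVG = "EGIIVIVVG",
    MNISIKRFLMILLEIIIIIAL = "EIIIIIAL",
    MKKQKLLLLVVLVCEGIIVILVG = "EGIIVILVG")
  for (pre in names(pairs))
    expect_equal(predictMatureForm(pre), unname(pairs[pre]), info = pre)
  ## no acidic residue -> flagged for manual override
  expect_true(is.na(predictMatureForm("MKKKKKKLLLLLLLL")))
})

test_that("predicted mature forms are D/E-initial suffixes", {
  set.seed(23)
  for (i in 1:200) {
    pre <- randomPeptide(sample(8:40, 1))
    m <- predictMatureForm(pre)
    if (!is.na(m)) {
      expect_true(endsWith(pre, m))
      expect_true(substr(m, 1, 1) %in% c("D", "E"))
    }
  }
})

test_that("seed matching transfers classes by global-alignment identity", {
  seeds <- RRNPPminer:::.DEFAULT_AIP_SEEDS
  self <- matchKnownAips(seeds$sequence[1], seeds)
  expect_equal(self$identity_pct, 100)
  expect_equal(self$class, "SHP")
  ## a seed mutated at 30% of positions still transfers, near 70%
  set.seed(24)
  mut <- mutateProtein(seeds$sequence[7], 0.7, keepFirst = FALSE)$sequence
  hit <- matchKnownAips(mut, seeds)
  expect_false(is.null(hit))
  expect_equal(hit$seed_id, seeds$seed_id[7])
  expect_gt(hit$identity_pct, 55)
  expect_lt(hit$identity_pct, 85)
  ## unrelated random peptides essentially never transfer
  nohit <- sum(vapply(1:100, function(i)
    is.null(matchKnownAips(randomPeptide(25), seeds)), logical(1)))
  expect_gte(nohit, 95)
})

test_that("AIP seed sets round-trip through FASTA", {
  seeds <- RRNPPminer:::.DEFAULT_AIP_SEEDS
  path <- tempfile(fileext = ".faa")
  writeAipSeeds(seeds, path)
  back <- readAipSeeds(path)
  expect_equal(back, seeds)
  bad <- tempfile(fileext = ".faa")
  writeLines(c(">x Strange", "MKL"), bad)
  expect_error(readAipSeeds(bad), "unknown AIP class")
})

test_that("gene orientation follows the forward-axis geometry", {
  reg <- list(start = 1000L, end = 1900L, strand = "+")
  aipL <- list(start = 700L, end = 780L, strand = "-")
  aipR <- list(start = 2000L, end = 2080L, strand = "-")
  expect_equal(assignOrientation(aipL, reg), "divergent")
  expect_equal(assignOrientation(aipR, reg), "convergent")
  expect_equal(assignOrientation(list(start = 700L, end = 780L,
                                      strand = "+"), reg), "co_upstream")
  expect_equal(assignOrientation(list(start = 2000L, end = 2080L,
                                      strand = "+"), reg), "co_downstream")
  ## invariant under reverse-complementing the whole contig
  set.seed(25)
  L <- 5000L
  flipf <- function(f) list(start = L - f$end, end = L - f$start,
                            strand = if (f$strand == "+") "-" else "+")
  for (i in 1:100) {
    s <- sort(sample(0:(L - 200L), 2))
    a <- list(start = s[1], end = s[1] + 60L,
              strand = sample(c("+", "-"), 1))
    r <- list(start = s[2] + 100L, end = s[2] + 190L,
              strand = sample(c("+", "-"), 1))
    expect_equal(assignOrientation(flipf(a), flipf(r)),
                 assignOrientation(a, r))
  }
})

test_that("regulator annotation recovers planted SHPs and stays quiet on decoys", {
  corp <- generateCorpus(smallCorpusConfig())
  m <- trainCdsModel(corp$genomes[1:2])
  aips <- corp$manifest$aips
  found <- 0L
  for (g in corp$genomes) {
    gid <- genomeId(g)
    a <- aips[aips$genome_id == gid, , drop = FALSE]
    if (!nrow(a)) next
    cand <- predictShortCds(g, m)
    ft <- featureTable(g)
    for (i in seq_len(nrow(a))) {
      feat <- ft[ft$feature_id == a$regulator_id[i], , drop = FALSE]
      nb <- neighborhoodScan(cand, feat)
      ann <- annotateRegulator(feat, nb, seeds = corp$seeds)
      sel <- ann[ann$aa_sequence == a$precursor[i], , drop = FALSE]
      if (nrow(sel)) {
        found <- found + 1L
        expect_equal(sel$aip_class[1], "SHP")
        expect_equal(sel$mature_form[1], a$mature[i])
        expect_equal(sel$orientation[1], a$orientation[i])
        ## decoy neighbors never reach a confident SHP call by features
        others <- ann[ann$aa_sequence != a$precursor[i], , drop = FALSE]
        if (nrow(others))
          expect_lt(mean(others$score >= 3), 0.2)
      }
    }
  }
  expect_gte(found, nrow(aips) * 0.9)
  ## empty neighborhood -> empty annotation
  empty <- annotateRegulator(list(start = 0L, end = 10L, strand = "+"),
                             NULL)
  expect_equal(nrow(empty), 0L)
})
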