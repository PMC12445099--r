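test_that("pairwise identity uses mutually non-gap columns", {
  expect_equal(pairwiseIdentity("ACDG", "ACDG"), 1)
  expect_equal(pairwiseIdentity("AC-G", "AC-T"), 2 / 3)
  expect_equal(pairwiseIdentity("A---", "-AAA"), 0)
  expect_error(pairwiseIdentity("AC", "ACD"), "length")
  ## symmetry + brute-force oracle on random gapped rows
  set.seed(13)
  alpha <- c("A", "C", "D", "E", "-")
  for (i in 1:200) {
    n <- sample(5:30, 1)
    a <- sample(alpha, n, replace = TRUE)
    b <- sample(alpha, n, replace = TRUE)
    expect_equal(pairwiseIdentity(a, b), identityBrute(a, b))
    expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
  }
})

test_that("connected components match transitive closure semantics", {
  ## single row -> singleton
  m1 <- matrix("A", 1, 4, dimnames = list("h1", NULL))
  expect_equal(clusterHits(m1), list("h1"))
  ## chained identities merge transitively: a-b .92, b-c .91, a-c .85
  idm <- matrix(c(1, .92, .85, .92, 1, .91, .85, .91, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(clusterHits(NULL, idMat = idm), list(c("a", "b", "c")))
  ## 50 random rows vs the O(n^3) closure oracle
  set.seed(14)
  n <- 50
  idr <- matrix(runif(n * n, 0.5, 1), n, n)
  idr <- (idr + t(idr)) / 2; diag(idr) <- 1
  rownames(idr) <- colnames(idr) <- sprintf("h%02d", 1:n)
  cl <- clusterHits(NULL, cutoff = 0.9, idMat = idr)
  memb <- integer(n); names(memb) <- rownames(idr)
  for (k in seq_along(cl)) memb[cl[[k]]] <- k
  oracle <- naiveClosure(idr > 0.9 & !diag(TRUE, n))
  expect_equal(adjustedRand(memb, oracle), 1)
})

test_that("raising the cutoff refines the partition", {
  set.seed(15)
  n <- 30
  idr <- matrix(runif(n * n, 0.7, 1), n, n)
  idr <- (idr + t(idr)) / 2; diag(idr) <- 1
  rownames(idr) <- colnames(idr) <- sprintf("h%02d", 1:n)
  lo <- clusterHits(NULL, cutoff = 0.90, idMat = idr)
  hi <- clusterHits(NULL, cutoff = 0.95, idMat = idr)
  membLo <- integer(n); names(membLo) <- rownames(idr)
  for (k in seq_along(lo)) membLo[lo[[k]]] <- k
  ## every 0.95-cluster sits inside a single 0.90-cluster
  for (cl in hi) expect_length(unique(membLo[cl]), 1L)
})

test_that("strict and inclusive edge rules differ exactly at the cutoff", {
  idm <- matrix(c(1, .9, .9, 1), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  expect_length(clusterHits(NULL, idMat = idm, strict = TRUE), 2L)
  expect_length(clusterHits(NULL, idMat = idm, strict = FALSE), 1L)
})

test_that("family transfer finds the closest bait and flags 'like'", {
  set.seed(16)
  baits <- smallBaits(6, 150)
  baits$subfamily <- c("SHP/Rgg", "SHP/Rgg", "LCP/RopB", "LCP/RopB",
                       "MutS/MutR", "MutS/MutR")
  self <- assignFamily(baits$aligned[3], baits)
  expect_equal(self$best_bait, "b3")
  expect_equal(self$subfamily, "LCP/RopB")
  expect_equal(self$identity_pct, 100)
  expect_false(self$like_flag)
  ## a mutant at 55% identity keeps its family, no "like" flag
  mut <- mutateProtein(baits$aligned[5], 0.55)$sequence
  am <- assignFamily(mut, baits)
  expect_equal(am$family, "Rgg")
  expect_false(am$like_flag)
  expect_gt(am$identity_pct, 40)
  ## an unrelated random protein is "like" or unclassified
  ar <- assignFamily(randomPeptide(150), baits)
  expect_true(isTRUE(ar$like_flag) || isTRUE(ar$unclassified))
})

test_that("cluster naming is species-scoped with per-(family, scope) counters", {
  subf <- c("PapR/TprA", "Rgg", "LCP/RopB", "SHP/Rgg", "SHP/Rgg", "SHP/Rgg")
  fam <- c("PlcR", "Rgg", "Rgg", "Rgg", "Rgg", "Rgg")
  like <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  sets <- list("S. thermophilus", "S. thermophilus", "S. thermophilus",
               "S. thermophilus", "S. thermophilus",
               c("S. thermophilus", "S. salivarius"))
  ids <- nameClusters(subf, fam, sets, like)
  expect_equal(ids, c("PapR/TprA-like_Sthermo_1_", "Rgg-like_Sthermo_1_",
                      "LCP/RopB_Sthermo_2_", "SHP/Rgg_Sthermo_3_",
                      "SHP/Rgg_Sthermo_4_", "SHP/Rgg_gp_sali_1_"))
  ## deterministic given identical input ordering
  expect_equal(nameClusters(subf, fam, sets, like), ids)
})

test_that("context-gene clustering requires mutual coverage", {
  prot <- randomPeptide(100)
  two <- data.frame(protein_id = c("p1", "p2"),
                    sequence = c(prot, prot),
                    product = c("ABC transporter", "ABC transporter"))
  cl <- clusterContextGenes(two)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members, c("p1", "p2"))
  expect_equal(cl[[1]]$annotation_consensus, "ABC transporter")
  ## a perfect 50-aa local match inside a 100-aa protein fails the
  ## 70%-of-both rule
  short <- substr(prot, 26, 75)
  pair <- data.frame(protein_id = c("long", "short"),
                     sequence = c(prot, short))
  cl2 <- clusterContextGenes(pair)
  expect_length(cl2, 2L)
})

test_that("context partition equals the naive closure oracle", {
  set.seed(17)
  fams <- replicate(4, randomPeptide(80))
  prot <- data.frame(
    protein_id = sprintf("p%02d", 1:16),
    sequence = vapply(1:16, function(i)
      mutateProtein(fams[(i - 1) %% 4 + 1], 0.9)$sequence, character(1)),
    stringsAsFactors = FALSE)
  cl <- clusterContextGenes(prot)
  memb <- integer(16); names(memb) <- prot$protein_id
  for (k in seq_along(cl)) memb[cl[[k]]$members] <- k
  ## oracle: recompute the edge matrix independently and close it
  adj <- matrix(FALSE, 16, 16)
  for (i in 1:15) for (j in (i + 1):16) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prot$sequence[i]),
      Biostrings::AAString(prot$sequence[j]), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    s <- Biostrings::score(aln)
    ev <- 0.041 * nchar(prot$sequence[i]) * nchar(prot$sequence[j]) *
      exp(-0.267 * s)
    wa <- Biostrings::width(Biostrings::pattern(aln))
    wb <- Biostrings::width(Biostrings::subject(aln))
    adj[i, j] <- adj[j, i] <- s > 0 && ev <= 1e-3 &&
      wa >= 0.7 * nchar(prot$sequence[i]) &&
      wb >= 0.7 * nchar(prot$sequence[j])
  }
  expect_equal(adjustedRand(memb, naiveClosure(adj)), 1)
})

test_that("the 2-kbp neighborhood window collects flanking CDSs", {
  corp <- generateCorpus(smallCorpusConfig())
  reg <- corp$manifest$regulators
  ctx <- corp$manifest$context
  gid <- ctx$genome_id[1]
  g <- corp$genomes[[which(vapply(corp$genomes, genomeId,
                                  character(1)) == gid)]]
  nb <- neighborhoodProteins(g, ctx$regulator_id[1])
  expect_true(ctx$feature_id[1] %in% nb$protein_id)
  expect_false(ctx$regulator_id[1] %in% nb$protein_id)
})
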