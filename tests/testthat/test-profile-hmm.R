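test_that("match states follow the gap-fraction rule and sum to one", {
  ## two identical ungapped rows: every column is a match state with the
  ## observed residue as the modal emission
  b <- data.frame(bait_id = c("a", "b"), family = "Rgg", subfamily = "Rgg",
                  aligned = c("MKLVF", "MKLVF"))
  p <- buildProfile(b)
  expect_equal(profileLength(p), 5L)
  expect_equal(colnames(matchEmissions(p))[apply(matchEmissions(p), 1,
                                                 which.max)],
               c("M", "K", "L", "V", "F"))
  ## a column with 60% gaps is not a match state
  b2 <- data.frame(aligned = c("M-KL", "M-KL", "MAKL", "M-KL", "MAKL",
                               "M-KL", "M-KL", "MAKL", "M-KL", "M-KL"))
  expect_equal(profileLength(buildProfile(b2)), 3L)
  expect_equal(buildProfile(b2)@matchColumnMap, c(1L, 3L, 4L))
  expect_error(buildProfile(data.frame(aligned = c("--", "--"))), "gap")
  ## column-count oracle on a generated 33-row alignment
  corp <- generateCorpus(smallCorpusConfig())
  p33 <- buildProfile(corp$baits)
  chars <- do.call(rbind, strsplit(corp$baits$aligned, ""))
  expect_equal(profileLength(p33), sum(colMeans(chars == "-") <= 0.5))
  expect_true(all(abs(rowSums(matchEmissions(p33)) - 1) < 1e-9))
})

test_that("E-value formula is monotone in score and linear in database size", {
  set.seed(6)
  b <- smallBaits(6, 60)
  p <- calibrateEvalues(buildProfile(b), nRandom = 200, seed = 3,
                        lengths = 80L, dbSize = 100L)
  calib <- calibration(p)
  s <- seq(0, 50, by = 5)
  e <- evalueOf(s, calib, 100L)
  expect_true(all(diff(e) < 0))
  expect_equal(evalueOf(s, calib, 200L), 2 * e, tolerance = 1e-12)
  expect_error(calibrateEvalues(buildProfile(b), nRandom = 50),
               "nRandom")
})

test_that("calibrated E-values are honest on fresh random sequences", {
  set.seed(7)
  b <- smallBaits(6, 60)
  p <- calibrateEvalues(buildProfile(b), nRandom = 500, seed = 11,
                        lengths = 80L, dbSize = 1000L)
  sm <- RRNPPminer:::.scoreModel(p)
  fresh <- vapply(1:1000, function(i) randomPeptide(80), character(1))
  bits <- RRNPPminer:::.viterbiBits(sm, fresh)
  e <- evalueOf(bits, calibration(p), 1000L)
  expect_gte(sum(e <= 1), 0)
  expect_lte(sum(e <= 1), 5)
})

test_that("Viterbi equals exhaustive path enumeration on toy profiles", {
  set.seed(8)
  for (rep in 1:8) {
    M <- sample(2:4, 1)
    rows <- vapply(1:3, function(i) randomPeptide(M), character(1))
    b <- data.frame(aligned = rows)
    p <- buildProfile(b, pseudocountWeight = 2)
    sm <- RRNPPminer:::.scoreModel(p)
    target <- randomPeptide(sample(2:4, 1))
    enc <- RRNPPminer:::.encodeProtein(target)
    dp <- RRNPPminer:::.hmm_viterbi(enc, sm$mlo, sm$ilo, sm$tr, sm$entry,
                                    FALSE)$score / log(2)
    expect_equal(dp, bruteViterbi(enc, sm), tolerance = 1e-9)
  }
})

test_that("forward-backward is consistent and dominates Viterbi", {
  set.seed(9)
  b <- smallBaits(5, 40)
  p <- buildProfile(b)
  sm <- RRNPPminer:::.scoreModel(p)
  for (rep in 1:10) {
    target <- randomPeptide(sample(20:60, 1))
    enc <- RRNPPminer:::.encodeProtein(target)
    vit <- RRNPPminer:::.hmm_viterbi(enc, sm$mlo, sm$ilo, sm$tr, sm$entry,
                                     FALSE)$score
    fb <- RRNPPminer:::.hmm_forward_backward(enc, sm$mlo, sm$ilo, sm$tr,
                                             sm$entry)
    expect_equal(fb$logZ_forward, fb$logZ_backward, tolerance = 1e-6)
    expect_lte(vit, fb$logZ_forward + 1e-9)
    expect_true(all(fb$posteriors >= 0 & fb$posteriors <= 1))
  }
})

test_that("a bait finds itself; shuffled baits are not significant", {
  set.seed(10)
  b <- smallBaits(8, 120)
  p <- calibrateEvalues(buildProfile(b), nRandom = 400, seed = 5,
                        lengths = 120L, dbSize = 100L)
  self <- data.frame(protein_id = "self", genome_id = "g",
                     sequence = b$aligned[1])
  h <- searchProfile(p, self, dbSize = 100L)
  expect_equal(nrow(h), 1L)
  expect_gte(h$coverage, 0.9)
  expect_lt(h$evalue, 1e-5)
  ## residue-shuffled bait: no significant hit in >= 95/100 shuffles
  res <- strsplit(b$aligned[1], "")[[1]]
  sm <- RRNPPminer:::.scoreModel(p)
  shuffles <- vapply(1:100, function(i) paste(sample(res), collapse = ""),
                     character(1))
  bits <- RRNPPminer:::.viterbiBits(sm, shuffles)
  e <- evalueOf(bits, calibration(p), 100L)
  expect_gte(sum(e > 1e-5), 95)
})

test_that("hit filtering keeps boundary values and is idempotent", {
  hits <- data.frame(
    protein_id = c("reject_e", "reject_start", "boundary", "strong"),
    genome_id = "g",
    bit_score = c(10, 300, 40, 200),
    evalue = c(1e-4, 1e-20, 1e-5, 1e-30),
    profile_start = c(1L, 11L, 10L, 1L),
    profile_end = c(100L, 100L, 99L, 100L),
    coverage = c(1.0, 1.0, 0.90, 1.0),
    aligned_row = "x", stringsAsFactors = FALSE)
  kept <- filterHits(hits)
  expect_equal(kept$protein_id, c("boundary", "strong"))
  expect_identical(filterHits(kept), kept)
})

test_that("retained columns follow the mean-posterior rule exactly", {
  mk <- function(post, ps = 1L, pe = length(post)) {
    data.frame(protein_id = "h", genome_id = "g", bit_score = 1, evalue = 0,
               profile_start = ps, profile_end = pe,
               target_start = 1L, target_end = 10L, coverage = 1,
               aligned_row = paste(rep("A", length(post)), collapse = ""),
               posteriors = I(list(post)), stringsAsFactors = FALSE)
  }
  h1 <- rbind(mk(rep(1, 6)), mk(rep(1, 6)))
  expect_true(all(retainedColumns(h1)$mask))
  h2 <- rbind(mk(c(1, 1, 0.5, 1, 1, 1)), mk(c(1, 1, 0.5, 1, 1, 1)))
  expect_equal(which(!retainedColumns(h2, 0.85)$mask), 3L)
  ## recount oracle on random posteriors
  set.seed(11)
  hs <- do.call(rbind, lapply(1:5, function(i) mk(runif(6))))
  rc <- retainedColumns(hs, 0.5)
  manual <- colMeans(do.call(rbind, hs$posteriors))
  expect_equal(sum(rc$mask), sum(manual >= 0.5) + (!any(manual >= 0.5)))
  expect_equal(rc$meanPosterior, manual)
})

test_that("profile text serialization round-trips searches", {
  set.seed(12)
  b <- smallBaits(5, 50)
  p <- calibrateEvalues(buildProfile(b), nRandom = 200, seed = 2,
                        lengths = 60L, dbSize = 10L)
  path <- tempfile(fileext = ".hmm")
  writeProfileHMM(p, path)
  p2 <- readProfileHMM(path)
  expect_equal(profileLength(p2), profileLength(p))
  expect_equal(calibration(p2)@lambda, calibration(p)@lambda,
               tolerance = 1e-6)
  target <- data.frame(protein_id = "t", genome_id = "g",
                       sequence = b$aligned[2])
  h1 <- searchProfile(p, target, dbSize = 10L)
  h2 <- searchProfile(p2, target, dbSize = 10L)
  ## emissions are stored to 6 decimals; scores agree to that precision
  expect_equal(h1$bit_score, h2$bit_score, tolerance = 1e-2)
  expect_equal(h1$profile_start, h2$profile_start)
})
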