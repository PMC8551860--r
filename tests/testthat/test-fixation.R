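test_that("fixation matrix recodes initially heterozygous entries only", {
  g0 <- toy_geno(cbind(a = c(1L, 1L, 1L, 1L, 0L, 2L, NA),
                       b = c(1L, 1L, 0L, 2L, 1L, 1L, 1L)))
  g8 <- toy_geno(cbind(a = c(0L, 2L, 1L, NA, 2L, 0L, 1L),
                       b = c(1L, 1L, 1L, 1L, 0L, 2L, NA)))
  fm <- build_fixation_matrix(g0, g8)
  expect_identical(unname(fm[, "a"]),
                   c(-1L, 1L, 0L, NA, NA, NA, NA))
  expect_identical(unname(fm[, "b"]),
                   c(0L, 0L, NA, NA, -1L, 1L, NA))
  # unmasked entries = count of initially heterozygous calls
  expect_identical(sum(attr(fm, "het0")), sum(g0 == 1L, na.rm = TRUE))
  # mismatched identifiers are rejected
  g8b <- g8
  rownames(g8b)[1] <- "other"
  expect_error(build_fixation_matrix(g0, g8b), "identifiers")
})

test_that("AFR and RFD follow the count definitions", {
  g0 <- toy_geno(cbind(a = rep(1L, 4), b = rep(1L, 4), c = rep(1L, 4)))
  g8 <- toy_geno(cbind(a = c(2L, 2L, 0L, 1L),  # +1 +1 -1 0
                       b = rep(1L, 4),
                       c = rep(2L, 4)))
  s <- fixation_summary(build_fixation_matrix(g0, g8))
  expect_equal(s$AFR, c(0.75, 0, 1))
  expect_equal(s$RFD, c(0.25, 0, 1))
  expect_equal(s$n_het0, c(4, 4, 4), ignore_attr = TRUE)
})

test_that("RFD matches the counts reported for a strongly selected locus", {
  # 78 initially heterozygous lines: 67 fixed elite, 7 fixed wild, 4 retained
  g0 <- toy_geno(cbind(ppd = rep(1L, 78)))
  g8 <- toy_geno(cbind(ppd = c(rep(0L, 67), rep(2L, 7), rep(1L, 4))))
  s <- fixation_summary(build_fixation_matrix(g0, g8))
  expect_equal(s$AFR, 74 / 78)
  expect_equal(s$RFD, (7 - 67) / 78)
})

test_that("missing later calls stay in the denominator unless complete_pairs", {
  g0 <- toy_geno(cbind(a = rep(1L, 5)))
  g8 <- toy_geno(cbind(a = c(0L, 2L, 1L, NA, NA)))
  fm <- build_fixation_matrix(g0, g8)
  s <- fixation_summary(fm)
  expect_equal(s$AFR, 2 / 5)
  expect_equal(s$n_miss, 2)
  sc <- fixation_summary(fm, complete_pairs = TRUE)
  expect_equal(sc$AFR, 2 / 3)
})

test_that("matrix statistics equal naive per-entry counting", {
  set.seed(17)
  for (i in 1:60) {
    pr <- rand_pair(sample(4:20, 1), sample(3:50, 1))
    fm <- build_fixation_matrix(pr$g0, pr$g8)
    s <- fixation_summary(fm)
    for (j in seq_len(ncol(pr$g0))) {
      ne <- nw <- nh <- 0
      for (i2 in seq_len(nrow(pr$g0))) {
        if (!is.na(pr$g0[i2, j]) && pr$g0[i2, j] == 1L) {
          nh <- nh + 1
          v <- pr$g8[i2, j]
          if (!is.na(v) && v == 0L) ne <- ne + 1
          if (!is.na(v) && v == 2L) nw <- nw + 1
        }
      }
      expect_equal(s$n_het0[j], nh, ignore_attr = TRUE)
      if (nh > 0) {
        expect_equal(s$AFR[j], (ne + nw) / nh)
        expect_equal(s$RFD[j], (nw - ne) / nh)
      } else {
        expect_true(is.na(s$AFR[j]))
      }
    }
    ok <- !is.na(s$AFR)
    expect_true(all(abs(s$RFD[ok]) <= s$AFR[ok] + 1e-12))
    expect_true(all(s$AFR[ok] <= 1 + 1e-12))
  }
})

test_that("windows slide within chromosomes and use the 1-df chi-square", {
  sm <- data.frame(snp = sprintf("s%02d", 1:17),
                   chrom = rep(c("1H", "2H"), c(12, 5)),
                   cM = c(1:12, 1:5),
                   n_het0 = 20, n_elite = 0, n_wild = 0, n_ret = 20,
                   n_miss = 0, AFR = 0, RFD = 0)
  # first window 1:1, second window all-elite, rest empty
  sm$n_elite[1:2] <- c(10, 10)
  sm$n_wild[1] <- 20
  w <- sliding_windows(sm, window = 10, step = 1)
  expect_identical(nrow(w), 3L) # 12 - 10 + 1; 2H too short
  expect_true(all(w$chrom == "1H"))
  # window 1: counts (20, 20): exact 1:1
  expect_equal(w$chisq[1], 0)
  expect_equal(w$p[1], 1)
  # window 2 (SNPs 2-11): counts (10, 0)
  expect_equal(w$chisq[2], 10)
  expect_equal(w$p[2], stats::pchisq(10, 1, lower.tail = FALSE))
  # window 3 (SNPs 3-12): no fixed alleles, untestable
  expect_false(w$testable[3])
  expect_true(is.na(w$chisq[3]))
  # (20, 0) survival value
  sm2 <- sm
  sm2$n_elite[1:12] <- 0
  sm2$n_wild[1:12] <- 0
  sm2$n_elite[5] <- 20
  w2 <- sliding_windows(sm2, window = 10, step = 1)
  expect_equal(w2$chisq[1], 20)
  expect_equal(w2$p[1], 7.744216e-06, tolerance = 1e-6)
  # agreement with the stock goodness-of-fit test
  ct <- suppressWarnings(stats::chisq.test(c(20, 0), p = c(0.5, 0.5),
                                           correct = FALSE))
  expect_equal(w2$p[1], ct$p.value)
  # all-zero windows are untestable
  sm3 <- sm
  sm3$n_elite[] <- 0
  sm3$n_wild[] <- 0
  w3 <- sliding_windows(sm3, window = 10)
  expect_true(all(!w3$testable))
  expect_true(all(is.na(w3$p)))
  expect_error(sliding_windows(sm, window = 0), "window")
})

test_that("Bonferroni control divides alpha by the testable windows", {
  w <- data.frame(chrom = "1H", p = c(1e-5, 5e-4, NA),
                  testable = c(TRUE, TRUE, FALSE))
  w <- rbind(w, data.frame(chrom = "1H", p = stats::runif(98, 0.2, 1),
                           testable = TRUE))
  res <- bonferroni_scan(w, alpha = 0.01)
  expect_identical(attr(res, "n_testable"), 100L)
  expect_true(res$significant[1])        # 1e-5 < 1e-4
  expect_false(res$significant[2])       # 5e-4 >= 1e-4
  expect_false(res$significant[3])       # untestable, never flagged
  single <- bonferroni_scan(data.frame(p = 0.009, testable = TRUE),
                            alpha = 0.01)
  expect_true(single$significant)
})

test_that("swapping allele labels negates RFD and fixes AFR and chi-square", {
  set.seed(23)
  map <- sim_genetic_map(30, n_chrom = 1)
  pr <- rand_pair(40, 30)
  colnames(pr$g0) <- colnames(pr$g8) <- map$snp
  fit <- fixation_scan(pr$g0, pr$g8, map, min_het = 1)
  sw <- function(g) {
    out <- g
    out[g == 0L] <- 2L
    out[g == 2L] <- 0L
    genotypes(out)
  }
  fit2 <- fixation_scan(sw(pr$g0), sw(pr$g8), map, min_het = 1)
  expect_equal(fit2$snp$RFD, -fit$snp$RFD)
  expect_equal(fit2$snp$AFR, fit$snp$AFR)
  expect_equal(fit2$windows$chisq, fit$windows$chisq)
  expect_equal(fit2$windows$significant, fit$windows$significant)
})
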