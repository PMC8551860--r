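test_that("genetic maps are validated and ordered deterministically", {
  map <- sim_genetic_map(30, n_chrom = 3, chrom_length = 100)
  expect_identical(nrow(map), 30L)
  expect_identical(length(unique(map$chrom)), 3L)
  for (ch in unique(map$chrom))
    expect_true(all(diff(map$cM[map$chrom == ch]) >= 0))
  # ties broken by SNP identifier
  m <- check_map(data.frame(snp = c("b", "a"), chrom = "1H", cM = c(5, 5)))
  expect_identical(m$snp, c("a", "b"))
  expect_error(check_map(data.frame(snp = c("a", "a"), chrom = "1H",
                                    cM = c(1, 2))), "duplicated")
})

test_that("founder donors carry wild alleles at the polymorphism rate", {
  map <- sim_genetic_map(1000, n_chrom = 2)
  f1 <- sim_founders(25, map, wild_polymorphism_rate = 1, seed = 1)
  expect_true(all(f1$mask))
  f2 <- sim_founders(1, map, wild_polymorphism_rate = 0.5, seed = 2)
  expect_lt(abs(sum(f2$mask) - 500), 3 * sqrt(1000 * 0.25))
  expect_error(sim_founders(25, map, wild_polymorphism_rate = 0), "0, 1")
})

test_that("gametes are parental mosaics with map-scaled recombination", {
  map <- mini_map(seq(0, 100, by = 0.5))
  n <- length(map$snp)
  hom <- plant_hom(n, 1L)
  expect_identical(sim_gamete(hom, map, seed = 1), rep(1L, n))

  # allele conservation: gamete alleles always drawn from the parent
  set.seed(42)
  par <- list(hap1 = sample(0:1, n, TRUE), hap2 = sample(0:1, n, TRUE))
  for (i in 1:10) {
    g <- sim_gamete(par, map)
    expect_true(all(g == par$hap1 | g == par$hap2))
  }

  # crossover count over a 100 cM chromosome: mean 1 (Poisson, Haldane)
  het <- plant_het(n)
  set.seed(43)
  switches <- replicate(2000, sum(diff(sim_gamete(het, map)) != 0))
  expect_lt(abs(mean(switches) - 1), 3 * sqrt(1 / 2000))

  # adjacent SNPs 1 cM apart: recombinant fraction (1 - exp(-0.02))/2
  map2 <- mini_map(c(0, 1))
  het2 <- plant_het(2)
  set.seed(44)
  rec <- mean(replicate(8000, {
    g <- sim_gamete(het2, map2)
    g[1] != g[2]
  }))
  p <- (1 - exp(-0.02)) / 2
  expect_lt(abs(rec - p), 3 * sqrt(p * (1 - p) / 8000))
})

test_that("BC1S3 plants segregate 71.875 : 6.25 : 21.875 at polymorphic loci", {
  map <- sim_genetic_map(60, n_chrom = 2, chrom_length = 140)
  founders <- sim_founders(25, map, seed = 5)
  pop <- sim_bc1s3(founders, lines_per_family = 40, seed = 6)
  g0 <- pop$g0
  n <- nrow(g0)
  p_elite <- mean(g0 == 0L)
  p_het <- mean(g0 == 1L)
  p_wild <- mean(g0 == 2L)
  # SNPs within a line are correlated; bound noise by the line count only
  expect_lt(abs(p_het - 0.0625), 3 * sqrt(0.0625 * 0.9375 / n))
  expect_lt(abs(p_elite - 0.71875), 3 * sqrt(0.71875 * 0.28125 / n))
  expect_lt(abs(p_wild - 0.21875), 3 * sqrt(0.21875 * 0.78125 / n))
})

test_that("family-monomorphic SNPs never segregate", {
  map <- sim_genetic_map(200, n_chrom = 1)
  founders <- sim_founders(3, map, wild_polymorphism_rate = 0.5, seed = 7)
  pop <- sim_bc1s3(founders, lines_per_family = 8, seed = 8)
  fam <- attr(pop$g0, "family")
  for (f in founders$family) {
    mono <- !founders$mask[f, ]
    expect_true(all(pop$g0[fam == f, mono] == 0L))
  }
})

test_that("schedules validate season counts", {
  expect_error(heb_schedule(integer(0)), "at least one season")
  expect_error(heb_schedule(c(60, 60), c(70, 0)), "more ears than plants")
  s <- heb_schedule()
  expect_identical(nrow(s), 5L) # five selfing generations
})

test_that("neutral propagation preserves the selfing expectation", {
  map <- mini_map(c(0, 30, 60))
  plant <- list(hap1 = c(0L, 0L, 0L), hap2 = c(0L, 1L, 0L)) # het at snp 2
  set.seed(21)
  fr <- replicate(1000, {
    coh <- propagate_line(plant, map, heb_schedule())
    gt <- vapply(coh, function(p) p$hap1[2] + p$hap2[2], numeric(1))
    c(het = mean(gt == 1), wild = mean(gt == 2))
  })
  het_bar <- mean(fr["het", ])
  expect_lt(abs(het_bar - 0.03125), 3 * stats::sd(fr["het", ]) / sqrt(1000))
  # no drift bias: wild-homozygote fraction centred on 0.484375
  expect_lt(abs(mean(fr["wild", ]) - 0.484375),
            3 * stats::sd(fr["wild", ]) / sqrt(1000))
})

test_that("homozygous lines are invariant under propagation", {
  map <- mini_map(c(0, 10, 20, 30))
  plant <- list(hap1 = c(0L, 1L, 0L, 1L), hap2 = c(0L, 1L, 0L, 1L))
  coh <- propagate_line(plant, map, heb_schedule(), seed = 3)
  for (p in coh) {
    expect_identical(p$hap1, plant$hap1)
    expect_identical(p$hap2, plant$hap2)
  }
})

test_that("strong viability selection drives the wild allele up", {
  map <- mini_map(c(0, 50))
  plant <- list(hap1 = c(0L, 0L), hap2 = c(0L, 1L))
  sel <- selection_model("s002", s = 5, h = 0.5, phase = "viability")
  set.seed(77)
  up <- replicate(100, {
    coh <- propagate_line(plant, map, heb_schedule(), selection = sel)
    mean(vapply(coh, function(p) p$hap1[2] + p$hap2[2], numeric(1))) / 2 > 0.5
  })
  expect_gte(mean(up), 0.95)
})

test_that("mean fixation direction increases with the selection coefficient", {
  map <- mini_map(c(0, 50))
  plant <- list(hap1 = c(0L, 0L), hap2 = c(0L, 1L))
  set.seed(99)
  mean_dir <- vapply(c(-0.9, 0, 0.9), function(s) {
    sel <- if (s == 0) NULL else selection_model("s002", s = s)
    mean(replicate(120, {
      coh <- propagate_line(plant, map, heb_schedule(), selection = sel)
      gt <- vapply(coh, function(p) p$hap1[2] + p$hap2[2], numeric(1))
      mean(gt == 2) - mean(gt == 0)
    }))
  }, numeric(1))
  expect_true(all(diff(mean_dir) > 0))
})

test_that("pooled calling follows the minor-allele tolerance", {
  mk <- function(n0, n2) c(replicate(n0, plant_hom(1, 0L), simplify = FALSE),
                           replicate(n2, plant_hom(1, 1L), simplify = FALSE))
  # 6 elite + 6 wild homozygotes: reconstructed heterozygous call
  expect_identical(pool_and_call(mk(6, 6), 12, 0.2, seed = 1), 1L)
  # 10 + 2 at 20% tolerance: minor fraction 1/6 -> homozygous elite
  expect_identical(pool_and_call(mk(10, 2), 12, 0.2, seed = 1), 0L)
  # same pool at zero tolerance stays heterozygous
  expect_identical(pool_and_call(mk(10, 2), 12, 0, seed = 1), 1L)
  # unanimous pool is homozygous even at zero tolerance
  expect_identical(pool_and_call(mk(12, 0), 12, 0, seed = 1), 0L)
  expect_identical(pool_and_call(mk(0, 12), 12, 0, seed = 1), 2L)
  expect_error(pool_and_call(mk(3, 3), 12), "cohort")
  # failure rate produces missing calls
  g <- pool_and_call(rep(list(plant_hom(500, 0L)), 12), 12,
                     failure_rate = 1, seed = 2)
  expect_true(all(is.na(g)))
})

test_that("experiments are reproducible and internally consistent", {
  map <- sim_genetic_map(40, n_chrom = 2)
  a <- sim_heb_experiment(map, n_families = 4, lines_per_family = 5, seed = 10)
  b <- sim_heb_experiment(map, n_families = 4, lines_per_family = 5, seed = 10)
  expect_identical(a$g0, b$g0)
  expect_identical(a$g8, b$g8)
  c2 <- sim_heb_experiment(map, n_families = 4, lines_per_family = 5, seed = 11)
  expect_false(identical(a$g8, c2$g8))
  expect_identical(dimnames(a$g0), dimnames(a$g8))
  expect_identical(nrow(a$g0), 20L)
  # loci homozygous at the genotyped plant never change
  hom0 <- !is.na(a$g0) & a$g0 != 1L
  expect_true(all(a$g8[hom0] == a$g0[hom0]))
  sel <- selection_model(map$snp[3], s = 1)
  d <- sim_heb_experiment(map, n_families = 3, lines_per_family = 4,
                          selection = sel, seed = 12)
  expect_identical(d$truth, sel)
  expect_error(sim_heb_experiment(map, schedule = heb_schedule()[0, ]),
               "non-empty")
})
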