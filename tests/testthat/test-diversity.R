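test_that("observed heterozygosity counts typed diploids only", {
  expect_equal(observed_heterozygosity(hw_pop(c(1, 1), c(1, 1)), "L1"), 0)
  expect_equal(observed_heterozygosity(hw_pop(c(1, 1), c(2, 2)), "L1"), 1)
  expect_equal(observed_heterozygosity(hw_pop(c(1, 1, 1, 2),
                                              c(1, 1, 2, 1)), "L1"), 0.5)
  p <- make_pop(ids = c("m1", "f1"), sex = c("male", "female"),
                ploidy = c("haploid", "diploid"),
                L1.1 = c(104, NA), L1.2 = c(NA, NA))
  expect_warning(ho <- observed_heterozygosity(p, "L1"), "no typed diploid")
  expect_true(is.na(ho))
})

test_that("unbiased expected heterozygosity matches closed forms", {
  expect_equal(
    expected_heterozygosity_unbiased(allele_freq_table(c(a = 9L))), 0)
  expect_equal(
    expected_heterozygosity_unbiased(allele_freq_table(c(a = 3L, b = 1L))),
    (4 / 3) * (1 - 10 / 16))
  # converges to 1 - sum(p^2) as copies grow
  big <- allele_freq_table(c(a = 500000L, b = 500000L))
  expect_equal(expected_heterozygosity_unbiased(big), 0.5, tolerance = 1e-5)
  expect_error(
    expected_heterozygosity_unbiased(allele_freq_table(c(a = 1L))),
    "2 gene copies")
})

test_that("the exact HW test enumerates Levene's distribution", {
  # two A/a heterozygotes: table {2 hets} has prob 2/3, {AA, aa} 1/3;
  # every table is at most as probable as the observed one -> p = 1
  p1 <- hw_pop(c(1, 1), c(2, 2))
  res <- hw_exact_test(p1, "L1")
  expect_equal(as.numeric(res), 1)
  expect_equal(attr(res, "method"), "enumeration")

  # observed {AA, aa}: only that table (prob 1/3) is as improbable -> p = 1/3
  p2 <- hw_pop(c(1, 2), c(1, 2))
  expect_equal(as.numeric(hw_exact_test(p2, "L1")), 1 / 3)

  expect_equal(as.numeric(hw_exact_test(hw_pop(c(1, 1, 1), c(1, 1, 1)),
                                        "L1")), 1)
  expect_error(hw_exact_test(hw_pop(1, 1), "L1"), "at least 2")
})

test_that("Monte-Carlo HW agrees with enumeration on small tables", {
  set.seed(31)
  for (r in 1:3) {
    n <- 25
    g1 <- sample.int(3, n, TRUE, c(.5, .3, .2))
    g2 <- sample.int(3, n, TRUE, c(.5, .3, .2))
    pop <- hw_pop(g1, g2)
    pe <- hw_exact_test(pop, "L1", max_enum = 1e6)
    n_mc <- 20000
    pm <- hw_exact_test(pop, "L1", max_enum = 1, n_mc = n_mc,
                        seed = 400 + r)
    se <- sqrt(as.numeric(pe) * (1 - as.numeric(pe)) / n_mc)
    expect_equal(attr(pm, "method"), "monte_carlo")
    expect_lt(abs(as.numeric(pm) - as.numeric(pe)), 3 * se + 1e-3)
  }
})

test_that("HW p-values are uniform under the null", {
  set.seed(77)
  ps <- replicate(120, {
    n <- 40
    g1 <- sample.int(4, n, TRUE)
    g2 <- sample.int(4, n, TRUE)
    as.numeric(hw_exact_test(hw_pop(g1, g2), "L1", max_enum = 4000,
                             n_mc = 1500, seed = sample.int(1e6, 1)))
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the genotypic LD permutation test detects coupling only", {
  set.seed(12)
  n <- 20
  ga <- sample.int(2, n, TRUE)
  coupled <- make_pop(ids = sprintf("i%02d", 1:n), sex = "female",
                      ploidy = "diploid",
                      A.1 = ga, A.2 = ga, B.1 = ga, B.2 = ga)
  expect_lte(as.numeric(genotypic_ld_test(coupled, "A", "B",
                                          n_perm = 2000, seed = 5)), 0.01)

  monob <- make_pop(ids = sprintf("i%02d", 1:n), sex = "female",
                    ploidy = "diploid",
                    A.1 = ga, A.2 = ga,
                    B.1 = rep(1L, n), B.2 = rep(1L, n))
  res <- genotypic_ld_test(monob, "A", "B", n_perm = 100, seed = 5)
  expect_equal(as.numeric(res), 1)
  expect_equal(attr(res, "method"), "monomorphic")

  # independent loci: p-values roughly uniform
  set.seed(13)
  ps <- replicate(60, {
    a1 <- sample.int(2, 30, TRUE); a2 <- sample.int(2, 30, TRUE)
    b1 <- sample.int(2, 30, TRUE); b2 <- sample.int(2, 30, TRUE)
    pop <- make_pop(ids = sprintf("i%02d", 1:30), sex = "female",
                    ploidy = "diploid",
                    A.1 = pmin(a1, a2), A.2 = pmax(a1, a2),
                    B.1 = pmin(b1, b2), B.2 = pmax(b1, b2))
    as.numeric(genotypic_ld_test(pop, "A", "B", n_perm = 400,
                                 seed = sample.int(1e6, 1)))
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Fisher's combination follows the chi-square identity", {
  r <- fisher_combine(c(1, 1))
  expect_equal(r$chi2, 0)
  expect_equal(r$df, 4L)
  expect_equal(r$p, 1)
  r2 <- fisher_combine(c(0.05, 0.05))
  expect_equal(r2$chi2, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(r2$chi2, 11.98, tolerance = 1e-3)
  r3 <- fisher_combine(0.5)
  expect_equal(r3$chi2, 1.386, tolerance = 1e-3)
  expect_equal(r3$df, 2L)
  expect_error(fisher_combine(c(0.5, 0)), "floor")
})

test_that("null-allele EM finds the boundary and interior optima", {
  # genotype counts exactly at HW with no blanks: r-hat collapses to 0
  d <- data.frame(id = sprintf("i%03d", 1:100), sex = "female",
                  ploidy = "diploid",
                  L1.1 = c(rep(1L, 64), rep(1L, 32), rep(2L, 4)),
                  L1.2 = c(rep(1L, 64), rep(2L, 32), rep(2L, 4)))
  pop <- population_sample("p", "mainland", d)
  em <- null_allele_em(pop, "L1")
  expect_lt(em$null_freq, 1e-6)
  expect_true(em$converged)

  # recovery of a true null frequency of 0.2 at n = 500
  set.seed(19)
  est <- replicate(30, {
    pop <- population_sample("p", "mainland", null_locus_data(500, 0.2))
    null_allele_em(pop, "L1")$null_freq
  })
  expect_true(all(abs(est - 0.2) <= 0.05))
  expect_lt(abs(mean(est) - 0.2), 0.02)

  # r = 0 truth: estimates pile up near zero
  set.seed(23)
  est0 <- replicate(20, {
    pop <- population_sample("p", "mainland", null_locus_data(500, 0))
    null_allele_em(pop, "L1")$null_freq
  })
  expect_gte(mean(est0 < 0.03), 0.95)
})

test_that("EM matches a brute-force likelihood grid on a small dataset", {
  set.seed(29)
  pop <- population_sample("p", "mainland",
                           null_locus_data(120, 0.15, p = c(0.6, 0.4)))
  em <- null_allele_em(pop, "L1")
  oracle <- null_em_grid_oracle(pop, "L1")
  expect_lt(abs(em$null_freq - oracle), 1e-3)
})

test_that("rarefied richness obeys its combinatorial identities", {
  expect_equal(
    unname(rarefied_allelic_richness(list(p = c(A = 3, B = 1)), g = 2)),
    1.5)
  # g = N returns the observed allele count
  cnt <- c(A = 5, B = 2, C = 1)
  expect_equal(
    unname(rarefied_allelic_richness(list(p = cnt), g = sum(cnt))), 3)
  expect_equal(
    unname(rarefied_allelic_richness(list(p = c(A = 7)), g = 3)), 1)
  # non-decreasing in g
  r <- vapply(1:8, function(g)
    unname(rarefied_allelic_richness(list(p = cnt), g = g)), 0)
  expect_true(all(diff(r) >= -1e-12))
  expect_error(rarefied_allelic_richness(list(a = c(A = 3), b = c(A = 9)),
                                         g = 5), "exceeds")
})

test_that("private alleles are counted per population", {
  p1 <- make_pop("P1", ids = c("a1", "a2"), sex = "female",
                 ploidy = "diploid", L1.1 = c(1, 1), L1.2 = c(2, 2))
  p2 <- make_pop("P2", ids = c("b1", "b2"), sex = "female",
                 ploidy = "diploid", L1.1 = c(2, 2), L1.2 = c(3, 3))
  p3 <- make_pop("P3", ids = "c1", sex = "female", ploidy = "diploid",
                 L1.1 = 2, L1.2 = 2)
  cnt <- private_allele_counts(genotype_dataset(list(p1, p2, p3)))
  expect_equal(unname(cnt), c(1L, 1L, 0L))
  expect_lte(sum(cnt), 3)  # never more than the distinct alleles

  # identical populations share everything
  p2b <- make_pop("P2", ids = c("b1", "b2"), sex = "female",
                  ploidy = "diploid", L1.1 = c(1, 1), L1.2 = c(2, 2))
  expect_equal(unname(private_allele_counts(
    genotype_dataset(list(p1, p2b)))), c(0L, 0L))

  expect_warning(private_allele_counts(genotype_dataset(list(p1))),
                 "single population")
})

test_that("population_summary composes its parts consistently", {
  ds <- random_dataset(101, n_pops = 3, n_loci = 4)
  s <- suppressWarnings(
    population_summary(ds, mode = "females_diploid", hw_n_mc = 500,
                       seed = 1))
  # richness column equals a direct per-locus rarefaction
  for (l in ds$loci$name) {
    tabs <- lapply(ds$populations, function(p) {
      keep <- p$data$ploidy == "diploid"
      pp <- population_sample(p$name, p$habitat,
                              p$data[keep, , drop = FALSE],
                              allow_partial = TRUE)
      allele_frequencies(pp, l)
    })
    if (any(vapply(tabs, function(t) t$n_copies, 0L) < 1)) next
    direct <- rarefied_allelic_richness(tabs)
    got <- s$by_locus$richness[s$by_locus$locus == l]
    names(got) <- s$by_locus$population[s$by_locus$locus == l]
    expect_equal(got[names(direct)], direct)
  }
  # invariant under a GENEPOP round-trip
  f <- tempfile(fileext = ".gen")
  write_genepop(ds, f)
  s2 <- suppressWarnings(
    population_summary(read_genepop(f), mode = "females_diploid",
                       hw_n_mc = 500, seed = 1))
  expect_equal(s2$by_locus, s$by_locus)
  expect_equal(s2$by_population, s$by_population)
})

test_that("a HW-equilibrium dataset is not flagged after FDR control", {
  set.seed(41)
  pops <- lapply(1:2, function(pi) {
    n <- 60
    d <- data.frame(id = sprintf("p%d_%03d", pi, 1:n), sex = "female",
                    ploidy = "diploid", stringsAsFactors = FALSE)
    for (l in sprintf("L%d", 1:5)) {
      a1 <- sample.int(4, n, TRUE); a2 <- sample.int(4, n, TRUE)
      d[[paste0(l, ".1")]] <- pmin(a1, a2)
      d[[paste0(l, ".2")]] <- pmax(a1, a2)
    }
    population_sample(sprintf("pop%d", pi), "mainland", d)
  })
  s <- population_summary(genotype_dataset(pops), mode = "females_diploid",
                          hw_n_mc = 2000, seed = 3)
  expect_true(all(s$by_locus$hw_p_fdr > 0.05, na.rm = TRUE))
})

test_that("males_merged_pairs mode merges called haploids and keeps diploids", {
  # 5 males: 2 clear diploids (heterozygous), 3 haploids
  cols <- list()
  for (l in sprintf("L%02d", 1:8)) {
    cols[[paste0(l, ".1")]] <- c(101L, 101L, 103L, 105L, 107L)
    cols[[paste0(l, ".2")]] <- c(103L, 105L, 103L, 105L, 107L)
  }
  p <- do.call(make_pop, c(list(ids = sprintf("m%d", 1:5), sex = "male",
                                ploidy = "unknown"), cols))
  s <- suppressWarnings(suppressMessages(
    population_summary(genotype_dataset(list(p)),
                       mode = "males_merged_pairs", min_typed = 8,
                       tests = FALSE)))
  bp <- s$by_population
  expect_equal(bp$n_diploid, 2L)
  expect_equal(bp$n_haploid, 3L)
  expect_equal(bp$dmp, 0.4)
  # 2 diploids + 1 merged pseudo-diploid (one haploid dropped as unpaired)
  expect_equal(bp$n_individuals, 3L)
})
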