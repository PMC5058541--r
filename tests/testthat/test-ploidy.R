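test_that("heterozygosity-based ploidy calls follow the decision rule", {
  alle <- function(het_at, n_typed) {
    # 10 loci; loci beyond n_typed are missing; locus in het_at heterozygous
    cols <- list()
    for (l in 1:10) {
      typed <- l <= n_typed
      cols[[sprintf("L%02d.1", l)]] <- if (typed) 104L else NA_integer_
      cols[[sprintf("L%02d.2", l)]] <-
        if (!typed) NA_integer_ else if (l %in% het_at) 106L else 104L
    }
    do.call(make_pop, c(list(ids = "m1", sex = "male", ploidy = "unknown"),
                        cols))
  }
  expect_equal(call_ploidy(alle(het_at = 3, n_typed = 10))$call, "diploid")
  expect_equal(call_ploidy(alle(het_at = 0, n_typed = 10))$call, "haploid")
  expect_equal(call_ploidy(alle(het_at = 0, n_typed = 7))$call, "excluded")
  expect_equal(call_ploidy(alle(het_at = 2, n_typed = 7),
                           min_typed = 7)$call, "diploid")

  expect_error(call_ploidy(make_pop(ids = "f1", sex = "female",
                                    ploidy = "diploid",
                                    L1.1 = 1, L1.2 = 2)),
               "males")
})

test_that("every simulated diploid male with a heterozygous locus is called diploid", {
  cfg <- build_scenario("captive_small", generations = 8,
                        carrying_capacity = 400, seed = 17)
  sim <- simulate_population(cfg)
  n_m <- sum(sim$individuals$sex == "male")
  ds <- sample_trap_survey(sim, n_males = n_m, n_females = 0, seed = 2)
  calls <- call_ploidy(ds)
  truth <- attr(ds, "truth")
  tp <- truth$true_ploidy[match(calls$id, truth$id)]
  # no false diploids: called diploid implies truly diploid
  expect_true(all(tp[calls$call == "diploid"] == "diploid"))
  # true diploids with an observed heterozygous locus are always recovered
  dip <- calls[tp == "diploid" & calls$call != "excluded", ]
  expect_true(all(dip$call[dip$n_het >= 1] == "diploid"))
})

test_that("pedigree kinship reproduces haplodiploid and diploid sib values", {
  expect_equal(sibling_kinship_haplodiploid(), 0.25)

  ped <- pedigree(id = c("a", "b"), mother = NA, father = NA,
                  ploidy = c(2L, 1L))
  expect_equal(kinship_pedigree(ped)["a", "b"], 0)

  dip <- pedigree(id = c("m", "f", "s1", "s2"),
                  mother = c(NA, NA, "m", "m"),
                  father = c(NA, NA, "f", "f"), ploidy = 2L)
  expect_equal(kinship_pedigree(dip)["s1", "s2"], 0.25)

  expect_error(pedigree(id = c("m", "x"), mother = c(NA, "m"),
                        father = c(NA, "ghost"), ploidy = 2L),
               "not in pedigree")
  expect_error(pedigree(id = "h", mother = NA, father = "h", ploidy = 1L),
               "unfertilized")
})

test_that("kinship enumeration agrees with a forward gene-drop simulation", {
  # brother-sister pair: drop unique founder alleles through the pedigree
  set.seed(42)
  n <- 2e6
  # grandmother carries alleles 1, 2; grandfather allele 3
  bro <- ifelse(runif(n) < 0.5, 1L, 2L)
  sis_m <- ifelse(runif(n) < 0.5, 1L, 2L)
  sis <- cbind(sis_m, 3L)
  pick <- runif(n) < 0.5
  sis_draw <- ifelse(pick, sis[, 1], sis[, 2])
  sim_kinship <- mean(sis_draw == bro)
  expect_lt(abs(sim_kinship - sibling_kinship_haplodiploid()), 1e-3)
})

test_that("all-homozygous probability matches its closed form and oracle", {
  # degenerate cases
  mono <- allele_freq_table(c(`104` = 10L), "L1")
  expect_equal(all_homozygous_probability(list(mono, mono), F = 0.1), 1)
  expect_equal(all_homozygous_probability(c(0.3, 0.7), F = 1), 1)
  expect_error(all_homozygous_probability(numeric(0)), "empty")

  # worked closed form: two balanced biallelic loci, F = 1/4
  expect_equal(all_homozygous_probability(c(0.5, 0.5), F = 0.25),
               (0.25 + 0.75 * 0.5)^2)
  expect_equal(all_homozygous_probability(c(0.5, 0.5), F = 0.25), 0.390625)

  # frequency-table pathway equals the He pathway
  biall <- allele_freq_table(c(`100` = 50L, `102` = 50L), "L1")
  expect_equal(all_homozygous_probability(list(biall, biall), F = 0.25),
               all_homozygous_probability(c(0.5, 0.5), F = 0.25))

  # Monte-Carlo sib-pedigree oracle, 1e5 pedigrees, three skewed loci
  freqs <- list(c(0.6, 0.4), c(0.5, 0.3, 0.2), c(0.25, 0.25, 0.25, 0.25))
  closed <- all_homozygous_probability(
    lapply(freqs, function(f)
      allele_freq_table(stats::setNames(as.integer(f * 1000),
                                        seq_along(f)))),
    F = sibling_kinship_haplodiploid())
  n_ped <- 1e5
  mc <- simulate_sib_sons_homozygous(freqs, n_ped, seed = 99)
  se <- sqrt(closed * (1 - closed) / n_ped)
  expect_lt(abs(mc - closed), 3 * se)
})

test_that("DMP estimates reproduce their binomial arithmetic", {
  e <- dmp_estimate(8, 42)
  expect_equal(e$dmp, 0.16)
  expect_equal(e$se, sqrt(0.16 * 0.84 / 50), tolerance = 1e-12)
  expect_lte(e$ci_low, e$dmp)
  expect_gte(e$ci_high, e$dmp)

  z <- dmp_estimate(0, 30)
  expect_equal(z$dmp, 0)
  expect_equal(z$ci_low, 0)

  # CI width shrinks with n at fixed proportion
  w <- vapply(c(1, 4, 16), function(m)
    with(dmp_estimate(2 * m, 8 * m), ci_high - ci_low), 0)
  expect_true(all(diff(w) < 0))

  # Wilson is an alternative, also covering the point estimate
  wls <- dmp_estimate(8, 42, ci_method = "wilson")
  expect_lte(wls$ci_low, wls$dmp)
  expect_gte(wls$ci_high, wls$dmp)

  calls <- data.frame(call = c(rep("diploid", 2), rep("haploid", 6),
                               rep("excluded", 3)))
  s <- summarize_dmp(calls)
  expect_equal(s$dmp, 0.25)
  expect_error(summarize_dmp(data.frame(call = "excluded")), "excluded")
})

test_that("false-haploid rate in sib-mated pedigrees matches the model", {
  # simulate diploid sons of brother-sister pairs at the 4-locus panel and
  # compare the realized all-homozygous rate with the closed form
  freqs <- list(c(0.5, 0.5), c(0.4, 0.3, 0.3), c(0.7, 0.3),
                c(0.4, 0.2, 0.2, 0.2))
  closed <- all_homozygous_probability(
    lapply(freqs, function(f)
      allele_freq_table(stats::setNames(as.integer(f * 1000), seq_along(f)))))
  n_ped <- 2e5
  rate <- simulate_sib_sons_homozygous(freqs, n_ped, seed = 7)
  se <- sqrt(closed * (1 - closed) / n_ped)
  expect_lt(abs(rate - closed), 3 * se)
})
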