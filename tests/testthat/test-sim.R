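test_that("scenario presets encode the population histories", {
  expect_equal(build_scenario("captive_small")$n_founder_females, 11L)
  expect_equal(build_scenario("captive_large")$n_founder_females, 120L)
  expect_gt(build_scenario("mainland")$migration_rate, 0)
  expect_equal(build_scenario("island")$migration_rate, 0)
  expect_equal(build_scenario("captive_small", generations = 0)$generations, 0L)
  expect_error(build_scenario("captive_small", nonsense = 1), "unknown")
  expect_error(build_scenario("atlantis"), "arg")
})

test_that("sim_config validates probabilities and frequencies", {
  expect_error(sim_config(10, 5, 1, 100, fertilization_prob = 1.5), "0, 1")
  expect_error(sim_config(10, 1, 1, 100), "n_csd_alleles")
  expect_error(sim_config(10, 3, 1, 100,
                          csd_frequencies = c(0.5, 0.4)), "length")
})

test_that("unfertilized-only reproduction yields only haploid males", {
  cfg <- sim_config(n_founder_females = 40, n_csd_alleles = 4,
                    generations = 1, carrying_capacity = 1000,
                    fertilization_prob = 0, seed = 1)
  sim <- simulate_population(cfg)
  x <- sim$individuals
  expect_true(all(x$sex == "male"))
  expect_true(all(x$ploidy == 1L))
  expect_true(is.na(sim$dmp_fertilized[1]))
})

test_that("sex-determination invariants hold in every generation", {
  cfg <- build_scenario("captive_small", generations = 6,
                        carrying_capacity = 120, seed = 7)
  sim <- simulate_population(cfg, keep_history = TRUE)
  for (coh in sim$adults_history) {
    fem <- coh$sex == "female"
    dm <- coh$sex == "male" & coh$ploidy == 2L
    hm <- coh$sex == "male" & coh$ploidy == 1L
    expect_true(all(coh$csd[fem, 1] != coh$csd[fem, 2]))
    expect_true(all(coh$csd[dm, 1] == coh$csd[dm, 2]))
    expect_true(all(is.na(coh$csd[hm, 2])))
  }
})

test_that("without migration the marker allele set never grows", {
  cfg <- build_scenario("captive_small", generations = 8,
                        carrying_capacity = 150, seed = 11)
  sim <- simulate_population(cfg)
  for (l in seq_len(cfg$n_loci)) {
    founder_lab <- 100L + 2L * (seq_len(cfg$marker_allele_counts[l]) - 1L)
    final <- c(sim$individuals$markers[, 2 * l - 1],
               sim$individuals$markers[, 2 * l])
    expect_true(all(stats::na.omit(final) %in% founder_lab))
  }
})

test_that("closed captive populations lose heterozygosity by drift", {
  finals <- founders <- numeric(20)
  for (r in 1:20) {
    cfg <- build_scenario("captive_small", generations = 10,
                          carrying_capacity = 150, seed = 8000 + r)
    sim <- simulate_population(cfg)
    founders[r] <- mean(vapply(sim$founder$marker_frequencies,
                               function(f) 1 - sum(f^2), 0))
    finals[r] <- sim$history$mean_marker_he[nrow(sim$history)]
  }
  expect_lt(mean(finals), mean(founders) - 0.01)
})

test_that("diploid male fraction among fertilized eggs approaches 1/k", {
  k <- 5
  reps <- vapply(1:10, function(r) {
    cfg <- sim_config(n_founder_females = 300, n_csd_alleles = k,
                      generations = 1, carrying_capacity = 100000,
                      fertilization_prob = 0.5, seed = 3000 + r)
    simulate_population(cfg)$dmp_fertilized[1]
  }, 0)
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 1 / k), 3 * se + 1e-12)
})

test_that("simulations are reproducible from their seed", {
  cfg <- build_scenario("island", generations = 4,
                        carrying_capacity = 100, seed = 99)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$individuals, s2$individuals)
  expect_identical(s1$dmp_fertilized, s2$dmp_fertilized)
})

test_that("trap surveys keep truth hidden but intact", {
  cfg <- build_scenario("captive_small", generations = 5,
                        carrying_capacity = 200, seed = 5)
  sim <- simulate_population(cfg)
  n_m <- sum(sim$individuals$sex == "male")
  ds <- sample_trap_survey(sim, n_males = n_m, n_females = 2, seed = 1)
  p <- ds$populations[[1]]
  expect_equal(sum(p$data$sex == "male"), n_m)
  expect_true(all(p$data$ploidy[p$data$sex == "male"] == "unknown"))
  truth <- attr(ds, "truth")
  expect_setequal(truth$id, p$data$id)
  expect_true(all(truth$true_ploidy %in% c("haploid", "diploid")))
  # diploid males in truth are csd-homozygous
  dm <- truth$sex == "male" & truth$true_ploidy == "diploid"
  expect_true(all(truth$csd1[dm] == truth$csd2[dm]))

  expect_error(sample_trap_survey(sim, n_males = n_m + 1, n_females = 0),
               "available")

  # different seeds give different samples
  d1 <- sample_trap_survey(sim, 10, 0, seed = 1)$populations[[1]]$data$id
  d2 <- sample_trap_survey(sim, 10, 0, seed = 2)$populations[[1]]$data$id
  expect_false(identical(sort(d1), sort(d2)))
})

test_that("female-only surveys are possible", {
  cfg <- build_scenario("captive_large", generations = 3,
                        carrying_capacity = 150, seed = 3)
  sim <- simulate_population(cfg)
  ds <- sample_trap_survey(sim, n_males = 0, n_females = 5, seed = 1)
  expect_true(all(ds$populations[[1]]$data$sex == "female"))
})
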