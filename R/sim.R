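# Forward simulator of haplodiploid populations under single-locus
# complementary sex determination (sl-CSD).
#
# Unfertilized eggs are hemizygous at the csd locus and develop into haploid
# males; fertilized eggs develop into females when csd-heterozygous and into
# sterile diploid males when csd-homozygous. The csd locus exists only as
# simulator truth (no csd marker is genotyped); neutral microsatellite-like
# markers are inherited Mendelianly alongside it.

NULL_ALLELE <- 999L  # internal marker label for a non-amplifying allele

#' Configure an sl-CSD forward simulation
#'
#' @param n_founder_females number of founding females (each csd-heterozygous).
#' @param n_csd_alleles number of csd alleles `k` in the founder pool (>= 2).
#' @param generations number of discrete, non-overlapping generations (>= 0).
#' @param carrying_capacity maximum number of adults per generation; offspring
#'   are truncated to this number uniformly at random.
#' @param fertilization_prob probability that an egg is fertilized (phi).
#' @param sibmating_rate probability that a female mates with a brother
#'   (same mother) when one is available (alpha).
#' @param csd_frequencies founder csd allele frequencies (default uniform).
#' @param n_loci number of neutral marker loci.
#' @param marker_allele_counts integer vector of founder allele counts per
#'   locus (recycled to `n_loci`). The default is a realistic 10-locus
#'   microsatellite panel with 2-12 alleles per locus.
#' @param marker_founder_frequencies per-locus founder frequencies: `NULL`
#'   for a geometric series (ratio 0.7, giving expected heterozygosities of
#'   roughly 0.45-0.88 across the default panel), a list of simplex vectors,
#'   or a single positive number used as a symmetric Dirichlet concentration
#'   from which frequencies are drawn once at simulation start.
#' @param diploid_male_mating `"sterile_sons_only"`: diploid males mate but
#'   their mates produce only (haploid) sons, as in *Venturia canescens*;
#'   `"excluded"`: diploid males never mate.
#' @param missing_rate per-genotype probability of a missing score at
#'   genotyping time (applied by [sample_trap_survey()]).
#' @param null_allele_rate founder frequency of a non-amplifying (null) allele
#'   at every locus; one visible/null heterozygote scores as an apparent
#'   homozygote, a null/null genotype scores as missing.
#' @param migration_rate per-generation fraction of adults replaced by
#'   migrants drawn from the founder allele pool.
#' @param n_founder_males number of founding haploid males (defaults to
#'   `n_founder_females`).
#' @param mean_clutch mean Poisson clutch size per female.
#' @param seed RNG seed for the whole simulation.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_founder_females, n_csd_alleles, generations,
                       carrying_capacity, fertilization_prob = 0.5,
                       sibmating_rate = 0, csd_frequencies = NULL,
                       n_loci = 10,
                       marker_allele_counts = c(7, 11, 7, 4, 8, 7, 7, 12, 2, 8),
                       marker_founder_frequencies = NULL,
                       diploid_male_mating = c("sterile_sons_only", "excluded"),
                       missing_rate = 0, null_allele_rate = 0,
                       migration_rate = 0, n_founder_males = NULL,
                       mean_clutch = 8, seed = NULL) {
  diploid_male_mating <- match.arg(diploid_male_mating)
  stopifnot(n_founder_females >= 1, n_csd_alleles >= 2, generations >= 0,
            carrying_capacity >= 2, n_loci >= 1, mean_clutch > 0)
  for (p in c(fertilization_prob, sibmating_rate, missing_rate,
              null_allele_rate, migration_rate))
    if (p < 0 || p > 1) stop_f("probabilities must lie in [0, 1]")
  if (!is.null(csd_frequencies)) {
    stopifnot(length(csd_frequencies) == n_csd_alleles,
              all(csd_frequencies >= 0),
              abs(sum(csd_frequencies) - 1) < 1e-8)
  }
  marker_allele_counts <- rep_len(as.integer(marker_allele_counts), n_loci)
  stopifnot(all(marker_allele_counts >= 2))
  if (is.list(marker_founder_frequencies)) {
    stopifnot(length(marker_founder_frequencies) == n_loci)
    for (l in seq_len(n_loci)) {
      f <- marker_founder_frequencies[[l]]
      stopifnot(length(f) == marker_allele_counts[l], all(f >= 0),
                abs(sum(f) - 1) < 1e-8)
    }
  } else if (!is.null(marker_founder_frequencies)) {
    stopifnot(is.numeric(marker_founder_frequencies),
              length(marker_founder_frequencies) == 1L,
              marker_founder_frequencies > 0)
  }
  structure(list(
    n_founder_females = as.integer(n_founder_females),
    n_csd_alleles = as.integer(n_csd_alleles),
    generations = as.integer(generations),
    carrying_capacity = as.integer(carrying_capacity),
    fertilization_prob = fertilization_prob,
    sibmating_rate = sibmating_rate,
    csd_frequencies = csd_frequencies,
    n_loci = as.integer(n_loci),
    marker_allele_counts = marker_allele_counts,
    marker_founder_frequencies = marker_founder_frequencies,
    diploid_male_mating = diploid_male_mating,
    missing_rate = missing_rate,
    null_allele_rate = null_allele_rate,
    migration_rate = migration_rate,
    n_founder_males = as.integer(n_founder_males %||% n_founder_females),
    mean_clutch = mean_clutch,
    seed = seed), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sl-CSD simulation configuration\n")
  cat(sprintf("  founders: %d females + %d males, csd alleles k = %d\n",
              x$n_founder_females, x$n_founder_males, x$n_csd_alleles))
  cat(sprintf("  %d generations, capacity %d, phi = %.2f, alpha = %.2f, migration = %.3f\n",
              x$generations, x$carrying_capacity, x$fertilization_prob,
              x$sibmating_rate, x$migration_rate))
  cat(sprintf("  %d marker loci (%s alleles), missing %.2f, null %.2f\n",
              x$n_loci, paste(range(x$marker_allele_counts), collapse = "-"),
              x$missing_rate, x$null_allele_rate))
  invisible(x)
}

#' Habitat scenario presets
#'
#' Returns a [sim_config()] describing one of four study-population
#' histories: `mainland` (large, connected by migration), `island` (moderate,
#' closed), `captive_large` (about 120 foundresses, closed mass rearing) and
#' `captive_small` (11 foundresses, closed mass rearing). Any field of
#' [sim_config()] may be overridden through `...`.
#'
#' @param preset scenario name.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`; attribute `"habitat"` carries the habitat label.
#' @export
build_scenario <- function(preset = c("mainland", "island", "captive_large",
                                      "captive_small"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    mainland = list(n_founder_females = 200, n_csd_alleles = 20,
                    generations = 20, carrying_capacity = 1000,
                    migration_rate = 0.02, sibmating_rate = 0.05),
    island = list(n_founder_females = 30, n_csd_alleles = 20,
                  generations = 30, carrying_capacity = 200,
                  migration_rate = 0, sibmating_rate = 0.05),
    captive_large = list(n_founder_females = 120, n_csd_alleles = 20,
                         generations = 20, carrying_capacity = 300,
                         migration_rate = 0, sibmating_rate = 0.05),
    captive_small = list(n_founder_females = 11, n_csd_alleles = 20,
                         generations = 18, carrying_capacity = 300,
                         migration_rate = 0, sibmating_rate = 0.05))
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]]))
    overrides <- overrides[[1L]]
  bad <- setdiff(names(overrides), names(formals(sim_config)))
  if (length(bad)) stop_f("unknown sim_config field(s): %s",
                          paste(bad, collapse = ", "))
  base[names(overrides)] <- overrides
  cfg <- do.call(sim_config, base)
  attr(cfg, "habitat") <- switch(preset, mainland = "mainland",
                                 island = "island", "captive")
  attr(cfg, "preset") <- preset
  cfg
}

# Founder marker frequencies for one locus.
founder_marker_freqs <- function(config) {
  L <- config$n_loci
  spec <- config$marker_founder_frequencies
  out <- vector("list", L)
  for (l in seq_len(L)) {
    k <- config$marker_allele_counts[l]
    if (is.list(spec)) {
      f <- spec[[l]]
    } else if (is.numeric(spec)) {           # symmetric Dirichlet draw
      g <- stats::rgamma(k, shape = spec)
      f <- g / sum(g)
    } else {                                  # geometric series, ratio 0.7
      f <- 0.7 ^ (seq_len(k) - 1)
      f <- f / sum(f)
    }
    if (config$null_allele_rate > 0)
      f <- c(f * (1 - config$null_allele_rate), config$null_allele_rate)
    out[[l]] <- f
  }
  out
}

marker_labels <- function(k, has_null) {
  lab <- 100L + 2L * (seq_len(k) - 1L)
  if (has_null) lab <- c(lab, NULL_ALLELE)
  lab
}

# Draw n founder-style individuals from the founder pools.
draw_founders <- function(n, sex, config, csd_p, mk_freqs, id_start) {
  L <- config$n_loci
  hapl <- sex == "male"
  csd <- matrix(NA_integer_, n, 2L)
  markers <- matrix(NA_integer_, n, 2L * L)
  k <- config$n_csd_alleles
  for (i in seq_len(n)) {
    if (hapl[i]) {
      csd[i, 1L] <- sample.int(k, 1L, prob = csd_p)
    } else {
      csd[i, ] <- sample.int(k, 2L, prob = csd_p)  # without replacement: heterozygous
    }
  }
  for (l in seq_len(L)) {
    lab <- marker_labels(config$marker_allele_counts[l],
                         config$null_allele_rate > 0)
    markers[, 2L * l - 1L] <- sample(lab, n, TRUE, prob = mk_freqs[[l]])
    if (any(!hapl))
      markers[!hapl, 2L * l] <- sample(lab, sum(!hapl), TRUE,
                                       prob = mk_freqs[[l]])
  }
  list(id = id_start + seq_len(n) - 1L,
       sex = sex,
       ploidy = ifelse(hapl, 1L, 2L),
       csd = csd, markers = markers,
       mother = rep(NA_integer_, n), father = rep(NA_integer_, n))
}

subset_cohort <- function(x, idx) {
  list(id = x$id[idx], sex = x$sex[idx], ploidy = x$ploidy[idx],
       csd = x$csd[idx, , drop = FALSE],
       markers = x$markers[idx, , drop = FALSE],
       mother = x$mother[idx], father = x$father[idx])
}

bind_cohorts <- function(a, b) {
  list(id = c(a$id, b$id), sex = c(a$sex, b$sex),
       ploidy = c(a$ploidy, b$ploidy),
       csd = rbind(a$csd, b$csd), markers = rbind(a$markers, b$markers),
       mother = c(a$mother, b$mother), father = c(a$father, b$father))
}

check_csd_invariants <- function(x) {
  fem <- x$sex == "female"
  dm <- x$sex == "male" & x$ploidy == 2L
  hm <- x$sex == "male" & x$ploidy == 1L
  if (any(fem & (is.na(x$csd[, 2L]) | x$csd[, 1L] == x$csd[, 2L])))
    stop_f("internal: csd-homozygous or hemizygous female")
  if (any(dm & (is.na(x$csd[, 2L]) | x$csd[, 1L] != x$csd[, 2L])))
    stop_f("internal: csd-heterozygous diploid male")
  if (any(hm & !is.na(x$csd[, 2L])))
    stop_f("internal: haploid male with two csd alleles")
  invisible(TRUE)
}

#' Run an sl-CSD forward simulation
#'
#' Simulates discrete non-overlapping generations. Each female mates once
#' (monoandry): with probability `sibmating_rate` with a brother (same mother,
#' when one is among the adult males), otherwise with a random adult male.
#' Each egg is fertilized with probability `fertilization_prob`; fertilized
#' csd-heterozygous eggs become females, fertilized csd-homozygous eggs
#' become sterile diploid males, unfertilized eggs become haploid males.
#' Females mated to a diploid male produce only haploid sons. Clutch sizes
#' are Poisson; adults are truncated to the carrying capacity uniformly at
#' random; migration replaces a binomial fraction of adults with individuals
#' drawn from the founder allele pool.
#'
#' @param config a [sim_config()].
#' @param keep_history keep every generation's adult cohort (for diagnostics
#'   and invariant checks; memory-hungry for large runs).
#' @return an object of class `sim_population`: the final adult cohort, the
#'   per-generation realized fraction of diploid males among fertilized eggs
#'   (`dmp_fertilized`), per-generation summaries (`history`), the founder
#'   pools, and an `extinct` flag set when some generation had no mates or no
#'   females.
#' @export
simulate_population <- function(config, keep_history = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_population_impl(config, keep_history))
}

simulate_population_impl <- function(config, keep_history) {
  L <- config$n_loci
  csd_p <- config$csd_frequencies %||%
    rep(1 / config$n_csd_alleles, config$n_csd_alleles)
  mk_freqs <- founder_marker_freqs(config)

  adults <- bind_cohorts(
    draw_founders(config$n_founder_females, rep("female", config$n_founder_females),
                  config, csd_p, mk_freqs, 1L),
    draw_founders(config$n_founder_males, rep("male", config$n_founder_males),
                  config, csd_p, mk_freqs, config$n_founder_females + 1L))
  next_id <- config$n_founder_females + config$n_founder_males + 1L
  check_csd_invariants(adults)

  dmp_fert <- rep(NA_real_, config$generations)
  history <- vector("list", config$generations)
  adults_history <- if (keep_history) vector("list", config$generations) else NULL
  extinct <- FALSE

  for (g in seq_len(config$generations)) {
    fem <- which(adults$sex == "female")
    males <- which(adults$sex == "male")
    if (config$diploid_male_mating == "excluded")
      males <- males[adults$ploidy[males] == 1L]
    if (length(fem) == 0L || length(males) == 0L) { extinct <- TRUE; break }

    # monoandrous mate choice, sib-mating with probability alpha
    mate <- males[sample.int(length(males), length(fem), replace = TRUE)]
    if (config$sibmating_rate > 0) {
      sib <- stats::runif(length(fem)) < config$sibmating_rate
      if (any(sib)) {
        bro_by_mother <- split(males, adults$mother[males])
        for (i in which(sib)) {
          mo <- adults$mother[fem[i]]
          if (is.na(mo)) next
          bros <- bro_by_mother[[as.character(mo)]]
          if (length(bros) > 0L)
            mate[i] <- bros[sample.int(length(bros), 1L)]
        }
      }
    }

    clutch <- stats::rpois(length(fem), config$mean_clutch)
    n_eggs <- sum(clutch)
    if (n_eggs == 0L) { extinct <- TRUE; break }
    moi <- rep(fem, clutch)          # mother row index per egg
    fai <- rep(mate, clutch)         # father row index per egg

    fert <- stats::runif(n_eggs) < config$fertilization_prob
    fert[adults$ploidy[fai] == 2L] <- FALSE  # diploid-male mates: sons only

    pickm <- stats::runif(n_eggs) < 0.5
    mat_csd <- ifelse(pickm, adults$csd[moi, 1L], adults$csd[moi, 2L])
    pat_csd <- adults$csd[fai, 1L]           # fathers are haploid
    dipmale <- fert & mat_csd == pat_csd
    female  <- fert & !dipmale
    dmp_fert[g] <- if (any(fert)) sum(dipmale) / sum(fert) else NA_real_

    off_csd <- cbind(mat_csd, ifelse(fert, pat_csd, NA_integer_))
    off_markers <- matrix(NA_integer_, n_eggs, 2L * L)
    for (l in seq_len(L)) {
      c1 <- 2L * l - 1L; c2 <- 2L * l
      u <- stats::runif(n_eggs) < 0.5
      mat_a <- ifelse(u, adults$markers[moi, c1], adults$markers[moi, c2])
      off_markers[, c1] <- mat_a
      off_markers[fert, c2] <- adults$markers[fai[fert], c1]
    }
    off <- list(id = next_id + seq_len(n_eggs) - 1L,
                sex = ifelse(female, "female", "male"),
                ploidy = ifelse(fert, 2L, 1L),
                csd = off_csd, markers = off_markers,
                mother = adults$id[moi],
                father = ifelse(fert, adults$id[fai], NA_integer_))
    next_id <- next_id + n_eggs

    if (n_eggs > config$carrying_capacity)
      off <- subset_cohort(off, sample.int(n_eggs, config$carrying_capacity))

    if (config$migration_rate > 0) {
      n_ad <- length(off$id)
      n_mig <- stats::rbinom(1L, n_ad, config$migration_rate)
      if (n_mig > 0L) {
        repl <- sample.int(n_ad, n_mig)
        mig <- draw_founders(n_mig, off$sex[repl], config, csd_p, mk_freqs,
                             next_id)
        next_id <- next_id + n_mig
        keep <- setdiff(seq_len(n_ad), repl)
        off <- bind_cohorts(subset_cohort(off, keep), mig)
      }
    }

    adults <- off
    check_csd_invariants(adults)
    history[[g]] <- data.frame(
      generation = g,
      n_adults = length(adults$id),
      n_females = sum(adults$sex == "female"),
      n_haploid_males = sum(adults$sex == "male" & adults$ploidy == 1L),
      n_diploid_males = sum(adults$sex == "male" & adults$ploidy == 2L),
      dmp_fertilized = dmp_fert[g],
      mean_marker_he = mean_marker_he(adults, L))
    if (keep_history) adults_history[[g]] <- adults
  }

  structure(list(
    individuals = adults,
    generation = if (extinct) g - 1L else config$generations,
    dmp_fertilized = dmp_fert,
    extinct = extinct,
    history = do.call(rbind, history[!vapply(history, is.null, TRUE)]),
    adults_history = adults_history,
    founder = list(csd_frequencies = csd_p, marker_frequencies = mk_freqs),
    config = config), class = "sim_population")
}

# Mean expected heterozygosity (1 - sum p^2) over marker loci of a cohort,
# null alleles included as a real allele (this is truth-level diversity).
mean_marker_he <- function(x, L) {
  he <- numeric(L)
  for (l in seq_len(L)) {
    a <- c(x$markers[, 2L * l - 1L], x$markers[, 2L * l])
    a <- a[!is.na(a)]
    p <- as.numeric(table(a)) / length(a)
    he[l] <- 1 - sum(p^2)
  }
  mean(he)
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("sl-CSD simulated population after %d generation(s)%s\n",
              x$generation, if (x$extinct) " [EXTINCT]" else ""))
  n <- length(x$individuals$id)
  cat(sprintf("  %d adults: %d females, %d haploid males, %d diploid males\n",
              n, sum(x$individuals$sex == "female"),
              sum(x$individuals$sex == "male" & x$individuals$ploidy == 1L),
              sum(x$individuals$sex == "male" & x$individuals$ploidy == 2L)))
  dm <- x$dmp_fertilized[!is.na(x$dmp_fertilized)]
  if (length(dm))
    cat(sprintf("  diploid males among fertilized eggs, last generation: %.3f\n",
                dm[length(dm)]))
  invisible(x)
}

#' Sample a trap survey from a simulated population
#'
#' Draws males and females uniformly without replacement from the adult
#' cohort and returns a single-population [genotype_dataset()] as a field
#' survey would record it: male ploidy declared unknown, genotyping noise
#' (missing scores, null alleles) applied. The simulator's hidden truth
#' (true ploidy, csd genotype) is attached as attribute `"truth"`.
#'
#' @param pop a [simulate_population()] result.
#' @param n_males,n_females numbers to sample (errors when more are requested
#'   than are available).
#' @param seed RNG seed for the sampling and genotyping noise.
#' @param name population name for the resulting sample.
#' @param habitat habitat label (defaults to the scenario preset's habitat).
#' @return a `genotype_dataset` with one population.
#' @export
sample_trap_survey <- function(pop, n_males, n_females, seed = NULL,
                               name = "sim", habitat = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  x <- pop$individuals
  habitat <- habitat %||% attr(pop$config, "habitat") %||% NA_character_
  males <- which(x$sex == "male")
  females <- which(x$sex == "female")
  if (n_males > length(males) || n_females > length(females))
    stop_f("requested %d males / %d females but only %d / %d available",
           n_males, n_females, length(males), length(females))
  with_seed(seed, {
    take <- c(if (n_males > 0) males[sample.int(length(males), n_males)],
              if (n_females > 0) females[sample.int(length(females), n_females)])
    s <- subset_cohort(x, take)
    L <- pop$config$n_loci
    lnames <- sprintf("L%02d", seq_len(L))
    d <- data.frame(id = sprintf("ind%06d", s$id),
                    sex = s$sex,
                    ploidy = ifelse(s$sex == "male", "unknown", "diploid"),
                    stringsAsFactors = FALSE)
    for (l in seq_len(L)) {
      a1 <- s$markers[, 2L * l - 1L]
      a2 <- s$markers[, 2L * l]
      # null alleles at genotyping: visible/null scores as an apparent
      # homozygote, null/null (or a hemizygous null) scores as missing
      n1 <- !is.na(a1) & a1 == NULL_ALLELE
      n2 <- !is.na(a2) & a2 == NULL_ALLELE
      both <- n1 & n2
      a1[both] <- NA_integer_; a2[both] <- NA_integer_
      a1[n1 & !both] <- a2[n1 & !both]
      a2[n2 & !both & !is.na(a1)] <- a1[n2 & !both & !is.na(a1)]
      hapnull <- n1 & is.na(a2) & !both  # hemizygous null
      a1[hapnull] <- NA_integer_
      if (pop$config$missing_rate > 0) {
        drop <- stats::runif(length(a1)) < pop$config$missing_rate
        a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
      }
      d[[paste0(lnames[l], ".1")]] <- a1
      d[[paste0(lnames[l], ".2")]] <- a2
    }
    samp <- population_sample(name, habitat, d, allow_partial = TRUE)
    ds <- genotype_dataset(list(samp))
    attr(ds, "truth") <- data.frame(
      id = d$id, sex = s$sex,
      true_ploidy = ifelse(s$ploidy == 1L, "haploid", "diploid"),
      csd1 = s$csd[, 1L], csd2 = s$csd[, 2L],
      stringsAsFactors = FALSE)
    ds
  })
}
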