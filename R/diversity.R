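# Per-locus and per-population diversity statistics on mixed-ploidy samples.

#' Observed heterozygosity at a locus
#'
#' Fraction of typed diploid individuals carrying two distinct alleles.
#' Haploid males never contribute: their "heterozygosity" is undefined.
#'
#' @param pop a [population_sample()].
#' @param locus locus name.
#' @return a proportion, or `NA` (with a warning) when no typed diploid is
#'   available.
#' @export
observed_heterozygosity <- function(pop, locus) {
  stopifnot(inherits(pop, "population_sample"))
  if (!locus %in% pop$loci) stop_f("unknown locus '%s'", locus)
  d <- pop$data[pop$data$ploidy == "diploid", , drop = FALSE]
  a1 <- d[[paste0(locus, ".1")]]
  a2 <- d[[paste0(locus, ".2")]]
  typed <- !is.na(a1) & !is.na(a2)
  if (!any(typed)) {
    warn_f("no typed diploid individuals at %s in '%s'", locus, pop$name)
    return(NA_real_)
  }
  mean(a1[typed] != a2[typed])
}

#' Nei's unbiased expected heterozygosity
#'
#' He = n/(n - 1) * (1 - sum p_i^2) computed on gene copies (n = number of
#' gene copies, 2 per diploid), truncated at 1. This is the small-sample
#' correction used by GENEPOP.
#'
#' @param freqs an `allele_freq_table` (see [allele_frequencies()]).
#' @return expected heterozygosity in [0, 1].
#' @export
expected_heterozygosity_unbiased <- function(freqs) {
  stopifnot(inherits(freqs, "allele_freq_table"))
  n <- freqs$n_copies
  if (n < 2L) stop_f("need at least 2 gene copies")
  min(1, n / (n - 1) * (1 - sum(aft_freqs(freqs)^2)))
}

# log conditional probability of a genotype table under Levene's distribution
# given allele counts m (length k) among N diploids; a is the k x k upper
# genotype count matrix flattened by pair index, h the heterozygote count.
levene_log_const <- function(m, N) {
  lfactorial(N) + sum(lfactorial(m)) - lfactorial(2L * N)
}

#' Exact Hardy-Weinberg test (probability test)
#'
#' Tests a locus in the typed diploids of a population against
#' Hardy-Weinberg genotype proportions. Conditional on the allele counts,
#' genotype tables follow Levene's distribution; the p-value is the total
#' probability of tables no more probable than the observed one. Tables are
#' enumerated completely when their number does not exceed `max_enum`,
#' otherwise the null is sampled by Monte-Carlo pairing of gene copies and
#' the p-value estimated as (k + 1)/(n_mc + 1).
#'
#' @param pop a [population_sample()].
#' @param locus locus name.
#' @param n_mc Monte-Carlo sample size.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @param max_enum largest number of genotype tables enumerated exactly.
#' @return p-value; attribute `"method"` is `"enumeration"` or
#'   `"monte_carlo"`, and monomorphic loci return 1 flagged
#'   `"monomorphic"`.
#' @export
hw_exact_test <- function(pop, locus, n_mc = 100000, seed = NULL,
                          max_enum = 100000) {
  stopifnot(inherits(pop, "population_sample"))
  d <- pop$data[pop$data$ploidy == "diploid", , drop = FALSE]
  a1 <- d[[paste0(locus, ".1")]]
  a2 <- d[[paste0(locus, ".2")]]
  typed <- !is.na(a1) & !is.na(a2)
  a1 <- a1[typed]; a2 <- a2[typed]
  if (length(a1) < 2L) stop_f("need at least 2 typed diploids at %s", locus)
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2L)
    return(structure(1, method = "monomorphic"))
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  N <- length(lo)
  m <- tabulate(c(i1, i2), k)            # allele copy counts
  obs <- matrix(0L, k, k)
  for (r in seq_len(N)) obs[lo[r], hi[r]] <- obs[lo[r], hi[r]] + 1L
  lconst <- levene_log_const(m, N)
  lp_of <- function(tab) {
    h <- sum(tab[upper.tri(tab)])
    lconst + h * log(2) - sum(lfactorial(tab[upper.tri(tab, diag = TRUE)]))
  }
  lp_obs <- lp_of(obs)
  tol <- 1e-7

  enum <- tryCatch(hw_enumerate(m, N, lconst, lp_obs + tol, max_enum),
                   hw_enum_overflow = function(e) NULL)
  if (!is.null(enum)) {
    p <- min(1, enum$p_le)
    return(structure(p, method = "enumeration", n_tables = enum$n_tables))
  }

  # Monte-Carlo: random pairings of the observed gene copies
  with_seed(seed, {
    copies <- c(i1, i2)
    odd <- seq(1L, 2L * N, by = 2L)
    cnt <- 0L
    for (b in seq_len(n_mc)) {
      s <- sample(copies)
      x <- pmin(s[odd], s[odd + 1L]); y <- pmax(s[odd], s[odd + 1L])
      tab <- tabulate((x - 1L) * k + y, k * k)
      h <- sum(x != y)
      lp <- lconst + h * log(2) - sum(lfactorial(tab[tab > 0L]))
      if (lp <= lp_obs + tol) cnt <- cnt + 1L
    }
    structure((cnt + 1) / (n_mc + 1), method = "monte_carlo", n_mc = n_mc)
  })
}

# Complete enumeration of genotype tables with fixed allele margins.
# Signals condition "hw_enum_overflow" when more than max_tables leaves exist.
hw_enumerate <- function(m, N, lconst, lp_cut, max_tables) {
  k <- length(m)
  pairs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  n_pairs <- nrow(pairs)
  last_of_row <- c(pairs[-1L, 1L] != pairs[-n_pairs, 1L], TRUE)
  env <- new.env()
  env$p_le <- 0; env$p_tot <- 0; env$n_tables <- 0L; env$n_nodes <- 0L
  max_nodes <- 20 * max_tables   # bound total work, not only completed tables
  overflow <- function() {
    cond <- structure(class = c("hw_enum_overflow", "condition"),
                      list(message = "enumeration overflow", call = NULL))
    stop(cond)
  }
  log2v <- log(2)
  rec <- function(pi, rem, lfact_sum, h) {
    env$n_nodes <- env$n_nodes + 1L
    if (env$n_nodes > max_nodes) overflow()
    if (pi > n_pairs) {
      env$n_tables <- env$n_tables + 1L
      if (env$n_tables > max_tables) overflow()
      lp <- lconst + h * log2v - lfact_sum
      pr <- exp(lp)
      env$p_tot <- env$p_tot + pr
      if (lp <= lp_cut) env$p_le <- env$p_le + pr
      return(invisible())
    }
    i <- pairs[pi, 1L]; j <- pairs[pi, 2L]
    if (last_of_row[pi]) {
      # the row's last cell is forced: it must absorb all remaining i-copies
      if (i == j) {
        if (rem[i] %% 2L == 0L) {
          a <- rem[i] %/% 2L
          rem2 <- rem; rem2[i] <- 0L
          rec(pi + 1L, rem2, lfact_sum + lfactorial(a), h)
        }
      } else if (rem[i] <= rem[j]) {
        a <- rem[i]
        rem2 <- rem; rem2[i] <- 0L; rem2[j] <- rem2[j] - a
        rec(pi + 1L, rem2, lfact_sum + lfactorial(a), h + a)
      }
    } else if (i == j) {
      for (a in 0:(rem[i] %/% 2L)) {
        rem2 <- rem; rem2[i] <- rem2[i] - 2L * a
        rec(pi + 1L, rem2, lfact_sum + lfactorial(a), h)
      }
    } else {
      for (a in 0:min(rem[i], rem[j])) {
        rem2 <- rem; rem2[i] <- rem2[i] - a; rem2[j] <- rem2[j] - a
        rec(pi + 1L, rem2, lfact_sum + lfactorial(a), h + a)
      }
    }
  }
  rec(1L, m, 0, 0L)
  list(p_le = env$p_le, p_tot = env$p_tot, n_tables = env$n_tables)
}

#' Genotypic linkage-disequilibrium test between two loci
#'
#' Log-likelihood-ratio G statistic on the genotype-by-genotype contingency
#' table of the typed diploids, with the null distribution obtained by
#' permuting one locus's genotypes across individuals.
#'
#' @param pop a [population_sample()].
#' @param locusA,locusB locus names.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return p-value = (k + 1)/(n_perm + 1); loci with a single genotype class
#'   return 1 flagged `"monomorphic"`.
#' @export
genotypic_ld_test <- function(pop, locusA, locusB, n_perm = 10000,
                              seed = NULL) {
  stopifnot(inherits(pop, "population_sample"))
  d <- pop$data[pop$data$ploidy == "diploid", , drop = FALSE]
  g <- function(l) {
    a1 <- d[[paste0(l, ".1")]]; a2 <- d[[paste0(l, ".2")]]
    ifelse(is.na(a1) | is.na(a2), NA_character_,
           paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
  }
  gA <- g(locusA); gB <- g(locusB)
  ok <- !is.na(gA) & !is.na(gB)
  gA <- factor(gA[ok]); gB <- factor(gB[ok])
  if (length(gA) < 2L) stop_f("need at least 2 diploids typed at both loci")
  if (nlevels(gA) < 2L || nlevels(gB) < 2L)
    return(structure(1, method = "monomorphic"))
  g_stat <- function(a, b) {
    tab <- table(a, b)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- tab[tab > 0]
    2 * sum(o * log(o / e[tab > 0]))
  }
  g_obs <- g_stat(gA, gB)
  with_seed(seed, {
    cnt <- 0L
    n <- length(gB)
    for (b in seq_len(n_perm))
      if (g_stat(gA, gB[sample.int(n)]) >= g_obs - 1e-12) cnt <- cnt + 1L
    structure((cnt + 1) / (n_perm + 1), method = "permutation",
              statistic = g_obs)
  })
}

#' Fisher's method for combining independent p-values
#'
#' chi2 = -2 * sum(log p), on 2 * length(p) degrees of freedom. Zero
#' p-values are rejected: Monte-Carlo p-values must be floored upstream at
#' 1/(n + 1), which keeps the combination finite.
#'
#' @param pvalues p-values in (0, 1].
#' @return list with `chi2`, `df`, `p`.
#' @export
fisher_combine <- function(pvalues) {
  stopifnot(length(pvalues) >= 1L, is.numeric(pvalues))
  if (any(pvalues <= 0 | pvalues > 1))
    stop_f("p-values must lie in (0, 1]; floor Monte-Carlo p-values upstream")
  chi2 <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Null-allele frequency by expectation-maximization
#'
#' Fits the null-allele model of microsatellite genotyping: visible alleles i
#' with frequencies p_i plus one non-amplifying allele with frequency r, under
#' Hardy-Weinberg proportions. An apparent homozygote i/i pools true i/i and
#' i/null genotypes; blank individuals (typed diploids with no score at this
#' locus) are treated as null/null. The E-step apportions apparent homozygote
#' counts between i/i and i/null at current frequencies, the M-step
#' re-normalizes gene counts; iteration stops when no parameter moves by more
#' than `tol`. When there are no blanks and the likelihood at r = 0 is at
#' least as high as at the EM solution, the boundary estimate r = 0 is
#' returned.
#'
#' @param pop a [population_sample()].
#' @param locus locus name.
#' @param tol convergence tolerance on parameter change.
#' @param max_iter maximum EM iterations.
#' @return list with `null_freq` (r), `freqs` (named visible-allele
#'   frequencies), `n_iter`, `loglik`, `converged`.
#' @export
null_allele_em <- function(pop, locus, tol = 1e-8, max_iter = 10000) {
  stopifnot(inherits(pop, "population_sample"))
  d <- pop$data[pop$data$ploidy == "diploid", , drop = FALSE]
  a1 <- d[[paste0(locus, ".1")]]
  a2 <- d[[paste0(locus, ".2")]]
  typed <- !is.na(a1) & !is.na(a2)
  n_blank <- sum(is.na(a1) & is.na(a2))
  if (sum(typed) < 2L) stop_f("need at least 2 typed diploids at %s", locus)
  alleles <- sort(unique(c(a1[typed], a2[typed])))
  k <- length(alleles)
  i1 <- match(a1[typed], alleles); i2 <- match(a2[typed], alleles)
  hom <- i1 == i2
  n_hom <- tabulate(i1[hom], k)                       # apparent homozygotes
  het <- tabulate(c(i1[!hom], i2[!hom]), k)           # het gene counts
  N <- sum(typed) + n_blank
  ll_of <- function(p, r) {
    lhom <- sum(n_hom * log(p^2 + 2 * p * r))
    lhet <- sum(het * log(p)) + sum(!hom) * log(2)
    lblank <- if (n_blank > 0) 2 * n_blank * log(r) else 0
    lhom + lhet + lblank
  }
  # init from naive counts
  r <- max(0.01, sqrt(n_blank / N))
  p <- (2 * n_hom + het); p <- p / sum(p) * (1 - r)
  it <- 0L
  repeat {
    it <- it + 1L
    e_i0 <- ifelse(n_hom > 0, n_hom * 2 * r / (p + 2 * r), 0)  # i/null counts
    e_ii <- n_hom - e_i0
    p_new <- (2 * e_ii + e_i0 + het) / (2 * N)
    r_new <- (sum(e_i0) + 2 * n_blank) / (2 * N)
    delta <- max(abs(c(p_new - p, r_new - r)))
    p <- p_new; r <- r_new
    if (delta < tol) break
    if (it >= max_iter)
      stop_f("null-allele EM did not converge in %d iterations (last r = %.6g, change = %.3g)",
             max_iter, r, delta)
  }
  conv <- TRUE
  ll <- ll_of(p, r)
  if (n_blank == 0L) {
    p0 <- p / sum(p)
    ll0 <- ll_of(p0, 0)
    if (ll0 >= ll - 1e-7) { r <- 0; p <- p0; ll <- ll0 }
  }
  names(p) <- alleles
  list(null_freq = r, freqs = p, n_iter = it, loglik = ll, converged = conv)
}

#' Rarefied allelic richness (El Mousadik & Petit)
#'
#' Expected number of alleles in a standardized subsample of `g` gene copies,
#' comparable across populations of unequal size:
#' richness = sum_i \[1 - C(N - N_i, g) / C(N, g)\] with N the population's
#' gene copies at the locus and N_i the copies of allele i. Computed with
#' log-gamma binomials.
#'
#' @param counts_by_pop per-population allele counts for one locus: a list of
#'   `allele_freq_table`s or of named count vectors.
#' @param g gene-copy target; defaults to the minimum number of copies across
#'   populations (so every population can be rarefied).
#' @return named numeric vector of per-population richness.
#' @export
rarefied_allelic_richness <- function(counts_by_pop, g = NULL) {
  stopifnot(is.list(counts_by_pop), length(counts_by_pop) >= 1L)
  tabs <- lapply(counts_by_pop, function(x) {
    if (inherits(x, "allele_freq_table")) x else allele_freq_table(x)
  })
  ns <- vapply(tabs, function(t) t$n_copies, 0L)
  if (any(ns < 1L)) stop_f("every population needs at least 1 gene copy")
  g <- g %||% min(ns)
  if (g < 1L || g > min(ns))
    stop_f("rarefaction size g = %s exceeds some population's gene copies (min %d)",
           format(g), min(ns))
  out <- vapply(tabs, function(t) {
    N <- t$n_copies
    sum(1 - exp(lchoose(N - t$counts, g) - lchoose(N, g)))
  }, 0)
  names(out) <- names(counts_by_pop)
  out
}

#' Count private alleles per population
#'
#' An allele is private to a population when, at its locus, it is observed in
#' that population and in no other.
#'
#' @param dataset a [genotype_dataset()].
#' @return named integer vector (one count per population, summed over loci).
#' @export
private_allele_counts <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  pops <- dataset$populations
  if (length(pops) < 2L)
    warn_f("single population: every observed allele is counted private")
  counts <- stats::setNames(integer(length(pops)), names(pops))
  for (l in dataset$loci$name) {
    sets <- lapply(pops, function(p) {
      a <- c(p$data[[paste0(l, ".1")]], p$data[[paste0(l, ".2")]])
      unique(a[!is.na(a)])
    })
    all_alleles <- unlist(sets)
    priv <- names(which(table(all_alleles) == 1L))
    if (length(priv) == 0L) next
    for (i in seq_along(pops))
      counts[i] <- counts[i] + sum(sets[[i]] %in% as.integer(priv))
  }
  counts
}

#' Per-locus and per-population diversity summary
#'
#' Assembles the module's statistics into one table pair, in one of two
#' modes. `females_diploid` analyses the declared diploids of each population
#' as-is (the marker-validation layout). `males_merged_pairs` first calls
#' male ploidy ([call_ploidy()]), drops excluded males, merges called
#' haploids pairwise into "false diploids" ([merge_haploid_pairs()]) and
#' keeps called diploids unchanged, so that diploid-only statistics can be
#' computed on an all-male survey without changing allele frequencies.
#'
#' @param dataset a [genotype_dataset()].
#' @param mode `"females_diploid"` or `"males_merged_pairs"`.
#' @param min_typed ploidy-call threshold (males mode).
#' @param hw_n_mc,hw_max_enum Hardy-Weinberg test sizes (see
#'   [hw_exact_test()]).
#' @param seed RNG seed for the Monte-Carlo Hardy-Weinberg branches.
#' @param g rarefaction size (defaults to per-locus minimum copies).
#' @param tests run the per-locus Hardy-Weinberg tests and null-allele EM
#'   (set `FALSE` for a fast allele-based summary: richness, private
#'   alleles, heterozygosities and ploidy-call counts only).
#' @return an object of class `diversity_summary`: `by_locus` (population,
#'   locus, n typed, allele count, Ho, He, raw and BH-adjusted HW p,
#'   null-allele frequency, rarefied richness), `by_population` (sample
#'   sizes, ploidy-call counts and DMP in males mode, mean allele number with
#'   SE, mean rarefied richness, private alleles), plus the excluded-male log.
#' @export
population_summary <- function(dataset,
                               mode = c("females_diploid", "males_merged_pairs"),
                               min_typed = 8, hw_n_mc = 10000,
                               hw_max_enum = 2000, seed = NULL, g = NULL,
                               tests = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "genotype_dataset"))
  loci <- dataset$loci$name
  pops <- dataset$populations
  dropped <- NULL; merge_log <- list(); call_counts <- NULL

  if (mode == "males_merged_pairs") {
    analysis <- list(); counts <- list()
    for (p in pops) {
      if (!any(p$data$sex != "female")) next
      calls <- call_ploidy(p, min_typed = min_typed)
      dropped <- rbind(dropped, calls[calls$call == "excluded", , drop = FALSE])
      hap_ids <- calls$id[calls$call == "haploid"]
      dip_ids <- calls$id[calls$call == "diploid"]
      hap <- p$data[p$data$id %in% hap_ids, , drop = FALSE]
      hap$ploidy <- rep("haploid", nrow(hap))
      hap[paste0(loci, ".2")] <- NA_integer_  # drop duplicated homozygote codes
      dip <- p$data[p$data$id %in% dip_ids, , drop = FALSE]
      dip$ploidy <- rep("diploid", nrow(dip))
      merged <- if (nrow(hap) >= 2L)
        merge_haploid_pairs(population_sample(p$name, p$habitat, hap, p$year))
      else NULL
      if (!is.null(merged)) merge_log[[p$name]] <- attr(merged, "dropped")
      dat <- rbind(if (!is.null(merged)) merged$data, dip)
      if (is.null(dat) || nrow(dat) == 0L) next
      analysis[[p$name]] <- population_sample(p$name, p$habitat, dat, p$year,
                                              allow_partial = TRUE)
      counts[[p$name]] <- data.frame(
        population = p$name, n_sampled = sum(p$data$sex != "female"),
        n_haploid = length(hap_ids), n_diploid = length(dip_ids),
        n_excluded = sum(calls$call == "excluded"),
        stringsAsFactors = FALSE)
    }
    if (length(analysis) == 0L) stop_f("no analyzable males in dataset")
    call_counts <- do.call(rbind, c(counts, list(make.row.names = FALSE)))
  } else {
    analysis <- lapply(pops, function(p) {
      keep <- p$data$ploidy == "diploid"
      population_sample(p$name, p$habitat, p$data[keep, , drop = FALSE],
                        p$year, allow_partial = TRUE)
    })
    analysis <- Filter(function(p) nrow(p$data) > 0L, analysis)
    if (length(analysis) == 0L) stop_f("no diploid individuals in dataset")
  }

  # per-locus x population statistics
  rows <- list()
  freq_tabs <- list()
  for (pi in seq_along(analysis)) {
    p <- analysis[[pi]]
    for (li in seq_along(loci)) {
      l <- loci[li]
      ft <- allele_frequencies(p, l)
      freq_tabs[[paste(p$name, l, sep = "\r")]] <- ft
      a1 <- p$data[[paste0(l, ".1")]]; a2 <- p$data[[paste0(l, ".2")]]
      n_typed <- sum(!is.na(a1))
      full <- !is.na(a1) & !is.na(a2)
      ho <- if (any(full)) mean(a1[full] != a2[full]) else NA_real_
      he <- if (ft$n_copies >= 2L)
        expected_heterozygosity_unbiased(ft) else NA_real_
      hw <- if (tests && sum(full) >= 2L && length(ft$counts) >= 2L)
        as.numeric(hw_exact_test(p, l, n_mc = hw_n_mc,
                                 seed = derive_seed(seed, pi * 1000L + li),
                                 max_enum = hw_max_enum))
      else NA_real_
      nullf <- if (tests && sum(full) >= 2L)
        null_allele_em(p, l)$null_freq else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        population = p$name, locus = l, n_typed = n_typed,
        n_alleles = length(ft$counts), ho = ho, he = he, hw_p = hw,
        null_freq = nullf, stringsAsFactors = FALSE)
    }
  }
  by_locus <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  by_locus$hw_p_fdr <- NA_real_
  okp <- !is.na(by_locus$hw_p)
  by_locus$hw_p_fdr[okp] <- stats::p.adjust(by_locus$hw_p[okp], "BH")

  # rarefied richness per locus (per-locus minimum copies across populations)
  by_locus$richness <- NA_real_
  for (l in loci) {
    tabs <- lapply(analysis, function(p)
      freq_tabs[[paste(p$name, l, sep = "\r")]])
    names(tabs) <- names(analysis)
    if (any(vapply(tabs, function(t) t$n_copies, 0L) < 1L)) next
    r <- rarefied_allelic_richness(tabs)
    by_locus$richness[by_locus$locus == l] <-
      r[by_locus$population[by_locus$locus == l]]
  }

  priv <- private_allele_counts(
    genotype_dataset(unname(analysis), dataset$loci))
  pop_rows <- lapply(analysis, function(p) {
    bl <- by_locus[by_locus$population == p$name, , drop = FALSE]
    data.frame(
      population = p$name,
      habitat = p$habitat,
      n_individuals = nrow(p$data),
      mean_alleles = mean(bl$n_alleles),
      mean_alleles_se = stats::sd(bl$n_alleles) / sqrt(nrow(bl)),
      mean_richness = mean(bl$richness, na.rm = TRUE),
      private_alleles = unname(priv[p$name]),
      stringsAsFactors = FALSE)
  })
  by_population <- do.call(rbind, c(pop_rows, list(make.row.names = FALSE)))
  if (!is.null(call_counts)) {
    by_population <- merge(call_counts, by_population, by = "population",
                           sort = FALSE)
    by_population$dmp <- by_population$n_diploid /
      (by_population$n_diploid + by_population$n_haploid)
  }

  structure(list(by_locus = by_locus, by_population = by_population,
                 mode = mode, dropped = dropped, merge_log = merge_log),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Diversity summary (mode: %s)\n", x$mode))
  print(format(x$by_population, digits = digits), row.names = FALSE)
  if (!is.null(x$dropped) && nrow(x$dropped))
    cat(sprintf("%d male(s) excluded (fewer typed loci than required)\n",
                nrow(x$dropped)))
  invisible(x)
}
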