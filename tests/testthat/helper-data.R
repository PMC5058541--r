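# Fixture builders shared across the test files. Everything is generated in
# code; no genotype data ships with the tests.

# A population sample from explicit genotype columns.
make_pop <- function(name = "P1", habitat = "mainland", ids, sex, ploidy,
                     ..., year = NA_integer_, allow_partial = FALSE) {
  cols <- list(...)
  d <- data.frame(id = ids, sex = sex, ploidy = ploidy,
                  stringsAsFactors = FALSE)
  for (nm in names(cols)) d[[nm]] <- as.integer(cols[[nm]])
  population_sample(name, habitat, d, year, allow_partial = allow_partial)
}

# A population of diploid females from genotype index vectors (one locus).
hw_pop <- function(a1, a2, name = "P1") {
  make_pop(name, "mainland", ids = sprintf("i%03d", seq_along(a1)),
           sex = "female", ploidy = "diploid",
           L1.1 = pmin(a1, a2), L1.2 = pmax(a1, a2))
}

# Random mixed-ploidy dataset for round-trip properties.
random_dataset <- function(seed, n_pops = 2, n_loci = 3) {
  set.seed(seed)
  loci <- sprintf("LOC%d", seq_len(n_loci))
  pops <- lapply(seq_len(n_pops), function(pi) {
    n <- sample(4:10, 1)
    sex <- sample(c("male", "female"), n, TRUE)
    ploidy <- ifelse(sex == "female", "diploid",
                     sample(c("haploid", "diploid"), n, TRUE))
    d <- data.frame(id = sprintf("p%d_i%02d", pi, seq_len(n)),
                    sex = sex, ploidy = ploidy, stringsAsFactors = FALSE)
    for (l in loci) {
      lab <- 100L + 2L * (0:5)
      a1 <- sample(lab, n, TRUE)
      a2 <- sample(lab, n, TRUE)
      miss <- runif(n) < 0.15
      a1[miss] <- NA_integer_
      a2[miss | ploidy == "haploid"] <- NA_integer_
      a2[is.na(a1)] <- NA_integer_
      d[[paste0(l, ".1")]] <- a1
      d[[paste0(l, ".2")]] <- a2
    }
    population_sample(sprintf("pop%d", pi),
                      sample(c("mainland", "island", "captive"), 1),
                      d, year = sample(c(NA_integer_, 2012L, 2013L), 1))
  })
  genotype_dataset(pops)
}

# Total per-locus allele counts of a population sample (named by label).
pop_allele_counts <- function(pop) {
  out <- list()
  for (l in pop$loci) {
    a <- c(pop$data[[paste0(l, ".1")]], pop$data[[paste0(l, ".2")]])
    out[[l]] <- table(a[!is.na(a)])
  }
  out
}

# Monte-Carlo oracle for the all-homozygous probability: simulates diploid
# sons of brother-sister pairs by explicit gene dropping through the
# haplodiploid pedigree (grandmother diploid, grandfather haploid), with
# independent loci whose allele frequencies are given as a list.
simulate_sib_sons_homozygous <- function(freq_list, n_ped, seed) {
  set.seed(seed)
  all_hom <- rep(TRUE, n_ped)
  for (f in freq_list) {
    k <- length(f)
    gm1 <- sample.int(k, n_ped, TRUE, f)   # grandmother's two alleles
    gm2 <- sample.int(k, n_ped, TRUE, f)
    gf <- sample.int(k, n_ped, TRUE, f)    # grandfather's single allele
    u <- runif(n_ped) < 0.5
    bro <- ifelse(u, gm1, gm2)             # brother: one grandmaternal allele
    u <- runif(n_ped) < 0.5
    sis_m <- ifelse(u, gm1, gm2)           # sister: grandmaternal + paternal
    # diploid son: one allele from the sister, plus the brother's allele
    u <- runif(n_ped) < 0.5
    son_m <- ifelse(u, sis_m, gf)
    all_hom <- all_hom & (son_m == bro)
  }
  mean(all_hom)
}

# Genotypes at one locus with a true null allele of frequency r (visible
# allele frequencies proportional to p).
null_locus_data <- function(n, r, p = c(0.5, 0.3, 0.2)) {
  pv <- c(p / sum(p) * (1 - r), r)
  null_idx <- length(pv)
  g1 <- sample.int(null_idx, n, TRUE, pv)
  g2 <- sample.int(null_idx, n, TRUE, pv)
  a1 <- pmin(g1, g2); a2 <- pmax(g1, g2)
  vis1 <- ifelse(a1 == null_idx, NA_integer_,
                 ifelse(a2 == null_idx, a1, a1))
  vis2 <- ifelse(a1 == null_idx, NA_integer_,
                 ifelse(a2 == null_idx, a1, a2))
  data.frame(id = sprintf("i%05d", seq_len(n)), sex = "female",
             ploidy = "diploid", L1.1 = as.integer(vis1),
             L1.2 = as.integer(vis2), stringsAsFactors = FALSE)
}

# Brute-force grid-search ML oracle for the null-allele model with two
# visible alleles: maximizes the multinomial likelihood over (p1, r).
null_em_grid_oracle <- function(pop, locus, grid = 400) {
  d <- pop$data
  a1 <- d[[paste0(locus, ".1")]]; a2 <- d[[paste0(locus, ".2")]]
  typed <- !is.na(a1) & !is.na(a2)
  n_blank <- sum(is.na(a1) & is.na(a2))
  alleles <- sort(unique(c(a1[typed], a2[typed])))
  stopifnot(length(alleles) == 2)
  n11 <- sum(a1 == alleles[1] & a2 == alleles[1], na.rm = TRUE)
  n22 <- sum(a1 == alleles[2] & a2 == alleles[2], na.rm = TRUE)
  n12 <- sum(typed) - n11 - n22
  ll_fun <- function(r, p1) {
    p1v <- p1 * (1 - r); p2v <- (1 - p1) * (1 - r)
    n11 * log(p1v^2 + 2 * p1v * r) +
      n22 * log(p2v^2 + 2 * p2v * r) +
      n12 * log(2 * p1v * p2v) +
      (if (n_blank > 0) 2 * n_blank * log(max(r, 1e-300)) else 0)
  }
  search <- function(rs, ps) {
    best <- c(ll = -Inf, r = NA, p1 = NA)
    for (r in rs) for (p1 in ps)
      if ((ll <- ll_fun(r, p1)) > best[["ll"]])
        best <- c(ll = ll, r = r, p1 = p1)
    best
  }
  coarse <- search(seq(0, 0.5, length.out = grid),
                   seq(0.01, 0.99, length.out = grid))
  fine <- search(seq(max(0, coarse[["r"]] - 0.01),
                     min(0.5, coarse[["r"]] + 0.01), by = 1e-4),
                 seq(max(0.001, coarse[["p1"]] - 0.01),
                     min(0.999, coarse[["p1"]] + 0.01), by = 1e-4))
  fine[["r"]]
}
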