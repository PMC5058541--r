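# Mixed-ploidy multilocus genotype data model.
#
# A population sample is a data frame of individuals (id, sex, ploidy) plus a
# pair of integer allele columns per locus, named "<locus>.1" / "<locus>.2".
# Allele labels are fragment sizes (positive integers); NA means the allele
# (or the whole genotype, when both are NA) is missing. Haploid individuals
# carry their single allele in ".1" and NA in ".2".

HABITAT_LEVELS <- c("mainland", "island", "captive")
SEX_LEVELS     <- c("male", "female", "unknown")
PLOIDY_LEVELS  <- c("haploid", "diploid", "unknown")

#' Create a population sample of mixed-ploidy genotypes
#'
#' @param name population name (unique within a dataset).
#' @param habitat one of `"mainland"`, `"island"`, `"captive"`, or `NA` when
#'   the habitat is not recorded.
#' @param data data frame with character columns `id`, `sex`
#'   (male/female/unknown), `ploidy` (haploid/diploid/unknown) and two integer
#'   allele columns per locus named `"<locus>.1"` and `"<locus>.2"`.
#' @param year sampling year (optional).
#' @param allow_partial allow diploid genotypes with a single scored allele.
#'   Used for "false diploid" records built by [merge_haploid_pairs()], where
#'   one member of a pair may be missing at a locus.
#' @return an object of class `population_sample`.
#' @export
population_sample <- function(name, habitat = NA_character_, data,
                              year = NA_integer_, allow_partial = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  habitat <- as.character(habitat)
  if (!is.na(habitat) && !habitat %in% HABITAT_LEVELS)
    stop_f("habitat must be one of %s", paste(HABITAT_LEVELS, collapse = ", "))
  if (!is.data.frame(data)) stop_f("data must be a data frame")
  need <- c("id", "sex", "ploidy")
  if (!all(need %in% names(data)))
    stop_f("data needs columns %s", paste(need, collapse = ", "))
  data$id <- as.character(data$id)
  data$sex <- as.character(data$sex)
  data$ploidy <- as.character(data$ploidy)
  if (anyDuplicated(data$id)) stop_f("duplicate individual ids in '%s'", name)
  if (!all(data$sex %in% SEX_LEVELS)) stop_f("invalid sex value")
  if (!all(data$ploidy %in% PLOIDY_LEVELS)) stop_f("invalid ploidy value")
  if (any(data$sex == "female" & data$ploidy == "haploid"))
    stop_f("females cannot be declared haploid")

  loci <- loci_of_columns(setdiff(names(data), need))
  for (l in loci) {
    a1 <- data[[paste0(l, ".1")]] <- as.integer(data[[paste0(l, ".1")]])
    a2 <- data[[paste0(l, ".2")]] <- as.integer(data[[paste0(l, ".2")]])
    if (any(c(a1, a2) <= 0, na.rm = TRUE))
      stop_f("allele labels must be positive integers (locus %s)", l)
    if (any(is.na(a1) & !is.na(a2)))
      stop_f("locus %s: allele in '.2' without allele in '.1'", l)
    hap <- data$ploidy == "haploid"
    if (any(hap & !is.na(a2)))
      stop_f("locus %s: haploid individuals cannot carry two alleles", l)
    dip <- data$ploidy == "diploid"
    if (!allow_partial && any(dip & !is.na(a1) & is.na(a2)))
      stop_f("locus %s: diploid genotype with a single allele (see allow_partial)", l)
  }

  rownames(data) <- NULL
  structure(
    list(name = name, habitat = habitat, year = as.integer(year),
         data = data, loci = loci),
    class = "population_sample")
}

# Paired "<locus>.1"/"<locus>.2" column names -> ordered locus names.
loci_of_columns <- function(cols) {
  if (length(cols) == 0L) return(character())
  base <- sub("\\.[12]$", "", cols)
  suff <- sub("^.*\\.", "", cols)
  loci <- unique(base)
  for (l in loci) {
    s <- sort(suff[base == l])
    if (!identical(s, c("1", "2")))
      stop_f("locus %s must have exactly columns %s.1 and %s.2", l, l, l)
  }
  if (anyDuplicated(loci)) stop_f("duplicate locus name")
  loci
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("Population sample '%s' (%s%s): %d individuals, %d loci\n",
              x$name, ifelse(is.na(x$habitat), "habitat NA", x$habitat),
              ifelse(is.na(x$year), "", paste0(", ", x$year)),
              nrow(x$data), length(x$loci)))
  tab <- table(x$data$sex, x$data$ploidy)
  print(tab)
  invisible(x)
}

#' Bundle population samples into a genotype dataset
#'
#' @param populations list of [population_sample()] objects typed at the same
#'   ordered set of loci.
#' @param loci optional data frame of locus metadata with at least a `name`
#'   column (optionally `repeat_motif`, `size_min`, `size_max`, `multiplex`);
#'   defaults to the locus names of the first population.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(populations, loci = NULL) {
  if (inherits(populations, "population_sample"))
    populations <- list(populations)
  stopifnot(length(populations) >= 1L)
  lapply(populations, function(p)
    if (!inherits(p, "population_sample")) stop_f("not a population_sample"))
  nms <- vapply(populations, function(p) p$name, "")
  if (anyDuplicated(nms)) stop_f("population names must be unique")
  names(populations) <- nms
  locus_names <- populations[[1L]]$loci
  for (p in populations)
    if (!identical(p$loci, locus_names))
      stop_f("population '%s' is typed at different loci", p$name)
  if (is.null(loci)) {
    loci <- data.frame(name = locus_names, stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(loci), "name" %in% names(loci))
    if (anyDuplicated(loci$name)) stop_f("duplicate locus name")
    if (!identical(as.character(loci$name), locus_names))
      stop_f("locus metadata does not match population columns")
    if (all(c("size_min", "size_max") %in% names(loci)) &&
        any(loci$size_min > loci$size_max, na.rm = TRUE))
      stop_f("locus size_range lower bound exceeds upper bound")
  }
  structure(list(loci = loci, populations = populations),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("Genotype dataset: %d loci, %d populations\n",
              nrow(x$loci), length(x$populations)))
  for (p in x$populations)
    cat(sprintf("  %-10s %-8s n=%d\n", p$name,
                ifelse(is.na(p$habitat), "-", p$habitat), nrow(p$data)))
  invisible(x)
}

#' Allele counts and frequencies at one locus
#'
#' Counts gene copies at a locus in a population sample: haploid individuals
#' contribute one copy, diploids two (one for partial "false diploid"
#' genotypes); missing alleles are excluded.
#'
#' @param pop a [population_sample()].
#' @param locus locus name.
#' @param use which individuals contribute: all, haploids only, or diploids
#'   only (by declared ploidy).
#' @return an `allele_freq_table`: list with `locus`, `counts` (named integer
#'   vector of gene-copy counts) and `n_copies`.
#' @export
allele_frequencies <- function(pop, locus,
                               use = c("all", "haploids_only", "diploids_only")) {
  use <- match.arg(use)
  stopifnot(inherits(pop, "population_sample"))
  if (!locus %in% pop$loci) stop_f("unknown locus '%s'", locus)
  keep <- switch(use,
                 all = rep(TRUE, nrow(pop$data)),
                 haploids_only = pop$data$ploidy == "haploid",
                 diploids_only = pop$data$ploidy == "diploid")
  a <- c(pop$data[[paste0(locus, ".1")]][keep],
         pop$data[[paste0(locus, ".2")]][keep])
  a <- a[!is.na(a)]
  allele_freq_table(table_counts(a), locus)
}

table_counts <- function(a) {
  if (length(a) == 0L) return(integer())
  tab <- table(a)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(as.integer(names(counts)))]
}

#' Construct an allele frequency table from raw counts
#'
#' @param counts named non-negative integer vector of gene-copy counts
#'   (names are allele labels).
#' @param locus locus name the counts refer to.
#' @return an `allele_freq_table` object.
#' @export
allele_freq_table <- function(counts, locus = NA_character_) {
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop_f("negative allele count")
  structure(list(locus = locus, counts = counts,
                 n_copies = sum(counts)),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("Allele frequencies at %s (%d gene copies)\n",
              x$locus, x$n_copies))
  if (x$n_copies > 0) print(round(x$counts / x$n_copies, 4))
  invisible(x)
}

# Relative frequencies of an allele_freq_table.
aft_freqs <- function(x) {
  if (x$n_copies == 0L) return(numeric())
  x$counts / x$n_copies
}

#' Merge haploid males pairwise into "false diploids"
#'
#' Pools the single-allele genotypes of pairs of haploid males into
#' pseudo-diploid records so that diploid-only population-genetic software and
#' statistics can process haploid data without changing allele frequencies.
#' Males are sorted by id and paired sequentially; with an odd number the last
#' male is dropped (and reported). Per-locus allele counts of the output equal
#' those of the input minus the dropped male.
#'
#' @param pop a [population_sample()] whose individuals are all declared
#'   haploid.
#' @param shuffle pair in a random order instead of lexicographic id order.
#' @param seed RNG seed, used only when `shuffle = TRUE`.
#' @return a `population_sample` of pseudo-diploids; attribute `"dropped"`
#'   holds the id of an unpaired male, if any.
#' @export
merge_haploid_pairs <- function(pop, shuffle = FALSE, seed = NULL) {
  stopifnot(inherits(pop, "population_sample"))
  if (any(pop$data$ploidy != "haploid"))
    stop_f("merge_haploid_pairs requires all individuals to be haploid")
  d <- pop$data[order(pop$data$id), , drop = FALSE]
  if (shuffle)
    d <- with_seed(seed, d[sample.int(nrow(d)), , drop = FALSE])
  dropped <- character()
  if (nrow(d) %% 2L == 1L) {
    dropped <- d$id[nrow(d)]
    message(sprintf("merge_haploid_pairs: odd number of males in '%s'; dropping '%s'",
                    pop$name, dropped))
    d <- d[-nrow(d), , drop = FALSE]
  }
  n_pair <- nrow(d) %/% 2L
  i1 <- seq_len(n_pair) * 2L - 1L
  i2 <- i1 + 1L
  out <- data.frame(id = paste(d$id[i1], d$id[i2], sep = "+"),
                    sex = rep("male", n_pair),
                    ploidy = rep("diploid", n_pair),
                    stringsAsFactors = FALSE)
  for (l in pop$loci) {
    a1 <- d[[paste0(l, ".1")]][i1]
    a2 <- d[[paste0(l, ".1")]][i2]
    swap <- is.na(a1) & !is.na(a2)   # keep the single allele in ".1"
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    out[[paste0(l, ".1")]] <- a1
    out[[paste0(l, ".2")]] <- a2
  }
  res <- population_sample(pop$name, pop$habitat, out, pop$year,
                           allow_partial = TRUE)
  attr(res, "dropped") <- dropped
  res
}
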