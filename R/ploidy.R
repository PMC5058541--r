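# Diploid male detection from multilocus genotypes, and the probability model
# for mis-scoring a diploid male as haploid.

#' Call male ploidy from multilocus heterozygosity
#'
#' A male heterozygous at one or more typed loci is called diploid; a male
#' homozygous or single-allele at every typed locus is called haploid; a male
#' typed at fewer than `min_typed` loci is excluded. Declared ploidy is
#' ignored: the call is made from the genotypes alone.
#'
#' @param x a [population_sample()] or [genotype_dataset()]; females present
#'   in a sample are skipped (a ploidy call from heterozygosity is only
#'   meaningful for males).
#' @param min_typed minimum number of non-missing loci for a call (default 8,
#'   i.e. at least eight of the ten panel loci must have amplified).
#' @return data frame with columns `population`, `id`, `n_typed`, `n_het`,
#'   `call` (haploid/diploid/excluded).
#' @export
call_ploidy <- function(x, min_typed = 8) {
  if (inherits(x, "genotype_dataset")) {
    has_males <- vapply(x$populations,
                        function(p) any(p$data$sex != "female"), TRUE)
    if (!any(has_males)) stop_f("no males in dataset")
    out <- lapply(x$populations[has_males], call_ploidy,
                  min_typed = min_typed)
    return(do.call(rbind, c(out, list(make.row.names = FALSE))))
  }
  stopifnot(inherits(x, "population_sample"))
  d <- x$data
  if (all(d$sex == "female"))
    stop_f("no males in population '%s': ploidy is called for males only", x$name)
  d <- d[d$sex != "female", , drop = FALSE]
  n <- nrow(d)
  n_typed <- integer(n); n_het <- integer(n)
  for (l in x$loci) {
    a1 <- d[[paste0(l, ".1")]]
    a2 <- d[[paste0(l, ".2")]]
    typed <- !is.na(a1)
    n_typed <- n_typed + typed
    n_het <- n_het + (typed & !is.na(a2) & a1 != a2)
  }
  call <- ifelse(n_typed < min_typed, "excluded",
                 ifelse(n_het >= 1L, "diploid", "haploid"))
  data.frame(population = x$name, id = d$id, n_typed = n_typed,
             n_het = n_het, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a pedigree
#'
#' @param id character ids.
#' @param mother,father parental ids (`NA` for founders; haploid individuals
#'   have no father).
#' @param ploidy 1 (haploid, males from unfertilized eggs) or 2 (diploid).
#' @return a validated `pedigree` data frame.
#' @export
pedigree <- function(id, mother = NA, father = NA, ploidy = 2) {
  ped <- data.frame(id = as.character(id),
                    mother = as.character(rep_len(mother, length(id))),
                    father = as.character(rep_len(father, length(id))),
                    ploidy = as.integer(rep_len(ploidy, length(id))),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop_f("duplicate pedigree id")
  if (!all(ped$ploidy %in% 1:2)) stop_f("ploidy must be 1 or 2")
  known <- function(p) is.na(p) | p %in% ped$id
  if (!all(known(ped$mother)) || !all(known(ped$father)))
    stop_f("parent id not in pedigree")
  if (any(!is.na(ped$mother) & is.na(ped$father) & ped$ploidy == 2L))
    stop_f("diploid individual with a mother needs a father")
  if (any(ped$ploidy == 1L & !is.na(ped$father)))
    stop_f("haploid individuals develop from unfertilized eggs and have no father")
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Kinship matrix of a haplodiploid (or diploid) pedigree
#'
#' Computes coefficients of kinship f(i, j) -- the probability that one
#' allele drawn at random from i and one from j are identical by descent --
#' by the standard recursive enumeration of transmission paths, extended to
#' haplodiploidy: a haploid individual transmits its single maternal genome,
#' so f(i, .) = f(mother(i), .) and f(i, i) = 1.
#'
#' @param ped a [pedigree()].
#' @return symmetric numeric matrix with dimnames = ids.
#' @export
kinship_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  # topological order: parents before children
  placed <- logical(n); ord <- integer(0)
  while (length(ord) < n) {
    ready <- which(!placed &
      (is.na(ped$mother) | ped$mother %in% ped$id[placed]) &
      (is.na(ped$father) | ped$father %in% ped$id[placed]))
    if (length(ready) == 0L) stop_f("pedigree contains a cycle")
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  f <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  idx <- function(p) if (is.na(p)) NA_integer_ else match(p, ped$id)
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    mo <- idx(ped$mother[i]); fa <- idx(ped$father[i])
    # self-kinship
    if (ped$ploidy[i] == 1L) {
      f[i, i] <- 1
    } else if (is.na(mo)) {
      f[i, i] <- 0.5                       # non-inbred diploid founder
    } else {
      f[i, i] <- 0.5 * (1 + f[mo, fa])
    }
    # kinship with previously placed individuals
    for (j in ord[seq_len(pos - 1L)]) {
      fij <- if (is.na(mo) && is.na(fa)) {
        0                                  # founder, unrelated to earlier ids
      } else if (ped$ploidy[i] == 1L) {
        f[mo, j]
      } else {
        0.5 * (f[mo, j] + f[fa, j])
      }
      f[i, j] <- f[j, i] <- fij
    }
  }
  f
}

#' Brother-sister kinship under haplodiploidy
#'
#' Kinship between a haploid brother and his full diploid sister, computed by
#' pedigree enumeration of the 4-member family (dam, sire, brother, sister)
#' rather than hard-coded. This is also the inbreeding coefficient F of a
#' diploid male produced by that brother-sister pair.
#'
#' @return the kinship coefficient (0.25 for outbred, unrelated grandparents).
#' @export
sibling_kinship_haplodiploid <- function() {
  ped <- pedigree(id = c("dam", "sire", "brother", "sister"),
                  mother = c(NA, NA, "dam", "dam"),
                  father = c(NA, NA, NA, "sire"),
                  ploidy = c(2L, 1L, 1L, 2L))
  unname(kinship_pedigree(ped)["brother", "sister"])
}

#' Probability that a diploid male is homozygous at every panel locus
#'
#' The power calculation behind heterozygosity-based ploidy calling: a diploid
#' male homozygous at all loci of the marker panel is falsely scored haploid.
#' Per locus, P(homozygous) = F + (1 - F) * sum(p_i^2), where F is the
#' inbreeding coefficient of the male (the kinship of its parents) and
#' sum(p_i^2) the homozygosity-by-state; loci are assumed independent, so the
#' panel-wide probability is the product.
#'
#' @param x either a list of `allele_freq_table`s (one per locus; homozygosity
#'   computed as sum of squared frequencies) or a numeric vector of expected
#'   heterozygosities He (homozygosity taken as 1 - He). Both input pathways
#'   are supported because published tables typically print He only.
#' @param F inbreeding coefficient; defaults to the haplodiploid full-sib
#'   value from [sibling_kinship_haplodiploid()].
#' @return the probability of all-locus homozygosity.
#' @export
all_homozygous_probability <- function(x, F = sibling_kinship_haplodiploid()) {
  stopifnot(length(F) == 1L, F >= 0, F <= 1)
  if (length(x) == 0L) stop_f("empty marker panel")
  if (is.list(x)) {
    hom <- vapply(x, function(t) {
      if (!inherits(t, "allele_freq_table")) stop_f("expected allele_freq_table")
      if (t$n_copies == 0L) stop_f("empty allele frequency table")
      sum(aft_freqs(t)^2)
    }, 0)
  } else {
    stopifnot(is.numeric(x), all(x >= 0 & x <= 1))
    hom <- 1 - x
  }
  prod(F + (1 - F) * hom)
}

#' Point estimate and confidence interval for a diploid male proportion
#'
#' @param n_diploid,n_haploid counts of diploid and haploid calls.
#' @param ci_method `"clopper_pearson"` (exact, the default) or `"wilson"`.
#' @param level confidence level.
#' @return an object of class `dmp_estimate` with fields `n_diploid`,
#'   `n_haploid`, `dmp`, `se` (binomial standard error), `ci_low`, `ci_high`,
#'   `method`.
#' @export
dmp_estimate <- function(n_diploid, n_haploid,
                         ci_method = c("clopper_pearson", "wilson"),
                         level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(n_diploid >= 0, n_haploid >= 0)
  n <- n_diploid + n_haploid
  if (n == 0L) stop_f("no called males")
  x <- n_diploid
  p <- x / n
  se <- sqrt(p * (1 - p) / n)
  a <- 1 - level
  if (ci_method == "clopper_pearson") {
    lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - a / 2)
    ctr <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- max(0, ctr - hw); hi <- min(1, ctr + hw)
  }
  structure(list(n_diploid = as.integer(n_diploid),
                 n_haploid = as.integer(n_haploid),
                 dmp = p, se = se, ci_low = lo, ci_high = hi,
                 method = ci_method, level = level),
            class = "dmp_estimate")
}

#' @export
print.dmp_estimate <- function(x, ...) {
  cat(sprintf("DMP = %.3f +/- %.3f (%d diploid / %d males), %.0f%% CI [%.3f, %.3f] (%s)\n",
              x$dmp, x$se, x$n_diploid, x$n_diploid + x$n_haploid,
              100 * x$level, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Summarize ploidy calls into a diploid male proportion
#'
#' @param calls data frame from [call_ploidy()].
#' @param ci_method passed to [dmp_estimate()].
#' @return a [dmp_estimate()] over the non-excluded calls.
#' @export
summarize_dmp <- function(calls, ci_method = c("clopper_pearson", "wilson")) {
  stopifnot(is.data.frame(calls), "call" %in% names(calls))
  nd <- sum(calls$call == "diploid")
  nh <- sum(calls$call == "haploid")
  if (nd + nh == 0L) stop_f("all calls are excluded")
  dmp_estimate(nd, nh, ci_method)
}
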