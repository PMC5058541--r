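# Nested binomial GLM relating the diploid male proportion to habitat type
# and within-habitat genetic diversity.

DMP_TERMS <- c("habitat", "habitat:allelic_richness", "habitat:private_alleles")

#' Fit the nested DMP-diversity binomial GLM
#'
#' Models per-population diploid male counts against haploid male counts with
#' a binomial error and logit link. The design has habitat-type intercepts
#' and habitat-specific slopes of allelic richness and private-allele number
#' nested within habitat (the continuous covariates are meaningful only
#' relative to their habitat). Columns made unidentifiable by the data --
#' e.g. a slope over a habitat whose covariate is constant, or a saturated
#' two-population habitat -- are detected by the pivoted QR decomposition of
#' the IRLS fit, dropped, and reported in `aliased`, never silently absorbed.
#'
#' @param records data frame with one row per population: columns `habitat`
#'   (factor or character with 2-3 levels), `n_diploid`, `n_haploid`, and the
#'   covariates named by `include` (`allelic_richness`, `private_alleles`);
#'   a `population` column is carried through when present.
#' @param include model terms, a subset of
#'   `c("habitat", "habitat:allelic_richness", "habitat:private_alleles")`.
#' @return an object of class `dmp_glm` with components `fit` (the underlying
#'   `glm`), `records`, `include`, `aliased` (dropped design columns) and
#'   `flagged_separation` (quasi-complete separation heuristic:
#'   some |coefficient| > 10 on the logit scale).
#' @seealso [lr_type2_tests()] for the analysis of deviance;
#'   `print`, `summary`, `coef`, `predict`, `simulate`, `residuals` and
#'   `plot` methods are available.
#' @examples
#' recs <- data.frame(
#'   habitat = c("mainland", "mainland", "captive", "captive"),
#'   n_diploid = c(3, 4, 9, 11), n_haploid = c(97, 96, 91, 89),
#'   allelic_richness = c(3.5, 3.6, 2.4, 2.2),
#'   private_alleles = c(4, 2, 0, 0))
#' fit <- dmp_glm(recs)
#' coef(fit)
#' anova(fit)
#' @export
dmp_glm <- function(records, include = DMP_TERMS) {
  stopifnot(is.data.frame(records))
  include <- match.arg(include, DMP_TERMS, several.ok = TRUE)
  need <- unique(c("habitat", "n_diploid", "n_haploid",
                   unlist(lapply(strsplit(include, ":"), setdiff, "habitat"))))
  if (!all(need %in% names(records)))
    stop_f("records needs columns %s", paste(need, collapse = ", "))
  records <- as.data.frame(records)
  if (!is.factor(records$habitat))
    records$habitat <- factor(records$habitat,
                              levels = intersect(HABITAT_LEVELS,
                                                 unique(records$habitat)))
  records$habitat <- droplevels(records$habitat)
  if (nlevels(records$habitat) < 2L)
    stop_f("need populations from at least 2 habitat types")
  if (any(records$n_diploid < 0) || any(records$n_haploid < 0) ||
      sum(records$n_diploid + records$n_haploid) <= 0)
    stop_f("invalid male counts")

  fit <- fit_terms(include, records)
  if (!fit$converged)
    stop_f("IRLS did not converge in %d iterations (deviance %.4g)",
           fit$iter, fit$deviance)
  cf <- stats::coef(fit)
  aliased <- names(cf)[is.na(cf)]
  flagged <- any(abs(cf) > 10, na.rm = TRUE)
  structure(list(fit = fit, records = records, include = include,
                 aliased = aliased, flagged_separation = flagged,
                 call = match.call()),
            class = "dmp_glm")
}

# glm fit for a subset of nested terms (empty subset = intercept-only).
fit_terms <- function(terms, records) {
  rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
  f <- stats::as.formula(paste("cbind(n_diploid, n_haploid) ~", rhs))
  stats::glm(f, family = stats::binomial("logit"), data = records,
             control = stats::glm.control(epsilon = 1e-10, maxit = 200))
}

#' Type-II likelihood-ratio analysis of deviance
#'
#' Tests each model term with a likelihood-ratio chi-square that respects
#' marginality: the reference model for a term contains every other term that
#' does not itself contain the tested term, and the term's chi-square is the
#' deviance drop it produces over that reference. Degrees of freedom count
#' the estimable (non-aliased) columns the term adds, so a term whose columns
#' are entirely aliased is reported with df = 0 and no test.
#'
#' @param object a [dmp_glm()] fit.
#' @return data frame with columns `term`, `lr_chisq`, `df`, `p`; attribute
#'   `"notes"` lists terms with aliasing.
#' @export
lr_type2_tests <- function(object) {
  stopifnot(inherits(object, "dmp_glm"))
  records <- object$records
  terms <- object$include
  facs <- strsplit(terms, ":")
  contains <- function(a, b) all(facs[[b]] %in% facs[[a]]) && a != b
  rows <- list(); notes <- character()
  for (ti in seq_along(terms)) {
    base <- terms[vapply(seq_along(terms),
                         function(ui) ui != ti && !contains(ui, ti), TRUE)]
    m1 <- fit_terms(c(base, terms[ti]), records)
    m0 <- fit_terms(base, records)
    df <- m0$df.residual - m1$df.residual
    lr <- stats::deviance(m0) - stats::deviance(m1)
    if (df == 0L) {
      notes <- c(notes, sprintf(
        "term %s adds no estimable column (aliased); test omitted", terms[ti]))
      rows[[ti]] <- data.frame(term = terms[ti], lr_chisq = NA_real_,
                               df = 0L, p = NA_real_)
    } else {
      rows[[ti]] <- data.frame(
        term = terms[ti], lr_chisq = lr, df = df,
        p = stats::pchisq(lr, df, lower.tail = FALSE))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "notes") <- notes
  out
}

#' @export
print.dmp_glm <- function(x, ...) {
  cat("Nested binomial GLM for diploid male proportion (logit link)\n")
  cat("Terms:", paste(x$include, collapse = " + "), "\n")
  cf <- stats::coef(x$fit)
  print(round(cf[!is.na(cf)], 4))
  if (length(x$aliased))
    cat("Aliased (dropped) columns:", paste(x$aliased, collapse = ", "), "\n")
  if (x$flagged_separation)
    cat("Note: some coefficients are extreme; quasi-complete separation likely\n")
  invisible(x)
}

#' @export
summary.dmp_glm <- function(object, ...) {
  structure(list(coefficients = stats::coef(summary(object$fit)),
                 aliased = object$aliased,
                 flagged_separation = object$flagged_separation,
                 type2 = lr_type2_tests(object),
                 deviance = stats::deviance(object$fit),
                 null_deviance = object$fit$null.deviance,
                 include = object$include),
            class = "summary.dmp_glm")
}

#' @export
print.summary.dmp_glm <- function(x, ...) {
  cat("Nested binomial GLM for diploid male proportion\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients)
  if (length(x$aliased))
    cat("\nAliased (dropped) columns:", paste(x$aliased, collapse = ", "), "\n")
  cat(sprintf("\nNull deviance %.3f, residual deviance %.3f\n",
              x$null_deviance, x$deviance))
  cat("\nType-II likelihood-ratio tests:\n")
  print(x$type2, row.names = FALSE)
  for (n in attr(x$type2, "notes")) cat("  note:", n, "\n")
  if (x$flagged_separation)
    cat("Note: extreme coefficients; quasi-complete separation likely\n")
  invisible(x)
}

#' @export
coef.dmp_glm <- function(object, ...) stats::coef(object$fit)

#' @export
anova.dmp_glm <- function(object, ...) lr_type2_tests(object)

#' Predicted diploid male proportions
#'
#' @param object a [dmp_glm()] fit.
#' @param newdata optional data frame with the model covariates; defaults to
#'   the fitted records.
#' @param type `"response"` (DMP scale) or `"link"` (logit scale).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.dmp_glm <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    return(stats::predict(object$fit, type = type))
  stats::predict(object$fit, newdata = newdata, type = type)
}

#' @export
residuals.dmp_glm <- function(object, ...) stats::residuals(object$fit, ...)

#' Simulate diploid male counts from a fitted DMP model
#'
#' Parametric simulation: for each population, draws the diploid male count
#' from Binomial(n, p-hat) with n the genotyped males and p-hat the fitted
#' DMP.
#'
#' @param object a [dmp_glm()] fit.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return data frame with one column per replicate of simulated `n_diploid`.
#' @export
simulate.dmp_glm <- function(object, nsim = 1, seed = NULL, ...) {
  p <- stats::predict(object$fit, type = "response")
  n <- object$records$n_diploid + object$records$n_haploid
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, stats::rbinom(length(n), n, p)))
    names(out) <- paste0("sim_", seq_len(nsim))
    if (!is.null(object$records$population))
      rownames(out) <- object$records$population
    out
  })
}

#' @export
plot.dmp_glm <- function(x, ...) {
  obs <- x$records$n_diploid / (x$records$n_diploid + x$records$n_haploid)
  fitd <- stats::predict(x$fit, type = "response")
  plot(fitd, obs, xlab = "fitted DMP", ylab = "observed DMP",
       pch = 19, col = as.integer(x$records$habitat), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = levels(x$records$habitat),
                   col = seq_len(nlevels(x$records$habitat)), pch = 19,
                   bty = "n")
  invisible(x)
}
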