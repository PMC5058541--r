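# GENEPOP dialect reader/writer.
#
# GENEPOP files have no ploidy notation, so ploidy and sex travel in a
# tab-separated sidecar table (id, population, sex, ploidy, habitat, year);
# the sidecar is the authoritative ploidy carrier and haploid genotypes are
# written with the allele duplicated only for interoperability.

#' Write a genotype dataset in GENEPOP format
#'
#' Writes a standard GENEPOP file (title line, one locus name per line, `POP`
#' blocks, `id ,  aaabbb ...` records with 3-digit allele codes) plus a
#' ploidy sidecar TSV at `<path>.ploidy.tsv`. Haploid individuals are written
#' either with their allele duplicated (`duplicate`) or merged pairwise into
#' "false diploids" (`merge_pairs`, see [merge_haploid_pairs()]).
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file path.
#' @param haploid_mode `"duplicate"` or `"merge_pairs"`.
#' @param title title line; default names the package.
#' @return invisibly, a list with the genepop and sidecar paths.
#' @export
write_genepop <- function(dataset, path,
                          haploid_mode = c("duplicate", "merge_pairs"),
                          title = NULL) {
  haploid_mode <- match.arg(haploid_mode)
  stopifnot(inherits(dataset, "genotype_dataset"))
  pops <- dataset$populations
  if (haploid_mode == "merge_pairs") {
    pops <- lapply(pops, function(p) {
      hap <- p$data$ploidy == "haploid"
      if (!any(hap)) return(p)
      merged <- merge_haploid_pairs(
        population_sample(p$name, p$habitat, p$data[hap, , drop = FALSE],
                          p$year))
      rest <- p$data[!hap, , drop = FALSE]
      population_sample(p$name, p$habitat, rbind(rest, merged$data), p$year,
                        allow_partial = TRUE)
    })
  }

  loci <- dataset$loci$name
  for (p in pops) for (l in loci) {
    a <- c(p$data[[paste0(l, ".1")]], p$data[[paste0(l, ".2")]])
    if (any(a > 999, na.rm = TRUE))
      stop_f("allele label > 999 at locus %s: not representable as a 3-digit GENEPOP code", l)
  }

  code <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a))
  lines <- c(title %||% "slcsd genotype export", loci)
  sidecar <- list()
  for (p in pops) {
    lines <- c(lines, "POP")
    gcols <- character(nrow(p$data))
    for (l in loci) {
      a1 <- p$data[[paste0(l, ".1")]]
      a2 <- p$data[[paste0(l, ".2")]]
      a2 <- ifelse(p$data$ploidy == "haploid" & !is.na(a1), a1, a2)
      gcols <- paste(gcols, paste0(code(a1), code(a2)))
    }
    lines <- c(lines, paste0(p$data$id, " ,", gcols))
    sidecar[[p$name]] <- data.frame(
      id = p$data$id, population = p$name, sex = p$data$sex,
      ploidy = p$data$ploidy,
      habitat = ifelse(is.na(p$habitat), "NA", p$habitat),
      year = ifelse(is.na(p$year), "NA", as.character(p$year)),
      stringsAsFactors = FALSE)
  }
  writeLines(lines, path)
  sc_path <- paste0(path, ".ploidy.tsv")
  utils::write.table(do.call(rbind, sidecar), sc_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(genepop = path, sidecar = sc_path))
}

#' Read a GENEPOP file into a genotype dataset
#'
#' Parses the GENEPOP layout (title, locus names, `POP` blocks, comma-separated
#' individual records with 2- or 3-digit allele codes; `00`/`000` codes are
#' missing). A ploidy sidecar TSV (columns `id`, `population`, `sex`,
#' `ploidy`, optionally `habitat` and `year`) assigns sex and declared ploidy;
#' for haploid individuals the duplicated allele coding is collapsed back to a
#' single allele. Without a sidecar all individuals are read as sex-unknown
#' diploids.
#'
#' @param path GENEPOP file path.
#' @param ploidy_sidecar optional sidecar path (defaults to
#'   `<path>.ploidy.tsv` when that file exists).
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path, ploidy_sidecar = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop_f("%s: not a GENEPOP file (too short)", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop_f("%s: no POP line found", path)
  loci <- unlist(strsplit(lines[2:(first_pop - 1L)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop_f("%s: duplicate locus name", path)
  n_loci <- length(loci)

  sc <- NULL
  if (is.null(ploidy_sidecar) && file.exists(paste0(path, ".ploidy.tsv")))
    ploidy_sidecar <- paste0(path, ".ploidy.tsv")
  if (!is.null(ploidy_sidecar)) {
    sc <- utils::read.delim(ploidy_sidecar, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("id", "population", "sex", "ploidy")
    if (!all(need %in% names(sc)))
      stop_f("sidecar needs columns %s", paste(need, collapse = ", "))
    if (anyDuplicated(sc$id)) stop_f("duplicate id in sidecar")
  }

  # split POP blocks
  blocks <- split(seq_along(lines)[-seq_len(first_pop - 1L)] , cumsum(is_pop)[-seq_len(first_pop - 1L)])
  pops <- list()
  all_ids <- character()
  for (b in blocks) {
    rows <- b[!is_pop[b]]
    if (length(rows) == 0L) next
    ids <- character(length(rows))
    amat <- matrix(NA_integer_, length(rows), 2L * n_loci)
    for (r in seq_along(rows)) {
      ln <- lines[rows[r]]
      pieces <- strsplit(ln, ",")[[1L]]
      if (length(pieces) < 2L)
        stop_f("%s: malformed individual record at line %d", path, rows[r])
      ids[r] <- trimws(pieces[1L])
      toks <- strsplit(trimws(paste(pieces[-1L], collapse = ",")),
                       "[[:space:]]+")[[1L]]
      if (length(toks) != n_loci)
        stop_f("%s: line %d has %d genotypes, expected %d",
               path, rows[r], length(toks), n_loci)
      for (j in seq_len(n_loci)) {
        tk <- toks[j]
        w <- nchar(tk) / 2L
        if (!nchar(tk) %in% c(4L, 6L) || grepl("[^0-9]", tk))
          stop_f("%s: line %d, locus %s: bad genotype code '%s'",
                 path, rows[r], loci[j], tk)
        a1 <- as.integer(substr(tk, 1L, w))
        a2 <- as.integer(substr(tk, w + 1L, 2L * w))
        amat[r, 2L * j - 1L] <- ifelse(a1 == 0L, NA_integer_, a1)
        amat[r, 2L * j]      <- ifelse(a2 == 0L, NA_integer_, a2)
      }
    }
    if (anyDuplicated(ids))
      stop_f("%s: duplicate individual id in POP block", path)
    all_ids <- c(all_ids, ids)
    pops[[length(pops) + 1L]] <- list(ids = ids, amat = amat)
  }
  if (!is.null(sc) && !all(sc$id %in% all_ids))
    stop_f("sidecar id(s) not present in %s: %s", path,
           paste(setdiff(sc$id, all_ids), collapse = ", "))

  samples <- vector("list", length(pops))
  for (i in seq_along(pops)) {
    ids <- pops[[i]]$ids
    amat <- pops[[i]]$amat
    sex <- rep("unknown", length(ids))
    ploidy <- rep("diploid", length(ids))
    name <- paste0("pop", i)
    habitat <- NA_character_; year <- NA_integer_
    if (!is.null(sc)) {
      m <- match(ids, sc$id)
      hit <- !is.na(m)
      sex[hit] <- sc$sex[m[hit]]
      ploidy[hit] <- sc$ploidy[m[hit]]
      if (any(hit)) {
        name <- sc$population[m[hit][1L]]
        if ("habitat" %in% names(sc)) {
          h <- sc$habitat[m[hit][1L]]
          habitat <- ifelse(h == "NA", NA_character_, h)
        }
        if ("year" %in% names(sc)) {
          y <- sc$year[m[hit][1L]]
          year <- ifelse(y == "NA", NA_integer_, as.integer(y))
        }
      }
    }
    d <- data.frame(id = ids, sex = sex, ploidy = ploidy,
                    stringsAsFactors = FALSE)
    for (j in seq_along(loci)) {
      a1 <- amat[, 2L * j - 1L]
      a2 <- amat[, 2L * j]
      # single scored allele: keep it in ".1"
      swap <- is.na(a1) & !is.na(a2)
      a1[swap] <- a2[swap]; a2[swap] <- NA_integer_
      hap <- ploidy == "haploid"
      if (any(hap & !is.na(a1) & !is.na(a2) & a1 != a2))
        stop_f("%s: haploid individual with two distinct alleles at %s",
               path, loci[j])
      a2[hap] <- NA_integer_  # collapse duplicated coding
      d[[paste0(loci[j], ".1")]] <- a1
      d[[paste0(loci[j], ".2")]] <- a2
    }
    samples[[i]] <- population_sample(name, habitat, d, year,
                                      allow_partial = TRUE)
  }
  genotype_dataset(samples)
}
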