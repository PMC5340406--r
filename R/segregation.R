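#' Read or build a sample sheet
#'
#' @param path TSV with columns `sample`, `phenotype`
#'   (`affected`/`unaffected`), `relation` (`case`, `parent`,
#'   `grandparent`, `sibling`, `population`, `other`) and
#'   `obligate_carrier` (logical).
#' @return data.frame sample sheet.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("character", "character", "character",
                                     "logical"))
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  stopifnot(all(c("sample", "phenotype", "relation", "obligate_carrier") %in%
                names(sheet)))
  if (anyDuplicated(sheet$sample)) stop("duplicate sample ids in sheet")
  if (!all(sheet$phenotype %in% c("affected", "unaffected")))
    stop("phenotype must be affected/unaffected")
  if (!all(sheet$relation %in% c("case", "parent", "grandparent", "sibling",
                                 "population", "other")))
    stop("unknown relation in sample sheet")
  if (any(sheet$phenotype == "affected" & sheet$relation != "case") ||
      any(sheet$relation == "case" & sheet$phenotype != "affected"))
    stop("affected phenotype and case relation must coincide")
  sheet
}

#' Check genotypes of one variant against recessive segregation
#'
#' Expected genotype sets: affected cases hom-alt; obligate carriers
#' het; unaffected non-obligate relatives/population het or hom-ref.
#' Samples absent from `genotypes` (or with a missing call) are listed
#' as inconsistencies with observation `"missing"`, never silently
#' dropped.
#'
#' @param genotypes named integer vector of alt-allele counts, names are
#'   sample ids.
#' @param sheet sample sheet data.frame (see [read_sample_sheet()]).
#' @return object of class `segregation_report`: list with
#'   `n_consistent`, `inconsistencies` (data.frame `sample`, `expected`,
#'   `observed`), `fully_segregating`.
#' @export
check_recessive_segregation <- function(genotypes, sheet) {
  sheet <- validate_sample_sheet(sheet)
  code_lab <- function(g) c("hom-ref", "het", "hom-alt")[g + 1L]
  inc <- list()
  n_consistent <- 0L
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample[i]
    expected <- if (sheet$relation[i] == "case") 2L
                else if (isTRUE(sheet$obligate_carrier[i])) 1L
                else c(0L, 1L)
    exp_lab <- paste(code_lab(expected), collapse = "|")
    g <- if (sid %in% names(genotypes)) genotypes[[sid]] else NA_integer_
    if (is.na(g)) {
      inc[[length(inc) + 1]] <- data.frame(sample = sid, expected = exp_lab,
                                           observed = "missing")
    } else if (g %in% expected) {
      n_consistent <- n_consistent + 1L
    } else {
      inc[[length(inc) + 1]] <- data.frame(sample = sid, expected = exp_lab,
                                           observed = code_lab(g))
    }
  }
  inconsistencies <- if (length(inc)) do.call(rbind, inc)
    else data.frame(sample = character(), expected = character(),
                    observed = character())
  structure(list(n_consistent = n_consistent,
                 inconsistencies = inconsistencies,
                 fully_segregating = nrow(inconsistencies) == 0),
            class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat("segregation_report:", x$n_consistent, "consistent,",
      nrow(x$inconsistencies), "inconsistent;",
      if (x$fully_segregating) "fully segregating" else "NOT fully segregating",
      "\n")
  if (nrow(x$inconsistencies)) print(x$inconsistencies)
  invisible(x)
}

#' Carrier frequency in a population screen
#'
#' Heterozygotes among the screened population; the percentage is
#' rounded half-up to one decimal. Hom-alt individuals are reported
#' separately as genetically affected, not as carriers.
#'
#' @param genotypes named integer vector of alt-allele counts.
#' @param population_ids ids of the screened population sample.
#' @return list of class `carrier_estimate`: `n_het`, `n_screened`,
#'   `frequency_pct`, `n_genetically_affected`.
#' @export
carrier_frequency <- function(genotypes, population_ids) {
  if (length(population_ids) == 0) stop("empty population sample")
  miss <- setdiff(population_ids, names(genotypes))
  if (length(miss))
    stop("population sample(s) not genotyped: ", paste(miss, collapse = ", "))
  g <- genotypes[population_ids]
  n_screened <- length(population_ids)
  n_het <- sum(g == 1L, na.rm = TRUE)
  structure(list(n_het = n_het, n_screened = n_screened,
                 frequency_pct = round_half_up(100 * n_het / n_screened, 1),
                 n_genetically_affected = sum(g == 2L, na.rm = TRUE)),
            class = "carrier_estimate")
}

#' @export
print.carrier_estimate <- function(x, ...) {
  cat(sprintf("carrier_estimate: %d/%d heterozygotes (%.1f%%), %d genetically affected\n",
              x$n_het, x$n_screened, x$frequency_pct, x$n_genetically_affected))
  invisible(x)
}

#' Build a 2x2 allelic contingency table
#'
#' Each hom-alt individual contributes two alternate alleles, each het
#' one of each, each hom-ref two reference alleles. Samples with a
#' missing genotype are excluded and counted in attribute `n_excluded`.
#'
#' @param case_genotypes,control_genotypes integer vectors of alt-allele
#'   counts.
#' @return object of class `allelic_table`: list with `case_alt`,
#'   `case_ref`, `control_alt`, `control_ref`.
#' @export
build_allelic_table <- function(case_genotypes, control_genotypes) {
  ca <- case_genotypes[!is.na(case_genotypes)]
  co <- control_genotypes[!is.na(control_genotypes)]
  out <- structure(list(case_alt = sum(ca), case_ref = 2L * length(ca) - sum(ca),
                        control_alt = sum(co),
                        control_ref = 2L * length(co) - sum(co)),
                   class = "allelic_table")
  attr(out, "n_excluded") <- (length(case_genotypes) - length(ca)) +
    (length(control_genotypes) - length(co))
  out
}

#' @export
print.allelic_table <- function(x, ...) {
  m <- matrix(c(x$case_alt, x$case_ref, x$control_alt, x$control_ref),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("case", "control"), c("alt", "ref")))
  print(m)
  invisible(x)
}

#' Pearson allelic chi-square association test
#'
#' Chi-square on the 2x2 allele-count table, 1 df, no continuity
#' correction. The tail probability is computed on the survival-function
#' side (never as `1 - CDF`), so p-values far below 1e-300 in log10
#' form remain meaningful; `log10_p` is reported alongside `p_value`.
#'
#' @param table an [build_allelic_table()] result.
#' @return object of class `assoc_result`: `chi_square`, `df`,
#'   `p_value`, `log10_p`.
#' @export
allelic_chisq <- function(table) {
  # doubles: the margin products overflow 32-bit integers on large cohorts
  a <- as.numeric(table$case_alt); b <- as.numeric(table$case_ref)
  c <- as.numeric(table$control_alt); d <- as.numeric(table$control_ref)
  n <- a + b + c + d
  if (any(c(a + b, c + d, a + c, b + d) == 0))
    stop("undefined statistic: zero margin in allelic table")
  chi <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  structure(list(chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 log10_p = stats::pchisq(chi, df = 1, lower.tail = FALSE,
                                         log.p = TRUE) / log(10)),
            class = "assoc_result")
}

#' Allelic association test (chi-square default, Fisher alternative)
#'
#' @param table an [build_allelic_table()] result.
#' @param method `"chisq"` (Pearson, df = 1, no Yates; default) or
#'   `"fisher"` (two-sided exact test on the allele table).
#' @return an `assoc_result` (Fisher results carry `chi_square = NA`).
#' @export
allelic_assoc <- function(table, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (method == "chisq") return(allelic_chisq(table))
  m <- matrix(c(table$case_alt, table$case_ref,
                table$control_alt, table$control_ref), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(m)$p.value
  structure(list(chi_square = NA_real_, df = NA_integer_, p_value = p,
                 log10_p = log10(p)), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result: chi-square = %.4f (df = %s), p = %.4g (log10 p = %.2f)\n",
              x$chi_square, x$df, x$p_value, x$log10_p))
  invisible(x)
}
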