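#' Segregation summary with an exact binomial test
#'
#' Summarizes the proportion of affected animals in a cross and tests it
#' against the Mendelian expectation (default 1/4, autosomal recessive)
#' with a two-sided exact binomial test (minimum-likelihood convention, as
#' in [stats::binom.test()]). The proportion is reported in percent,
#' rounded to `digits` decimal places (default whole percent).
#'
#' @param n_affected,n_total Affected and total counts.
#' @param expected_ratio Expected affected fraction under the model.
#' @param digits Decimal places of the reported percentage.
#' @return List of class `segregation_summary`: `n_total`, `n_affected`,
#'   `proportion` (percent, rounded), `p_value`, `expected_ratio`.
#' @examples
#' segregation_summary(12, 52)  # 23 percent, consistent with 1:4
#' @export
segregation_summary <- function(n_affected, n_total, expected_ratio = 0.25,
                                digits = 0L) {
  if (n_total <= 0 || n_affected < 0 || n_affected > n_total) {
    stop("invalid counts: need 0 <= n_affected <= n_total, n_total > 0")
  }
  p <- stats::binom.test(n_affected, n_total, p = expected_ratio,
                         alternative = "two.sided")$p.value
  structure(list(
    n_total = as.integer(n_total),
    n_affected = as.integer(n_affected),
    proportion = round(100 * n_affected / n_total, digits),
    p_value = p,
    expected_ratio = expected_ratio
  ), class = "segregation_summary")
}

#' @export
print.segregation_summary <- function(x, ...) {
  cat(sprintf("%d of %d affected (%s%%); exact binomial vs %.3g: p = %.4g\n",
              x$n_affected, x$n_total, format(x$proportion), x$expected_ratio,
              x$p_value))
  invisible(x)
}

#' Genotype-phenotype concordance under the recessive rule
#'
#' Cross-tabulates genotype (`hom_ref`, `het`, `hom_mut`) against
#' phenotype (`wildtype`, `mutant`) and lists individuals discordant with
#' a fully penetrant recessive model (mutant phenotype if and only if
#' `hom_mut`).
#'
#' @param genotypes Character/factor vector over `hom_ref`, `het`,
#'   `hom_mut`.
#' @param phenotypes Character/factor vector over `wildtype`, `mutant`.
#' @return List of class `concordance_table`: `table` (3 x 2 counts),
#'   `discordant_count`, `discordant_ids` (indices or names).
#' @export
concordance_table <- function(genotypes, phenotypes) {
  g_lev <- c("hom_ref", "het", "hom_mut")
  p_lev <- c("wildtype", "mutant")
  if (length(genotypes) != length(phenotypes)) stop("length mismatch")
  if (!all(genotypes %in% g_lev)) stop("unknown genotype category")
  if (!all(phenotypes %in% p_lev)) stop("unknown phenotype category")
  tab <- table(genotype = factor(genotypes, g_lev),
               phenotype = factor(phenotypes, p_lev))
  disc <- (genotypes == "hom_mut" & phenotypes == "wildtype") |
    (genotypes != "hom_mut" & phenotypes == "mutant")
  ids <- if (!is.null(names(genotypes))) names(genotypes)[disc] else which(disc)
  structure(list(table = tab, discordant_count = sum(disc),
                 discordant_ids = ids), class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  print(x$table)
  cat(sprintf("discordant with recessive rule: %d\n", x$discordant_count))
  invisible(x)
}

#' Expected pool allele frequencies and dAF under an inheritance model
#'
#' For a recessive locus in an F2 intercross with phenotype-selected
#' pools: the mutant-phenotype pool contains only homozygous mutants, so
#' its expected mutant-allele frequency is 1; a phenotypically wild-type
#' F2 animal is `hom_ref` with probability 1/3 and `het` with probability
#' 2/3, giving a wild-type-pool frequency of 1/3 and an expected dAF of
#' 2/3. An alternative `"equal-carrier-classes"` composition weights the
#' two wild-type genotype classes equally (frequency 1/4, dAF 3/4); this
#' is not the F2 phenotype-conditional distribution but is provided
#' because expected values of 0.75 are sometimes quoted for this design.
#'
#' @param mode Inheritance mode; only `"recessive"` is supported.
#' @param composition `"phenotype-selected"` (default) or
#'   `"equal-carrier-classes"`.
#' @return List: `mut_pool_freq`, `wt_pool_freq`, `expected_daf`,
#'   `composition`.
#' @export
expected_pool_daf <- function(mode = "recessive",
                              composition = c("phenotype-selected",
                                              "equal-carrier-classes")) {
  if (!identical(mode, "recessive")) {
    stop("unsupported inheritance mode: ", mode)
  }
  composition <- match.arg(composition)
  wt <- if (composition == "phenotype-selected") {
    # P(hom_ref | wildtype phenotype) = 1/3, P(het | .) = 2/3
    (1 / 3) * 0 + (2 / 3) * 0.5
  } else {
    0.5 * 0 + 0.5 * 0.5
  }
  list(mut_pool_freq = 1, wt_pool_freq = wt, expected_daf = 1 - wt,
       composition = composition)
}

#' Relative expression from quantification cycles (-dCq)
#'
#' `-dCq = -(Cq_target - Cq_reference)`; the fold change on the linear
#' scale is `2^(-dCq)`. Vectors of technical replicates are summarized by
#' the mean with min/max range.
#'
#' @param cq_target,cq_reference Quantification cycles (vectors of
#'   replicates allowed; recycled to common length).
#' @return List: `minus_dcq` (per replicate), `fold` (per replicate),
#'   `mean_minus_dcq`, `range_minus_dcq` (min, max).
#' @export
delta_cq <- function(cq_target, cq_reference) {
  if (!all(is.finite(cq_target)) || !all(is.finite(cq_reference))) {
    stop("Cq values must be finite")
  }
  mdcq <- -(cq_target - cq_reference)
  list(minus_dcq = mdcq, fold = 2^mdcq,
       mean_minus_dcq = mean(mdcq),
       range_minus_dcq = range(mdcq))
}
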