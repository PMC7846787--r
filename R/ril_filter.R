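#' Filter RIL variants by quality, MAF, heterozygosity and coverage
#'
#' Applies the GBS marker filters in two stages. First, individual calls
#' with GQ below `min_genotype_quality` are set to missing (unknown GQ
#' passes). Then markers are removed if, over non-missing non-parent
#' samples, minor allele frequency is below `min_maf`, the heterozygous
#' fraction exceeds `max_het_rate`, or fewer than
#' `min_genotyped_individuals` samples are genotyped. Each removed marker
#' is attributed to the first failing rule, in the order
#' coverage, MAF, heterozygosity, for a deterministic audit trail.
#'
#' @param m A [marker_geno()] with designated parents.
#' @param config A [pipeline_config()].
#' @return The filtered [marker_geno()]; attribute `filter_report` is a
#'   list with `quality_induced_missing` (calls masked by GQ) and per-rule
#'   removal counts.
#' @export
filter_variants <- function(m, config = pipeline_config()) {
  if (is.null(m$parents)) stop("filter_variants requires designated parents")
  n_masked <- 0L
  if (!is.null(m$gq)) {
    mask <- !is.na(m$gq) & m$gq < config$min_genotype_quality &
      !is.na(m$calls)
    n_masked <- sum(mask)
    if (n_masked > 0L) {
      m$calls[mask] <- NA_integer_
      m$gq[mask] <- NA_real_
    }
  }
  st <- marker_stats(m)
  fail_cov <- st$n_genotyped < config$min_genotyped_individuals
  fail_maf <- !fail_cov & (is.na(st$maf) | st$maf < config$min_maf)
  fail_het <- !fail_cov & !fail_maf & st$het_rate > config$max_het_rate
  keep <- !(fail_cov | fail_maf | fail_het)
  if (!any(keep))
    stop("all markers removed by filtering")
  out <- subset_markers(m, keep)
  attr(out, "filter_report") <- list(
    quality_induced_missing = n_masked,
    coverage = sum(fail_cov),
    maf = sum(fail_maf),
    het = sum(fail_het),
    retained = sum(keep))
  out
}
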