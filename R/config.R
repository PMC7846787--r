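#' Pipeline configuration
#'
#' Collects every numeric threshold used by the anchoring pipeline in one
#' validated object. Defaults reproduce the published analysis settings:
#' genotype-quality, minor-allele-frequency, heterozygosity and coverage
#' filters for the GBS calls; the two-state imputation HMM (`-k 2 -c 0.003`
#' style switch probability); the r-squared > 0.8 contig-linkage rule; the
#' five-generations-of-crossover centimorgan rule; the 1 Mbp / 200 kbp
#' Marey sliding window; and the 2 Mbp/cM pericentromere cutoff.
#'
#' @param min_genotype_quality Minimum Phred genotype quality; individual
#'   calls below it are set to missing before marker-level filters.
#' @param min_maf Minimum minor allele frequency across non-parent samples.
#' @param max_het_rate Maximum per-marker heterozygous-call fraction.
#' @param min_genotyped_individuals Minimum non-missing non-parent samples.
#' @param hmm_switch_prob Per adjacent-marker transition probability of the
#'   parental-assignment HMM.
#' @param hmm_states Number of HMM states (two parents).
#' @param hmm_error_rate Probability of observing the opposite homozygote.
#' @param r2_threshold r-squared above which a marker pair counts as
#'   linkage evidence between contigs.
#' @param segment_r2_threshold r-squared below which adjacent markers on
#'   one contig are considered unlinked, splitting the contig's markers
#'   into candidate-chimera segments.
#' @param min_ld_pairs Number of high-LD pairs required before two contigs
#'   are joined in the linkage graph.
#' @param ld_pair_cap Maximum inter-contig marker pairs evaluated per
#'   contig pair (deterministic, evenly spaced subsample per contig).
#' @param generations_of_crossover Effective generations of crossover in
#'   the breakpoint-to-centimorgan rule (may be non-integer; see vignette).
#' @param crossovers_per_chr_per_gen Expected crossovers per chromosome per
#'   generation assumed by that rule.
#' @param end_window_bp Window at each contig end in which barcodes are
#'   collected (truncated to half the contig for short contigs).
#' @param min_shared_barcodes Shared barcodes required to keep a
#'   scaffold-graph edge.
#' @param max_end_occurrences Barcodes seen at more than this many contig
#'   ends are discarded as promiscuous (repeat-driven).
#' @param marey_window_bp Sliding window size for recombination rates.
#' @param marey_step_bp Step between successive windows.
#' @param pericentromere_mbp_per_cm Mbp-per-cM above which a window is
#'   pericentromeric (rate below `1/pericentromere_mbp_per_cm` cM/Mbp).
#' @param agp_gap_bp Gap length inserted between placed components.
#' @param seed Integer seed from which all stochastic steps derive
#'   substreams.
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(min_genotype_quality = 30,
                            min_maf = 0.3,
                            max_het_rate = 0.05,
                            min_genotyped_individuals = 100,
                            hmm_switch_prob = 0.003,
                            hmm_states = 2,
                            hmm_error_rate = 0.01,
                            r2_threshold = 0.8,
                            segment_r2_threshold = 0.2,
                            min_ld_pairs = 3,
                            ld_pair_cap = 200,
                            generations_of_crossover = 5,
                            crossovers_per_chr_per_gen = 1,
                            end_window_bp = 20000,
                            min_shared_barcodes = 5,
                            max_end_occurrences = 4,
                            marey_window_bp = 1000000,
                            marey_step_bp = 200000,
                            pericentromere_mbp_per_cm = 2.0,
                            agp_gap_bp = 100,
                            seed = 1L) {
  cfg <- list(
    min_genotype_quality = min_genotype_quality,
    min_maf = min_maf,
    max_het_rate = max_het_rate,
    min_genotyped_individuals = min_genotyped_individuals,
    hmm_switch_prob = hmm_switch_prob,
    hmm_states = hmm_states,
    hmm_error_rate = hmm_error_rate,
    r2_threshold = r2_threshold,
    segment_r2_threshold = segment_r2_threshold,
    min_ld_pairs = min_ld_pairs,
    ld_pair_cap = ld_pair_cap,
    generations_of_crossover = generations_of_crossover,
    crossovers_per_chr_per_gen = crossovers_per_chr_per_gen,
    end_window_bp = end_window_bp,
    min_shared_barcodes = min_shared_barcodes,
    max_end_occurrences = max_end_occurrences,
    marey_window_bp = marey_window_bp,
    marey_step_bp = marey_step_bp,
    pericentromere_mbp_per_cm = pericentromere_mbp_per_cm,
    agp_gap_bp = agp_gap_bp,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  probs <- c("min_maf", "max_het_rate", "hmm_switch_prob", "hmm_error_rate",
             "r2_threshold", "segment_r2_threshold")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("config field '%s' must be a probability in [0,1]", p))
  }
  counts <- c("min_genotyped_individuals", "hmm_states", "min_ld_pairs",
              "ld_pair_cap", "max_end_occurrences",
              "end_window_bp", "min_shared_barcodes", "marey_window_bp",
              "marey_step_bp", "agp_gap_bp")
  for (p in counts) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 ||
        v != round(v))
      stop(sprintf("config field '%s' must be a positive integer", p))
  }
  pos <- c("min_genotype_quality", "generations_of_crossover",
           "crossovers_per_chr_per_gen", "pericentromere_mbp_per_cm")
  for (p in pos) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("config field '%s' must be positive", p))
  }
  if (cfg$marey_step_bp > cfg$marey_window_bp)
    stop("marey_step_bp must not exceed marey_window_bp")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("anchormap pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a pipeline configuration from a key: value text file
#'
#' Accepts a minimal YAML-like syntax: one `key: value` pair per line,
#' `#` comments and blank lines ignored. Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A [pipeline_config()] with the file's overrides applied.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- formals(pipeline_config)
  args <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[[i]], ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("config line %d is not 'key: value': '%s'", i, lines[[i]]))
    key <- trimws(kv[[1]]); val <- trimws(kv[[2]])
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key '%s' (line %d)", key, i))
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) stop(sprintf("non-numeric value for '%s' (line %d)", key, i))
    args[[key]] <- num
  }
  do.call(pipeline_config, args)
}
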