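#' The package's reference simulation
#'
#' One stated synthetic world used by the acceptance tests and the
#' worked examples: an 11-chromosome inbred genome totalling 55 Mbp,
#' fragmented into ~120 contigs (exponential lengths, mean 460 kbp,
#' minimum 20 kbp), an F8 single-seed-descent RIL population of
#' `n_individuals` lines genotyped at ~3300 markers (60 per Mbp) with
#' 10% missingness and 1% genotyping error, and 30x linked-read
#' molecule coverage (exponential molecules, mean 50 kbp, two molecules
#' per barcode, 0.3 reads per kbp). Each chromosome is 50 cM, which
#' preserves the published map's genetic spacing per contig (about 5 cM)
#' at the scaled-down physical size; see the vignette for why that, and
#' not the per-chromosome genetic length, is the invariant that matters
#' to the LD and ordering steps. The matching analysis configuration
#' scales the coverage filter to the population size
#' (`min_genotyped_individuals = n_individuals / 2`) and uses package
#' defaults otherwise.
#'
#' @param seed Master seed.
#' @param n_individuals RIL lines.
#' @param n_chimeras Injected chimeric contigs.
#' @param coverage Linked-read molecule coverage (x genome).
#' @param with_linked_reads Simulate the barcode table (the expensive
#'   part); set `FALSE` when only genotypes are needed.
#' @return List: `genome`, `truth`, `pop`, `m` (genotype matrix with
#'   parents), `aln` (barcode table or `NULL`), `contig_lengths`,
#'   `config`.
#' @export
reference_simulation <- function(seed = 1, n_individuals = 100,
                                 n_chimeras = 3, coverage = 30,
                                 with_linked_reads = TRUE) {
  genome <- simulate_genome(11, rep(5e6, 11), rep(50, 11),
                            plateau_fraction = 0, marker_density = 60,
                            seed = seed)
  truth <- fragment_genome(genome, 460000, n_chimeras = n_chimeras,
                           seed = seed)
  pop <- simulate_ril_population(genome, n_individuals, 7, seed = seed)
  m <- genotype_population(pop, genome, truth, missing_rate = 0.1,
                           error_rate = 0.01, seed = seed)
  aln <- NULL
  if (with_linked_reads) {
    mol_mean <- 50000
    n_bc <- ceiling(coverage * sum(genome$chrom$length_bp) /
                      (mol_mean * 2))
    aln <- simulate_linked_reads(truth, genome, mol_mean, 2, n_bc,
                                 reads_per_kbp = 0.3, seed = seed)
  }
  config <- pipeline_config(
    min_genotyped_individuals = max(2, round(n_individuals / 2)),
    seed = seed)
  list(genome = genome, truth = truth, pop = pop, m = m, aln = aln,
       contig_lengths = stats::setNames(truth$contig_len$length,
                                        truth$contig_len$contig),
       config = config)
}
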