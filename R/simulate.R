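#' Simulate an inbred reference genome with a Marey-shaped recombination map
#'
#' Each chromosome gets a piecewise-linear Marey function (physical bp to
#' cumulative cM) with an optional central low-recombination plateau
#' emulating a pericentromere: the plateau spans `plateau_fraction` of the
#' physical length and recombines at `plateau_rate_ratio` times the arm
#' rate, with the arm rate solved so the total genetic length is honoured.
#' Markers are placed uniformly at random, deduplicated and sorted.
#'
#' @param n_chr Number of chromosomes.
#' @param lengths_bp Physical lengths (bp), length `n_chr`.
#' @param cm_lengths Genetic lengths (cM), length `n_chr`.
#' @param plateau_fraction Fraction of each chromosome occupied by the
#'   central plateau (0 = uniform recombination).
#' @param plateau_rate_ratio Plateau rate as a fraction of the arm rate,
#'   in (0, 1].
#' @param marker_density Markers per Mbp.
#' @param seed Integer seed.
#' @return An object of class `true_genome`: chromosome table, per
#'   chromosome Marey breakpoints, and a marker catalog.
#' @export
simulate_genome <- function(n_chr, lengths_bp, cm_lengths,
                            plateau_fraction = 0, plateau_rate_ratio = 0.1,
                            marker_density = 50, seed = 1L) {
  stopifnot(length(lengths_bp) == n_chr, length(cm_lengths) == n_chr)
  if (any(cm_lengths <= 0 & lengths_bp > 0))
    stop("chromosomes with physical length need a positive genetic length")
  if (plateau_fraction < 0 || plateau_fraction >= 1)
    stop("plateau_fraction must be in [0,1)")
  if (plateau_fraction > 0 &&
      (plateau_rate_ratio <= 0 || plateau_rate_ratio > 1))
    stop("plateau_rate_ratio must be in (0,1]")
  names_chr <- sprintf("chr%02d", seq_len(n_chr))
  marey <- vector("list", n_chr)
  names(marey) <- names_chr
  plateau <- data.frame(chrom = names_chr, start = NA_real_, end = NA_real_)
  for (i in seq_len(n_chr)) {
    L <- lengths_bp[[i]]; G <- cm_lengths[[i]]; f <- plateau_fraction
    if (f > 0) {
      # total cM: r_a * (1-f) * L + r_a * ratio * f * L = G
      r_arm <- G / (L * (1 - f + plateau_rate_ratio * f))
      a <- (1 - f) * L / 2
      x <- c(0, a, a + f * L, L)
      y <- c(0, r_arm * a,
             r_arm * a + r_arm * plateau_rate_ratio * f * L, G)
      plateau$start[i] <- a
      plateau$end[i] <- a + f * L
    } else {
      x <- c(0, L); y <- c(0, G)
    }
    marey[[i]] <- list(x = x, y = y)
  }
  markers <- with_seed(substream_seed(seed, "markers"), {
    out <- lapply(seq_len(n_chr), function(i) {
      n <- max(2L, round(marker_density * lengths_bp[[i]] / 1e6))
      pos <- sort(unique(floor(stats::runif(n, 0, lengths_bp[[i]]))))
      data.frame(chrom = names_chr[[i]], pos = pos)
    })
    do.call(rbind, out)
  })
  structure(list(
    chrom = data.frame(name = names_chr, length_bp = lengths_bp,
                       length_cm = cm_lengths),
    marey = marey, plateau = plateau, markers = markers, seed = seed),
    class = "true_genome")
}

#' @export
print.true_genome <- function(x, ...) {
  cat(sprintf("true_genome: %d chromosomes, %.1f Mbp, %.0f cM, %d markers\n",
              nrow(x$chrom), sum(x$chrom$length_bp) / 1e6,
              sum(x$chrom$length_cm), nrow(x$markers)))
  invisible(x)
}

#' Evaluate the Marey function (bp to cM) of a chromosome
#' @param genome A `true_genome`.
#' @param chrom Chromosome name.
#' @param bp Physical positions.
#' @return Cumulative cM at each position.
#' @export
marey_cm <- function(genome, chrom, bp) {
  m <- genome$marey[[chrom]]
  stats::approx(m$x, m$y, xout = bp, rule = 2)$y
}

# Inverse Marey: cM -> bp (valid because every piece has positive rate).
marey_bp <- function(genome, chrom, cm) {
  m <- genome$marey[[chrom]]
  stats::approx(m$y, m$x, xout = cm, rule = 2)$y
}

# --- haplotype mosaics -----------------------------------------------------
# A homolog is a mosaic list(brk, lab): internal breakpoints (sorted,
# strictly inside (0, L)) and parental labels (1 = A, 2 = B) of the
# length(brk)+1 segments.

mosaic_label_at <- function(h, pos) {
  h$lab[findInterval(pos, h$brk) + 1L]
}

compress_mosaic <- function(brk, lab) {
  if (length(lab) > 1L) {
    same <- lab[-1] == lab[-length(lab)]
    if (any(same)) {
      brk <- brk[!same]
      keep <- c(TRUE, !same)
      lab <- lab[keep]
    }
  }
  list(brk = brk, lab = lab)
}

# Meiotic product of two homologs given crossover positions xs (bp) and a
# starting homolog (1 or 2); alternates source homolog at each crossover.
recombine_mosaic <- function(h1, h2, xs, start, L) {
  if (length(xs) == 0L) return(if (start == 1L) h1 else h2)
  hs <- list(h1, h2)
  bounds <- c(0, xs, L)
  cur <- start
  brk <- numeric(0); lab <- integer(0)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[[i]]; b <- bounds[[i + 1L]]
    h <- hs[[cur]]
    inside <- h$brk[h$brk > a & h$brk < b]
    seg_lab <- h$lab[findInterval(c(a, inside), h$brk) + 1L]
    if (i > 1L) brk <- c(brk, a)
    brk <- c(brk, inside)
    lab <- c(lab, seg_lab)
    cur <- 3L - cur
  }
  compress_mosaic(brk, lab)
}

#' Simulate a recombinant inbred line population by single-seed descent
#'
#' Starts from a genome-wide heterozygous F1 (one A homolog, one B
#' homolog per chromosome) and advances each line independently by
#' `n_selfing_generations` rounds of selfing, keeping one offspring per
#' line per generation. Each meiosis draws a crossover count per
#' chromosome from Poisson(genetic length / 100) — no interference
#' (Haldane) — and places crossovers by inverting the Marey function, so
#' crossover density follows the recombination landscape.
#'
#' @param genome A `true_genome`.
#' @param n_individuals Number of RIL lines (>= 2).
#' @param n_selfing_generations Selfing rounds; 7 takes an F1 to F8.
#' @param seed Integer seed.
#' @return An object of class `ril_population`.
#' @export
simulate_ril_population <- function(genome, n_individuals,
                                    n_selfing_generations = 7, seed = 1L) {
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  chroms <- genome$chrom$name
  with_seed(substream_seed(seed, "ril"), {
    inds <- vector("list", n_individuals)
    for (j in seq_len(n_individuals)) {
      ind <- lapply(chroms, function(cn) {
        list(h1 = list(brk = numeric(0), lab = 1L),
             h2 = list(brk = numeric(0), lab = 2L))
      })
      names(ind) <- chroms
      inds[[j]] <- ind
    }
    if (n_selfing_generations > 0) {
      for (gen in seq_len(n_selfing_generations)) {
        for (j in seq_len(n_individuals)) {
          for (ci in seq_along(chroms)) {
            cn <- chroms[[ci]]
            L <- genome$chrom$length_bp[[ci]]
            G <- genome$chrom$length_cm[[ci]]
            pair <- inds[[j]][[cn]]
            gam <- replicate(2, {
              k <- stats::rpois(1L, G / 100)
              xs <- if (k > 0)
                sort(marey_bp(genome, cn, stats::runif(k, 0, G)))
              else numeric(0)
              recombine_mosaic(pair$h1, pair$h2, xs,
                               sample(1:2, 1L), L)
            }, simplify = FALSE)
            inds[[j]][[cn]] <- list(h1 = gam[[1]], h2 = gam[[2]])
          }
        }
      }
    }
    structure(list(individuals = inds,
                   n_selfing_generations = n_selfing_generations,
                   chrom = genome$chrom),
              class = "ril_population")
  })
}

#' @export
print.ril_population <- function(x, ...) {
  cat(sprintf("ril_population: %d lines at F%d (%d selfing generations)\n",
              length(x$individuals), x$n_selfing_generations + 1L,
              x$n_selfing_generations))
  invisible(x)
}

# True diploid call (CALL_A/CALL_B/CALL_H) of one individual at marker
# positions on one chromosome.
true_calls_chrom <- function(ind_chrom, pos) {
  l1 <- mosaic_label_at(ind_chrom$h1, pos)
  l2 <- mosaic_label_at(ind_chrom$h2, pos)
  out <- rep(CALL_H, length(pos))
  hom <- l1 == l2
  out[hom] <- l1[hom]
  out
}

# Map genome coordinates (chrom, gpos) into contig space through a truth
# placement. Returns data.frame(contig, pos, strand).
project_to_contigs <- function(placement, chrom, gpos) {
  parts <- placement$parts
  out_contig <- character(length(gpos))
  out_pos <- integer(length(gpos))
  out_strand <- character(length(gpos))
  for (cn in unique(chrom)) {
    sel <- which(chrom == cn)
    p <- parts[parts$chrom == cn, , drop = FALSE]
    p <- p[order(p$src_start), , drop = FALSE]
    idx <- findInterval(gpos[sel], p$src_start)
    if (any(idx < 1L | gpos[sel] >= p$src_end[idx]))
      stop("position outside the tiled chromosome")
    fwd <- p$strand[idx] == "+"
    cpos <- ifelse(fwd,
                   p$offset[idx] + (gpos[sel] - p$src_start[idx]),
                   p$offset[idx] + (p$src_end[idx] - 1 - gpos[sel]))
    out_contig[sel] <- p$contig[idx]
    out_pos[sel] <- as.integer(cpos)
    out_strand[sel] <- p$strand[idx]
  }
  data.frame(contig = out_contig, pos = out_pos, strand = out_strand)
}

#' Genotype a simulated RIL population at the genome's markers
#'
#' Derives each marker's true call (A, B or H) from the line's haplotype
#' mosaic, then applies missingness and genotyping error: with probability
#' `missing_rate` the call becomes missing; otherwise with probability
#' `error_rate` it is replaced by a uniformly random different non-missing
#' call. Marker coordinates are expressed in contig space through the
#' truth placement (chimeras included). Parent samples `P_A`/`P_B` with
#' error-free homozygous calls are appended when `include_parents`.
#'
#' @param pop A `ril_population`.
#' @param genome The `true_genome` it was simulated from.
#' @param placement A `truth_placement` from [fragment_genome()].
#' @param missing_rate,error_rate Per-call probabilities in [0,1).
#' @param gq_pass Phred GQ emitted for every non-missing call.
#' @param include_parents Append designated parent samples.
#' @param seed Integer seed.
#' @return A [marker_geno()] whose attribute `truth` holds the error-free
#'   call matrix.
#' @export
genotype_population <- function(pop, genome, placement,
                                missing_rate = 0, error_rate = 0,
                                gq_pass = 40, include_parents = TRUE,
                                seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1 || error_rate < 0 ||
      error_rate >= 1)
    stop("rates must be in [0,1)")
  mk <- genome$markers
  n <- length(pop$individuals)
  truth <- matrix(NA_integer_, nrow(mk), n)
  for (ci in seq_len(nrow(genome$chrom))) {
    cn <- genome$chrom$name[[ci]]
    sel <- which(mk$chrom == cn)
    for (j in seq_len(n))
      truth[sel, j] <- true_calls_chrom(pop$individuals[[j]][[cn]],
                                        mk$pos[sel])
  }
  calls <- with_seed(substream_seed(seed, "genotype"), {
    out <- truth
    ncell <- length(out)
    drop <- stats::runif(ncell) < missing_rate
    err <- !drop & stats::runif(ncell) < error_rate
    if (any(err)) {
      # uniformly random different non-missing call
      shift <- sample(1:2, sum(err), replace = TRUE)
      out[err] <- ((out[err] - 1L + shift) %% 3L) + 1L
    }
    out[drop] <- NA_integer_
    out
  })
  proj <- project_to_contigs(placement, mk$chrom, mk$pos)
  samples <- sprintf("RIL%03d", seq_len(n))
  parents <- NULL
  if (include_parents) {
    calls <- cbind(calls, rep(CALL_A, nrow(mk)), rep(CALL_B, nrow(mk)))
    truth <- cbind(truth, rep(CALL_A, nrow(mk)), rep(CALL_B, nrow(mk)))
    samples <- c(samples, "P_A", "P_B")
    parents <- c("P_A", "P_B")
  }
  gq <- matrix(gq_pass, nrow(calls), ncol(calls))
  gq[is.na(calls)] <- NA_real_
  markers <- data.frame(
    marker_id = sprintf("%s_%d", mk$chrom, mk$pos),
    contig = proj$contig, pos = proj$pos)
  ord <- order(markers$contig, markers$pos)
  m <- marker_geno(markers, calls, samples, parents, gq)
  attr(m, "truth") <- truth[ord, , drop = FALSE]
  attr(m, "genome_marker") <- mk[ord, , drop = FALSE]
  m
}

#' Fragment a genome into contigs, optionally injecting chimeras
#'
#' Chromosomes are cut at exponentially spaced breakpoints (mean
#' `mean_contig_bp`), producing contigs that tile each chromosome exactly.
#' A random half of the contigs are recorded with `-` source strand
#' (their local coordinates run against the chromosome). `n_chimeras`
#' misassemblies are then injected by concatenating two fragments from
#' different chromosomes into a single contig, recording the junction
#' offset.
#'
#' @param genome A `true_genome`.
#' @param mean_contig_bp Mean fragment length.
#' @param n_chimeras Number of chimeric contigs to create.
#' @param min_contig_bp Minimum fragment length; cuts that would create a
#'   shorter fragment are suppressed (assemblers do not emit, and
#'   anchoring pipelines do not consume, sub-20 kbp slivers).
#' @param seed Integer seed.
#' @return A `truth_placement`: `parts` (contig, part, chrom, src_start,
#'   src_end, strand, offset), `contig_len`, and `chimeras` (contig,
#'   junction).
#' @export
fragment_genome <- function(genome, mean_contig_bp, n_chimeras = 0,
                            min_contig_bp = 20000, seed = 1L) {
  if (mean_contig_bp >= min(genome$chrom$length_bp))
    stop("mean_contig_bp must be below the shortest chromosome")
  with_seed(substream_seed(seed, "fragment"), {
    frags <- list()
    for (i in seq_len(nrow(genome$chrom))) {
      L <- genome$chrom$length_bp[[i]]
      cuts <- numeric(0)
      at <- 0
      repeat {
        at <- at + stats::rexp(1L, 1 / mean_contig_bp)
        if (at >= L) break
        if (at - max(0, cuts[length(cuts)]) >= min_contig_bp)
          cuts <- c(cuts, floor(at))
      }
      cuts <- cuts[cuts > 0 & cuts < L]
      # merge a trailing short fragment into its neighbour
      if (length(cuts) && L - cuts[length(cuts)] < min_contig_bp)
        cuts <- cuts[-length(cuts)]
      b <- c(0, cuts, L)
      frags[[i]] <- data.frame(chrom = genome$chrom$name[[i]],
                               src_start = b[-length(b)], src_end = b[-1])
    }
    frags <- do.call(rbind, frags)
    nf <- nrow(frags)
    frags$strand <- sample(rep(c("+", "-"), length.out = nf))
    if (n_chimeras > 0) {
      # pairs of fragments from different chromosomes
      ok <- FALSE
      for (try in 1:50) {
        pick <- sample(nf, 2L * n_chimeras)
        a <- pick[seq_len(n_chimeras)]
        b <- pick[n_chimeras + seq_len(n_chimeras)]
        if (all(frags$chrom[a] != frags$chrom[b])) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw chimera pairs from different chromosomes")
    }
    parts <- list(); lens <- list(); chim <- list()
    used <- rep(FALSE, nf)
    if (n_chimeras > 0) used[c(a, b)] <- TRUE
    k <- 0L
    for (i in seq_len(nf)) {
      if (used[[i]]) next
      k <- k + 1L
      id <- sprintf("ctg%04d", k)
      len <- frags$src_end[[i]] - frags$src_start[[i]]
      parts[[length(parts) + 1L]] <- data.frame(
        contig = id, part = 1L, chrom = frags$chrom[[i]],
        src_start = frags$src_start[[i]], src_end = frags$src_end[[i]],
        strand = frags$strand[[i]], offset = 0)
      lens[[length(lens) + 1L]] <- data.frame(contig = id, length = len)
    }
    if (n_chimeras > 0) {
      for (q in seq_len(n_chimeras)) {
        id <- sprintf("chim%02d", q)
        i1 <- a[[q]]; i2 <- b[[q]]
        len1 <- frags$src_end[[i1]] - frags$src_start[[i1]]
        len2 <- frags$src_end[[i2]] - frags$src_start[[i2]]
        parts[[length(parts) + 1L]] <- data.frame(
          contig = id, part = 1L, chrom = frags$chrom[[i1]],
          src_start = frags$src_start[[i1]], src_end = frags$src_end[[i1]],
          strand = frags$strand[[i1]], offset = 0)
        parts[[length(parts) + 1L]] <- data.frame(
          contig = id, part = 2L, chrom = frags$chrom[[i2]],
          src_start = frags$src_start[[i2]], src_end = frags$src_end[[i2]],
          strand = frags$strand[[i2]], offset = len1)
        lens[[length(lens) + 1L]] <- data.frame(contig = id,
                                                length = len1 + len2)
        chim[[length(chim) + 1L]] <- data.frame(contig = id,
                                                junction = len1)
      }
    }
    structure(list(parts = do.call(rbind, parts),
                   contig_len = do.call(rbind, lens),
                   chimeras = if (length(chim)) do.call(rbind, chim)
                   else data.frame(contig = character(),
                                   junction = numeric())),
              class = "truth_placement")
  })
}

#' @export
print.truth_placement <- function(x, ...) {
  cat(sprintf("truth_placement: %d contigs (%d chimeric), %.1f Mbp\n",
              nrow(x$contig_len), nrow(x$chimeras),
              sum(x$contig_len$length) / 1e6))
  invisible(x)
}

#' Simulate linked-read barcoded alignments
#'
#' Molecules are drawn on the true genome (exponential length, uniform
#' start, chromosome chosen proportional to length), reads are placed
#' uniformly within each molecule at `reads_per_kbp`, and read positions
#' are projected into contig coordinates through the truth placement
#' (strand-aware). A molecule spanning a contig junction therefore
#' deposits the same barcode near the facing ends of adjacent contigs —
#' the signal the scaffold graph exploits. Chimeric junctions, which do
#' not exist on the true genome, receive no spanning molecules.
#'
#' @param placement A `truth_placement`.
#' @param genome The matching `true_genome`.
#' @param molecule_mean_bp Mean molecule length.
#' @param molecules_per_barcode Molecules sharing one barcode.
#' @param n_barcodes Number of barcodes.
#' @param reads_per_kbp Read density within molecules.
#' @param seed Integer seed.
#' @return A `data.table` (barcode, contig, pos, strand) sorted by
#'   (contig, pos).
#' @export
simulate_linked_reads <- function(placement, genome,
                                  molecule_mean_bp = 50000,
                                  molecules_per_barcode = 2,
                                  n_barcodes = 10000,
                                  reads_per_kbp = 0.3, seed = 1L) {
  if (molecule_mean_bp <= 0) stop("molecule_mean_bp must be positive")
  with_seed(substream_seed(seed, "linkedreads"), {
    n_mol <- n_barcodes * molecules_per_barcode
    chrom_i <- sample(nrow(genome$chrom), n_mol, replace = TRUE,
                      prob = genome$chrom$length_bp)
    L <- genome$chrom$length_bp[chrom_i]
    start <- floor(stats::runif(n_mol, 0, L))
    len <- stats::rexp(n_mol, 1 / molecule_mean_bp)
    end <- pmin(start + pmax(len, 1), L)
    n_reads <- stats::rpois(n_mol, (end - start) / 1000 * reads_per_kbp)
    barcode <- rep(sprintf("BX%06d", rep(seq_len(n_barcodes),
                                         each = molecules_per_barcode)),
                   n_reads)
    mol_id <- rep(seq_len(n_mol), n_reads)
    gpos <- floor(stats::runif(length(mol_id), start[mol_id], end[mol_id]))
    chrom <- genome$chrom$name[chrom_i[mol_id]]
    proj <- project_to_contigs(placement, chrom, gpos)
    tab <- data.table::data.table(barcode = barcode, contig = proj$contig,
                                  pos = proj$pos, strand = proj$strand)
    data.table::setorder(tab, contig, pos)
    tab[]
  })
}
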