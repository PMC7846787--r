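#' Segment contig markers where adjacent-marker LD collapses
#'
#' Within each contig (physical marker order), r-squared between every
#' pair of adjacent markers is computed from the imputed parental labels;
#' where it falls below `segment_r2_threshold` the contig's markers are
#' split into separate segments. Genuinely co-located adjacent markers in
#' a dense map are in near-perfect LD, so a collapse marks either a
#' chimeric junction or a large genetic gap; undefined r-squared
#' (monomorphic marker) is treated as no evidence. Segments are the
#' marker-level units used for linkage-group inference, so a chimeric
#' contig cannot silently bridge two chromosomes.
#'
#' @param m A filtered [marker_geno()] or a `parental_haplotypes`.
#' @param config A [pipeline_config()].
#' @return Character vector, one unit id per marker row of `m`
#'   (`"<contig>"` for single-segment contigs, `"<contig>#<k>"`
#'   otherwise).
#' @export
segment_markers_by_ld <- function(m, config = pipeline_config()) {
  x01 <- calls01_of(m)
  units <- m$markers$contig
  for (ctg in unique(m$markers$contig)) {
    idx <- which(m$markers$contig == ctg)
    if (length(idx) < 2L) next
    idx <- idx[order(m$markers$pos[idx])]
    lab <- x01[idx, , drop = FALSE]
    r2 <- vapply(seq_len(length(idx) - 1L), function(i) {
      keep <- !is.na(lab[i, ]) & !is.na(lab[i + 1L, ])
      if (sum(keep) < 2L) return(NA_real_)
      x <- lab[i, keep]; y <- lab[i + 1L, keep]
      if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
      stats::cor(x, y)^2
    }, 0)
    cut <- !is.na(r2) & r2 < config$segment_r2_threshold
    if (!any(cut)) next
    seg <- cumsum(c(1L, as.integer(cut)))
    units[idx] <- sprintf("%s#%d", ctg, seg)
  }
  units
}

# Per-marker linkage-group assignment via LD-consistent segments of the
# filtered genotype matrix (raw homozygote calls: the Viterbi MAP path
# suppresses one-marker segments at contig ends, which would bias
# cross-junction LD).
unit_marker_groups <- function(mf, config) {
  units <- segment_markers_by_ld(mf, config)
  mu <- mf
  mu$markers <- data.frame(marker_id = mf$markers$marker_id,
                           contig = units, pos = mf$markers$pos)
  lg <- infer_linkage_groups(mu, config)
  data.frame(contig = mf$markers$contig, pos = mf$markers$pos,
             group = unname(lg$groups[units]))
}

#' Detect chimeric joins within one contig
#'
#' A contig is suspect when its markers fall in more than one linkage
#' group. If each group occupies a contiguous stretch of the contig, one
#' break is called inside every inter-marker gap separating two discordant
#' stretches; if the groups interleave, the contig is flagged
#' unresolvable and should be excluded from anchoring. The break position
#' within a gap is chosen by barcode continuity: candidate breakpoints on
#' a 10 kbp grid across the gap are scored by the number of barcodes with
#' reads within `end_window_bp` on both sides, and the minimum wins (a
#' true chimeric junction has no spanning molecules, so continuity
#' collapses there). Ties take the leftmost candidate.
#'
#' @param contig Contig id.
#' @param aln Barcode alignment table (may cover all contigs).
#' @param marker_groups data.frame with `contig`, `pos`, `group` for
#'   markers (linkage-group assignment).
#' @param config A [pipeline_config()].
#' @return Numeric vector of break positions (bp, possibly empty), with
#'   attribute `unresolvable` set `TRUE` when groups interleave.
#' @export
detect_misassemblies <- function(contig, aln, marker_groups,
                                 config = pipeline_config()) {
  aln <- as.data.frame(aln)  # avoid data.table NSE on the contig column
  mk <- marker_groups[marker_groups$contig == contig, , drop = FALSE]
  mk <- mk[order(mk$pos), , drop = FALSE]
  out <- numeric(0)
  attr(out, "unresolvable") <- FALSE
  if (nrow(mk) < 2L || length(unique(mk$group)) < 2L) return(out)
  runs <- rle(as.character(mk$group))
  if (anyDuplicated(runs$values)) {
    attr(out, "unresolvable") <- TRUE
    return(out)
  }
  reads <- aln[aln$contig == contig, , drop = FALSE]
  idx_end <- cumsum(runs$lengths)
  w <- config$end_window_bp
  breaks <- numeric(length(runs$lengths) - 1L)
  for (k in seq_along(breaks)) {
    lo <- mk$pos[idx_end[[k]]]
    hi <- mk$pos[idx_end[[k]] + 1L]
    cand <- seq(lo, hi, by = 10000)
    if (cand[length(cand)] < hi) cand <- c(cand, (lo + hi) / 2)
    cand <- sort(unique(pmin(pmax(cand, lo + 1), hi)))
    score <- continuity_at(reads, cand, w)
    breaks[[k]] <- cand[[which.min(score)]]
  }
  attr(breaks, "unresolvable") <- FALSE
  breaks
}

#' Scan one contig for barcode-continuity collapses
#'
#' Complements [detect_misassemblies()] with a marker-free signal: on a
#' 10 kbp grid along the contig interior, the number of barcodes with
#' reads within `end_window_bp` on both sides of the grid point is
#' computed; a chimeric junction has essentially no spanning molecules,
#' so continuity collapses there while staying near the molecule
#' coverage elsewhere. A break is called at the local minimum of every
#' run of grid points whose continuity falls below
#' `rel_threshold x median` (and below `abs_threshold`). Contigs whose
#' median continuity is below `min_median` are skipped — without
#' adequate molecule coverage the scan cannot distinguish a junction
#' from noise.
#'
#' @param contig Contig id.
#' @param aln Barcode alignment table.
#' @param contig_length Length of the contig.
#' @param config A [pipeline_config()].
#' @param rel_threshold Fraction of the median continuity below which a
#'   grid point is break-suspect.
#' @param abs_threshold Absolute spanning-barcode ceiling for a suspect.
#' @param min_median Minimum median continuity for the scan to run.
#' @return Numeric vector of break positions (possibly empty).
#' @export
scan_barcode_breaks <- function(contig, aln, contig_length,
                                config = pipeline_config(),
                                rel_threshold = 0.15, abs_threshold = 5,
                                min_median = 10) {
  aln <- as.data.frame(aln)
  reads <- aln[aln$contig == contig, , drop = FALSE]
  w <- config$end_window_bp
  if (contig_length < 3 * w || nrow(reads) == 0L) return(numeric(0))
  grid <- seq(w, contig_length - w, by = 10000)
  score <- continuity_at(reads, grid, w)
  med <- stats::median(score)
  if (med < min_median) return(numeric(0))
  low <- score < pmin(rel_threshold * med, abs_threshold)
  if (!any(low)) return(numeric(0))
  r <- rle(low)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  out <- numeric(0)
  for (k in which(r$values)) {
    seg <- idx_start[[k]]:idx_end[[k]]
    # demand healthy continuity within 60 kbp on both flanks: molecule
    # coverage ramps up from zero at a true sequence terminus, which
    # would otherwise mimic a junction near contig ends
    lo <- grid[seg[[1L]]]; hi <- grid[seg[[length(seg)]]]
    left_ok <- any(score >= 0.5 * med &
                     grid >= lo - 60000 & grid < lo)
    right_ok <- any(score >= 0.5 * med &
                      grid > hi & grid <= hi + 60000)
    if (!left_ok || !right_ok) next
    out <- c(out, grid[seg][which.min(score[seg])])
  }
  out
}

# Number of barcodes with >=1 read in [p-w, p-gap) and >=1 in
# [p+gap, p+w) for every position p in x. The guard gap makes the score
# collapse to ~0 whenever a junction lies within `gap` of p (reads from
# the strip adjacent to the junction cannot fake continuity), so a
# 10 kbp scan grid always has a near-zero point at a true junction.
continuity_at <- function(reads, x, w, gap = 6000) {
  vapply(x, function(p) {
    lhs <- reads$pos >= p - w & reads$pos < p - gap
    rhs <- reads$pos >= p + gap & reads$pos < p + w
    if (!any(lhs) || !any(rhs)) return(0L)
    length(intersect(unique(reads$barcode[lhs]),
                     unique(reads$barcode[rhs])))
  }, 0L)
}

#' Split contigs at detected break positions
#'
#' Applies breakpoints to the marker matrix, the barcode alignment table,
#' the contig length catalog and (when supplied) the truth placement, so
#' the split fragments re-enter the pipeline as first-class contigs named
#' `<contig>_1`, `<contig>_2`, ... Truth parts are trimmed to the split
#' intervals so downstream evaluation can score split fragments.
#'
#' @param breaks Named list: contig id -> numeric break positions.
#' @param m A [marker_geno()] (or `NULL`).
#' @param aln Barcode alignment table (or `NULL`).
#' @param contig_lengths Named vector of contig lengths.
#' @param truth Optional `truth_placement` to carry along.
#' @return List with updated `m`, `aln`, `contig_lengths`, `truth`.
#' @export
apply_breaks <- function(breaks, m = NULL, aln = NULL, contig_lengths,
                         truth = NULL) {
  breaks <- breaks[lengths(breaks) > 0]
  for (ctg in names(breaks)) {
    L <- contig_lengths[[ctg]]
    cuts <- sort(breaks[[ctg]])
    bounds <- c(0, cuts, L)
    ids <- sprintf("%s_%d", ctg, seq_len(length(bounds) - 1L))
    # lengths
    newlen <- diff(bounds)
    contig_lengths <- contig_lengths[names(contig_lengths) != ctg]
    contig_lengths[ids] <- newlen
    relocate <- function(pos) {
      piece <- findInterval(pos, bounds, rightmost.closed = TRUE)
      piece <- pmin(pmax(piece, 1L), length(ids))
      list(contig = ids[piece], pos = pos - bounds[piece])
    }
    if (!is.null(m)) {
      sel <- m$markers$contig == ctg
      if (any(sel)) {
        r <- relocate(m$markers$pos[sel])
        m$markers$contig[sel] <- r$contig
        m$markers$pos[sel] <- r$pos
        m <- marker_geno(m$markers, m$calls, m$samples, m$parents, m$gq)
      }
    }
    if (!is.null(aln)) {
      sel <- aln$contig == ctg
      if (any(sel)) {
        r <- relocate(aln$pos[sel])
        aln$contig[sel] <- r$contig
        aln$pos[sel] <- as.integer(r$pos)
      }
    }
    if (!is.null(truth)) {
      sel <- truth$parts$contig == ctg
      parts <- truth$parts[sel, , drop = FALSE]
      newparts <- list()
      for (pi in seq_len(nrow(parts))) {
        p <- parts[pi, ]
        p_lo <- p$offset
        p_hi <- p$offset + (p$src_end - p$src_start)
        for (k in seq_along(ids)) {
          lo <- max(bounds[[k]], p_lo)
          hi <- min(bounds[[k + 1L]], p_hi)
          if (hi <= lo) next
          if (p$strand == "+") {
            ss <- p$src_start + (lo - p_lo)
            se <- p$src_start + (hi - p_lo)
          } else {
            se <- p$src_end - (lo - p_lo)
            ss <- p$src_end - (hi - p_lo)
          }
          newparts[[length(newparts) + 1L]] <- data.frame(
            contig = ids[[k]], part = 1L, chrom = p$chrom,
            src_start = ss, src_end = se, strand = p$strand,
            offset = lo - bounds[[k]])
        }
      }
      np <- do.call(rbind, newparts)
      np <- np[order(np$contig, np$offset), , drop = FALSE]
      np$part <- stats::ave(seq_len(nrow(np)), np$contig,
                            FUN = seq_along)
      truth$parts <- rbind(truth$parts[!sel, , drop = FALSE], np)
      truth$contig_len <-
        rbind(truth$contig_len[truth$contig_len$contig != ctg, ,
                               drop = FALSE],
              data.frame(contig = ids, length = newlen))
      truth$chimeras <-
        truth$chimeras[truth$chimeras$contig != ctg, , drop = FALSE]
    }
  }
  list(m = m, aln = aln, contig_lengths = contig_lengths, truth = truth)
}
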