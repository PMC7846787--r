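#' Build per-chromosome Marey point sets
#'
#' Joins anchored marker physical positions (pseudomolecule coordinates)
#' with their cumulative genetic positions. Points are sorted by bp;
#' duplicate bp positions collapse to the maximum cM; chromosomes with
#' fewer than two markers are excluded with a warning.
#'
#' @param map Genetic map data.frame: `marker_id`, `contig`, `pos`,
#'   `linkage_group`, `cM` (as produced by [run_anchoring()]).
#' @param pseudo A [pseudomolecule_set()] giving each contig's object,
#'   offset and orientation (used to lift contig coordinates).
#' @return data.frame: `chrom`, `bp`, `cM`, sorted by (chrom, bp).
#' @export
build_marey_profile <- function(map, pseudo) {
  lay <- agp_layout(pseudo)
  w <- lay[lay$component_type == "W", , drop = FALSE]
  idx <- match(map$contig, w$component_id)
  if (anyNA(idx)) {
    map <- map[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  beg <- as.integer(w$object_beg[idx])
  endc <- as.integer(w$object_end[idx])
  fwd <- w$orientation[idx] == "+"
  bp <- ifelse(fwd, beg - 1L + map$pos, endc - 1L - map$pos)
  pts <- data.frame(chrom = w$object[idx], bp = bp, cM = map$cM)
  pts <- stats::aggregate(cM ~ chrom + bp, data = pts, FUN = max)
  pts <- pts[order(pts$chrom, pts$bp), c("chrom", "bp", "cM")]
  n_per <- table(pts$chrom)
  drop <- names(n_per)[n_per < 2L]
  if (length(drop)) {
    warning(sprintf("excluding %d chromosome(s) with <2 markers", length(drop)))
    pts <- pts[!(pts$chrom %in% drop), , drop = FALSE]
  }
  # enforce monotone non-decreasing cM along bp within each chromosome
  pts$cM <- unlist(lapply(split(pts$cM, pts$chrom), cummax),
                   use.names = FALSE)
  rownames(pts) <- NULL
  pts
}

#' Sliding-window recombination rates from Marey points
#'
#' For each window of `marey_window_bp` advanced by `marey_step_bp` from
#' position 0, the rate is the genetic distance spanned by the window
#' divided by the window size in Mbp, with cM at arbitrary bp obtained by
#' linear interpolation between flanking markers and constant
#' extrapolation beyond the terminal markers. Trailing partial windows
#' are dropped, giving `floor((L - window) / step) + 1` windows for a
#' chromosome of length `L >= window`.
#'
#' @param marey data.frame (`chrom`, `bp`, `cM`) from
#'   [build_marey_profile()].
#' @param config A [pipeline_config()].
#' @param chrom_lengths Optional named lengths; defaults to the last
#'   marker position per chromosome.
#' @return data.frame: `chrom`, `window_start`, `window_end`,
#'   `rate_cM_per_Mbp`.
#' @export
sliding_window_rate <- function(marey, config = pipeline_config(),
                                chrom_lengths = NULL) {
  win <- config$marey_window_bp; step <- config$marey_step_bp
  out <- list()
  for (cn in unique(marey$chrom)) {
    pts <- marey[marey$chrom == cn, , drop = FALSE]
    if (nrow(pts) < 2L) next
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[cn]] else max(pts$bp)
    if (L < win) next
    starts <- seq(0, L - win, by = step)
    cm_at <- function(x) stats::approx(pts$bp, pts$cM, xout = x,
                                       rule = 2, ties = max)$y
    rate <- (cm_at(starts + win) - cm_at(starts)) / (win / 1e6)
    out[[length(out) + 1L]] <- data.frame(
      chrom = cn, window_start = starts, window_end = starts + win,
      rate_cM_per_Mbp = rate)
  }
  if (!length(out))
    return(data.frame(chrom = character(), window_start = numeric(),
                      window_end = numeric(), rate_cM_per_Mbp = numeric()))
  do.call(rbind, out)
}

#' Call pericentromeric intervals from a recombination profile
#'
#' A window is low-rate when its recombination rate is strictly below
#' `1 / pericentromere_mbp_per_cm` cM/Mbp (0.5 cM/Mbp at the published
#' 2 Mbp/cM rule; a window exactly at the boundary is not
#' pericentromeric). Consecutive or overlapping low-rate windows are
#' merged into maximal intervals.
#'
#' @param profile Output of [sliding_window_rate()].
#' @param config A [pipeline_config()].
#' @return data.frame: `chrom`, `start`, `end` of merged intervals.
#' @export
call_pericentromeres <- function(profile, config = pipeline_config()) {
  thr <- 1 / config$pericentromere_mbp_per_cm
  out <- list()
  for (cn in unique(profile$chrom)) {
    pr <- profile[profile$chrom == cn, , drop = FALSE]
    pr <- pr[order(pr$window_start), , drop = FALSE]
    low <- pr$rate_cM_per_Mbp < thr
    if (!any(low)) next
    r <- rle(low)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn,
        start = pr$window_start[[idx_start[[k]]]],
        end = pr$window_end[[idx_end[[k]]]])
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Summary statistics of an anchored genetic map
#'
#' @param map Genetic map data.frame (`marker_id`, `contig`, `pos`,
#'   `linkage_group`, `cM`).
#' @param pseudo A [pseudomolecule_set()] (for physical lengths).
#' @return List: total cM, marker and unique-locus counts (markers at
#'   identical cM on the same contig collapse to one locus), mean
#'   adjacent-locus spacing in cM and Mbp, per-chromosome kbp-per-cM
#'   (physical length / genetic length), and the largest inter-locus cM
#'   gap per chromosome.
#' @export
map_summary_stats <- function(map, pseudo) {
  lay <- agp_layout(pseudo)
  w <- lay[lay$component_type == "W", , drop = FALSE]
  obj_len <- tapply(as.integer(lay$object_end), lay$object, max)
  per_chr <- list()
  total_cm <- 0
  spacings_cm <- numeric(0); spacings_bp <- numeric(0)
  marey <- build_marey_profile(map, pseudo)
  for (cn in unique(marey$chrom)) {
    pts <- marey[marey$chrom == cn, , drop = FALSE]
    glen <- max(pts$cM) - min(pts$cM)
    total_cm <- total_cm + glen
    loci <- !duplicated(pts$cM)
    lp <- pts[loci, , drop = FALSE]
    if (nrow(lp) > 1L) {
      spacings_cm <- c(spacings_cm, diff(lp$cM))
      spacings_bp <- c(spacings_bp, diff(lp$bp))
    }
    per_chr[[cn]] <- list(
      genetic_length_cm = glen,
      physical_length_bp = unname(obj_len[[cn]]),
      kbp_per_cm = if (glen > 0) unname(obj_len[[cn]]) / 1000 / glen
      else NA_real_,
      largest_gap_cm = if (nrow(lp) > 1L) max(diff(lp$cM)) else 0)
  }
  list(total_cm = total_cm,
       n_markers = nrow(map),
       n_unique_loci = nrow(unique(map[, c("contig", "cM")])),
       mean_spacing_cm = if (length(spacings_cm)) mean(spacings_cm)
       else NA_real_,
       mean_spacing_mbp = if (length(spacings_bp))
         mean(spacings_bp) / 1e6 else NA_real_,
       per_chromosome = per_chr)
}
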