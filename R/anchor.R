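#' Assign scaffolds to linkage groups by marker majority
#'
#' A scaffold's group is the majority linkage group over its contigs'
#' markers. Scaffolds without markers are unplaced; a scaffold whose
#' minority-group marker share strictly exceeds 0.2 is flagged
#' conflicting (candidate misassembly).
#'
#' @param scaffolds A `scaffold_set` (list of contig/orientation paths).
#' @param marker_groups data.frame with `contig` and `group` per marker.
#' @return data.frame: `scaffold` (index), `group` (NA when unplaced),
#'   `n_markers`, `minority_share`, `conflict`.
#' @export
assign_to_linkage_groups <- function(scaffolds, marker_groups) {
  out <- lapply(seq_along(scaffolds), function(i) {
    ctgs <- scaffolds[[i]]$contig
    g <- marker_groups$group[marker_groups$contig %in% ctgs]
    if (length(g) == 0L)
      return(data.frame(scaffold = i, group = NA_integer_, n_markers = 0L,
                        minority_share = 0, conflict = FALSE))
    tab <- sort(table(g), decreasing = TRUE)
    maj <- as.integer(names(tab)[[1L]])
    share <- 1 - tab[[1L]] / length(g)
    data.frame(scaffold = i, group = maj, n_markers = length(g),
               minority_share = share, conflict = share > 0.2)
  })
  do.call(rbind, out)
}

# Marker row-indices of `h` along one scaffold path, respecting contig
# orientations (a '-' contig contributes its markers in reverse).
scaffold_marker_order <- function(path, markers) {
  idx <- integer(0)
  for (i in seq_len(nrow(path))) {
    sel <- which(markers$contig == path$contig[[i]])
    sel <- sel[order(markers$pos[sel])]
    if (path$orientation[[i]] == "-") sel <- rev(sel)
    idx <- c(idx, sel)
  }
  idx
}

# Consensus parental-label vector of up to n_end markers at one scaffold
# end ("first" = start of the path, "last" = its end).
end_signature <- function(h, ord, which_end, n_end = 5L) {
  take <- if (which_end == "first") utils::head(ord, n_end)
  else utils::tail(ord, n_end)
  lab <- h$labels[take, , drop = FALSE]
  ifelse(colMeans(lab == 2L) > 0.5, 2L, 1L)
}

#' Chain the scaffolds of one linkage group into a single genetic order
#'
#' Orders and orients scaffolds within a linkage group by greedy joining
#' of nearest scaffold ends, where the distance between two ends is the
#' fraction of RIL samples whose consensus parental labels differ
#' (an estimate of the recombination fraction between the scaffold
#' termini). Join candidates are visited by increasing distance and
#' accepted when both ends are free and the join does not close a cycle,
#' yielding one chain; the chain direction is canonicalised to start at
#' the lexicographically smallest terminal contig.
#'
#' @param paths List of scaffold paths (data.frames contig/orientation)
#'   in this linkage group.
#' @param h A `parental_haplotypes` covering the group's markers.
#' @return List of the same paths, reordered, each possibly flipped
#'   (contig order reversed, orientations inverted).
#' @export
chain_scaffolds <- function(paths, h) {
  k <- length(paths)
  if (k == 1L) return(paths)
  ords <- lapply(paths, scaffold_marker_order, markers = h$markers)
  sigs <- list()
  for (i in seq_len(k)) {
    sigs[[paste0(i, ":first")]] <- end_signature(h, ords[[i]], "first")
    sigs[[paste0(i, ":last")]] <- end_signature(h, ords[[i]], "last")
  }
  cand <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    for (ei in c("first", "last")) for (ej in c("first", "last")) {
      d <- mean(sigs[[paste0(i, ":", ei)]] != sigs[[paste0(j, ":", ej)]])
      cand[[length(cand) + 1L]] <- data.frame(
        i = i, ei = ei, j = j, ej = ej, d = d)
    }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$d, cand$i, cand$j, cand$ei, cand$ej), ,
               drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  used <- character(0)
  joins <- list()
  for (r in seq_len(nrow(cand))) {
    id1 <- paste0(cand$i[[r]], ":", cand$ei[[r]])
    id2 <- paste0(cand$j[[r]], ":", cand$ej[[r]])
    if (id1 %in% used || id2 %in% used) next
    r1 <- find(cand$i[[r]]); r2 <- find(cand$j[[r]])
    if (r1 == r2) next
    parent[[r1]] <- r2
    used <- c(used, id1, id2)
    joins[[id1]] <- id2
    joins[[id2]] <- id1
    if (length(joins) / 2L == k - 1L) break
  }
  # walk the chain from a free terminal
  free <- setdiff(unlist(lapply(seq_len(k), function(i)
    paste0(i, c(":first", ":last")))), used)
  # canonical start: free end on the scaffold whose first contig id is
  # smallest
  first_ctg <- vapply(strsplit(free, ":"), function(s)
    paths[[as.integer(s[[1L]])]]$contig[[1L]], "")
  start <- free[[order(first_ctg, free)[[1L]]]]
  out <- list()
  cur <- start
  repeat {
    sp <- strsplit(cur, ":")[[1L]]
    i <- as.integer(sp[[1L]]); entry <- sp[[2L]]
    p <- paths[[i]]
    if (entry == "last") {
      p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      p$orientation <- ifelse(p$orientation == "+", "-", "+")
      rownames(p) <- NULL
    }
    out[[length(out) + 1L]] <- p
    exit <- paste0(i, ":", if (entry == "first") "last" else "first")
    nxt <- joins[[exit]]
    if (is.null(nxt)) break
    cur <- nxt
  }
  out
}

#' Order and orient scaffolds of one linkage group into a pseudomolecule
#'
#' Scaffolds are sorted by median marker cM (ties broken by more markers
#' first, then by first contig id) and oriented by the sign of the
#' Spearman correlation between within-scaffold physical position and
#' cM over their markers; an undefined or zero correlation, or a single
#' marker, yields `+` with an orientation-unknown flag. Scaffolds are
#' then expanded to contig placements separated by `agp_gap_bp` gaps.
#'
#' @param paths List of scaffold paths in the linkage group.
#' @param marker_map data.frame: `marker_id`, `contig`, `pos`, `cM`.
#' @param contig_lengths Named vector of contig lengths.
#' @param object_name Pseudomolecule name for the output rows.
#' @param config A [pipeline_config()].
#' @return data.frame of placements (`object`, `component`,
#'   `orientation`, `length`) with attribute `orientation_unknown`
#'   (character vector of first contigs of unresolved scaffolds).
#' @export
order_and_orient <- function(paths, marker_map, contig_lengths,
                             object_name, config = pipeline_config()) {
  info <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    offs <- cumsum(c(0, as.numeric(contig_lengths[p$contig])))
    rows <- list()
    for (ci in seq_len(nrow(p))) {
      sel <- marker_map$contig == p$contig[[ci]]
      if (!any(sel)) next
      pos <- marker_map$pos[sel]
      L <- contig_lengths[[p$contig[[ci]]]]
      local <- if (p$orientation[[ci]] == "+") pos else L - 1 - pos
      rows[[length(rows) + 1L]] <- data.frame(
        spos = offs[[ci]] + local, cM = marker_map$cM[sel])
    }
    mk <- if (length(rows)) do.call(rbind, rows)
    else data.frame(spos = numeric(), cM = numeric())
    list(i = i, mk = mk, median_cm = stats::median(mk$cM),
         n = nrow(mk))
  })
  info <- info[!vapply(info, function(x) x$n == 0L, TRUE)]
  if (length(info) == 0L)
    stop("no scaffold in this group has mapped markers")
  med <- vapply(info, function(x) x$median_cm, 0)
  nmk <- vapply(info, function(x) x$n, 0L)
  fst <- vapply(info, function(x) paths[[x$i]]$contig[[1L]], "")
  ord <- order(med, -nmk, fst)
  placements <- list()
  unknown <- character(0)
  for (x in info[ord]) {
    p <- paths[[x$i]]
    flip <- FALSE
    if (x$n >= 2L) {
      rho <- suppressWarnings(
        stats::cor(x$mk$spos, x$mk$cM, method = "spearman"))
      if (is.na(rho) || rho == 0) unknown <- c(unknown, p$contig[[1L]])
      else flip <- rho < 0
    } else unknown <- c(unknown, p$contig[[1L]])
    if (flip) {
      p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      p$orientation <- ifelse(p$orientation == "+", "-", "+")
    }
    placements[[length(placements) + 1L]] <- data.frame(
      object = object_name, component = p$contig,
      orientation = p$orientation,
      length = as.numeric(contig_lengths[p$contig]))
  }
  out <- do.call(rbind, placements)
  rownames(out) <- NULL
  attr(out, "orientation_unknown") <- unknown
  out
}

#' Evaluate a pseudomolecule reconstruction against the simulated truth
#'
#' Reports the placement rate (anchored contigs over all truth contigs,
#' and over marker-bearing contigs when `informative_contigs` is given),
#' group purity (anchored contigs whose source chromosome matches their
#' object's majority chromosome), adjacency accuracy (truth-adjacent
#' anchored pairs that are adjacent in the output) and orientation
#' accuracy (anchored contigs, optionally restricted to those with at
#' least `min_markers` markers, whose orientation matches truth after
#' composing strands and aligning each object's direction by majority
#' vote — a reconstructed chromosome read end-to-beginning is equivalent).
#'
#' @param pseudo A [pseudomolecule_set()].
#' @param truth A `truth_placement` (split-adjusted if contigs were
#'   broken).
#' @param informative_contigs Optional character vector (e.g. contigs
#'   carrying markers) used as the placement-rate denominator.
#' @param contig_markers Optional named count of markers per contig for
#'   the orientation denominator.
#' @param min_markers Minimum markers for the orientation denominator.
#' @return List of class `evaluation_report`.
#' @export
evaluate_against_truth <- function(pseudo, truth,
                                   informative_contigs = NULL,
                                   contig_markers = NULL,
                                   min_markers = 1L) {
  p <- pseudo$placements
  unknown <- setdiff(p$component, truth$contig_len$contig)
  if (length(unknown))
    stop(sprintf("contig '%s' absent from truth", unknown[[1L]]))
  # dominant source chromosome and strand per contig (longest part wins)
  parts <- truth$parts
  parts$len <- parts$src_end - parts$src_start
  dom <- do.call(rbind, lapply(split(parts, parts$contig), function(s) {
    s[which.max(s$len), c("contig", "chrom", "strand")]
  }))
  anchored <- p$component
  placement_rate <- length(anchored) / nrow(truth$contig_len)
  placement_rate_informative <- if (!is.null(informative_contigs))
    length(intersect(anchored, informative_contigs)) /
    length(informative_contigs) else NA_real_
  # group purity
  p$true_chrom <- dom$chrom[match(p$component, dom$contig)]
  obj_chrom <- vapply(split(seq_len(nrow(p)), p$object), function(ii) {
    len <- p$length[ii]
    names(sort(tapply(len, p$true_chrom[ii], sum), decreasing = TRUE))[[1L]]
  }, "")
  purity <- mean(p$true_chrom == obj_chrom[p$object])
  # adjacency over dominant parts only: a residual sliver left by an
  # imprecise break (or a chimera's minor part) does not define where a
  # contig truly belongs
  dom_parts <- do.call(rbind, lapply(split(parts, parts$contig),
                                     function(s) s[which.max(s$len), ]))
  ts <- dom_parts[order(dom_parts$chrom, dom_parts$src_start), ]
  same <- ts$chrom[-1] == ts$chrom[-nrow(ts)] &
    ts$contig[-1] != ts$contig[-nrow(ts)]
  truth_adj <- unique(data.frame(
    a = pmin(ts$contig[-nrow(ts)][same], ts$contig[-1][same]),
    b = pmax(ts$contig[-nrow(ts)][same], ts$contig[-1][same])))
  truth_adj <- truth_adj[truth_adj$a %in% anchored &
                           truth_adj$b %in% anchored, , drop = FALSE]
  out_adj <- do.call(rbind, lapply(split(p, p$object), function(s) {
    if (nrow(s) < 2L) return(NULL)
    data.frame(a = pmin(s$component[-nrow(s)], s$component[-1]),
               b = pmax(s$component[-nrow(s)], s$component[-1]))
  }))
  adj_hit <- if (nrow(truth_adj) == 0L) NA_real_ else {
    key_t <- paste(truth_adj$a, truth_adj$b)
    key_o <- if (is.null(out_adj)) character(0)
    else paste(out_adj$a, out_adj$b)
    mean(key_t %in% key_o)
  }
  # orientation, per-object direction aligned by majority
  p$true_strand <- dom$strand[match(p$component, dom$contig)]
  elig <- rep(TRUE, nrow(p))
  if (!is.null(contig_markers)) {
    cm <- contig_markers[p$component]
    cm[is.na(cm)] <- 0
    elig <- cm >= min_markers
  }
  ori_ok <- logical(0)
  for (ob in unique(p$object)) {
    s <- p[p$object == ob, ]
    agree <- s$orientation == s$true_strand
    flip_better <- sum(!agree) > sum(agree)
    ok <- if (flip_better) !agree else agree
    ori_ok <- c(ori_ok, ok[elig[p$object == ob]])
  }
  orientation_accuracy <- if (length(ori_ok)) mean(ori_ok) else NA_real_
  structure(list(placement_rate = placement_rate,
                 placement_rate_informative = placement_rate_informative,
                 group_purity = purity,
                 adjacency_accuracy = adj_hit,
                 orientation_accuracy = orientation_accuracy,
                 n_anchored = length(anchored),
                 n_truth_adjacent_pairs = nrow(truth_adj)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  for (nm in names(x))
    cat(sprintf("  %-28s %s\n", nm,
                if (is.numeric(x[[nm]])) format(round(x[[nm]], 4))
                else format(x[[nm]])))
  invisible(x)
}
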