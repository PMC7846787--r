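#' Run the full anchoring pipeline
#'
#' Orchestrates: variant filtering, HMM parental assignment, LD
#' linkage-group inference, chimeric-contig detection and splitting
#' (after which haplotypes and linkage groups are recomputed), barcode
#' scaffold-graph construction and greedy path clustering, scaffold-to-
#' group assignment, genetic ordering/orientation, and breakpoint-based
#' genetic map estimation. The ends newly created by a split are excluded
#' from the barcode graph because the break position is uncertain; the
#' genetic map still anchors both fragments.
#'
#' @param m A [marker_geno()] with designated parents.
#' @param aln Barcode alignment table.
#' @param contig_lengths Named vector of contig lengths.
#' @param config A [pipeline_config()].
#' @param truth Optional `truth_placement` carried through splits for
#'   later evaluation.
#' @return List of class `anchoring_result`: `pseudo`
#'   ([pseudomolecule_set()]), `map` (genetic map data.frame), `groups`,
#'   `scaffolds`, `breaks` (applied break positions), `unresolvable`,
#'   `haplotypes`, `truth` (split-adjusted), `contig_lengths`, `filter_report`.
#' @export
run_anchoring <- function(m, aln, contig_lengths,
                          config = pipeline_config(), truth = NULL) {
  mf <- filter_variants(m, config)
  filter_report <- attr(mf, "filter_report")
  h <- assign_parental_haplotypes(mf, config)
  # linkage groups over LD-consistent marker segments, so a chimeric
  # contig is represented by one node per constituent region rather than
  # bridging two chromosomes
  marker_groups <- unit_marker_groups(mf, config)
  # chimera detection: contigs whose markers span several groups
  multi <- names(which(tapply(marker_groups$group, marker_groups$contig,
                              function(g) length(unique(g))) > 1L))
  breaks <- list(); unresolvable <- character(0)
  for (ctg in multi) {
    b <- detect_misassemblies(ctg, aln, marker_groups, config)
    if (isTRUE(attr(b, "unresolvable"))) unresolvable <- c(unresolvable, ctg)
    else if (length(b)) breaks[[ctg]] <- as.numeric(b)
  }
  # marker-free barcode-continuity scan catches chimeras whose minor
  # part carries no (post-filter) markers
  for (ctg in names(contig_lengths)) {
    sb <- scan_barcode_breaks(ctg, aln, contig_lengths[[ctg]], config)
    if (!length(sb)) next
    have <- breaks[[ctg]] %||% numeric(0)
    fresh <- sb[vapply(sb, function(x)
      all(abs(x - have) > 50000), TRUE)]
    if (length(fresh)) breaks[[ctg]] <- sort(c(have, fresh))
  }
  cut_ends <- character(0)
  if (length(breaks)) {
    log_msg("breaking %d contigs at %d positions", length(breaks),
            sum(lengths(breaks)))
    for (ctg in names(breaks)) {
      npiece <- length(breaks[[ctg]]) + 1L
      ids <- sprintf("%s_%d", ctg, seq_len(npiece))
      cut_ends <- c(cut_ends,
                    paste0(ids[-npiece], ":tail"),
                    paste0(ids[-1L], ":head"))
    }
    upd <- apply_breaks(breaks, mf, aln, contig_lengths, truth)
    mf <- upd$m; aln <- upd$aln
    contig_lengths <- upd$contig_lengths; truth <- upd$truth
    h <- assign_parental_haplotypes(mf, config)
    marker_groups <- unit_marker_groups(mf, config)
  }
  lg <- contig_groups_from_markers(marker_groups)
  if (length(unresolvable)) {
    keep <- !(mf$markers$contig %in% unresolvable)
    mf <- subset_markers(mf, keep)
    h <- assign_parental_haplotypes(mf, config)
  }
  # scaffold graph over all contigs (markerless ones included)
  eb <- collect_end_barcodes(aln, contig_lengths, config)
  g <- build_scaffold_graph(eb, config)
  if (length(cut_ends) && nrow(g$edges)) {
    e1 <- paste0(g$edges$contig1, ":", g$edges$end1)
    e2 <- paste0(g$edges$contig2, ":", g$edges$end2)
    g$edges <- g$edges[!(e1 %in% cut_ends | e2 %in% cut_ends), ,
                       drop = FALSE]
  }
  contigs <- setdiff(names(contig_lengths), unresolvable)
  scaffolds <- greedy_scaffold_paths(g, contigs)
  assign <- assign_to_linkage_groups(scaffolds, marker_groups)
  # per group: chain, map, order
  placements <- list(); maps <- list()
  group_len <- tapply(
    vapply(scaffolds, function(p)
      sum(as.numeric(contig_lengths[p$contig])), 0),
    assign$group, sum)
  groups_sorted <- as.integer(names(sort(group_len, decreasing = TRUE)))
  for (oi in seq_along(groups_sorted)) {
    grp <- groups_sorted[[oi]]
    obj <- sprintf("pm%02d", oi)
    in_grp <- which(!is.na(assign$group) & assign$group == grp)
    chained <- chain_scaffolds(scaffolds[in_grp], h)
    ord <- unlist(lapply(chained, scaffold_marker_order,
                         markers = h$markers))
    gm <- count_breakpoints_and_estimate_cm(h, ord, config)
    marker_map <- data.frame(
      marker_id = gm$marker_id,
      contig = h$markers$contig[ord],
      pos = h$markers$pos[ord],
      linkage_group = obj,
      cM = gm$cM)
    maps[[length(maps) + 1L]] <- marker_map
    placements[[length(placements) + 1L]] <-
      order_and_orient(chained, marker_map, contig_lengths, obj, config)
  }
  pseudo <- pseudomolecule_set(do.call(rbind, placements),
                               config$agp_gap_bp)
  structure(list(pseudo = pseudo,
                 map = do.call(rbind, maps),
                 groups = lg, scaffolds = scaffolds, assign = assign,
                 breaks = breaks, unresolvable = unresolvable,
                 haplotypes = h, truth = truth,
                 contig_lengths = contig_lengths,
                 filter_report = filter_report),
            class = "anchoring_result")
}

# Majority linkage group per contig from marker-level assignments.
contig_groups_from_markers <- function(marker_groups) {
  groups <- vapply(split(marker_groups$group, marker_groups$contig),
                   function(g) as.integer(names(sort(table(g),
                                                     decreasing = TRUE))[1L]),
                   0L)
  structure(list(groups = groups, edges = NULL,
                 n_groups = length(unique(groups))),
            class = "contig_linkage")
}

#' @export
print.anchoring_result <- function(x, ...) {
  cat(sprintf("anchoring_result: %d pseudomolecules, %d contigs anchored, %d broken, %d unresolvable\n",
              length(unique(x$pseudo$placements$object)),
              nrow(x$pseudo$placements), length(x$breaks),
              length(x$unresolvable)))
  invisible(x)
}
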