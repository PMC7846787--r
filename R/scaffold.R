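#' Collect barcodes observed near each contig end
#'
#' The head set of a contig holds every barcode with at least one read in
#' `[0, w)` and the tail set those with a read in `[L - w, L)`, where
#' `w = min(end_window_bp, floor(L / 2))` so the two windows of a short
#' contig never overlap. A barcode may appear in both sets.
#'
#' @param aln Barcode alignment table (barcode, contig, pos, strand).
#' @param contig_lengths Named vector of contig lengths.
#' @param config A [pipeline_config()].
#' @return data.table with columns `contig`, `end` ("head"/"tail"),
#'   `barcode`, one row per distinct (end, barcode).
#' @export
collect_end_barcodes <- function(aln, contig_lengths,
                                 config = pipeline_config()) {
  tab <- data.table::as.data.table(aln)
  tab$L <- as.numeric(contig_lengths[tab$contig])
  if (anyNA(tab$L)) stop("alignment references unknown contigs")
  w <- pmin(config$end_window_bp, floor(tab$L / 2))
  head_rows <- tab[tab$pos < w, c("contig", "barcode")]
  tail_rows <- tab[tab$pos >= tab$L - w, c("contig", "barcode")]
  out <- rbind(cbind(head_rows, end = "head"),
               cbind(tail_rows, end = "tail"))
  unique(out[, c("contig", "end", "barcode")])
}

#' Build the barcode-sharing scaffold graph over contig ends
#'
#' Vertices are contig ends; an edge records how many barcodes two ends
#' on different contigs share. Barcodes present at more than
#' `max_end_occurrences` ends are discarded globally as promiscuous
#' (repeat-driven) before counting. Edges with fewer than
#' `min_shared_barcodes` shared barcodes are dropped; the retained edge
#' weight is the shared count normalised by the smaller of the two end
#' set sizes, correcting for coverage asymmetry.
#'
#' @param end_barcodes Output of [collect_end_barcodes()].
#' @param config A [pipeline_config()].
#' @return An object of class `scaffold_graph`: data.frame `edges`
#'   (`contig1`, `end1`, `contig2`, `end2`, `count`, `weight`) and the
#'   end set sizes.
#' @export
build_scaffold_graph <- function(end_barcodes,
                                 config = pipeline_config()) {
  eb <- data.table::as.data.table(end_barcodes)
  if (nrow(eb) == 0L)
    return(structure(list(edges = empty_scaffold_edges(),
                          set_sizes = integer(0)),
                     class = "scaffold_graph"))
  eb$end_id <- paste0(eb$contig, ":", eb$end)
  occ <- eb[, list(n_ends = length(unique(end_id))), by = "barcode"]
  keep_bc <- occ$barcode[occ$n_ends <= config$max_end_occurrences]
  eb <- eb[eb$barcode %in% keep_bc, ]
  sizes <- table(eb$end_id)
  if (nrow(eb) == 0L)
    return(structure(list(edges = empty_scaffold_edges(),
                          set_sizes = sizes),
                     class = "scaffold_graph"))
  pairs <- merge(eb[, c("barcode", "end_id", "contig")],
                 eb[, c("barcode", "end_id", "contig")],
                 by = "barcode", allow.cartesian = TRUE,
                 suffixes = c("1", "2"))
  pairs <- pairs[pairs$end_id1 < pairs$end_id2 &
                   pairs$contig1 != pairs$contig2, ]
  if (nrow(pairs) == 0L)
    return(structure(list(edges = empty_scaffold_edges(),
                          set_sizes = sizes),
                     class = "scaffold_graph"))
  cnt <- pairs[, list(count = .N), by = c("end_id1", "end_id2")]
  cnt <- cnt[cnt$count >= config$min_shared_barcodes, ]
  edges <- as.data.frame(cnt)
  if (nrow(edges)) {
    edges$weight <- edges$count /
      pmin(as.integer(sizes[edges$end_id1]),
           as.integer(sizes[edges$end_id2]))
    sp1 <- strsplit(edges$end_id1, ":", fixed = TRUE)
    sp2 <- strsplit(edges$end_id2, ":", fixed = TRUE)
    edges <- data.frame(
      contig1 = vapply(sp1, `[[`, "", 1L),
      end1 = vapply(sp1, `[[`, "", 2L),
      contig2 = vapply(sp2, `[[`, "", 1L),
      end2 = vapply(sp2, `[[`, "", 2L),
      count = edges$count, weight = edges$weight)
  } else edges <- empty_scaffold_edges()
  structure(list(edges = edges, set_sizes = sizes),
            class = "scaffold_graph")
}

empty_scaffold_edges <- function() {
  data.frame(contig1 = character(), end1 = character(),
             contig2 = character(), end2 = character(),
             count = integer(), weight = numeric())
}

#' @export
print.scaffold_graph <- function(x, ...) {
  cat(sprintf("scaffold_graph: %d ends with barcodes, %d edges\n",
              length(x$set_sizes), nrow(x$edges)))
  invisible(x)
}

#' Greedy Salsa-style decomposition of the scaffold graph into paths
#'
#' Edges are visited in decreasing normalised weight (ties: higher count,
#' then lexicographic end pair) and accepted when both ends are still
#' unused and joining them does not close a cycle over contigs
#' (union-find check). Accepted edges plus the implicit internal edge of
#' each contig decompose the graph into simple paths; orientations follow
#' from which ends are joined (exiting a contig through its tail means
#' `+`). Contigs with no accepted edge become singleton `+` paths.
#' Tie-breaking is total, so the result is invariant to input order.
#'
#' @param graph A `scaffold_graph`.
#' @param contigs Character vector of all contig ids (singletons
#'   included).
#' @return List of class `scaffold_set`; each element is a data.frame
#'   (`contig`, `orientation`) in path order, with joining-edge weights
#'   as attribute `weights`.
#' @export
greedy_scaffold_paths <- function(graph, contigs) {
  e <- graph$edges
  ord <- order(-e$weight, -e$count,
               paste(e$contig1, e$end1, e$contig2, e$end2))
  e <- e[ord, , drop = FALSE]
  parent <- stats::setNames(seq_along(contigs), contigs)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  used <- character(0)
  accepted <- e[0, , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    id1 <- paste0(e$contig1[[i]], ":", e$end1[[i]])
    id2 <- paste0(e$contig2[[i]], ":", e$end2[[i]])
    if (id1 %in% used || id2 %in% used) next
    r1 <- find(match(e$contig1[[i]], contigs))
    r2 <- find(match(e$contig2[[i]], contigs))
    if (r1 == r2) next
    parent[[r1]] <- r2
    used <- c(used, id1, id2)
    accepted <- rbind(accepted, e[i, , drop = FALSE])
  }
  # matching: end id -> (other contig, other end, weight)
  link <- list()
  for (i in seq_len(nrow(accepted))) {
    id1 <- paste0(accepted$contig1[[i]], ":", accepted$end1[[i]])
    id2 <- paste0(accepted$contig2[[i]], ":", accepted$end2[[i]])
    link[[id1]] <- list(contig = accepted$contig2[[i]],
                        end = accepted$end2[[i]],
                        weight = accepted$weight[[i]])
    link[[id2]] <- list(contig = accepted$contig1[[i]],
                        end = accepted$end1[[i]],
                        weight = accepted$weight[[i]])
  }
  deg <- table(c(accepted$contig1, accepted$contig2))
  paths <- list()
  visited <- character(0)
  starts <- contigs[order(contigs)]
  for (ctg in starts) {
    if (ctg %in% visited) next
    ndeg <- if (ctg %in% names(deg)) deg[[ctg]] else 0L
    if (ndeg == 2L) next  # interior contig; reached from a terminal
    # choose entry end: the free one (head preferred when both free)
    entry <- if (is.null(link[[paste0(ctg, ":head")]])) "head" else "tail"
    path <- list(); wts <- numeric(0)
    cur <- ctg; cur_entry <- entry
    repeat {
      visited <- c(visited, cur)
      orient <- if (cur_entry == "head") "+" else "-"
      path[[length(path) + 1L]] <- data.frame(contig = cur,
                                              orientation = orient)
      exit <- if (cur_entry == "head") "tail" else "head"
      nxt <- link[[paste0(cur, ":", exit)]]
      if (is.null(nxt) || nxt$contig %in% visited) break
      wts <- c(wts, nxt$weight)
      cur <- nxt$contig
      cur_entry <- nxt$end
    }
    path <- do.call(rbind, path)
    paths[[length(paths) + 1L]] <- canonical_path(path, wts)
  }
  paths <- paths[order(vapply(paths, function(p) p$contig[[1L]], ""))]
  structure(paths, class = "scaffold_set")
}

# Canonical direction: the representation whose contig sequence (then
# orientation string) is lexicographically smaller wins.
canonical_path <- function(path, wts) {
  rev_path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
  rev_path$orientation <- ifelse(rev_path$orientation == "+", "-", "+")
  rownames(path) <- rownames(rev_path) <- NULL
  key_f <- paste(paste(path$contig, collapse = ","),
                 paste(path$orientation, collapse = ""))
  key_r <- paste(paste(rev_path$contig, collapse = ","),
                 paste(rev_path$orientation, collapse = ""))
  if (key_r < key_f) {
    attr(rev_path, "weights") <- rev(wts)
    rev_path
  } else {
    attr(path, "weights") <- wts
    path
  }
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat(sprintf("scaffold_set: %d paths over %d contigs\n", length(x),
              sum(vapply(x, nrow, 0L))))
  invisible(x)
}
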