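#' Marker genotype matrix
#'
#' Container for RIL genotype calls at markers located on contigs. Calls
#' are stored as an integer matrix (markers x samples) with codes
#' 1 = A, 2 = B, 3 = H and `NA` = missing; `gq` holds per-call Phred
#' genotype qualities (`NA` = unknown, treated as passing quality filters).
#'
#' @param markers data.frame with columns `marker_id`, `contig`, `pos`
#'   (0-based bp within the contig).
#' @param calls Integer matrix, one row per marker, one column per sample.
#' @param samples Character vector of sample ids (column names).
#' @param parents Character vector of length 2 naming the samples that are
#'   the A and B parent, or `NULL` if undesignated.
#' @param gq Numeric matrix of genotype qualities or `NULL`.
#' @return An object of class `marker_geno`.
#' @export
marker_geno <- function(markers, calls, samples, parents = NULL, gq = NULL) {
  markers <- as.data.frame(markers)
  stopifnot(all(c("marker_id", "contig", "pos") %in% names(markers)))
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(markers))
    stop("calls must have one row per marker")
  if (ncol(calls) != length(samples))
    stop("calls must have one column per sample")
  if (!is.null(gq)) {
    gq <- as.matrix(gq)
    stopifnot(dim(gq)[1] == nrow(calls), dim(gq)[2] == ncol(calls))
  }
  if (!is.null(parents)) {
    stopifnot(length(parents) == 2L, all(parents %in% samples))
  }
  ord <- order(markers$contig, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  if (!is.null(gq)) gq <- gq[ord, , drop = FALSE]
  key <- paste(markers$contig, markers$pos)
  if (anyDuplicated(key))
    stop("duplicate marker coordinates (contig, pos) are not allowed")
  rownames(calls) <- markers$marker_id
  colnames(calls) <- samples
  if (!is.null(gq)) dimnames(gq) <- dimnames(calls)
  structure(list(markers = markers, calls = calls, gq = gq,
                 samples = samples, parents = parents),
            class = "marker_geno")
}

#' @export
print.marker_geno <- function(x, ...) {
  cat(sprintf("marker_geno: %d markers x %d samples on %d contigs\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$markers$contig))))
  if (!is.null(x$parents))
    cat(sprintf("  parents: %s (A), %s (B)\n", x$parents[1], x$parents[2]))
  tab <- table(factor(call_levels[x$calls], levels = call_levels),
               useNA = "always")
  cat(sprintf("  calls: A=%d B=%d H=%d missing=%d\n",
              tab[["A"]], tab[["B"]], tab[["H"]],
              sum(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.marker_geno <- function(x) dim(x$calls)

# Subset markers by logical/integer index, keeping all slots aligned.
subset_markers <- function(m, idx) {
  marker_geno(m$markers[idx, , drop = FALSE],
              m$calls[idx, , drop = FALSE],
              m$samples, m$parents,
              if (!is.null(m$gq)) m$gq[idx, , drop = FALSE] else NULL)
}

# Columns of non-parent (RIL) samples.
ril_columns <- function(m) {
  if (is.null(m$parents)) seq_along(m$samples)
  else which(!(m$samples %in% m$parents))
}

# Per-marker summary statistics over non-missing, non-parent samples.
# MAF counts H as half an allele each; het rate and genotyped count are
# over all non-missing RIL calls.
marker_stats <- function(m) {
  calls <- m$calls[, ril_columns(m), drop = FALSE]
  nA <- rowSums(calls == CALL_A, na.rm = TRUE)
  nB <- rowSums(calls == CALL_B, na.rm = TRUE)
  nH <- rowSums(calls == CALL_H, na.rm = TRUE)
  n <- nA + nB + nH
  pA <- (nA + nH / 2) / pmax(n, 1)
  maf <- pmin(pA, 1 - pA)
  maf[n == 0] <- NA_real_
  data.frame(marker_id = m$markers$marker_id,
             n_genotyped = n, maf = maf,
             het_rate = ifelse(n > 0, nH / n, NA_real_))
}
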