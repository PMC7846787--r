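#' Pairwise linkage disequilibrium between two markers
#'
#' r-squared is the squared Pearson correlation of 0/1 allele indicators
#' over samples that are non-missing homozygotes (A or B) at both
#' markers; heterozygous and missing calls are excluded pairwise, because
#' the population is inbred and LD is computed "among pairs of alleles".
#' If fewer than two complete samples remain, or a marker is monomorphic
#' after exclusion, the result is undefined and returned as `NA` (never
#' coerced to 0).
#'
#' @param a,b Marker call vectors in internal coding (1 = A, 2 = B,
#'   3 = H, `NA` missing) or as `"A"/"B"/"H"/NA` characters.
#' @return r-squared in [0,1], or `NA` if undefined.
#' @export
pairwise_r2 <- function(a, b) {
  a <- encode_calls01(a); b <- encode_calls01(b)
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 2L) return(NA_real_)
  x <- a[keep]; y <- b[keep]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# Map calls to 0/1 allele dosage of homozygotes; H and missing -> NA.
encode_calls01 <- function(v) {
  if (is.character(v)) v <- match(v, call_levels)
  out <- rep(NA_real_, length(v))
  out[!is.na(v) & v == CALL_A] <- 0
  out[!is.na(v) & v == CALL_B] <- 1
  out
}

# 0/1 matrix (markers x RIL samples) from either container. Imputed
# labels are never missing; genotype calls lose H and missing to NA.
calls01_of <- function(m) {
  if (inherits(m, "parental_haplotypes")) return(m$labels - 1)
  x <- encode_calls01(m$calls[, ril_columns(m), drop = FALSE])
  dim(x) <- c(nrow(m$calls), length(ril_columns(m)))
  x
}

# Full pairwise-complete r^2 matrix for a 0/1 matrix with NAs
# (markers x samples), via three cross-products. Undefined entries NA.
r2_matrix <- function(x01) {
  M <- (!is.na(x01)) * 1
  Z <- x01; Z[is.na(Z)] <- 0
  n <- M %*% t(M)
  Sxy <- Z %*% t(Z)
  Sx <- Z %*% t(M)            # Sx[i,j] = sum of x_i over joint-complete
  num <- n * Sxy - Sx * t(Sx)
  vi <- n * Sx - Sx^2          # n * sum(x^2) - sum(x)^2, x binary
  den2 <- vi * t(vi)
  r2 <- matrix(NA_real_, nrow(x01), nrow(x01))
  ok <- n >= 2 & den2 > 0
  r2[ok] <- num[ok]^2 / den2[ok]
  r2
}

# Deterministic subsample of marker row-indices per contig so that any
# contig pair contributes at most ~cap inter-contig pairs. Markers are
# taken from the two contig ends (half each), because junction-proximal
# pairs carry the inter-contig linkage signal.
subsample_per_contig <- function(contig, cap) {
  k <- max(2L, floor(sqrt(cap)))
  unlist(lapply(split(seq_along(contig), contig), function(idx) {
    if (length(idx) <= k) idx
    else c(utils::head(idx, ceiling(k / 2)), utils::tail(idx, floor(k / 2)))
  }), use.names = FALSE)
}

#' Infer linkage groups of contigs from inter-contig LD
#'
#' Evaluates r-squared between markers on different contigs and joins two
#' contigs when at least `min_ld_pairs` marker pairs exceed
#' `r2_threshold` (the published rule is a bare r-squared > 0.8; the
#' pair-count floor suppresses single-pair spurious joins and can be set
#' to 1 for strict behaviour). Connected components of the resulting
#' contig graph are the linkage groups. Marker pairs per contig pair are
#' capped at `ld_pair_cap` by a deterministic, evenly spaced per-contig
#' subsample that always includes each contig's terminal markers.
#'
#' @param m A `parental_haplotypes` (preferred: imputed, error-smoothed)
#'   or filtered [marker_geno()].
#' @param config A [pipeline_config()].
#' @param contig_lengths Optional named vector used to order groups by
#'   decreasing total length (ties broken by smallest contig id); marker
#'   span is used when absent.
#' @return A list of class `contig_linkage`: `groups` (named integer
#'   vector contig -> group id), `edges` (contig pair, supporting pair
#'   count, max r-squared), `n_groups`.
#' @export
infer_linkage_groups <- function(m, config = pipeline_config(),
                                 contig_lengths = NULL) {
  x01 <- calls01_of(m)
  markers <- m$markers
  keep <- subsample_per_contig(markers$contig, config$ld_pair_cap)
  keep <- sort(keep)
  x01 <- x01[keep, , drop = FALSE]
  ctg <- markers$contig[keep]
  r2 <- r2_matrix(x01)
  hits <- which(r2 > config$r2_threshold, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  ci <- ctg[hits[, 1]]; cj <- ctg[hits[, 2]]
  inter <- ci != cj
  edges <- data.frame(a = pmin(ci[inter], cj[inter]),
                      b = pmax(ci[inter], cj[inter]),
                      r2 = r2[hits[inter, , drop = FALSE]])
  if (nrow(edges)) {
    agg <- stats::aggregate(r2 ~ a + b, data = edges,
                            FUN = function(v) c(n = length(v), max = max(v)))
    edges <- data.frame(a = agg$a, b = agg$b,
                        n_pairs = agg$r2[, "n"], max_r2 = agg$r2[, "max"])
    edges <- edges[edges$n_pairs >= config$min_ld_pairs, , drop = FALSE]
  } else {
    edges <- data.frame(a = character(), b = character(),
                        n_pairs = integer(), max_r2 = numeric())
  }
  contigs <- sort(unique(markers$contig))
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = contigs)
  comp <- igraph::components(g)$membership
  # order groups by decreasing total contig length, ties by smallest id
  if (is.null(contig_lengths)) {
    span <- tapply(markers$pos, markers$contig, function(p)
      max(p) - min(p) + 1)
    contig_lengths <- span
  }
  glen <- tapply(as.numeric(contig_lengths[names(comp)]), comp, sum,
                 na.rm = TRUE)
  gmin <- tapply(names(comp), comp, min)
  ord <- order(-glen, gmin)
  remap <- integer(length(ord))
  remap[as.integer(names(glen))[ord]] <- seq_along(ord)
  groups <- remap[comp]
  names(groups) <- names(comp)
  structure(list(groups = groups, edges = edges,
                 n_groups = length(unique(groups))),
            class = "contig_linkage")
}

#' @export
print.contig_linkage <- function(x, ...) {
  cat(sprintf("contig_linkage: %d contigs in %d groups, %d edges\n",
              length(x$groups), x$n_groups, nrow(x$edges)))
  invisible(x)
}

#' LD decay curve over physical distance
#'
#' Bins all same-chromosome marker pairs within `max_distance` by
#' physical distance (bins of `bin_width`, conventionally 10 or 100 kbp)
#' and averages r-squared per bin; undefined pairs are excluded from both
#' numerator and count.
#'
#' @param m A [marker_geno()] or `parental_haplotypes`.
#' @param positions data.frame with `chrom` and `pos` (bp) per marker,
#'   aligned with the marker rows (anchored coordinates).
#' @param bin_width Bin width in bp.
#' @param max_distance Maximum pair distance in bp.
#' @return data.frame: `bin_start`, `bin_end`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(m, positions, bin_width = 10000,
                     max_distance = 1000000) {
  x01 <- calls01_of(m)
  stopifnot(nrow(positions) == nrow(x01))
  n_bins <- ceiling(max_distance / bin_width)
  sums <- numeric(n_bins); counts <- integer(n_bins)
  for (cn in unique(positions$chrom)) {
    sel <- which(positions$chrom == cn)
    if (length(sel) < 2L) next
    r2 <- r2_matrix(x01[sel, , drop = FALSE])
    pos <- positions$pos[sel]
    d <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(d)
    ok <- ut & d <= max_distance & d > 0 & !is.na(r2)
    bin <- pmin(n_bins, floor(d[ok] / bin_width) + 1L)
    sums <- sums + as.numeric(tapply(r2[ok], factor(bin, levels = 1:n_bins),
                                     sum, default = 0))
    counts <- counts + as.integer(tapply(rep(1L, sum(ok)),
                                         factor(bin, levels = 1:n_bins),
                                         sum, default = 0))
  }
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_width,
             bin_end = seq_len(n_bins) * bin_width,
             mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
             n_pairs = counts)
}
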