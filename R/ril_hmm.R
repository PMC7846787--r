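#' Assign parental haplotypes by a two-state Viterbi HMM
#'
#' Imputes missing genotypes and labels every marker of every RIL sample
#' with a parent of origin, contig by contig, in the style of NGSEP's
#' ImputeVCF (`-k 2 -c 0.003`). States are the two parents; the
#' transition probability between adjacent markers is
#' `hmm_switch_prob`. Emission probabilities: the matching homozygote has
#' probability `1 - hmm_error_rate`, the opposite homozygote
#' `hmm_error_rate`; heterozygous calls are emitted with a fixed small
#' probability (0.05) from both states and missing calls are
#' uninformative (probability 1 from both states). Markers whose parent
#' calls are not homozygous and opposite cannot be polarized and are
#' dropped with a warning. Contigs with fewer than two informative
#' markers fall back to the per-sample majority call and are flagged.
#'
#' @param m A filtered [marker_geno()] with designated parents. Markers
#'   whose A-parent carries the B allele are re-polarized (A and B calls
#'   swapped) before decoding.
#' @param config A [pipeline_config()].
#' @return A `parental_haplotypes` object: `labels` (integer matrix,
#'   1 = parent A, 2 = parent B, no missing entries, RIL samples only),
#'   `markers`, `samples`, per-sample `switch_count`, and
#'   `fallback_contigs`.
#' @export
assign_parental_haplotypes <- function(m, config = pipeline_config()) {
  if (is.null(m$parents)) stop("parents must be designated")
  pa <- match(m$parents[[1]], m$samples)
  pb <- match(m$parents[[2]], m$samples)
  ca <- m$calls[, pa]; cb <- m$calls[, pb]
  polarizable <- !is.na(ca) & !is.na(cb) &
    ca != CALL_H & cb != CALL_H & ca != cb
  if (!all(polarizable)) {
    warning(sprintf("dropping %d markers that cannot be polarized by parents",
                    sum(!polarizable)))
    m <- subset_markers(m, polarizable)
    ca <- ca[polarizable]
  }
  if (nrow(m$calls) == 0L) stop("no polarizable markers remain")
  flip <- ca == CALL_B
  calls <- m$calls
  if (any(flip)) {
    sub <- calls[flip, , drop = FALSE]
    swapped <- sub
    swapped[sub == CALL_A] <- CALL_B
    swapped[sub == CALL_B] <- CALL_A
    calls[flip, ] <- swapped
  }
  rc <- ril_columns(m)
  calls <- calls[, rc, drop = FALSE]
  samples <- m$samples[rc]

  e <- config$hmm_error_rate
  # emission[state, obs] with obs codes A=1, B=2, H=3, missing=4
  emis <- rbind(c(1 - e, e, 0.05, 1),
                c(e, 1 - e, 0.05, 1))
  obs <- calls
  obs[is.na(obs)] <- 4L

  labels <- matrix(NA_integer_, nrow(calls), ncol(calls),
                   dimnames = dimnames(calls))
  fallback <- character(0)
  for (ctg in unique(m$markers$contig)) {
    idx <- which(m$markers$contig == ctg)
    informative <- idx[rowSums(!is.na(calls[idx, , drop = FALSE])) > 0]
    if (length(idx) < 2L || length(informative) < 2L) {
      # majority-call fallback per sample
      for (j in seq_len(ncol(calls))) {
        v <- calls[idx, j]
        nA <- sum(v == CALL_A, na.rm = TRUE)
        nB <- sum(v == CALL_B, na.rm = TRUE)
        labels[idx, j] <- if (nB > nA) 2L else 1L
      }
      fallback <- c(fallback, ctg)
      next
    }
    for (j in seq_len(ncol(calls)))
      labels[idx, j] <- viterbi_two_state(obs[idx, j], emis,
                                          config$hmm_switch_prob)
  }
  switch_count <- colSums(labels[-1, , drop = FALSE] !=
                            labels[-nrow(labels), , drop = FALSE] &
                            m$markers$contig[-1] ==
                            m$markers$contig[-nrow(labels)])
  structure(list(labels = labels, markers = m$markers, samples = samples,
                 switch_count = switch_count,
                 fallback_contigs = fallback),
            class = "parental_haplotypes")
}

#' @export
print.parental_haplotypes <- function(x, ...) {
  cat(sprintf("parental_haplotypes: %d markers x %d samples, mean %.1f switches/sample\n",
              nrow(x$labels), ncol(x$labels), mean(x$switch_count)))
  invisible(x)
}

# Log-space Viterbi for a 2-state chain with symmetric switch probability.
# obs: integer vector with codes 1..4; emis: 2 x 4 emission matrix.
viterbi_two_state <- function(obs, emis, switch_prob) {
  n <- length(obs)
  le <- log(emis)
  ls <- log(switch_prob)
  lk <- log1p(-switch_prob)
  # delta[state]: best log-prob ending in state; uniform prior
  back <- matrix(0L, 2L, n)
  d1 <- le[1L, obs[[1L]]]
  d2 <- le[2L, obs[[1L]]]
  if (n > 1L) for (t in 2:n) {
    s11 <- d1 + lk; s21 <- d2 + ls
    s12 <- d1 + ls; s22 <- d2 + lk
    if (s11 >= s21) { n1 <- s11; back[1L, t] <- 1L }
    else { n1 <- s21; back[1L, t] <- 2L }
    if (s22 >= s12) { n2 <- s22; back[2L, t] <- 2L }
    else { n2 <- s12; back[2L, t] <- 1L }
    d1 <- n1 + le[1L, obs[[t]]]
    d2 <- n2 + le[2L, obs[[t]]]
  }
  path <- integer(n)
  path[[n]] <- if (d1 >= d2) 1L else 2L
  if (n > 1L) for (t in n:2) path[[t - 1L]] <- back[path[[t]], t]
  path
}
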