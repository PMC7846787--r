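# Independent oracles used across test files. These deliberately avoid
# the package's own code paths.

# Log-probability of a fixed 2-state label path given observations,
# symmetric switch probability and an emission matrix (2 x 4).
path_logprob <- function(path, obs, emis, switch_prob) {
  lp <- log(emis[path[1], obs[1]])
  if (length(obs) > 1) for (t in 2:length(obs)) {
    lp <- lp + log(ifelse(path[t] == path[t - 1],
                          1 - switch_prob, switch_prob)) +
      log(emis[path[t], obs[t]])
  }
  lp
}

# Exhaustive maximum over all 2^m label paths.
best_path_logprob <- function(obs, emis, switch_prob) {
  m <- length(obs)
  grid <- as.matrix(expand.grid(rep(list(1:2), m)))
  max(apply(grid, 1, path_logprob, obs = obs, emis = emis,
            switch_prob = switch_prob))
}

# Hand-rolled union-find connected components over an edge list.
uf_components <- function(nodes, a, b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_along(a)) {
    ra <- find(a[[i]]); rb <- find(b[[i]])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, "")
}

# Emission matrix matching the package HMM (obs: A=1,B=2,H=3,missing=4).
hmm_emissions <- function(e) rbind(c(1 - e, e, 0.05, 1),
                                   c(e, 1 - e, 0.05, 1))

# Tiny deterministic marker_geno builder. calls: character matrix with
# "A"/"B"/"H"/NA; rows markers, cols samples.
toy_geno <- function(calls, contig = "ctg1", pos = NULL, parents = NULL,
                     gq = NULL) {
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  code <- matrix(match(calls, c("A", "B", "H")), nrow = n)
  marker_geno(
    data.frame(marker_id = sprintf("m%02d", seq_len(n)),
               contig = rep_len(contig, n), pos = pos),
    code, colnames(calls, do.NULL = FALSE, prefix = "S"),
    parents = parents, gq = gq)
}

# Interval intersection length.
interval_overlap <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))
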