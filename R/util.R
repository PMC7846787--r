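# Internal helpers shared across modules.

# Genotype call codes used throughout: integer matrix with
#   1 = A (first-parent homozygote), 2 = B, 3 = H (heterozygote),
#   NA = missing. Kept internal; user-facing I/O uses "A"/"B"/"H"/NA.
CALL_A <- 1L
CALL_B <- 2L
CALL_H <- 3L

call_levels <- c("A", "B", "H")

# Derive a reproducible substream seed from a master seed and a label, so
# each pipeline stage is independently reproducible. Stays below 2^31.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) {
  if (isTRUE(getOption("anchormap.verbose", FALSE)))
    message(sprintf("[anchormap] %s", sprintf(...)))
  invisible(NULL)
}
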