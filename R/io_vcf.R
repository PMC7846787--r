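#' Read a VCF file into a marker genotype matrix
#'
#' Parses VCF 4.x genotype records into a [marker_geno()] object. Only
#' biallelic single-nucleotide records are used; multiallelic and non-SNV
#' records are skipped and counted. Genotypes are coded from GT
#' (unphased or phased): `0/0` -> A, `1/1` -> B, `0/1`/`1/0` -> H,
#' `./.` -> missing. A GQ FORMAT field, when present, is stored per call;
#' absent GQ is recorded as `NA` ("unknown") and treated as passing
#' quality filters downstream.
#'
#' This is a purpose-built reader for GT/GQ matrices rather than a general
#' VCF stack: it reports malformed lines by line number and accounts for
#' every skipped record, which the pipeline's filter report requires.
#'
#' @param path Path to an uncompressed VCF file.
#' @param config A [pipeline_config()] (reserved; parsing itself applies
#'   no thresholds).
#' @param parents Optional character vector of length 2 naming the parent
#'   samples (A parent first).
#' @return A [marker_geno()]; attribute `skipped` counts records skipped
#'   as non-biallelic-SNV.
#' @export
read_genotype_matrix <- function(path, config = pipeline_config(),
                                 parents = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L)
    stop("not a VCF: expected exactly one #CHROM header line")
  cols <- strsplit(lines[[hdr]], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L)
    stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body_idx <- which(seq_along(lines) > hdr & !startsWith(lines, "#") &
                      nzchar(lines))
  n_skipped <- 0L
  recs <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[[k]]
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols))
      stop(sprintf("malformed VCF line %d: %d fields, expected %d",
                   i, length(f), length(cols)))
    ref <- f[[4]]; alt <- f[[5]]
    if (nchar(ref) != 1L || nchar(alt) != 1L || grepl(",", alt, fixed = TRUE) ||
        !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
      n_skipped <- n_skipped + 1L
      next
    }
    pos <- suppressWarnings(as.integer(f[[2]]))
    if (is.na(pos)) stop(sprintf("malformed VCF line %d: non-integer POS", i))
    fmt <- strsplit(f[[9]], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop(sprintf("VCF line %d lacks GT in FORMAT", i))
    gq_i <- match("GQ", fmt)
    sm <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    gt <- vapply(sm, function(s) s[[gt_i]], "")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    call <- rep(NA_integer_, length(gt))
    call[gt == "0/0"] <- CALL_A
    call[gt == "1/1"] <- CALL_B
    call[gt %in% c("0/1", "1/0")] <- CALL_H
    bad <- !(gt %in% c("0/0", "1/1", "0/1", "1/0", "./.", "."))
    if (any(bad))
      stop(sprintf("malformed VCF line %d: unparseable GT '%s'",
                   i, gt[bad][1]))
    gq <- rep(NA_real_, length(gt))
    if (!is.na(gq_i)) {
      raw <- vapply(sm, function(s)
        if (length(s) >= gq_i) s[[gq_i]] else ".", "")
      gq <- suppressWarnings(as.numeric(raw))
    }
    recs[[k]] <- list(contig = f[[1]], pos = pos - 1L,
                      id = if (f[[3]] == ".")
                        sprintf("%s_%d", f[[1]], pos) else f[[3]],
                      call = call, gq = gq)
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0L)
    stop("no usable biallelic SNV records in VCF")
  if (n_skipped > 0L)
    log_msg("skipped %d non-biallelic-SNV VCF records", n_skipped)
  markers <- data.frame(
    marker_id = vapply(recs, `[[`, "", "id"),
    contig = vapply(recs, `[[`, "", "contig"),
    pos = vapply(recs, `[[`, 0L, "pos"))
  calls <- do.call(rbind, lapply(recs, `[[`, "call"))
  gq <- do.call(rbind, lapply(recs, `[[`, "gq"))
  m <- marker_geno(markers, calls, samples, parents, gq)
  attr(m, "skipped") <- n_skipped
  m
}

#' Write a marker genotype matrix as a minimal VCF
#'
#' Emits VCF 4.2 with GT and GQ fields, placeholder REF/ALT alleles (A/T)
#' since only the biallelic coding matters downstream. Positions are
#' written 1-based per the VCF convention.
#'
#' @param m A [marker_geno()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(m, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", m$samples), collapse = "\t"))
  gt_str <- matrix("./.", nrow(m$calls), ncol(m$calls))
  gt_str[m$calls == CALL_A] <- "0/0"
  gt_str[m$calls == CALL_B] <- "1/1"
  gt_str[m$calls == CALL_H] <- "0/1"
  gq <- m$gq
  if (is.null(gq)) gq <- matrix(NA_real_, nrow(m$calls), ncol(m$calls))
  cell <- matrix(paste0(gt_str, ":",
                        ifelse(is.na(gq), ".", format(gq, trim = TRUE))),
                 nrow(m$calls), ncol(m$calls))
  body <- paste(m$markers$contig, m$markers$pos + 1L, m$markers$marker_id,
                "A", "T", ".", "PASS", ".", "GT:GQ",
                apply(cell, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
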