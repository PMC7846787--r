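#' Read a barcode alignment table
#'
#' Barcoded read alignments are exchanged as 4-column TSV
#' (`barcode`, `contig`, `position`, `strand`), the product of an external
#' one-liner over BX-tagged BAMs, e.g.
#' `samtools view in.bam | awk -v OFS='\t' '{for(i=12;i<=NF;i++) if($i ~ /^BX:Z:/) print substr($i,6), $3, $4-1, ($2%32>=16 ? "-" : "+")}'`.
#' Positions are 0-based.
#'
#' @param path TSV path; a header line is detected and skipped.
#' @param contig_lengths Optional named vector of contig lengths; rows
#'   referencing unknown contigs or positions outside `[0, length)` are
#'   rejected.
#' @return A `data.table` with columns `barcode`, `contig`, `pos`,
#'   `strand`, sorted by (contig, pos).
#' @export
read_barcode_alignments <- function(path, contig_lengths = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    warning("empty barcode alignment file")
    return(data.table::data.table(barcode = character(), contig = character(),
                                  pos = integer(), strand = character()))
  }
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  tab <- data.table::fread(path, header = has_header, sep = "\t",
                           colClasses = list(character = c(1L, 2L, 4L)),
                           col.names = c("barcode", "contig", "pos", "strand"))
  if (nrow(tab) == 0L) {
    warning("empty barcode alignment table")
    return(tab)
  }
  if (!is.numeric(tab$pos) || anyNA(suppressWarnings(as.integer(tab$pos)))) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$pos))))[1]
    stop(sprintf("non-integer position at data line %d", bad))
  }
  tab$pos <- as.integer(tab$pos)
  if (any(tab$pos < 0))
    stop(sprintf("negative position at data line %d", which(tab$pos < 0)[1]))
  if (!all(tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(!nzchar(tab$barcode)))
    stop("empty barcode")
  if (!is.null(contig_lengths)) {
    unknown <- !(tab$contig %in% names(contig_lengths))
    if (any(unknown))
      stop(sprintf("unknown contig id '%s'", tab$contig[unknown][1]))
    over <- tab$pos >= contig_lengths[tab$contig]
    if (any(over))
      stop(sprintf("position beyond contig end for contig '%s'",
                   tab$contig[over][1]))
  }
  data.table::setorder(tab, contig, pos)
  tab[]
}

#' Write a barcode alignment table
#' @param tab Table as returned by [read_barcode_alignments()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_barcode_alignments <- function(tab, path) {
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Write a genetic map TSV
#'
#' Columns: `marker_id`, `contig`, `position`, `linkage_group`, `cM`.
#'
#' @param map data.frame with those columns (as produced by
#'   [count_breakpoints_and_estimate_cm()] plus marker metadata).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(all(c("marker_id", "contig", "position", "linkage_group", "cM")
                %in% names(map)))
  data.table::fwrite(as.data.frame(map)[, c("marker_id", "contig", "position",
                                            "linkage_group", "cM")],
                     path, sep = "\t")
  invisible(path)
}

#' Read a genetic map TSV written by [write_genetic_map()]
#' @param path TSV path.
#' @return data.frame with the map columns.
#' @export
read_genetic_map <- function(path) {
  tab <- data.table::fread(path, sep = "\t",
                           colClasses = list(character = c("marker_id",
                                                           "contig")))
  need <- c("marker_id", "contig", "position", "linkage_group", "cM")
  if (!all(need %in% names(tab)))
    stop("genetic map TSV lacks required columns")
  as.data.frame(tab)
}

#' Write pericentromere intervals as 3-column BED
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(intervals, path) {
  data.table::fwrite(as.data.frame(intervals)[, c("chrom", "start", "end")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a recombination profile TSV
#' @param profile data.frame with `chrom`, `window_start`, `window_end`,
#'   `rate_cM_per_Mbp`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_marey_profile <- function(profile, path) {
  data.table::fwrite(as.data.frame(profile)[, c("chrom", "window_start",
                                                "window_end",
                                                "rate_cM_per_Mbp")],
                     path, sep = "\t")
  invisible(path)
}

#' Write contig sequences as FASTA
#'
#' Sequence content is irrelevant downstream (only lengths matter), so
#' random bases are generated to the catalogued lengths. Requires the
#' Biostrings package.
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param path Output FASTA path.
#' @param seed Seed for the (arbitrary) base content.
#' @return `path`, invisibly.
#' @export
write_contig_fasta <- function(contig_lengths, path, seed = 1L) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("write_contig_fasta requires the Biostrings package")
  seqs <- with_seed(substream_seed(seed, "fasta"), {
    vapply(contig_lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      "")
  })
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(contig_lengths)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
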