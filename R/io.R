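# Plain-text table input/output for the pipeline's interchange formats.

#' Read a tab-separated table with a header row
#'
#' @param path File path.
#' @param genome_build Optional genome-build string attached as attribute
#'   `genome_build` (coordinate tables are 1-based inclusive).
#' @return A data frame.
#' @export
read_tsv_table <- function(path, genome_build = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(genome_build)) attr(x, "genome_build") <- genome_build
  x
}

#' Write a tab-separated table with a header row
#'
#' @param x Data frame.
#' @param path File path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export junctions in BEDPE-style coordinates
#'
#' Converts 1-based inclusive breakpoint positions to the 0-based half-open
#' convention explicitly (start = pos - 1, end = pos).
#'
#' @param junctions Junction data frame (see [filter_junctions()]).
#' @param path Optional path; when supplied the table is written as TSV.
#' @return The BEDPE-style data frame, invisibly when written.
#' @export
junctions_to_bedpe <- function(junctions, path = NULL) {
  bed <- data.frame(
    chrom1 = junctions$chrom_a, start1 = junctions$pos_a - 1L,
    end1 = junctions$pos_a,
    chrom2 = junctions$chrom_b, start2 = junctions$pos_b - 1L,
    end2 = junctions$pos_b,
    name = rownames(junctions) %||% seq_len(nrow(junctions)),
    score = junctions$mate_pairs %||% 0L,
    strand1 = junctions$strand_a, strand2 = junctions$strand_b,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    write_tsv_table(bed, path)
    return(invisible(bed))
  }
  bed
}
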