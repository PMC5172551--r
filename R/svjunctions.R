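# Structural-variant breakpoint junction filtering, typing, and
# non-template nucleotide counting.

junction_criteria <- c("mate-pairs", "assembly", "mapping-diversity",
                       "repeat-overlap", "dbsnp", "transposon-deletion",
                       "baseline-genomes")

#' Filter junctions with the seven high-confidence criteria
#'
#' A junction passes iff all seven hold: (1) at least ten mate pairs in the
#' discordant-read cluster; (2) successful de novo assembly; (3) mapping
#' diversity span strictly more than 70 bp; (4) no underrepresented-repeat
#' overlap; (5) absent from dbSNP; (6) not a transposable-element (AluY/L1)
#' deletion signature; (7) absent from the baseline set of normal genomes.
#' Failure reasons enumerate every violated criterion per record.
#'
#' @param records Junction data frame with columns `mate_pairs`,
#'   `assembled`, `span`, `repeat_overlap`, `in_dbsnp`, `te_deletion`,
#'   `in_baseline`.
#' @return A list with `pass` (the passing records, input order preserved),
#'   `records` (the input with a logical `pass` column and a `reasons`
#'   semicolon-separated string column), and `reasons` (a list of character
#'   vectors, empty iff the record passes).
#' @export
filter_junctions <- function(records) {
  need <- c("mate_pairs", "assembled", "span", "repeat_overlap",
            "in_dbsnp", "te_deletion", "in_baseline")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("missing junction attribute(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(records[need], anyNA, logical(1)))) {
    stop("junction attributes must not contain NA", call. = FALSE)
  }
  viol <- cbind(
    records$mate_pairs < 10,     # "at least ten" is inclusive
    !records$assembled,
    records$span <= 70,          # "more than 70 bp" is strict
    records$repeat_overlap,
    records$in_dbsnp,
    records$te_deletion,
    records$in_baseline
  )
  reasons <- apply(viol, 1L, function(v) junction_criteria[v],
                   simplify = FALSE)
  pass <- !apply(viol, 1L, any)
  out <- records
  out$pass <- pass
  out$reasons <- vapply(reasons, paste, character(1), collapse = ";")
  list(pass = records[pass, , drop = FALSE], records = out,
       reasons = reasons)
}

#' Type rearrangements from filtered junctions
#'
#' Per sample: inter-chromosomal junctions are translocations;
#' intra-chromosomal junctions are typed from the strand pair after
#' ordering the two breakpoints by position -- (+,-) deletion-type, (-,+)
#' duplication-type, same-strand inversion-type. Junctions with any
#' breakpoint within `complex_window` bp of another junction's breakpoint on
#' the same chromosome (same sample) are merged into a single complex call.
#'
#' @param junctions Junction data frame with `sample`, `chrom_a`, `pos_a`,
#'   `strand_a`, `chrom_b`, `pos_b`, `strand_b` and optionally
#'   `nontemplate_len`.
#' @param complex_window Breakpoint-proximity window (bp) for complex-call
#'   merging, default 1000.
#' @return A data frame of rearrangement calls: `sample`, `type`,
#'   `n_junctions`, `members` (semicolon-joined input row indices).
#' @export
type_rearrangements <- function(junctions, complex_window = 1000) {
  if (!nrow(junctions)) {
    return(data.frame(sample = character(0), type = character(0),
                      n_junctions = integer(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  simple_type <- function(rec) {
    if (rec$chrom_a != rec$chrom_b) return("translocation")
    # order breakpoints by position, carrying strands along
    if (rec$pos_a <= rec$pos_b) {
      s <- c(rec$strand_a, rec$strand_b)
    } else {
      s <- c(rec$strand_b, rec$strand_a)
    }
    if (s[1] == s[2]) "inversion"
    else if (s[1] == "+") "deletion"
    else "duplication"
  }
  out <- list()
  for (smp in unique(junctions$sample)) {
    idx <- which(junctions$sample == smp)
    sub <- junctions[idx, , drop = FALSE]
    k <- length(idx)
    # union-find over junctions sharing a nearby breakpoint
    parent <- seq_len(k)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    bp <- rbind(
      data.frame(j = seq_len(k), chrom = sub$chrom_a, pos = sub$pos_a),
      data.frame(j = seq_len(k), chrom = sub$chrom_b, pos = sub$pos_b)
    )
    if (k > 1L) {
      for (a in seq_len(nrow(bp) - 1L)) {
        for (b in (a + 1L):nrow(bp)) {
          if (bp$j[a] != bp$j[b] && bp$chrom[a] == bp$chrom[b] &&
              abs(bp$pos[a] - bp$pos[b]) <= complex_window) {
            ra <- find(bp$j[a])
            rb <- find(bp$j[b])
            if (ra != rb) parent[ra] <- rb
          }
        }
      }
    }
    comp <- vapply(seq_len(k), find, integer(1))
    for (g in unique(comp)) {
      members <- which(comp == g)
      type <- if (length(members) > 1L) "complex"
              else simple_type(sub[members, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        sample = smp, type = type, n_junctions = length(members),
        members = paste(idx[members], collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Count non-template nucleotides at a junction
#'
#' The inserted-nucleotide count is the junction sequence length minus the
#' maximal prefix exactly matching reference flank A and the maximal suffix
#' exactly matching reference flank B, floored at zero (micro-homology
#' overlap between the flank matches yields 0).
#'
#' @param junction_seq,flank_a,flank_b Non-empty uppercase A/C/G/T/N
#'   strings; `flank_a`/`flank_b` are the reference sequences flanking the
#'   two sides of the junction.
#' @return Integer insert length, between 0 and `nchar(junction_seq)`.
#' @export
count_nontemplate <- function(junction_seq, flank_a, flank_b) {
  for (s in c(junction_seq, flank_a, flank_b)) {
    if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
      stop("sequences must be single non-empty strings", call. = FALSE)
    }
    if (grepl("[^ACGTN]", s)) {
      stop("non-nucleotide characters in sequence", call. = FALSE)
    }
  }
  sj <- strsplit(junction_seq, "")[[1]]
  sa <- strsplit(flank_a, "")[[1]]
  sb <- strsplit(flank_b, "")[[1]]
  npre <- min(length(sj), length(sa))
  pre <- 0L
  while (pre < npre && sj[pre + 1L] == sa[pre + 1L]) pre <- pre + 1L
  nsuf <- min(length(sj), length(sb))
  suf <- 0L
  while (suf < nsuf &&
         sj[length(sj) - suf] == sb[length(sb) - suf]) suf <- suf + 1L
  max(0L, length(sj) - pre - suf)
}
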