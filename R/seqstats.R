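# Base-composition, codon-usage and variation statistics per sequence class
# (protein-coding, rRNA, intergenic).

#' GC content
#'
#' (G + C) / (A + C + G + T); N bases are excluded from both numerator and
#' denominator.
#'
#' @param seq DNA string (gaps "-" are ignored).
#' @return fraction in [0, 1].
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  b <- seq_bytes(gsub("-", "", seq, fixed = TRUE))
  gc <- sum(b == 71L | b == 67L)
  at <- sum(b == 65L | b == 84L)
  if (gc + at == 0L) stop("undefined GC content: no unambiguous bases")
  gc / (gc + at)
}

# standard genetic code keyed by codon; sense codons only
codon_code <- function() {
  if (is.null(.plastcomp_cache$code)) {
    gc <- Biostrings::GENETIC_CODE
    .plastcomp_cache$code <- gc
    .plastcomp_cache$sense <- names(gc)[gc != "*"]
  }
  .plastcomp_cache$code
}

sense_codons <- function() {
  codon_code()
  .plastcomp_cache$sense
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate an in-frame CDS (standard code)
#' @param cds DNA string, length divisible by 3.
#' @return amino-acid string ("*" for stops, "X" for ambiguous codons).
#' @export
translate_cds <- function(cds) {
  code <- codon_code()
  cods <- split_codons(toupper(cds))
  aa <- code[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Codon usage, RSCU, GC and GC3 of a CDS set
#'
#' RSCU(c) = k * n_c / sum of counts over c's k-fold synonymous family; values
#' above 1 mark codons used more often than expected under uniform usage
#' within the family.  GC3 is the G+C fraction at third codon positions.
#' Stop codons and codons containing N are excluded from both RSCU and GC3.
#'
#' @param cds_set named character vector of in-frame CDS sequences.
#' @return list of class `codon_usage`: `counts` (named, 64), `rscu` (named,
#'   sense codons; NA for unused families), `gc`, `gc3`, `preferred` (named
#'   by amino acid), `n_codons`.
#' @export
rscu <- function(cds_set) {
  cds_set <- vapply(cds_set, toupper, "")
  code <- codon_code()
  all_cods <- character()
  for (g in names(cds_set)) {
    cods <- tryCatch(split_codons(cds_set[[g]]), error = function(e)
      stop("gene ", g, ": ", conditionMessage(e)))
    aa <- code[cods]
    internal_stop <- which(aa == "*" & seq_along(cods) < length(cods))
    if (length(internal_stop))
      stop("internal stop codon in gene ", g, " at codon ",
           internal_stop[1L])
    all_cods <- c(all_cods, cods)
  }
  counts64 <- table(factor(all_cods, levels = names(code)))
  sense <- sense_codons()
  usable <- all_cods[all_cods %in% sense]  # drops stops and N-containing
  counts <- table(factor(usable, levels = sense))
  fam <- split(sense, code[sense])
  rscu_v <- stats::setNames(rep(NA_real_, length(sense)), sense)
  preferred <- character(0)
  for (a in names(fam)) {
    cods <- fam[[a]]
    tot <- sum(counts[cods])
    if (tot > 0L) {
      rscu_v[cods] <- length(cods) * as.numeric(counts[cods]) / tot
      preferred[a] <- cods[which.max(rscu_v[cods])]
    }
  }
  third <- substr(usable, 3L, 3L)
  gc3 <- if (length(third)) mean(third %in% c("G", "C")) else NA_real_
  list_out <- list(counts = c(counts64), rscu = rscu_v,
                   gc = gc_content(paste(cds_set, collapse = "")),
                   gc3 = gc3, preferred = preferred,
                   n_codons = length(usable))
  class(list_out) <- "codon_usage"
  list_out
}

#' @export
print.codon_usage <- function(x, ...) {
  cat("<codon_usage> ", x$n_codons, " codons, GC = ",
      round(x$gc, 4), ", GC3 = ", round(x$gc3, 4), "\n", sep = "")
  invisible(x)
}

aln_rows <- function(alignment, target, reference) {
  if (!target %in% names(alignment)) stop("target '", target,
                                          "' absent from alignment")
  if (!reference %in% names(alignment)) stop("reference '", reference,
                                             "' absent from alignment")
  t <- strsplit(toupper(alignment[[target]]), "")[[1L]]
  r <- strsplit(toupper(alignment[[reference]]), "")[[1L]]
  if (length(t) != length(r)) stop("alignment rows differ in length")
  list(t = t, r = r)
}

#' Indel frequency relative to a reference
#'
#' Counts alignment columns where exactly one of target/reference is gapped
#' (indel bases, the base-wise definition: mutated bases over total plastome
#' bases), divided by `total_len`.  An event-wise count (number of contiguous
#' gap runs) is also returned for diagnostics.
#'
#' @param alignment named character vector of aligned sequences (gaps "-").
#' @param target,reference row names.
#' @param total_len denominator: total plastome length of the target.
#' @return list: `indel_bases`, `indel_events`, `frequency`,
#'   `frequency_class` (bases over the target's ungapped length in this
#'   alignment).
#' @export
indel_frequency <- function(alignment, target, reference, total_len) {
  rows <- aln_rows(alignment, target, reference)
  gap_t <- rows$t == "-"
  gap_r <- rows$r == "-"
  ind <- xor(gap_t, gap_r)
  events <- sum(rle(ind)$values)
  class_len <- sum(!gap_t)
  list(indel_bases = sum(ind), indel_events = events,
       frequency = sum(ind) / total_len,
       frequency_class = if (class_len) sum(ind) / class_len else NA_real_)
}

#' SNV frequency relative to a reference
#'
#' Counts aligned columns where target and reference both carry unambiguous
#' bases and they differ, divided by `total_len`.
#'
#' @inheritParams indel_frequency
#' @return list: `snv_sites`, `frequency`, `frequency_class`.
#' @export
snv_frequency <- function(alignment, target, reference, total_len) {
  rows <- aln_rows(alignment, target, reference)
  base <- c("A", "C", "G", "T")
  both <- rows$t %in% base & rows$r %in% base
  snv <- sum(both & rows$t != rows$r)
  class_len <- sum(rows$t != "-")
  list(snv_sites = snv, frequency = snv / total_len,
       frequency_class = if (class_len) snv / class_len else NA_real_)
}

#' Per-class variation statistics for one taxon
#'
#' Convenience wrapper running [indel_frequency()] and [snv_frequency()] on
#' each sequence-class alignment (protein-coding, rRNA, intergenic).
#'
#' @param class_alignments named list of alignments (each a named character
#'   vector including `target` and `reference` rows).
#' @param target,reference row names.
#' @param total_len total plastome length of the target (shared denominator).
#' @return data.frame (class, indel_bases, indel_freq, snv_sites, snv_freq,
#'   indel_freq_class, snv_freq_class).
#' @export
class_variation_stats <- function(class_alignments, target, reference,
                                  total_len) {
  res <- lapply(names(class_alignments), function(cl) {
    a <- class_alignments[[cl]]
    iv <- indel_frequency(a, target, reference, total_len)
    sv <- snv_frequency(a, target, reference, total_len)
    data.frame(class = cl, indel_bases = iv$indel_bases,
               indel_freq = iv$frequency, snv_sites = sv$snv_sites,
               snv_freq = sv$frequency,
               indel_freq_class = iv$frequency_class,
               snv_freq_class = sv$frequency_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Extract sequence classes from an annotated record
#'
#' Splits a plastome into protein-coding (CDS), rRNA and intergenic
#' sequences from its annotations; classes are disjoint by construction.
#'
#' @param record a `genome_record`.
#' @return list with `protein_coding`, `rRNA` (named character vectors of
#'   gene sequences, minus-strand genes reverse-complemented), `intergenic`
#'   (unnamed character vector), and `total_len`.
#' @export
sequence_classes <- function(record) {
  f <- record$features
  s <- record$sequence
  get_seq <- function(row) {
    x <- substr0(s, f$start[row], f$end[row])
    if (f$strand[row] == "-") revcomp(x) else x
  }
  cds_rows <- which(f$kind == "CDS" & !f$pseudo)
  rrn_rows <- which(f$kind == "rRNA")
  pc <- stats::setNames(vapply(cds_rows, get_seq, ""), f$locus[cds_rows])
  rr <- stats::setNames(vapply(rrn_rows, get_seq, ""), f$locus[rrn_rows])
  # intergenic: complement of all annotated spans
  cov <- rep(FALSE, nchar(s))
  for (row in seq_len(nrow(f))) {
    if (f$end[row] > f$start[row])
      cov[(f$start[row] + 1L):f$end[row]] <- TRUE
  }
  runs <- rle(!cov)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ig <- character(0)
  for (ri in which(runs$values)) {
    ig <- c(ig, substr(s, starts[ri], ends[ri]))
  }
  list(protein_coding = pc, rRNA = rr, intergenic = ig,
       total_len = nchar(s))
}
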