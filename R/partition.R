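# Quadripartite partitioning: locate the two large exact reverse-complement
# duplications (IR_A / IR_B) on the circle, label the longer gap LSC and the
# shorter SSC, collapse one IR copy for downstream single-copy analyses, and
# classify which copy an IR-lacking plastome has lost relative to a
# reference with both.

#' Partition a plastome into LSC / SSC / IR_A / IR_B
#'
#' Finds the longest pair of exact reverse-complement repeats of at least
#' `min_ir_len` bp on the (circularized) sequence.  If such a pair exists the
#' two repeat copies are labelled IR_A (the copy following the longer
#' single-copy gap, i.e. LSC) and IR_B, and the gaps LSC (longer) and SSC
#' (shorter).  When rRNA features are annotated, a candidate IR must contain
#' the rRNA core; between equally long candidates the one containing rRNA
#' genes wins (with a warning about the ambiguity).
#'
#' @param record a `genome_record`.
#' @param min_ir_len minimum length (bp) for a canonical IR; default 1000.
#' @return list with 0-based half-open intervals `lsc`, `ssc`, `ir_a`,
#'   `ir_b` and `ir_status` ("both" or "none").
#' @export
partition_regions <- function(record, min_ir_len = 1000L) {
  stopifnot(inherits(record, "genome_record"))
  if (min_ir_len < 100L) stop("min_ir_len must be >= 100")
  s <- record$sequence
  L <- nchar(s)
  pairs <- maximal_repeat_pairs(s, min_len = min_ir_len,
                                circular = record$circular)
  inv <- pairs[pairs$strand2 == "-", , drop = FALSE]
  # copies must not overlap (a fold-back palindrome is not an IR pair)
  if (nrow(inv)) {
    keep <- inv$start2 >= inv$end1 | inv$end2 <= inv$start1
    inv <- inv[keep, , drop = FALSE]
  }
  if (!nrow(inv))
    return(list(lsc = c(0L, L), ssc = NULL, ir_a = NULL, ir_b = NULL,
                ir_status = "none"))
  inv <- inv[order(-inv$len), , drop = FALSE]
  best_len <- inv$len[1L]
  cand <- inv[inv$len == best_len, , drop = FALSE]
  pick <- 1L
  rr <- record$features[record$features$kind == "rRNA", , drop = FALSE]
  if (nrow(cand) > 1L) {
    warning("ambiguous partition: multiple IR candidates of equal length; ",
            "choosing the one containing the rRNA core")
    if (nrow(rr)) {
      contains <- vapply(seq_len(nrow(cand)), function(i) {
        any(rr$start >= cand$start1[i] & rr$end <= cand$end1[i]) ||
          any(rr$start >= cand$start2[i] & rr$end <= cand$end2[i])
      }, logical(1L))
      if (any(contains)) pick <- which(contains)[1L]
    }
  } else if (nrow(rr)) {
    contains <- any(rr$start >= cand$start1[1L] & rr$end <= cand$end1[1L]) ||
      any(rr$start >= cand$start2[1L] & rr$end <= cand$end2[1L])
    if (!contains)
      warning("longest inverted duplication does not contain the rRNA core")
  }
  irx <- c(cand$start1[pick], cand$end1[pick])
  iry <- c(cand$start2[pick], cand$end2[pick])
  if (irx[1L] > iry[1L]) { tmp <- irx; irx <- iry; iry <- tmp }
  # gaps between the two copies (linear coordinates; gap2 wraps the origin)
  gap1 <- c(irx[2L], iry[1L])
  gap2_len <- L - iry[2L] + irx[1L]
  gap1_len <- gap1[2L] - gap1[1L]
  if (gap2_len >= gap1_len) {
    # wrap-around gap is the LSC; first copy in linear order is IR_A
    lsc <- c(iry[2L] %% L, irx[1L])   # may wrap; keep as (start, end) pair
    ssc <- gap1
    ir_a <- irx
    ir_b <- iry
  } else {
    lsc <- gap1
    ssc <- c(iry[2L] %% L, irx[1L])
    ir_a <- iry
    ir_b <- irx
  }
  list(lsc = lsc, ssc = ssc, ir_a = ir_a, ir_b = ir_b, ir_status = "both")
}

#' Collapse one inverted-repeat copy
#'
#' Removes IR_B (the copy following the SSC in LSC, IR_A, SSC, IR_B order) so
#' that repeat and rearrangement statistics are not inflated by the duplicated
#' region; feature coordinates are remapped and features inside IR_B dropped.
#' Records whose `ir_status` is not "both" are returned unchanged with a
#' warning.  Idempotent.
#'
#' @param record a `genome_record` whose `partition` has `ir_status = "both"`
#'   (the partition is computed on the fly when absent).
#' @param min_ir_len passed to [partition_regions()] when needed.
#' @return a `genome_record` without IR_B.
#' @export
collapse_ir <- function(record, min_ir_len = 1000L) {
  stopifnot(inherits(record, "genome_record"))
  part <- record$partition
  if (is.null(part)) part <- partition_regions(record, min_ir_len)
  if (!identical(part$ir_status, "both")) {
    warning("record ", record$id, " has ir_status=", part$ir_status,
            "; returned unchanged")
    record$partition <- part
    return(record)
  }
  b <- part$ir_b
  cut_len <- b[2L] - b[1L]
  s <- record$sequence
  newseq <- paste0(substr0(s, 0L, b[1L]), substr0(s, b[2L], nchar(s)))
  f <- record$features
  inside <- f$start >= b[1L] & f$end <= b[2L]
  straddle <- !inside & f$start < b[2L] & f$end > b[1L]
  if (any(straddle))
    warning("dropping ", sum(straddle), " feature part(s) straddling the IR_B boundary")
  f <- f[!(inside | straddle), , drop = FALSE]
  shift <- f$start >= b[2L]
  f$start[shift] <- f$start[shift] - cut_len
  f$end[f$end > b[1L]] <- f$end[f$end > b[1L]] - cut_len
  shift_iv <- function(iv) {
    if (is.null(iv)) return(NULL)
    iv - ifelse(iv >= b[2L], cut_len, 0L)
  }
  newpart <- list(lsc = shift_iv(part$lsc), ssc = shift_iv(part$ssc),
                  ir_a = shift_iv(part$ir_a), ir_b = NULL,
                  ir_status = "B_lost")
  out <- genome_record(record$id, newseq, f, circular = record$circular,
                       partition = newpart)
  attr(out, "collapsed_ir") <- TRUE
  out
}

#' Classify which IR copy an IR-lacking plastome has lost
#'
#' Relative to a reference record with both IRs, decides whether the target's
#' remaining IR block sits in the IR_A slot (between LSC and SSC genes,
#' meaning IR_B was lost) or in the IR_B slot (after the SSC genes, meaning
#' IR_A was lost), based on the position of the rRNA core within the shared
#' gene order.
#'
#' @param record IR-lacking `genome_record` (ir_status "none" after
#'   [partition_regions()], but still carrying one copy of the original IR
#'   genes).
#' @param reference `genome_record` with canonical IRs (its partition is
#'   computed if absent).
#' @param min_ir_len threshold for the reference partition.
#' @return one of "A_lost", "B_lost", "both", "none".
#' @export
classify_ir_loss <- function(record, reference, min_ir_len = 1000L) {
  own <- partition_regions(record, min_ir_len)
  if (identical(own$ir_status, "both")) return("both")
  refpart <- reference$partition
  if (is.null(refpart)) refpart <- partition_regions(reference, min_ir_len)
  if (!identical(refpart$ir_status, "both"))
    stop("reference record must have both IRs")
  rf <- reference$features
  in_iv <- function(pos, iv) pos >= iv[1L] & pos < iv[2L]
  lsc_genes <- canonical_locus(rf$locus[in_iv(rf$start, refpart$lsc)])
  ssc_genes <- canonical_locus(rf$locus[in_iv(rf$start, refpart$ssc)])
  ira_genes <- canonical_locus(rf$locus[in_iv(rf$start, refpart$ir_a)])
  tf <- record$features
  tloc <- canonical_locus(tf$locus)
  core <- tf$start[tloc %in% ira_genes & tf$kind == "rRNA"]
  if (!length(core)) core <- tf$start[tloc %in% ira_genes]
  if (!length(core)) return("none")
  core_mid <- stats::median(core)
  lsc_pos <- tf$start[tloc %in% setdiff(lsc_genes, ssc_genes)]
  ssc_pos <- tf$start[tloc %in% setdiff(ssc_genes, lsc_genes)]
  if (!length(lsc_pos) || !length(ssc_pos)) return("none")
  # order along the linearized circle: LSC .. [IR slot] .. SSC .. [IR slot]
  if (stats::median(lsc_pos) < stats::median(ssc_pos)) {
    if (core_mid > stats::median(lsc_pos) && core_mid < stats::median(ssc_pos))
      "B_lost" else "A_lost"
  } else {
    if (core_mid > stats::median(ssc_pos) && core_mid < stats::median(lsc_pos))
      "A_lost" else "B_lost"
  }
}

#' Shared single-copy gene order across records
#'
#' Restricts to loci annotated exactly once in every record (multi-copy loci
#' are excluded with a warning), orders them by start coordinate, and signs
#' each locus "+" when its strand matches the reference copy and "-"
#' otherwise.  Records should have their IRs collapsed first.
#'
#' @param records named list of `genome_record` (names = record ids).
#' @param reference_id id of the reference record.
#' @return named list (per record) of signed locus vectors; a locus on the
#'   opposite strand from the reference carries a "-" prefix.
#' @export
shared_locus_order <- function(records, reference_id) {
  if (is.null(names(records)))
    names(records) <- vapply(records, `[[`, "", "id")
  if (!reference_id %in% names(records))
    stop("reference record '", reference_id, "' not among records")
  loctabs <- lapply(records, function(r) {
    f <- r$features[!duplicated(r$features$feature_id), , drop = FALSE]
    f$canon <- canonical_locus(f$locus)
    f
  })
  per_rec <- lapply(loctabs, function(f) table(f$canon))
  shared <- Reduce(intersect, lapply(per_rec, names))
  multi <- unique(unlist(lapply(per_rec, function(tb)
    names(tb)[tb > 1L])))
  multi <- intersect(multi, shared)
  if (length(multi))
    warning("excluding multi-copy loci: ", paste(multi, collapse = ", "))
  shared <- setdiff(shared, multi)
  if (length(shared) < 3L)
    stop("insufficient shared loci (", length(shared), " < 3)")
  ref <- loctabs[[reference_id]]
  ref <- ref[ref$canon %in% shared, , drop = FALSE]
  ref_strand <- stats::setNames(ref$strand, ref$canon)
  lapply(loctabs, function(f) {
    f <- f[f$canon %in% shared, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    sign <- ifelse(f$strand == ref_strand[f$canon], "", "-")
    paste0(sign, f$canon)
  })
}
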