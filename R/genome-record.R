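# The annotated-plastome container used throughout the package: a circular
# DNA sequence plus a feature table in 0-based half-open coordinates, and an
# optional quadripartite partition (LSC / SSC / IR_A / IR_B).

#' Construct an annotated plastome record
#'
#' @param id record identifier.
#' @param sequence circular DNA string over A/C/G/T/N.
#' @param features data frame with columns `locus`, `kind` (one of CDS, tRNA,
#'   rRNA, other), `strand` ("+"/"-"), `start`, `end` (0-based half-open),
#'   `pseudo` (logical); optional `feature_id` groups the parts of a
#'   multi-interval (join) feature.
#' @param circular is the molecule circular (plastomes are).
#' @param partition optional region partition, see [partition_regions()].
#' @return object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, features = NULL, circular = TRUE,
                          partition = NULL) {
  sequence <- check_dna(sequence)
  if (nchar(sequence) == 0L) stop("input error: zero-length sequence")
  if (is.null(features)) {
    features <- data.frame(locus = character(), kind = character(),
                           strand = character(), start = integer(),
                           end = integer(), pseudo = logical(),
                           feature_id = integer(),
                           stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(features$pseudo)) features$pseudo <- FALSE
  if (is.null(features$feature_id) || !nrow(features))
    features$feature_id <- seq_len(nrow(features))
  stopifnot(all(c("locus", "kind", "strand", "start", "end") %in%
                  names(features)))
  if (nrow(features)) {
    if (any(!nzchar(features$locus))) stop("locus_name must be nonempty")
    if (any(features$end <= features$start))
      stop("feature span must have length >= 1")
    if (any(features$end > nchar(sequence)))
      stop("feature span exceeds sequence length")
    if (any(!features$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = id, sequence = sequence, features = features,
                 circular = circular, partition = partition),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$id, ": ", nchar(x$sequence), " bp, ",
      nrow(x$features), " features",
      if (x$circular) ", circular" else ", linear", "\n", sep = "")
  if (!is.null(x$partition)) {
    p <- x$partition
    cat("  partition [ir_status=", p$ir_status, "]", sep = "")
    for (r in c("lsc", "ir_a", "ssc", "ir_b")) {
      if (!is.null(p[[r]]))
        cat(" ", r, "=", p[[r]][1], "-", p[[r]][2], sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Census of annotated genes
#'
#' Counts distinct features by kind and reports the per-locus table, the
#' style used when summarizing gene content across plastomes (e.g. number of
#' protein-coding genes).
#'
#' @param record a `genome_record`.
#' @return list with `counts` (named vector by kind, distinct feature count)
#'   and `table` (one row per feature part: record_id, locus, kind, strand,
#'   start, end, pseudo).
#' @export
gene_census <- function(record) {
  stopifnot(inherits(record, "genome_record"))
  f <- record$features
  first <- f[!duplicated(f$feature_id), , drop = FALSE]
  counts <- table(factor(first$kind, levels = c("CDS", "tRNA", "rRNA", "other")))
  tab <- data.frame(record_id = record$id, locus = f$locus, kind = f$kind,
                    strand = f$strand, start = f$start, end = f$end,
                    pseudo = f$pseudo, stringsAsFactors = FALSE)
  list(counts = c(counts), table = tab)
}

#' Write the gene census as TSV
#'
#' @param records list of `genome_record`.
#' @param path output TSV path.
#' @return invisibly, the combined table.
#' @export
write_gene_census <- function(records, path) {
  tabs <- do.call(rbind, lapply(records, function(r) gene_census(r)$table))
  utils::write.table(tabs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tabs)
}

# canonical gene symbols: case-insensitive, with a small synonym table;
# unmatched symbols pass through verbatim (lowercased)
canonical_locus <- function(x) {
  syn <- c("rrn16s" = "rrn16", "rrn23s" = "rrn23", "rrn5s" = "rrn5",
           "rrn4.5s" = "rrn4.5", "16s rrna" = "rrn16", "23s rrna" = "rrn23",
           "infa" = "infA")
  lx <- tolower(x)
  hit <- match(lx, names(syn))
  out <- ifelse(is.na(hit), lx, syn[pmax(hit, 1L)])
  unname(out)
}
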