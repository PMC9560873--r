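# Minimal GenBank flat-file reader/writer for annotated plastomes.  GenBank
# coordinates are 1-based inclusive; internally everything is 0-based
# half-open, so s..e maps to [s-1, e).  join()/order() locations become
# multi-interval features sharing one feature_id; complement() sets the
# strand.  Only the feature keys CDS, tRNA and rRNA are retained as typed
# features ('gene' keys duplicate them and are skipped; anything else is
# kept with kind "other").

GB_KINDS <- c("CDS", "tRNA", "rRNA")

#' Read a GenBank flat file
#'
#' @param path path to a GenBank flat file containing a single record.
#' @return a [genome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1L]))
    stop("parse error at line 1: expected LOCUS header")
  locus <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  id <- locus[2L]
  circular <- any(tolower(locus) == "circular")

  ofs <- grep("^ORIGIN", lines)
  if (!length(ofs)) stop("parse error: no ORIGIN block")
  ofs <- ofs[1L]
  seq_lines <- lines[(ofs + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("input error: zero-length sequence")

  ffs <- grep("^FEATURES", lines)
  feats <- list()
  if (length(ffs)) {
    block <- lines[(ffs[1L] + 1L):(ofs - 1L)]
    # feature starts: exactly 5 leading spaces then a key
    starts <- grep("^ {5}\\S", block)
    for (si in seq_along(starts)) {
      from <- starts[si]
      to <- if (si < length(starts)) starts[si + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^ {5}(\\S+).*", "\\1", chunk[1L])
      if (key %in% c("source", "gene")) next
      # location may continue over lines until the first qualifier
      qual_at <- grep("^ +/", chunk)
      loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(chunk)
      loc <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", chunk[1L]),
                            if (loc_end >= 2L) chunk[2:loc_end] else NULL)),
                   collapse = "")
      parsed <- tryCatch(parse_gb_location(loc), error = function(e)
        stop("parse error near line ", ffs[1L] + from,
             ": bad location '", loc, "'"))
      quals <- paste(chunk[seq_along(chunk) >= loc_end + 1L], collapse = "\n")
      locus_name <- gb_qualifier(quals, "gene")
      if (is.na(locus_name)) locus_name <- gb_qualifier(quals, "locus_tag")
      if (is.na(locus_name)) locus_name <- gb_qualifier(quals, "product")
      if (is.na(locus_name)) locus_name <- key
      pseudo <- grepl("/pseudo(\\s|$|\n)", paste0(quals, "\n"))
      kind <- if (key %in% GB_KINDS) key else "other"
      feats[[length(feats) + 1L]] <- data.frame(
        locus = locus_name, kind = kind,
        strand = if (parsed$complement) "-" else "+",
        start = parsed$ivs[, 1L] - 1L, end = parsed$ivs[, 2L],
        pseudo = pseudo, feature_id = length(feats) + 1L,
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  genome_record(id = id, sequence = sequence, features = features,
                circular = circular)
}

parse_gb_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  complement <- FALSE
  if (grepl("^complement\\(", loc)) {
    complement <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  ivs <- t(vapply(parts, function(p) {
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    } else if (grepl("^\\d+$", p)) {
      rep(as.integer(p), 2L)
    } else stop("bad span: ", p)
  }, integer(2L)))
  if (any(ivs[, 2L] < ivs[, 1L])) stop("reversed span")
  list(ivs = ivs, complement = complement)
}

gb_qualifier <- function(quals, name) {
  m <- regmatches(quals, regexec(paste0('/', name, '="([^"]*)"'), quals))[[1L]]
  if (length(m) == 2L) m[2L] else NA_character_
}

#' Write a GenBank flat file
#'
#' Inverse of [read_genbank()] for records the package produces; internal
#' 0-based half-open spans are written back as 1-based inclusive.
#'
#' @param record a `genome_record`.
#' @param path output path.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "genome_record"))
  seqlen <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN",
                     record$id, seqlen,
                     if (record$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s plastome.", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", seqlen), con)
  f <- record$features
  if (nrow(f)) {
    for (fid in unique(f$feature_id)) {
      parts <- f[f$feature_id == fid, , drop = FALSE]
      spans <- sprintf("%d..%d", parts$start + 1L, parts$end)
      loc <- if (length(spans) > 1L)
        sprintf("join(%s)", paste(spans, collapse = ",")) else spans
      if (parts$strand[1L] == "-") loc <- sprintf("complement(%s)", loc)
      kind <- parts$kind[1L]
      key <- if (kind %in% GB_KINDS) kind else "misc_feature"
      writeLines(sprintf("     %-16s%s", key, loc), con)
      writeLines(sprintf('                     /gene="%s"', parts$locus[1L]), con)
      if (isTRUE(parts$pseudo[1L]))
        writeLines("                     /pseudo", con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, seqlen, by = 60L)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59L, seqlen))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tolower(tens), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  # aligned sequences may carry '-' gaps (part of the DNA alphabet)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
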