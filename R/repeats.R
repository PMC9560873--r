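# Exact repeat detection.  Dispersed repeats are maximal exact repeated
# substrings (direct or reverse-complement) of at least `min_len` bp found by
# seeding shared k-mers and collapsing them along diagonals: if the k-mer at
# i matches the k-mer at i+d for every i in a..b and for neither a-1 nor b+1,
# then seq[a, b+k) is a maximal match at offset d.  Only exact matching is
# supported (the mismatch-free setting used for plastome repeat censuses).

# All maximal exact matching pairs of length >= min_len.
# Returns 0-based half-open copies; strand2 is "-" for reverse-complement
# matches.  seed_len caps the k-mer length so that large min_len (IR
# detection) stays cheap.
maximal_repeat_pairs <- function(seq, min_len, circular = FALSE,
                                 seed_len = min(min_len, 31L)) {
  seq <- toupper(seq)
  L <- nchar(seq)
  k <- as.integer(seed_len)
  empty <- data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      strand2 = character(), len = integer(),
                      stringsAsFactors = FALSE)
  if (L < 2L * k) return(empty)
  scan <- if (circular) paste0(seq, substr(seq, 1L, k - 1L)) else seq
  Ls <- nchar(scan)

  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    km <- substring(s, 1:(n - k + 1L), k:n)
    km[grepl("N", km, fixed = TRUE)] <- NA_character_
    km
  }
  run_collapse <- function(ii, jj) {
    # maximal runs of simultaneous +1 steps in both coordinates
    o <- order(jj - ii, ii)
    ii <- ii[o]; jj <- jj[o]
    d <- jj - ii
    brk <- c(TRUE, !(d[-1L] == d[-length(d)] & ii[-1L] == ii[-length(ii)] + 1L))
    gid <- cumsum(brk)
    a <- tapply(ii, gid, min)
    b <- tapply(ii, gid, max)
    j0 <- tapply(jj, gid, min)
    data.frame(i = as.integer(a), j = as.integer(j0),
               len = as.integer(b - a + k))
  }

  km1 <- kmers_of(scan)
  out <- list()

  # direct repeats: duplicate k-mers within the sequence
  dup <- !is.na(km1) & (duplicated(km1) | duplicated(km1, fromLast = TRUE))
  if (any(dup)) {
    pos <- which(dup)
    grp <- split(pos, km1[dup])
    cmb <- do.call(cbind, lapply(grp, function(g)
      if (length(g) > 1L) utils::combn(g, 2L) else NULL))
    ii <- cmb[1L, ]; jj <- cmb[2L, ]
    if (length(ii)) {
      runs <- run_collapse(ii, jj)
      runs <- runs[runs$len >= min_len, , drop = FALSE]
      if (nrow(runs))
        out[[length(out) + 1L]] <- data.frame(
          start1 = runs$i - 1L, end1 = runs$i - 1L + runs$len,
          start2 = runs$j - 1L, end2 = runs$j - 1L + runs$len,
          strand2 = "+", len = runs$len, stringsAsFactors = FALSE)
    }
  }

  # inverted repeats: k-mers shared between the sequence and its
  # reverse complement
  rc <- revcomp(scan)
  km2 <- kmers_of(rc)
  common <- intersect(km1[!is.na(km1)], km2[!is.na(km2)])
  if (length(common)) {
    in1 <- km1 %in% common
    in2 <- km2 %in% common
    p1 <- split(which(in1), km1[in1])
    p2 <- split(which(in2), km2[in2])
    p2 <- p2[names(p1)]
    ii <- unlist(Map(function(a, b) rep(a, each = length(b)), p1, p2),
                 use.names = FALSE)
    jj <- unlist(Map(function(a, b) rep(b, times = length(a)), p1, p2),
                 use.names = FALSE)
    if (length(ii)) {
      runs <- run_collapse(ii, jj)
      runs <- runs[runs$len >= min_len, , drop = FALSE]
      if (nrow(runs)) {
        # map reverse-complement coordinates back to the forward strand
        s2 <- Ls - (runs$j - 1L) - runs$len
        inv <- data.frame(start1 = runs$i - 1L, end1 = runs$i - 1L + runs$len,
                          start2 = s2, end2 = s2 + runs$len,
                          strand2 = "-", len = runs$len,
                          stringsAsFactors = FALSE)
        # each pair is found twice (seq vs rc is symmetric): canonicalize
        swap <- inv$start1 > inv$start2
        tmp <- inv[swap, c("start2", "end2")]
        inv[swap, c("start2", "end2")] <- inv[swap, c("start1", "end1")]
        inv[swap, c("start1", "end1")] <- tmp
        inv <- inv[!duplicated(inv[, c("start1", "start2", "len")]), ,
                   drop = FALSE]
        # a perfect palindrome matches itself: drop identical copies
        inv <- inv[!(inv$start1 == inv$start2), , drop = FALSE]
        if (nrow(inv)) out[[length(out) + 1L]] <- inv
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  if (circular) {
    # copies found once thanks to the wrap pad; reduce starts modulo L
    res <- res[res$start1 < L & res$start2 < L, , drop = FALSE]
    res <- res[!duplicated(res[, c("start1", "start2", "len", "strand2")]), ,
               drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Find dispersed repeats (exact, both strands)
#'
#' Reports all maximal exact repeated substrings of at least `min_len` bp
#' occurring at least twice, on either strand, grouped into families that
#' share the same sequence.  Copies of one pair may overlap only if the
#' overlap is shorter than half the repeat length (larger overlaps are
#' tandem structures, the jurisdiction of [find_ssrs()]).
#'
#' @param seq DNA string.
#' @param min_len minimum repeat length (bp); default 30.
#' @param max_mismatch only 0 (exact matching) is supported.
#' @param circular scan with a wrap-around pad so origin-spanning repeats are
#'   found once.
#' @return object of class `dispersed_repeats`: list with `families`
#'   (family_id, length, orientation, frequency, seq) and `copies`
#'   (family_id, start, end, strand; 0-based half-open).
#' @export
find_dispersed_repeats <- function(seq, min_len = 30L, max_mismatch = 0,
                                   circular = FALSE) {
  if (max_mismatch != 0)
    stop("unsupported: only exact matching (max_mismatch = 0) is implemented")
  seq <- toupper(seq)
  if (nchar(seq) < 2L * min_len)
    stop("sequence shorter than 2 * min_len")
  pairs <- maximal_repeat_pairs(seq, min_len, circular = circular)
  # overlap rule: drop pairs whose copies overlap by >= len/2
  if (nrow(pairs)) {
    ov <- pmin(pairs$end1, pairs$end2) - pmax(pairs$start1, pairs$start2)
    pairs <- pairs[ov < pairs$len / 2, , drop = FALSE]
  }
  fam_empty <- list(
    families = data.frame(family_id = integer(), length = integer(),
                          orientation = character(), frequency = integer(),
                          seq = character(), stringsAsFactors = FALSE),
    copies = data.frame(family_id = integer(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE))
  if (!nrow(pairs)) return(structure(fam_empty, class = "dispersed_repeats"))

  padded <- paste0(seq, if (circular) substr(seq, 1L, min_len) else "")
  sub_of <- function(s0, e0) substr(padded, s0 + 1L, e0)
  copies <- list()
  for (r in seq_len(nrow(pairs))) {
    s1 <- sub_of(pairs$start1[r], pairs$end1[r])
    s2 <- if (pairs$strand2[r] == "+") s1 else revcomp(s1)
    key <- min(s1, revcomp(s1))
    copies[[2L * r - 1L]] <- data.frame(key = key, start = pairs$start1[r],
                                        end = pairs$end1[r],
                                        strand = if (s1 == key) "+" else "-",
                                        stringsAsFactors = FALSE)
    copies[[2L * r]] <- data.frame(key = key, start = pairs$start2[r],
                                   end = pairs$end2[r],
                                   strand = if (s2 == key) "+" else "-",
                                   stringsAsFactors = FALSE)
  }
  cp <- do.call(rbind, copies)
  cp <- cp[!duplicated(cp[, c("key", "start", "strand")]), , drop = FALSE]
  keys <- sort(unique(cp$key))
  fam <- data.frame(family_id = seq_along(keys), seq = keys,
                    stringsAsFactors = FALSE)
  fam$length <- nchar(fam$seq)
  cp$family_id <- match(cp$key, keys)
  cp <- cp[order(cp$family_id, cp$start), c("family_id", "start", "end",
                                            "strand")]
  rownames(cp) <- NULL
  np <- tapply(cp$strand == "+", cp$family_id, sum)
  nm <- tapply(cp$strand == "-", cp$family_id, sum)
  fam$frequency <- as.integer(np + nm)
  fam$orientation <- ifelse(np == 0L | nm == 0L, "direct",
                            ifelse(fam$frequency == 2L, "inverted", "mixed"))
  fam <- fam[, c("family_id", "length", "orientation", "frequency", "seq")]
  rownames(fam) <- NULL
  structure(list(families = fam, copies = cp), class = "dispersed_repeats")
}

#' @export
print.dispersed_repeats <- function(x, ...) {
  cat("<dispersed_repeats> ", nrow(x$families), " families, ",
      nrow(x$copies), " copies\n", sep = "")
  invisible(x)
}

#' Remove redundant nested repeat families
#'
#' A family S is contained in a longer family F when every copy of S lies
#' within some copy of F.  Two filters are applied in order: (1) a containing
#' family at most 10 bp longer than its contained family is dropped (the
#' shorter representative is kept); (2) among the survivors, a contained
#' family is dropped when the containing family occurs at least three times.
#'
#' @param x a `dispersed_repeats` object.
#' @return filtered `dispersed_repeats`.
#' @export
filter_redundant_repeats <- function(x) {
  stopifnot(inherits(x, "dispersed_repeats"))
  fam <- x$families
  cp <- x$copies
  if (nrow(fam) < 2L) return(x)
  contained_in <- function(sid, fid) {
    sc <- cp[cp$family_id == sid, , drop = FALSE]
    fc <- cp[cp$family_id == fid, , drop = FALSE]
    all(vapply(seq_len(nrow(sc)), function(i)
      any(sc$start[i] >= fc$start & sc$end[i] <= fc$end), logical(1L)))
  }
  ids <- fam$family_id
  len <- stats::setNames(fam$length, ids)
  freq <- stats::setNames(fam$frequency, ids)
  pairs <- expand.grid(s = ids, f = ids)
  pairs <- pairs[len[as.character(pairs$f)] > len[as.character(pairs$s)], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    cont <- vapply(seq_len(nrow(pairs)), function(i)
      contained_in(pairs$s[i], pairs$f[i]), logical(1L))
    pairs <- pairs[cont, , drop = FALSE]
  }
  drop1 <- unique(pairs$f[len[as.character(pairs$f)] -
                            len[as.character(pairs$s)] <= 10L])
  keep <- setdiff(ids, drop1)
  p2 <- pairs[pairs$f %in% keep & pairs$s %in% keep, , drop = FALSE]
  drop2 <- unique(p2$s[freq[as.character(p2$f)] >= 3L])
  keep <- setdiff(keep, drop2)
  structure(list(families = fam[fam$family_id %in% keep, , drop = FALSE],
                 copies = cp[cp$family_id %in% keep, , drop = FALSE]),
            class = "dispersed_repeats")
}

#' Find simple sequence repeats (microsatellites)
#'
#' Maximal perfect tandem runs of 1-6 bp motifs meeting the per-unit-size
#' minimum repeat counts (defaults: mono >= 10, di >= 6, tri/tetra/penta/hexa
#' >= 5 units).  Motifs must be primitive (an AA motif inside a mononucleotide
#' run is not reported twice).  SSRs separated by at most `max_interrupt` bp
#' are flagged as components of one compound locus.
#'
#' @param seq DNA string.
#' @param min_units integer vector of length 6: minimum unit counts for unit
#'   sizes 1..6.
#' @param max_interrupt maximum gap (bp) joining two SSRs into a compound
#'   locus; default 100.
#' @return data.frame (motif, unit_size, n_units, start, end, compound,
#'   compound_id); coordinates 0-based half-open covering the complete units.
#' @export
find_ssrs <- function(seq, min_units = c(10L, 6L, 5L, 5L, 5L, 5L),
                      max_interrupt = 100L) {
  stopifnot(length(min_units) == 6L)
  seq <- toupper(seq)
  b <- seq_bytes(seq)
  L <- length(b)
  valid <- b %in% c(65L, 67L, 71L, 84L)
  res <- list()
  for (u in 1:6) {
    if (L < u * 2L) next
    eq <- b[seq_len(L - u)] == b[(u + 1L):L] &
      valid[seq_len(L - u)] & valid[(u + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths + u >= u * min_units[u])
    for (h in hit) {
      i0 <- starts[h]                      # 1-based position of first base
      tract <- r$lengths[h] + u
      n <- tract %/% u
      if (n < min_units[u]) next
      motif <- substr(seq, i0, i0 + u - 1L)
      if (!is_primitive_motif(motif)) next
      res[[length(res) + 1L]] <- data.frame(
        motif = motif, unit_size = u, n_units = n,
        start = i0 - 1L, end = i0 - 1L + n * u, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(motif = character(), unit_size = integer(),
                      n_units = integer(), start = integer(), end = integer(),
                      compound = logical(), compound_id = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  gap_new <- c(TRUE, out$start[-1L] - out$end[-nrow(out)] > max_interrupt)
  out$compound_id <- cumsum(gap_new)
  sizes <- table(out$compound_id)
  out$compound <- sizes[as.character(out$compound_id)] > 1L
  out[, c("motif", "unit_size", "n_units", "start", "end", "compound",
          "compound_id")]
}

is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        strrep(substr(motif, 1L, d), u %/% d) == motif)
      return(FALSE)
  }
  TRUE
}

#' Count tandem-repeat loci
#'
#' The tandem-repeat-number trait: compound loci count as the number of their
#' component SSRs (the convention recorded in the output metadata of
#' [find_ssrs()]).
#'
#' @param ssrs output of [find_ssrs()].
#' @return integer count.
#' @export
tandem_repeat_count <- function(ssrs) nrow(ssrs)

#' Associate dispersed repeats with inversion endpoints
#'
#' A repeat family hits an inversion when any copy overlaps, or lies within
#' `window` bp of, either endpoint breakpoint.  Per inversion, the longest
#' associated repeat length is also reported (censuses list one to a few
#' repeat lengths per inversion).
#'
#' @param repeats a `dispersed_repeats` object (same coordinate frame as the
#'   inversions).
#' @param inversions data.frame with breakpoint columns `start_bp`, `end_bp`.
#' @param window association window in bp (default 500).
#' @return list with `hits` (inversion, family_id, dist_start, dist_end) and
#'   `per_inversion` (inversion, n_families, longest_repeat).
#' @export
associate_repeats_with_inversions <- function(repeats, inversions,
                                              window = 500L) {
  stopifnot(inherits(repeats, "dispersed_repeats"))
  inv <- as.data.frame(inversions)
  stopifnot(all(c("start_bp", "end_bp") %in% names(inv)))
  cp <- repeats$copies
  fam <- repeats$families
  hits <- list()
  bp_dist <- function(s, e, b) ifelse(b >= s & b <= e, 0L, pmin(abs(s - b),
                                                                abs(b - e)))
  for (iv in seq_len(nrow(inv))) {
    if (!nrow(cp)) break
    ds <- bp_dist(cp$start, cp$end, inv$start_bp[iv])
    de <- bp_dist(cp$start, cp$end, inv$end_bp[iv])
    fds <- tapply(ds, cp$family_id, min)
    fde <- tapply(de, cp$family_id, min)
    fid <- as.integer(names(fds))
    sel <- pmin(fds, fde) <= window
    if (any(sel))
      hits[[length(hits) + 1L]] <- data.frame(
        inversion = iv, family_id = fid[sel],
        dist_start = as.integer(fds[sel]), dist_end = as.integer(fde[sel]))
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(inversion = integer(), family_id = integer(),
               dist_start = integer(), dist_end = integer())
  per_inv <- data.frame(inversion = seq_len(nrow(inv)),
                        n_families = 0L, longest_repeat = NA_integer_)
  if (nrow(hits)) {
    lens <- stats::setNames(fam$length, fam$family_id)
    for (iv in unique(hits$inversion)) {
      fams <- hits$family_id[hits$inversion == iv]
      per_inv$n_families[iv] <- length(unique(fams))
      per_inv$longest_repeat[iv] <- max(lens[as.character(fams)])
    }
  }
  list(hits = hits, per_inversion = per_inv)
}
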