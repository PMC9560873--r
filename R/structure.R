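# Signed-permutation rearrangement machinery.  The minimum number of signed
# reversals transforming a permutation into the identity is computed exactly
# from the breakpoint graph via the Hannenhalli-Pevzner formula
#     d = (n + 1) - c + h + f
# (c alternating cycles, h hurdles, f fortress indicator), and a sorting
# scenario attaining it is produced greedily: from any permutation some
# reversal lowers the formula by one.

#' Build a signed permutation from two signed locus orders
#'
#' Reference loci are numbered 1..n in reference order with sign +, and the
#' target order is re-expressed in those labels.
#'
#' @param target_order,reference_order character vectors of loci, "-" prefix
#'   marking the opposite strand; both must contain the same locus set once.
#' @return integer vector of class `signed_permutation`.
#' @export
to_signed_permutation <- function(target_order, reference_order) {
  parse <- function(x) {
    neg <- startsWith(x, "-")
    data.frame(locus = sub("^-", "", x), sign = ifelse(neg, -1L, 1L),
               stringsAsFactors = FALSE)
  }
  tg <- parse(target_order)
  rf <- parse(reference_order)
  extra_t <- setdiff(tg$locus, rf$locus)
  extra_r <- setdiff(rf$locus, tg$locus)
  if (length(extra_t) || length(extra_r) || anyDuplicated(tg$locus) ||
      anyDuplicated(rf$locus))
    stop("locus sets differ: only in target {",
         paste(extra_t, collapse = ","), "}, only in reference {",
         paste(extra_r, collapse = ","), "}")
  lab <- match(tg$locus, rf$locus)
  p <- as.integer(lab * tg$sign * rf$sign[lab])
  structure(p, class = "signed_permutation",
            loci = rf$locus)
}

#' Validate a signed permutation
#' @param p integer vector; magnitudes must be exactly 1..n, each once.
#' @return p, invisibly.
#' @export
validate_signed_permutation <- function(p) {
  p <- as.integer(p)
  n <- length(p)
  if (!n || any(p == 0L) || !setequal(abs(p), seq_len(n)))
    stop("not a signed permutation: magnitudes must be 1..n each once")
  invisible(p)
}

#' Apply a reversal
#' @param p signed permutation.
#' @param i,j 1-based inclusive interval to reverse (order flipped, signs
#'   negated).
#' @return the transformed permutation.
#' @export
apply_reversal <- function(p, i, j) {
  stopifnot(i >= 1L, j <= length(p), i <= j)
  p[i:j] <- -rev(p[i:j])
  p
}

# ---- breakpoint graph ------------------------------------------------------

hp_graph <- function(p) {
  n <- length(p)
  nodes <- integer(2L * n + 2L)
  nodes[1L] <- 0L
  for (k in seq_len(n)) {
    x <- p[k]
    if (x > 0L) {
      nodes[2L * k] <- 2L * x - 1L
      nodes[2L * k + 1L] <- 2L * x
    } else {
      nodes[2L * k] <- -2L * x
      nodes[2L * k + 1L] <- -2L * x - 1L
    }
  }
  nodes[2L * n + 2L] <- 2L * n + 1L
  pos <- integer(2L * n + 2L)          # pos[v+1] = 1-based position of node v
  pos[nodes + 1L] <- seq_along(nodes)

  # partners: black edges join positions (2m+1, 2m+2); gray edges join node
  # values (2i, 2i+1)
  black <- integer(2L * n + 2L)
  for (m in 0:n) {
    a <- nodes[2L * m + 1L]
    b <- nodes[2L * m + 2L]
    black[a + 1L] <- b
    black[b + 1L] <- a
  }
  gray <- integer(2L * n + 2L)
  for (i in 0:n) {
    gray[2L * i + 1L] <- 2L * i + 1L
    gray[2L * i + 2L] <- 2L * i
  }

  # alternating cycles
  cyc <- integer(2L * n + 2L)          # cycle id per node
  ncyc <- 0L
  nblack <- integer(0)
  for (v in 0:(2L * n + 1L)) {
    if (cyc[v + 1L] == 0L) {
      ncyc <- ncyc + 1L
      nb <- 0L
      u <- v
      repeat {
        cyc[u + 1L] <- ncyc
        u2 <- black[u + 1L]; nb <- nb + 1L
        cyc[u2 + 1L] <- ncyc
        u <- gray[u2 + 1L]
        if (u == v) break
      }
      nblack <- c(nblack, nb)
    }
  }
  list(n = n, nodes = nodes, pos = pos, cyc = cyc, ncyc = ncyc,
       nblack = nblack)
}

hp_components <- function(g) {
  n <- g$n
  # gray edges with their positions and orientation (same position parity
  # means the edge is oriented); trivial cycles (single black edge) excluded
  ge <- data.frame(i = 0:n)
  ge$u <- 2L * ge$i
  ge$v <- 2L * ge$i + 1L
  ge$pu <- g$pos[ge$u + 1L]
  ge$pv <- g$pos[ge$v + 1L]
  ge$lo <- pmin(ge$pu, ge$pv)
  ge$hi <- pmax(ge$pu, ge$pv)
  ge$cyc <- g$cyc[ge$u + 1L]
  ge$oriented <- (ge$pu %% 2L) == (ge$pv %% 2L)
  nontrivial <- which(g$nblack >= 2L)
  ge <- ge[ge$cyc %in% nontrivial, , drop = FALSE]
  if (!nrow(ge))
    return(data.frame(comp = integer(), oriented = logical(),
                      lo = integer(), hi = integer()))
  # union-find over cycles via interleaving gray edges
  parent <- seq_len(g$ncyc)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  m <- nrow(ge)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a < b && ge$cyc[a] != ge$cyc[b]) {
        inter <- xor(ge$lo[b] > ge$lo[a] && ge$lo[b] < ge$hi[a],
                     ge$hi[b] > ge$lo[a] && ge$hi[b] < ge$hi[a])
        if (inter) {
          ra <- find(ge$cyc[a]); rb <- find(ge$cyc[b])
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  comp <- vapply(ge$cyc, find, integer(1L))
  agg <- data.frame(comp = sort(unique(comp)))
  agg$oriented <- vapply(agg$comp, function(cc) any(ge$oriented[comp == cc]),
                         logical(1L))
  agg$lo <- vapply(agg$comp, function(cc) min(ge$lo[comp == cc]), integer(1L))
  agg$hi <- vapply(agg$comp, function(cc) max(ge$hi[comp == cc]), integer(1L))
  agg
}

# hurdles among unoriented components: minimal ones (span containing no other
# unoriented component) plus the greatest one (span containing all others)
hp_hurdle_ids <- function(uns) {
  k <- nrow(uns)
  if (!k) return(integer(0))
  if (k == 1L) return(uns$comp)
  contains <- outer(seq_len(k), seq_len(k), function(a, b)
    uns$lo[a] <= uns$lo[b] & uns$hi[a] >= uns$hi[b]) & !diag(k)
  minimal <- !apply(contains, 1L, any)
  greatest <- vapply(seq_len(k), function(a)
    all(contains[a, -a]), logical(1L))
  ids <- uns$comp[minimal | greatest]
  unique(ids)
}

hp_hurdles <- function(uns) {
  ids <- hp_hurdle_ids(uns)
  h <- length(ids)
  f <- 0L
  if (h > 0L && h %% 2L == 1L && nrow(uns) > h) {
    # fortress when every hurdle is a superhurdle: deleting it would turn a
    # non-hurdle unoriented component into a hurdle
    super <- vapply(ids, function(id) {
      rest <- uns[uns$comp != id, , drop = FALSE]
      new_ids <- hp_hurdle_ids(rest)
      length(setdiff(new_ids, ids)) > 0L
    }, logical(1L))
    if (all(super)) f <- 1L
  }
  list(h = h, f = f)
}

hp_distance <- function(p) {
  p <- validate_signed_permutation(p)
  n <- length(p)
  g <- hp_graph(p)
  comps <- hp_components(g)
  uns <- comps[!comps$oriented, , drop = FALSE]
  hf <- hp_hurdles(uns)
  as.integer(n + 1L - g$ncyc + hf$h + hf$f)
}

#' Exact signed reversal distance with an optimal scenario
#'
#' @param p signed permutation (integer vector, magnitudes 1..n each once).
#' @param scenario also return a minimum-length sorting scenario (list of
#'   (i, j) reversal intervals transforming `p` into the identity).
#' @return list with `distance` and `scenario` (data.frame i, j).
#' @export
reversal_distance <- function(p, scenario = TRUE) {
  p <- validate_signed_permutation(p)
  d <- hp_distance(p)
  steps <- data.frame(i = integer(), j = integer())
  if (scenario && d > 0L) {
    cur <- p
    dd <- d
    while (dd > 0L) {
      n <- length(cur)
      found <- FALSE
      for (i in seq_len(n)) {
        for (j in i:n) {
          nxt <- apply_reversal(cur, i, j)
          if (hp_distance(nxt) == dd - 1L) {
            steps <- rbind(steps, data.frame(i = i, j = j))
            cur <- nxt
            dd <- dd - 1L
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (!found) stop("internal error: no distance-reducing reversal found")
    }
  }
  list(distance = d, scenario = steps)
}

#' Exact reversal distance by exhaustive breadth-first search
#'
#' Independent oracle: the full reversal graph for n elements is explored by
#' BFS from the identity (feasible for n <= 8), and the distance read off the
#' resulting table.  Tables are cached per session.
#'
#' @param p signed permutation with n <= 8.
#' @return integer distance.
#' @export
oracle_distance <- function(p) {
  p <- validate_signed_permutation(p)
  n <- length(p)
  if (n > 8L) stop("state-space guard: oracle refuses n > 8")
  tab <- oracle_table(n)
  tab[encode_signed_perm(p) + 1L]
}

oracle_table <- function(n) {
  key <- paste0("bfs", n)
  if (is.null(.plastcomp_cache[[key]]))
    .plastcomp_cache[[key]] <- bfs_reversal_table(n)
  .plastcomp_cache[[key]]
}

#' Normalize the SSC orientation of a signed locus order
#'
#' The orientation of the small single-copy region is an arbitrary isomer in
#' IR-present plastomes; comparisons should not be inflated by it.  Flips the
#' SSC-resident block (order reversed, signs negated).  With
#' `convention = "min_distance"`, use [best_ssc_isomer()] instead, which
#' evaluates both isomers against a reference.
#'
#' @param order signed locus vector (see [shared_locus_order()]).
#' @param ssc_loci character vector of loci residing in the SSC.
#' @return the order with the SSC block flipped.
#' @export
flip_ssc <- function(order, ssc_loci) {
  bare <- sub("^-", "", order)
  idx <- which(bare %in% ssc_loci)
  if (!length(idx)) return(order)
  if (!all(diff(idx) == 1L))
    stop("SSC loci do not form a contiguous block in this order; ",
         "blocks must respect region boundaries")
  blk <- order[idx]
  flipped <- rev(ifelse(startsWith(blk, "-"), sub("^-", "", blk),
                        paste0("-", blk)))
  order[idx] <- flipped
  order
}

#' Reversal distance minimized over the two SSC isomers
#'
#' Computes the distance between target and reference orders under both SSC
#' orientations of the reference and reports the minimum, removing the
#' arbitrary-isomer inflation without any manual reversal step.
#'
#' @param target_order,reference_order signed locus vectors.
#' @param ssc_loci loci residing in the reference SSC.
#' @return list with `distance`, `flipped` (was the flipped isomer better),
#'   and `permutation` used.
#' @export
best_ssc_isomer <- function(target_order, reference_order, ssc_loci) {
  p1 <- to_signed_permutation(target_order, reference_order)
  d1 <- reversal_distance(p1, scenario = FALSE)$distance
  ref2 <- flip_ssc(reference_order, ssc_loci)
  p2 <- to_signed_permutation(target_order, ref2)
  d2 <- reversal_distance(p2, scenario = FALSE)$distance
  if (d2 < d1) list(distance = d2, flipped = TRUE, permutation = p2)
  else list(distance = d1, flipped = FALSE, permutation = p1)
}

#' Map a sorting scenario onto genomic intervals
#'
#' Replays the scenario on the target genome: each reversal step yields the
#' breakpoint interval it affects, in the coordinate frame current at that
#' step (locus coordinates are reflected within each reversed segment as the
#' replay proceeds).  Breakpoint convention: an interval a..b flanks the
#' reversed segment, so its length is exactly b - a.
#'
#' @param scenario data.frame (i, j) from [reversal_distance()].
#' @param locus_coords data.frame with columns `locus`, `start`, `end`
#'   (0-based half-open spans in the target genome) for every locus of the
#'   permutation, in target order.
#' @return data.frame (step, start_bp, end_bp, length_bp).
#' @export
map_reversals_to_intervals <- function(scenario, locus_coords) {
  lc <- as.data.frame(locus_coords)
  stopifnot(all(c("locus", "start", "end") %in% names(lc)))
  out <- data.frame(step = integer(), start_bp = integer(),
                    end_bp = integer(), length_bp = integer())
  if (!nrow(scenario)) return(out)
  cur <- lc[order(lc$start), , drop = FALSE]
  for (s in seq_len(nrow(scenario))) {
    i <- scenario$i[s]; j <- scenario$j[s]
    if (j < i) stop("degenerate reversal spanning zero loci")
    if (i < 1L || j > nrow(cur))
      stop("missing coordinates for locus at position ", max(i, j))
    a <- cur$start[i]
    bpe <- cur$end[j]
    out <- rbind(out, data.frame(step = s, start_bp = a, end_bp = bpe,
                                 length_bp = bpe - a))
    # reflect the segment for subsequent steps
    seg <- i:j
    ns <- a + (bpe - cur$end[seg])
    ne <- a + (bpe - cur$start[seg])
    cur$start[seg] <- ns
    cur$end[seg] <- ne
    cur[seg, ] <- cur[rev(seg), , drop = FALSE]
  }
  out
}

#' Read a GRIMM-style permutation file
#'
#' Stanzas of the form `>name` followed by whitespace-separated signed
#' integers terminated by `$`.
#'
#' @param path input file.
#' @return named list of integer vectors.
#' @export
read_grimm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  name <- NULL
  buf <- character()
  flush <- function() {
    if (!is.null(name)) {
      toks <- unlist(strsplit(paste(buf, collapse = " "), "\\s+"))
      toks <- toks[nzchar(toks) & toks != "$"]
      out[[name]] <<- as.integer(toks)
    }
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      name <- trimws(sub("^>", "", ln))
      buf <- character()
    } else buf <- c(buf, ln)
  }
  flush()
  out
}

#' Write a GRIMM-style permutation file
#' @param perms named list of integer vectors.
#' @param path output file.
#' @export
write_grimm <- function(perms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(perms)) {
    writeLines(paste0(">", nm), con)
    writeLines(paste(c(sprintf("%+d", perms[[nm]]), "$"), collapse = " "), con)
  }
  invisible(path)
}
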