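# Shared fixtures and independent oracles used across the suite.

random_seq <- function(len, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# enumerate all permutations of a vector (small n only)
all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

random_signed_perm <- function(n) {
  as.integer(sample(n) * sample(c(-1L, 1L), n, replace = TRUE))
}

# Independent brute-force repeat oracle: for every offset, compare the
# sequence against itself (direct) and against its reverse complement
# (inverted) with a vectorized byte scan, and collect maximal runs.  Shares
# no code with the k-mer diagonal detector.
brute_repeat_pairs <- function(s, min_len) {
  b <- utf8ToInt(s)
  L <- length(b)
  valid <- b %in% utf8ToInt("ACGT")
  out <- list()
  collect <- function(eq, map_pair) {
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (h in which(r$values & r$lengths >= min_len))
      out[[length(out) + 1L]] <<- map_pair(starts[h], r$lengths[h])
  }
  for (d in 1:(L - min_len)) {
    eq <- b[1:(L - d)] == b[(1 + d):L] & valid[1:(L - d)] & valid[(1 + d):L]
    collect(eq, function(i, len)
      data.frame(start1 = i - 1L, end1 = i - 1L + len, start2 = i - 1L + d,
                 end2 = i - 1L + d + len, strand2 = "+", len = len))
  }
  rb <- rev(utf8ToInt(chartr("ACGTN", "TGCAN", s)))
  rvalid <- rev(valid)
  for (d in 0:(L - min_len)) {
    eq <- b[1:(L - d)] == rb[(1 + d):L] & valid[1:(L - d)] & rvalid[(1 + d):L]
    collect(eq, function(i, len) {
      s1 <- i - 1L
      s2 <- L - (i + d - 1L) - len
      data.frame(start1 = s1, end1 = s1 + len, start2 = s2, end2 = s2 + len,
                 strand2 = "-", len = len)
    })
    if (d > 0) {
      eq <- b[(1 + d):L] == rb[1:(L - d)] & valid[(1 + d):L] & rvalid[1:(L - d)]
      collect(eq, function(i, len) {
        s1 <- i + d - 1L
        s2 <- L - (i - 1L) - len
        data.frame(start1 = s1, end1 = s1 + len, start2 = s2, end2 = s2 + len,
                   strand2 = "-", len = len)
      })
    }
  }
  if (!length(out))
    return(data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      strand2 = character(), len = integer()))
  res <- do.call(rbind, out)
  sw <- res$start1 > res$start2
  tmp <- res[sw, c("start2", "end2")]
  res[sw, c("start2", "end2")] <- res[sw, c("start1", "end1")]
  res[sw, c("start1", "end1")] <- tmp
  res <- res[!(res$strand2 == "-" & res$start1 == res$start2), ]
  res <- res[!duplicated(res[, c("start1", "start2", "len", "strand2")]), ]
  res <- res[order(res$start1, res$start2, res$len), ]
  rownames(res) <- NULL
  res
}

sort_pairs <- function(p) {
  p <- p[order(p$start1, p$start2, p$len), c("start1", "end1", "start2",
                                             "end2", "strand2", "len")]
  rownames(p) <- NULL
  p
}

# small cached quadripartite genome shared by several test files
base_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_plastome(sim_config(seed = 7, ir_kb = 6,
                                             n_lsc_genes = 20L,
                                             n_ssc_genes = 8L))
    cache
  }
})
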