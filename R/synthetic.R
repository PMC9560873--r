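# Synthetic-data generators with known ground truth: quadripartite plastomes
# (LSC + IR_A + SSC + IR_B with IR_B the exact reverse complement of IR_A),
# inversion histories optionally mediated by planted inverted repeat pairs,
# codon alignments evolved under the same MG94-style process the estimator
# fits, and Brownian traits with group shifts.  Every generator is a pure
# function of its configuration and seed.

# real plastid gene inventory used to name synthetic genes
LSC_GENE_POOL <- c(
  "psbA", "matK", "rps16", "psbK", "psbI", "atpA", "atpF", "atpH", "atpI",
  "rps2", "rpoC2", "rpoC1", "rpoB", "petN", "psbM", "psbD", "psbC", "psbZ",
  "rps14", "psaB", "psaA", "ycf3", "rps4", "ndhJ", "ndhK", "ndhC", "atpE",
  "atpB", "rbcL", "accD", "psaI", "ycf4", "cemA", "petA", "psbJ", "psbL",
  "psbF", "psbE", "petL", "petG", "psaJ", "rpl33", "rps18", "rpl20", "clpP",
  "psbB", "psbT", "psbN", "psbH", "petB", "petD", "rpoA", "rps11", "rpl36",
  "rps8", "rpl14", "rpl16", "rps3", "rpl22", "rps19")
SSC_GENE_POOL <- c("ndhF", "rpl32", "ccsA", "ndhD", "psaC", "ndhE", "ndhG",
                   "ndhI", "ndhA", "ndhH", "rps15", "ycf1")
# canonical IR content: the rRNA/tRNA core plus IR-resident protein genes
IR_GENE_SET <- data.frame(
  locus = c("rpl2", "rpl23", "ycf2", "ndhB", "rps7", "rps12", "trnI-GAU",
            "trnA-UGC", "rrn16", "rrn23", "rrn4.5", "rrn5"),
  kind = c("CDS", "CDS", "CDS", "CDS", "CDS", "CDS", "tRNA", "tRNA", "rRNA",
           "rRNA", "rRNA", "rRNA"),
  len = c(825L, 282L, 2100L, 1533L, 468L, 372L, 72L, 73L, 1490L, 2810L,
          95L, 121L),
  stringsAsFactors = FALSE)

#' Simulation configuration for synthetic plastomes
#'
#' @param seed RNG seed (fixed seed implies byte-identical output).
#' @param n_lsc_genes,n_ssc_genes number of LSC / SSC genes (drawn in order
#'   from the real plastid inventory).
#' @param ir_kb approximate IR length in kb (gene content fixed, spacers
#'   padded to reach it); the canonical range is roughly 15-30 kb.
#' @param mean_intergenic mean intergenic spacer length (bp, geometric).
#' @param gc intergenic GC fraction (coding sequence follows codon draws).
#' @param cds_codons range of CDS lengths in codons.
#' @param ir_deleted "none", "A" or "B": delete one IR copy to emulate an
#'   IR-lacking lineage.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_lsc_genes = 30L, n_ssc_genes = 10L,
                       ir_kb = 8, mean_intergenic = 150L, gc = 0.36,
                       cds_codons = c(150L, 400L), ir_deleted = "none") {
  stopifnot(ir_deleted %in% c("none", "A", "B"), mean_intergenic > 0,
            gc > 0, gc < 1)
  structure(list(seed = seed, n_lsc_genes = n_lsc_genes,
                 n_ssc_genes = n_ssc_genes, ir_kb = ir_kb,
                 mean_intergenic = mean_intergenic, gc = gc,
                 cds_codons = cds_codons, ir_deleted = ir_deleted),
            class = "sim_config")
}

random_cds <- function(n_codons) {
  sense <- setdiff(sense_codons(), c("ATG", "TGG"))
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# build one region: genes with intergenic spacers; returns sequence and a
# feature table in region-local coordinates
build_region <- function(genes, kinds, lens, cfg) {
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  for (i in seq_along(genes)) {
    spacer <- random_dna(1L + stats::rgeom(1L, 1 / cfg$mean_intergenic),
                         gc = cfg$gc)
    pieces <- c(pieces, spacer)
    pos <- pos + nchar(spacer)
    gseq <- if (kinds[i] == "CDS") {
      nc <- if (is.na(lens[i]))
        sample(cfg$cds_codons[1L]:cfg$cds_codons[2L], 1L) else
          lens[i] %/% 3L
      random_cds(nc)
    } else random_dna(lens[i], gc = 0.5)
    strand <- if (kinds[i] == "CDS" && stats::runif(1L) < 0.4) "-" else "+"
    if (strand == "-") gseq <- revcomp(gseq)
    pieces <- c(pieces, gseq)
    feats[[i]] <- data.frame(locus = genes[i], kind = kinds[i],
                             strand = strand, start = pos,
                             end = pos + nchar(gseq), pseudo = FALSE,
                             stringsAsFactors = FALSE)
    pos <- pos + nchar(gseq)
  }
  tail_sp <- random_dna(1L + stats::rgeom(1L, 1 / cfg$mean_intergenic),
                        gc = cfg$gc)
  list(seq = paste(c(pieces, tail_sp), collapse = ""),
       features = do.call(rbind, feats))
}

#' Simulate a quadripartite plastome with known ground truth
#'
#' Constructs LSC + IR_A + SSC + IR_B, with IR_B the exact reverse
#' complement of IR_A (so the IR genes, including the rRNA core, appear
#' twice), linearized at the LSC start.  Optionally deletes one IR copy.
#'
#' @param cfg a [sim_config()].
#' @param id record id.
#' @return list with `record` (a [genome_record()], partition attached) and
#'   `truth` (planted intervals and gene lists).
#' @export
simulate_plastome <- function(cfg = sim_config(), id = "synthetic") {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    lsc_genes <- LSC_GENE_POOL[seq_len(min(cfg$n_lsc_genes,
                                           length(LSC_GENE_POOL)))]
    ssc_genes <- SSC_GENE_POOL[seq_len(min(cfg$n_ssc_genes,
                                           length(SSC_GENE_POOL)))]
    lsc <- build_region(lsc_genes, rep("CDS", length(lsc_genes)),
                        rep(NA_integer_, length(lsc_genes)), cfg)
    ssc <- build_region(ssc_genes, rep("CDS", length(ssc_genes)),
                        rep(NA_integer_, length(ssc_genes)), cfg)
    ira <- build_region(IR_GENE_SET$locus, IR_GENE_SET$kind, IR_GENE_SET$len,
                        cfg)
    pad_needed <- round(cfg$ir_kb * 1000) - nchar(ira$seq)
    if (pad_needed > 0) ira$seq <- paste0(ira$seq, random_dna(pad_needed,
                                                              gc = cfg$gc))
    if (nchar(lsc$seq) <= nchar(ssc$seq))
      stop("config error: LSC must be longer than SSC")

    l_lsc <- nchar(lsc$seq); l_ir <- nchar(ira$seq); l_ssc <- nchar(ssc$seq)
    irb_seq <- revcomp(ira$seq)
    # mirror IR_A features into IR_B
    fb <- ira$features
    fb2 <- data.frame(locus = fb$locus, kind = fb$kind,
                      strand = ifelse(fb$strand == "+", "-", "+"),
                      start = l_ir - fb$end, end = l_ir - fb$start,
                      pseudo = FALSE, stringsAsFactors = FALSE)

    shift <- function(f, by) { f$start <- f$start + by; f$end <- f$end + by; f }
    segs <- list(list(seq = lsc$seq, f = lsc$features),
                 list(seq = ira$seq, f = ira$features),
                 list(seq = ssc$seq, f = ssc$features),
                 list(seq = irb_seq, f = fb2))
    seg_names <- c("lsc", "ir_a", "ssc", "ir_b")
    if (cfg$ir_deleted == "A") { segs <- segs[c(1, 3, 4)]; seg_names <- seg_names[c(1, 3, 4)] }
    if (cfg$ir_deleted == "B") { segs <- segs[1:3]; seg_names <- seg_names[1:3] }
    offset <- 0L
    feats <- list()
    ivs <- list()
    for (i in seq_along(segs)) {
      feats[[i]] <- shift(segs[[i]]$f, offset)
      ivs[[seg_names[i]]] <- c(offset, offset + nchar(segs[[i]]$seq))
      offset <- offset + nchar(segs[[i]]$seq)
    }
    sequence <- paste(vapply(segs, `[[`, "", "seq"), collapse = "")
    if (cfg$ir_deleted == "none") {
      # pin the planted IR boundaries: force a mismatch at the four flanking
      # spacer positions so exact maximal matching cannot extend the IRs
      L <- nchar(sequence)
      comp <- function(b) chartr("ACGT", "TGCA", b)
      not_comp <- function(partner) if (comp(partner) == "A") "C" else "A"
      # outer: base before IR_A pairs with the base after IR_B (wraps to 0)
      outer_pos <- ivs$ir_a[1L]             # 1-based index of base before IR_A
      outer_partner <- substr(sequence, ivs$ir_b[2L] %% L + 1L,
                              ivs$ir_b[2L] %% L + 1L)
      substr(sequence, outer_pos, outer_pos) <- not_comp(outer_partner)
      # inner: base after IR_A pairs with the base before IR_B
      inner_pos <- ivs$ir_a[2L] + 1L        # first SSC base (spacer)
      inner_partner <- substr(sequence, ivs$ir_b[1L], ivs$ir_b[1L])
      substr(sequence, inner_pos, inner_pos) <- not_comp(inner_partner)
    }
    features <- do.call(rbind, feats)
    part <- list(lsc = ivs$lsc, ssc = ivs$ssc, ir_a = ivs$ir_a,
                 ir_b = ivs$ir_b,
                 ir_status = switch(cfg$ir_deleted, none = "both",
                                    A = "A_lost", B = "B_lost"))
    rec <- genome_record(id, sequence, features, circular = TRUE,
                         partition = part)
    list(record = rec,
         truth = list(intervals = ivs, ir_deleted = cfg$ir_deleted,
                      lsc_genes = lsc_genes, ssc_genes = ssc_genes,
                      ir_genes = IR_GENE_SET$locus, config = cfg))
  })
}

#' Apply random inversions to a plastome, optionally repeat-mediated
#'
#' Chooses `k` non-overlapping gene-boundary-respecting segments and
#' reverse-complements them.  For the repeat-mediated fraction, an inverted
#' repeat pair of length `repeat_len` is first planted immediately outside
#' the two breakpoints, emulating recombinationally active small repeats; the
#' inversion endpoints then coincide with the repeat inner edges.  The event
#' ledger records each inversion as flanking breakpoints a-b with length
#' b - a, in final-genome coordinates.
#'
#' @param record a `genome_record` (typically IR-lacking or IR-collapsed).
#' @param k number of inversions.
#' @param fraction_repeat_mediated fraction of events with a planted repeat
#'   pair.
#' @param repeat_len planted repeat length (>= 30 bp).
#' @param seed RNG seed.
#' @param region optional 0-based half-open interval; inversions are
#'   restricted to features inside it (e.g. the LSC, so the IR pair stays
#'   intact).
#' @return list with `record` (rearranged), `events` (data.frame start_bp,
#'   end_bp, length_bp, repeat_mediated, repeat_len), `segments` (gene index
#'   ranges inverted).
#' @export
apply_inversions <- function(record, k, fraction_repeat_mediated = 0.15,
                             repeat_len = 40L, seed = NULL, region = NULL) {
  stopifnot(inherits(record, "genome_record"), k >= 0L)
  if (k == 0L)
    return(list(record = record,
                events = data.frame(start_bp = integer(), end_bp = integer(),
                                    length_bp = integer(),
                                    repeat_mediated = logical(),
                                    repeat_len = integer()),
                segments = NULL))
  f <- record$features
  nf <- nrow(f)
  idx_ok <- if (is.null(region)) seq_len(nf) else
    which(f$start >= region[1L] & f$end <= region[2L])
  if (2L * k > length(idx_ok) - 1L) stop("k too large for gene count")
  rlo <- min(idx_ok); rhi <- max(idx_ok)
  with_seed(seed, {
    # pick k disjoint gene index ranges, separated by at least one gene
    picks <- list()
    tries <- 0L
    while (length(picks) < k && tries < 10000L) {
      tries <- tries + 1L
      a <- rlo + sample.int(rhi - rlo, 1L) - 1L
      b <- min(rhi, a + sample.int(3L, 1L) - 1L)
      ok <- all(vapply(picks, function(p) b < p[1L] - 1L || a > p[2L] + 1L,
                       logical(1L)))
      if (ok) picks[[length(picks) + 1L]] <- c(a, b)
    }
    if (length(picks) < k) stop("could not place ", k, " disjoint inversions")
    picks <- picks[order(vapply(picks, `[[`, 0L, 1L))]
    mediated <- stats::runif(k) < fraction_repeat_mediated

    s <- record$sequence
    # breakpoints: midpoint of the intergenic gap flanking the segment
    cuts <- lapply(seq_len(k), function(i) {
      a <- picks[[i]][1L]; b <- picks[[i]][2L]
      left <- if (a == 1L) f$start[1L] %/% 2L else
        (f$end[a - 1L] + f$start[a]) %/% 2L
      right <- if (b == nf) (f$end[b] + nchar(s)) %/% 2L else
        (f$end[b] + f$start[b + 1L]) %/% 2L
      c(left, right)
    })

    # assemble the final genome left to right
    pieces <- character(0)
    events <- list()
    newf <- list()
    pos_in <- 0L     # consumed position in source genome
    offset <- 0L     # emitted length so far
    reflect_feats <- function(rows, seg_lo, seg_hi, new_lo) {
      # reflect features of source interval [seg_lo, seg_hi) to start new_lo
      g <- f[rows, , drop = FALSE]
      w <- seg_hi - seg_lo
      ns <- new_lo + (w - (g$end - seg_lo))
      ne <- new_lo + (w - (g$start - seg_lo))
      g$start <- ns; g$end <- ne
      g$strand <- ifelse(g$strand == "+", "-", "+")
      g
    }
    plain_feats <- function(rows, delta) {
      g <- f[rows, , drop = FALSE]
      g$start <- g$start + delta; g$end <- g$end + delta
      g
    }
    for (i in seq_len(k)) {
      lo <- cuts[[i]][1L]; hi <- cuts[[i]][2L]
      # untouched stretch before the segment
      pre_rows <- which(f$start >= pos_in & f$end <= lo)
      pieces <- c(pieces, substr0(s, pos_in, lo))
      newf[[length(newf) + 1L]] <- plain_feats(pre_rows, offset - pos_in)
      offset <- offset + (lo - pos_in)
      rep_seq <- NULL
      if (mediated[i]) {
        rep_seq <- random_dna(repeat_len, gc = 0.45)
        pieces <- c(pieces, rep_seq)
        offset <- offset + repeat_len
      }
      start_bp <- offset
      seg_rows <- which(f$start >= lo & f$end <= hi)
      pieces <- c(pieces, revcomp(substr0(s, lo, hi)))
      newf[[length(newf) + 1L]] <- reflect_feats(seg_rows, lo, hi, offset)
      offset <- offset + (hi - lo)
      end_bp <- offset
      if (mediated[i]) {
        pieces <- c(pieces, revcomp(rep_seq))
        offset <- offset + repeat_len
      }
      events[[i]] <- data.frame(start_bp = start_bp, end_bp = end_bp,
                                length_bp = end_bp - start_bp,
                                repeat_mediated = mediated[i],
                                repeat_len = if (mediated[i]) repeat_len
                                else NA_integer_)
      pos_in <- hi
    }
    tail_rows <- which(f$start >= pos_in)
    pieces <- c(pieces, substr0(s, pos_in, nchar(s)))
    newf[[length(newf) + 1L]] <- plain_feats(tail_rows, offset - pos_in)
    newseq <- paste(pieces, collapse = "")
    features <- do.call(rbind, newf)
    out <- genome_record(record$id, newseq, features,
                         circular = record$circular, partition = NULL)
    list(record = out, events = do.call(rbind, events), segments = picks)
  })
}

#' Simulate codon evolution under the MG94-style process
#'
#' Evolves `n_codons` codons along the tree by exact stochastic simulation
#' (exponential waiting times from the current codon's exit rate), using the
#' same rate structure the estimator fits: HKY exchangeabilities, F3x4
#' frequencies, omega multiplier on nonsynonymous changes, branch lengths in
#' expected substitutions per codon under each branch's own omega.
#'
#' @param tree `ape::phylo` with branch lengths (expected substitutions per
#'   codon).
#' @param n_codons number of codons (>= 10).
#' @param kappa transition/transversion rate ratio.
#' @param omega scalar, or vector over edges of `tree` (postorder after
#'   `ape::reorder.phylo(tree, "postorder")`), or named by tip for terminal
#'   branches with a `default` entry.
#' @param tfreq position-specific nucleotide frequencies (12, rows A C G T
#'   per position); default uniform.
#' @param seed RNG seed.
#' @return list: `alignment` (a [codon_alignment()]), `events` per edge
#'   (syn, nonsyn counts), `edge_omega`, `true_ds`, `true_dn` per edge
#'   (model-expected values from the branch length).
#' @export
simulate_codon_evolution <- function(tree, n_codons, kappa = 2, omega = 0.2,
                                     tfreq = rep(0.25, 12L), seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_codons >= 10L)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nedge <- nrow(tr$edge)
  if (length(omega) == 1L && is.null(names(omega))) {
    om_edge <- rep(omega, nedge)
  } else if (!is.null(names(omega))) {
    om_edge <- rep(if ("default" %in% names(omega))
      omega[["default"]] else stop("named omega needs a 'default'"), nedge)
    tipedge <- match(seq_len(ntip), tr$edge[, 2L])
    for (nm in setdiff(names(omega), "default")) {
      i <- match(nm, tr$tip.label)
      if (!is.na(i)) om_edge[tipedge[i]] <- omega[[nm]]
    }
  } else {
    stopifnot(length(omega) == nedge)
    om_edge <- omega
  }
  gens <- lapply(unique(om_edge), function(o)
    mg94_generator(kappa, o, tfreq))
  names(gens) <- as.character(unique(om_edge))
  cs <- codon_setup()
  syn_pair <- matrix(FALSE, length(cs$sense), length(cs$sense))
  syn_pair[cs$pairs[, c("i", "j")] + 1L] <- cs$pairs[, "syn"] == 1L

  with_seed(seed, {
    pi <- gens[[1L]]$pi
    root_state <- sample.int(length(pi), n_codons, replace = TRUE, prob = pi)
    node_states <- vector("list", ntip + tr$Nnode)
    root <- tr$edge[nedge, 1L]
    node_states[[root]] <- root_state
    events <- data.frame(edge = seq_len(nedge), syn = 0L, nonsyn = 0L)
    for (e in rev(seq_len(nedge))) {          # parent-before-child order
      parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      g <- gens[[as.character(om_edge[e])]]
      Q <- g$Q
      exit <- -diag(Q)
      st <- node_states[[parent]]
      tleft <- rep(tr$edge.length[e], n_codons)
      repeat {
        lam <- exit[st]
        wait <- stats::rexp(n_codons, rate = pmax(lam, 1e-12))
        jump <- which(wait < tleft & lam > 0)
        if (!length(jump)) break
        for (site in jump) {
          i <- st[site]
          pr <- Q[i, ]; pr[i] <- 0
          j <- sample.int(length(pr), 1L, prob = pr)
          if (syn_pair[i, j]) events$syn[e] <- events$syn[e] + 1L
          else events$nonsyn[e] <- events$nonsyn[e] + 1L
          st[site] <- j
        }
        tleft <- tleft - wait
        tleft[-jump] <- 0
      }
      node_states[[child]] <- st
    }
    seqs <- vapply(seq_len(ntip), function(i)
      paste(cs$sense[node_states[[i]]], collapse = ""), "")
    names(seqs) <- tr$tip.label
    rho_s <- vapply(gens, `[[`, 0, "rho_s")[as.character(om_edge)]
    s_sites <- 3 * mg94_generator(kappa, 1, tfreq)$rho_s
    list(alignment = codon_alignment(seqs, gene_set = "simulated"),
         events = events, edge_omega = om_edge, tree = tr,
         true_ds = tr$edge.length * rho_s / s_sites,
         true_dn = tr$edge.length * (1 - rho_s) / (3 - s_sites))
  })
}

#' Simulate Brownian traits on a tree with group shifts
#'
#' Brownian motion along branches from a root value of zero; after
#' simulation, group-specific shifts are added at the tips.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param groups named group labels per tip (optional when no shifts).
#' @param group_shifts named numeric shifts per group (default none).
#' @param seed RNG seed.
#' @return named numeric vector of tip values.
#' @export
simulate_brownian_traits <- function(tree, sigma2, groups = NULL,
                                     group_shifts = NULL, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nedge <- nrow(tr$edge)
  with_seed(seed, {
    val <- numeric(ntip + tr$Nnode)
    for (e in rev(seq_len(nedge))) {
      parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      val[child] <- val[parent] +
        stats::rnorm(1L, 0, sqrt(sigma2 * tr$edge.length[e]))
    }
    y <- stats::setNames(val[seq_len(ntip)], tr$tip.label)
    if (!is.null(group_shifts)) {
      stopifnot(!is.null(groups))
      add <- unlist(group_shifts)[as.character(groups[names(y)])]
      add[is.na(add)] <- 0
      y <- y + unname(add)
    }
    y
  })
}

# mutate a record's sequence in place (coordinates unchanged): intergenic
# substitutions at rate sub_rate, and synonymous third-position recoding of
# CDS codons toward a target GC3, both restricted to positions outside the
# excluded intervals (the IR copies, so their exact duplication survives)
tweak_record <- function(record, exclude = list(), sub_rate = 0,
                         syn_rate = 0, syn_gc3 = 0.3, seed = NULL) {
  with_seed(seed, {
    s <- strsplit(record$sequence, "")[[1L]]
    L <- length(s)
    blocked <- rep(FALSE, L)
    for (iv in exclude)
      if (!is.null(iv) && iv[2L] > iv[1L]) blocked[(iv[1L] + 1L):iv[2L]] <- TRUE
    f <- record$features
    covered <- rep(FALSE, L)
    for (r in seq_len(nrow(f))) covered[(f$start[r] + 1L):f$end[r]] <- TRUE
    if (sub_rate > 0) {
      ig <- which(!covered & !blocked)
      hit <- ig[stats::runif(length(ig)) < sub_rate]
      if (length(hit)) {
        for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
      }
    }
    if (syn_rate > 0) {
      code <- codon_code()
      fam <- split(names(code)[code != "*"], code[code != "*"])
      cds_rows <- which(f$kind == "CDS" & !f$pseudo)
      for (r in cds_rows) {
        if (any(blocked[(f$start[r] + 1L):f$end[r]])) next
        span <- (f$start[r] + 1L):f$end[r]
        gseq <- paste(s[span], collapse = "")
        if (f$strand[r] == "-") gseq <- revcomp(gseq)
        cods <- split_codons(gseq)
        pick <- which(stats::runif(length(cods)) < syn_rate)
        for (ci in pick) {
          aa <- code[[cods[ci]]]
          if (is.null(aa) || aa == "*") next
          opts <- fam[[aa]]
          if (length(opts) < 2L) next
          third <- substr(opts, 3L, 3L)
          w <- ifelse(third %in% c("G", "C"), syn_gc3, 1 - syn_gc3)
          cods[ci] <- sample(opts, 1L, prob = w)
        }
        gseq <- paste(cods, collapse = "")
        if (f$strand[r] == "-") gseq <- revcomp(gseq)
        s[span] <- strsplit(gseq, "")[[1L]]
      }
    }
    record$sequence <- paste(s, collapse = "")
    record
  })
}

# reference class sequences mutated into a gapped alignment row: point
# substitutions at sub_rate, deletion events at indel_rate per bp with
# geometric lengths (mean 3 bp, typical plastome microstructure)
mutate_alignment_row <- function(ref, sub_rate, indel_rate) {
  x <- strsplit(ref, "")[[1L]]
  n <- length(x)
  sub <- which(stats::runif(n) < sub_rate & x %in% c("A", "C", "G", "T"))
  for (i in sub) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
  ev <- which(stats::runif(n) < indel_rate)
  for (i in ev) {
    len <- 1L + stats::rgeom(1L, 1 / 3)
    x[i:min(n, i + len - 1L)] <- "-"
  }
  paste(x, collapse = "")
}

#' Simulate a full comparative study with known ground truth
#'
#' Builds one ancestral quadripartite plastome, derives per-taxon records
#' (IR-lacking taxa lose IR_A; all taxa get taxon-specific intergenic
#' substitutions and synonymous GC3 recoding, plus group-dependent numbers
#' of LSC inversions), an ultrametric tree, per-class alignments with
#' group-dependent substitution and indel rates, and a codon alignment whose
#' IR-lacking terminal branches are elongated by `ds_mult` (an elevated
#' synonymous rate).  Everything needed by [run_comparison()], with the
#' planted parameters returned as ground truth.
#'
#' @param seed master seed.
#' @param n_per_group named integer vector over the groups "IR_lacking",
#'   "IR_present", "CRCIR".
#' @param k_inversions named list of k ranges (min, max) per group.
#' @param sub_rate,indel_rate named per-group rates for the class
#'   alignments.
#' @param gc3_target named per-group synonymous-recoding GC3 target.
#' @param ds_mult terminal-branch length multiplier for IR-lacking taxa in
#'   the codon simulation.
#' @param n_codons codon-alignment length.
#' @param base_cfg `sim_config` overrides for the ancestral genome (its
#'   `seed`/`ir_deleted` fields are managed internally).
#' @return list: records, tree, groups, reference, class_alignments,
#'   codon_aln, truth.
#' @export
synthetic_study <- function(seed = 1L,
                            n_per_group = c(IR_lacking = 4L, IR_present = 4L,
                                            CRCIR = 4L),
                            k_inversions = list(IR_lacking = c(2L, 5L),
                                                IR_present = c(2L, 5L),
                                                CRCIR = c(0L, 1L)),
                            sub_rate = c(IR_lacking = 0.02,
                                         IR_present = 0.02, CRCIR = 0.005),
                            indel_rate = c(IR_lacking = 0.002,
                                           IR_present = 0.002,
                                           CRCIR = 0.0005),
                            gc3_target = c(IR_lacking = 0.45,
                                           IR_present = 0.45, CRCIR = 0.25),
                            ds_mult = 3, n_codons = 300L,
                            base_cfg = sim_config()) {
  base_cfg$seed <- seed
  base_cfg$ir_deleted <- "none"
  base <- simulate_plastome(base_cfg, id = "ancestor")
  base_cfg_A <- base_cfg
  base_cfg_A$ir_deleted <- "A"
  base_A <- simulate_plastome(base_cfg_A, id = "ancestor_A")

  groups <- rep(names(n_per_group), n_per_group)
  taxa <- paste0(rep(c(IR_lacking = "lack", IR_present = "pres",
                       CRCIR = "crcir")[groups]),
                 unlist(lapply(n_per_group, seq_len)))
  names(groups) <- taxa
  tree <- with_seed(seed + 1L, ape::rcoal(length(taxa), tip.label = sample(taxa)))
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))

  records <- list()
  truth_k <- integer(0)
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    g <- groups[tx]
    lacking <- g == "IR_lacking"
    src <- if (lacking) base_A else base
    rec <- src$record
    rec$id <- tx
    excl <- if (lacking) list() else
      list(src$truth$intervals$ir_a, src$truth$intervals$ir_b)
    rec <- tweak_record(rec, exclude = excl, sub_rate = 0.01,
                        syn_rate = 0.3, syn_gc3 = gc3_target[[g]],
                        seed = seed * 1000L + i)
    kr <- k_inversions[[g]]
    k <- with_seed(seed * 1000L + 500L + i,
                   sample(kr[1L]:kr[2L], 1L))
    region <- src$truth$intervals$lsc
    inv <- apply_inversions(rec, k, fraction_repeat_mediated = 0.3,
                            repeat_len = 40L, seed = seed * 1000L + 250L + i,
                            region = region)
    records[[tx]] <- inv$record
    truth_k[tx] <- k
  }
  reference <- taxa[groups == "CRCIR"][1L]

  # per-class alignments: reference class sequences, rows mutated per taxon
  ref_classes <- sequence_classes(
    suppressWarnings(collapse_ir(records[[reference]])))
  make_aln <- function(refseq) {
    rows <- with_seed(seed + 7L, {
      vapply(taxa, function(tx) {
        if (tx == reference) return(refseq)
        g <- groups[tx]
        mutate_alignment_row(refseq, sub_rate[[g]], indel_rate[[g]])
      }, "")
    })
    stats::setNames(rows, taxa)
  }
  class_alignments <- list(
    protein_coding = make_aln(paste(ref_classes$protein_coding,
                                    collapse = "")),
    rRNA = make_aln(paste(ref_classes$rRNA, collapse = "")),
    intergenic = make_aln(paste(ref_classes$intergenic, collapse = "")))

  # codon alignment: IR-lacking terminal branches elongated by ds_mult
  sim_tree <- tree
  tipedge <- match(seq_along(taxa), sim_tree$edge[, 2L])
  lack_tips <- which(sim_tree$tip.label %in% taxa[groups == "IR_lacking"])
  sim_tree$edge.length <- sim_tree$edge.length * 0.05
  sim_tree$edge.length[tipedge[lack_tips]] <-
    sim_tree$edge.length[tipedge[lack_tips]] * ds_mult
  codon_sim <- simulate_codon_evolution(sim_tree, n_codons = n_codons,
                                        kappa = 2, omega = 0.2,
                                        seed = seed + 13L)
  list(records = records, tree = tree, groups = groups,
       reference = reference, class_alignments = class_alignments,
       codon_aln = codon_sim$alignment,
       truth = list(k_inversions = truth_k, ds_mult = ds_mult,
                    codon_tree = sim_tree, codon_events = codon_sim$events,
                    base = base))
}
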