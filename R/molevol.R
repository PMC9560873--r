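# MG94-style codon-model machinery: back-translated codon alignments,
# maximum-likelihood estimation of branch lengths, kappa and omega under
# one-ratio / two-ratio / free-ratio branch models, per-branch dS and dN by
# the expected-substitutions decomposition, and likelihood-ratio tests.

# ---- codon machinery -------------------------------------------------------

NT <- c("A", "C", "G", "T")

codon_setup <- function() {
  if (!is.null(.plastcomp_cache$codon_setup))
    return(.plastcomp_cache$codon_setup)
  code <- codon_code()
  sense <- sense_codons()
  ns <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  pairs <- list()
  ts_pair <- function(a, b) (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i == j) next
      diff <- which(mat[i, ] != mat[j, ])
      if (length(diff) == 1L) {
        pos <- diff
        pairs[[length(pairs) + 1L]] <- c(
          i - 1L, j - 1L,
          as.integer(ts_pair(mat[i, pos], mat[j, pos])),
          as.integer(code[sense[i]] == code[sense[j]]),
          (pos - 1L) * 4L + match(mat[j, pos], NT) - 1L)
      }
    }
  }
  pr <- do.call(rbind, pairs)
  colnames(pr) <- c("i", "j", "ts", "syn", "tidx")
  .plastcomp_cache$codon_setup <- list(sense = sense, mat = mat, pairs = pr)
  .plastcomp_cache$codon_setup
}

# position-specific nucleotide frequencies (3 x 4, flattened row-wise) from
# ungapped codons; small floor keeps the chain irreducible
f3x4_freqs <- function(codons, floor = 1e-4) {
  m <- do.call(rbind, strsplit(codons, ""))
  tf <- numeric(12L)
  for (p in 1:3) {
    tab <- table(factor(m[, p], levels = NT))
    f <- as.numeric(tab) / sum(tab)
    f <- pmax(f, floor)
    tf[(p - 1L) * 4L + 1:4] <- f / sum(f)
  }
  tf
}

codon_pi <- function(tfreq, sense = sense_codons()) {
  mat <- do.call(rbind, strsplit(sense, ""))
  pi <- tfreq[match(mat[, 1L], NT)] *
    tfreq[4L + match(mat[, 2L], NT)] *
    tfreq[8L + match(mat[, 3L], NT)]
  pi / sum(pi)
}

# normalized MG94 generator built in R (used by the simulator and by the
# dS/dN decomposition; the likelihood builds its own copy in compiled code)
mg94_generator <- function(kappa, omega, tfreq) {
  cs <- codon_setup()
  ns <- length(cs$sense)
  Q <- matrix(0, ns, ns)
  pr <- cs$pairs
  rate <- tfreq[pr[, "tidx"] + 1L] *
    ifelse(pr[, "ts"] == 1L, kappa, 1) *
    ifelse(pr[, "syn"] == 1L, 1, omega)
  Q[cbind(pr[, "i"] + 1L, pr[, "j"] + 1L)] <- rate
  diag(Q) <- -rowSums(Q)
  pi <- codon_pi(tfreq)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  rho_s <- sum(pi[pr[, "i"] + 1L] * Q[cbind(pr[, "i"] + 1L, pr[, "j"] + 1L)] *
                 (pr[, "syn"] == 1L))
  list(Q = Q, pi = pi, rho_s = rho_s, rho_n = 1 - rho_s)
}

# ---- codon alignments ------------------------------------------------------

#' Construct a codon alignment
#'
#' @param seqs named character vector of aligned nucleotide sequences whose
#'   length is divisible by 3; every ungapped codon must be a sense codon of
#'   the standard code (gapped or N-containing codons are treated as missing
#'   data downstream).
#' @param gene_set label for the gene set.
#' @return object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs, gene_set = "") {
  seqs <- vapply(seqs, toupper, "")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("rows differ in length")
  if (lens[1L] %% 3L != 0L) stop("alignment length not divisible by 3")
  code <- codon_code()
  for (nm in names(seqs)) {
    cods <- split_codons(seqs[[nm]])
    clean <- !grepl("[^ACGT]", cods)
    bad <- clean & code[cods] == "*"
    bad[is.na(bad)] <- FALSE
    if (any(bad))
      stop("stop codon in row ", nm, " at codon ", which(bad)[1L])
  }
  structure(list(seqs = seqs, n_codons = unname(lens[1L]) %/% 3L,
                 gene_set = gene_set), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$seqs), " taxa x ", x$n_codons,
      " codons", if (nzchar(x$gene_set)) paste0(" [", x$gene_set, "]"),
      "\n", sep = "")
  invisible(x)
}

codon_state_matrix <- function(aln) {
  cs <- codon_setup()
  t(vapply(aln$seqs, function(s) {
    cods <- split_codons(s)
    idx <- match(cods, cs$sense) - 1L
    idx[is.na(idx)] <- -1L
    idx
  }, integer(aln$n_codons)))
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Each amino acid (or gap) of the protein alignment is replaced by the
#' corresponding codon (or "---") of the unaligned CDS, preserving frame.
#' A trailing stop codon on the CDS is dropped.
#'
#' @param protein_alignment named character vector of aligned amino-acid
#'   sequences (gaps "-").
#' @param cds_map named character vector of unaligned CDS, same names; each
#'   CDS must translate exactly to its ungapped protein row.
#' @param gene_set label passed through.
#' @return a [codon_alignment()].
#' @export
back_translate <- function(protein_alignment, cds_map, gene_set = "") {
  out <- character(0)
  for (nm in names(protein_alignment)) {
    if (!nm %in% names(cds_map)) stop("no CDS for row ", nm)
    prot <- strsplit(toupper(protein_alignment[[nm]]), "")[[1L]]
    cds <- toupper(cds_map[[nm]])
    aa_cds <- strsplit(translate_cds(cds), "")[[1L]]
    if (length(aa_cds) && aa_cds[length(aa_cds)] == "*") {
      aa_cds <- aa_cds[-length(aa_cds)]
      cds <- substr(cds, 1L, nchar(cds) - 3L)
    }
    ungapped <- prot[prot != "-"]
    if (length(ungapped) != length(aa_cds))
      stop("length mismatch for ", nm, ": protein ", length(ungapped),
           " aa vs CDS ", length(aa_cds), " codons")
    mism <- which(ungapped != aa_cds)
    if (length(mism))
      stop("translation mismatch for ", nm, " at position ", mism[1L],
           ": ", ungapped[mism[1L]], " vs ", aa_cds[mism[1L]])
    cods <- split_codons(cds)
    row <- character(length(prot))
    k <- 0L
    for (x in seq_along(prot)) {
      if (prot[x] == "-") row[x] <- "---"
      else { k <- k + 1L; row[x] <- cods[k] }
    }
    out[nm] <- paste(row, collapse = "")
  }
  codon_alignment(out, gene_set = gene_set)
}

# ---- gene classification ---------------------------------------------------

OTHER_HK <- c("accD", "clpP", "matK", "ycf1", "ycf2", "ycf12")
OTHER_PS <- c("ccsA", "cemA", "rbcL", "ycf3", "ycf4")
IR_GENES_ANGIOSPERM <- c("rps12", "rps7", "ndhB", "ycf2", "ycf1", "rpl23",
                         "rpl2")
IR_GENES_GYMNOSPERM <- c("ycf2", "ndhB", "rps12", "rps7")

#' Classify plastid protein-coding genes into functional sets
#'
#' The eleven single-copy classes are the nine gene-family prefixes (atp,
#' chl, ndh, pet, psa, psb, rpl, rpo, rps) plus other housekeeping
#' (other-HK: accD, clpP, matK, ycf1, ycf2, ycf12) and other photosynthesis
#' (other-PS: ccsA, cemA, rbcL, ycf3, ycf4) genes.  The IR-resident gene set
#' depends on lineage: rps12, rps7, ndhB, ycf2, ycf1, rpl23, rpl2 for
#' angiosperms; ycf2, ndhB, rps12, rps7 for gymnosperms.
#'
#' @param gene_names character vector of gene symbols.
#' @param lineage_kind "angiosperm" or "gymnosperm".
#' @return data.frame (gene, class, ir_gene).
#' @export
classify_genes <- function(gene_names,
                           lineage_kind = c("angiosperm", "gymnosperm")) {
  lineage_kind <- match.arg(lineage_kind)
  lw <- tolower(gene_names)
  cls <- rep("unclassified", length(gene_names))
  cls[lw %in% tolower(OTHER_HK)] <- "other-HK"
  cls[lw %in% tolower(OTHER_PS)] <- "other-PS"
  for (pre in c("atp", "chl", "ndh", "pet", "psa", "psb", "rpl", "rpo",
                "rps")) {
    hit <- cls == "unclassified" & startsWith(lw, pre)
    cls[hit] <- pre
  }
  if (any(cls == "unclassified"))
    warning("unclassified genes: ",
            paste(gene_names[cls == "unclassified"], collapse = ", "))
  ir_set <- if (lineage_kind == "angiosperm") IR_GENES_ANGIOSPERM else
    IR_GENES_GYMNOSPERM
  data.frame(gene = gene_names, class = cls,
             ir_gene = lw %in% tolower(ir_set), stringsAsFactors = FALSE)
}

# ---- model fitting ---------------------------------------------------------

#' Fit an MG94-style codon model
#'
#' Maximizes the pruning log-likelihood of a codon alignment on a tree under
#' HKY-type nucleotide exchangeabilities (single kappa), F3x4 codon
#' frequencies from the data, and an omega multiplier on nonsynonymous
#' changes.  `mode` selects the branch model: a single omega ("one_ratio"),
#' separate foreground/background omegas ("two_ratio"), or one omega per
#' branch ("free_ratio").  Branch lengths are expected substitutions per
#' codon.  Per-branch dS and dN come from the standard decomposition:
#' synonymous site proportion from the omega = 1 opportunity, expected
#' synonymous flux under the fitted omega.
#'
#' @param aln a [codon_alignment()] (or named character vector coerced to
#'   one).
#' @param tree `ape::phylo` whose tips are a subset of the alignment rows
#'   (the tree is unrooted for fitting; the model is reversible).
#' @param mode one of "one_ratio", "two_ratio", "free_ratio".
#' @param foreground for two_ratio: tip labels (terminal branches) and/or
#'   edge indices forming the foreground branch set.
#' @param init optional warm start: list(t, kappa, omega).
#' @param starts number of optimizer starts (extra starts jitter omega).
#' @param control optim control overrides.
#' @return object of class `rate_result`: lnL, kappa, per-edge table
#'   (parent, child, tip, t, omega, dS, dN), pi, mode, convergence info.
#' @export
fit_codon_model <- function(aln, tree,
                            mode = c("one_ratio", "two_ratio", "free_ratio"),
                            foreground = NULL, init = NULL, starts = 2L,
                            control = list()) {
  mode <- match.arg(mode)
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% names(aln$seqs)))
    stop("tree tips absent from alignment: ",
         paste(setdiff(tree$tip.label, names(aln$seqs)), collapse = ", "))
  if (length(tree$tip.label) < 2L) stop("need at least 2 taxa")
  work <- if (length(tree$tip.label) >= 3L) ape::unroot(tree) else tree
  work <- ape::reorder.phylo(work, "postorder")
  ntip <- length(work$tip.label)
  nedge <- nrow(work$edge)
  nnode <- ntip + work$Nnode

  states_full <- codon_state_matrix(aln)
  states <- states_full[work$tip.label, , drop = FALSE]
  keycols <- apply(states, 2L, paste, collapse = ",")
  upat <- !duplicated(keycols)
  pat <- states[, upat, drop = FALSE]
  w <- as.numeric(table(keycols)[keycols[upat]])

  cods <- unlist(lapply(aln$seqs[work$tip.label], split_codons),
                 use.names = FALSE)
  cods <- cods[!grepl("[^ACGT]", cods)]
  tfreq <- f3x4_freqs(cods)
  pi <- codon_pi(tfreq)
  cs <- codon_setup()

  if (mode == "two_ratio" && is.null(foreground))
    stop("two_ratio requires a foreground branch set")
  oclass <- rep(1L, nedge)
  if (mode == "two_ratio") {
    fg_edges <- integer(0)
    fg_tips <- foreground[foreground %in% work$tip.label]
    if (length(fg_tips))
      fg_edges <- which(work$edge[, 2L] %in% match(fg_tips, work$tip.label))
    fg_idx <- suppressWarnings(as.integer(foreground))
    fg_idx <- fg_idx[!is.na(fg_idx)]
    fg_edges <- union(fg_edges, fg_idx[fg_idx >= 1L & fg_idx <= nedge])
    if (!length(fg_edges)) stop("foreground matched no branch")
    oclass[fg_edges] <- 2L
  } else if (mode == "free_ratio") {
    oclass <- seq_len(nedge)
  }
  nom <- max(oclass)

  edge0 <- work$edge - 1L
  negloglik <- function(par) {
    t_edge <- exp(par[seq_len(nedge)])
    kappa <- exp(par[nedge + 1L])
    om <- exp(par[nedge + 1L + seq_len(nom)])
    -mg94_loglik_cpp(edge0, t_edge, om[oclass], kappa, pat, w,
                     cs$pairs, tfreq, pi, nnode)
  }

  lower <- c(rep(log(1e-6), nedge), log(0.05), rep(log(1e-4), nom))
  upper <- c(rep(log(30), nedge), log(100), rep(log(20), nom))
  ctl <- utils::modifyList(list(maxit = 500L, factr = 1e8), control)

  make_init <- function(s) {
    if (!is.null(init)) {
      t0 <- rep_len(init$t, nedge)
      k0 <- init$kappa
      o0 <- rep_len(init$omega, nom)
    } else {
      t0 <- rep(0.1, nedge)
      k0 <- 2
      o0 <- rep(0.2, nom)
    }
    if (s > 1L) o0 <- rep_len(c(1, 0.05, 5)[s - 1L], nom)
    pmin(pmax(c(log(t0), log(k0), log(o0)), lower), upper)
  }

  best <- NULL
  for (s in seq_len(max(1L, starts))) {
    fit <- stats::optim(make_init(s), negloglik, method = "L-BFGS-B",
                        lower = lower, upper = upper, control = ctl)
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  t_hat <- exp(best$par[seq_len(nedge)])
  kappa_hat <- exp(best$par[nedge + 1L])
  om_hat <- exp(best$par[nedge + 1L + seq_len(nom)])
  saturated <- any(t_hat > 29)

  # dS / dN decomposition
  gen_neutral <- mg94_generator(kappa_hat, 1, tfreq)
  s_prop <- gen_neutral$rho_s          # synonymous opportunity
  s_sites <- 3 * s_prop
  edge_tab <- data.frame(parent = work$edge[, 1L], child = work$edge[, 2L],
                         tip = ifelse(work$edge[, 2L] <= ntip,
                                      work$tip.label[work$edge[, 2L]], NA),
                         t = t_hat, omega = om_hat[oclass])
  rho_s_e <- vapply(om_hat, function(o)
    mg94_generator(kappa_hat, o, tfreq)$rho_s, numeric(1L))[oclass]
  edge_tab$dS <- t_hat * rho_s_e / s_sites
  edge_tab$dN <- t_hat * (1 - rho_s_e) / (3 - s_sites)
  structure(list(mode = mode, gene_set = aln$gene_set,
                 lnL = -best$value, kappa = kappa_hat,
                 omega = om_hat, omega_class = oclass,
                 edges = edge_tab, tree = work, pi = pi, tfreq = tfreq,
                 s_sites = s_sites,
                 convergence = best$convergence, saturated = saturated,
                 foreground = if (mode == "two_ratio") which(oclass == 2L)),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat("<rate_result> ", x$mode, " model",
      if (nzchar(x$gene_set)) paste0(" [", x$gene_set, "]"),
      ": lnL = ", round(x$lnL, 3), ", kappa = ", round(x$kappa, 3),
      ", omega = ", paste(round(x$omega, 4), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Terminal-branch dS per taxon
#' @param fit a `rate_result` (typically free_ratio).
#' @return named numeric vector of dS on each tip's terminal branch.
#' @export
terminal_ds <- function(fit) {
  e <- fit$edges[!is.na(fit$edges$tip), ]
  stats::setNames(e$dS, e$tip)
}

#' Likelihood-ratio test between nested codon models
#'
#' @param lnl0,lnl1 log-likelihoods of the null and alternative model.
#' @param df degrees of freedom (number of extra parameters).
#' @param tolerance allowed numerical dip of lnl1 below lnl0.
#' @return upper-tail chi-squared p-value.
#' @export
lrt <- function(lnl0, lnl1, df = 1L, tolerance = 1e-3) {
  if (df < 1L) stop("df must be >= 1")
  if (lnl1 < lnl0 - tolerance)
    stop("optimizer fault: alternative lnL below null lnL (",
         lnl1, " < ", lnl0, ")")
  stat <- max(0, 2 * (lnl1 - lnl0))
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' One-ratio vs two-ratio branch-model test
#'
#' Fits the one-ratio model, then the two-ratio model warm-started from it
#' (guaranteeing the likelihood nesting), and reports the LRT.
#'
#' @inheritParams fit_codon_model
#' @return list of class `branch_model_test`: omega0 (one-ratio), omega1
#'   (foreground omega), omega_bg (background omega), lnl0, lnl1, p_value,
#'   fits.
#' @export
branch_model_test <- function(aln, tree, foreground, starts = 2L,
                              control = list()) {
  fit0 <- fit_codon_model(aln, tree, "one_ratio", starts = starts,
                          control = control)
  fit1 <- fit_codon_model(aln, tree, "two_ratio", foreground = foreground,
                          init = list(t = fit0$edges$t, kappa = fit0$kappa,
                                      omega = fit0$omega),
                          starts = 1L, control = control)
  structure(list(omega0 = unname(fit0$omega[1L]),
                 omega1 = unname(fit1$omega[2L]),
                 omega_bg = unname(fit1$omega[1L]),
                 lnl0 = fit0$lnL, lnl1 = fit1$lnL,
                 p_value = lrt(fit0$lnL, fit1$lnL, df = 1L),
                 foreground = foreground,
                 fits = list(one_ratio = fit0, two_ratio = fit1)),
            class = "branch_model_test")
}

#' @export
print.branch_model_test <- function(x, ...) {
  cat("<branch_model_test> omega0 = ", round(x$omega0, 4),
      ", omega1 = ", round(x$omega1, 4), ", p = ",
      format.pval(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Synonymous-rate ratio summaries
#'
#' `type = "group"` emits dS(focal) / dS(reference) per gene set (the
#' IR-lacking over canonical-IR comparison).  `type = "ir_sc"` emits
#' dS(IR copy) / dS(single-copy) per gene, flagged "IR-like" below 0.5 and
#' "SC-like" above 3.7.
#'
#' @param x data.frame: for "group", columns `set`, `ds_focal`,
#'   `ds_reference`; for "ir_sc", columns `gene`, `ds_ir`, `ds_sc`.
#' @param type "group" or "ir_sc".
#' @return the input with `ratio` and (for ir_sc) `flag` columns; ratios
#'   with a zero denominator are NA and flagged "undefined".
#' @export
ds_summary <- function(x, type = c("group", "ir_sc")) {
  type <- match.arg(type)
  x <- as.data.frame(x)
  if (type == "group") {
    stopifnot(all(c("set", "ds_focal", "ds_reference") %in% names(x)))
    x$ratio <- ifelse(x$ds_reference > 0, x$ds_focal / x$ds_reference, NA)
  } else {
    stopifnot(all(c("gene", "ds_ir", "ds_sc") %in% names(x)))
    x$ratio <- ifelse(x$ds_sc > 0, x$ds_ir / x$ds_sc, NA)
    x$flag <- ifelse(is.na(x$ratio), "undefined",
                     ifelse(x$ratio < 0.5, "IR-like",
                            ifelse(x$ratio > 3.7, "SC-like", "intermediate")))
  }
  x
}
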