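# End-to-end orchestration: from annotated genomes, a tree and group labels
# to the per-taxon comparative variables (dispersed/tandem repeat numbers,
# rearrangement distance, indel/SNV frequencies, GC, CDS GC, GC3, dS) and
# the phylogenetically corrected tests, plus the reporting helpers that
# label selection-pressure changes.

#' Default run parameters
#'
#' Defaults equal the standard plastome repeat-census settings: dispersed
#' repeats >= 30 bp with 0% mismatch; SSR minimum unit counts
#' 1-10 2-6 3-5 4-5 5-5 6-5 with a 100 bp compound interruption; 500 bp
#' repeat/inversion association window.
#'
#' @param min_repeat_len minimum dispersed repeat length (bp).
#' @param ssr_min_units SSR unit-count minima for unit sizes 1..6.
#' @param ssr_interrupt compound-SSR interruption (bp).
#' @param assoc_window repeat/inversion association window (bp).
#' @param n_sim phylogenetic-ANOVA simulation count.
#' @param seed RNG seed for the stochastic tests.
#' @return list of class `run_params`.
#' @export
run_params <- function(min_repeat_len = 30L,
                       ssr_min_units = c(10L, 6L, 5L, 5L, 5L, 5L),
                       ssr_interrupt = 100L, assoc_window = 500L,
                       n_sim = 1000L, seed = 1L) {
  structure(list(min_repeat_len = min_repeat_len,
                 ssr_min_units = ssr_min_units,
                 ssr_interrupt = ssr_interrupt,
                 assoc_window = assoc_window, n_sim = n_sim, seed = seed),
            class = "run_params")
}

#' Run the full plastome comparison
#'
#' Computes the per-taxon comparative variables from annotated records
#' (IRs collapsed first), the rearrangement distance of each taxon against
#' the reference gene order (minimized over the reference's SSC isomers when
#' a partition is available), indel/SNV frequencies from the supplied
#' per-class alignments, GC statistics, and terminal-branch dS and omega
#' from a free-ratio codon-model fit; then runs the phylogenetic t-test per
#' variable (group 0 vs group 1), the phylogenetic regressions, and (when
#' three groups are present) the phylogenetic ANOVA with post-hoc tests.
#'
#' @param records named list of `genome_record`.
#' @param tree rooted `ape::phylo`, tips = record names.
#' @param groups named character vector per taxon, levels among
#'   "IR_lacking", "IR_present", "CRCIR".
#' @param reference taxon id used as rearrangement/variation reference.
#' @param class_alignments named list (protein_coding, rRNA, intergenic) of
#'   alignments (named character vectors including all taxa); optional.
#' @param codon_aln a [codon_alignment()] over all taxa, for dS/omega;
#'   optional.
#' @param params a [run_params()].
#' @return list of class `comparison_bundle`: traits, ttests, pgls, anova,
#'   structure (per-taxon scenario/association details), params.
#' @export
run_comparison <- function(records, tree, groups, reference,
                           class_alignments = NULL, codon_aln = NULL,
                           params = run_params()) {
  taxa <- names(records)
  if (is.null(taxa)) stop("records must be named")
  missing_tree <- setdiff(taxa, tree$tip.label)
  if (length(missing_tree))
    stop("taxa missing from tree: ", paste(missing_tree, collapse = ", "))
  if (!all(taxa %in% names(groups)))
    stop("taxa missing from groups: ",
         paste(setdiff(taxa, names(groups)), collapse = ", "))
  if (!reference %in% taxa) stop("reference not among records")

  collapsed <- lapply(records, function(r) {
    part <- r$partition
    if (is.null(part)) part <- tryCatch(partition_regions(r),
                                        error = function(e) NULL)
    r$partition <- part
    if (!is.null(part) && identical(part$ir_status, "both"))
      suppressWarnings(collapse_ir(r)) else r
  })

  orders <- shared_locus_order(collapsed, reference)
  ref_rec <- collapsed[[reference]]
  ssc_loci <- character(0)
  if (!is.null(ref_rec$partition) && !is.null(ref_rec$partition$ssc)) {
    fref <- ref_rec$features
    iv <- ref_rec$partition$ssc
    ssc_loci <- canonical_locus(
      fref$locus[fref$start >= iv[1L] & fref$end <= iv[2L]])
  }

  struct <- list()
  traits <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    rec <- collapsed[[tx]]
    reps <- filter_redundant_repeats(
      find_dispersed_repeats(rec$sequence, params$min_repeat_len))
    ssrs <- find_ssrs(rec$sequence, params$ssr_min_units,
                      params$ssr_interrupt)
    dist_info <- if (tx == reference) {
      list(distance = 0L,
           permutation = seq_along(orders[[tx]]))
    } else if (length(ssc_loci)) {
      tryCatch(best_ssc_isomer(orders[[tx]], orders[[reference]], ssc_loci),
               error = function(e)
                 list(distance = reversal_distance(
                   to_signed_permutation(orders[[tx]], orders[[reference]]),
                   scenario = FALSE)$distance,
                   permutation = to_signed_permutation(
                     orders[[tx]], orders[[reference]])))
    } else {
      p <- to_signed_permutation(orders[[tx]], orders[[reference]])
      c(reversal_distance(p, scenario = FALSE), list(permutation = p))
    }
    # map an optimal scenario onto intervals and associate repeats
    assoc <- NULL
    inv_tab <- NULL
    if (dist_info$distance > 0L) {
      perm <- dist_info$permutation
      scen <- reversal_distance(perm, scenario = TRUE)$scenario
      f1 <- rec$features[!duplicated(rec$features$feature_id), , drop = FALSE]
      f1$canon <- canonical_locus(f1$locus)
      bare <- sub("^-", "", orders[[tx]])
      lc <- f1[match(bare, f1$canon), c("canon", "start", "end")]
      names(lc)[1L] <- "locus"
      inv_tab <- map_reversals_to_intervals(scen, lc)
      assoc <- associate_repeats_with_inversions(
        reps, data.frame(start_bp = inv_tab$start_bp,
                         end_bp = inv_tab$end_bp),
        window = params$assoc_window)
    }
    struct[[tx]] <- list(distance = dist_info$distance,
                         inversions = inv_tab, association = assoc)
    classes <- sequence_classes(rec)
    cu <- rscu(classes$protein_coding)
    traits$dispersed_repeat_n[i] <- nrow(reps$families)
    traits$tandem_repeat_n[i] <- tandem_repeat_count(ssrs)
    traits$rearrangement_distance[i] <- dist_info$distance
    traits$gc[i] <- gc_content(rec$sequence)
    traits$gc_cds[i] <- cu$gc
    traits$gc3[i] <- cu$gc3
    if (!is.null(class_alignments)) {
      cv <- class_variation_stats(class_alignments, tx, reference,
                                  total_len = nchar(rec$sequence))
      traits$indel_freq[i] <- sum(cv$indel_bases) / nchar(rec$sequence)
      traits$snv_freq[i] <- sum(cv$snv_sites) / nchar(rec$sequence)
    }
  }

  if (!is.null(codon_aln)) {
    fit <- fit_codon_model(codon_aln, ape::keep.tip(tree, taxa),
                           mode = "free_ratio", starts = 1L)
    ds <- terminal_ds(fit)
    e <- fit$edges[!is.na(fit$edges$tip), ]
    om <- stats::setNames(e$omega, e$tip)
    traits$dS <- unname(ds[taxa])
    traits$omega <- unname(om[taxa])
  }
  traits$group <- unname(groups[taxa])

  vars <- intersect(c("dispersed_repeat_n", "tandem_repeat_n",
                      "rearrangement_distance", "indel_freq", "snv_freq",
                      "gc", "gc_cds", "gc3", "dS"), names(traits))

  # phylogenetic t-tests: IR-lacking (0) vs CRCIR (1)
  tt_taxa <- taxa[groups[taxa] %in% c("IR_lacking", "CRCIR")]
  ttests <- list()
  if (length(unique(groups[tt_taxa])) == 2L && length(tt_taxa) >= 3L) {
    g01 <- as.numeric(groups[tt_taxa] == "CRCIR")
    for (v in vars) {
      yv <- stats::setNames(traits[[v]][match(tt_taxa, traits$taxon)],
                            tt_taxa)
      ttests[[v]] <- tryCatch(phylo_ttest(yv, g01, tree),
                              error = function(e) e)
    }
  }

  # phylogenetic regressions
  pgls_res <- list()
  tv <- function(v) stats::setNames(traits[[v]], traits$taxon)
  if (all(c("dispersed_repeat_n", "rearrangement_distance") %in% vars))
    pgls_res$repeats_vs_distance <- tryCatch(
      pgls(tv("rearrangement_distance"), tv("dispersed_repeat_n"), tree),
      error = function(e) e)
  if ("omega" %in% names(traits))
    pgls_res$distance_vs_omega <- tryCatch(
      pgls(tv("omega"), tv("rearrangement_distance"), tree),
      error = function(e) e)
  # repeat length vs inversion length across taxa with associated repeats
  pairs_tab <- do.call(rbind, lapply(taxa, function(tx) {
    st <- struct[[tx]]
    if (is.null(st$association) || !nrow(st$association$hits)) return(NULL)
    pi_ <- st$association$per_inversion
    hit <- pi_[!is.na(pi_$longest_repeat), , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    best <- hit[which.max(hit$longest_repeat), ]
    data.frame(taxon = tx, repeat_len = best$longest_repeat,
               inversion_len = st$inversions$length_bp[best$inversion])
  }))
  if (!is.null(pairs_tab) && nrow(pairs_tab) >= 3L) {
    yv <- stats::setNames(pairs_tab$inversion_len, pairs_tab$taxon)
    xv <- stats::setNames(as.numeric(pairs_tab$repeat_len), pairs_tab$taxon)
    pgls_res$repeat_len_vs_inversion_len <- tryCatch(
      pgls(yv, xv, tree), error = function(e) e)
  }

  # three-group phylogenetic ANOVA
  anova_res <- list()
  if (length(unique(groups[taxa])) >= 3L) {
    for (v in vars) {
      yv <- tv(v)
      anova_res[[v]] <- tryCatch(
        phylo_anova(yv, groups[taxa], tree, n_sim = params$n_sim,
                    seed = params$seed + match(v, vars)),
        error = function(e) e)
    }
  }

  structure(list(traits = traits, ttests = ttests, pgls = pgls_res,
                 anova = anova_res, structure = struct, params = params,
                 reference = reference),
            class = "comparison_bundle")
}

#' Label selection direction and change from branch-model estimates
#'
#' Direction: "Negative" (purifying) when the omegas are below 1, "Positive"
#' when the foreground omega exceeds 1.  Change: "relaxation" when the
#' foreground omega is closer to 1 than the background (selection weakened),
#' "intensification" when farther.  Significance from the LRT p-value.
#'
#' @param omega0 one-ratio (background) omega estimate.
#' @param omega1 two-ratio foreground omega estimate.
#' @param p LRT p-value.
#' @param alpha significance level.
#' @return data.frame (significance, selection, change), vectorized.
#' @export
label_selection <- function(omega0, omega1, p, alpha = 0.05) {
  sig <- ifelse(p < alpha, "significant", "not significant")
  sel <- ifelse(omega1 > 1, "Positive", "Negative")
  chg <- ifelse(abs(omega1 - 1) < abs(omega0 - 1), "relaxation",
                ifelse(abs(omega1 - 1) > abs(omega0 - 1),
                       "intensification", ""))
  data.frame(significance = sig, selection = sel, change = chg,
             stringsAsFactors = FALSE)
}

#' Render a human-readable summary of a comparison bundle
#'
#' @param bundle output of [run_comparison()].
#' @return character vector of report lines (also printed).
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "comparison_bundle"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  add("Plastome comparison report")
  add("==========================")
  add("taxa: ", nrow(bundle$traits), "; reference: ", bundle$reference)
  add("")
  add("Per-taxon variables:")
  tr <- bundle$traits
  num <- vapply(tr, is.numeric, logical(1L))
  tr[num] <- lapply(tr[num], function(x) signif(x, 4))
  add(paste(utils::capture.output(print(tr, row.names = FALSE)),
            collapse = "\n"))
  if (length(bundle$ttests)) {
    add("")
    add("Phylogenetic t-tests (group 0 = IR-lacking, 1 = CRCIR):")
    for (v in names(bundle$ttests)) {
      t <- bundle$ttests[[v]]
      if (inherits(t, "error")) add("  ", v, ": failed (", conditionMessage(t), ")")
      else add(sprintf("  %-24s effect = %9.4g  t = %7.3f  p = %.4g",
                       v, t$estimate, t$statistic, t$p))
    }
  }
  if (length(bundle$pgls)) {
    add("")
    add("Phylogenetic regressions:")
    for (v in names(bundle$pgls)) {
      t <- bundle$pgls[[v]]
      if (inherits(t, "error")) add("  ", v, ": failed (", conditionMessage(t), ")")
      else add(sprintf("  %-32s slope = %9.4g  p = %.4g", v, t$estimate, t$p))
    }
  }
  if (length(bundle$anova)) {
    add("")
    add("Phylogenetic ANOVA (simulation p):")
    for (v in names(bundle$anova)) {
      t <- bundle$anova[[v]]
      if (inherits(t, "error")) add("  ", v, ": failed (", conditionMessage(t), ")")
      else add(sprintf("  %-24s F = %8.3f  p = %.4g", v, t$F, t$p))
    }
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}

#' Curated inversion coordinates with boundary-repeat lengths
#'
#' Published inversion sites (flanking-breakpoint convention a-b, length
#' b - a) and the lengths of dispersed repeats found within 500 bp of the
#' endpoints, for IR-lacking plastome lineages.  Used as worked examples for
#' the coordinate-convention and association rules.
#'
#' @return data.frame (species, start, end, length, repeat_lengths).
#' @export
load_inversion_sites <- function() {
  path <- system.file("extdata", "inversion_sites.tsv",
                      package = "plastcomp", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Curated branch-model selection-test results
#'
#' Published one-ratio / two-ratio omega estimates with LRT p-values and
#' their selection/change labels per IR-lacking lineage; used as worked
#' examples for the labeling rule.
#'
#' @return data.frame (lineage, omega0, omega1, p_value, significance,
#'   selection, change).
#' @export
load_selection_tests <- function() {
  path <- system.file("extdata", "selection_tests.tsv",
                      package = "plastcomp", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
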