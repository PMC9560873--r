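# Codon alignments, back-translation, gene classification, codon-model
# fitting, and likelihood-ratio tests.

test_that("back-translation preserves frame and round-trips", {
  out <- back_translate(c(t1 = "MK"), c(t1 = "ATGAAA"))
  expect_identical(unname(out$seqs["t1"]), "ATGAAA")
  out2 <- back_translate(c(t1 = "M-K"), c(t1 = "ATGAAA"))
  expect_identical(unname(out2$seqs["t1"]), "ATG---AAA")
  # trailing stop dropped; mismatches are named with a position
  out3 <- back_translate(c(t1 = "MK"), c(t1 = "ATGAAATAA"))
  expect_identical(unname(out3$seqs["t1"]), "ATGAAA")
  expect_error(back_translate(c(t1 = "MM"), c(t1 = "ATGAAA")), "position 2")
  expect_error(back_translate(c(t1 = "MKK"), c(t1 = "ATGAAA")),
               "length mismatch")
  # random protein/CDS pairs: translate(back_translate(x)) = protein
  set.seed(6)
  sense <- setdiff(plastcomp:::sense_codons(), "ATG")
  for (i in 1:10) {
    n <- sample(20:60, 1)
    cds <- paste0("ATG", paste(sample(sense, n, replace = TRUE),
                               collapse = ""))
    prot <- translate_cds(cds)
    gapped <- strsplit(prot, "")[[1]]
    ins <- sort(sample(length(gapped) + 1, 3))
    for (k in rev(ins)) gapped <- append(gapped, "-", after = k - 1)
    pa <- paste(gapped, collapse = "")
    bt <- back_translate(stats::setNames(pa, "x"),
                         stats::setNames(cds, "x"))
    expect_identical(translate_cds(gsub("-", "", bt$seqs[["x"]])), prot)
  }
})

test_that("codon alignments validate frame and sense codons", {
  expect_error(codon_alignment(c(a = "ATGA")), "divisible")
  expect_error(codon_alignment(c(a = "ATGTAAAAA")), "stop codon")
  a <- codon_alignment(c(a = "ATG---AAA", b = "ATGCCCAAA"))
  expect_equal(a$n_codons, 3L)
})

test_that("gene classification reproduces the eleven single-copy sets", {
  cl <- classify_genes(c("accD", "rbcL", "atpA", "psaB", "psbA", "rpoC1",
                         "rps12", "ndhB", "ycf1", "petD", "chlB", "rpl2"),
                       "angiosperm")
  expect_identical(cl$class[cl$gene == "accD"], "other-HK")
  expect_identical(cl$class[cl$gene == "rbcL"], "other-PS")
  expect_identical(cl$class[cl$gene == "atpA"], "atp")
  expect_identical(cl$class[cl$gene == "psaB"], "psa")
  expect_identical(cl$class[cl$gene == "psbA"], "psb")
  expect_identical(cl$class[cl$gene == "chlB"], "chl")
  # angiosperm IR set includes rpl2 and ycf1; gymnosperm set does not
  expect_true(cl$ir_gene[cl$gene == "rpl2"])
  expect_true(cl$ir_gene[cl$gene == "ycf1"])
  clg <- classify_genes(c("ndhB", "rpl2", "ycf1", "rps7"), "gymnosperm")
  expect_true(clg$ir_gene[clg$gene == "ndhB"])
  expect_false(clg$ir_gene[clg$gene == "rpl2"])
  expect_false(clg$ir_gene[clg$gene == "ycf1"])
  expect_warning(classify_genes("mysteryORF", "angiosperm"), "unclassified")
})

test_that("identical sequences fit to zero branch lengths and dS = dN = 0", {
  a <- codon_alignment(c(t1 = "ATGAAACCCGGGTTTGCA", t2 = "ATGAAACCCGGGTTTGCA"))
  tr <- ape::read.tree(text = "(t1:0.1,t2:0.1);")
  fit <- fit_codon_model(a, tr, "one_ratio", starts = 1)
  expect_lt(max(fit$edges$dS), 1e-4)
  expect_lt(max(fit$edges$dN), 1e-4)
})

test_that("simulate-and-refit recovers omega and likelihoods nest", {
  set.seed(31)
  tree <- ape::rtree(6)
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.25)
  sim <- simulate_codon_evolution(tree, n_codons = 600, kappa = 2,
                                  omega = 0.25, seed = 77)
  f1 <- fit_codon_model(sim$alignment, tree, "one_ratio", starts = 1)
  expect_lt(abs(f1$omega - 0.25), 0.08)
  expect_lt(abs(f1$kappa - 2), 0.6)
  f2 <- fit_codon_model(sim$alignment, tree, "two_ratio",
                        foreground = tree$tip.label[1:2],
                        init = list(t = f1$edges$t, kappa = f1$kappa,
                                    omega = f1$omega), starts = 1)
  f3 <- fit_codon_model(sim$alignment, tree, "free_ratio",
                        init = list(t = f2$edges$t, kappa = f2$kappa,
                                    omega = mean(f2$omega)), starts = 1)
  expect_gte(f2$lnL, f1$lnL - 1e-3)
  expect_gte(f3$lnL, f2$lnL - 1e-3)
})

test_that("an omega = 0 branch produces no nonsynonymous change", {
  tree <- ape::read.tree(text = "(a:0.3,b:0.3);")
  sim <- simulate_codon_evolution(tree, n_codons = 400, kappa = 2,
                                  omega = 1e-9, seed = 5)
  expect_equal(sum(sim$events$nonsyn), 0L)
  expect_gt(sum(sim$events$syn), 0L)
})

test_that("substitution counts scale with branch length", {
  tree1 <- ape::read.tree(text = "(a:0.1,b:0.1);")
  tree2 <- ape::read.tree(text = "(a:0.2,b:0.2);")
  n1 <- n2 <- 0
  for (i in 1:5) {
    n1 <- n1 + sum(simulate_codon_evolution(tree1, 500, seed = 100 + i)$events[, c("syn", "nonsyn")])
    n2 <- n2 + sum(simulate_codon_evolution(tree2, 500, seed = 200 + i)$events[, c("syn", "nonsyn")])
  }
  # doubling branch lengths doubles the expected count (Poisson tolerance)
  expect_gt(n2 / n1, 1.6)
  expect_lt(n2 / n1, 2.4)
})

test_that("LRT follows the chi-squared tail and rejects optimizer faults", {
  expect_equal(lrt(-100, -100, 1), 1)
  expect_equal(lrt(0, 3.841 / 2, 1), 0.05, tolerance = 1e-3)
  # same regime as a non-significant branch test (2*Delta = 0.27)
  expect_equal(lrt(0, 0.135, 1), 0.603, tolerance = 1e-2)
  expect_error(lrt(-10, -20, 1), "optimizer fault")
  expect_error(lrt(-10, -9, 0), "df")
})

test_that("branch test recovers an elevated foreground omega", {
  set.seed(33)
  tree <- ape::rtree(6)
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.2)
  fg <- tree$tip.label[1:2]
  om <- stats::setNames(c(0.8, 0.8, 0.15), c(fg, "default"))
  sim <- simulate_codon_evolution(tree, n_codons = 500, kappa = 2,
                                  omega = om, seed = 41)
  bt <- branch_model_test(sim$alignment, tree, foreground = fg, starts = 1)
  expect_gt(bt$omega1, bt$omega_bg)
  expect_lt(bt$p_value, 0.05)
})

test_that("dS ratio summaries flag IR-like and SC-like genes", {
  x <- data.frame(set = c("atp", "rps"), ds_focal = c(2, 1),
                  ds_reference = c(1, 0))
  out <- ds_summary(x, "group")
  expect_equal(out$ratio, c(2, NA))
  y <- data.frame(gene = c("rpl2", "ndhB", "rps7", "ycf2"),
                  ds_ir = c(0.4, 4, 1, 0.2), ds_sc = c(1, 1, 1, 0))
  out2 <- ds_summary(y, "ir_sc")
  expect_identical(out2$flag, c("IR-like", "SC-like", "intermediate",
                                "undefined"))
  # equal rates give ratios of exactly 1
  z <- ds_summary(data.frame(set = "psb", ds_focal = 0.3,
                             ds_reference = 0.3), "group")
  expect_equal(z$ratio, 1)
})
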