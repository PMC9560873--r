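# Generator determinism and ground-truth integrity.

test_that("generators are pure functions of configuration and seed", {
  cfg <- sim_config(seed = 19, ir_kb = 5, n_lsc_genes = 15L, n_ssc_genes = 6L)
  a <- simulate_plastome(cfg)
  b <- simulate_plastome(cfg)
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$record$features, b$record$features)
  rec <- a$record
  inv1 <- apply_inversions(rec, 2, seed = 4)
  inv2 <- apply_inversions(rec, 2, seed = 4)
  expect_identical(inv1$record$sequence, inv2$record$sequence)
  expect_identical(inv1$events, inv2$events)
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  s1 <- simulate_codon_evolution(tr, 100, seed = 2)
  s2 <- simulate_codon_evolution(tr, 100, seed = 2)
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  y1 <- simulate_brownian_traits(tr, 1, seed = 3)
  y2 <- simulate_brownian_traits(tr, 1, seed = 3)
  expect_identical(y1, y2)
})

test_that("inversion events land at gene boundaries with the breakpoint convention", {
  sim <- base_sim()
  rec <- sim$record
  rec$partition <- partition_regions(rec)
  col <- suppressWarnings(collapse_ir(rec))
  out <- apply_inversions(col, k = 4, fraction_repeat_mediated = 0.5,
                          repeat_len = 40, seed = 23)
  ev <- out$events
  expect_equal(nrow(ev), 4L)
  expect_equal(ev$length_bp, ev$end_bp - ev$start_bp)
  expect_true(all(ev$length_bp > 0))
  # no feature may straddle an event breakpoint
  f <- out$record$features
  for (r in seq_len(nrow(ev))) {
    expect_false(any(f$start < ev$start_bp[r] & f$end > ev$start_bp[r]))
    expect_false(any(f$start < ev$end_bp[r] & f$end > ev$end_bp[r]))
  }
  # k = 0 leaves the record untouched
  same <- apply_inversions(col, 0)
  expect_identical(same$record$sequence, col$sequence)
  expect_error(apply_inversions(col, 1000, seed = 1), "too large")
})

test_that("repeat-mediated events are recovered by the 500-bp association rule", {
  sim <- base_sim()
  rec <- sim$record
  rec$partition <- partition_regions(rec)
  col <- suppressWarnings(collapse_ir(rec))
  out <- apply_inversions(col, k = 3, fraction_repeat_mediated = 1,
                          repeat_len = 40, seed = 29)
  reps <- find_dispersed_repeats(out$record$sequence, 30)
  assoc <- associate_repeats_with_inversions(
    reps, data.frame(start_bp = out$events$start_bp,
                     end_bp = out$events$end_bp), window = 500)
  expect_true(all(assoc$per_inversion$n_families >= 1))
  # the planted pair flanks the segment: endpoint distances are zero
  med <- which(out$events$repeat_mediated)
  for (iv in med) {
    h <- assoc$hits[assoc$hits$inversion == iv, ]
    expect_true(any(h$dist_start == 0 & h$dist_end == 0))
  }
})

test_that("codon simulation exposes true per-branch rates", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.2);")
  sim <- simulate_codon_evolution(tr, 500, kappa = 2, omega = 0.2, seed = 37)
  expect_equal(length(sim$true_ds), nrow(tr$edge))
  expect_true(all(sim$true_ds > 0))
  # realized synonymous events per codon are near the branch expectation
  exp_syn <- sum(tr$edge.length * 500 *
                   plastcomp:::mg94_generator(2, 0.2,
                                              rep(0.25, 12))$rho_s)
  expect_gt(sum(sim$events$syn), exp_syn * 0.6)
  expect_lt(sum(sim$events$syn), exp_syn * 1.4)
})

test_that("synthetic_study assembles a consistent bundle", {
  st <- synthetic_study(seed = 3,
                        n_per_group = c(IR_lacking = 2L, IR_present = 2L,
                                        CRCIR = 2L),
                        n_codons = 60L)
  expect_setequal(names(st$records), st$tree$tip.label)
  expect_setequal(names(st$records), names(st$groups))
  expect_true(st$reference %in% names(st$records))
  # IR-lacking records have no long inverted duplication; others do
  for (tx in names(st$records)) {
    part <- partition_regions(st$records[[tx]], 1000)
    if (st$groups[tx] == "IR_lacking")
      expect_identical(part$ir_status, "none")
    else expect_identical(part$ir_status, "both")
  }
  # alignments cover every taxon and include the reference row
  for (cl in names(st$class_alignments)) {
    expect_setequal(names(st$class_alignments[[cl]]), names(st$records))
  }
  expect_s3_class(st$codon_aln, "codon_alignment")
  # same seed, same bundle
  st2 <- synthetic_study(seed = 3,
                         n_per_group = c(IR_lacking = 2L, IR_present = 2L,
                                         CRCIR = 2L),
                         n_codons = 60L)
  expect_identical(st$records[[1]]$sequence, st2$records[[1]]$sequence)
  expect_identical(st$codon_aln$seqs, st2$codon_aln$seqs)
})
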