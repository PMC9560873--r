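# Annotated-plastome I/O, quadripartite partitioning and IR collapsing.

test_that("GenBank coordinate conventions round-trip", {
  # minimal hand-written record: 1-based inclusive 1..6 on plus strand
  gb <- c("LOCUS       mini 12 bp    DNA     circular PLN",
          "FEATURES             Location/Qualifiers",
          "     source          1..12",
          "     CDS             1..6",
          '                     /gene="demo"',
          "ORIGIN",
          "        1 atggcataaa cg",
          "//")
  f <- tempfile(fileext = ".gb")
  writeLines(gb, f)
  rec <- read_genbank(f)
  expect_equal(rec$sequence, "ATGGCATAAACG")
  expect_equal(rec$features$start, 0L)   # [0, 6) internally
  expect_equal(rec$features$end, 6L)
  expect_equal(rec$features$strand, "+")
  expect_true(rec$circular)

  # full round trip on a generated record incl. minus-strand features
  rec2 <- base_sim()$record
  f2 <- tempfile(fileext = ".gb")
  write_genbank(rec2, f2)
  rt <- read_genbank(f2)
  expect_identical(rt$sequence, rec2$sequence)
  cols <- c("locus", "kind", "strand", "start", "end", "pseudo")
  a <- rec2$features[order(rec2$features$start, rec2$features$locus), cols]
  b <- rt$features[order(rt$features$start, rt$features$locus), cols]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("join locations become multi-interval features and pseudo is kept", {
  gb <- c("LOCUS       j 30 bp    DNA     linear PLN",
          "FEATURES             Location/Qualifiers",
          "     CDS             complement(join(3..8,13..21))",
          '                     /gene="split"',
          "                     /pseudo",
          "ORIGIN",
          "        1 acgtacgtac gtacgtacgt acgtacgtac",
          "//")
  f <- tempfile(fileext = ".gb")
  writeLines(gb, f)
  rec <- read_genbank(f)
  expect_equal(nrow(rec$features), 2L)
  expect_equal(length(unique(rec$features$feature_id)), 1L)
  expect_equal(rec$features$start, c(2L, 12L))
  expect_equal(rec$features$end, c(8L, 21L))
  expect_true(all(rec$features$strand == "-"))
  expect_true(all(rec$features$pseudo))
})

test_that("malformed or empty GenBank input is rejected with a parse error", {
  f <- tempfile()
  writeLines(c("not a genbank file"), f)
  expect_error(read_genbank(f), "LOCUS")
  writeLines(c("LOCUS x 0 bp", "ORIGIN", "//"), f)
  expect_error(read_genbank(f), "zero-length")
})

test_that("gene census counts distinct features by kind", {
  rec <- base_sim()$record
  cen <- gene_census(rec)
  # 20 LSC + 8 SSC single-copy CDS + 6 IR CDS x 2 copies
  expect_equal(unname(cen$counts["CDS"]), 20L + 8L + 12L)
  expect_equal(unname(cen$counts["rRNA"]), 8L)    # 4 rRNAs x 2 copies
  expect_equal(unname(cen$counts["tRNA"]), 4L)
  expect_setequal(names(cen$table),
                  c("record_id", "locus", "kind", "strand", "start", "end",
                    "pseudo"))
})

test_that("partition recovers planted quadripartite boundaries exactly", {
  sim <- base_sim()
  part <- partition_regions(sim$record, min_ir_len = 1000L)
  expect_identical(part$ir_status, "both")
  expect_identical(part$ir_a, sim$truth$intervals$ir_a)
  expect_identical(part$ir_b, sim$truth$intervals$ir_b)
  expect_identical(part$lsc, sim$truth$intervals$lsc)
  expect_identical(part$ssc, sim$truth$intervals$ssc)
  # IR_A must be the exact reverse complement of IR_B
  s <- sim$record$sequence
  ira <- substr(s, part$ir_a[1] + 1, part$ir_a[2])
  irb <- substr(s, part$ir_b[1] + 1, part$ir_b[2])
  expect_identical(ira, revcomp(irb))
})

test_that("partition recovery holds across seeded genomes (5-30 kb IRs)", {
  for (i in 1:25) {
    cfg <- sim_config(seed = 100 + i, ir_kb = sample(5:30, 1),
                      n_lsc_genes = 18L, n_ssc_genes = 6L)
    sim <- simulate_plastome(cfg)
    part <- partition_regions(sim$record, min_ir_len = 1000L)
    expect_identical(part$ir_a, sim$truth$intervals$ir_a, info = i)
    expect_identical(part$ir_b, sim$truth$intervals$ir_b, info = i)
  }
})

test_that("genomes without a long inverted duplication get ir_status none", {
  s <- random_seq(20000, seed = 3)
  rec <- genome_record("r", s)
  part <- partition_regions(rec, min_ir_len = 1000L)
  expect_identical(part$ir_status, "none")
})

test_that("collapse_ir removes exactly IR_B, deduplicates IR genes, and is idempotent", {
  sim <- base_sim()
  rec <- sim$record
  rec$partition <- partition_regions(rec)
  col <- collapse_ir(rec)
  irb_len <- rec$partition$ir_b[2] - rec$partition$ir_b[1]
  expect_equal(nchar(col$sequence), nchar(rec$sequence) - irb_len)
  expect_equal(sum(col$features$locus == "trnI-GAU"), 1L)
  expect_equal(sum(col$features$locus == "rrn16"), 1L)
  expect_identical(col$partition$ir_status, "B_lost")
  # idempotent: collapsing again is a warning no-op
  expect_warning(col2 <- collapse_ir(col), "ir_status")
  expect_identical(col2$sequence, col$sequence)
  # a record with no IR passes through unchanged
  rec0 <- genome_record("r", random_seq(5000, seed = 4))
  expect_warning(out <- collapse_ir(rec0, min_ir_len = 1000L), "none")
  expect_identical(out$sequence, rec0$sequence)
})

test_that("lost IR copy is classified against a canonical reference", {
  ref <- base_sim()$record
  ref$partition <- partition_regions(ref)
  cfgA <- sim_config(seed = 7, ir_kb = 6, n_lsc_genes = 20L, n_ssc_genes = 8L,
                     ir_deleted = "A")
  cfgB <- sim_config(seed = 7, ir_kb = 6, n_lsc_genes = 20L, n_ssc_genes = 8L,
                     ir_deleted = "B")
  expect_identical(classify_ir_loss(simulate_plastome(cfgA)$record, ref),
                   "A_lost")
  expect_identical(classify_ir_loss(simulate_plastome(cfgB)$record, ref),
                   "B_lost")
})

test_that("shared locus order restricts to single-copy shared loci with signs", {
  sim <- base_sim()
  rec <- sim$record
  rec$partition <- partition_regions(rec)
  col <- collapse_ir(rec)
  # identical records: identical all-positive lists
  ords <- shared_locus_order(list(a = col, b = col), "a")
  expect_identical(ords$a, ords$b)
  expect_false(any(startsWith(ords$a, "-")))
  # one block reverse-complemented: loci negated and order-reversed
  inv <- apply_inversions(col, k = 1, fraction_repeat_mediated = 0,
                          seed = 5)
  ords2 <- shared_locus_order(list(a = col, b = inv$record), "a")
  changed <- which(ords2$b != ords2$a)
  expect_true(length(changed) >= 1L)
  expect_true(all(startsWith(ords2$b[changed], "-")))
  expect_identical(sub("^-", "", ords2$b[changed]),
                   rev(ords2$a[changed]))
  # a locus absent from one record disappears from every output list
  drop <- col
  drop$features <- drop$features[drop$features$locus != "rbcL", ]
  ords3 <- shared_locus_order(list(a = col, b = drop), "a")
  expect_false(any(grepl("rbcl", unlist(ords3))))
  # fewer than 3 shared loci is an error
  tiny <- col
  tiny$features <- tiny$features[1:2, ]
  expect_error(shared_locus_order(list(a = col, b = tiny), "a"),
               "insufficient shared loci")
})
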