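# Dispersed-repeat detection (vs brute force), redundancy filtering, SSR
# thresholds, and repeat/inversion endpoint association.

test_that("planted direct and inverted repeats are found as families", {
  s <- random_seq(4000, seed = 11)
  u <- random_seq(40, seed = 12)
  v <- random_seq(35, seed = 13)
  substr(s, 201, 240) <- u
  substr(s, 2001, 2040) <- u
  substr(s, 1001, 1035) <- v
  substr(s, 3001, 3035) <- revcomp(v)
  reps <- find_dispersed_repeats(s, min_len = 30)
  fu <- reps$families[grepl(substr(u, 3, 38), reps$families$seq) |
                        grepl(substr(revcomp(u), 3, 38), reps$families$seq), ]
  expect_equal(nrow(fu), 1L)
  expect_identical(fu$orientation, "direct")
  expect_equal(fu$frequency, 2L)
  expect_gte(fu$length, 40L)
  fv <- reps$families[grepl(substr(v, 3, 33), reps$families$seq) |
                        grepl(substr(revcomp(v), 3, 33), reps$families$seq), ]
  expect_equal(nrow(fv), 1L)
  expect_identical(fv$orientation, "inverted")
  # random i.i.d. sequence alone: no repeat >= 30 bp
  s0 <- random_seq(10000, seed = 14)
  expect_equal(nrow(find_dispersed_repeats(s0, 30)$families), 0L)
  expect_equal(nrow(brute_repeat_pairs(s0, 30)), 0L)
  # only exact matching is supported
  expect_error(find_dispersed_repeats(s, 30, max_mismatch = 0.1),
               "unsupported")
})

test_that("detector equals the brute-force all-offset scan on planted fixtures", {
  set.seed(21)
  for (i in 1:20) {
    L <- 2500
    s <- random_seq(L)
    for (r in seq_len(sample(2:4, 1))) {
      len <- sample(30:60, 1)
      u <- random_seq(len)
      a <- sample(L - len, 1)
      b <- sample(L - len, 1)
      substr(s, a, a + len - 1) <- u
      substr(s, b, b + len - 1) <- if (runif(1) < 0.5) u else revcomp(u)
    }
    mine <- sort_pairs(plastcomp:::maximal_repeat_pairs(s, 30))
    ref <- sort_pairs(brute_repeat_pairs(s, 30))
    expect_equal(mine, ref, info = paste("fixture", i))
  }
})

test_that("ambiguous bases split candidate repeats", {
  u <- random_seq(60, seed = 31)
  u2 <- u
  substr(u2, 30, 30) <- "N"
  s <- paste0(random_seq(200, seed = 32), u, random_seq(150, seed = 33),
              u2, random_seq(200, seed = 34))
  reps <- find_dispersed_repeats(s, min_len = 20)
  # the N breaks the 60-mer into flanking exact matches only
  expect_true(all(nchar(reps$families$seq) < 60))
  expect_true(any(reps$families$length >= 20))
})

test_that("redundancy filter drops near-identical containers and absorbed children", {
  build <- function(fams, cops) {
    structure(list(families = fams, copies = cops),
              class = "dispersed_repeats")
  }
  # rule 1: 45-bp family (freq 2) containing a 40-bp family -> container dropped
  fams <- data.frame(family_id = 1:2, length = c(40L, 45L),
                     orientation = "direct", frequency = c(2L, 2L),
                     seq = c(strrep("A", 40), strrep("B", 45)))
  cops <- data.frame(family_id = c(1L, 1L, 2L, 2L),
                     start = c(2L, 102L, 0L, 100L),
                     end = c(42L, 142L, 45L, 145L), strand = "+")
  out <- filter_redundant_repeats(build(fams, cops))
  expect_identical(out$families$family_id, 1L)
  # rule 2: 60-bp family with frequency 3 absorbs its contained 30-bp family
  fams2 <- data.frame(family_id = 1:2, length = c(30L, 60L),
                      orientation = "direct", frequency = c(2L, 3L),
                      seq = c(strrep("A", 30), strrep("B", 60)))
  cops2 <- data.frame(family_id = c(1L, 1L, 2L, 2L, 2L),
                      start = c(10L, 110L, 0L, 100L, 200L),
                      end = c(40L, 140L, 60L, 160L, 260L), strand = "+")
  out2 <- filter_redundant_repeats(build(fams2, cops2))
  expect_identical(out2$families$family_id, 2L)
  # no containment: untouched, and the filter is idempotent
  s <- random_seq(3000, seed = 41)
  u <- random_seq(40, seed = 42)
  substr(s, 101, 140) <- u
  substr(s, 2001, 2040) <- u
  reps <- find_dispersed_repeats(s, 30)
  f1 <- filter_redundant_repeats(reps)
  f2 <- filter_redundant_repeats(f1)
  expect_identical(f1$families, f2$families)
  expect_identical(f1$copies, f2$copies)
})

test_that("SSR unit-size thresholds match the census definition", {
  bg <- function(core) paste0("GCTAGCTAGGATCCTTAGCGCATGCAAGTC", core,
                              "CGATCGTAGCTAGGCCTAAGCTTGGATCCA")
  cases <- list(list(strrep("A", 10), 1L, 10L, TRUE),
                list(strrep("A", 9), 1L, 9L, FALSE),
                list(strrep("AT", 6), 2L, 6L, TRUE),
                list(strrep("AT", 5), 2L, 5L, FALSE),
                list(strrep("AGC", 5), 3L, 5L, TRUE),
                list(strrep("AGC", 4), 3L, 4L, FALSE),
                list(strrep("AGCT", 5), 4L, 5L, TRUE),
                list(strrep("AGCT", 4), 4L, 4L, FALSE),
                list(strrep("AGCTC", 5), 5L, 5L, TRUE),
                list(strrep("AGCTC", 4), 5L, 4L, FALSE),
                list(strrep("AGCTTC", 5), 6L, 5L, TRUE),
                list(strrep("AGCTTC", 4), 6L, 4L, FALSE))
  for (cs in cases) {
    hits <- find_ssrs(bg(cs[[1]]))
    if (cs[[4]]) {
      expect_equal(nrow(hits), 1L, info = cs[[1]])
      expect_equal(hits$unit_size, cs[[2]])
      expect_equal(hits$n_units, cs[[3]])
      expect_equal(hits$end - hits$start, hits$unit_size * hits$n_units)
    } else {
      expect_equal(nrow(hits), 0L, info = cs[[1]])
    }
  }
})

test_that("SSR motifs are primitive and nearby SSRs form compound loci", {
  bg <- "GCTAGCTAGGATCCTTAGCGCATGCAAGTC"
  # A x 12 must not additionally be reported as (AA) x 6
  hits <- find_ssrs(paste0(bg, strrep("A", 12), bg))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit_size, 1L)
  # two SSRs 20 bp apart: compound; 150 bp apart: separate
  near <- paste0(bg, strrep("A", 10), random_seq(20, seed = 51, gc = 1),
                 strrep("CT", 7), bg)
  h2 <- find_ssrs(near)
  expect_equal(nrow(h2), 2L)
  expect_true(all(h2$compound))
  expect_equal(length(unique(h2$compound_id)), 1L)
  far <- paste0(bg, strrep("A", 10), random_seq(150, seed = 52, gc = 1),
                strrep("CT", 7), bg)
  h3 <- find_ssrs(far)
  expect_equal(nrow(h3), 2L)
  expect_false(any(h3$compound))
  expect_equal(tandem_repeat_count(h2), 2L)   # components counted separately
})

test_that("repeat copies within 500 bp of inversion endpoints are hits", {
  L <- 6000
  s <- random_seq(L, seed = 61)
  u <- random_seq(40, seed = 62)
  # inversion with endpoints at 3000 and 4500
  inv <- data.frame(start_bp = 3000L, end_bp = 4500L)
  # flanking sentinels differ between the two copies so the maximal match
  # is exactly the planted 40-mer (distances stay pinned to the bp)
  place <- function(s, at, fl) {
    substr(s, at, at) <- fl
    substr(s, at + 1, at + 40) <- u
    substr(s, at + 41, at + 41) <- fl
    s
  }
  # copy ending 499 bp before the start breakpoint: hit
  s1 <- place(place(s, 3000L - 499L - 40L, "A"), 100L, "C")
  r1 <- find_dispersed_repeats(s1, 30)
  a1 <- associate_repeats_with_inversions(r1, inv, window = 500)
  expect_gte(nrow(a1$hits), 1L)
  expect_equal(a1$per_inversion$longest_repeat[1], max(r1$families$length))
  # copy 501 bp away from both endpoints: no hit
  s2 <- place(place(s, 3000L - 501L - 40L, "A"), 5600L, "C")
  r2 <- find_dispersed_repeats(s2, 30)
  expect_gte(nrow(r2$families), 1L)
  a2 <- associate_repeats_with_inversions(r2, inv, window = 500)
  expect_equal(nrow(a2$hits), 0L)
})
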