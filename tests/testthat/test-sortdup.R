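test_that("region sorting orders by POS with content-based tie-breaks", {
  b <- read_batch(0L)
  for (spec in list(c("x", 5), c("y", 1), c("z", 3))) {
    b <- batch_append(b, to_keyed(make_rec(spec[1], pos = as.integer(spec[2]),
                                           read_len = 4L)))
  }
  s <- sort_region(batch_seal(b))
  expect_equal(s$pos, c(1L, 3L, 5L))

  tie <- read_batch(0L)
  tie <- batch_append(tie, to_keyed(make_rec("b", pos = 7L, read_len = 4L)))
  tie <- batch_append(tie, to_keyed(make_rec("a", pos = 7L, read_len = 4L)))
  s2 <- sort_region(batch_seal(tie))
  expect_equal(substr(s2$sam, 1, 1), c("a", "b"))

  expect_equal(batch_length(sort_region(batch_seal(read_batch(0L)))), 0L)
})

test_that("clip profiles sum soft/hard clips and reference consumption", {
  expect_equal(clip_profile("100M"),
               list(leading_clip = 0L, trailing_clip = 0L, ref_span = 100L))
  expect_equal(clip_profile("10S90M"),
               list(leading_clip = 10L, trailing_clip = 0L, ref_span = 90L))
  expect_equal(clip_profile("50M10D40M5S"),
               list(leading_clip = 0L, trailing_clip = 5L, ref_span = 100L))
  expect_equal(clip_profile("5H10S85M")$leading_clip, 15L)
  expect_equal(clip_profile("10M5I10M")$ref_span, 20L)  # I consumes no reference
  expect_error(clip_profile("10Q"), "CIGAR")
  expect_error(clip_profile("M10"), "CIGAR")
})

test_that("unclipped 5' coordinates undo clipping on the correct end", {
  fwd <- make_rec(pos = 1000L, cigar = "100M")
  expect_equal(unclipped_5prime(fwd)$coord, 1000L)

  clipped <- make_rec(pos = 1000L, cigar = "10S90M")
  expect_equal(unclipped_5prime(clipped)$coord, 990L)

  rev <- make_rec(pos = 1000L, flag = 0x10, cigar = "90M10S")
  e <- unclipped_5prime(rev)
  expect_equal(e$coord, 1099L)  # 1000 + 90 - 1 + 10
  expect_equal(e$strand, "R")

  # excluded records return NULL and pass through unmarked
  expect_null(unclipped_5prime(make_rec(flag = 0x4, cigar = "*")))
  expect_null(unclipped_5prime(make_rec(flag = 0x100)))
  expect_null(unclipped_5prime(make_rec(flag = 0x800)))
})

test_that("duplicate scores sum base qualities of at least 15", {
  r30 <- make_rec(qual = qual_of(rep(30L, 10)), read_len = 10L)
  expect_equal(duplicate_score(list(r30)), 300L)

  rmix <- make_rec(qual = qual_of(c(10L, 20L, 14L, 15L)), read_len = 4L)
  expect_equal(duplicate_score(list(rmix)), 35L)

  expect_equal(duplicate_score(list(r30, rmix)), 335L)

  rstar <- make_rec(read_len = 4L)
  rstar$qual <- "*"
  expect_equal(duplicate_score(list(rstar)), 0L)
})

test_that("candidate construction separates pairs, fragments and exclusions", {
  pr <- make_pair_recs("p1")
  out <- build_pair_candidates(pr)
  expect_length(out$pairs, 1)
  expect_length(out$fragments, 0)
  expect_equal(out$pairs[[1]]$orientation, "FR")

  # mate unmapped -> fragment
  solo <- make_rec("s1", flag = 0x1 + 0x8 + 0x40, pos = 500L, read_len = 10L,
                   cigar = "10M")
  out2 <- build_pair_candidates(list(solo))
  expect_length(out2$pairs, 0)
  expect_length(out2$fragments, 1)

  # supplementary alignment of a pair is excluded entirely
  supp <- make_rec("p1", flag = 0x1 + 0x20 + 0x40 + 0x800, pos = 4000L,
                   read_len = 10L, cigar = "10M")
  out3 <- build_pair_candidates(c(pr, list(supp)))
  expect_length(out3$pairs, 1)
  expect_length(out3$fragments, 0)

  # three primary records under one qname is a data-integrity error
  third <- make_rec("p1", flag = 0x1 + 0x20 + 0x40, pos = 4000L,
                    read_len = 10L, cigar = "10M", rnext = "=", pnext = 1200L)
  expect_error(build_pair_candidates(c(pr, list(third))), "data-integrity")
})

test_that("within a key group only the highest-scoring pair survives", {
  hi <- make_pair_recs("hi", pos1 = 1000L, pos2 = 1200L,
                       qual1 = qual_of(rep(30L, 10)), qual2 = qual_of(rep(30L, 10)))
  lo <- make_pair_recs("lo", pos1 = 1000L, pos2 = 1200L,
                       qual1 = qual_of(rep(20L, 10)), qual2 = qual_of(rep(20L, 10)))
  out <- build_pair_candidates(c(hi, lo))
  dec <- mark_duplicates(out$pairs, out$fragments)
  expect_equal(dec$qname, "lo")
  # agrees with the brute-force oracle
  expect_equal(sort(dec$qname), oracle_mark_duplicates(c(hi, lo)))

  # ties are broken by ascending qname: smallest kept
  twin <- make_pair_recs("aa", pos1 = 1000L, pos2 = 1200L,
                         qual1 = qual_of(rep(30L, 10)),
                         qual2 = qual_of(rep(30L, 10)))
  out2 <- build_pair_candidates(c(hi, twin))
  dec2 <- mark_duplicates(out2$pairs, out2$fragments)
  expect_equal(dec2$qname, "hi")
})

test_that("a fragment colliding with a pair end is flagged regardless of score", {
  pr <- make_pair_recs("pp", pos1 = 1000L, pos2 = 1200L,
                       qual1 = qual_of(rep(20L, 10)),
                       qual2 = qual_of(rep(20L, 10)))
  # unpaired read whose unclipped 5' equals the pair's forward end, huge score
  frag <- make_rec("ff", flag = 0L, pos = 1000L, cigar = "10M",
                   qual = qual_of(rep(40L, 10)), read_len = 10L)
  out <- build_pair_candidates(c(pr, list(frag)))
  dec <- mark_duplicates(out$pairs, out$fragments)
  expect_equal(dec$qname, "ff")
  expect_equal(dec$kind, "fragment")
  expect_equal(sort(dec$qname), oracle_mark_duplicates(c(pr, list(frag))))

  # fragment-only group: max score kept
  f2 <- make_rec("f2", flag = 0L, pos = 5000L, cigar = "10M",
                 qual = qual_of(rep(40L, 10)), read_len = 10L)
  f3 <- make_rec("f3", flag = 0L, pos = 5000L, cigar = "10M",
                 qual = qual_of(rep(20L, 10)), read_len = 10L)
  out2 <- build_pair_candidates(list(f2, f3))
  dec2 <- mark_duplicates(out2$pairs, out2$fragments)
  expect_equal(dec2$qname, "f3")
})

test_that("marks only touch FLAG and conserve everything else", {
  b <- read_batch(0L)
  for (r in c(make_pair_recs("ka", pos1 = 10L, pos2 = 60L),
              make_pair_recs("kb", pos1 = 10L, pos2 = 60L))) {
    b <- batch_append(b, to_keyed(r))
  }
  b <- batch_seal(b)

  expect_identical(apply_marks(b, character(0))$sam, b$sam)

  marked <- apply_marks(b, "kb")
  expect_equal(batch_length(marked), batch_length(b))
  changed <- which(marked$sam != b$sam)
  expect_length(changed, 2)  # both mates of kb, nothing else
  for (i in changed) {
    fo <- strsplit(b$sam[i], "\t")[[1]]
    fn <- strsplit(marked$sam[i], "\t")[[1]]
    expect_identical(fo[-2], fn[-2])
    expect_equal(bitwAnd(as.integer(fn[2]), 0x400), 0x400)
  }

  expect_error(apply_marks(b, "ghost"), "reconciliation")
})

test_that("marking equals the brute-force oracle on random synthetic regions", {
  ref <- tiny_reference()
  tab <- tiny_table(ref)
  for (seed in c(3L, 17L, 23L)) {
    rs <- simulate_read_set(ref, n_pairs = 120, dup_rate = 0.15,
                            clip_prob = 0.15, seed = seed)
    dec <- mark_duplicates_routed(rs$records, rs$header, tab)
    expect_identical(sort(unique(dec$qname)),
                     oracle_mark_duplicates(rs$records, rs$header$rg_lb,
                                            tab$contig_order$rname))
  }
})

test_that("marking is idempotent and invariant to input permutation", {
  ref <- tiny_reference()
  tab <- tiny_table(ref)
  rs <- simulate_read_set(ref, n_pairs = 120, dup_rate = 0.2, clip_prob = 0.1,
                          seed = 8)
  dec <- mark_duplicates_routed(rs$records, rs$header, tab)

  # idempotence: set 0x400 on flagged records, re-derive, same set
  marked <- lapply(rs$records, function(r) {
    if (r$qname %in% dec$qname) r$flag <- bitwOr(r$flag, 0x400L)
    r
  })
  dec2 <- mark_duplicates_routed(marked, rs$header, tab)
  expect_setequal(dec2$qname, dec$qname)

  # permutation invariance
  perm <- withr::with_seed(1, sample(length(rs$records)))
  dec3 <- mark_duplicates_routed(rs$records[perm], rs$header, tab)
  expect_setequal(dec3$qname, dec$qname)
})

test_that("per-region routed marking equals global marking", {
  ref <- tiny_reference()
  tab <- tiny_table(ref)
  rs <- simulate_read_set(ref, n_pairs = 150, dup_rate = 0.15, clip_prob = 0.1,
                          seed = 31)
  routed <- mark_duplicates_routed(rs$records, rs$header, tab)
  cands <- build_pair_candidates(rs$records, rs$header$rg_lb,
                                 tab$contig_order$rname)
  global <- mark_duplicates(cands$pairs, cands$fragments)
  expect_setequal(routed$qname, global$qname)
})

test_that("the MC tag recovers a missing mate's clipped end", {
  pr <- make_pair_recs("m1", pos1 = 1000L, pos2 = 1200L,
                       cigar2 = "8M2S")  # mate 5' = 1200 + 8 - 1 + 2 = 1209
  only_r1 <- pr[1]
  out <- build_pair_candidates(only_r1)
  expect_length(out$pairs, 1)
  expect_equal(out$pairs[[1]]$end2$coord, 1209L)
  expect_equal(attr(out, "mc_missing"), 0L)

  # without MC, PNEXT is used clip-unaware and counted
  r1_no_mc <- only_r1[[1]]
  r1_no_mc$tags <- r1_no_mc$tags[!startsWith(r1_no_mc$tags, "MC:")]
  out2 <- build_pair_candidates(list(r1_no_mc))
  expect_equal(out2$pairs[[1]]$end2$coord, 1200L)
  expect_equal(attr(out2, "mc_missing"), 1L)
})
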