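test_that("microhomology equals the junction shift-range width", {
  mh <- annotate_microhomology(
    list(event_class = "deletion", del_start = 3, del_end = 6),
    "TTTCAGCAGTTT")
  expect_equal(mh$mh_len, 3L)
  expect_equal(mh$mh_seq, "CAG")

  mh <- annotate_microhomology(
    list(event_class = "deletion", del_start = 3, del_end = 6),
    "AAACCCGGGTTT")
  expect_equal(mh$mh_len, 0L)
  expect_equal(mh$mh_seq, "")

  mh <- annotate_microhomology(
    list(event_class = "intact", del_start = 0, del_end = 0), "ACGTACGT")
  expect_equal(mh$mh_len, 0L)

  expect_error(
    annotate_microhomology(
      list(event_class = "deletion", del_start = 5, del_end = 99), "ACGTACGT"),
    "inconsistent")
})

test_that("microhomology length equals placement count minus one on random deletions", {
  withr::with_seed(31, {
    for (i in 1:200) {
      ref <- random_dna_str(50)
      L <- sample(1:8, 1)
      a <- sample(0:(50 - L), 1)
      read <- reassemble(ref, a, a + L, "")
      pl <- enumerate_placements(ref, L, "", read)
      mh <- annotate_microhomology(
        list(event_class = "deletion", del_start = min(pl$start),
             del_end = min(pl$start) + L), ref)
      expect_equal(mh$mh_len, nrow(pl) - 1L)
    }
  })
})

test_that("template search finds planted direct and reverse copies", {
  loc <- test_locus()
  cut <- loc$cut_pos
  word <- substr(loc$amplicon, cut - 12 + 1, cut - 4)   # 8-mer at [cut-12, cut-4)

  tm <- find_template(word, loc)
  expect_equal(tm$category, "perfect")
  expect_equal(tm$coverage, 1)
  expect_equal(nrow(tm$segments), 1L)
  expect_equal(tm$segments$orientation, "direct")
  expect_equal(tm$segments$ref_pos, cut - 12L)

  tm_rc <- find_template(revcomp(word), loc)
  expect_equal(tm_rc$category, "reverse")
  expect_equal(tm_rc$coverage, 1)
  expect_equal(tm_rc$segments$ref_pos, cut - 12L)

  tm_short <- find_template("TT", loc)
  expect_equal(tm_short$category, "none")
  expect_false(tm_short$searched)
})

test_that("partial decomposition covers chimeric insertions and respects min_seed", {
  loc <- test_locus()
  cut <- loc$cut_pos
  left <- substr(loc$amplicon, cut - 30 + 1, cut - 30 + 8)
  right <- revcomp(substr(loc$amplicon, cut + 10 + 1, cut + 10 + 6))
  # joint word absent from the window as a whole -> partial, two segments
  ins <- paste0(left, right)
  tm <- find_template(ins, loc)
  if (tm$category == "partial") {
    expect_gt(tm$coverage, 0)
    expect_true(all(tm$segments$ins_len >= 4))
    # segments must not overlap on the insertion
    sorted <- tm$segments[order(tm$segments$ins_offset), ]
    if (nrow(sorted) > 1) {
      expect_true(all(utils::head(sorted$ins_offset + sorted$ins_len, -1) <=
                        utils::tail(sorted$ins_offset, -1)))
    }
  } else {
    expect_equal(tm$category, "perfect")   # accidental full match
  }

  # coverage is monotonically non-increasing in min_seed
  withr::with_seed(12, {
    for (i in 1:20) {
      ins <- random_dna_str(sample(6:14, 1))
      covs <- vapply(c(4L, 6L, 8L), function(ms) {
        find_template(ins, loc, min_seed = ms)$coverage
      }, numeric(1))
      expect_true(all(diff(covs) <= 1e-12))
    }
  })
})

test_that("orientation flips when the insertion is reverse-complemented", {
  loc <- test_locus()
  cut <- loc$cut_pos
  withr::with_seed(21, {
    flips <- 0L
    for (off in c(-40, -25, 15, 30)) {
      word <- substr(loc$amplicon, cut + off + 1, cut + off + 10)
      a <- find_template(word, loc)
      b <- find_template(revcomp(word), loc)
      expect_true(a$category %in% c("perfect", "reverse"))
      # a direct full match must become a reverse full match and vice versa
      if (a$category == "perfect") expect_equal(b$category, "reverse")
      if (a$category == "reverse") expect_equal(b$category, "perfect")
      flips <- flips + 1L
    }
    expect_equal(flips, 4L)
  })
})

test_that("primer identity measures the flank/template word match", {
  #            0123456789...
  ref <- paste0("AAAC", "GATC", "TTTTTTTT", "GATC", "CCCCCCCC", "AAAATTTTCC")
  # left flank ends at a=8 with ...GATC; template at t=20 preceded by GATC
  match <- structure(
    list(category = "perfect",
         segments = dplyr::tibble(ins_offset = 0L, ins_len = 8L,
                                  ref_pos = 20L, orientation = "direct")),
    class = "template_match")
  pid <- primer_identity(match, list(del_start = 8L), ref)
  expect_equal(pid$length, 4L)
  expect_true(pid$primed)

  # a template with mismatching upstream context is unprimed
  match$segments$ref_pos <- 28L   # upstream is GATC-CCCC -> compare vs GATC
  pid <- primer_identity(match, list(del_start = 12L), ref)  # flank ...TTTT
  expect_equal(pid$length, 0L)
  expect_false(pid$primed)

  none <- structure(list(category = "none"), class = "template_match")
  expect_equal(primer_identity(none, list(del_start = 8L), ref)$length, 0L)
})

test_that("annotation summary counts templated and primed insertions per genotype", {
  loc <- test_locus()
  cfg <- simulation_config(loc, 120, genotype = "ku80", seed = 14)
  tr <- suppressMessages(simulate_clones(cfg))
  fps <- call_footprints(truth_to_reads(tr), loc)
  ev <- annotate_footprints(dedupe_events(fps), loc)
  expect_true(all(c("template_category", "primer_identity_len", "primed") %in%
                    names(ev)))
  ins_rows <- ev[ev$event_class %in% c("insertion", "delins"), ]
  expect_true(all(!is.na(ins_rows$template_category)))
  smry <- summarize_templates(ev)
  expect_equal(smry$n_insertions, nrow(ins_rows))
  expect_true(smry$n_templated <= smry$n_insertions)
  expect_true(smry$n_primed <= smry$n_insertions)

  # zero-insertion event set: an empty summary
  del_only <- ev[ev$event_class == "deletion", ]
  expect_equal(nrow(summarize_templates(del_only)), 0L)
})
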