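pstI <- restriction_enzyme("PstI", "CTGCAG")
fauI <- restriction_enzyme("FauI", "CCCGC")

test_that("recognition sites are found on both strands, palindromes once", {
  hits <- find_recognition_sites("AACTGCAGAA", pstI)
  expect_equal(hits$position, 2L)
  expect_equal(hits$strand, "+")   # palindromic window reported once, as +

  expect_equal(nrow(find_recognition_sites("AAAA", fauI)), 0L)

  # revcomp(CCCGC) = GCGGG at 0-based position 2
  hits <- find_recognition_sites("TTGCGGGTT", fauI)
  expect_equal(hits$position, 2L)
  expect_equal(hits$strand, "-")

  expect_error(find_recognition_sites("ACGN", pstI), "non-ACGT")
})

test_that("site scan agrees with a naive sliding-window oracle", {
  withr::with_seed(101, {
    for (i in 1:1000) {
      seq <- random_dna_str(sample(20:60, 1))
      enz <- if (i %% 2 == 0) pstI else fauI
      got <- find_recognition_sites(seq, enz)
      want <- oracle_sites(seq, enz$recognition)
      if (nrow(want) == 0) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(got$position, want$position)
        expect_equal(got$strand, want$strand)
      }
    }
  })
})

test_that("cut position sits 3 bp 5' of the PAM on either strand", {
  stub <- function(strand, pam) {
    structure(list(protospacer_strand = strand,
                   pam_interval = as.integer(pam)),
              class = "target_locus")
  }
  expect_equal(compute_cut_position(stub("+", c(50, 53))), 47L)
  expect_equal(compute_cut_position(stub("-", c(27, 30))), 33L)
  expect_equal(compute_cut_position(stub("+", c(20, 23))), 17L)

  loc <- test_locus()
  expect_equal(compute_cut_position(loc), loc$cut_pos)   # idempotent
})

test_that("locus validation enforces PAM, site uniqueness and primers", {
  loc <- test_locus()
  # NGG holds by construction
  expect_equal(substr(loc$amplicon, loc$pam_interval[1] + 2, loc$pam_interval[2]),
               "GG")
  bad_pam <- loc$amplicon
  substr(bad_pam, loc$pam_interval[1] + 2, loc$pam_interval[2]) <- "AT"
  expect_error(
    target_locus("x", bad_pam, loc$protospacer_interval, "+",
                 loc$pam_interval, loc$enzyme, loc$primer_fwd,
                 loc$primer_rev),
    "NGG")
  # duplicated recognition site
  dup <- paste0(loc$amplicon, "CTGCAG", revcomp(loc$primer_rev))
  expect_error(
    target_locus("x", dup, loc$protospacer_interval, "+", loc$pam_interval,
                 loc$enzyme, loc$primer_fwd, loc$primer_rev),
    "exactly once")
  expect_error(
    target_locus("x", loc$amplicon, loc$protospacer_interval, "+",
                 loc$pam_interval, loc$enzyme, "AAAAAAAA", loc$primer_rev),
    "primer_fwd")
})

test_that("digest detectability reflects loss of the recognition site", {
  loc <- test_locus()
  expect_false(is_detectable(loc$amplicon, loc$enzyme))   # wild type digests

  site <- loc$site_interval
  no_site <- paste0(substr(loc$amplicon, 1, site[1]),
                    substring(loc$amplicon, site[2] + 1))
  expect_true(is_detectable(no_site, loc$enzyme))

  # 1 bp deletion 10 bp away from the site leaves the site intact
  p <- site[1] - 10
  one_bp <- paste0(substr(loc$amplicon, 1, p - 1), substring(loc$amplicon, p + 1))
  expect_false(is_detectable(one_bp, loc$enzyme))
})

test_that("detection bias matches brute-force re-digestion", {
  loc <- test_locus()
  site <- loc$site_interval
  no_site <- paste0(substr(loc$amplicon, 1, site[1]),
                    substring(loc$amplicon, site[2] + 1))
  p <- site[1] - 10
  one_bp <- paste0(substr(loc$amplicon, 1, p - 1), substring(loc$amplicon, p + 1))

  truth <- dplyr::tibble(
    event_class = rep(c("deletion", "deletion"), c(100, 50)),
    del_len = rep(c(12L, 1L), c(100, 50)),
    read = rep(c(paste0(substr(loc$amplicon, 1, site[1] - 3),
                        substring(loc$amplicon, site[2] + 4)),  # 12 bp, site gone
                 one_bp), c(100, 50)))
  bias <- detection_bias(truth, loc)
  expect_true(all(bias$fraction >= 0 & bias$fraction <= 1))
  expect_equal(sum(bias$n), nrow(truth))
  expect_equal(bias$fraction[bias$del_bin == "10-19"], 1)   # site deleted
  expect_equal(bias$fraction[bias$del_bin == "<10"], 0)     # 1 bp, site kept

  # brute-force agreement on a mixed simulated set
  cfg <- simulation_config(loc, 60, seed = 5)
  tr <- suppressMessages(simulate_clones(cfg))
  bias <- detection_bias(tr, loc)
  manual <- vapply(tr$read, is_detectable, logical(1), enzyme = loc$enzyme)
  expect_equal(sum(bias$n_detectable), sum(manual))
  expect_error(detection_bias(tr[0, ], loc), "non-empty")
})

test_that("locus JSON round-trips", {
  loc <- test_locus()
  path <- withr::local_tempfile(fileext = ".json")
  write_locus_json(loc, path)
  back <- read_locus_json(path)
  expect_equal(back$amplicon, loc$amplicon)
  expect_equal(back$cut_pos, loc$cut_pos)
  expect_equal(back$enzyme$recognition, loc$enzyme$recognition)
  expect_error(read_locus_json(file.path(tempdir(), "nope.json")), "not found")
})

test_that("the shipped synthetic locus fixture loads and is valid", {
  path <- system.file("extdata", "synthetic_cru_like_locus.json",
                      package = "dsbfootprints")
  loc <- read_locus_json(path)
  expect_s3_class(loc, "target_locus")
  expect_false(is_detectable(loc$amplicon, loc$enzyme))
})
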