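# Target-locus model: amplicon, protospacer + PAM, predicted blunt cut site,
# and the restriction enzyme used for loss-of-site preselection. All
# coordinates are 0-based half-open on the amplicon; the cut position is a
# between-base junction coordinate (0..len).

#' Restriction enzyme with an exact recognition sequence
#'
#' Matching is exact-sequence on both strands; non-palindromic sites (such as
#' FauI's CCCGC) are found via the reverse complement. Degenerate IUPAC codes
#' are not supported.
#'
#' @param name Enzyme label, e.g. `"PstI"`.
#' @param recognition Recognition sequence over `{A,C,G,T}`, e.g. `"CTGCAG"`.
#' @return A `restriction_enzyme` object.
#' @examples
#' restriction_enzyme("PstI", "CTGCAG")
#' restriction_enzyme("FauI", "CCCGC")
#' @export
restriction_enzyme <- function(name, recognition) {
  check_dna(recognition, sprintf("recognition sequence of %s", name))
  structure(list(name = name, recognition = recognition),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s (%s)\n", x$name, x$recognition))
  invisible(x)
}

#' Describe a nuclease target locus
#'
#' Bundles the amplicon reference with the protospacer/PAM geometry, the
#' predicted blunt cut position (3 nt 5' of the PAM, canonical SpCas9
#' geometry, overridable via `cut_pos`), the restriction enzyme whose site
#' loss marks a clone as mutated, and the amplification primers.
#'
#' @param name Locus label.
#' @param amplicon Uppercase amplicon reference sequence.
#' @param protospacer_interval Integer pair `[start, end)`, 0-based half-open;
#'   length must be 20.
#' @param protospacer_strand `"+"` or `"-"` relative to the amplicon.
#' @param pam_interval Integer pair `[start, end)`; length must be 3, the PAM
#'   must read NGG on `protospacer_strand` and abut the protospacer 3' end.
#' @param enzyme A [restriction_enzyme()]; its site must occur exactly once in
#'   the amplicon (on either strand).
#' @param primer_fwd,primer_rev Amplification primers; the amplicon must start
#'   with `primer_fwd` and end with the reverse complement of `primer_rev`.
#' @param cut_pos Optional between-base cut coordinate; defaults to the
#'   canonical placement computed by [compute_cut_position()].
#' @return A `target_locus` object.
#' @export
target_locus <- function(name, amplicon, protospacer_interval,
                         protospacer_strand, pam_interval, enzyme,
                         primer_fwd, primer_rev, cut_pos = NULL) {
  check_dna(amplicon, sprintf("amplicon of locus %s", name))
  check_dna(primer_fwd, "primer_fwd")
  check_dna(primer_rev, "primer_rev")
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  ps <- as.integer(protospacer_interval)
  pam <- as.integer(pam_interval)
  len <- nchar(amplicon)
  if (ps[2] - ps[1] != 20L) {
    abort(sprintf("protospacer of %s must be 20 nt, got %d", name, ps[2] - ps[1]))
  }
  if (pam[2] - pam[1] != 3L) abort("PAM interval must have length 3")
  if (!protospacer_strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  pam_seq <- subseq0(amplicon, pam[1], pam[2])
  pam_read <- if (protospacer_strand == "+") pam_seq else revcomp(pam_seq)
  if (substr(pam_read, 2, 3) != "GG") {
    abort(sprintf("PAM of %s reads %s on strand %s; NGG required",
                  name, pam_read, protospacer_strand))
  }
  adjacent <- if (protospacer_strand == "+") pam[1] == ps[2] else pam[2] == ps[1]
  if (!adjacent) abort("PAM must be immediately 3'-adjacent to the protospacer")
  loc <- structure(
    list(name = name, amplicon = amplicon,
         protospacer_interval = ps, protospacer_strand = protospacer_strand,
         pam_interval = pam, cut_pos = NA_integer_, enzyme = enzyme,
         primer_fwd = primer_fwd, primer_rev = primer_rev),
    class = "target_locus")
  canonical <- compute_cut_position(loc)
  loc$cut_pos <- if (is.null(cut_pos)) canonical else as.integer(cut_pos)
  if (loc$cut_pos < ps[1] || loc$cut_pos > ps[2]) {
    abort("cut_pos must lie within the protospacer interval")
  }
  sites <- find_recognition_sites(amplicon, enzyme)
  if (nrow(sites) != 1L) {
    abort(sprintf("%s site must occur exactly once in amplicon of %s (found %d)",
                  enzyme$name, name, nrow(sites)))
  }
  if (!startsWith(amplicon, primer_fwd)) {
    abort("amplicon must start with primer_fwd")
  }
  if (!endsWith(amplicon, revcomp(primer_rev))) {
    abort("amplicon must end with the reverse complement of primer_rev")
  }
  loc$site_interval <- c(sites$position[1], sites$position[1] +
                           nchar(enzyme$recognition))
  loc
}

#' @export
print.target_locus <- function(x, ...) {
  cat(sprintf("<target_locus> %s: %d bp amplicon, protospacer [%d,%d)%s, cut at %d, %s site at [%d,%d)\n",
              x$name, nchar(x$amplicon), x$protospacer_interval[1],
              x$protospacer_interval[2], x$protospacer_strand, x$cut_pos,
              x$enzyme$name, x$site_interval[1], x$site_interval[2]))
  invisible(x)
}

#' Predicted blunt cut position for a locus
#'
#' Returns the between-base junction coordinate 3 bp 5' of the PAM on the
#' protospacer strand, mapped to amplicon coordinates.
#'
#' @param locus A [target_locus()].
#' @return Integer junction coordinate in amplicon coordinates.
#' @export
compute_cut_position <- function(locus) {
  stopifnot(inherits(locus, "target_locus"))
  if (locus$protospacer_strand == "+") {
    locus$pam_interval[1] - 3L
  } else {
    locus$pam_interval[2] + 3L
  }
}

#' Find exact restriction recognition sites on both strands
#'
#' Scans for exact occurrences of the recognition sequence (reported on
#' strand `+`) and of its reverse complement (strand `-`). A palindromic
#' window is reported once, with strand `+`.
#'
#' @param seq Uppercase DNA string to scan.
#' @param enzyme A [restriction_enzyme()].
#' @return Tibble with columns `position` (0-based window start) and `strand`.
#' @examples
#' find_recognition_sites("AACTGCAGAA", restriction_enzyme("PstI", "CTGCAG"))
#' @export
find_recognition_sites <- function(seq, enzyme) {
  check_dna(seq, "sequence scanned for recognition sites")
  fwd <- find_all(seq, enzyme$recognition)
  rc <- revcomp(enzyme$recognition)
  rev_hits <- if (rc == enzyme$recognition) integer() else find_all(seq, rc)
  rev_hits <- setdiff(rev_hits, fwd)
  out <- tibble(
    position = c(fwd, rev_hits),
    strand = c(rep("+", length(fwd)), rep("-", length(rev_hits))))
  arrange(out, .data$position)
}

#' Does a mutated amplicon survive the restriction digest?
#'
#' A clone enters the sequenced pool only if erroneous repair destroyed the
#' recognition site: `TRUE` iff no site remains on either strand.
#'
#' @param mutated_amplicon DNA string of the (possibly mutated) amplicon.
#' @param enzyme A [restriction_enzyme()].
#' @return Logical scalar.
#' @export
is_detectable <- function(mutated_amplicon, enzyme) {
  nrow(find_recognition_sites(mutated_amplicon, enzyme)) == 0L
}

#' Detectability of simulated events by the loss-of-site assay
#'
#' Re-digests every rendered read and tabulates, per event class (and per
#' deletion-length bin for deletions), the fraction of events the
#' loss-of-restriction-site preselection would retain. Quantifies the assay's
#' blind spot: small events that do not touch the recognition site keep the
#' site and are never sequenced.
#'
#' @param truth Tibble of truth records with at least `event_class`,
#'   `del_len`, and `read` (rendered read sequence) columns, e.g. from
#'   [simulate_clones()].
#' @param locus The [target_locus()] the reads were rendered from.
#' @return Tibble with `event_class`, `del_bin` (`NA` for non-deletions),
#'   `n`, `n_detectable`, `fraction`.
#' @export
detection_bias <- function(truth, locus) {
  stopifnot(inherits(locus, "target_locus"))
  if (!is.data.frame(truth) || nrow(truth) == 0L) {
    abort("detection_bias() needs a non-empty truth table")
  }
  truth |>
    mutate(
      detectable = purrr::map_lgl(.data$read, is_detectable, enzyme = locus$enzyme),
      del_bin = ifelse(.data$event_class == "deletion",
                       as.character(bin_del_lengths(pmax(.data$del_len, 1L))),
                       NA_character_)) |>
    group_by(.data$event_class, .data$del_bin) |>
    summarise(n = n(), n_detectable = sum(.data$detectable),
              fraction = .data$n_detectable / .data$n, .groups = "drop")
}

#' Read a target-locus definition from JSON
#'
#' The JSON object carries `name`, `amplicon` (or `amplicon_fasta` +
#' `amplicon_id` pointing at a FASTA record), `protospacer` (`start`, `end`,
#' `strand`), `pam` (`start`, `end`), `enzyme` (`name`, `recognition`),
#' `primer_fwd`, `primer_rev`, and optionally `cut_pos`.
#'
#' @param path Path to the JSON file.
#' @return A [target_locus()].
#' @export
read_locus_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("locus file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("name", "protospacer", "pam", "enzyme", "primer_fwd", "primer_rev")) {
    if (is.null(cfg[[key]])) abort(sprintf("locus config %s lacks key '%s'", path, key))
  }
  amplicon <- cfg$amplicon
  if (is.null(amplicon)) {
    if (is.null(cfg$amplicon_fasta)) {
      abort(sprintf("locus config %s needs 'amplicon' or 'amplicon_fasta'", path))
    }
    fa_path <- cfg$amplicon_fasta
    if (!file.exists(fa_path)) {
      fa_path <- file.path(dirname(path), cfg$amplicon_fasta)
    }
    seqs <- read_reads_fasta(fa_path)
    rec <- seqs$sequence[seqs$clone_id == cfg$amplicon_id]
    if (length(rec) != 1L) {
      abort(sprintf("record '%s' not found in %s", cfg$amplicon_id, fa_path))
    }
    amplicon <- rec
  }
  target_locus(
    name = cfg$name, amplicon = amplicon,
    protospacer_interval = c(cfg$protospacer$start, cfg$protospacer$end),
    protospacer_strand = cfg$protospacer$strand,
    pam_interval = c(cfg$pam$start, cfg$pam$end),
    enzyme = restriction_enzyme(cfg$enzyme$name, cfg$enzyme$recognition),
    primer_fwd = cfg$primer_fwd, primer_rev = cfg$primer_rev,
    cut_pos = cfg$cut_pos)
}

#' Write a target-locus definition to JSON
#'
#' @param locus A [target_locus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_json <- function(locus, path) {
  stopifnot(inherits(locus, "target_locus"))
  cfg <- list(
    name = locus$name, amplicon = locus$amplicon,
    protospacer = list(start = locus$protospacer_interval[1],
                       end = locus$protospacer_interval[2],
                       strand = locus$protospacer_strand),
    pam = list(start = locus$pam_interval[1], end = locus$pam_interval[2]),
    enzyme = list(name = locus$enzyme$name,
                  recognition = locus$enzyme$recognition),
    primer_fwd = locus$primer_fwd, primer_rev = locus$primer_rev,
    cut_pos = locus$cut_pos)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Synthetic example locus
#'
#' The published amplicon sequences live in the article supplement and are
#' not redistributed here; this constructor builds a synthetic locus with the
#' same geometry: a 480 bp amplicon, a 20 nt protospacer on `+` with an NGG
#' PAM, a blunt cut 3 nt 5' of the PAM, and a single restriction site near
#' (8 bp downstream of) but not overlapping the cut — so 1-2 bp events at
#' the cut leave the site intact, reproducing the assay's blind spot. The
#' `"cru_like"` flavour carries a PstI-type palindromic site (CTGCAG), the
#' `"ppo_like"` flavour a FauI-type non-palindromic site (CCCGC).
#'
#' @param flavour `"cru_like"` or `"ppo_like"`.
#' @param seed Integer seed controlling the random amplicon background.
#' @return A [target_locus()].
#' @examples
#' synthetic_locus("cru_like")
#' @export
synthetic_locus <- function(flavour = c("cru_like", "ppo_like"), seed = 2016L) {
  flavour <- match.arg(flavour)
  enzyme <- switch(flavour,
                   cru_like = restriction_enzyme("PstI", "CTGCAG"),
                   ppo_like = restriction_enzyme("FauI", "CCCGC"))
  with_seed(seed + match(flavour, c("cru_like", "ppo_like")), {
    len <- 480L
    ps <- c(230L, 250L)   # protospacer; PAM [250,253); cut at 247
    site_start <- 255L
    repeat {
      base <- strsplit(random_dna(len), "", fixed = TRUE)[[1]]
      base[252:253] <- c("G", "G")   # NGG PAM (0-based 251,252)
      rec <- strsplit(enzyme$recognition, "", fixed = TRUE)[[1]]
      base[(site_start + 1):(site_start + length(rec))] <- rec
      amplicon <- paste(base, collapse = "")
      if (nrow(find_recognition_sites(amplicon, enzyme)) == 1L) break
    }
    target_locus(
      name = paste0("synthetic_", flavour), amplicon = amplicon,
      protospacer_interval = ps, protospacer_strand = "+",
      pam_interval = c(250L, 253L), enzyme = enzyme,
      primer_fwd = substr(amplicon, 1, 20),
      primer_rev = revcomp(substr(amplicon, len - 19, len)))
  })
}
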