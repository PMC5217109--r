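# End-anchored footprint calling. Each clone is modelled as one contiguous
# repair event: reference[:start] + ins_seq + reference[end:] == read. The
# longest common prefix/suffix pin the event; equivalent junction placements
# (microhomology) are canonicalized to the leftmost.

#' Enumerate all equivalent junction placements of a footprint
#'
#' Brute-force oracle for junction ambiguity: every `(start, start+del_len)`
#' such that excising that reference interval and inserting `ins_seq`
#' reproduces the read exactly.
#'
#' @param reference Reference amplicon sequence.
#' @param del_len Deleted length (>= 0).
#' @param ins_seq Inserted sequence (possibly `""`).
#' @param read Clone read sequence.
#' @return Tibble with columns `start`, `end`, ascending; zero rows signal an
#'   inconsistent footprint. The degenerate intact event (`del_len == 0`,
#'   empty insertion, `read == reference`) returns the single canonical
#'   placement `(0, 0)`.
#' @examples
#' enumerate_placements("TTTCAGCAGTTT", 3, "", "TTTCAGTTT")
#' @export
enumerate_placements <- function(reference, del_len, ins_seq, read) {
  del_len <- as.integer(del_len)
  stopifnot(del_len >= 0L)
  n_ref <- nchar(reference)
  if (del_len == 0L && !nzchar(ins_seq) && identical(reference, read)) {
    return(tibble(start = 0L, end = 0L))
  }
  starts <- integer()
  for (a in 0:(n_ref - del_len)) {
    candidate <- paste0(subseq0(reference, 0L, a), ins_seq,
                        subseq0(reference, a + del_len, n_ref))
    if (candidate == read) starts <- c(starts, a)
  }
  tibble(start = starts, end = starts + del_len)
}

#' Classify a footprint by deleted/inserted lengths
#'
#' @param del_len Deleted reference length.
#' @param ins_seq Inserted sequence (`""` for none).
#' @return One of `"intact"`, `"deletion"`, `"insertion"`, `"substitution"`
#'   (equal-length replacement), `"delins"`.
#' @export
classify_event <- function(del_len, ins_seq) {
  ins_len <- nchar(ins_seq)
  dplyr::case_when(
    del_len == 0L & ins_len == 0L ~ "intact",
    ins_len == 0L ~ "deletion",
    del_len == 0L ~ "insertion",
    del_len == ins_len ~ "substitution",
    TRUE ~ "delins")
}

# Core single-read caller; returns a named list of footprint fields.
call_one <- function(reference, sequence) {
  n_ref <- nchar(reference)
  n_read <- nchar(sequence)
  p_max <- lcp_len(reference, sequence)
  s_max <- lcs_len(reference, sequence)
  s_adj <- min(s_max, n_ref - p_max, n_read - p_max)
  del_len <- n_ref - p_max - s_adj
  ins_len <- n_read - p_max - s_adj
  a_lo <- max(0L, n_ref - s_max - del_len)
  a_hi <- min(p_max, n_ref - del_len)
  ins_canon <- subseq0(sequence, a_lo, a_lo + ins_len)
  if (ins_len == 0L) {
    valid <- a_lo:a_hi
  } else {
    valid <- Filter(function(a) subseq0(sequence, a, a + ins_len) == ins_canon,
                    a_lo:a_hi)
  }
  if (del_len == 0L && ins_len == 0L) valid <- 0L   # intact: degenerate (0,0)
  shift_min <- min(valid)
  shift_max <- max(valid)
  cls <- classify_event(del_len, ins_canon)
  list(event_class = cls,
       del_start = shift_min, del_end = shift_min + del_len,
       del_len = del_len, ins_seq = ins_canon,
       mh_len = if (cls == "deletion") shift_max - shift_min else 0L,
       shift_min = shift_min, shift_max = shift_max)
}

#' Call one repair footprint per clone read
#'
#' End-anchored comparison of each read to the reference amplicon: the
#' longest shared prefix and suffix delimit a single contiguous event whose
#' canonical (leftmost) placement, junction-ambiguity range and class are
#' reported. Reads anchored by neither amplification primer are flagged
#' `"unalignable"`; called events reaching further than `max_radius` from
#' the cut (scattered mismatches inflating the event) are flagged
#' `"complex"`. Both are excluded from downstream statistics but kept in the
#' table for accounting.
#'
#' @param reads Tibble of clone reads with columns `clone_id`, `line_id`,
#'   `genotype`, `nuclease`, `sequence`.
#' @param locus A [target_locus()] providing the reference amplicon, primers,
#'   cut position and digest enzyme.
#' @param max_radius Maximum distance (bp) the called event may extend from
#'   the cut before the clone is flagged complex.
#' @return Tibble: one row per read with `status` (`ok`/`unalignable`/
#'   `complex`), `event_class`, `del_start`, `del_end`, `del_len`, `ins_seq`,
#'   `mh_len`, `shift_min`, `shift_max`, `detectable`. For every `ok` row the
#'   round trip `reference[:del_start] + ins_seq + reference[del_end:]`
#'   reproduces the read exactly.
#' @export
call_footprints <- function(reads, locus, max_radius = 250L) {
  stopifnot(inherits(locus, "target_locus"))
  req <- c("clone_id", "line_id", "genotype", "nuclease", "sequence")
  missing_cols <- setdiff(req, names(reads))
  if (length(missing_cols) > 0L) {
    abort(paste("reads table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  ref <- locus$amplicon
  rc_rev <- revcomp(locus$primer_rev)
  rows <- purrr::pmap(
    list(reads$clone_id, reads$sequence),
    function(clone_id, sequence) {
      check_dna(sequence, sprintf("sequence of clone %s", clone_id))
      anchored <- startsWith(sequence, locus$primer_fwd) ||
        endsWith(sequence, rc_rev)
      if (!anchored) {
        warn(sprintf("unalignable clone %s: neither primer anchor found; excluded",
                     clone_id))
        return(tibble(status = "unalignable", event_class = NA_character_,
                      del_start = NA_integer_, del_end = NA_integer_,
                      del_len = NA_integer_, ins_seq = NA_character_,
                      mh_len = NA_integer_, shift_min = NA_integer_,
                      shift_max = NA_integer_))
      }
      fp <- call_one(ref, sequence)
      complex <- (fp$del_len > 0L || nzchar(fp$ins_seq)) &&
        (fp$del_start < locus$cut_pos - max_radius ||
           fp$del_end > locus$cut_pos + max_radius)
      tibble(status = if (complex) "complex" else "ok",
             event_class = fp$event_class, del_start = fp$del_start,
             del_end = fp$del_end, del_len = fp$del_len, ins_seq = fp$ins_seq,
             mh_len = fp$mh_len, shift_min = fp$shift_min,
             shift_max = fp$shift_max)
    })
  out <- dplyr::bind_cols(
    reads |> select("clone_id", "line_id", "genotype", "nuclease"),
    dplyr::bind_rows(rows))
  out$detectable <- purrr::map_lgl(reads$sequence, is_detectable,
                                   enzyme = locus$enzyme)
  out
}

#' Collapse identical footprints within a plant line to one event
#'
#' Identical sequences recovered from the same line may be PCR siblings and
#' are counted as a single mutagenesis event; identical footprints in
#' different lines arose independently and are kept as distinct events.
#' Only `status == "ok"` rows are considered.
#'
#' @param footprints Tibble from [call_footprints()].
#' @return Tibble of deduplicated events with an `n_clones` column (clones
#'   collapsed into each event). Attribute `duplicates_removed` records the
#'   number of collapsed rows.
#' @export
dedupe_events <- function(footprints) {
  ok <- filter(footprints, .data$status == "ok")
  out <- ok |>
    group_by(.data$line_id, .data$event_class, .data$del_start,
             .data$del_end, .data$ins_seq) |>
    mutate(n_clones = n()) |>
    dplyr::slice(1L) |>
    ungroup() |>
    arrange(.data$clone_id)
  attr(out, "duplicates_removed") <- nrow(ok) - nrow(out)
  out
}
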