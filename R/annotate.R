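# Junction annotation: microhomology at deletion junctions, and template
# search for inserted sequences within +/-100 bp of the cut (direct, partial
# and reverse-complement matches, plus primer identity) -- the signature of
# polymerase-theta-mediated end joining.

#' Microhomology at a deletion junction
#'
#' The repeated word shared by the two junction flanks, whose length equals
#' the width of the junction's equivalent-placement range. Computed directly
#' by flank extension from the canonical (leftmost) placement, independently
#' of [enumerate_placements()]. Non-deletion footprints return length 0.
#'
#' @param footprint A one-row tibble or named list with `event_class`,
#'   `del_start`, `del_end` (canonical leftmost placement).
#' @param reference Reference amplicon sequence.
#' @return Tibble with `mh_len`, `mh_seq`, `p_min`, `p_max`.
#' @examples
#' fp <- list(event_class = "deletion", del_start = 3, del_end = 6)
#' annotate_microhomology(fp, "TTTCAGCAGTTT")
#' @export
annotate_microhomology <- function(footprint, reference) {
  a <- as.integer(footprint$del_start)
  b <- as.integer(footprint$del_end)
  n <- nchar(reference)
  if (is.na(a) || is.na(b) || a < 0L || b < a || b > n) {
    abort("inconsistent footprint: deletion interval outside the reference")
  }
  if (!identical(footprint$event_class, "deletion")) {
    return(tibble(mh_len = 0L, mh_seq = "", p_min = a, p_max = a))
  }
  # leftmost placement: extend rightwards while the flanks agree; the shared
  # word may exceed the deletion length (tandem repeats), so no cap at b - a
  k <- 0L
  while (b + k < n &&
         substr(reference, a + k + 1L, a + k + 1L) ==
         substr(reference, b + k + 1L, b + k + 1L)) {
    k <- k + 1L
  }
  tibble(mh_len = k, mh_seq = subseq0(reference, a, a + k),
         p_min = a, p_max = a + k)
}

#' Search the cut neighbourhood for the template of an inserted sequence
#'
#' The search space is `reference[cut - window_bp, cut + window_bp)` (clipped
#' to the amplicon) and its reverse complement. A full-length direct match is
#' `"perfect"`; a full-length reverse-complement match is `"reverse"`;
#' otherwise the insertion is greedily decomposed into maximal matched
#' substrings of length >= `min_seed` (longest first, leftmost tie-break,
#' direct preferred over reverse) and any coverage makes it `"partial"`,
#' else `"none"`. Insertions shorter than `min_search_len` are not searched.
#'
#' @param ins_seq Inserted sequence (non-empty).
#' @param locus A [target_locus()].
#' @param window_bp Search half-window around the cut (bp).
#' @param min_search_len Insertions shorter than this are not searched.
#' @param min_seed Minimum matched-substring length in the partial
#'   decomposition.
#' @return A `template_match` object: list with `category`, `coverage`,
#'   `searched`, and `segments` (tibble `ins_offset`, `ins_len`, `ref_pos`,
#'   `orientation`; `ref_pos` is the plus-strand 0-based start of the matched
#'   reference region, leftmost occurrence in the scanned orientation).
#' @export
find_template <- function(ins_seq, locus, window_bp = 100L,
                          min_search_len = 3L, min_seed = 4L) {
  stopifnot(inherits(locus, "target_locus"))
  check_dna(ins_seq, "inserted sequence")
  ref <- locus$amplicon
  win_start <- max(0L, locus$cut_pos - window_bp)
  win_end <- min(nchar(ref), locus$cut_pos + window_bp)
  win <- subseq0(ref, win_start, win_end)
  win_rc <- revcomp(win)
  n_win <- nchar(win)
  L <- nchar(ins_seq)
  no_segments <- tibble(ins_offset = integer(), ins_len = integer(),
                        ref_pos = integer(), orientation = character())
  empty <- function(searched) {
    structure(list(category = "none", coverage = 0, searched = searched,
                   segments = no_segments,
                   window = c(win_start, win_end)),
              class = "template_match")
  }
  if (L < min_search_len) return(empty(FALSE))

  locate <- function(sub) {
    hit <- find_all(win, sub)
    if (length(hit) > 0L) {
      return(list(ref_pos = win_start + hit[1L], orientation = "direct"))
    }
    hit <- find_all(win_rc, sub)
    if (length(hit) > 0L) {
      # leftmost on the minus strand; plus-strand start of the matched region
      return(list(ref_pos = win_start + n_win - hit[1L] - nchar(sub),
                  orientation = "reverse"))
    }
    NULL
  }

  full <- locate(ins_seq)
  if (!is.null(full)) {
    category <- if (full$orientation == "direct") "perfect" else "reverse"
    return(structure(
      list(category = category, coverage = 1, searched = TRUE,
           segments = tibble(ins_offset = 0L, ins_len = L,
                             ref_pos = full$ref_pos,
                             orientation = full$orientation),
           window = c(win_start, win_end)),
      class = "template_match"))
  }

  matched <- rep(FALSE, L)
  segments <- no_segments
  repeat {
    best <- NULL
    for (len in seq(L, min_seed)) {
      if (len > L) next
      for (off in 0:(L - len)) {
        if (any(matched[(off + 1L):(off + len)])) next
        hit <- locate(subseq0(ins_seq, off, off + len))
        if (!is.null(hit)) {
          best <- c(list(ins_offset = off, ins_len = len), hit)
          break
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) break
    matched[(best$ins_offset + 1L):(best$ins_offset + best$ins_len)] <- TRUE
    segments <- bind_rows(segments,
                          tibble(ins_offset = best$ins_offset,
                                 ins_len = best$ins_len,
                                 ref_pos = best$ref_pos,
                                 orientation = best$orientation))
  }
  coverage <- mean(matched)
  if (coverage == 0) return(empty(TRUE))
  structure(list(category = "partial", coverage = coverage, searched = TRUE,
                 segments = arrange(segments, .data$ins_offset),
                 window = c(win_start, win_end)),
            class = "template_match")
}

#' @export
print.template_match <- function(x, ...) {
  cat(sprintf("<template_match> %s, coverage %.2f, %d segment(s)\n",
              x$category, x$coverage, nrow(x$segments)))
  invisible(x)
}

#' Primer identity between the junction 3' end and the template upstream
#'
#' Length of the exact match between the terminal bases of the retained left
#' flank abutting the insertion (the 3' end that primed synthesis) and the
#' bases immediately upstream of the template start, read in template
#' orientation. Uses the 5'-most segment of the insertion. A match of
#' `primed_min` (default 2) or more bases flags the junction as primed.
#'
#' @param match A `template_match` from [find_template()].
#' @param footprint One-row tibble or list with `del_start` (canonical).
#' @param reference Reference amplicon sequence.
#' @param primed_min Minimum identity length to call the junction primed.
#' @return List with `length` and `primed`.
#' @export
primer_identity <- function(match, footprint, reference, primed_min = 2L) {
  if (!inherits(match, "template_match") || match$category == "none") {
    return(list(length = 0L, primed = FALSE))
  }
  seg <- match$segments[1L, ]
  a <- as.integer(footprint$del_start)   # primer 3' end is reference[a-1]
  n <- nchar(reference)
  j <- 0L
  if (seg$orientation == "direct") {
    t0 <- seg$ref_pos
    while (a - j >= 1L && t0 - j >= 1L &&
           substr(reference, a - j, a - j) ==
           substr(reference, t0 - j, t0 - j)) {
      j <- j + 1L
    }
  } else {
    # minus-strand template: upstream in template orientation lies at
    # increasing plus-strand positions past the segment end, complemented
    t1 <- seg$ref_pos + seg$ins_len   # 0-based plus-strand position
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    while (a - j >= 1L && t1 + j < n &&
           substr(reference, a - j, a - j) ==
           comp[[substr(reference, t1 + j + 1L, t1 + j + 1L)]]) {
      j <- j + 1L
    }
  }
  list(length = j, primed = j >= primed_min)
}

segments_compact <- function(segments) {
  if (nrow(segments) == 0L) return("")
  paste(sprintf("%d:%d@%d%s", segments$ins_offset, segments$ins_len,
                segments$ref_pos,
                ifelse(segments$orientation == "direct", "+", "-")),
        collapse = ";")
}

#' Annotate deduplicated events with microhomology and template matches
#'
#' Re-derives junction microhomology for pure deletions and runs the
#' template search plus primer-identity call for every insertion-bearing
#' event (insertions and delins; substitutions are carried but flagged).
#'
#' @param events Deduplicated footprint tibble from [dedupe_events()].
#' @param locus A [target_locus()].
#' @inheritParams find_template
#' @inheritParams primer_identity
#' @return `events` with added columns `mh_seq`, `template_category`,
#'   `template_coverage`, `template_searched`, `segments` (compact
#'   `off:len@pos+/-` strings), `primer_identity_len`, `primed`.
#' @export
annotate_footprints <- function(events, locus, window_bp = 100L,
                                min_search_len = 3L, min_seed = 4L,
                                primed_min = 2L) {
  stopifnot(inherits(locus, "target_locus"))
  ref <- locus$amplicon
  ann <- purrr::pmap(
    list(events$event_class, events$del_start, events$del_end,
         events$ins_seq),
    function(event_class, del_start, del_end, ins_seq) {
      fp <- list(event_class = event_class, del_start = del_start,
                 del_end = del_end)
      mh <- annotate_microhomology(fp, ref)
      if (event_class %in% c("insertion", "delins", "substitution") &&
          nzchar(ins_seq)) {
        tm <- find_template(ins_seq, locus, window_bp = window_bp,
                            min_search_len = min_search_len,
                            min_seed = min_seed)
        pid <- primer_identity(tm, fp, ref, primed_min = primed_min)
        tibble(mh_seq = mh$mh_seq, template_category = tm$category,
               template_coverage = tm$coverage,
               template_searched = tm$searched,
               segments = segments_compact(tm$segments),
               primer_identity_len = pid$length, primed = pid$primed)
      } else {
        tibble(mh_seq = mh$mh_seq, template_category = NA_character_,
               template_coverage = NA_real_, template_searched = FALSE,
               segments = "", primer_identity_len = NA_integer_,
               primed = NA)
      }
    })
  dplyr::bind_cols(events, dplyr::bind_rows(ann))
}

#' Per-genotype summary of templated insertions
#'
#' Counts insertion-bearing events (classes insertion and delins), those
#' with any template match in the cut neighbourhood, and those with primer
#' identity at the junction.
#'
#' @param annotated Tibble from [annotate_footprints()].
#' @return Tibble per genotype x nuclease: `n_insertions`, `n_templated`,
#'   `n_primed`, `frac_templated`, `frac_primed`.
#' @export
summarize_templates <- function(annotated) {
  annotated |>
    filter(.data$event_class %in% c("insertion", "delins")) |>
    group_by(.data$genotype, .data$nuclease) |>
    summarise(
      n_insertions = n(),
      n_templated = sum(.data$template_category != "none", na.rm = TRUE),
      n_primed = sum(.data$primed, na.rm = TRUE),
      frac_templated = .data$n_templated / .data$n_insertions,
      frac_primed = .data$n_primed / .data$n_insertions,
      .groups = "drop")
}
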