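# Simulator of Cas9 repair outcomes: a pathway mixture (intact clones, small
# indels at the cut, microhomology-mediated deletions, templated insertions)
# at a defined cut site, with truth records so every downstream stage can be
# checked against what was planted. Deletion lengths follow per-genotype
# preset models calibrated to published length-bin fractions.

EVENT_CLASSES <- c("intact", "small_indel", "mmej_deletion",
                   "templated_insertion")
GENOTYPES <- c("WT", "parp1parp2", "ku80", "ku80parp1parp2")
NUCLEASES <- c("Cas9-CRU", "Cas9-PPO")

preset_env <- new.env(parent = emptyenv())

del_len_presets <- function() {
  if (is.null(preset_env$presets)) {
    path <- system.file("extdata", "del_len_presets.json",
                        package = "dsbfootprints")
    preset_env$presets <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  preset_env$presets
}

#' Analytic length-bin probabilities of a deletion-length model
#'
#' The model is a mixture of two shifted geometric distributions with
#' support >= 3 bp (the scored-deletion regime; 1-2 bp events are generated
#' by the separate small-indel class). Returns the probability of each of
#' the four length bins `[3,9]`, `[10,19]`, `[20,49]`, `[50,Inf)`.
#'
#' @param model List with `p_short`, `p_long`, `lambda_long`, `shift_short`,
#'   `shift_long` (e.g. `preset_profile(...)$del_len_model`).
#' @return Numeric vector of four bin probabilities summing to 1.
#' @export
del_bin_probs <- function(model) {
  cdf_s <- function(x) {
    ifelse(x < 3 + model$shift_short, 0,
           1 - (1 - model$p_short)^(x - 2 - model$shift_short))
  }
  cdf_l <- function(x) {
    ifelse(x < 3 + model$shift_long, 0,
           1 - (1 - model$p_long)^(x - 2 - model$shift_long))
  }
  cdf <- function(x) {
    (1 - model$lambda_long) * cdf_s(x) + model$lambda_long * cdf_l(x)
  }
  c(cdf(9), cdf(19) - cdf(9), cdf(49) - cdf(19), 1 - cdf(49))
}

#' Draw deletion lengths from a preset model
#'
#' @param model Deletion-length model (see [del_bin_probs()]).
#' @param n Number of draws.
#' @param max_len Lengths above this are redrawn (amplicon feasibility).
#' @return Integer vector of deletion lengths (>= 3 bp).
#' @export
sample_del_lengths <- function(model, n, max_len = 200L) {
  draw <- function(m) {
    long <- runif(m) < model$lambda_long
    3L + ifelse(long,
                model$shift_long + rgeom(m, model$p_long),
                model$shift_short + rgeom(m, model$p_short))
  }
  out <- draw(n)
  for (i in 1:50) {
    over <- out > max_len
    if (!any(over)) break
    out[over] <- draw(sum(over))
  }
  if (any(out > max_len)) abort("could not draw feasible deletion lengths")
  as.integer(out)
}

#' Genotype/nuclease preset parameters
#'
#' Returns the simulation parameters that emulate a genotype x nuclease
#' condition: the calibrated deletion-length model (analytic bin
#' probabilities matching the published per-genotype bin fractions), event
#' class weights (KU-deficient backgrounds carry more templated-insertion
#' events), microhomology and insertion-length distributions, and the
#' polymerase-theta signature rates.
#'
#' @param genotype One of `"WT"`, `"parp1parp2"`, `"ku80"`,
#'   `"ku80parp1parp2"`.
#' @param nuclease `"Cas9-CRU"` or `"Cas9-PPO"`.
#' @return Named list of simulation parameters (a [simulation_config()]
#'   fragment).
#' @export
preset_profile <- function(genotype, nuclease) {
  if (!genotype %in% GENOTYPES) {
    abort(sprintf("unknown genotype '%s'; valid presets: %s", genotype,
                  paste(GENOTYPES, collapse = ", ")))
  }
  if (!nuclease %in% NUCLEASES) {
    abort(sprintf("unknown nuclease '%s'; valid presets: %s", nuclease,
                  paste(NUCLEASES, collapse = ", ")))
  }
  key <- paste(genotype, nuclease, sep = ".")
  model <- del_len_presets()$presets[[key]]
  ku <- grepl("ku80", genotype)
  class_weights <- if (ku) {
    c(intact = 0.05, small_indel = 0.10, mmej_deletion = 0.60,
      templated_insertion = 0.25)
  } else {
    c(intact = 0.05, small_indel = 0.15, mmej_deletion = 0.65,
      templated_insertion = 0.15)
  }
  ins_len_dist <- 0.88^(0:59)
  list(genotype = genotype, nuclease = nuclease,
       del_len_model = model[c("p_short", "p_long", "lambda_long",
                               "shift_short", "shift_long")],
       class_weights = class_weights,
       mh_len_dist = c(`0` = 0.35, `1` = 0.25, `2` = 0.20, `3` = 0.12,
                       `4` = 0.05, `5` = 0.02, `6` = 0.01),
       ins_len_dist = ins_len_dist / sum(ins_len_dist),
       template_window = 100L, p_reverse = 0.3, p_primed = 0.5,
       delins_del_multiplier = 2)
}

#' Assemble a simulation configuration
#'
#' @param locus A [target_locus()].
#' @param n_clones Number of clones to simulate (> 0).
#' @param genotype,nuclease Preset labels (see [preset_profile()]).
#' @param seed Integer seed; recorded in every output.
#' @param clones_per_line Clones per simulated plant line (pooled-seedling
#'   sampling gives several clones per independent transformant).
#' @param noise_rate Optional per-base substitution-noise rate applied to
#'   rendered reads (default 0: Sanger clone consensus is near-noiseless).
#' @param ... Overrides for any [preset_profile()] parameter.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(locus, n_clones, genotype = "WT",
                              nuclease = "Cas9-CRU", seed = 1L,
                              clones_per_line = 10L, noise_rate = 0, ...) {
  stopifnot(inherits(locus, "target_locus"))
  n_clones <- as.integer(n_clones)
  if (is.na(n_clones) || n_clones <= 0L) abort("n_clones must be positive")
  cfg <- preset_profile(genotype, nuclease)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    abort(paste("unknown simulation parameter(s):",
                paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  for (p in c("class_weights", "mh_len_dist", "ins_len_dist")) {
    if (abs(sum(cfg[[p]]) - 1) > 1e-6) {
      abort(sprintf("%s must sum to 1", p))
    }
  }
  cfg$locus <- locus
  cfg$n_clones <- n_clones
  cfg$seed <- as.integer(seed)
  cfg$clones_per_line <- as.integer(clones_per_line)
  cfg$noise_rate <- noise_rate
  structure(cfg, class = "simulation_config")
}

# flank-agreement width of a deletion [a,b): number of equivalent junction
# shifts; equals the microhomology length the caller will report
placement_width <- function(ref, a, b) {
  n <- nchar(ref)
  right <- 0L
  while (b + right < n &&
         substr(ref, a + right + 1L, a + right + 1L) ==
         substr(ref, b + right + 1L, b + right + 1L)) right <- right + 1L
  left <- 0L
  while (a - left > 0L &&
         substr(ref, a - left, a - left) ==
         substr(ref, b - left, b - left)) left <- left + 1L
  c(width = left + right, left = left)
}

# realized primer identity for a planted template (mirrors primer_identity())
planted_primer_len <- function(ref, a, t, il, orientation) {
  n <- nchar(ref)
  j <- 0L
  if (orientation == "direct") {
    while (a - j >= 1L && t - j >= 1L &&
           substr(ref, a - j, a - j) == substr(ref, t - j, t - j)) j <- j + 1L
  } else {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    while (a - j >= 1L && t + il + j < n &&
           substr(ref, a - j, a - j) ==
           comp[[substr(ref, t + il + j + 1L, t + il + j + 1L)]]) j <- j + 1L
  }
  j
}

#' Draw one repair event (truth record, without rendering)
#'
#' Event class from the configured class weights. Deletions straddle the cut
#' with the left/right split drawn uniformly over valid splits (both primer
#' anchors always retained). Microhomology-mediated deletions search local
#' endpoints so the junction flanks share exactly the drawn m-mer, jittering
#' the length by up to 3 bp before falling back to the closest achievable
#' width. Templated insertions copy a window substring (reverse-complement
#' with probability `p_reverse`), aiming for >= 2 bp of planted primer
#' identity with probability `p_primed`, and carry an accompanying deletion
#' scaled by `delins_del_multiplier`; the truth record stores the realized
#' template position, orientation, primer-identity length, and whether the
#' inserted word occurs uniquely in the search window.
#'
#' @param cfg A [simulation_config()].
#' @return One-row tibble of truth fields (no `read` column yet).
#' @export
sample_event <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  locus <- cfg$locus
  ref <- locus$amplicon
  n <- nchar(ref)
  cut <- locus$cut_pos
  lo <- nchar(locus$primer_fwd)          # deletions stay within the anchors
  hi <- n - nchar(locus$primer_rev)
  cls <- sample(EVENT_CLASSES, 1L, prob = cfg$class_weights)

  truth <- tibble(event_class = cls, del_start = 0L, del_end = 0L,
                  ins_seq = "", mh_planted = NA_integer_,
                  mh_fallback = FALSE, template_pos = NA_integer_,
                  template_orientation = NA_character_,
                  template_unique = NA, primer_len_planted = NA_integer_)

  straddling_starts <- function(L) {
    a_lo <- max(lo, cut - L)
    a_hi <- min(cut, hi - L)
    if (a_hi < a_lo) return(integer())
    a_lo:a_hi
  }

  if (cls == "intact") {
    return(truth)
  }

  if (cls == "small_indel") {
    kind <- sample(c("del1", "del2", "ins1"), 1L)
    if (kind == "ins1") {
      truth$del_start <- truth$del_end <- cut
      truth$ins_seq <- sample(DNA_ALPHABET, 1L)
    } else {
      L <- if (kind == "del1") 1L else 2L
      ss <- straddling_starts(L)
      a <- ss[sample.int(length(ss), 1L)]
      left <- placement_width(ref, a, a + L)[["left"]]
      truth$del_start <- a - left   # canonical leftmost placement
      truth$del_end <- a - left + L
    }
    return(truth)
  }

  if (cls == "mmej_deletion") {
    L <- sample_del_lengths(cfg$del_len_model, 1L)
    m <- as.integer(sample(names(cfg$mh_len_dist), 1L, prob = cfg$mh_len_dist))
    best <- NULL
    for (jit in c(0L, 1L, -1L, 2L, -2L, 3L, -3L)) {
      Lt <- L + jit
      if (Lt < 1L) next
      starts <- straddling_starts(Lt)
      if (length(starts) == 0L) next
      for (a in starts[sample.int(length(starts))]) {
        pw <- placement_width(ref, a, a + Lt)
        if (pw[["width"]] == m) {
          best <- c(a, Lt, m, 0L)
          break
        }
        if (is.null(best) || abs(pw[["width"]] - m) <
              abs(best[3L] - m)) {
          best <- c(a, Lt, pw[["width"]], 1L)
        }
      }
      if (!is.null(best) && best[4L] == 0L) break
    }
    if (is.null(best)) abort("locus too short for requested deletion")
    left <- placement_width(ref, best[1L], best[1L] + best[2L])[["left"]]
    truth$del_start <- best[1L] - left   # canonical leftmost placement
    truth$del_end <- best[1L] - left + best[2L]
    truth$mh_planted <- best[3L]
    truth$mh_fallback <- best[4L] == 1L
    return(truth)
  }

  # templated insertion with accompanying deletion
  il <- sample(seq_along(cfg$ins_len_dist), 1L, prob = cfg$ins_len_dist)
  starts <- integer()
  for (try in 1:50) {   # rejection: accompanying deletion must fit the locus
    d <- as.integer(round(cfg$delins_del_multiplier *
                            sample_del_lengths(cfg$del_len_model, 1L)))
    starts <- straddling_starts(d)
    if (length(starts) > 0L) break
  }
  if (length(starts) == 0L) abort("locus too short for requested deletion")
  a <- starts[sample.int(length(starts), 1L)]
  b <- a + d
  orientation <- if (runif(1) < cfg$p_reverse) "reverse" else "direct"
  want_primed <- runif(1) < cfg$p_primed
  w <- cfg$template_window
  t_lo <- max(0L, cut - w)
  t_hi <- min(n, cut + w) - il
  if (t_hi < t_lo) abort("insertion longer than the template window")
  t_all <- t_lo:t_hi
  cand <- t_all[sample.int(length(t_all), min(200L, length(t_all)))]
  pick <- NULL
  for (t in cand) {
    j <- planted_primer_len(ref, a, t, il, orientation)
    if ((want_primed && j >= 2L) || (!want_primed && j <= 1L)) {
      pick <- c(t, j)
      break
    }
    if (is.null(pick)) pick <- c(t, j)
  }
  t <- pick[1L]
  word <- subseq0(ref, t, t + il)
  ins <- if (orientation == "direct") word else revcomp(word)
  win <- subseq0(ref, t_lo, min(n, cut + w))
  n_occ <- length(find_all(win, ins)) + length(find_all(revcomp(win), ins))
  truth$del_start <- a
  truth$del_end <- b
  truth$ins_seq <- ins
  truth$template_pos <- t
  truth$template_orientation <- orientation
  truth$template_unique <- n_occ == 1L
  truth$primer_len_planted <- pick[2L]
  truth
}

#' Render the read of a truth record
#'
#' Deterministic concatenation `reference[:del_start] + ins_seq +
#' reference[del_end:]`.
#'
#' @param truth One-row tibble or list with `del_start`, `del_end`,
#'   `ins_seq`.
#' @param locus A [target_locus()].
#' @return The clone read as a character scalar.
#' @export
render_read <- function(truth, locus) {
  a <- as.integer(truth$del_start)
  b <- as.integer(truth$del_end)
  n <- nchar(locus$amplicon)
  if (a < 0L || b < a || b > n) abort("deletion interval out of bounds")
  paste0(subseq0(locus$amplicon, 0L, a), truth$ins_seq,
         subseq0(locus$amplicon, b, n))
}

#' Simulate a set of clone reads with truth records
#'
#' Draws `n_clones` events under the configured preset, renders each read,
#' assigns clones to simulated plant lines in blocks of `clones_per_line`,
#' and marks digest detectability. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return Truth tibble: clone metadata, planted event fields, `read`,
#'   `detectable`. Attribute `mh_fallbacks` counts microhomology targets
#'   that had no achievable endpoints.
#' @export
simulate_clones <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    events <- purrr::map(seq_len(cfg$n_clones), function(i) sample_event(cfg))
    truth <- bind_rows(events)
    truth <- truth |>
      mutate(
        clone_id = sprintf("clone%04d", row_number()),
        line_id = sprintf("line%03d",
                          (row_number() - 1L) %/% cfg$clones_per_line + 1L),
        genotype = cfg$genotype, nuclease = cfg$nuclease,
        del_len = .data$del_end - .data$del_start,
        .before = 1L)
    truth$read <- purrr::pmap_chr(
      truth[c("del_start", "del_end", "ins_seq")],
      function(del_start, del_end, ins_seq) {
        render_read(list(del_start = del_start, del_end = del_end,
                         ins_seq = ins_seq), cfg$locus)
      })
    if (cfg$noise_rate > 0) {
      truth$read <- purrr::map_chr(truth$read, function(s) {
        chars <- strsplit(s, "", fixed = TRUE)[[1]]
        hit <- runif(length(chars)) < cfg$noise_rate
        chars[hit] <- vapply(chars[hit], function(ch) {
          sample(setdiff(DNA_ALPHABET, ch), 1L)
        }, character(1))
        paste(chars, collapse = "")
      })
    }
    truth$detectable <- purrr::map_lgl(truth$read, is_detectable,
                                       enzyme = cfg$locus$enzyme)
    attr(truth, "mh_fallbacks") <- sum(truth$mh_fallback, na.rm = TRUE)
    if (attr(truth, "mh_fallbacks") > 0L) {
      inform(sprintf("%d mmej event(s) fell back to the closest achievable microhomology width",
                     attr(truth, "mh_fallbacks")))
    }
    truth
  })
}

#' Write a simulated dataset to disk
#'
#' Writes `reads.fasta`, `truth.tsv`, and `sample_sheet.tsv` into `out_dir`.
#' Identical configuration and seed give byte-identical files.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the truth tibble.
#' @export
generate_dataset <- function(cfg, out_dir) {
  truth <- simulate_clones(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reads <- Biostrings::DNAStringSet(setNames(truth$read, truth$clone_id))
  Biostrings::writeXStringSet(reads, file.path(out_dir, "reads.fasta"))
  readr::write_tsv(truth |> select(-"read"),
                   file.path(out_dir, "truth.tsv"))
  readr::write_tsv(truth |> select("clone_id", "line_id", "genotype",
                                   "nuclease"),
                   file.path(out_dir, "sample_sheet.tsv"))
  invisible(truth)
}
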