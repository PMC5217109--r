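# Deletion/insertion length statistics: the published length bins, two-tailed
# Mann-Whitney U contrasts (exact by rank-sum enumeration for small tie-free
# samples, tie-corrected normal approximation otherwise), and the
# digest-resistant band fraction.

DEL_BIN_BREAKS <- c(0, 9, 19, 49, Inf)
DEL_BIN_LABELS <- c("<10", "10-19", "20-49", ">=50")

bin_del_lengths <- function(lengths) {
  cut(lengths, breaks = DEL_BIN_BREAKS, labels = DEL_BIN_LABELS)
}

#' Bin deletion lengths into the standard length classes
#'
#' Bins are `[1,9]`, `[10,19]`, `[20,49]`, `[50,Inf)` bp. Intact events
#' (length 0) must not reach this function.
#'
#' @param lengths Integer vector of deletion lengths (>= 1), one per
#'   deduplicated event.
#' @return A `length_distribution` tibble: `bin`, `count`, `fraction`, with
#'   attribute `n`.
#' @examples
#' bin_deletions(c(5, 10, 25, 50))
#' @export
bin_deletions <- function(lengths) {
  if (length(lengths) == 0L) abort("no deletion lengths to bin")
  if (any(lengths < 1L)) {
    abort("deletion length 0 in input: intact events must not reach statistics")
  }
  tab <- table(bin_del_lengths(lengths))
  out <- tibble(bin = factor(DEL_BIN_LABELS, levels = DEL_BIN_LABELS),
                count = as.integer(tab),
                fraction = as.integer(tab) / length(lengths))
  attr(out, "n") <- length(lengths)
  class(out) <- c("length_distribution", class(out))
  out
}

# Exact two-tailed p for U by dynamic programming over rank sums (tie-free):
# count subsets of size n1 of ranks 1..N by rank sum, fold to U.
mwu_exact_p <- function(u_obs, n1, n2) {
  N <- n1 + n2
  max_w <- sum((n2 + 1):N)
  # counts[k+1, s+1] = number of k-subsets of 1..N with rank sum s
  counts <- matrix(0, nrow = n1 + 1L, ncol = max_w + 1L)
  counts[1L, 1L] <- 1
  for (r in seq_len(N)) {
    for (k in rev(seq_len(min(r, n1)))) {
      s_range <- seq_len(max_w + 1L - r)
      counts[k + 1L, s_range + r] <- counts[k + 1L, s_range + r] +
        counts[k, s_range]
    }
  }
  w_vals <- 0:max_w
  u_vals <- w_vals - n1 * (n1 + 1) / 2
  dist <- counts[n1 + 1L, ]
  total <- choose(N, n1)
  mu <- n1 * n2 / 2
  p <- sum(dist[abs(u_vals - mu) >= abs(u_obs - mu) - 1e-9]) / total
  min(1, p)
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact p by enumeration of rank assignments when `n1 + n2 <= exact_max_n`
#' (default 12) and there are no ties; otherwise a normal approximation with
#' tie-corrected variance and 0.5 continuity correction. Samples with ties
#' always use the approximation.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max_n Largest combined sample size for the exact path.
#' @return An `mwu_test` object: `U` (statistic for `x`), `n1`, `n2`,
#'   `p_two_tailed`, `method` (`"exact"` or `"normal_approx"`), `medians`.
#'   `U` for `x` and `U` for `y` always sum to `n1 * n2`.
#' @examples
#' mwu_test(c(1, 2), c(3, 4))
#' @export
mwu_test <- function(x, y, exact_max_n = 12L) {
  if (length(x) == 0L || length(y) == 0L) {
    abort("mwu_test() needs non-empty groups")
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  combined <- c(x, y)
  r <- rank(combined)
  w1 <- sum(r[seq_len(n1)])
  u1 <- w1 - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(combined) > 0L
  if (!has_ties && N <= exact_max_n) {
    p <- mwu_exact_p(u1, n1, n2)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(combined)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u1 - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal_approx"
  }
  structure(list(U = u1, n1 = n1, n2 = n2, p_two_tailed = p,
                 method = method,
                 medians = c(median(x), median(y))),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Two-tailed Mann-Whitney U test (%s)\nU = %g, n = (%d, %d), medians = (%g, %g), p = %.4g\n",
              x$method, x$U, x$n1, x$n2, x$medians[1], x$medians[2],
              x$p_two_tailed))
  invisible(x)
}

#' @rdname mwu_test
#' @param x An `mwu_test` object.
#' @param ... Unused.
#' @method tidy mwu_test
#' @export
tidy.mwu_test <- function(x, ...) {
  tibble(U = x$U, n1 = x$n1, n2 = x$n2,
         median1 = x$medians[1], median2 = x$medians[2],
         p.value = x$p_two_tailed, method = x$method)
}

#' @rdname mwu_test
#' @method glance mwu_test
#' @export
glance.mwu_test <- function(x, ...) {
  tibble(p.value = x$p_two_tailed, method = x$method, nobs = x$n1 + x$n2)
}

event_lengths <- function(events, measure) {
  if (measure == "del_len") {
    events |>
      filter(.data$event_class %in% c("deletion", "delins")) |>
      dplyr::pull(.data$del_len)
  } else {
    events |>
      filter(.data$event_class %in% c("insertion", "delins")) |>
      mutate(ins_len = nchar(.data$ins_seq)) |>
      dplyr::pull(.data$ins_len)
  }
}

mwu_row <- function(x, y, alpha, min_n) {
  if (length(x) < min_n || length(y) < min_n) {
    warn(sprintf("group below minimum size (%d vs %d events); emitting NA row",
                 length(x), length(y)))
    return(tibble(n1 = length(x), n2 = length(y), median1 = NA_real_,
                  median2 = NA_real_, U = NA_real_, p.value = NA_real_,
                  method = NA_character_, significant = NA))
  }
  t <- tidy(mwu_test(x, y))
  tibble(n1 = t$n1, n2 = t$n2, median1 = t$median1, median2 = t$median2,
         U = t$U, p.value = t$p.value, method = t$method,
         significant = t$p.value < alpha)
}

#' Genotype contrasts of deletion or insertion lengths
#'
#' For `measure = "del_len"`: wild type versus each mutant genotype, per
#' nuclease, on deletion lengths (classes deletion and delins; the deleted
#' reference bases of a delins count, its insertion does not). For
#' `measure = "ins_len"`: the same contrasts on insertion lengths, pooled
#' across nucleases (insertion and delins classes). Substitutions are
#' excluded throughout. Raw p-values are flagged at `alpha` without
#' multiple-testing correction; `holm = TRUE` adds a Holm-adjusted column.
#'
#' @param events Deduplicated event tibble (from [dedupe_events()] or
#'   [annotate_footprints()]).
#' @param measure `"del_len"` or `"ins_len"`.
#' @param reference_genotype Genotype used as the comparison baseline.
#' @param alpha Significance threshold for the flag.
#' @param min_n Minimum events per group; smaller groups yield an NA row
#'   with a warning.
#' @param holm Add Holm-adjusted p-values.
#' @return Tibble: one row per (nuclease, contrast) with group sizes,
#'   medians, `U`, `p.value`, `method`, `significant`.
#' @export
compare_genotypes <- function(events, measure = c("del_len", "ins_len"),
                              reference_genotype = "WT", alpha = 0.05,
                              min_n = 2L, holm = FALSE) {
  measure <- match.arg(measure)
  groups <- if (measure == "del_len") {
    split(events, events$nuclease)
  } else {
    list(pooled = events)   # both targets combined
  }
  rows <- purrr::imap(groups, function(ev, nuc) {
    mutants <- setdiff(unique(ev$genotype), reference_genotype)
    ref_lens <- event_lengths(filter(ev, .data$genotype == reference_genotype),
                              measure)
    purrr::map(sort(mutants), function(g) {
      mut_lens <- event_lengths(filter(ev, .data$genotype == g), measure)
      bind_cols(tibble(nuclease = nuc, measure = measure,
                       group1 = reference_genotype, group2 = g),
                mwu_row(ref_lens, mut_lens, alpha, min_n))
    }) |> bind_rows()
  }) |> bind_rows()
  if (holm) rows$p.holm <- stats::p.adjust(rows$p.value, method = "holm")
  rows
}

#' Are deletions accompanied by insertions longer?
#'
#' Two-tailed Mann-Whitney U of deletion lengths partitioned by presence of
#' an insertion (delins versus pure deletion), pooled across genotypes and
#' targets.
#'
#' @param events Deduplicated event tibble.
#' @param alpha Significance threshold for the flag.
#' @return One-row tibble (`group1` = with insertion, `group2` = without);
#'   NA row if either partition is empty.
#' @export
deletion_with_without_insertion <- function(events, alpha = 0.05) {
  with_ins <- events |> filter(.data$event_class == "delins") |>
    dplyr::pull(.data$del_len)
  without <- events |> filter(.data$event_class == "deletion") |>
    dplyr::pull(.data$del_len)
  bind_cols(tibble(measure = "del_len", group1 = "with_insertion",
                   group2 = "without_insertion"),
            mwu_row(with_ins, without, alpha, min_n = 1L))
}

#' Fraction of mutated molecules from band intensities
#'
#' The relative number of nuclease-induced mutations in a lane: intensity of
#' the digest-resistant band divided by the total intensity of all bands.
#'
#' @param resistant_intensity Intensity of the digest-resistant band (>= 0).
#' @param all_band_intensities Intensities of all bands in the lane,
#'   including the resistant one.
#' @return Fraction in `[0, 1]`.
#' @examples
#' resistant_fraction(30, c(30, 70))
#' @export
resistant_fraction <- function(resistant_intensity, all_band_intensities) {
  if (resistant_intensity < 0 || any(all_band_intensities < 0)) {
    abort("band intensities must be non-negative")
  }
  total <- sum(all_band_intensities)
  if (total <= 0) abort("total band intensity must be positive")
  if (resistant_intensity > total + 1e-9) {
    abort("resistant band intensity exceeds the lane total")
  }
  resistant_intensity / total
}
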