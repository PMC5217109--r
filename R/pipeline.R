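# Pipeline orchestration: file I/O, the full call -> dedupe -> filter ->
# annotate -> stats chain, a run manifest for reproducibility accounting,
# and a plain-text report. TSV outputs are deterministic for fixed inputs.

#' Read clone reads from a FASTA file
#'
#' @param path FASTA path.
#' @return Tibble with `clone_id` (record id up to the first space) and
#'   `sequence`.
#' @export
read_reads_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  tibble(clone_id = sub("\\s.*$", "", names(ss)),
         sequence = as.character(ss))
}

#' Read a sample sheet mapping clone ids to line/genotype/nuclease
#'
#' @param path TSV with columns `clone_id`, `line_id`, `genotype`,
#'   `nuclease`.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(sprintf("sample sheet not found: %s", path))
  sheet <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("clone_id", "line_id", "genotype", "nuclease")
  missing_cols <- setdiff(req, names(sheet))
  if (length(missing_cols) > 0L) {
    abort(paste("sample sheet lacks columns:",
                paste(missing_cols, collapse = ", ")))
  }
  sheet
}

# Parse "cloneID|line|genotype|nuclease" FASTA headers (fallback channel
# when no sample sheet is given).
metadata_from_headers <- function(reads) {
  parts <- stringr::str_split(reads$clone_id, stringr::fixed("|"))
  if (any(lengths(parts) != 4L)) {
    abort("no sample sheet given and FASTA headers do not follow 'cloneID|line|genotype|nuclease'")
  }
  m <- do.call(rbind, parts)
  tibble(clone_id = reads$clone_id, line_id = m[, 2L],
         genotype = m[, 3L], nuclease = m[, 4L])
}

pkg_version <- function() as.character(utils::packageVersion("dsbfootprints"))

file_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

write_manifest <- function(out_dir, stage, params, inputs, counts,
                           seed = NA_integer_) {
  manifest <- list(
    tool = "dsbfootprints", version = pkg_version(), stage = stage,
    seed = seed, parameters = params,
    inputs = file_checksums(inputs),
    counts = counts, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Read a simulation configuration from JSON
#'
#' Keys: `locus` (path to a locus JSON, or an inline locus object),
#' `n_clones`, `genotype`, `nuclease`, `seed`, optional `clones_per_line`,
#' `noise_rate`, and `params` (overrides for [preset_profile()] values).
#'
#' @param path JSON path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("simulation config not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("locus", "n_clones")) {
    if (is.null(cfg[[key]])) {
      abort(sprintf("simulation config %s lacks key '%s'", path, key))
    }
  }
  locus <- if (is.character(cfg$locus)) {
    lp <- cfg$locus
    if (!file.exists(lp)) lp <- file.path(dirname(path), cfg$locus)
    read_locus_json(lp)
  } else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(cfg$locus, tmp, auto_unbox = TRUE)
    read_locus_json(tmp)
  }
  args <- c(list(locus = locus, n_clones = cfg$n_clones,
                 genotype = cfg$genotype %||% "WT",
                 nuclease = cfg$nuclease %||% "Cas9-CRU",
                 seed = cfg$seed %||% 1L,
                 clones_per_line = cfg$clones_per_line %||% 10L,
                 noise_rate = cfg$noise_rate %||% 0),
            as.list(cfg$params))
  do.call(simulation_config, args)
}

#' Simulate a dataset and write it with a manifest
#'
#' @param config A [simulation_config()] or path to a simulation JSON.
#' @param out_dir Output directory.
#' @return Invisibly, the truth tibble.
#' @export
run_simulate <- function(config, out_dir) {
  cfg <- if (inherits(config, "simulation_config")) config else {
    read_simulation_config(config)
  }
  truth <- generate_dataset(cfg, out_dir)
  write_manifest(
    out_dir, "simulate",
    params = list(genotype = cfg$genotype, nuclease = cfg$nuclease,
                  n_clones = cfg$n_clones,
                  clones_per_line = cfg$clones_per_line,
                  noise_rate = cfg$noise_rate, locus = cfg$locus$name),
    inputs = character(),
    counts = list(clones_written = nrow(truth),
                  detectable = sum(truth$detectable),
                  mh_fallbacks = attr(truth, "mh_fallbacks")),
    seed = cfg$seed)
  invisible(truth)
}

#' Run the full footprint-analysis chain on a set of clone reads
#'
#' Stages, in order: footprint calling, per-line deduplication, optional
#' loss-of-restriction-site filter (`predigest = TRUE` keeps only
#' digest-resistant clones, emulating enrichment by predigestion),
#' microhomology/template annotation, and genotype statistics. All
#' thresholds are echoed into the manifest so the run is self-describing.
#'
#' @param locus A [target_locus()] or path to a locus JSON.
#' @param reads_fasta FASTA of clone reads.
#' @param sample_sheet TSV mapping clone ids to line/genotype/nuclease, or
#'   `NULL` to parse `cloneID|line|genotype|nuclease` FASTA headers.
#' @param out_dir Output directory.
#' @param predigest Restrict statistics to digest-resistant clones.
#' @param window_bp,min_search_len,min_seed,primed_min Template-search
#'   thresholds (see [find_template()], [primer_identity()]).
#' @param alpha Significance threshold for contrast flags.
#' @param max_radius Complex-clone radius for [call_footprints()].
#' @return Invisibly, a list with `footprints`, `events` (annotated),
#'   `stats`, `distributions`, `manifest`.
#' @export
run_analyze <- function(locus, reads_fasta, sample_sheet = NULL, out_dir,
                        predigest = TRUE, window_bp = 100L,
                        min_search_len = 3L, min_seed = 4L, primed_min = 2L,
                        alpha = 0.05, max_radius = 250L) {
  if (is.character(locus)) locus <- read_locus_json(locus)
  stopifnot(inherits(locus, "target_locus"))
  reads <- read_reads_fasta(reads_fasta)
  sheet <- if (is.null(sample_sheet)) {
    metadata_from_headers(reads)
  } else {
    read_sample_sheet(sample_sheet)
  }
  orphans <- setdiff(reads$clone_id, sheet$clone_id)
  if (length(orphans) > 0L) {
    abort(paste("FASTA ids missing from sample sheet:",
                paste(head(orphans, 10L), collapse = ", ")))
  }
  reads <- left_join(reads, sheet, by = "clone_id") |>
    select("clone_id", "line_id", "genotype", "nuclease", "sequence")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  footprints <- call_footprints(reads, locus, max_radius = max_radius)
  readr::write_tsv(footprints, file.path(out_dir, "footprints.tsv"))

  events <- dedupe_events(footprints)
  duplicates_removed <- attr(events, "duplicates_removed")
  n_dedup <- nrow(events)
  filtered_by_digest <- 0L
  if (predigest) {
    filtered_by_digest <- sum(!events$detectable)
    events <- filter(events, .data$detectable)
  }
  events <- annotate_footprints(events, locus, window_bp = window_bp,
                                min_search_len = min_search_len,
                                min_seed = min_seed, primed_min = primed_min)
  readr::write_tsv(events, file.path(out_dir, "annotations.tsv"))

  mutated <- filter(events, .data$event_class != "intact")
  stats_tbl <- NULL
  dist_tbl <- NULL
  if (nrow(mutated) == 0L) {
    warn("empty event set after filtering; statistics skipped")
  } else {
    deletions <- filter(mutated, .data$event_class %in% c("deletion", "delins"))
    dist_tbl <- deletions |>
      group_by(.data$genotype, .data$nuclease) |>
      dplyr::group_modify(~ bin_deletions(.x$del_len)) |>
      ungroup()
    readr::write_tsv(dist_tbl, file.path(out_dir, "distributions.tsv"))
    jsonlite::write_json(dist_tbl, file.path(out_dir, "distributions.json"),
                         digits = NA)
    stats_tbl <- dplyr::bind_rows(
      if (length(unique(mutated$genotype)) > 1L) bind_rows(
        compare_genotypes(mutated, "del_len", alpha = alpha),
        compare_genotypes(mutated, "ins_len", alpha = alpha)),
      deletion_with_without_insertion(mutated, alpha = alpha))
    readr::write_tsv(stats_tbl, file.path(out_dir, "stats.tsv"))
    jsonlite::write_json(stats_tbl, file.path(out_dir, "stats.json"),
                         digits = NA)
    readr::write_tsv(summarize_templates(mutated),
                     file.path(out_dir, "template_summary.tsv"))
  }

  counts <- list(
    clones_read = nrow(reads),
    unalignable = sum(footprints$status == "unalignable"),
    complex = sum(footprints$status == "complex"),
    duplicates_removed = duplicates_removed,
    events_after_dedup = n_dedup,
    filtered_by_digest = filtered_by_digest,
    events_final = nrow(events))
  manifest <- write_manifest(
    out_dir, "analyze",
    params = list(predigest = predigest, window_bp = window_bp,
                  min_search_len = min_search_len, min_seed = min_seed,
                  primed_min = primed_min, alpha = alpha,
                  max_radius = max_radius, locus = locus$name),
    inputs = c(reads_fasta, if (!is.null(sample_sheet)) sample_sheet),
    counts = counts)
  invisible(list(footprints = footprints, events = events,
                 stats = stats_tbl, distributions = dist_tbl,
                 manifest = manifest))
}

fmt_table <- function(df) {
  paste(utils::capture.output(print(as.data.frame(df), row.names = FALSE)),
        collapse = "\n")
}

#' Write a human-readable summary of an analysis directory
#'
#' Re-reads the manifest and TSV outputs of [run_analyze()] (numbers in the
#' report therefore byte-match the TSVs) and writes `report.txt`.
#'
#' @param out_dir Directory produced by [run_analyze()].
#' @return Invisibly, the report path.
#' @export
run_report <- function(out_dir) {
  man_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(man_path)) abort(sprintf("missing stage output: %s", man_path))
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  ann_path <- file.path(out_dir, "annotations.tsv")
  if (!file.exists(ann_path)) abort(sprintf("missing stage output: %s", ann_path))
  events <- readr::read_tsv(ann_path, show_col_types = FALSE)

  lines <- c(
    sprintf("dsbfootprints %s analysis report", manifest$version),
    sprintf("run: %s (stage %s)", manifest$timestamp, manifest$stage),
    "",
    "Stage counts:",
    paste(sprintf("  %-20s %s", names(manifest$counts),
                  unlist(manifest$counts)), collapse = "\n"),
    "")
  dist_path <- file.path(out_dir, "distributions.tsv")
  if (file.exists(dist_path)) {
    dist_tbl <- readr::read_tsv(dist_path, show_col_types = FALSE)
    lines <- c(lines, "Deletion-length distributions (deduplicated events):",
               fmt_table(dist_tbl), "")
  }
  stats_path <- file.path(out_dir, "stats.tsv")
  if (file.exists(stats_path)) {
    stats_tbl <- readr::read_tsv(stats_path, show_col_types = FALSE)
    lines <- c(lines, "Genotype contrasts (two-tailed Mann-Whitney U):",
               fmt_table(stats_tbl), "")
  }
  ins <- filter(events, .data$event_class %in% c("insertion", "delins"))
  if (nrow(ins) == 0L) {
    lines <- c(lines, "Insertions: none observed.")
  } else {
    lines <- c(lines, "Templated-insertion summary:",
               fmt_table(summarize_templates(ins)))
  }
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
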