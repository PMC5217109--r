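# Independent oracles and fixture builders used across the suite.

# naive O(n*m) sliding-window site scan on both strands
oracle_sites <- function(seq, recognition) {
  m <- nchar(recognition)
  rc <- revcomp(recognition)
  hits <- list()
  for (i in 0:(nchar(seq) - m)) {
    win <- substr(seq, i + 1, i + m)
    if (win == recognition) {
      hits[[length(hits) + 1]] <- list(position = i, strand = "+")
    } else if (win == rc) {
      hits[[length(hits) + 1]] <- list(position = i, strand = "-")
    }
  }
  dplyr::bind_rows(hits)
}

# full-enumeration two-tailed Mann-Whitney p via combn (tie-free samples)
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  labelings <- utils::combn(N, n1)
  ranks_all <- seq_len(N)
  u_all <- apply(labelings, 2, function(idx) sum(ranks_all[idx])) -
    n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# truth tibble -> reads tibble for call_footprints()
truth_to_reads <- function(truth) {
  dplyr::tibble(clone_id = truth$clone_id, line_id = truth$line_id,
                genotype = truth$genotype, nuclease = truth$nuclease,
                sequence = truth$read)
}

# reassemble a called footprint without using package caller internals
reassemble <- function(reference, del_start, del_end, ins_seq) {
  paste0(substr(reference, 1, del_start), ins_seq,
         substring(reference, del_end + 1))
}

test_locus <- function() synthetic_locus("cru_like")
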