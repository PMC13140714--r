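# Independent oracles and small fixture builders, kept deliberately naive so
# they cannot share a defect with the implementation they check.

# BH step-up straight from the definition: adjusted p for the i-th order
# statistic is min(1, min_{j >= i} m * p_(j) / j), O(m^2).
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    adj_sorted[i] <- min(1, min(cand))
  }
  adj_sorted[order(o)]
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# n-subsets of a universe of size N containing K successes (N <= 12 or so).
hyper_tail_bruteforce <- function(k, K, N, n) {
  universe <- seq_len(N)
  successes <- seq_len(K)
  draws <- utils::combn(universe, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% successes))
  mean(hits >= k)
}

# Cross-tab cell counts by direct row-wise enumeration over assignments.
crosstab_bruteforce <- function(assign_df) {
  counts <- list()
  for (i in seq_len(nrow(assign_df))) {
    r <- assign_df[i, ]
    key <- paste(r$relation_to_island, r$refgene_group, r$state_case,
                 r$change_class, sep = "|")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  counts
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny beta matrix + sheet with explicit per-group values per probe.
make_beta <- function(control, case, probe_ids = NULL) {
  stopifnot(nrow(control) == nrow(case))
  if (is.null(probe_ids)) probe_ids <- sprintf("cg%05d", seq_len(nrow(control)))
  mat <- cbind(control, case)
  rownames(mat) <- probe_ids
  colnames(mat) <- sprintf("S%03d", seq_len(ncol(mat)))
  sheet <- data.frame(
    sample_id = colnames(mat),
    group = c(rep("Control", ncol(control)), rep("Periodontitis", ncol(case))),
    dataset_id = "DS1", stringsAsFactors = FALSE)
  list(beta = mat, sheet = sheet)
}

# Sheet for an existing matrix: first n_control columns are Control.
make_sheet <- function(mat, n_control) {
  data.frame(sample_id = colnames(mat),
             group = rep(c("Control", "Periodontitis"),
                         c(n_control, ncol(mat) - n_control)),
             dataset_id = "DS1", stringsAsFactors = FALSE)
}

# Manifest row builder for hand-made annotation cases.
make_manifest <- function(probe_id, genes = "", groups = "", relation = "OpenSea",
                          refseq = "") {
  data.frame(IlmnID = probe_id, CHR = "1", MAPINFO = seq_along(probe_id),
             UCSC_RefGene_Name = genes, UCSC_RefGene_Group = groups,
             Relation_to_Island = relation, RefSeq_ID = refseq,
             stringsAsFactors = FALSE)
}
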