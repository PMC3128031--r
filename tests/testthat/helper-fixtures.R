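# Shared fixtures and independent oracles.  Everything is built in code;
# no binary or external data.

# A small reference table in the classical SSR layout: 3 samples, 4
# markers, one missing call at (Sample2, SSR2).
reference_table <- function() {
  genotype_table(
    matrix(c("177/181", "177/181", "175/177",
             "191/193", "-",       "193",
             "172",     "172/174", "168/172",
             "176/182/186", "176", "180/182"), 3, 4),
    sample_ids = paste0("Sample", 1:3),
    marker_ids = paste0("SSR", 1:4))
}

# Random per-marker allele-set lists for pair-level kernel tests.
random_genotype <- function(n_markers, allele_pool = 100:115,
                            max_ploidy = 4, missing_prob = 0) {
  g <- lapply(seq_len(n_markers), function(k) {
    if (stats::runif(1) < missing_prob) return(NULL)
    sort(sample(allele_pool, sample.int(max_ploidy, 1)))
  })
  names(g) <- paste0("M", seq_len(n_markers))
  g
}

# Independent brute-force Dice oracle on pooled marker-tagged allele sets
# (missing = empty set, matching the package default).
dice_oracle <- function(a, b, markers = names(a)) {
  tag <- function(g) {
    unlist(lapply(markers, function(k) {
      if (is.null(g[[k]])) character(0) else paste0(k, ":", g[[k]])
    }))
  }
  ta <- tag(a); tb <- tag(b)
  2 * length(intersect(ta, tb)) / (length(ta) + length(tb))
}

# Pairwise-deletion variant of the oracle.
dice_oracle_pairwise <- function(a, b, markers = names(a)) {
  keep <- markers[!vapply(a[markers], is.null, logical(1)) &
                    !vapply(b[markers], is.null, logical(1))]
  dice_oracle(a, b, keep)
}

# Deterministic 4-group table where marker M1 splits {G1,G2}|{G3,G4},
# M2 duplicates M1 exactly, and M3 makes the complementary split
# {G1,G3}|{G2,G4}; M4 is constant noise.  Groups are only fully separable
# by combining M1 and M3.  One sample per group is flipped in M1/M2 and a
# different one in M3 so the empirical uncertainty coefficients sit
# strictly inside (0, 1) with positive asymptotic variance (a perfectly
# deterministic balanced map has variance 0 and an infinite Z-score).
complementary_table <- function(per_group = 6) {
  groups <- rep(paste0("G", 1:4), each = per_group)
  m1 <- ifelse(groups %in% c("G1", "G2"), "100", "102")
  m3 <- ifelse(groups %in% c("G1", "G3"), "200", "202")
  first_of_group <- match(paste0("G", 1:4), groups)
  m1[first_of_group] <- ifelse(m1[first_of_group] == "100", "102", "100")
  m3[first_of_group + 1L] <- ifelse(m3[first_of_group + 1L] == "200",
                                    "202", "200")
  genotype_table(cbind(M1 = m1, M2 = m1, M3 = m3,
                       M4 = rep("300", length(groups))),
                 sample_ids = paste0("s", seq_along(groups)),
                 marker_ids = c("M1", "M2", "M3", "M4"),
                 labels = groups)
}

# A perfectly separable world: disjoint per-group allele pools, no noise.
separable_spec <- function(n_groups = 3, per_group = 6, n_markers = 4,
                           seed = 5) {
  synth_spec(n_groups = n_groups, samples_per_group = per_group,
             n_markers = n_markers, informative_markers = n_markers,
             alleles_per_marker = n_groups, ploidy = 1,
             miscall_rate = 0, missing_rate = 0, private_alleles = TRUE,
             seed = seed)
}
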