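#' @title Synthetic SSR genotype generator
#' @name synth_data
#'
#' @description
#' Generates genotype tables with controlled group structure so that every
#' other module is testable without external data.  The generator emulates
#' the features of real SSR panels that matter for kernel classification
#' and kit selection: several groups; per-group allele-frequency profiles
#' at *informative* markers and one shared profile at *noise* markers;
#' 1-4 alleles drawn per sample per marker (functional-diploid-like calls);
#' optional replicate samples; miscall noise; missing calls; and marker
#' pairs constrained to duplicate each other (to exercise redundancy
#' skipping).
#'
#' Allele sizes live on a di-nucleotide-like ladder (marker base size plus
#' 2 bp per repeat unit), and a miscall shifts an allele by one repeat unit
#' (+/- 2 bp) rather than resampling it — mimicking fragment-analysis
#' misreads.
NULL

#' Specify a synthetic SSR dataset
#'
#' @param n_groups Number of classes.
#' @param samples_per_group Samples per class (scalar or vector of length
#'   `n_groups`).  Replicates are implicit: samples of a group share the
#'   group's allele-frequency profile.
#' @param n_markers Total number of markers.
#' @param informative_markers How many markers (or which marker indices)
#'   carry group-specific profiles; the rest share one profile across
#'   groups.
#' @param alleles_per_marker Number of distinct allele sizes segregating at
#'   each marker (scalar or range `c(lo, hi)`).
#' @param ploidy Alleles drawn per sample per marker before set collapse
#'   (1-4).
#' @param concentration Dirichlet concentration of the per-group profiles;
#'   small values give each group a few dominant private-ish alleles
#'   (strong signal), large values make groups similar.
#' @param miscall_rate Probability that a drawn allele is shifted by one
#'   repeat unit.
#' @param missing_rate Probability that a call is dropped entirely.
#' @param redundancy_pairs Optional list of 2-vectors of marker indices;
#'   the second marker of each pair copies the first's genotypes (before
#'   miscall/missing perturbation).  Pairs must be disjoint.
#' @param private_alleles If `TRUE`, the allele ladder of every informative
#'   marker is partitioned into contiguous per-group blocks, so groups have
#'   disjoint allele pools (a maximally separable world; with one allele
#'   per block and `ploidy = 1` the genotypes are deterministic per group).
#' @param seed Integer seed; the generated table is fully determined by the
#'   spec including this seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_groups, samples_per_group, n_markers,
                       informative_markers = n_markers,
                       alleles_per_marker = c(4L, 8L), ploidy = 2L,
                       concentration = 0.3, miscall_rate = 0.02,
                       missing_rate = 0.01, redundancy_pairs = NULL,
                       private_alleles = FALSE, seed = 1L) {
  stopifnot(n_groups >= 1, n_markers >= 1, ploidy >= 1, ploidy <= 4,
            miscall_rate >= 0, miscall_rate <= 1,
            missing_rate >= 0, missing_rate <= 1, concentration > 0)
  if (length(samples_per_group) == 1L) {
    samples_per_group <- rep(samples_per_group, n_groups)
  }
  stopifnot(length(samples_per_group) == n_groups, all(samples_per_group >= 1))
  if (length(informative_markers) == 1L &&
      informative_markers <= n_markers && informative_markers >= 0 &&
      !is.logical(informative_markers)) {
    informative_markers <- seq_len(informative_markers)
  }
  stopifnot(all(informative_markers %in% seq_len(n_markers)))
  if (length(alleles_per_marker) == 1L) {
    alleles_per_marker <- rep(alleles_per_marker, 2L)
  }
  stopifnot(alleles_per_marker[1L] >= ploidy)
  if (isTRUE(private_alleles) && alleles_per_marker[1L] < n_groups) {
    stop("private_alleles needs at least one allele per group: increase ",
         "alleles_per_marker", call. = FALSE)
  }
  if (!is.null(redundancy_pairs)) {
    flat <- unlist(redundancy_pairs)
    stopifnot(all(vapply(redundancy_pairs, length, 1L) == 2L),
              all(flat %in% seq_len(n_markers)), !anyDuplicated(flat))
  }
  structure(list(n_groups = as.integer(n_groups),
                 samples_per_group = as.integer(samples_per_group),
                 n_markers = as.integer(n_markers),
                 informative_markers = as.integer(informative_markers),
                 alleles_per_marker = as.integer(alleles_per_marker),
                 ploidy = as.integer(ploidy),
                 concentration = concentration,
                 miscall_rate = miscall_rate,
                 missing_rate = missing_rate,
                 redundancy_pairs = redundancy_pairs,
                 private_alleles = isTRUE(private_alleles),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# rgamma-based Dirichlet draw
rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  while (sum(g) == 0) g <- stats::rgamma(k, shape = conc)
  g / sum(g)
}

#' Generate a synthetic genotype table
#'
#' Draws, for every sample and marker, `ploidy` alleles from the group's
#' profile (informative markers) or the shared profile (noise markers),
#' collapses them to a set, copies redundant markers, then applies miscall
#' shifts and missingness.  Fully determined by `spec$seed`; the caller's
#' RNG state is left untouched.
#'
#' @param spec A [synth_spec()].
#' @return A labelled [genotype_table()].
#' @export
generate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- sum(spec$samples_per_group)
  m <- spec$n_markers
  groups <- rep(paste0("G", seq_len(spec$n_groups)),
                spec$samples_per_group)
  # di-nucleotide ladders: per-marker base size + 2 bp per repeat step
  allele_range <- spec$alleles_per_marker[1L]:spec$alleles_per_marker[2L]
  n_alleles <- allele_range[sample.int(length(allele_range), m,
                                       replace = TRUE)]
  base_size <- sample(seq(80L, 300L, by = 2L), m, replace = TRUE)
  ladders <- lapply(seq_len(m), function(k) {
    base_size[k] + 2L * seq_len(n_alleles[k])
  })
  shared_profiles <- lapply(seq_len(m), function(k) {
    rdirichlet1(n_alleles[k], 1)
  })
  group_profiles <- lapply(seq_len(m), function(k) {
    if (k %in% spec$informative_markers) {
      lapply(seq_len(spec$n_groups), function(g) {
        prof <- rdirichlet1(n_alleles[k], spec$concentration)
        if (spec$private_alleles) {
          # contiguous per-group ladder blocks: disjoint allele pools
          block <- floor(n_alleles[k] * (g - 1) / spec$n_groups) +
            seq_len(max(floor(n_alleles[k] / spec$n_groups), 1L))
          block <- block[block <= n_alleles[k]]
          masked <- rep(0, n_alleles[k])
          masked[block] <- prof[block] + 1e-12
          prof <- masked / sum(masked)
        }
        prof
      })
    } else NULL
  })

  cells <- matrix(vector("list", n * m), n, m)
  group_idx <- rep(seq_len(spec$n_groups), spec$samples_per_group)
  copy_from <- integer(0); copy_to <- integer(0)
  for (pr in spec$redundancy_pairs) {
    copy_from <- c(copy_from, pr[1L]); copy_to <- c(copy_to, pr[2L])
  }
  for (i in seq_len(n)) {
    for (k in seq_len(m)) {
      if (k %in% copy_to) next
      prof <- if (is.null(group_profiles[[k]])) shared_profiles[[k]]
              else group_profiles[[k]][[group_idx[i]]]
      draw <- ladders[[k]][sample.int(n_alleles[k], spec$ploidy,
                                      replace = TRUE, prob = prof)]
      cells[[i, k]] <- sort(unique(draw))
    }
    # redundant markers duplicate the source marker's call (same ladder)
    for (t in seq_along(copy_to)) {
      cells[[i, copy_to[t]]] <- cells[[i, copy_from[t]]]
    }
    for (k in seq_len(m)) {
      a <- cells[[i, k]]
      if (spec$miscall_rate > 0) {
        shift <- stats::runif(length(a)) < spec$miscall_rate
        if (any(shift)) {
          a[shift] <- a[shift] + sample(c(-2L, 2L), sum(shift),
                                        replace = TRUE)
          a <- sort(unique(pmax(a, 2L)))
        }
      }
      if (spec$missing_rate > 0 && stats::runif(1) < spec$missing_rate) {
        a <- NULL
      }
      cells[i, k] <- list(a)
    }
  }
  genotype_table(cells,
                 sample_ids = paste0("S", seq_len(n)),
                 marker_ids = paste0("SSR", seq_len(m)),
                 labels = groups)
}

#' Preset dataset shapes
#'
#' Four `synth_spec`s whose shapes (samples, markers, classes) mirror the
#' panel designs common in tobacco variety identification studies:
#'
#' * `tobtype`: 91 samples, 186 markers, 3 tobacco types;
#' * `landrace`: 250 samples (10 landraces x 25 replicates), 19 markers;
#' * `geovar`: 93 samples, 48 markers, 12 regional subtypes;
#' * `orvar`: 88 samples, 48 markers, 8 variety families.
#'
#' Group-profile strength, miscall and missing rates are fixed, realistic
#' defaults; see the methods vignette for the rationale.
#'
#' @param seed Base seed stored in each spec (presets get offsets so the
#'   four tables are independent).
#' @return A named list of [synth_spec()] objects.
#' @export
dataset_presets <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    tobtype = synth_spec(n_groups = 3, samples_per_group = c(30, 30, 31),
                         n_markers = 186, informative_markers = 60,
                         miscall_rate = 0.02, missing_rate = 0.01,
                         seed = seed),
    landrace = synth_spec(n_groups = 10, samples_per_group = 25,
                          n_markers = 19, informative_markers = 12,
                          miscall_rate = 0.02, missing_rate = 0.01,
                          seed = seed + 1L),
    geovar = synth_spec(n_groups = 12,
                        samples_per_group = c(rep(8, 9), rep(7, 3)),
                        n_markers = 48, informative_markers = 24,
                        miscall_rate = 0.02, missing_rate = 0.02,
                        seed = seed + 2L),
    orvar = synth_spec(n_groups = 8, samples_per_group = 11,
                       n_markers = 48, informative_markers = 24,
                       miscall_rate = 0.02, missing_rate = 0.01,
                       seed = seed + 3L))
}
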