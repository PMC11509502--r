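#' Configuration for the synthetic paired-proteome generator
#'
#' The defaults emulate the data shape of a 10-subject, two-tissue label-free
#' study: ~2773 proteins, heavy zero-inflation, a planted set of
#' condition-unique proteins at the presence fractions seen in such studies
#' (one at 9/10, ..., several at 4/10 in one condition and 0/10 in the
#' other), log-normal positive intensities on the log2 scale, and a block of
#' proteins with a multiplicative paired intensity shift.
#'
#' @param n_subjects number of paired subjects (default 10).
#' @param n_proteins total proteins (default 2773).
#' @param conditions length-2 character vector of condition labels.
#' @param unique_fractions_a,unique_fractions_b presence fractions of the
#'   planted condition-unique proteins (each in (0, 1]); their lengths set
#'   the planted counts (defaults: 5 for A, 18 for B).
#' @param n_shifted proteins detected everywhere whose condition-A
#'   intensities are multiplied by `shift_effect` (default 50).
#' @param shift_effect multiplicative effect size (default 8, i.e. 3 log2
#'   units — a strong but realistic tissue effect).
#' @param detection_prob baseline per-sample detection probability for
#'   background proteins (default 0.8; see the methods vignette for the
#'   rationale).
#' @param intensity_log_mean,intensity_log_sd mean and sd of log2 intensity
#'   for detected proteins (defaults 20 and 2, typical of label-free
#'   reported intensities).
#' @param enriched_set_size members of the planted enriched annotation set
#'   (default 15).
#' @param n_decoy_sets,decoy_set_size decoy annotation sets of random
#'   background proteins (defaults 10 sets of 15).
#' @param seed optional integer seed; when non-`NULL`,
#'   [generate_paired_proteome()] seeds the RNG itself.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 10L,
                             n_proteins = 2773L,
                             conditions = c("orbital", "abdominal"),
                             unique_fractions_a = c(0.9, 0.5, 0.4, 0.4, 0.4),
                             unique_fractions_b = c(rep(0.6, 3), rep(0.5, 8),
                                                    rep(0.4, 7)),
                             n_shifted = 50L,
                             shift_effect = 8,
                             detection_prob = 0.8,
                             intensity_log_mean = 20,
                             intensity_log_sd = 2,
                             enriched_set_size = 15L,
                             n_decoy_sets = 10L,
                             decoy_set_size = 15L,
                             seed = NULL) {
  stopifnot(n_subjects >= 2L, n_proteins >= 1L, length(conditions) == 2L,
            n_shifted >= 0L, shift_effect > 0,
            detection_prob >= 0, detection_prob <= 1,
            intensity_log_sd > 0, enriched_set_size >= 0L,
            n_decoy_sets >= 0L, decoy_set_size >= 1L)
  if (any(unique_fractions_a <= 0 | unique_fractions_a > 1) ||
      any(unique_fractions_b <= 0 | unique_fractions_b > 1))
    stop("unique presence fractions must lie in (0, 1]")
  n_planted <- length(unique_fractions_a) + length(unique_fractions_b) +
    n_shifted
  if (n_planted > n_proteins)
    stop("planted counts (", n_planted, ") exceed n_proteins (",
         n_proteins, ")")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_proteins = as.integer(n_proteins),
                 conditions = as.character(conditions),
                 unique_fractions_a = unique_fractions_a,
                 unique_fractions_b = unique_fractions_b,
                 n_shifted = as.integer(n_shifted),
                 shift_effect = shift_effect,
                 detection_prob = detection_prob,
                 intensity_log_mean = intensity_log_mean,
                 intensity_log_sd = intensity_log_sd,
                 enriched_set_size = as.integer(enriched_set_size),
                 n_decoy_sets = as.integer(n_decoy_sets),
                 decoy_set_size = as.integer(decoy_set_size),
                 seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic paired proteome
#'
#' Background proteins are detected independently per sample with
#' probability `detection_prob`; planted condition-unique proteins get bit 1
#' in exactly `round(fraction * n_subjects)` randomly chosen subjects of
#' their condition and 0 everywhere in the other; shifted proteins are
#' detected in all samples with condition-A intensities multiplied by
#' `shift_effect`. Detected intensities are `2^rnorm(log_mean, log_sd)`.
#' Fully reproducible given `config$seed` (or the caller's RNG state when
#' `seed` is `NULL`).
#'
#' @param config a [synthetic_config()].
#' @return A list with fields `intensities` ([intensity_matrix()]),
#'   `design` ([paired_design()]) and `truth` (list with `unique_a`,
#'   `unique_b`, `shifted`: disjoint planted protein id vectors).
#' @export
generate_paired_proteome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ns <- config$n_subjects
  np <- config$n_proteins
  width <- max(4L, nchar(as.character(np)))
  ids <- sprintf(paste0("PROT%0", width, "d"), seq_len(np))
  subjects <- sprintf("subj%02d", seq_len(ns))
  sample_a <- paste(subjects, config$conditions[1L], sep = "_")
  sample_b <- paste(subjects, config$conditions[2L], sep = "_")
  design <- paired_design(subjects, config$conditions[1L],
                          config$conditions[2L], sample_a, sample_b)

  nua <- length(config$unique_fractions_a)
  nub <- length(config$unique_fractions_b)
  planted <- sample.int(np, nua + nub + config$n_shifted)
  idx_ua <- planted[seq_len(nua)]
  idx_ub <- planted[nua + seq_len(nub)]
  idx_sh <- planted[nua + nub + seq_len(config$n_shifted)]

  bits <- matrix(stats::rbinom(np * 2L * ns, 1L, config$detection_prob),
                 nrow = np)
  colnames(bits) <- c(sample_a, sample_b)
  ca <- seq_len(ns)
  cb <- ns + seq_len(ns)
  plant_unique <- function(bits, idx, fracs, own, other) {
    for (j in seq_along(idx)) {
      bits[idx[j], c(own, other)] <- 0L
      k <- round(fracs[j] * ns)
      bits[idx[j], own[sample.int(ns, k)]] <- 1L
    }
    bits
  }
  bits <- plant_unique(bits, idx_ua, config$unique_fractions_a, ca, cb)
  bits <- plant_unique(bits, idx_ub, config$unique_fractions_b, cb, ca)
  bits[idx_sh, ] <- 1L

  values <- matrix(0, nrow = np, ncol = 2L * ns,
                   dimnames = list(ids, c(sample_a, sample_b)))
  ndet <- sum(bits)
  values[bits == 1L] <- 2^stats::rnorm(ndet, config$intensity_log_mean,
                                       config$intensity_log_sd)
  values[idx_sh, ca] <- values[idx_sh, ca] * config$shift_effect

  list(intensities = intensity_matrix(ids, c(sample_a, sample_b), values),
       design = design,
       truth = list(unique_a = ids[idx_ua], unique_b = ids[idx_ub],
                    shifted = ids[idx_sh]))
}

#' Deterministic appearance fixture at tabled presence fractions
#'
#' Builds a 23-protein, 10-subject, two-condition appearance matrix whose
#' per-condition presence counts match a published two-tissue unique-protein
#' inventory: condition A ("orbital") holds proteins present in 9, 5, 4, 4
#' and 4 subjects, condition B ("abdominal") proteins present in 6, 6, 6,
#' then 5 (x8) and 4 (x7) subjects — each absent from every sample of the
#' opposite condition. Presence is assigned to the lowest-index subjects;
#' the proportion test depends only on counts, so this choice is
#' immaterial.
#'
#' @return A list with fields `appearance` ([appearance_matrix()]) and
#'   `design` ([paired_design()]).
#' @export
build_tables_fixture <- function() {
  orbital <- c("Q16678" = 9L, "O94788" = 5L, "P02812" = 4L, "Q13740" = 4L,
               "P08582" = 4L)
  abdominal <- c("P28330" = 6L, "Q96HY7" = 6L, "P04440" = 6L, "P47712" = 5L,
                 "Q8IWW8" = 5L, "Q10713" = 5L, "Q6GTX8; Q6ISS4" = 5L,
                 "Q13424" = 5L, "Q5TFE4" = 5L, "Q92552" = 5L, "Q96GG9" = 5L,
                 "Q14008" = 4L, "Q6L8Q7" = 4L, "P10619" = 4L, "P27918" = 4L,
                 "Q9BYT8" = 4L, "O94925" = 4L, "P06454" = 4L)
  ns <- 10L
  subjects <- sprintf("patient%02d", seq_len(ns))
  sample_a <- paste0(subjects, "_orbital")
  sample_b <- paste0(subjects, "_abdominal")
  ids <- c(names(orbital), names(abdominal))
  bits <- matrix(0L, nrow = length(ids), ncol = 2L * ns,
                 dimnames = list(ids, c(sample_a, sample_b)))
  for (i in seq_along(orbital))
    bits[names(orbital)[i], seq_len(orbital[[i]])] <- 1L
  for (i in seq_along(abdominal))
    bits[names(abdominal)[i], ns + seq_len(abdominal[[i]])] <- 1L
  list(appearance = appearance_matrix(ids, c(sample_a, sample_b), bits),
       design = paired_design(subjects, "orbital", "abdominal",
                              sample_a, sample_b))
}

#' Generate annotation gene sets with a planted enriched set
#'
#' Builds one planted set drawn from the ground-truth effect proteins
#' (condition-unique proteins first — they carry extreme proportion-test
#' ranks — then shifted proteins), plus decoy sets of random background
#' proteins disjoint from the planted set. The planted set is named
#' `"planted_set"`; decoys `"decoy_01"`, ...
#'
#' @param truth the `truth` field of [generate_paired_proteome()] output.
#' @param config the [synthetic_config()] used for generation.
#' @return A [gene_set_collection()].
#' @export
generate_annotation_sets <- function(truth, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  pool <- c(truth$unique_a, truth$unique_b, truth$shifted)
  planted <- utils::head(pool, config$enriched_set_size)
  if (!length(planted)) stop("no planted effect proteins in ground truth")
  width <- max(4L, nchar(as.character(config$n_proteins)))
  all_ids <- sprintf(paste0("PROT%0", width, "d"),
                     seq_len(config$n_proteins))
  background <- setdiff(all_ids, c(pool, planted))
  sets <- list(planted_set = list(
    description = "planted truly-differential proteins", members = planted))
  for (j in seq_len(config$n_decoy_sets)) {
    sets[[sprintf("decoy_%02d", j)]] <- list(
      description = "random background proteins",
      members = sample(background, min(config$decoy_set_size,
                                       length(background))))
  }
  gene_set_collection(sets)
}
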