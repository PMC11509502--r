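#' Construct an appearance matrix
#'
#' Binary presence/absence patterns: 1 if a protein was observed with any
#' positive intensity in a sample, 0 otherwise.
#'
#' @param protein_ids,sample_ids unique identifier vectors.
#' @param bits integer matrix of 0/1 values, proteins x samples.
#' @return An object of class `appearance_matrix`.
#' @export
appearance_matrix <- function(protein_ids, sample_ids, bits) {
  protein_ids <- as.character(protein_ids)
  sample_ids <- as.character(sample_ids)
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (anyDuplicated(protein_ids))
    stop("duplicate protein id: ", protein_ids[duplicated(protein_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id")
  if (nrow(bits) != length(protein_ids) || ncol(bits) != length(sample_ids))
    stop("bits must be ", length(protein_ids), " x ", length(sample_ids))
  if (any(is.na(bits)) || any(!bits %in% c(0L, 1L)))
    stop("appearance bits must be 0 or 1")
  dimnames(bits) <- list(protein_ids, sample_ids)
  structure(list(protein_ids = protein_ids, sample_ids = sample_ids,
                 bits = bits),
            class = "appearance_matrix")
}

#' @export
print.appearance_matrix <- function(x, ...) {
  cat("appearance_matrix:", length(x$protein_ids), "proteins x",
      length(x$sample_ids), "samples;", sum(x$bits), "one-bits\n")
  invisible(x)
}

#' Binarize an intensity matrix into appearance patterns
#'
#' A protein is scored present (bit 1) in a sample iff its intensity is
#' strictly positive; zero (which also encodes blank/`NA` cells after
#' loading) scores absent.
#'
#' @param m an [intensity_matrix()].
#' @return An [appearance_matrix()] of the same shape and ids.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  appearance_matrix(m$protein_ids, m$sample_ids, (m$values > 0) * 1L)
}

#' Per-condition presence counts
#'
#' For each protein, counts the subjects whose condition-A (resp. -B) sample
#' contains the protein. Presence is evaluated through the design pairing,
#' so matrix columns not referenced by the design are ignored (with a
#' warning).
#'
#' @param a an [appearance_matrix()].
#' @param d a [paired_design()]; all design samples must be columns of `a`.
#' @return A data frame with columns `protein_id`, `k_a`, `k_b` and
#'   attributes `n_subjects` and `conditions`.
#' @export
condition_presence_counts <- function(a, d) {
  stopifnot(inherits(a, "appearance_matrix"), inherits(d, "paired_design"))
  design_samples <- c(d$pairs$sample_a, d$pairs$sample_b)
  missing <- setdiff(design_samples, a$sample_ids)
  if (length(missing))
    stop("design sample(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(a$sample_ids, design_samples)
  if (length(extra))
    warning("ignoring ", length(extra),
            " sample column(s) not referenced by the design: ",
            paste(utils::head(extra, 5L), collapse = ", "))
  out <- data.frame(
    protein_id = a$protein_ids,
    k_a = as.integer(rowSums(a$bits[, d$pairs$sample_a, drop = FALSE])),
    k_b = as.integer(rowSums(a$bits[, d$pairs$sample_b, drop = FALSE])),
    stringsAsFactors = FALSE)
  attr(out, "n_subjects") <- length(d$subjects)
  attr(out, "conditions") <- c(d$condition_a, d$condition_b)
  out
}

# vectorized two-sided pooled two-proportion z p-value (no continuity
# correction); degenerate pooled frequency 0 or 1 -> z = 0, p = 1
prop_z_p <- function(k1, n1, k2, n2) {
  phat <- (k1 + k2) / (n1 + n2)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (k1 / n1 - k2 / n2) / se, 0)
  list(z = z, p = ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1))
}

#' Two-proportion z-test on appearance frequencies
#'
#' Pooled two-sample proportion z statistic with a two-sided standard-normal
#' p-value and no continuity correction:
#' `z = (k1/n1 - k2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with pooled
#' `phat = (k1 + k2) / (n1 + n2)`. When the pooled frequency is 0 or 1 (both
#' groups all-absent or all-present) the statistic is defined as `z = 0`,
#' `p = 1`, keeping downstream ranking total.
#'
#' @param k1,n1 successes and trials in group 1 (`0 <= k1 <= n1`, `n1 >= 1`).
#' @param k2,n2 successes and trials in group 2.
#' @return An object of class `proportion_test`: a list with fields `k1`,
#'   `n1`, `k2`, `n2`, `z` and `p_value`.
#' @examples
#' proportion_z_test(9, 10, 0, 10)$p_value  # 5.23e-05
#' @export
proportion_z_test <- function(k1, n1, k2, n2) {
  for (v in list(k1, n1, k2, n2))
    if (length(v) != 1L || is.na(v) || v != round(v))
      stop("counts must be single non-negative integers")
  if (n1 < 1L || n2 < 1L) stop("group sizes must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("need 0 <= k <= n in each group")
  r <- prop_z_p(k1, n1, k2, n2)
  structure(list(k1 = as.integer(k1), n1 = as.integer(n1),
                 k2 = as.integer(k2), n2 = as.integer(n2),
                 z = r$z, p_value = r$p),
            class = "proportion_test")
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf("two-proportion z-test: %d/%d vs %d/%d, z = %.4g, p = %.4g\n",
              x$k1, x$n1, x$k2, x$n2, x$z, x$p_value))
  invisible(x)
}

#' Detect condition-unique proteins
#'
#' A protein is unique for condition X when it is present in at least
#' `ceiling(min_fraction * n_subjects)` subjects of X and in zero subjects
#' of the other condition. Each record carries the two-proportion p-value of
#' its presence count against zero, and a Benjamini-Hochberg q-value over
#' all reported records.
#'
#' @param a an [appearance_matrix()].
#' @param d a [paired_design()].
#' @param min_fraction minimum presence fraction in the unique condition,
#'   in (0, 1]; default 0.4 (i.e. 4 of 10 subjects).
#' @return A data frame with columns `protein_id`, `condition`, `n_present`,
#'   `fraction`, `p_value`, `q_value`, sorted by descending fraction then
#'   protein id. May have zero rows.
#' @export
detect_unique_proteins <- function(a, d, min_fraction = 0.4) {
  stopifnot(is.numeric(min_fraction), length(min_fraction) == 1L,
            min_fraction > 0, min_fraction <= 1)
  cc <- condition_presence_counts(a, d)
  n <- attr(cc, "n_subjects")
  conds <- attr(cc, "conditions")
  # tolerance guards against 0.4 * 10 landing a hair above 4 in floating point
  thr <- ceiling(min_fraction * n - 1e-9)
  rec <- function(sel, k, cond) {
    data.frame(protein_id = cc$protein_id[sel],
               condition = rep(cond, sum(sel)),
               n_present = k[sel], fraction = k[sel] / n,
               p_value = prop_z_p(k[sel], n, rep(0L, sum(sel)), n)$p,
               stringsAsFactors = FALSE)
  }
  out <- rbind(rec(cc$k_a >= thr & cc$k_b == 0L, cc$k_a, conds[1L]),
               rec(cc$k_b >= thr & cc$k_a == 0L, cc$k_b, conds[2L]))
  out$q_value <- benjamini_hochberg(out$p_value)
  out <- out[order(-out$fraction, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed proteins per sample
#'
#' Number of proteins detected (bit 1) in each sample; the per-sample
#' protein inventory distribution.
#'
#' @param a an [appearance_matrix()].
#' @return A named integer vector, one count per sample.
#' @export
per_sample_protein_counts <- function(a) {
  stopifnot(inherits(a, "appearance_matrix"))
  counts <- colSums(a$bits)
  stats::setNames(as.integer(counts), a$sample_ids)
}
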