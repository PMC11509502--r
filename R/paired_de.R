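#' Paired Student t-test
#'
#' Classic paired t on within-subject differences `d = x - y`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with the sample (n-1) standard
#' deviation, two-sided p from the t distribution with `n - 1` degrees of
#' freedom. Zero-variance differences yield the undefined marker (`NA`
#' statistic and p), which downstream ranking treats as least significant.
#'
#' @param x,y numeric vectors of per-subject values in the two conditions,
#'   equal length `n >= 2`.
#' @return A list with fields `statistic` and `p_value` (both `NA` when the
#'   differences have zero variance).
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0)
    return(list(statistic = NA_real_, p_value = NA_real_))
  tt <- mean(d) / (s / sqrt(n))
  list(statistic = tt, p_value = 2 * stats::pt(-abs(tt), df = n - 1L))
}

# exact null distribution of the positive-rank sum W+ for n untied ranks:
# counts of each achievable W in 0..n(n+1)/2, via the generating function
# prod_k (1 + x^k); cached per n
.signrank_cache <- new.env(parent = emptyenv())
signrank_counts <- function(n) {
  key <- as.character(n)
  if (!is.null(.signrank_cache[[key]])) return(.signrank_cache[[key]])
  v <- 1
  for (k in seq_len(n)) v <- c(v, numeric(k)) + c(numeric(k), v)
  .signrank_cache[[key]] <- v
  v
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (classic treatment); `W` is the sum of the
#' ranks of positive differences among the ranks of `|d|` (average ranks for
#' ties). The two-sided p-value is exact — by enumeration of the sign-pattern
#' null distribution — when the number of nonzero differences is at most
#' `max_exact` and `|d|` has no ties; otherwise a normal approximation with
#' tie correction is used. Fewer than `min_nonzero` nonzero differences
#' yield the undefined marker rather than an error, so a full proteome sweep
#' completes.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_nonzero minimum nonzero differences required (default 3).
#' @param max_exact largest nonzero-difference count for which the exact
#'   null distribution is used (default 12).
#' @return A list with fields `statistic` (W), `p_value`, `n_used` (nonzero
#'   differences) and `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y, min_nonzero = 3L, max_exact = 12L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < min_nonzero)
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = n,
                exact = NA))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= max_exact) {
    cnt <- signrank_counts(n)
    tot <- 2^n
    # W takes integer values 0..n(n+1)/2 when ranks are untied
    w <- as.integer(round(W))
    p_ge <- sum(cnt[(w + 1L):length(cnt)]) / tot
    p_le <- sum(cnt[1:(w + 1L)]) / tot
    p <- min(1, 2 * min(p_ge, p_le))
    return(list(statistic = W, p_value = p, n_used = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_sizes <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_sizes^3 - tie_sizes) / 48
  if (sig2 <= 0)
    return(list(statistic = W, p_value = NA_real_, n_used = n, exact = FALSE))
  z <- (W - mu) / sqrt(sig2)
  list(statistic = W, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       n_used = n, exact = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, capped at 1, returned in the
#' original order. `NA` entries (undefined tests) are excluded from `m` and
#' receive `NA` q-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Numeric vector of adjusted q-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  if (!any(ok)) return(q)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  qs <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  tmp <- q[ok]
  tmp[o] <- qs
  q[ok] <- tmp
  q
}

rank_with_undefined <- function(p, ids) {
  # ascending-p ranks 1..n_defined, ties broken by protein id;
  # undefined p-values all share the maximum rank n (least significant)
  n <- length(p)
  r <- rep(n, n)
  def <- which(!is.na(p))
  r[def[order(p[def], ids[def])]] <- seq_along(def)
  as.integer(r)
}

#' Run three-way paired differential expression
#'
#' For every protein, computes (i) the paired t-test, (ii) the Wilcoxon
#' signed-rank test on paired intensities (missing values enter as 0; no
#' imputation), and (iii) the two-proportion appearance test on per-condition
#' presence counts. P-values are BH-adjusted within each test family;
#' ascending-p ranks (ties broken by protein id, undefined last at rank
#' `n_proteins`) are combined into the minimum rank used for enrichment
#' ordering. The effect is the median paired difference (condition A minus
#' condition B) on the analysis scale.
#'
#' @param m an [intensity_matrix()].
#' @param d a [paired_design()].
#' @param transform `"raw"` (default; mirrors feeding label-free intensities
#'   straight into the tests) or `"log2p1"` for `log2(x + 1)`.
#' @param min_nonzero minimum nonzero paired differences for a defined
#'   Wilcoxon p (default 3).
#' @return A data frame with columns `protein_id`, `effect`, `t_stat`,
#'   `t_p`, `q_t`, `w_stat`, `w_p`, `q_w`, `prop_p`, `q_prop`, `rank_t`,
#'   `rank_w`, `rank_prop`, `min_rank`.
#' @export
run_differential_expression <- function(m, d,
                                        transform = c("raw", "log2p1"),
                                        min_nonzero = 3L) {
  stopifnot(inherits(m, "intensity_matrix"), inherits(d, "paired_design"))
  transform <- match.arg(transform)
  missing <- setdiff(c(d$pairs$sample_a, d$pairs$sample_b), m$sample_ids)
  if (length(missing))
    stop("design sample(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  X <- m$values[, d$pairs$sample_a, drop = FALSE]
  Y <- m$values[, d$pairs$sample_b, drop = FALSE]
  if (transform == "log2p1") {
    X <- log2(X + 1)
    Y <- log2(Y + 1)
  }
  n <- length(d$subjects)
  np <- length(m$protein_ids)
  D <- X - Y
  effect <- apply(D, 1L, stats::median)

  # paired t, vectorized across proteins
  dbar <- rowMeans(D)
  ss <- pmax(0, rowSums((D - dbar)^2))
  sdd <- sqrt(ss / (n - 1L))
  t_stat <- ifelse(sdd > 0, dbar / (sdd / sqrt(n)), NA_real_)
  t_p <- ifelse(is.na(t_stat), NA_real_,
                2 * stats::pt(-abs(t_stat), df = n - 1L))

  w_stat <- w_p <- rep(NA_real_, np)
  for (i in seq_len(np)) {
    w <- wilcoxon_signed_rank(X[i, ], Y[i, ], min_nonzero = min_nonzero)
    w_stat[i] <- w$statistic
    w_p[i] <- w$p_value
  }

  kA <- rowSums(X > 0)
  kB <- rowSums(Y > 0)
  prop_p <- prop_z_p(kA, n, kB, n)$p
  # a protein observed in neither condition carries no appearance evidence:
  # undefined rather than the degenerate p = 1, so it ranks last
  prop_p[kA == 0 & kB == 0] <- NA_real_

  ids <- m$protein_ids
  out <- data.frame(
    protein_id = ids, effect = effect,
    t_stat = t_stat, t_p = t_p, q_t = benjamini_hochberg(t_p),
    w_stat = w_stat, w_p = w_p, q_w = benjamini_hochberg(w_p),
    prop_p = prop_p, q_prop = benjamini_hochberg(prop_p),
    rank_t = rank_with_undefined(t_p, ids),
    rank_w = rank_with_undefined(w_p, ids),
    rank_prop = rank_with_undefined(prop_p, ids),
    stringsAsFactors = FALSE)
  out$min_rank <- pmin(out$rank_t, out$rank_w, out$rank_prop)
  rownames(out) <- NULL
  out
}

#' Min-rank ordered protein list
#'
#' Orders proteins by ascending minimum rank across the three differential
#' tests; ties broken by ascending proportion-test p (undefined last), then
#' protein id. This is the ranked list fed into gene-set enrichment.
#'
#' @param t a table from [run_differential_expression()].
#' @return Character vector of protein ids, most differential first (a
#'   permutation of the input ids).
#' @export
min_rank_list <- function(t) {
  stopifnot(all(c("protein_id", "min_rank", "prop_p") %in% names(t)))
  pp <- t$prop_p
  pp[is.na(pp)] <- Inf
  t$protein_id[order(t$min_rank, pp, t$protein_id)]
}

#' Volcano-plot table
#'
#' Effect size against `-log10 p` for one of the three tests; proteins with
#' an undefined p-value are omitted.
#'
#' @param t a table from [run_differential_expression()].
#' @param test `"wilcoxon"` (default), `"t"` or `"proportion"`.
#' @return A data frame with columns `protein_id`, `effect`, `neg_log10_p`.
#' @export
volcano_table <- function(t, test = c("wilcoxon", "t", "proportion")) {
  test <- match.arg(test)
  pcol <- c(wilcoxon = "w_p", t = "t_p", proportion = "prop_p")[[test]]
  keep <- !is.na(t[[pcol]])
  if (!any(keep))
    stop("no defined p-values for test '", test, "'")
  out <- data.frame(protein_id = t$protein_id[keep],
                    effect = t$effect[keep],
                    neg_log10_p = -log10(t[[pcol]][keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
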