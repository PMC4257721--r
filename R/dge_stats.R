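# Statistical core: RPKM, zero-substituted log2 fold change, the exact
# two-library equal-expression test, Benjamini-Hochberg FDR, DEG calling.

#' Test configuration for DEG calling
#'
#' Defaults follow the thresholds standard in two-library digital gene
#' expression studies: FDR at or below 0.001 together with an absolute
#' log2 ratio of at least 1; zero RPKM values are replaced by 0.01 before
#' forming the ratio.
#'
#' @param fdr_threshold Maximum adjusted p-value for a DEG call (inclusive).
#' @param min_abs_log2 Minimum absolute log2 RPKM ratio (inclusive).
#' @param zero_substitute Value substituted for a zero RPKM in the ratio.
#' @param rpkm_scale Scaling constant of the RPKM formula (reads per
#'   kilobase per million mapped reads = 1e9 in count x bp x reads units).
#' @return An object of class `test_config`.
#' @export
test_config <- function(fdr_threshold = 0.001, min_abs_log2 = 1,
                        zero_substitute = 0.01, rpkm_scale = 1e9) {
  vals <- c(fdr_threshold, min_abs_log2, zero_substitute, rpkm_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    domain_error("all test_config fields must be strictly positive")
  structure(list(fdr_threshold = fdr_threshold, min_abs_log2 = min_abs_log2,
                 zero_substitute = zero_substitute, rpkm_scale = rpkm_scale),
            class = "test_config")
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = scale * count / (length_bp * library_total)` with the
#' conventional scale 1e9 (reads, base pairs, reads). Vectorised over all
#' arguments.
#'
#' @param count Non-negative integer read count(s).
#' @param length_bp Positive integer gene length(s) in base pairs.
#' @param library_total Positive integer library total(s).
#' @param scale Scaling constant, default 1e9.
#' @return Non-negative numeric; zero exactly when `count` is zero.
#' @examples
#' compute_rpkm(1000, 1000, 1e9)  # units cancel: 1
#' compute_rpkm(18, 688, 25603968)
#' @export
compute_rpkm <- function(count, length_bp, library_total, scale = 1e9) {
  if (any(!is.finite(count)) || any(count < 0) || any(count != trunc(count)))
    domain_error("count must be a non-negative integer")
  if (any(!is.finite(length_bp)) || any(length_bp < 1))
    domain_error("length_bp must be a positive integer")
  if (any(!is.finite(library_total)) || any(library_total < 1))
    domain_error("library_total must be a positive integer")
  scale * count / (length_bp * library_total)
}

#' Zero-substituted log2 expression ratio (S over L)
#'
#' Returns `log2(rpkm_S / rpkm_L)` after replacing any zero operand by
#' `zero_substitute`, so the ratio is always finite.
#'
#' @param rpkm_L,rpkm_S Non-negative RPKM values (vectorised).
#' @param zero_substitute Positive replacement for zero, default 0.01.
#' @return Finite numeric log2 ratio(s).
#' @examples
#' log2_fold_change(1, 2)          # 1
#' log2_fold_change(0, 5.12)       # 9: substitution gives 5.12/0.01 = 2^9
#' @export
log2_fold_change <- function(rpkm_L, rpkm_S, zero_substitute = 0.01) {
  if (any(rpkm_L < 0) || any(rpkm_S < 0))
    domain_error("RPKM values must be non-negative")
  if (!is.finite(zero_substitute) || zero_substitute <= 0)
    domain_error("zero_substitute must be strictly positive")
  l <- ifelse(rpkm_L == 0, zero_substitute, rpkm_L)
  s <- ifelse(rpkm_S == 0, zero_substitute, rpkm_S)
  log2(s / l)
}

check_audic_args <- function(x, y, N1, N2) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != trunc(x)) ||
      any(!is.finite(y)) || any(y < 0) || any(y != trunc(y)))
    domain_error("counts x and y must be non-negative integers")
  if (any(N1 < 1) || any(N2 < 1))
    domain_error("library totals must be positive")
}

#' Audic-Claverie probability of observing y given x
#'
#' The conditional probability of observing `y` reads for a gene in the
#' second library given `x` reads in the first, under the null hypothesis
#' of equal expression, for libraries of total depth `N1` and `N2`. With
#' depth ratio `r = N2/N1`,
#'
#' \deqn{p(y|x) = r^y \frac{(x+y)!}{x!\,y!\,(1+r)^{x+y+1}}}
#'
#' which for equal depths reduces to the classical Audic-Claverie form.
#' Evaluated in log space via `lgamma` so large counts do not overflow.
#' Vectorised over `x` and `y`.
#'
#' @param x,y Non-negative integer read counts in the two libraries.
#' @param N1,N2 Positive library totals (the depths conditioning the test).
#' @param log If `TRUE` return the log probability.
#' @return Probability in (0, 1] (or its log).
#' @examples
#' audic_pmf(0, 0, 1e6, 1e6)  # 0.5
#' @export
audic_pmf <- function(x, y, N1, N2, log = FALSE) {
  check_audic_args(x, y, N1, N2)
  logr <- base::log(N2) - base::log(N1)
  lp <- y * logr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(exp(logr))
  if (log) lp else exp(lp)
}

# Lower tail P(Y <= y | x): log-sum-exp over the finite sum k = 0..y.
audic_lower_tail <- function(x, y, logr) {
  if (y < 0) return(0)
  k <- 0:y
  lp <- k * logr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(exp(logr))
  exp(log_sum_exp(lp))
}

# Upper tail P(Y >= y | x). Below or at the pmf mode the upper tail is
# large, so the complement 1 - P(Y <= y-1) is accurate; above the mode the
# terms decay (ratio -> r/(1+r) < 1) and the tail is summed directly in
# chunks, which keeps tiny upper tails at full relative accuracy where the
# complement would lose all digits.
audic_upper_tail <- function(x, y, logr, lower_incl = NULL, chunk = 256L) {
  if (y <= 0) return(1)
  mode_k <- exp(logr) * (x + 1)  # location of the pmf maximum in k
  if (y <= mode_k) {
    if (is.null(lower_incl)) lower_incl <- audic_lower_tail(x, y, logr)
    pmf_y <- exp(y * logr + lgamma(x + y + 1) - lgamma(x + 1) -
                   lgamma(y + 1) - (x + y + 1) * log1p(exp(logr)))
    return(min(1, max(0, 1 - lower_incl + pmf_y)))
  }
  l0 <- y * logr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(exp(logr))
  acc <- 0
  k0 <- y
  repeat {
    k <- k0:(k0 + chunk - 1L)
    lp <- k * logr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * log1p(exp(logr))
    add <- sum(exp(lp - l0))
    acc <- acc + add
    k0 <- k0 + chunk
    if (add < acc * 1e-17) break
    if (k0 > y + 1e7) break  # safety valve; unreachable for sane inputs
  }
  min(1, exp(l0) * acc)
}

#' Two-sided exact p-value for equal expression in two libraries
#'
#' Doubles the smaller of the two tail probabilities of the conditional
#' distribution [audic_pmf()] and caps at 1:
#' `min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`.
#' Both tails are computed by direct summation (the lower tail is a finite
#' sum; the upper tail is truncated under a geometric bound), so even very
#' small tail probabilities keep full relative accuracy. Vectorised over
#' `x` and `y`.
#'
#' @inheritParams audic_pmf
#' @return p-value(s) in (0, 1].
#' @examples
#' audic_pvalue(5, 5, 1e6, 1e6)   # 1: observed equals expected
#' audic_pvalue(0, 0, 1e6, 2e6)   # 2/3
#' @export
audic_pvalue <- function(x, y, N1, N2) {
  check_audic_args(x, y, N1, N2)
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  logr <- rep_len(base::log(N2) - base::log(N1), n)
  vapply(seq_len(n), function(i) {
    lo <- audic_lower_tail(x[i], y[i], logr[i])
    up <- audic_upper_tail(x[i], y[i], logr[i], lower_incl = lo)
    min(1, 2 * min(lo, up))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Textbook step-up: order the m p-values ascending, set
#' `q_(i) = min_{j >= i} p_(j) * m / j`, cap at 1, and return the adjusted
#' values in the original input order. Output is elementwise no smaller
#' than the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    domain_error("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  # guard the adjustment-never-decreases invariant against the one-ulp
  # rounding of p * m / m
  pmax(out, p_values)
}

#' Call differentially expressed genes between two libraries
#'
#' Runs the full per-gene analysis: RPKM in each library, zero-substituted
#' log2 ratio (S over L), exact two-sided p-value, BH-adjusted FDR over
#' all testable genes jointly, and the DEG call
#' `is_deg = (fdr <= fdr_threshold) & (|log2_ratio| >= min_abs_log2)`
#' (both thresholds inclusive). Genes with zero reads in both libraries
#' are untestable and are dropped before testing; their ids are kept in
#' the `untestable` attribute.
#'
#' @param counts Count data frame with columns `gene_id`, `length_bp`,
#'   `reads_L`, `reads_S` (as from [read_counts()] or [generate_counts()]).
#' @param libs A [library_pair()] giving the totals N1 (L) and N2 (S).
#' @param config A [test_config()].
#' @return Data frame of class `diff_expr_table`, one row per testable
#'   gene, with columns `gene_id`, `length_bp`, `reads_L`, `reads_S`,
#'   `rpkm_L`, `rpkm_S`, `log2_ratio`, `p_value`, `fdr`, `direction`
#'   (`"up"`, `"down"` or `"none"`, S relative to L), `is_deg`; attributes
#'   `untestable` (dropped gene ids) and `summary` (named counts).
#' @export
call_degs <- function(counts, libs, config = test_config()) {
  if (!inherits(libs, "library_pair")) domain_error("libs must be a library_pair")
  if (!inherits(config, "test_config")) domain_error("config must be a test_config")
  if (nrow(counts) == 0L) domain_error("empty count table")

  untestable <- counts$gene_id[counts$reads_L == 0 & counts$reads_S == 0]
  keep <- counts$reads_L > 0 | counts$reads_S > 0
  d <- counts[keep, , drop = FALSE]
  if (nrow(d) == 0L) domain_error("no testable genes (all counts zero)")

  N1 <- libs$total_reads_L; N2 <- libs$total_reads_S
  rpkm_L <- compute_rpkm(d$reads_L, d$length_bp, N1, config$rpkm_scale)
  rpkm_S <- compute_rpkm(d$reads_S, d$length_bp, N2, config$rpkm_scale)
  lfc <- log2_fold_change(rpkm_L, rpkm_S, config$zero_substitute)
  p <- audic_pvalue(d$reads_L, d$reads_S, N1, N2)
  fdr <- bh_fdr(p)
  direction <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none"))
  is_deg <- fdr <= config$fdr_threshold & abs(lfc) >= config$min_abs_log2

  res <- data.frame(gene_id = d$gene_id, length_bp = d$length_bp,
                    reads_L = d$reads_L, reads_S = d$reads_S,
                    rpkm_L = rpkm_L, rpkm_S = rpkm_S, log2_ratio = lfc,
                    p_value = p, fdr = fdr, direction = direction,
                    is_deg = is_deg, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "untestable") <- untestable
  attr(res, "summary") <- c(genes_tested = nrow(res),
                            untestable = length(untestable),
                            degs_up = sum(is_deg & direction == "up"),
                            degs_down = sum(is_deg & direction == "down"))
  class(res) <- c("diff_expr_table", "data.frame")
  res
}

#' @export
print.diff_expr_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("differential expression: %d genes tested (%d untestable), %d DEGs up, %d DEGs down\n",
              s["genes_tested"], s["untestable"], s["degs_up"], s["degs_down"]))
  NextMethod()
}
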