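# Supporting count statistics: the Audic-Claverie digital-expression
# test, the fold-change + p-value DE filter, and the 2^-ddCt qPCR
# utility.

# log P(y | x) for libraries of sizes N1, N2; exactly the negative
# binomial with size x + 1 and success probability N1 / (N1 + N2)
.ac_log_pmf <- function(y, x, N1, N2) {
  stats::dnbinom(y, size = x + 1, prob = N1 / (N1 + N2), log = TRUE)
}

#' Audic-Claverie test for two digital-expression counts
#'
#' Probability of observing `y` counts in a library of size `N2` given
#' `x` counts in a library of size `N1` under equal underlying rates:
#' `P(y|x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))`, evaluated
#' in log-gamma space. The two-sided p-value sums `P(y'|x)` over all
#' outcomes no more probable than the observed one (1e-9 relative tie
#' tolerance), truncating once the accumulated tail mass is below 1e-12.
#'
#' @param x,y observed counts (non-negative integers).
#' @param N1,N2 library sizes, > 0.
#' @return p-value in (0, 1].
#' @export
audic_claverie_p <- function(x, y, N1, N2) {
  stopifnot(x >= 0, y >= 0, N1 > 0, N2 > 0)
  ymax <- max(stats::qnbinom(1e-13, size = x + 1, prob = N1 / (N1 + N2),
                             lower.tail = FALSE), y, 50L)
  lp <- .ac_log_pmf(0:ymax, x, N1, N2)
  p <- sum(exp(lp[lp <= lp[y + 1L] + 1e-9]))
  min(p, 1)
}

#' Fold-change + p-value differential-expression filter
#'
#' A gene is significantly differentially expressed when its fold change
#' is at least `fc_min` (in either direction, on pseudocounted
#' expression) and its p-value is below `p_max`; q-values come from
#' [bh_fdr()]. Down- and up-regulation in the second condition are
#' flagged separately.
#'
#' @param expr_a,expr_b normalized expression (e.g. RPKM) per gene in the
#'   two conditions; a `+1` pseudocount guards zero denominators.
#' @param p p-values per gene (e.g. from [audic_claverie_p()]).
#' @param gene_id optional identifiers.
#' @param fc_min fold-change threshold (default 1.5).
#' @param p_max p-value threshold (default 0.01).
#' @return `data.table` with `gene_id`, `fc` (condition A over B on
#'   pseudocounted values), `p_value`, `q_value`, `direction`
#'   (`"down_in_b"`, `"up_in_b"` or `""`), `significant`.
#' @export
de_filter <- function(expr_a, expr_b, p, gene_id = NULL,
                      fc_min = 1.5, p_max = 0.01) {
  n <- length(expr_a)
  stopifnot(length(expr_b) == n, length(p) == n)
  if (is.null(gene_id)) gene_id <- paste0("g", seq_len(n))
  fc <- (expr_a + 1) / (expr_b + 1)
  direction <- ifelse(fc >= fc_min, "down_in_b",
                      ifelse(1 / fc >= fc_min, "up_in_b", ""))
  significant <- direction != "" & p < p_max
  data.table::data.table(gene_id = gene_id, fc = fc, p_value = p,
                         q_value = bh_fdr(p), direction = direction,
                         significant = significant)
}

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target_case,ct_ref_case cycle thresholds of the target and
#'   reference gene in the case sample.
#' @param ct_target_ctrl,ct_ref_ctrl the same in the control sample.
#' @return `2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl -
#'   ct_ref_ctrl))`.
#' @export
ddct <- function(ct_target_case, ct_ref_case, ct_target_ctrl,
                 ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_case), is.finite(ct_ref_case),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))
}
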