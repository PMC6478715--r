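# Window-level enrichment statistics: the (a*d)/(b*c) score, moment
# dispersion estimation, and the conditional (beta-)binomial exact test.

#' Window enrichment score
#'
#' `(a * d) / (b * c)` with `a` the IP count in the window, `b` the
#' gene-median IP window count, `c` the input count in the window and `d`
#' the gene-median input count. Zero `a` or `c` are raised to 1
#' (pseudocount) so the score is finite; `b` and `d` are already >= 1
#' after [gene_median_offsets()].
#'
#' @param a,c window counts (IP, input); vectors allowed.
#' @param b,d gene-median offsets (IP, input), >= 1.
#' @return Numeric enrichment score(s).
#' @export
enrichment_score <- function(a, b, c, d) {
  stopifnot(all(a >= 0), all(c >= 0), all(b >= 1), all(d >= 1))
  a <- ifelse(a == 0, 1, a)
  c <- ifelse(c == 0, 1, c)
  (a * d) / (b * c)
}

#' Moment estimate of the common NB dispersion
#'
#' Per-window method-of-moments dispersion across replicate libraries of
#' the same kind (IP vs IP): `phi_w = max(0, (var - mean) / mean^2)`;
#' the common dispersion is the median over windows with mean >= 5,
#' floored at `dispersion_floor`. With fewer than two replicates the
#' fallback `default_dispersion` is returned.
#'
#' @param counts matrix of library-size-normalized window counts, one
#'   column per replicate (normalize to a common depth first, e.g. with
#'   [normalize_libsize()]).
#' @param dispersion_floor lower bound (default 0.01).
#' @param default_dispersion value used when no estimate is possible
#'   (default 0.05).
#' @return Scalar dispersion phi (variance = mu + phi * mu^2).
#' @export
estimate_dispersion <- function(counts, dispersion_floor = 0.01,
                                default_dispersion = 0.05) {
  counts <- as.matrix(counts)
  r <- ncol(counts)
  if (r < 2L) return(default_dispersion)
  m <- rowMeans(counts)
  v <- rowSums((counts - m)^2) / (r - 1L)
  sel <- m >= 5
  if (!any(sel)) return(dispersion_floor)
  phi_w <- pmax(0, (v[sel] - m[sel]) / m[sel]^2)
  max(dispersion_floor, stats::median(phi_w))
}

#' Library-size normalize a count matrix
#'
#' Scales each column (library) to the mean library depth.
#'
#' @param counts matrix of counts, one column per library.
#' @return Numeric matrix of the same shape.
#' @export
normalize_libsize <- function(counts) {
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("empty library")
  sweep(counts, 2L, mean(libsize) / libsize, `*`)
}

# log pmf of the conditional null for the IP count j out of n, given the
# offset proportion pi0 and dispersion phi (beta-binomial; binomial at 0)
.cond_log_pmf <- function(j, n, pi0, phi) {
  if (phi <= 0) {
    lchoose(n, j) + j * log(pi0) + (n - j) * log1p(-pi0)
  } else {
    rho <- phi / (1 + phi)
    alpha <- pi0 * (1 - rho) / rho
    beta <- (1 - pi0) * (1 - rho) / rho
    lchoose(n, j) + lbeta(j + alpha, n - j + beta) - lbeta(alpha, beta)
  }
}

#' Conditional (beta-)binomial window test
#'
#' Exact two-sided test for IP-vs-input imbalance in one window,
#' conditional on the window total `n = a + c`. Under the null the IP
#' count follows `Binomial(n, pi0)` with `pi0 = b/(b + d)` when the
#' dispersion is zero, and a beta-binomial with mean `pi0` and intra-class
#' correlation `rho = phi/(1 + phi)` otherwise; normalization thus enters
#' through the gene-median offsets rather than by rescaling counts. The
#' p-value is the minimum-likelihood sum: the total probability of all
#' outcomes no more likely than the observed one (ties compared with a
#' 1e-9 relative tolerance).
#'
#' @param a IP count in the window.
#' @param c input count in the window.
#' @param b,d gene-median offsets (IP, input), >= 1.
#' @param phi dispersion (0 gives the exact binomial test).
#' @return p-value in (0, 1]; `n = 0` returns 1.
#' @export
nb_window_test <- function(a, c, b, d, phi = 0) {
  stopifnot(a >= 0, c >= 0, b >= 1, d >= 1, phi >= 0)
  n <- a + c
  if (n == 0) return(1)
  pi0 <- b / (b + d)
  lp <- .cond_log_pmf(0:n, n, pi0, phi)
  p <- sum(exp(lp[lp <= lp[a + 1L] + 1e-9]))
  min(p, 1)
}

# vectorised wrapper used by the peak caller
nb_window_test_many <- function(a, c, b, d, phi = 0) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- nb_window_test(a[i], c[i], b[i], d[i], phi)
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment of a p-value vector (wrapper over
#' [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}
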