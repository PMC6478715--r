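# Sliding-window machinery: window grids, midpoint counting, the 1/20
# low-count filter, and gene-median offsets.

#' Build the sliding-window grid for a transcript
#'
#' Windows of `window_size` nt advance by `step` nt from position 0; the
#' last start is the largest multiple of `step` not exceeding
#' `transcript_len - window_size`. A transcript shorter than one window
#' gets a single full-length window.
#'
#' @param transcript_len transcript length in nt (>= 1).
#' @param window_size window width in nt (default 100).
#' @param step step in nt (default 10).
#' @return `data.table` with columns `start`, `end` (half-open transcript
#'   coordinates) and `index` (0-based ordinal).
#' @export
make_windows <- function(transcript_len, window_size = 100L, step = 10L) {
  stopifnot(transcript_len >= 1L, step >= 1L, step <= window_size)
  if (transcript_len < window_size) {
    starts <- 0L
    ends <- as.integer(transcript_len)
  } else {
    starts <- seq.int(0L, transcript_len - window_size, by = step)
    ends <- starts + as.integer(window_size)
  }
  data.table::data.table(start = as.integer(starts), end = ends,
                         index = seq_along(starts) - 1L)
}

#' Count fragment midpoints per window
#'
#' A midpoint at position p is counted by every window with
#' `start <= p < end` (half-open).
#'
#' @param midpoints integer vector of transcript positions.
#' @param windows window grid from [make_windows()].
#' @param transcript_len transcript length in nt.
#' @return Integer vector of counts, one per window.
#' @export
count_midpoints <- function(midpoints, windows, transcript_len) {
  midpoints <- midpoints[!is.na(midpoints)]
  if (length(midpoints) &&
      (min(midpoints) < 0L || max(midpoints) >= transcript_len))
    stop("midpoint outside transcript")
  tab <- tabulate(midpoints + 1L, nbins = transcript_len)
  cs <- c(0L, cumsum(tab))
  as.integer(cs[windows$end + 1L] - cs[windows$start + 1L])
}

#' Low-count window filter
#'
#' Windows whose read count is below `low_frac` of the transcript's top
#' window in both the IP and the input sample are excluded; a window at or
#' above the threshold in either sample survives. This guards against bias
#' from inaccurate gene structure and the longest-isoform convention. A
#' transcript with all-zero counts in both samples has every window
#' excluded.
#'
#' @param ip,input integer count vectors over one transcript's windows
#'   (one replicate).
#' @param low_frac fraction of the top window (default 1/20).
#' @return Logical vector: `TRUE` for windows kept.
#' @export
filter_low_windows <- function(ip, input, low_frac = 1 / 20) {
  stopifnot(length(ip) == length(input), low_frac > 0, low_frac < 1)
  max_ip <- max(ip); max_in <- max(input)
  if (max_ip == 0L && max_in == 0L) return(rep(FALSE, length(ip)))
  !(ip < low_frac * max_ip & input < low_frac * max_in)
}

# lower-middle median: keeps integer offsets integral
lower_median <- function(x) {
  n <- length(x)
  stopifnot(n >= 1L)
  sort(x)[ceiling(n / 2)]
}

#' Gene-median normalization offsets
#'
#' Per transcript and replicate, window counts are normalized by the
#' median count over that gene's (surviving) windows: `b` for the IP
#' sample and `d` for the input sample. The median of an even-length list
#' is its lower-middle element, and zero medians are replaced by 1 so the
#' enrichment score stays finite.
#'
#' @param ip,input count vectors over the transcript's surviving windows.
#' @return Named numeric vector `c(b = ..., d = ...)`.
#' @export
gene_median_offsets <- function(ip, input) {
  b <- lower_median(ip)
  d <- lower_median(input)
  c(b = max(b, 1), d = max(d, 1))
}
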