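# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package internals.

# Exhaustive enumeration of fully tryptic (start, end) spans.
oracle_digest <- function(sequence, max_missed = 2, min_length = 6) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_site <- chars %in% c("K", "R")
  seqs <- character(0); missed <- integer(0)
  starts <- integer(0); ends <- integer(0)
  for (s in seq_len(n)) {
    if (!(s == 1 || is_site[s - 1])) next
    for (e in s:n) {
      if (!(e == n || is_site[e])) next
      if (e - s + 1 < min_length) next
      m <- if (e > s) sum(is_site[s:(e - 1)]) else 0L
      if (m > max_missed) next
      seqs <- c(seqs, paste(chars[s:e], collapse = ""))
      missed <- c(missed, m); starts <- c(starts, s); ends <- c(ends, e)
    }
  }
  tibble::tibble(sequence = seqs, n_missed_cleavages = as.integer(missed),
                 start = starts, end = ends)
}

random_protein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# Repeated pairwise merge to fixpoint, member-weighted (O(n^2) per pass).
oracle_cluster_merge <- function(d, ppm, rt_gap = 0) {
  d <- as.data.frame(d)
  if (!"n_members" %in% names(d)) d$n_members <- 1
  repeat {
    n <- nrow(d)
    hit <- FALSE
    for (i in seq_len(max(n - 1, 0))) {
      for (j in (i + 1):n) {
        lo <- min(d$mz[i], d$mz[j]); hi <- max(d$mz[i], d$mz[j])
        mz_ok <- (hi - lo) / lo * 1e6 <= ppm
        rt_ok <- d$rt_start[j] <= d$rt_end[i] + rt_gap + 1e-9 &&
          d$rt_start[i] <= d$rt_end[j] + rt_gap + 1e-9
        if (mz_ok && rt_ok) {
          w <- d$n_members[i] + d$n_members[j]
          d$mz[i] <- (d$mz[i] * d$n_members[i] + d$mz[j] * d$n_members[j]) / w
          d$rt_start[i] <- min(d$rt_start[i], d$rt_start[j])
          d$rt_end[i] <- max(d$rt_end[i], d$rt_end[j])
          d$n_members[i] <- w
          d <- d[-j, , drop = FALSE]
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (!hit) break
  }
  d <- d[order(d$mz, d$rt_start), c("mz", "rt_start", "rt_end", "n_members")]
  rownames(d) <- NULL
  d
}

# Random entry tables with well-separated cluster centers (>5x tolerance
# apart) and members within +/-0.4x tolerance of their center, so the
# transitive-closure result and the pairwise fixpoint provably coincide and
# the RT substructure does the interesting work.
random_entries <- function(max_clusters = 20, ppm = 10) {
  centers <- sort(stats::runif(max_clusters, 400, 1600))
  keep <- c(TRUE, diff(centers) / centers[-length(centers)] * 1e6 > 5 * ppm)
  centers <- centers[keep]
  rows <- lapply(centers, function(cm) {
    k <- sample(1:4, 1)
    mz <- cm * (1 + stats::runif(k, -0.4, 0.4) * ppm * 1e-6)
    rs <- stats::runif(k, 0, 90)
    tibble::tibble(mz = mz, rt_start = rs,
                   rt_end = rs + stats::runif(k, 0.5, 6))
  })
  dplyr::bind_rows(rows)
}

# Walk-based FDR acceptance: largest prefix all of whose prefixes keep the
# decoy/target ratio at or below alpha.
oracle_fdr <- function(score, is_decoy, alpha) {
  ord <- order(-score, -as.integer(is_decoy))
  dec <- is_decoy[ord]
  best <- 0L
  for (k in seq_along(dec)) {
    d <- sum(dec[seq_len(k)])
    t <- k - d
    if (d > alpha * t) break
    best <- k
  }
  acc <- logical(length(dec))
  if (best > 0) acc[ord[seq_len(best)]] <- !is_decoy[ord[seq_len(best)]]
  acc
}

# Count selection events that violate an in-force exclusion list.
count_exclusion_violations <- function(events, excl, ppm = 10) {
  if (is.null(excl) || nrow(excl) == 0 || nrow(events) == 0) return(0L)
  emz <- excl$mz; rs <- excl$rt_start; re <- excl$rt_end
  sum(vapply(seq_len(nrow(events)), function(i) {
    any(abs(events$mz[i] - emz) / emz * 1e6 <= ppm &
          rs <= events$time[i] & events$time[i] <= re)
  }, logical(1)))
}
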