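# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library functions never clobber the
# user's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a master seed
#'
#' Stages of an experiment (mixture generation, each acquisition run,
#' identification, reporter quantification) draw from independent streams so
#' any stage can be re-run in isolation. The derivation is a fixed integer
#' hash of the stage name folded into the master seed, kept below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label, e.g. `"mixture"` or `"run3"`.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(42, "mixture")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  code <- utf8ToInt(stage)
  offs <- sum(code * seq_along(code))
  as.integer((abs(as.numeric(seed)) * 10007 + offs) %% 2147483629)
}

# Positive scalar check with a readable error.
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    rlang::abort(sprintf("`%s` must be a positive number", name))
  }
  invisible(x)
}

# Quantile binning of a descriptor into at most `n` bins, as a pure function
# of the descriptor values (ties always land in the same bin). Degenerate
# descriptors collapse into fewer bins.
quantile_bin <- function(x, n) {
  stopifnot(n >= 1)
  if (length(x) == 0) return(integer(0))
  br <- stats::quantile(x, probs = seq(0, 1, length.out = n + 1),
                        names = FALSE, type = 7)
  br <- unique(br)
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
}
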