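# Internal helpers shared across modules.

#' Run an expression under a local random seed
#'
#' Evaluates `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so that no function call leaves global side effects.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# sample-standard-deviation z-scores (denominator n - 1); zero spread -> all 0
zscoreSafe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# half-open interval membership: any of [onset, offset) contains t.
# merge first, then a single findInterval over the interleaved bounds:
# odd slots are inside, and t == offset lands on an even slot (half-open).
inAnyInterval <- function(t, onset, offset) {
  if (length(onset) == 0L) return(rep(FALSE, length(t)))
  m <- mergeIntervals(onset, offset)
  bounds <- as.vector(rbind(m$onset, m$offset))
  findInterval(t, bounds) %% 2L == 1L
}

# merge sorted half-open intervals that touch or overlap
mergeIntervals <- function(onset, offset) {
  if (length(onset) == 0L)
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  o <- order(onset)
  onset <- onset[o]; offset <- offset[o]
  mo <- onset[1]; mf <- offset[1]
  res_on <- numeric(0); res_off <- numeric(0)
  for (i in seq_along(onset)[-1]) {
    if (onset[i] <= mf) {
      mf <- max(mf, offset[i])
    } else {
      res_on <- c(res_on, mo); res_off <- c(res_off, mf)
      mo <- onset[i]; mf <- offset[i]
    }
  }
  data.frame(onset = c(res_on, mo), offset = c(res_off, mf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
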