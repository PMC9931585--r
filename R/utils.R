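#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simple leveled logger. Level is set per call chain via options(imctme.log_level=).
#' @noRd
tme_log <- function(level = c("info", "warn", "debug"), ...) {
  level <- match.arg(level)
  ord <- c(debug = 1L, info = 2L, warn = 3L)
  min_level <- getOption("imctme.log_level", "info")
  if (ord[[level]] < ord[[min_level]]) return(invisible(NULL))
  msg <- paste0("[imctme ", level, "] ", paste0(..., collapse = ""))
  if (level == "warn") warning(msg, call. = FALSE) else message(msg)
  invisible(NULL)
}

#' Derive a child seed from a base seed and a label
#'
#' Deterministically maps a base seed and a stage/core label to a child
#' seed within 32-bit integer range, so every stage of a run draws from
#' its own reproducible stream.
#'
#' @param seed integer base seed.
#' @param label character label (stage or core id).
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(label)
  h <- as.double(seed %% 2147483647L)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a fixed RNG seed, restoring the caller RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Largest-remainder rounding of nonnegative fractions to percentages that
#' sum exactly to 100 at the given number of decimals.
#' @noRd
largest_remainder_percent <- function(frac, digits = 2L) {
  stopifnot(all(frac >= 0), abs(sum(frac) - 1) < 1e-8)
  mult <- 10^digits
  raw <- frac * 100 * mult
  base <- floor(raw)
  short <- round(100 * mult - sum(base))
  if (short > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  base / mult
}

#' z-score a numeric vector (sample sd).
#' @noRd
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance: z-scores undefined")
  (x - mean(x)) / s
}
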