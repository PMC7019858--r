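#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-stream seed from a root seed
#'
#' Each named random stream (genetic effects, GxE, residuals, ...) gets its
#' own seed derived deterministically from the root seed, so adding or
#' removing one stream never perturbs the draws of another.
#'
#' @param seed integer root seed.
#' @param stream character stream label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(stream)) {
    h <- (h * 31 + k) %% m
  }
  as.integer(h)
}

with_stream <- function(seed, stream, expr) {
  # localised RNG: restore the caller's RNG state afterwards
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  expr
}

stop_sg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_sg <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_sg("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_sg("`%s` must be a single number in [%s, %s]", name, min, max)
  }
  as.numeric(x)
}

#' @noRd
sg_log_level <- function() {
  lvl <- getOption("staygreen.log_level", "INFO")
  match.arg(toupper(lvl), c("DEBUG", "INFO", "WARNING", "ERROR"))
}

sg_log <- function(level, stage, fmt, ...) {
  ranks <- c(DEBUG = 1, INFO = 2, WARNING = 3, ERROR = 4)
  if (ranks[[level]] < ranks[[sg_log_level()]]) return(invisible(NULL))
  message(sprintf("[%s] %s: %s", level, stage, sprintf(fmt, ...)))
  invisible(NULL)
}
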