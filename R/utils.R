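#' @keywords internal
"_PACKAGE"

# Default base seed for stochastic routines when the caller supplies none.
DEFAULT_SEED <- 20230306L

logistic <- function(x) 1 / (1 + exp(-x))

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  stop_if_not(is.numeric(x) && length(x) == 1L && is.finite(x),
              "`%s` must be a single finite number", name)
  stop_if_not(x >= lower && x <= upper,
              "`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  stop_if_not(is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x),
              "`%s` must be a single integer", name)
  stop_if_not(x >= min, "`%s` must be >= %d, got %s", name, min, x)
  invisible(as.integer(x))
}

check_columns <- function(df, cols, where = "table") {
  missing <- setdiff(cols, names(df))
  stop_if_not(length(missing) == 0L, "%s is missing required column(s): %s",
              where, paste(missing, collapse = ", "))
  invisible(df)
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Fans one global seed out to independent per-stage seeds by stable string
#' hashing of the stage name, so each pipeline stage is reproducible on its
#' own regardless of execution order.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label.
#' @return An integer seed in \[0, 2^31 - 2\].
#' @export
stage_seed <- function(seed, stage) {
  check_count(seed, "seed", min = 0L)
  stopifnot(is.character(stage), length(stage) == 1L)
  # polynomial rolling hash over UTF-8 bytes, kept in double precision
  # (exact below 2^53) and reduced mod a prime < 2^31
  p <- 2147483629
  h <- as.numeric(seed) %% p
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% p
  as.integer(h)
}

# local RNG scope: evaluates expr under set.seed(seed) and restores the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
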