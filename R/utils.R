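# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state, so library functions are deterministic given
#' their `seed` argument without disturbing the session RNG.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a base seed and a label, kept within
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483587)
}

# A tiny RNG stream manager: each named stream has its own saved
# .Random.seed state, so draws on one stream do not perturb another.
rng_streams <- function(seed, names) {
  env <- new.env(parent = emptyenv())
  for (nm in names) {
    set.seed(derive_seed(seed, nm))
    assign(nm, get(".Random.seed", envir = globalenv()), envir = env)
  }
  env
}

stream_eval <- function(streams, name, code) {
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  out <- force(code)
  assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
  out
}

# Validation helpers ---------------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_calls <- function(calls) {
  if (!is.matrix(calls) || !is.numeric(calls)) {
    stopf("genotype calls must be a numeric matrix")
  }
  if (any(!calls %in% c(0, 1, 2))) {
    stopf("genotype calls must lie in {0, 1, 2}")
  }
  invisible(calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
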