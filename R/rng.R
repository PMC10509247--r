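#' Derive a reproducible sub-stream seed from a root seed and key strings
#'
#' All randomness in the pipeline flows from one root seed through named
#' sub-streams keyed by identifiers such as (species, area, habitat,
#' parameter). This makes draws for one unit invariant to which other units
#' are simulated in the same run, and to iteration order.
#'
#' Implementation: a 31-bit polynomial rolling hash over the concatenated
#' keys, mixed with the root seed. Deterministic across platforms.
#'
#' @param root_seed Integer root seed.
#' @param ... Character or numeric keys naming the sub-stream.
#' @return An integer in `[0, 2^31 - 2]`, suitable for `set.seed()`.
#' @export
substream_seed <- function(root_seed, ...) {
  keys <- paste(vapply(list(...), as.character, ""), collapse = "/")
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(root_seed) %% m
  for (b in utf8ToInt(keys)) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

#' Evaluate code under a private RNG stream
#'
#' Seeds the RNG with `seed`, evaluates `code`, and restores the caller's
#' RNG state afterwards, so library code never perturbs user-level
#' reproducibility.
#'
#' @param seed Integer seed (e.g. from [substream_seed()]); `NULL` uses the
#'   current RNG state without touching it.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_stream <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}
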