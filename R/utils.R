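#' Derive reproducible child seeds from a master seed
#'
#' Many pipeline stages (null-model standardization of each network,
#' per-origin community simulation) need their own random-number stream so
#' that any single stage can be re-run in isolation and reproduce its output
#' bit-identically. Child seeds are drawn from a private RNG seeded with the
#' master seed plus an integer hash of a stream label; the caller's RNG state
#' is left untouched.
#'
#' @param master_seed single integer master seed.
#' @param n number of child seeds to derive.
#' @param stream character label naming the consumer stream (e.g.
#'   `"standardize"`), so different stages never share a child-seed sequence.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seeds(1L, 3)
#' identical(derive_seeds(1L, 3), derive_seeds(1L, 3))
derive_seeds <- function(master_seed, n, stream = "sexnest") {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed),
            length(n) == 1L, n >= 1)
  chars <- utf8ToInt(stream)
  # small deterministic label hash, kept well inside 32-bit integer range
  key <- (as.double(master_seed) %% 1e9) + sum(chars * seq_along(chars)) %% 1e6
  withr::with_seed(as.integer(key), sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_sexnest <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sexnest_error")))
}
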