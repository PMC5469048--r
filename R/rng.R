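#' Derive a child seed from a root seed and a stream label
#'
#' Every stochastic stage of the pipeline draws from its own random stream so
#' that a single root seed reproduces the whole study bit-for-bit while stages
#' stay independent of each other's draw counts.  Child seeds are produced by
#' a small multiplicative-congruential hash of the root seed and any number of
#' integer stream labels (subject index, repetition, block, stage code, ...).
#'
#' @param root_seed Integer root seed (< 2^31).
#' @param ... Integer stream labels; character labels are hashed by their
#'   character codes.
#' @return A single integer in `[1, 2147483396]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "cohort", 3L)
#' @export
derive_seed <- function(root_seed, ...) {
  labs <- list(...)
  h <- as.double(root_seed) %% 2147483399
  mix <- function(h, k) (h * 48271 + as.double(k) * 30269 + 11) %% 2147483399
  for (lab in labs) {
    if (is.character(lab)) {
      for (cc in utf8ToInt(paste(lab, collapse = "|"))) h <- mix(h, cc)
    } else {
      for (k in lab) h <- mix(h, as.double(k))
    }
  }
  as.integer(h %% 2147483396) + 1L
}

# Evaluate `expr` under a derived seed, restoring the caller's RNG state.
with_stream <- function(root_seed, ..., expr) {
  withr::with_seed(derive_seed(root_seed, ...), expr)
}
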