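#' Noise conditions
#'
#' The three playback conditions, ordered from quiet to loud.
#' @export
CONDITIONS <- c("no_playback", "low", "high")

#' Randomized session design
#'
#' A session is nine consecutive blocks, three per noise condition, in an
#' order drawn uniformly at random among all orderings with no two adjacent
#' blocks sharing a condition (the playback randomization constraint).
#' Rejection sampling from uniformly random multiset permutations yields the
#' uniform distribution over the 174 valid orderings.
#'
#' @param block_duration_s Duration of each block in seconds (scalar, or one
#'   value per block). All durations must be > 0. Default 30 s: a desk-scale
#'   stand-in for the 5-min playback blocks; the full design is expressible
#'   by passing 300.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A `pv_session_design`: data.frame with columns `block`,
#'   `condition`, `duration_s`, `onset_s`, `offset_s`.
#' @export
make_session_design <- function(block_duration_s = 30, seed = 1L) {
  durations <- rep_len(block_duration_s, 9L)
  if (any(durations <= 0)) stop("block durations must be > 0")
  base <- rep(CONDITIONS, each = 3L)
  rng_local(derive_seed(seed, 1L), {
    repeat {
      ord <- sample(base)
      if (!any(ord[-1] == ord[-9])) break
    }
  })
  offs <- cumsum(durations)
  d <- data.frame(block = 1:9, condition = ord, duration_s = durations,
                  onset_s = c(0, offs[-9]), offset_s = offs,
                  stringsAsFactors = FALSE)
  class(d) <- c("pv_session_design", "data.frame")
  d
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
rng_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

validate_design <- function(design) {
  stopifnot(is.data.frame(design), nrow(design) == 9L)
  tab <- table(factor(design$condition, levels = CONDITIONS))
  if (!all(tab == 3L)) stop("design must have exactly 3 blocks per condition")
  if (any(design$condition[-1] == design$condition[-9]))
    stop("design has two adjacent blocks with the same condition")
  if (any(design$duration_s <= 0)) stop("design has non-positive block durations")
  invisible(design)
}
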