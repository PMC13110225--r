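# Internal helpers: argument checking and reproducible seed streams.

stop_dcimon <- function(msg, ..., class = "dcimon_error") {
  rlang::abort(sprintf(msg, ...), class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_dcimon("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_dcimon("`%s` = %g must lie in [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != floor(x)) stop_dcimon("`%s` must be an integer count", name)
  invisible(as.integer(x))
}

#' Derive reproducible child seeds from a master seed
#'
#' Splits one master seed into `n` independent stream seeds. Streams are a
#' pure function of `(seed, n)`, independent of the order in which they are
#' consumed, so per-patient / per-modality generation is reproducible even
#' when patients are generated in parallel or in a different order.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
seed_streams <- function(seed, n) {
  check_count(seed, "seed", lower = 0L)
  check_count(n, "n")
  # SplitMix-style multiplicative scramble, kept inside 31-bit range.
  s <- (as.double(seed) %% 2147483647) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647 # Lehmer MINSTD step
    out[i] <- s
  }
  as.integer(out)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}
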