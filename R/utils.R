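# Internal helpers shared across modules.

#' Clamp a numeric vector to an interval
#' @noRd
clamp <- function(x, lo = 0, up = 1) pmin(pmax(x, lo), up)

#' Round half away from zero
#'
#' Base R rounds half to even; report tables use the conventional
#' "half-up" rule so printed summaries match hand arithmetic.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.345, 2)  # 2.35
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Stable string -> integer hash (FNV-style, kept below 2^31 so the result
# is always a valid set.seed() argument). Used to derive independent,
# order-invariant substreams from one root seed.
hash_seed <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  # multiplier kept small enough that h * mult stays exact in doubles
  h <- 97531
  for (ch in utf8ToInt(s)) {
    h <- (h * 69069 + ch + 1) %% 2147483647
  }
  as.integer(h %% 2147483629L)
}

# Evaluate expr with a local RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards. A short burn-in decorrelates the
# stream from the raw seed (the first Mersenne-Twister draws after
# set.seed are strongly patterned across nearby seeds).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  stats::runif(20)
  expr
}

stopf <- function(fmt, ..., class = "framesim_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
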