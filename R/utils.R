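# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves rounded up (away from
#' zero for positive values), matching how percentages are conventionally
#' printed, rather than the round-half-even rule used by [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.345, 2)  # 2.35
#' round(2.345, 2)          # 2.34 under round-half-even
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Stable 31-ary string hash, independent of R's internals so that per-cell
# random substreams are reproducible across platforms and sessions.
stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(as.character(s))) h <- (h * 31 + code) %% 1048573L
  as.integer(h)
}

# Derive a secondary seed from a master seed and a stream tag; kept below
# 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 65011) * 32003 + stable_hash(tag)) %% .Machine$integer.max
}

state_vocab <- function() c("AW", "QW", "NREMS", "REMS", "CATAPLEXY")

wake_states <- function() c("AW", "QW")

# Derived bout labels belonging to the active-wake family.
aw_family <- function() c("AW", "AWO", "HAW")

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
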