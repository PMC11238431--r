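# shared internal helpers

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (0.005 -> 0.01), as used for
#' all reported percentages. Base `round()` rounds half to even, which would
#' change printed second decimals.
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic 32-bit sub-seed from a master seed and a stream tag, so each
# sub-generator draws from its own stream and adding one generator does not
# perturb the others.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.double(seed) %% 2147483647 + h) %% 2147483647)
}

stop_if_not_prob <- function(p, what = "p") {
  if (length(p) == 0L) stop(what, " must be non-empty")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop(what, " values must lie in [0, 1]")
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# accept gene class tables with either a `label` (classifier output) or
# `class` (generator ground truth) column
normalize_labels <- function(labels) {
  dt <- as.data.table(labels)
  if (!"label" %in% names(dt)) {
    if (!"class" %in% names(dt))
      stop("label table needs a 'label' or 'class' column")
    setnames(dt, "class", "label")
  }
  dt
}
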