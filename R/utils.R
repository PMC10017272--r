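#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed plus a stage label (and optional
#' index, e.g. a trial id) to a 32-bit seed, so that every stochastic stage
#' of an experiment draws from an independent, reproducible stream.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"train"`, `"inject"`).
#' @param index optional integer sub-index (trial id, site id, ...).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  mod <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 131 + ch) %% mod
  as.integer(((as.numeric(master) %% mod) * 69621 + h + as.numeric(index) * 10007) %% mod)
}

# max-precision numeric key; identical doubles give identical keys
.num_key <- function(x) paste(sprintf("%.17g", as.numeric(x)), collapse = "|")

.is_zero <- function(x) all(x == 0)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
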