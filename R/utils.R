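#' @importFrom rlang %||% .data
#' @importFrom stats rnorm runif sd var cor lm coef confint prcomp dist
#' @importFrom stats cor.test quantile setNames
#' @importFrom utils combn head
NULL

# Deterministic child seed derived from a master seed and a string key.
# Keeps every derived seed strictly below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, ...) {
  key <- paste(..., sep = "/")
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes))
  as.integer((as.double(seed) %% 2147483629 * 48271 + h * 7919 + 1) %% 2147483629)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

TREATMENTS <- c("ancestral", "monoculture", "polyculture")

check_treatment <- function(treatment) {
  assert_that(length(treatment) == 1 && treatment %in% TREATMENTS,
              sprintf("unknown treatment '%s'; must be one of %s",
                      treatment, paste(TREATMENTS, collapse = ", ")))
  treatment
}

# Standard error of the mean
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
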