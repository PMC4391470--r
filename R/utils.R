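#' @keywords internal
"_PACKAGE"

# Smallest p-value kept before taking logs; avoids -Inf in Fisher-type sums.
P_FLOOR <- 1e-300

# Genome-wide significance constant used for reporting only (never filtering).
GENOMEWIDE_ALPHA <- 5e-7

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a 32-bit seed, so
#' that every stochastic stage of a benchmark is reproducible from one master
#' seed and different stages (or replicates) decorrelate.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. "genotypes", "phenotype").
#' @return A single integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  s <- (abs(as.numeric(master)) %% m)
  # two rounds of a Lehmer-style mix keep distinct (master, stage) pairs apart
  s <- (s * 48271 + h + 1) %% m
  s <- (s * 69621 + 11) %% m
  as.integer(s + 1)
}

# stop() with a condition subclass so callers can branch on failure kind
stop_gwasbench <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "gwasbench_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop_gwasbench(sprintf("`%s` must be a single number in (0, 1)", name),
                   "gwasbench_invalid_parameter")
  invisible(x)
}

check_pvec <- function(p) {
  if (length(p) < 1L || anyNA(p) || any(p <= 0) || any(p > 1))
    stop_gwasbench("p-values must lie in (0, 1]", "gwasbench_domain_error")
  invisible(p)
}

floor_p <- function(p) pmax(p, P_FLOOR)

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without its scalar-x surprise: always samples elements of x
sample_from <- function(x, n = 1L, replace = TRUE, prob = NULL)
  x[sample.int(length(x), n, replace = replace, prob = prob)]
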