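#' @keywords internal
"_PACKAGE"

#' @importFrom stats pt qnorm runif rnorm rbinom coef predict var sd cor
#'   p.adjust phyper lm quantile hclust as.dist cutree setNames complete.cases
#'   dchisq rchisq pnorm residuals
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(master, index) {
  (as.numeric(master) * 48271 + as.numeric(index) * 10007) %% 2147483629
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == round(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x <= 1

## Truncated-normal draws by inverse-CDF; open interval endpoints have mass 0.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  if (pu <= pl) stop("degenerate truncation interval", call. = FALSE)
  qnorm(runif(n, pl, pu), mean, sd)
}

#' @importFrom stats pnorm
NULL
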