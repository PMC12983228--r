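#' @importFrom stats median rnorm runif rpois fft filter quantile pnorm dnorm
#'   rank predict shapiro.test sd
#' @importFrom utils combn write.csv read.csv
#' @importFrom rlang .data
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. NULL seed leaves the RNG untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop_param("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_param("`%s` must be in [%g, %g], got %g", name, lower, upper, x)
  }
  invisible(x)
}

# Indices of strict local maxima; runs of equal values (plateaus) contribute
# their first sample when flanked below on both sides. Endpoints excluded.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# ms -> whole samples at a given rate
ms_to_samples <- function(ms, rate) as.integer(round(ms / 1000 * rate))
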