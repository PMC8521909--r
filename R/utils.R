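#' @importFrom rlang abort warn %||% .data .env
#' @importFrom stats rnorm rpois runif sd var median fft pt setNames predict
#' @importFrom utils combn head
NULL

# metadata columns that precede the feature columns in a feature matrix
jae_meta_cols <- c("subject_id", "visit", "channel", "cycle", "label")

#' Derive a deterministic child seed from a parent seed and a tag
#'
#' Hashes the parent seed together with an arbitrary set of tags (subject id,
#' visit, channel name, ...) into an integer seed below 2^31. Used so that
#' every subject/channel in a synthetic cohort owns an isolated RNG stream:
#' adding subjects to a cohort never perturbs the waveforms of existing ones.
#'
#' @param ... scalars (coerced to character) hashed in order.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' jae_seed(1, "jia01", "left_medial")
jae_seed <- function(...) {
  parts <- vapply(list(...), function(x) paste(format(x), collapse = ","), character(1))
  s <- paste(parts, collapse = "/")
  h <- 7
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(msg) abort(msg, class = "jae_invalid_argument")

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) stop_invalid(sprintf("`%s` must be > %g", name, min))
  if (!strict_min && x < min) stop_invalid(sprintf("`%s` must be >= %g", name, min))
  invisible(x)
}

feature_columns <- function(x) setdiff(names(x), jae_meta_cols)

# population (n-denominator) standard deviation
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
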