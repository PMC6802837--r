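# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state
#' afterwards, so seeded operations do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a per-run child seed that stays inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k)) %% 2147483629)
}

# Inverse-CDF draw from a truncated normal.  Exactly one uniform is consumed
# per value, which keeps paired (common-random-number) simulation arms in
# lockstep even when truncation is active.
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  if (any(sd < 0)) stop("sd must be non-negative")
  if (all(sd == 0)) return(pmin(pmax(mean, lo), hi))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n)
  q <- stats::qnorm(plo + u * (phi - plo), mean, sd)
  # guard against infinities from degenerate truncation windows
  pmin(pmax(q, lo), hi)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stopf("'%s' must lie in [0, 1]", name)
  invisible(x)
}
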