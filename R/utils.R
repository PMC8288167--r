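# Internal helpers: structured conditions, seeded evaluation, small numerics.

#' @keywords internal
stop_metaedge <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "metaedge_error"), call = call))
}

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_metaedge(sprintf("`%s` must be a finite numeric scalar", name),
                  "metaedge_invalid_argument")
  }
  invisible(x)
}

check_positive_scalar <- function(x, name) {
  check_finite_scalar(x, name)
  if (x <= 0) {
    stop_metaedge(sprintf("`%s` must be > 0 (got %g)", name, x),
                  "metaedge_invalid_argument")
  }
  invisible(x)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded scene generators are pure functions of their spec.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# FNV-1a hash of an R object's serialization; used to stamp run reports.
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

relative_l2 <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
}

# Least-squares global complex constant c minimizing ||a - c*b||.
fit_global_constant <- function(a, b) {
  sum(Conj(b) * a) / sum(Mod(b)^2)
}
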