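#' @keywords internal
#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows rename pull across desc n all_of
#' @importFrom stats pf pt phyper rnbinom rnorm rbinom rlnorm runif setNames
#'   p.adjust sd uniroot optim var
"_PACKAGE"

# Internal unit system: mV, MOhm, pF, nA, ms (and fC for charge).
# Note mV/MOhm = nA, but pF*mV/ms = pA, so the membrane ODE carries an
# explicit 1e-3 factor converting nA to pA-compatible dV/dt terms.

stop_cochle <- function(msg, class) {
  abort(msg, class = c(class, "cochleaging_error"))
}

check_number <- function(x, name, min = -Inf, strict_min = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop_cochle(sprintf("`%s` must be a numeric of length %d", name, len),
                "config_error")
  }
  bad <- if (strict_min) any(x <= min) else any(x < min)
  if (bad) {
    stop_cochle(sprintf("`%s` must be %s %s", name,
                        if (strict_min) ">" else ">=", format(min)),
                "config_error")
  }
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_cochle(sprintf("`%s` must lie in [0, 1]", name), "config_error")
  }
  invisible(x)
}

# One RNG stream per top-level call: run `expr` under a local RNG seeded
# with `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    check_number(seed, "seed")
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}
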