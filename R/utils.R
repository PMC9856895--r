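# Internal validation helpers. All user-facing errors are rlang conditions
# with a class so callers (and the CLI) can distinguish configuration errors
# from computation errors.

abort_config <- function(msg, field = NULL) {
  rlang::abort(msg, class = "riplab_config_error", field = field)
}

abort_input <- function(msg, ...) {
  rlang::abort(msg, class = "riplab_input_error", ...)
}

check_scalar_num <- function(x, name, min = -Inf, max = Inf,
                             strict_min = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number.", name), name)
  }
  if (integerish && x != floor(x)) {
    abort_config(sprintf("`%s` must be a whole number.", name), name)
  }
  if (x < min || x > max || (strict_min && x <= min)) {
    abort_config(sprintf("`%s` = %s is out of range.", name, format(x)), name)
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_input(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Seeded evaluation that restores the caller's RNG state afterwards, so
# generator calls never perturb an enclosing simulation.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_scalar_num(seed, "seed", integerish = TRUE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
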