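#' Derive a reproducible per-stage random seed
#'
#' Every stochastic stage of the pipeline (simulation, each model fit, the
#' power grid, ...) derives its own integer seed from the single global seed
#' and the stage's name. Stages are therefore reproducible in isolation: the
#' lifespan fit draws the same chain whether or not the fecundity fit ran
#' before it.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label, e.g. `"simulate"` or `"fit-lifespan-A"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1L, "simulate")
#' derive_seed(1L, "fit-lifespan-A")
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # 32-bit mixing of the stage name into the seed; plain arithmetic so the
  # derivation is identical on every platform
  h <- 2166136261
  for (code in utf8ToInt(stage)) {
    h <- ((h * 16777619) %% 2147483647 + code) %% 2147483647
  }
  as.integer((abs(seed) + h) %% 2147483647)
}

# Run `expr` under the stage-derived seed, restoring the caller's RNG state.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stage))
  expr
}
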