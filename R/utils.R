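# Internal helpers shared across modules.

# Canonical order of the four cue objects: spatial validity varies slowest.
CUE_OBJECTS <- c("SvFv", "SvFi", "SiFv", "SiFi")

space_valid_of <- function(cue_object) {
  cue_object %in% c("SvFv", "SvFi")
}

feature_valid_of <- function(cue_object) {
  cue_object %in% c("SvFv", "SiFv")
}

# Derive n reproducible sub-seeds from one master seed without touching the
# caller's RNG stream afterwards. Seeds stay below 2^31 - 1.
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(2147483646L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ez <- function(...) stop(..., call. = FALSE)
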