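# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, class = "skyfilter_error") {
  if (!isTRUE(cond)) stop(errorCondition(msg, class = c(class, "error")))
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

.is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# All randomness in the package goes through this so results are reproducible
# from the seeds recorded in specs and configs. Seeds derived from a base seed
# stay below 2^31 - 1.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629) + 1L
}

# Bilinear resize of an image matrix [y, x] to (height, width).
# EBImage stores images [x, y], hence the transposes at this boundary.
resize_image <- function(img, height, width) {
  .assert(height >= 1 && width >= 1, "resize target must be positive")
  out <- EBImage::resize(t(img), w = as.integer(width), h = as.integer(height))
  t(as.matrix(out))
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
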