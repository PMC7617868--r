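`%||%` <- function(a, b) if (is.null(a)) b else a

# clamp a cosine into [-1, 1] before acos; dot products of unit vectors can
# overshoot by a few ulp
clamp_cos <- function(x) pmin(1, pmax(-1, x))

vec_norm <- function(v) sqrt(sum(v^2))

# deterministic per-run seed derived from a single user seed; kept < 2^31
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(stream)) %% 2147483647)
}

# run code with a private RNG stream, restoring the caller's state afterwards
with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  force(code)
}

fmt_num <- function(x) sprintf("%.17g", x)
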