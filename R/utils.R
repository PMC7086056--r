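#' @keywords internal
"_PACKAGE"

# Seed discipline: every stochastic operation takes an explicit `seed`.
# A non-NULL seed is applied locally and the caller's RNG state is restored
# on exit; seed = NULL continues from the current RNG stream.
local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(NULL)
}

# Derive a child seed from a parent seed and a stage offset, kept inside
# 32-bit integer range so downstream set.seed() never overflows.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Unordered genotype (i, j) with i <= j -> linear index in 1..K(K+1)/2.
geno_index <- function(i, j) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  hi * (hi - 1L) / 2L + lo
}

# Enumerate unordered genotypes for K alleles: matrix with columns a1 <= a2,
# row g is the genotype with geno_index(a1, a2) == g.
geno_space <- function(K) {
  hi <- rep(seq_len(K), seq_len(K))
  lo <- sequence(seq_len(K))
  cbind(a1 = lo, a2 = hi)
}

#' Record run parameters as a JSON sidecar
#'
#' Writes the seed and stage parameters next to a stage's output so any
#' table can be traced back to the exact settings that produced it.
#'
#' @param path Output path (conventionally `<output>.run.json`).
#' @param stage Stage name.
#' @param seed Integer seed used.
#' @param params Named list of stage parameters.
#' @return `path`, invisibly.
#' @export
write_run_sidecar <- function(path, stage, seed, params = list()) {
  jsonlite::write_json(list(stage = stage, seed = seed, params = params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
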