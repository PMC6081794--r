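# Internal helpers shared across modules.

# Deterministic substream seed derived from a top-level seed and a stream
# name, so each generated table consumes its own RNG stream and adding a
# table never perturbs the others. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

# Dirichlet draw via independent gammas; alpha may contain zeros (those
# components are fixed at zero mass).
rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  x[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  s <- sum(x)
  if (s == 0) stop("degenerate Dirichlet draw: all concentrations zero")
  names(x) <- names(alpha)
  x / s
}

# Log-normal draw with arithmetic mean m and coefficient of variation cv.
rlnorm_mean_cv <- function(n, m, cv) {
  if (any(cv < 0)) stop("coefficient of variation must be non-negative")
  if (all(cv == 0)) return(rep_len(m, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All n! permutations of 1..n as an n x n! matrix (small n only).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(cbind, lapply(seq_len(n), function(k) {
    rbind(rep(k, ncol(sub)),
          apply(sub, 2, function(p) (seq_len(n)[-k])[p]))
  }))
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
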