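#' @keywords internal
"_PACKAGE"

expit <- function(x) 1 / (1 + exp(-x))

## reverse cumulative sum: out[i] = sum(x[i:n])
rev_cumsum <- function(x) rev(cumsum(rev(x)))

## Evaluate expr under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

## Deterministic derived seeds, kept within 32-bit integer range.
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483629)
}

## Stratified train/test split indices; `fraction` goes to train.
stratified_split <- function(labels, fraction = 2 / 3, seed = 1L) {
  with_seed(seed, {
    train <- integer(0)
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      n_tr <- round(length(idx) * fraction)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

## Stratified k-fold assignment (vector of fold ids 1..k).
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

## Truncated normal draws by inverse-CDF (exact, vectorised).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lipokin <- function(msg, class) {
  stop(structure(class = c(class, "lipokin_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
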