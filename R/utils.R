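# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded package functions do not perturb the global random stream.
#' @noRd
with_seed_ <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic polynomial string hash (mod a prime below 2^26 so all
# products stay exact in double arithmetic). Used to key stratified fold
# assignment to food_id + seed, making fold membership invariant to the
# row order of the training table.
string_hash <- function(strings) {
  mod <- 67108859
  vapply(strings, function(s) {
    h <- 5381
    for (b in utf8ToInt(enc2utf8(s))) h <- (h * 131 + b) %% mod
    h
  }, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_foodprox <- function(..., class) {
  stop(structure(class = c(class, "foodprox_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}
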