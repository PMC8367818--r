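# internal helpers shared across modules

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so generators are deterministic without side
# effects on the session RNG.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# purine/pyrimidine classification; transition = within-class difference
.isTransition <- function(a, b) {
  pur <- c("A", "G")
  (a %in% pur) == (b %in% pur) & a != b
}

.isTransitionVec <- function(a, b) {
  purA <- a == "A" | a == "G"
  purB <- b == "A" | b == "G"
  (purA == purB) & (a != b)
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
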