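# Internal helpers shared across modules.

# Wrap angles to (-pi, pi].
wrap_pi <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

# Wrap degrees to [0, 360).
wrap_deg <- function(x) x %% 360

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. `seed = NULL` leaves the
# RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Circular mean (rad) and mean resultant length of a vector of angles.
circ_stats <- function(theta) {
  if (length(theta) == 0) return(list(mean = NA_real_, R = NA_real_))
  s <- mean(sin(theta))
  c <- mean(cos(theta))
  list(mean = atan2(s, c), R = sqrt(s^2 + c^2))
}

# sqrt(-2 log Rbar): circular standard deviation.
circ_sd <- function(R) {
  if (is.na(R)) return(NA_real_)
  if (R <= 0) return(Inf)
  sqrt(-2 * log(min(R, 1)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == round(x)
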