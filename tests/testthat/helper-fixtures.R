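# Shared fixtures built in code.

# Square cell mask for morphometrics tests.
square_mask <- function(size = 80L, lo = 20L, hi = 60L) {
  m <- matrix(FALSE, size, size)
  m[lo:hi, lo:hi] <- TRUE
  m
}

# Brute-force optimal assignment by permutation enumeration (oracle for
# the package's solver; only for n <= 7).
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  ps <- perms(seq_len(n))
  costs <- vapply(ps, function(p) sum(cost[cbind(seq_len(n), p)]),
                  numeric(1))
  list(perm = ps[[which.min(costs)]], cost = min(costs))
}

# Smooth unit-variance series for lag-recovery tests.
smooth_series <- function(n, seed) {
  set.seed(seed)
  v <- lamelloscope:::.gauss_smooth1d(rnorm(n), 2)
  v / sd(v)
}

# Shift a series by k frames (positive k: series values appear earlier),
# clamped at the ends.
shift_series <- function(x, k) {
  n <- length(x)
  x[pmin(n, pmax(1L, seq_len(n) + k))]
}
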