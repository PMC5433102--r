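# Enumeration helpers shared by the exhaustive sweeps.

# All profiles of length n with entries in 0..cap, as rows.
all_profiles <- function(n, cap) {
  as.matrix(expand.grid(rep(list(0:cap), n)))
}

# All interval events (s, t, b) on n positions with |b| <= bmax, as a
# data.frame in arbitrary but fixed order.
all_events <- function(n, bmax = 1L) {
  s <- unlist(lapply(seq_len(n), function(i) rep(i, n - i + 1L)))
  t <- unlist(lapply(seq_len(n), function(i) i:n))
  out <- expand.grid(idx = seq_along(s), b = setdiff(-bmax:bmax, 0L))
  events(s[out$idx], t[out$idx], out$b)
}

# A random event sequence on n positions.
random_events <- function(n, len, bmax = 2L) {
  if (len == 0L) return(events())
  s <- sample.int(n, len, replace = TRUE)
  t <- vapply(s, function(si) si + sample.int(n - si + 1L, 1L) - 1L,
              integer(1))
  b <- sample(setdiff(-bmax:bmax, 0L), len, replace = TRUE)
  events(s, t, b)
}
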