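# shared fixture builders; everything is generated in code at test time

# a sharply peaked periodic gene with programs for every condition
periodic_model <- function(id = "gA", b = 0.5, a = 4, phi = 0.2, kappa = 4,
                           regulon = "MBF",
                           program = "continue") {
  progs <- lapply(oscarrest:::regulon_programs()[[regulon]],
                  function(x) x)
  progs <- lapply(progs, function(x) program)  # force one program everywhere
  gene_model(id, b, a, phi, kappa, regulon = regulon, programs = progs)
}

flat_model <- function(id = "gF", b = 2) {
  gene_model(id, b, 0, 0, 0, regulon = "OTHER",
             programs = oscarrest:::regulon_programs()$OTHER)
}

perfect_sync <- function(period = 120, theta0 = 0, bud = 0.25) {
  synchrony_model(initial_phase = theta0, initial_sd = 0, period = period,
                  dispersion_rate = 0, bud_phase = bud)
}

default_sync <- function() synchrony_model()

tiny_matrix <- function() {
  time_series_matrix(matrix(c(1, 2, 4, 2, 2, 2), nrow = 2, byrow = TRUE),
                     c("g1", "g2"), c(0, 20, 40))
}

# brute-force BH step-up oracle: q(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive hypergeometric tail by enumerating all size-n draws
hyper_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  annotated <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% annotated))
  mean(hits >= k)
}

# independent recursive permutation enumerator for the exact-p oracle
perms_oracle <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms_oracle(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
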