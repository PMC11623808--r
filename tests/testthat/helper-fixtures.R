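# shared fixtures: tiny graphs built in code, plus an independent dense
# absorbing-chain oracle for the 1-D well-mixed birth-death process

path_graph <- function(n) {
  igraph::graph_from_edgelist(cbind(seq_len(n - 1), 2:n), directed = FALSE)
}

# dense linear-algebra oracle for the well-mixed chain: builds the full
# (N+1)-state transition matrix of the mutant-count process and solves
# absorption directly; independent of the product-formula implementation
wellmixed_fixation_oracle <- function(params, start = 1) {
  N <- params$N
  f <- vapply(1:(N - 1), relative_mutant_fitness, numeric(1), params = params)
  Tup <- Tdn <- numeric(N - 1)
  for (n in 1:(N - 1)) {
    W <- n * f[n] + (N - n)
    Tup[n] <- (n * f[n] / W) * (N - n) / (N - 1)
    Tdn[n] <- ((N - n) / W) * n / (N - 1)
  }
  Q <- matrix(0, N - 1, N - 1)
  b <- numeric(N - 1)
  for (n in 1:(N - 1)) {
    if (n < N - 1) Q[n, n + 1] <- Tup[n] else b[n] <- Tup[n]
    if (n > 1) Q[n, n - 1] <- Tdn[n]
    Q[n, n] <- 1 - Tup[n] - Tdn[n]
  }
  h <- solve(diag(N - 1) - Q, b)
  h[start]
}
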