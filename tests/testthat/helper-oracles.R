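# Independent oracles used across the suite. These re-derive model
# quantities from first principles (dimensional equations, naive matrix
# constructions) and deliberately share no code with the package
# internals they check.

# Right-hand side of the dimensional model (densities in cells/mL,
# phages/mL, arbitrium in concentration units), written directly from
# the growth/infection/burst/decay/uptake processes.
dimensional_rhs <- function(S, L, P, A, dp, phi_fun, mut = NULL) {
  N <- S + sum(L)
  phi <- phi_fun(A)
  growth <- dp$r * (1 - N / dp$K)
  infection <- dp$b * dp$a * S * P
  burst <- dp$B * (dp$alpha * L + (1 - phi) * infection)
  if (!is.null(mut)) burst <- as.vector(mut %*% burst)
  list(
    dS = growth * S - dp$b * dp$a * S * sum(P),
    dL = growth * L + phi * infection - dp$alpha * L,
    dP = burst - dp$delta * P - dp$a * N * P,
    dA = dp$c * dp$b * dp$a * S * sum(P) - dp$u * N * A
  )
}

# Naive dense construction of the nearest-neighbour mutation matrix for
# a factorial (n_phi x n_theta) grid, built by explicit mass ledger.
naive_mutation_matrix <- function(n_phi, n_theta, mu_phi, mu_theta) {
  axis_mat <- function(n, mu) {
    M <- diag(1 - mu, n)
    if (n == 1 || mu == 0) return(diag(1, n))
    for (i in seq_len(n)) {
      for (d in c(-1, 1)) {
        j <- i + d
        if (j >= 1 && j <= n) M[j, i] <- M[j, i] + mu / 2
        else M[i, i] <- M[i, i] + mu / 2   # boundary retention
      }
    }
    M
  }
  Mp <- axis_mat(n_phi, mu_phi)
  Mt <- axis_mat(n_theta, mu_theta)
  # variants ordered phi-fastest: full operator is Mt (x) Mp
  kronecker(Mt, Mp)
}

# Random valid system state for property tests.
random_state <- function(n, k = 1) {
  system_state(s = runif(1, 0, k),
               l = runif(n, 0, k / n),
               p = runif(n, 0, 1e-2),
               A = runif(1, 0, 1.2),
               k = k)
}

default_inoculum <- function(params) 1e-5 * params$B_eff
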