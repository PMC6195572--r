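# shared fixtures built in code

# token_sequence straight from an integer vector (synthetic alphabet)
ts <- function(tokens, D = NULL) token_sequence(tokens, D = D)

# small edge-list text used across io/cli tests
edge_lines <- function() c(
  "# sensor deployment, 20s resolution",
  "0 1 2",
  "0 2 3   extra column",
  "20 2 1",
  "40 3 1",
  "40 1 2"
)

# independent reachability oracle for beta = 1, gamma = 0: forward scan over
# the event sequence, a node is reached if it shares an edge with a reached
# node at or after the time the latter was reached
reachable_set <- function(edges, seed_node) {
  reached <- seed_node
  for (i in seq_len(nrow(edges))) {
    u <- edges$u[i]; v <- edges$v[i]
    if (u %in% reached && !(v %in% reached)) reached <- c(reached, v)
    else if (v %in% reached && !(u %in% reached)) reached <- c(reached, u)
  }
  sort(reached)
}

# random temporal edge list on N nodes
random_edges <- function(N, E) {
  u <- sample.int(N, E, replace = TRUE)
  v <- sample.int(N - 1L, E, replace = TRUE)
  v <- ifelse(v >= u, v + 1L, v)
  temporal_edges(seq_len(E) - 1L, u, v)
}
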