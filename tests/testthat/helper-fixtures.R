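# Shared fixtures and independent reference implementations used as oracles.

# random simple network via ER draws, guaranteed at least one edge
random_network <- function(n, p = 0.4) {
  repeat {
    net <- make_er(n, p)
    if (n_edges(net) > 0) return(net)
  }
}

# uniformly random labelled tree on n nodes (Prufer sequence)
random_tree <- function(n) {
  if (n == 1) return(cg_network(1, NULL))
  if (n == 2) return(cg_network(2, rbind(c(0, 1))))
  prufer <- sample.int(n, n - 2, replace = TRUE) - 1L
  degree <- rep(1L, n)
  for (p in prufer) degree[p + 1L] <- degree[p + 1L] + 1L
  edges <- matrix(integer(0), ncol = 2)
  for (p in prufer) {
    leaf <- which(degree == 1L)[1] - 1L
    edges <- rbind(edges, c(leaf, p))
    degree[leaf + 1L] <- 0L
    degree[p + 1L] <- degree[p + 1L] - 1L
  }
  last <- which(degree == 1L) - 1L
  edges <- rbind(edges, last)
  cg_network(n, edges)
}

random_edgeq <- function(net, m, sd = 1) {
  lapply(seq_len(n_edges(net)), function(e) matrix(rnorm(m * m, sd = sd), m, m))
}

# neighbour model with random observation counts
random_nm <- function(net, m, max_count = 20) {
  nm <- neighbor_model(net, m)
  for (key in names(nm$counts)) {
    nm$counts[[key]] <- matrix(sample.int(max_count + 1L, m * m,
                                          replace = TRUE) - 1L, m, m)
  }
  nm
}

# Independent reference for PV (Eq. written out directly, no shared helpers)
ref_potential_value <- function(i, a_i, cs, net, edgeq, nm) {
  tau <- net$adjacency[[i + 1]]
  nc <- setdiff(tau, cs)
  q_of <- function(k) {
    e <- which(net$edges[, 1] == min(i, k) & net$edges[, 2] == max(i, k))
    tab <- edgeq[[e]]
    if (i < k) tab else t(tab)
  }
  total <- 0
  for (j in cs) total <- total + max(q_of(j)[a_i, ])
  for (k in nc) {
    cnts <- nm$counts[[paste0(i, ":", k)]][a_i, ] + nm$smoothing
    total <- total + sum(cnts / sum(cnts) * q_of(k)[a_i, ])
  }
  total
}

ref_potential_loss <- function(i, nc, net, edgeq, nm) {
  tau <- net$adjacency[[i + 1]]
  m <- nm$n_actions
  pv <- function(cs) max(vapply(seq_len(m), function(a)
    ref_potential_value(i, a, cs, net, edgeq, nm), numeric(1)))
  pv(tau) - pv(setdiff(tau, nc))
}

# flatten edge Q tables row-major for the C++ kernel
flatten_edgeq <- function(edgeq) {
  as.numeric(unlist(lapply(edgeq, function(mm) as.vector(t(mm)))))
}
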