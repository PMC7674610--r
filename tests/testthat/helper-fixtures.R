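# hand-built trait_corr objects and edge lists for network tests
toy_corr <- function(edges, nodes, classes = NULL, alpha = 0.05) {
  # build a trait_corr by hand: significant p for listed pairs only
  k <- length(nodes)
  rho <- matrix(0, k, k, dimnames = list(nodes, nodes)); diag(rho) <- 1
  p <- matrix(0.9, k, k, dimnames = list(nodes, nodes)); diag(p) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    rho[a, b] <- rho[b, a] <- 0.9
    p[a, b] <- p[b, a] <- edges$p[i] %||% 0.01
  }
  classes <- classes %||% setNames(rep("physiological", k), nodes)
  structure(list(rho = rho, p = p,
                 n = matrix(10, k, k, dimnames = list(nodes, nodes)),
                 method = matrix("exact", k, k), traits = nodes,
                 classes = classes, constant_traits = character()),
            class = "trait_corr")
}

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
}

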