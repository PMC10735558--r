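# internal helpers shared across modules

wp_stop <- function(..., stage = NULL) {
  msg <- paste0(...)
  if (!is.null(stage)) msg <- sprintf("[%s] %s", stage, msg)
  rlang::abort(msg, class = "durumwp_error")
}

wp_note <- function(...) rlang::inform(paste0(...), class = "durumwp_log")

# silhouette width of a 2-group split on a numeric score vector (or matrix rows)
mean_silhouette <- function(x, groups) {
  x <- as.matrix(x)
  d <- as.matrix(dist(x))
  ug <- unique(groups)
  stopifnot(length(ug) == 2L)
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- groups == groups[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- mean(d[i, !own & seq_len(nrow(x)) != i])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# compact letter display from a logical "significantly different" matrix.
# Groups sharing a letter are NOT significantly different; letters are the
# maximal cliques of the not-different graph, ordered by best group mean.
compact_letters <- function(diff_mat, means) {
  k <- nrow(diff_mat)
  if (k == 1L) return("a")
  nd <- !diff_mat
  diag(nd) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(nd, mode = "undirected", diag = FALSE)
  cliques <- igraph::max_cliques(g)
  # order cliques by the highest mean they contain so 'a' tags the best group
  ord <- order(vapply(cliques, function(cl) -max(means[as.integer(cl)]), numeric(1)))
  cliques <- cliques[ord]
  letters_out <- character(k)
  for (j in seq_along(cliques)) {
    idx <- as.integer(cliques[[j]])
    letters_out[idx] <- paste0(letters_out[idx], letters[j])
  }
  letters_out
}

# deterministic seed derivation below 2^31 for sub-streams
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483399) + 1L
}
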