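# Minimal reverse-mode tape over the compiled kernels. Each node is an
# environment holding the value `v`, the accumulated gradient `g`, and a
# backward closure `bw` that scatters an incoming gradient to its parents.
# Graphs are rebuilt per sample (define-by-run); parameter gradients are read
# off the leaf nodes afterwards.

ag_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- vector("list", 128L)
  g$n <- 0L
  g
}

ag_node <- function(graph, value, bw = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- value
  n$g <- NULL
  n$bw <- bw
  graph$n <- graph$n + 1L
  if (graph$n > length(graph$nodes))
    graph$nodes <- c(graph$nodes, vector("list", length(graph$nodes)))
  graph$nodes[[graph$n]] <- n
  n
}

ag_leaf <- function(graph, value) ag_node(graph, value)

ag_accum <- function(node, d) {
  node$g <- if (is.null(node$g)) d else node$g + d
  invisible(NULL)
}

# reverse sweep; node creation order is a topological order
ag_backward <- function(graph, loss) {
  loss$g <- 1
  for (i in seq(graph$n, 1L)) {
    n <- graph$nodes[[i]]
    if (!is.null(n$g) && !is.null(n$bw)) n$bw(n$g)
  }
  invisible(NULL)
}

op_conv <- function(graph, x, w, b, k, dil) {
  v <- conv2d_fwd(x$v, w$v, b$v, k, dil)
  ag_node(graph, v, function(gy) {
    r <- conv2d_bwd(x$v, w$v, gy, k, dil)
    ag_accum(x, r$gx)
    ag_accum(w, r$gw)
    ag_accum(b, as.numeric(r$gb))
  })
}

op_dwconv <- function(graph, x, w, b, k, dil) {
  v <- dwconv2d_fwd(x$v, w$v, b$v, k, dil)
  ag_node(graph, v, function(gy) {
    r <- dwconv2d_bwd(x$v, w$v, gy, k, dil)
    ag_accum(x, r$gx)
    ag_accum(w, r$gw)
    ag_accum(b, as.numeric(r$gb))
  })
}

op_relu <- function(graph, x) {
  v <- pmax(x$v, 0)
  ag_node(graph, v, function(gy) ag_accum(x, gy * (x$v > 0)))
}

op_sigmoid <- function(graph, x) {
  v <- 1 / (1 + exp(-x$v))
  ag_node(graph, v, function(gy) ag_accum(x, gy * v * (1 - v)))
}

op_maxpool <- function(graph, x) {
  r <- maxpool2_fwd(x$v)
  h <- dim(x$v)[1]; w <- dim(x$v)[2]
  ag_node(graph, r$y, function(gy) ag_accum(x, maxpool2_bwd(gy, r$idx, h, w)))
}

op_upsample <- function(graph, x) {
  v <- upsample2_fwd(x$v)
  ag_node(graph, v, function(gy) ag_accum(x, upsample2_bwd(gy)))
}

op_add <- function(graph, a, b) {
  ag_node(graph, a$v + b$v, function(gy) {
    ag_accum(a, gy)
    ag_accum(b, gy)
  })
}

op_concat <- function(graph, a, b) {
  da <- dim(a$v); db <- dim(b$v)
  v <- array(c(a$v, b$v), dim = c(da[1], da[2], da[3] + db[3]))
  ag_node(graph, v, function(gy) {
    ag_accum(a, gy[, , seq_len(da[3]), drop = FALSE])
    ag_accum(b, gy[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

# convex gate mix: gate * a + (1 - gate) * b, all same shape
op_gate_mix <- function(graph, gate, a, b) {
  v <- gate$v * a$v + (1 - gate$v) * b$v
  ag_node(graph, v, function(gy) {
    ag_accum(gate, gy * (a$v - b$v))
    ag_accum(a, gy * gate$v)
    ag_accum(b, gy * (1 - gate$v))
  })
}

# truth: H x W integer matrix in 0..K-1; weights: length-K numeric
op_wce <- function(graph, scores, truth, weights) {
  r <- wce_loss(scores$v, truth, weights)
  ag_node(graph, r$loss, function(gy) ag_accum(scores, gy * r$g))
}
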