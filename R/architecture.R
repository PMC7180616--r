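# Declarative layer graph for a densely connected detection backbone.
# Nodes live in a data frame; edges are (from, to) id pairs. No tensors are
# ever materialized: the module does channel arithmetic and structural
# validation only.

new_graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$edges <- list()
  env$add_node <- function(kind, kernel = NA_real_, stride = 1,
                           in_channels = 0, out_channels = 0,
                           block = NA_integer_, branch = NA_character_,
                           role = NA_character_) {
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- data.frame(
      id = id, kind = kind, kernel = kernel, stride = stride,
      in_channels = in_channels, out_channels = out_channels,
      block = block, branch = branch, role = role,
      stringsAsFactors = FALSE)
    id
  }
  env$add_edge <- function(from, to) {
    env$edges[[length(env$edges) + 1L]] <- c(from = from, to = to)
  }
  env
}

# Dense layer: concat of all prior features -> 1x1 bottleneck -> 3x3 conv.
add_dense_layer <- function(bld, sources, in_ch, growth, bottleneck, block) {
  cc <- bld$add_node("concat", in_channels = in_ch, out_channels = in_ch,
                     block = block, role = "dense_concat")
  for (s in sources) bld$add_edge(s, cc)
  bn <- bld$add_node("bottleneck", kernel = 1, in_channels = in_ch,
                     out_channels = bottleneck, block = block)
  bld$add_edge(cc, bn)
  cv <- bld$add_node("conv", kernel = 3, in_channels = bottleneck,
                     out_channels = growth, block = block)
  bld$add_edge(bn, cv)
  cv
}

# Detection branch: two convolutions then the prediction layer.
add_detect_branch <- function(bld, src, in_ch, mid_ch, head_ch, branch) {
  c1 <- bld$add_node("conv", kernel = 1, in_channels = in_ch,
                     out_channels = mid_ch, branch = branch)
  bld$add_edge(src, c1)
  c2 <- bld$add_node("conv", kernel = 3, in_channels = mid_ch,
                     out_channels = mid_ch * 2, branch = branch)
  bld$add_edge(c1, c2)
  dt <- bld$add_node("detect", kernel = 1, in_channels = mid_ch * 2,
                     out_channels = head_ch, branch = branch)
  bld$add_edge(c2, dt)
  list(first_conv = c1, detect = dt)
}

#' Build the dense detection backbone graph
#'
#' Constructs the declarative layer graph of a densely connected detection
#' backbone with three multi-scale heads. Five dense blocks with the given
#' layer counts are chained with transition layers (1x1 convolution halving
#' the channels, stride-2 downsampling); inside a block each dense layer
#' takes the concatenation of the block input and all preceding layers'
#' outputs, passes it through a 1x1 bottleneck and a 3x3 convolution
#' emitting `growth_rate` channels, so a block of `L` layers contributes
#' `L * (L + 1) / 2` direct dense connections. Each of the three detection
#' branches carries exactly two convolutional layers before its prediction
#' node (the head stack is pruned from the conventional six, relying on the
#' dense feature reuse); deeper branches are routed to shallower scales by
#' a 1x1 route convolution, upsampling and concatenation. A circular-box
#' prediction node emits `n_anchors_per_scale * (4 + n_classes)` channels
#' per cell: three coordinates plus confidence per anchor, one coordinate
#' fewer than a rectangular head.
#'
#' @param block_sizes Dense layer counts per block (default
#'   `c(6, 12, 24, 16, 16)`).
#' @param growth_rate Channels added per dense layer (default 32).
#' @param n_classes Classes predicted per anchor (default 1).
#' @param n_anchors_per_scale Anchors per cell at each scale (default 3).
#' @param bottleneck_factor Bottleneck width as a multiple of the growth
#'   rate (default 4).
#' @param in_channels Image channels (default 3).
#' @return An object of class `arch_graph`: list with `nodes`, `edges`
#'   (data frames) and `meta` (the build parameters).
#' @export
build_graph <- function(block_sizes = c(6, 12, 24, 16, 16), growth_rate = 32,
                        n_classes = 1, n_anchors_per_scale = 3,
                        bottleneck_factor = 4, in_channels = 3) {
  if (any(block_sizes < 1)) stop_input("block sizes must be positive")
  if (growth_rate < 1) stop_input("growth_rate must be positive")
  nb <- length(block_sizes)
  if (nb < 3) stop_input("at least three blocks are needed for three scales")
  bld <- new_graph_builder()
  bneck <- bottleneck_factor * growth_rate
  head_ch <- n_anchors_per_scale * (4 + n_classes)

  input <- bld$add_node("input", out_channels = in_channels, role = "input")
  stem <- bld$add_node("conv", kernel = 3, stride = 2,
                       in_channels = in_channels,
                       out_channels = 2 * growth_rate, role = "stem")
  bld$add_edge(input, stem)

  src <- stem
  ch <- 2 * growth_rate
  block_out <- integer(nb)
  block_out_ch <- numeric(nb)
  for (b in seq_len(nb)) {
    feats <- src
    feat_ch <- ch
    for (l in seq_len(block_sizes[b])) {
      lay <- add_dense_layer(bld, feats, sum(feat_ch), growth_rate, bneck, b)
      feats <- c(feats, lay)
      feat_ch <- c(feat_ch, growth_rate)
    }
    out <- bld$add_node("concat", in_channels = sum(feat_ch),
                        out_channels = sum(feat_ch), block = b,
                        role = "block_out")
    for (s in feats) bld$add_edge(s, out)
    block_out[b] <- out
    block_out_ch[b] <- sum(feat_ch)
    if (b < nb) {
      tr <- bld$add_node("transition", kernel = 1, stride = 2,
                         in_channels = block_out_ch[b],
                         out_channels = floor(block_out_ch[b] / 2), block = b)
      bld$add_edge(out, tr)
      src <- tr
      ch <- floor(block_out_ch[b] / 2)
    }
  }

  # Coarse head on the last block; deeper branch features are routed to the
  # two shallower scales by 1x1 route conv + upsample + concat.
  coarse <- add_detect_branch(bld, block_out[nb], block_out_ch[nb],
                              block_out_ch[nb] %/% 2, head_ch, "coarse")
  route_from <- coarse$first_conv
  route_ch <- block_out_ch[nb] %/% 2
  for (scale in c("mid", "fine")) {
    skip_block <- if (scale == "mid") nb - 1L else nb - 2L
    rc <- bld$add_node("conv", kernel = 1, in_channels = route_ch,
                       out_channels = route_ch %/% 2, role = "route")
    bld$add_edge(route_from, rc)
    up <- bld$add_node("upsample", in_channels = route_ch %/% 2,
                       out_channels = route_ch %/% 2, role = "route")
    bld$add_edge(rc, up)
    fuse_ch <- route_ch %/% 2 + block_out_ch[skip_block]
    fuse <- bld$add_node("concat", in_channels = fuse_ch,
                         out_channels = fuse_ch, role = "fuse")
    bld$add_edge(up, fuse)
    bld$add_edge(block_out[skip_block], fuse)
    br <- add_detect_branch(bld, fuse, fuse_ch, fuse_ch %/% 4, head_ch, scale)
    route_from <- br$first_conv
    route_ch <- fuse_ch %/% 4
  }

  structure(list(
    nodes = do.call(rbind, bld$nodes),
    edges = as.data.frame(do.call(rbind, bld$edges)),
    meta = list(block_sizes = block_sizes, growth_rate = growth_rate,
                n_classes = n_classes,
                n_anchors_per_scale = n_anchors_per_scale,
                bottleneck_factor = bottleneck_factor,
                block_out_channels = block_out_ch)
  ), class = "arch_graph")
}

#' @export
print.arch_graph <- function(x, ...) {
  cat("Architecture graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  blocks:", paste(x$meta$block_sizes, collapse = ", "),
      "(growth", x$meta$growth_rate, ")\n")
  cat("  detect heads:", sum(x$nodes$kind == "detect"), "x",
      x$meta$n_anchors_per_scale * (4 + x$meta$n_classes), "channels\n")
  invisible(x)
}

topological_order <- function(g) {
  n <- nrow(g$nodes)
  indeg <- tabulate(g$edges$to, nbins = n)
  out_of <- split(g$edges$to, factor(g$edges$from, levels = seq_len(n)))
  queue <- which(indeg == 0)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in out_of[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < n) NULL else order
}

#' Validate an architecture graph
#'
#' Structural checks on an [build_graph()] result (or a modified graph):
#' acyclicity, channel bookkeeping (every node's input channels equal the
#' sum of its predecessors' output channels; concat nodes sum multiple
#' inputs), exactly three detection nodes, exactly two convolutions on
#' every detection branch, per-block dense connection counts of
#' `L * (L + 1) / 2`, and the circular-head channel count
#' `n_anchors * (4 + n_classes)`. Violations are reported, not raised.
#'
#' @param g An `arch_graph`.
#' @return A list with `pass` (logical) and `checks` (data frame with
#'   columns `check`, `pass`, `detail`).
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "arch_graph"))
  nd <- g$nodes; ed <- g$edges
  checks <- list()
  note <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }

  note("dag", !is.null(topological_order(g)),
       "graph must be acyclic")

  pred_sum <- vapply(nd$id, function(v) {
    p <- ed$from[ed$to == v]
    sum(nd$out_channels[match(p, nd$id)])
  }, 0)
  has_pred <- nd$id %in% ed$to
  bad <- which(has_pred & abs(pred_sum - nd$in_channels) > 1e-9)
  note("channels", length(bad) == 0,
       if (length(bad)) paste("channel mismatch at node(s)",
                              paste(bad, collapse = ", ")) else
         "in_channels equal sum of predecessors' out_channels")

  n_detect <- sum(nd$kind == "detect")
  note("three_heads", n_detect == 3L, paste("found", n_detect, "detect nodes"))

  branches <- unique(stats::na.omit(nd$branch))
  for (br in branches) {
    n_conv <- sum(nd$kind == "conv" & !is.na(nd$branch) & nd$branch == br)
    note(paste0("pruned_head_", br), n_conv == 2L,
         paste(n_conv, "convolutions before the", br, "detection layer"))
  }

  bs <- g$meta$block_sizes
  for (b in seq_along(bs)) {
    cc <- nd$id[nd$kind == "concat" & !is.na(nd$role) &
                  nd$role == "dense_concat" & nd$block == b]
    n_conn <- sum(ed$to %in% cc)
    expect <- bs[b] * (bs[b] + 1) / 2
    note(paste0("dense_connections_block", b), n_conn == expect,
         paste0(n_conn, " dense connections (expected L(L+1)/2 = ", expect, ")"))
  }

  head_ch <- g$meta$n_anchors_per_scale * (4 + g$meta$n_classes)
  det_ok <- all(nd$out_channels[nd$kind == "detect"] == head_ch)
  note("head_channels", det_ok,
       paste("circular head emits n_anchors * (4 + n_classes) =", head_ch,
             "channels"))

  checks <- do.call(rbind, checks)
  list(pass = all(checks$pass), checks = checks)
}

#' Parameter count of an architecture graph
#'
#' Sums convolution weights (`kernel^2 * in * out`) plus batch-norm affine
#' terms (`2 * out`) for convolutional, bottleneck and transition nodes;
#' detection nodes carry a bias instead of batch norm (`+ out`). Input,
#' concat and upsample nodes are parameter-free.
#'
#' @param g An `arch_graph`.
#' @return Total parameter count (numeric).
#' @export
count_params <- function(g) {
  stopifnot(inherits(g, "arch_graph"))
  nd <- g$nodes
  total <- 0
  for (i in seq_len(nrow(nd))) {
    total <- total + switch(nd$kind[i],
      conv = , bottleneck = , transition =
        nd$kernel[i]^2 * nd$in_channels[i] * nd$out_channels[i] +
        2 * nd$out_channels[i],
      detect = nd$kernel[i]^2 * nd$in_channels[i] * nd$out_channels[i] +
        nd$out_channels[i],
      0)
  }
  total
}

#' Export or import an architecture graph as JSON
#'
#' @param g An `arch_graph`.
#' @param path File path.
#' @return `write_graph_json` returns `path` invisibly; `read_graph_json`
#'   returns the `arch_graph`.
#' @export
write_graph_json <- function(g, path) {
  stopifnot(inherits(g, "arch_graph"))
  jsonlite::write_json(list(nodes = g$nodes, edges = g$edges, meta = g$meta),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- obj$meta
  meta$block_sizes <- as.numeric(meta$block_sizes)
  structure(list(nodes = as.data.frame(obj$nodes),
                 edges = as.data.frame(obj$edges), meta = meta),
            class = "arch_graph")
}
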