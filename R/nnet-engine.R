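# Compact CNN engine in base R.
#
# A network is a DAG of nodes (input / conv / bn / relu / avgpool / maxpool /
# gap / dense / concat) evaluated in topological order on a single H x W x C
# sample.  Convolutions are im2col + GEMM (BLAS); the conv backward scatter
# uses a cached sparse matrix (Matrix package).  Geometry (im2col indices)
# is cached per node and input size, so repeated forward/backward passes at a
# fixed patch size pay the indexing cost once.  Channel counts are static
# per architecture; spatial sizes may vary between calls.

nn_node <- function(id, op, .from = id - 1L, .args = list()) {
  list(id = id, op = op, from = as.integer(.from), args = .args)
}

# Propagate channel counts and initialize parameters (He init, seeded).
net_init <- function(nodes, in_channels = 3L, heads, seed = 1L) {
  ch <- integer(length(nodes))
  params <- vector("list", length(nodes))
  old <- local_rng_seed(seed)
  on.exit(restore_rng(old))
  for (nd in nodes) {
    i <- nd$id
    cin <- if (identical(nd$op, "input")) in_channels else ch[nd$from[1]]
    ch[i] <- switch(nd$op,
      input = in_channels,
      conv = {
        k <- nd$args$k; f <- nd$args$f
        fan_in <- k * k * cin
        params[[i]] <- list(
          W = matrix(stats::rnorm(f * fan_in, sd = sqrt(2 / fan_in)), f, fan_in),
          b = numeric(f))
        f
      },
      bn = {
        params[[i]] <- list(gamma = rep(1, cin), beta = numeric(cin))
        cin
      },
      dense = {
        u <- nd$args$units
        params[[i]] <- list(
          W = matrix(stats::rnorm(u * cin, sd = sqrt(1 / cin)), u, cin),
          b = numeric(u))
        u
      },
      concat = sum(ch[nd$from]),
      vconcat = sum(ch[nd$from]),
      cin)
  }
  state <- new.env(parent = emptyenv())
  for (nd in nodes) if (identical(nd$op, "bn"))
    assign(as.character(nd$id),
           list(mean = numeric(ch[nd$from[1]]), var = rep(1, ch[nd$from[1]])),
           envir = state)
  # a node needs a gradient w.r.t. its input only if some ancestor holds
  # parameters; skipping the rest avoids propagating into the pooling stem
  # and the raw input
  haspar <- !vapply(params, is.null, logical(1))
  needs <- logical(length(nodes))
  for (nd in nodes) if (!identical(nd$op, "input"))
    needs[nd$id] <- any(haspar[nd$from] | needs[nd$from])
  list(nodes = nodes, params = params, channels = ch, heads = heads,
       needs_input_grad = needs, state = state,
       geom = new.env(parent = emptyenv()))
}

conv_geom <- function(net, id, H, W, C, k, s, pad) {
  key <- paste(id, H, W, sep = "x")
  g <- net$geom[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Hout <- (Hp - k) %/% s + 1L; Wout <- (Wp - k) %/% s + 1L
  off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"))
  offc <- as.vector(outer(off, (0:(C - 1L)) * (Hp * Wp), "+"))
  base <- as.vector(outer((0:(Hout - 1L)) * s, (0:(Wout - 1L)) * s * Hp, "+"))
  idx <- outer(as.integer(offc), as.integer(base), "+") + 1L
  g <- list(Hp = Hp, Wp = Wp, Hout = Hout, Wout = Wout, idx = idx,
            idx1 = outer(as.integer(off), as.integer(base), "+") + 1L,
            scatter = NULL, key = key)
  net$geom[[key]] <- g
  g
}

pad_spatial <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(fill, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

net_forward <- function(net, x, train = FALSE) {
  nodes <- net$nodes
  outs <- vector("list", length(nodes))
  caches <- vector("list", length(nodes))
  for (nd in nodes) {
    i <- nd$id
    inp <- if (identical(nd$op, "input")) x else outs[[nd$from[1]]]
    res <- switch(nd$op,
      input = list(y = x),
      conv = {
        d <- dim(inp); a <- nd$args
        g <- conv_geom(net, i, d[1], d[2], d[3], a$k, a$s, a$pad)
        xp <- pad_spatial(inp, a$pad)
        cols <- matrix(xp[g$idx], nrow = nrow(g$idx))
        P <- net$params[[i]]
        o <- P$W %*% cols + P$b
        list(y = array(t(o), c(g$Hout, g$Wout, nrow(P$W))),
             cols = cols, g = g, din = d)
      },
      relu = list(y = pmax(inp, 0), mask = inp > 0),
      norm = {
        a <- nd$args
        y <- inp
        for (c in 1:3) y[, , c] <- (inp[, , c] - a$ref[c]) / a$scale
        list(y = y)
      },
      bn = bn_forward(net, i, inp, train),
      avgpool = {
        k <- nd$args$k; d <- dim(inp)
        h <- d[1] %/% k; w <- d[2] %/% k
        xc <- inp[seq_len(h * k), seq_len(w * k), , drop = FALSE]
        list(y = downscale_mean(xc, k), din = d)
      },
      maxpool = {
        a <- nd$args; d <- dim(inp)
        g <- conv_geom(net, i, d[1], d[2], d[3], a$k, a$s, a$pad)
        xp <- pad_spatial(inp, a$pad, fill = -Inf)
        k2 <- a$k * a$k
        if (is.null(g$full)) {
          full <- matrix(0L, k2, ncol(g$idx1) * d[3])
          for (c in seq_len(d[3]))
            full[, (c - 1L) * ncol(g$idx1) + seq_len(ncol(g$idx1))] <-
              g$idx1 + (c - 1L) * g$Hp * g$Wp
          g$full <- full
          net$geom[[g$key]] <- g
        }
        full <- g$full
        cols <- matrix(xp[full], nrow = k2)
        am <- max.col(t(cols), ties.method = "first")
        y <- cols[cbind(am, seq_along(am))]
        list(y = array(y, c(g$Hout, g$Wout, d[3])), am = am, full = full,
             g = g, din = d)
      },
      gap = {
        d <- dim(inp)
        list(y = colMeans(matrix(inp, d[1] * d[2], d[3])), din = d)
      },
      dense = {
        P <- net$params[[i]]
        list(y = as.numeric(P$W %*% inp + P$b), xin = inp)
      },
      concat = {
        parts <- outs[nd$from]
        d <- dim(parts[[1]])
        list(y = array(unlist(parts, use.names = FALSE),
                       c(d[1], d[2], sum(vapply(parts, function(p) dim(p)[3],
                                                numeric(1))))))
      },
      vconcat = list(y = unlist(outs[nd$from], use.names = FALSE)),
      stop("unknown op: ", nd$op))
    outs[[i]] <- res$y
    res$y <- NULL
    caches[[i]] <- res
  }
  list(outs = outs, caches = caches)
}

bn_forward <- function(net, id, x, train, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  P <- net$params[[id]]
  st <- net$state[[as.character(id)]]
  if (train) {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * va
    net$state[[as.character(id)]] <- st
  } else {
    mu <- st$mean; va <- st$var
  }
  sd_ <- sqrt(va + eps)
  xn <- sweep(sweep(m, 2L, mu), 2L, sd_, "/")
  y <- sweep(sweep(xn, 2L, P$gamma, "*"), 2L, P$beta, "+")
  list(y = array(y, d), xn = xn, sd = sd_, mu = mu, din = d, train = train,
       xmat = m)
}

# Backward pass.  dheads: named list of gradients w.r.t. head outputs
# (logits), names matching net$heads.  Returns list(grads) aligned with
# net$params.
net_backward <- function(net, fw, dheads) {
  nodes <- net$nodes
  n <- length(nodes)
  douts <- vector("list", n)
  grads <- vector("list", n)
  for (h in names(net$heads)) {
    i <- net$heads[[h]]
    douts[[i]] <- add_grad(douts[[i]], dheads[[h]])
  }
  for (i in rev(seq_len(n))) {
    nd <- nodes[[i]]
    dy <- douts[[i]]
    if (is.null(dy) || identical(nd$op, "input")) next
    ca <- fw$caches[[i]]
    from <- nd$from
    switch(nd$op,
      conv = {
        a <- nd$args; g <- ca$g
        f <- nrow(net$params[[i]]$W)
        D <- t(matrix(dy, g$Hout * g$Wout, f))
        grads[[i]] <- list(W = D %*% t(ca$cols), b = rowSums(D))
        if (!net$needs_input_grad[i]) next
        dx <- if (a$s == 1L)
          conv_backward_input(net, i, nd, ca, dy)
        else
          conv_backward_input_scatter(net, nd, ca, D)
        douts[[from]] <- add_grad(douts[[from]], dx)
      },
      relu = {
        if (net$needs_input_grad[i])
          douts[[from]] <- add_grad(douts[[from]], dy * ca$mask)
      },
      norm = {
        if (net$needs_input_grad[i])
          douts[[from]] <- add_grad(douts[[from]], dy / nd$args$scale)
      },
      bn = {
        d <- ca$din
        dym <- matrix(dy, d[1] * d[2], d[3])
        P <- net$params[[i]]
        grads[[i]] <- list(gamma = colSums(dym * ca$xn), beta = colSums(dym))
        if (!net$needs_input_grad[i]) next
        m <- d[1] * d[2]
        dxn <- sweep(dym, 2L, P$gamma, "*")
        if (isTRUE(ca$train)) {
          xc <- sweep(ca$xmat, 2L, ca$mu)
          dva <- colSums(dxn * xc) * (-0.5) / ca$sd^3
          dmu <- -colSums(dxn) / ca$sd + dva * (-2) * colMeans(xc)
          dx <- sweep(dxn, 2L, ca$sd, "/") +
            sweep(xc, 2L, 2 * dva / m, "*") +
            matrix(dmu / m, m, d[3], byrow = TRUE)
        } else {
          dx <- sweep(dxn, 2L, ca$sd, "/")
        }
        douts[[from]] <- add_grad(douts[[from]], array(dx, d))
      },
      avgpool = {
        if (!net$needs_input_grad[i]) next
        k <- nd$args$k; d <- ca$din
        h <- d[1] %/% k; w <- d[2] %/% k
        up <- dy[rep(seq_len(h), each = k), rep(seq_len(w), each = k), ,
                 drop = FALSE] / (k * k)
        dx <- array(0, d)
        dx[seq_len(h * k), seq_len(w * k), ] <- up
        douts[[from]] <- add_grad(douts[[from]], dx)
      },
      maxpool = {
        if (!net$needs_input_grad[i]) next
        g <- ca$g; d <- ca$din
        sel <- ca$full[cbind(ca$am, seq_along(ca$am))]
        agg <- rowsum(as.numeric(dy), sel)
        dxp <- numeric(g$Hp * g$Wp * d[3])
        dxp[as.integer(rownames(agg))] <- agg
        dim(dxp) <- c(g$Hp, g$Wp, d[3])
        pad <- nd$args$pad
        dx <- if (pad > 0L)
          dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE] else dxp
        douts[[from]] <- add_grad(douts[[from]], dx)
      },
      gap = {
        if (!net$needs_input_grad[i]) next
        d <- ca$din
        dx <- array(rep(dy / (d[1] * d[2]), each = d[1] * d[2]), d)
        douts[[from]] <- add_grad(douts[[from]], dx)
      },
      dense = {
        P <- net$params[[i]]
        grads[[i]] <- list(W = outer(dy, ca$xin), b = dy)
        if (!net$needs_input_grad[i]) next
        douts[[from]] <- add_grad(douts[[from]], as.numeric(crossprod(P$W, dy)))
      },
      vconcat = {
        if (!net$needs_input_grad[i]) next
        off <- 0L
        for (f_id in from) {
          cf <- net$channels[f_id]
          if (net$needs_input_grad[f_id] ||
              !is.null(net$params[[f_id]]))
            douts[[f_id]] <- add_grad(douts[[f_id]], dy[off + seq_len(cf)])
          off <- off + cf
        }
      },
      concat = {
        if (!net$needs_input_grad[i]) next
        off <- 0L
        for (f_id in from) {
          cf <- net$channels[f_id]
          douts[[f_id]] <- add_grad(douts[[f_id]],
                                    dy[, , off + seq_len(cf), drop = FALSE])
          off <- off + cf
        }
      })
  }
  grads
}


# Input gradient of a stride-1 convolution as a transposed convolution:
# correlate dY (zero-padded by k-1-pad) with the spatially flipped, channel-
# transposed kernel.  Pure GEMM; the flip permutation is cached per node.
conv_backward_input <- function(net, i, nd, ca, dy) {
  a <- nd$args
  k <- a$k
  C <- ca$din[3]
  f <- net$channels[i]
  g <- ca$g
  gb <- conv_geom(net, -i, g$Hout, g$Wout, f, k, 1L, k - 1L - a$pad)
  pkey <- paste0("flip", i)
  perm <- net$geom[[pkey]]
  if (is.null(perm)) {
    # W column order: di fastest, then dj, then input channel; backward
    # kernel Wt[c, (di, dj, f)] = W[f, (k-1-di, k-1-dj, c)]
    di <- rep(0:(k - 1L), times = k)
    dj <- rep(0:(k - 1L), each = k)
    col_f <- 1L + (k - 1L - di) + k * (k - 1L - dj)   # per (di, dj)
    perm <- matrix(0L, C, k * k * f)
    for (ff in seq_len(f)) for (cc in seq_len(C))
      perm[cc, (ff - 1L) * k * k + seq_len(k * k)] <-
        ff + f * (col_f - 1L + k * k * (cc - 1L))
    net$geom[[pkey]] <- perm
  }
  Wt <- net$params[[i]]$W[perm]
  dim(Wt) <- dim(perm)
  dyp <- pad_spatial(dy, k - 1L - a$pad)
  colsb <- matrix(dyp[gb$idx], nrow = nrow(gb$idx))
  array(t(Wt %*% colsb), ca$din)
}

# Fallback for strided convolutions: scatter-add through a cached sparse
# matrix (only used when a strided conv sits above parameterized layers).
conv_backward_input_scatter <- function(net, nd, ca, D) {
  a <- nd$args
  g <- ca$g
  dcols <- crossprod(net$params[[nd$id]]$W, D)
  if (is.null(g$scatter)) {
    g$scatter <- Matrix::sparseMatrix(
      i = as.vector(g$idx), j = seq_along(g$idx), x = 1,
      dims = c(g$Hp * g$Wp * ca$din[3], length(g$idx)))
    net$geom[[g$key]] <- g
  }
  dxp <- as.numeric(g$scatter %*% as.vector(dcols))
  dim(dxp) <- c(g$Hp, g$Wp, ca$din[3])
  if (a$pad > 0L)
    dxp[a$pad + seq_len(ca$din[1]), a$pad + seq_len(ca$din[2]), ,
        drop = FALSE] else dxp
}

add_grad <- function(acc, g) if (is.null(acc)) g else acc + g

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# ---- architectures ---------------------------------------------------------

# Small CPU-trainable trunk: an average-pooling stem that brings the patch to
# about 64 px, then three conv(3x3)-relu-avgpool(2) blocks and global average
# pooling feeding the two softmax heads.
arch_smallcnn <- function(patch_size) {
  stem <- 1L
  while (patch_size %% (2L * stem) == 0L && patch_size / (2L * stem) >= 64L)
    stem <- 2L * stem
  n <- list()
  add <- function(op, .from = length(n), ...) {
    n[[length(n) + 1L]] <<- nn_node(length(n) + 1L, op, .from, list(...))
    length(n)
  }
  stem_node <- add("input", .from = 0L)
  if (stem > 1L) stem_node <- add("avgpool", k = stem)
  stem_node <- add("norm", .from = stem_node, ref = he_ref_rgb(), scale = 35)
  add("conv", .from = stem_node, k = 3L, f = 12L, s = 1L, pad = 1L); add("relu"); add("avgpool", k = 2L)
  add("conv", k = 3L, f = 24L, s = 1L, pad = 1L); add("relu"); add("avgpool", k = 2L)
  add("conv", k = 3L, f = 32L, s = 1L, pad = 1L); add("relu"); add("avgpool", k = 2L)
  trunk <- add("gap")
  # color shortcut: global mean RGB of the stem output feeds the heads
  # directly, so stain-fraction statistics are available from step one
  color <- add("gap", .from = stem_node)
  feat <- add("vconcat", .from = c(trunk, color))
  g <- add("dense", .from = feat, units = 3L)
  a <- add("dense", .from = feat, units = 3L)
  list(nodes = n, heads = c(grade = g, agree = a))
}

# DenseNet-121: 7x7/2 conv stem with 3x3/2 max pooling, four dense blocks of
# (6, 12, 24, 16) bottleneck layers with growth rate 32, compression-0.5
# transitions, and a final BN-ReLU-GAP trunk feeding the two heads.
arch_densenet121 <- function(growth = 32L, blocks = c(6L, 12L, 24L, 16L)) {
  n <- list()
  add <- function(op, .from = length(n), ...) {
    n[[length(n) + 1L]] <<- nn_node(length(n) + 1L, op, .from, list(...))
    length(n)
  }
  add("input", .from = 0L)
  add("norm", ref = he_ref_rgb(), scale = 35)
  add("conv", k = 7L, f = 64L, s = 2L, pad = 3L)
  add("bn"); add("relu")
  cur <- add("maxpool", k = 3L, s = 2L, pad = 1L)
  ch <- 64L
  for (bi in seq_along(blocks)) {
    for (li in seq_len(blocks[bi])) {
      b1 <- add("bn", .from = cur); r1 <- add("relu", .from = b1)
      c1 <- add("conv", .from = r1, k = 1L, f = 4L * growth, s = 1L, pad = 0L)
      b2 <- add("bn", .from = c1); r2 <- add("relu", .from = b2)
      c2 <- add("conv", .from = r2, k = 3L, f = growth, s = 1L, pad = 1L)
      cur <- add("concat", .from = c(cur, c2))
      ch <- ch + growth
    }
    if (bi < length(blocks)) {
      b <- add("bn", .from = cur); r <- add("relu", .from = b)
      ch <- ch %/% 2L
      c1 <- add("conv", .from = r, k = 1L, f = ch, s = 1L, pad = 0L)
      cur <- add("avgpool", .from = c1, k = 2L)
    }
  }
  b <- add("bn", .from = cur); r <- add("relu", .from = b)
  trunk <- add("gap", .from = r)
  g <- add("dense", .from = trunk, units = 3L)
  a <- add("dense", .from = trunk, units = 3L)
  list(nodes = n, heads = c(grade = g, agree = a))
}

# Reference mean RGB of eosin-dominated H&E tissue; patches are centered on
# it and scaled so stain-fraction differences between grades are O(1).
he_ref_rgb <- function() c(212, 173, 201)

# ---- Adam optimizer --------------------------------------------------------

adam_state <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(m = lapply(params, function(p) if (is.null(p)) NULL else zero_like(p)),
       v = lapply(params, function(p) if (is.null(p)) NULL else zero_like(p)),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st$m[[i]][[nm]] <- beta1 * st$m[[i]][[nm]] + (1 - beta1) * g
      st$v[[i]][[nm]] <- beta2 * st$v[[i]][[nm]] + (1 - beta2) * g^2
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (st$m[[i]][[nm]] / bc1) / (sqrt(st$v[[i]][[nm]] / bc2) + eps)
    }
  }
  list(params = params, state = st)
}
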