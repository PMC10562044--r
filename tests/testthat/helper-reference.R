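# Pure-R double-precision reference of the network forward pass, used as
# an independent oracle for the compiled engine.

ref_net_forward <- function(plan, weights, biases, x, H, W, N) {
  feats <- list(array(x, c(H, W, 1, N)))
  cat_feats <- function(src) {
    parts <- lapply(src + 1L, function(s) feats[[s]])
    ch <- vapply(parts, function(p) dim(p)[3], 1L)
    out <- array(0, c(H, W, sum(ch), N))
    at <- 0L
    for (p in parts) {
      out[, , (at + 1):(at + dim(p)[3]), ] <- p
      at <- at + dim(p)[3]
    }
    out
  }
  for (l in seq_along(plan)) {
    lay <- plan[[l]]
    stack <- cat_feats(lay$src)
    cin <- dim(stack)[3]
    w <- weights[[l]]; b <- biases[[l]]
    out <- array(0, c(H, W, lay$cout, N))
    if (lay$k == 1) {
      for (n in 1:N) for (co in 1:lay$cout) {
        acc <- matrix(0, H, W)
        for (c in 1:cin) acc <- acc + w[co, c] * stack[, , c, n]
        out[, , co, n] <- acc + b[co]
      }
    } else {
      pad <- array(0, c(H + 2, W + 2, cin, N))
      pad[2:(H + 1), 2:(W + 1), , ] <- stack
      for (n in 1:N) for (co in 1:lay$cout) {
        acc <- matrix(0, H, W)
        for (kk in 0:8) {
          dw <- kk %/% 3 - 1; dh <- kk %% 3 - 1
          for (c in 1:cin)
            acc <- acc + w[co, kk * cin + c] *
              pad[(2 + dh):(H + 1 + dh), (2 + dw):(W + 1 + dw), c, n]
        }
        out[, , co, n] <- acc + b[co]
      }
    }
    if (lay$relu) out[out < 0] <- 0
    feats[[l + 1]] <- out
  }
  feats[[length(feats)]][, , 1, ]
}
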