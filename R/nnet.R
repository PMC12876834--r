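# R-side training loop (Adam) over the flat-parameter conv-net engine in
# src/nnet.cpp. All randomness (weight init, shuffling, augmentation draws)
# flows through the R RNG so a single seed fixes the whole fit.

# He-style initialization for the packed parameter vector given layer shapes:
# shapes is a list of c(fan_in, n_out) for weight blocks, interleaved with
# bias lengths (fan_in = NA).
init_theta <- function(blocks) {
  unlist(lapply(blocks, function(b) {
    if (is.na(b[1])) numeric(b[2])                    # bias -> zeros
    else rnorm(b[1] * b[2], 0, sqrt(2 / b[1]))        # weights
  }))
}

cnn_blocks <- function(ch) {
  list(c(27, ch[1]), c(NA, ch[1]),
       c(9 * ch[1], ch[2]), c(NA, ch[2]),
       c(9 * ch[2], ch[3]), c(NA, ch[3]),
       c(ch[3], 1), c(NA, 1))
}

unet_blocks <- function(ch) {
  list(c(27, ch[1]), c(NA, ch[1]),
       c(9 * ch[1], ch[2]), c(NA, ch[2]),
       c(9 * ch[2], ch[3]), c(NA, ch[3]),
       c(9 * (ch[3] + ch[2]), ch[2]), c(NA, ch[2]),
       c(9 * (ch[2] + ch[1]), ch[1]), c(NA, ch[1]),
       c(ch[1], 1), c(NA, 1))
}

# Minibatch Adam with a step decay (lr/3 over the last third of the epochs,
# which damps the oscillations these very small nets show near convergence).
# loss_grad(theta, idx) -> list(loss, grad).
adam_fit <- function(loss_grad, theta, n_samples, epochs, batch_size, lr) {
  m <- v <- numeric(length(theta))
  t <- 0
  for (ep in seq_len(epochs)) {
    lr_ep <- if (ep > ceiling(2 * epochs / 3)) lr / 3 else lr
    ord <- sample.int(n_samples)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (idx in batches) {
      lg <- loss_grad(theta, idx)
      t <- t + 1
      m <- 0.9 * m + 0.1 * lg$grad
      v <- 0.999 * v + 0.001 * lg$grad^2
      theta <- theta - lr_ep * (m / (1 - 0.9^t)) /
        (sqrt(v / (1 - 0.999^t)) + 1e-8)
    }
  }
  theta
}
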