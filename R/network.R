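## Minimal dense/1x1-convolution network engine used by the stand-in
## backbone and the regression head: forward, exact backpropagation and
## Adam, with per-layer freeze flags. Kept deliberately small -- the
## architecture the package trains is a pooling stem, a few pointwise
## (1x1) convolution layers and the fixed dense head, all of which reduce
## to matrix products.

relu <- function(x) pmax(x, 0)

## canonical backbone input rescaling: uint8 [0, 255] -> [-1, 1]
rescale_pixels <- function(pixels) pixels[, , 1L] / 127.5 - 1

## block-average pooling matrix (P x side), rows sum to 1
pool_matrix <- function(side, P) {
  if (side %% P != 0)
    stopf("image side %d is not a multiple of the pool size %d", side, P)
  b <- side %/% P
  w <- matrix(0, P, side)
  for (i in seq_len(P)) w[i, ((i - 1) * b + 1):(i * b)] <- 1 / b
  w
}

## fixed spatial basis: G x G grid of Gaussian bumps over the pooled
## [-1, 1]^2 plane (SD = half the bump spacing). Returns a (P^2 x G^2)
## matrix in column-major pixel order.
spatial_basis <- function(P, G) {
  cc <- seq(-1, 1, length.out = P)
  centers <- seq(-1, 1, length.out = G)
  sigma <- (centers[2L] - centers[1L]) / 2
  bump1 <- function(x) exp(-outer(x, centers, `-`)^2 / (2 * sigma^2))  # P x G
  bex <- bump1(cc); bem <- bump1(cc)
  B <- matrix(0, P * P, G * G)
  k <- 0L
  for (jem in seq_len(G)) for (iex in seq_len(G)) {
    k <- k + 1L
    B[, k] <- rep(bex[, iex], times = P) * rep(bem[, jem], each = P)
  }
  B
}

## stem: rescale, block-average to P x P, then emit per position the
## pooled intensity, intensity gated by each spatial-basis bump (a
## regional-pooling encoding: the global average of such a channel is a
## weighted regional mean intensity), and two coordinate channels (rows =
## excitation axis, columns = emission axis, each in [-1, 1]).
## Returns a (P^2 x (G^2 + 3)) matrix in column-major pixel order.
stem_features <- function(pixels, P, G) {
  side <- dim(pixels)[1L]
  A <- pool_matrix(side, P)
  pooled <- as.vector(A %*% rescale_pixels(pixels) %*% t(A))
  cc <- seq(-1, 1, length.out = P)
  cbind(pooled * spatial_basis(P, G),
        intensity = pooled,
        ex_coord = rep(cc, times = P),
        em_coord = rep(cc, each = P))
}

layer_has_params <- function(l) l$kind %in% c("conv1x1", "dense")

init_dense_weights <- function(fan_in, fan_out, final = FALSE) {
  sd <- if (final) sqrt(1 / fan_in) else sqrt(2 / fan_in)
  list(W = matrix(stats::rnorm(fan_in * fan_out, 0, sd), fan_in, fan_out),
       b = rep(0, fan_out))
}

## forward pass over a batch given precomputed stem features.
## stems: list of (P^2 x C0) matrices. Returns output plus per-layer caches
## for backprop.
nn_forward <- function(layers, stems, training = FALSE) {
  n <- length(stems)
  P2 <- nrow(stems[[1L]])
  X <- do.call(rbind, stems)
  grp <- rep(seq_len(n), each = P2)
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$kind == "stem") next
    if (l$kind %in% c("conv1x1", "dense")) {
      Z <- X %*% l$W + rep(l$b, each = nrow(X))
      A <- if (l$activation == "relu") relu(Z) else Z
      caches[[li]] <- list(input = X, pre = Z)
      X <- A
    } else if (l$kind == "bpool") {
      ## backbone's own spatial pooling: collapses the feature map to
      ## one position per sample (the head's GAP then sees a 1 x 1 map)
      caches[[li]] <- list(P2 = P2, grp = grp)
      X <- rowsum(X, grp) / P2
      grp <- seq_len(n)
      P2 <- 1L
    } else if (l$kind == "featnorm") {
      if (!is.null(l$mu)) {
        X <- sweep(sweep(X, 2L, l$mu), 2L, l$sd, "/")
        caches[[li]] <- list(sd = l$sd)
      }
    } else if (l$kind == "featclip") {
      caches[[li]] <- list(mask = abs(X) < l$limit)
      X <- clamp(X, -l$limit, l$limit)
    } else if (l$kind == "gap") {
      caches[[li]] <- list(P2 = P2, grp = grp, n = n)
      X <- rowsum(X, grp) / P2
    } else if (l$kind == "dropout") {
      if (training && l$rate > 0) {
        mask <- matrix(stats::runif(length(X)) >= l$rate, nrow(X), ncol(X)) /
          (1 - l$rate)
        caches[[li]] <- list(mask = mask)
        X <- X * mask
      }
    } else stopf("unknown layer kind '%s'", l$kind)
  }
  list(out = as.numeric(X), caches = caches)
}

## exact gradients of the MSE-style upstream gradient dout (n x 1)
nn_backward <- function(layers, fw, dout) {
  grads <- vector("list", length(layers))
  dX <- matrix(dout, ncol = 1L)
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    cc <- fw$caches[[li]]
    if (l$kind == "stem") next
    if (l$kind %in% c("conv1x1", "dense")) {
      dZ <- if (l$activation == "relu") dX * (cc$pre > 0) else dX
      grads[[li]] <- list(W = crossprod(cc$input, dZ), b = colSums(dZ))
      dX <- dZ %*% t(l$W)
    } else if (l$kind == "bpool") {
      dX <- dX[cc$grp, , drop = FALSE] / cc$P2
    } else if (l$kind == "featnorm") {
      if (!is.null(cc)) dX <- sweep(dX, 2L, cc$sd, "/")
    } else if (l$kind == "featclip") {
      dX <- dX * cc$mask
    } else if (l$kind == "gap") {
      dX <- dX[cc$grp, , drop = FALSE] / cc$P2
    } else if (l$kind == "dropout") {
      if (!is.null(cc)) dX <- dX * cc$mask
    }
  }
  grads
}

## feature matrix after layers[1:upto] (inference mode)
nn_features <- function(layers, stems, upto) {
  X <- do.call(rbind, stems)
  P2 <- nrow(stems[[1L]])
  grp <- rep(seq_along(stems), each = P2)
  for (li in seq_len(upto)) {
    l <- layers[[li]]
    if (l$kind == "stem") next
    if (l$kind %in% c("conv1x1", "dense")) {
      Z <- X %*% l$W + rep(l$b, each = nrow(X))
      X <- if (l$activation == "relu") relu(Z) else Z
    } else if (l$kind == "bpool") {
      X <- rowsum(X, grp) / P2
      grp <- seq_len(length(stems))
      P2 <- 1L
    } else if (l$kind == "featnorm" && !is.null(l$mu)) {
      X <- sweep(sweep(X, 2L, l$mu), 2L, l$sd, "/")
    } else if (l$kind == "featclip") {
      X <- clamp(X, -l$limit, l$limit)
    }
  }
  X
}

adam_init <- function(layers) {
  st <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (layer_has_params(l))
      st[[li]] <- list(mW = l$W * 0, vW = l$W * 0,
                       mb = l$b * 0, vb = l$b * 0)
  }
  list(state = st, t = 0L)
}

adam_step <- function(layers, grads, adam, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  adam$t <- adam$t + 1L
  c1 <- 1 - beta1^adam$t
  c2 <- 1 - beta2^adam$t
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (!layer_has_params(l) || !isTRUE(l$trainable) || is.null(grads[[li]]))
      next
    s <- adam$state[[li]]
    g <- grads[[li]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    l$W <- l$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    l$b <- l$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    adam$state[[li]] <- s
    layers[[li]] <- l
  }
  list(layers = layers, adam = adam)
}
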