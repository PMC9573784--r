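# Internal network kernels, checked against independent numerical oracles.

seg <- asNamespace("carpelseg")

test_that("convolution kernel matches a direct R implementation", {
  set.seed(11)
  H <- 6; W <- 5; Cin <- 2; Cout <- 3
  a <- array(rnorm(H * W * Cin), c(H, W, Cin))
  X <- seg$pad_flat(a)
  Wt <- matrix(rnorm(Cout * 9 * Cin), Cout, 9 * Cin)
  b <- rnorm(Cout)
  Y <- seg$conv3p_fw(X, Wt, b, H, W)
  # direct zero-padded 3x3 convolution, offset order (dc, dr) column-major
  ref <- array(0, c(H, W, Cout))
  for (co in 1:Cout) for (r in 1:H) for (c in 1:W) {
    acc <- b[co]; k <- 0
    for (dc in -1:1) for (dr in -1:1) {
      k <- k + 1
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W)
        for (ci in 1:Cin)
          acc <- acc + Wt[co, (k - 1) * Cin + ci] * a[rr, cc, ci]
    }
    ref[r, c, co] <- acc
  }
  ii <- seg$interior_index(H, W)
  expect_equal(Y[, ii], matrix(aperm(ref, c(3, 1, 2)), Cout, H * W),
               tolerance = 1e-12)
  # padding invariant: border stays zero
  expect_true(all(Y[, -ii] == 0))
})

test_that("backpropagated gradients match numerical differentiation", {
  set.seed(42)
  S <- 8
  net <- seg$unet_init(S, 2L, 2L, 2L, seed = 3)
  X <- seg$pad_flat(array(runif(3 * S * S), c(S, S, 3)))
  Tm <- matrix(rbinom(2 * S * S, 1, 0.4), 2)
  lossfun <- function(n) seg$soft_dice_loss(seg$unet_fw(n, X)$P, Tm)$loss
  fw <- seg$unet_fw(net, X, keep = TRUE)
  sd <- seg$soft_dice_loss(fw$P, Tm)
  g <- seg$unet_bw(net, fw, sd$dP)
  eps <- 1e-6
  for (nm in names(net$params)) {
    Wp <- net$params[[nm]]$W
    for (i in sample(length(Wp), min(4, length(Wp)))) {
      n2 <- net
      n2$params[[nm]]$W[i] <- Wp[i] + eps; lp <- lossfun(n2)
      n2$params[[nm]]$W[i] <- Wp[i] - eps; lm <- lossfun(n2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[[nm]]$W[i], num, tolerance = 1e-4,
                   label = sprintf("d/dW[%s][%d]", nm, i))
    }
  }
})

test_that("max pooling picks maxima and routes gradients to them", {
  set.seed(7)
  H <- 6; W <- 4; C <- 2
  X <- seg$pad_flat(array(rnorm(H * W * C), c(H, W, C)))
  mp <- seg$maxpool2p(X, H, W)
  ii_coarse <- seg$interior_index(H / 2, W / 2)
  # reference: block maxima computed from the array
  a <- array(t(X[, seg$interior_index(H, W)]), c(H, W, C))
  for (ch in 1:C) {
    ref <- matrix(0, H / 2, W / 2)
    for (rc in 1:(H / 2)) for (cc in 1:(W / 2))
      ref[rc, cc] <- max(a[(2 * rc - 1):(2 * rc), (2 * cc - 1):(2 * cc), ch])
    expect_equal(mp$out[ch, ii_coarse], as.vector(ref))
  }
  # gradient mass is conserved through pooling
  dY <- mp$out * 0; dY[, ii_coarse] <- 1
  dX <- seg$maxpool2p_bw(dY, mp$argmax, ncol(X))
  expect_equal(sum(dX), length(ii_coarse) * C)
  expect_true(all(dX %in% c(0, 1)))
})

test_that("soft Dice loss is bounded and exact on known overlaps", {
  P <- matrix(c(rep(1, 50), rep(0, 50)), 1)
  Tm <- matrix(c(rep(1, 25), rep(0, 75)), 1)
  l <- seg$soft_dice_loss(P, Tm, smooth = 0)
  expect_equal(l$loss, 1 - 2 * 25 / (50 + 25))
  expect_equal(seg$soft_dice_loss(Tm, Tm)$loss, 0, tolerance = 1e-6)
  for (i in 1:5) {
    P <- matrix(runif(100), 2)
    Tm <- matrix(rbinom(100, 1, 0.3), 2)
    l <- seg$soft_dice_loss(P, Tm)$loss
    expect_gte(l, 0); expect_lte(l, 1)
  }
})
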