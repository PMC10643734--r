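test_that("L1/MSE/PSNR match brute force to 1e-9 on small fixtures", {
  set.seed(4)
  a <- matrix(runif(256, -1, 1), 16, 16)
  b <- matrix(runif(256, -1, 1), 16, 16)
  q <- quality(a, b)
  expect_equal(q$l1, mean(abs(a - b)), tolerance = 1e-9)
  expect_equal(q$mse, mean((a - b)^2), tolerance = 1e-9)
  expect_equal(q$psnr, 10 * log10(4 / mean((a - b)^2)), tolerance = 1e-9)
  # closed-form example: constant offset 0.1 on range 2
  q2 <- quality(b + 0.1, b)
  expect_equal(q2$mse, 0.01, tolerance = 1e-12)
  expect_equal(q2$psnr, 10 * log10(4 / 0.01), tolerance = 1e-9)
  # identical images
  q3 <- quality(a, a)
  expect_equal(q3$l1, 0)
  expect_identical(q3$psnr, Inf)
  expect_equal(q3$ssim, 1, tolerance = 1e-12)
  expect_equal(q3$vifp, 1, tolerance = 1e-6)
})

test_that("SSIM matches a brute-force windowed recomputation to 1e-4", {
  set.seed(5)
  a <- matrix(runif(256, -1, 1), 16, 16)
  b <- a + matrix(rnorm(256, 0, 0.2), 16, 16)
  g <- exp(-((1:11) - 6)^2 / (2 * 1.5^2)); g <- g / sum(g)
  K <- outer(g, g)
  C1 <- (0.01 * 2)^2; C2 <- (0.03 * 2)^2
  vals <- c()
  for (i in 1:6) for (j in 1:6) {
    wa <- a[i:(i + 10), j:(j + 10)]; wb <- b[i:(i + 10), j:(j + 10)]
    m1 <- sum(K * wa); m2 <- sum(K * wb)
    s1 <- sum(K * wa^2) - m1^2; s2 <- sum(K * wb^2) - m2^2
    s12 <- sum(K * wa * wb) - m1 * m2
    vals <- c(vals, ((2 * m1 * m2 + C1) * (2 * s12 + C2)) /
                ((m1^2 + m2^2 + C1) * (s1 + s2 + C2)))
  }
  expect_equal(ssim(a, b), mean(vals), tolerance = 1e-4)
  # anticorrelated textured images with zero local mean score negative
  # (zero windowed mean keeps the luminance term positive so the sign comes
  # from the inverted structure term)
  tex <- 0.5 * outer((-1)^(1:32), (-1)^(1:32))
  expect_lt(ssim(-tex, tex), 0)
})

test_that("VIFp matches an independent recomputation to 1e-4", {
  set.seed(7)
  ref <- matrix(runif(256, 0, 1), 16, 16)
  dis <- ref * 0.8 + matrix(rnorm(256, 0, 0.05), 16, 16)
  # independent oracle: direct reimplementation with explicit loops
  gk <- function(n, sd) { u <- seq_len(n) - (n + 1) / 2
    g <- exp(-u^2 / (2 * sd^2)); g / sum(g) }
  fv <- function(m, g) { L <- length(g)
    H <- nrow(m) - L + 1; W <- ncol(m) - L + 1
    out <- matrix(0, H, W)
    for (i in seq_len(H)) for (j in seq_len(W))
      out[i, j] <- sum(outer(g, g) * m[i:(i + L - 1), j:(j + L - 1)])
    out }
  odd_fit <- function(n, lim) { k <- min(n, lim); k - (k + 1) %% 2 }
  num <- 0; den <- 0; r <- ref; d <- dis
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    if (scale > 1) {
      Ns <- odd_fit(N, min(dim(r))); if (Ns < 3) break
      g <- gk(Ns, Ns / 5)
      r <- fv(r, g); d <- fv(d, g)
      r <- r[seq(1, nrow(r), 2), seq(1, ncol(r), 2), drop = FALSE]
      d <- d[seq(1, nrow(d), 2), seq(1, ncol(d), 2), drop = FALSE]
    }
    N <- odd_fit(N, min(dim(r))); if (N < 3) break
    g <- gk(N, N / 5)
    mu1 <- fv(r, g); mu2 <- fv(d, g)
    s11 <- pmax(fv(r * r, g) - mu1^2, 0)
    s22 <- pmax(fv(d * d, g) - mu2^2, 0)
    s12 <- fv(r * d, g) - mu1 * mu2
    gg <- s12 / (s11 + 1e-10); sv <- s22 - gg * s12
    gg[s11 < 1e-10] <- 0; sv[s11 < 1e-10] <- s22[s11 < 1e-10]
    s11[s11 < 1e-10] <- 0
    gg[s22 < 1e-10] <- 0; sv[s22 < 1e-10] <- 0
    sv[gg < 0] <- s22[gg < 0]; gg[gg < 0] <- 0
    sv[sv <= 1e-10] <- 1e-10
    num <- num + sum(log10(1 + gg^2 * s11 / (sv + 2)))
    den <- den + sum(log10(1 + s11 / 2))
  }
  expect_equal(vifp(ref, dis), num / den, tolerance = 1e-4)
})

test_that("the spine mask equals a brute-force distance map exactly", {
  set.seed(8)
  seg <- matrix(FALSE, 18, 22)
  seg[cbind(sample(18, 4), sample(22, 4))] <- TRUE
  img <- matrix(runif(18 * 22), 18, 22)
  sm <- spine_mask(img, img, seg, radius = 10)
  pts <- which(seg, arr.ind = TRUE)
  bf <- matrix(FALSE, 18, 22)
  for (i in 1:18) for (j in 1:22)
    bf[i, j] <- sqrt(min((i - pts[, 1])^2 + (j - pts[, 2])^2)) <= 10
  expect_identical(sm$keep, bf)
  # radius 0 retains only the segmented voxels themselves
  sm0 <- spine_mask(img, img, seg, radius = 0)
  expect_identical(sm0$keep, seg)
  # full coverage is the identity
  smf <- spine_mask(img, img, matrix(TRUE, 18, 22), radius = 10)
  expect_identical(smf$a, img)
  expect_error(spine_mask(img, img, seg & FALSE, 10), "empty")
})

test_that("metrics ignore voxels outside the retained mask region", {
  cs <- normalized_phantom(seed = 19)
  a <- cs$ct$data[, , 10]; b <- a + 0.05
  seg <- cs$mask$data[, , 10]
  q1 <- quality(a, b, seg = seg, mask_radius = 5)
  far <- spine_mask(a, b, seg, radius = 5)$keep
  a2 <- a; a2[!far] <- 99  # vandalise far-away voxels
  q2 <- quality(a2, b, seg = seg, mask_radius = 5)
  expect_equal(q1$psnr, q2$psnr)
  expect_equal(q1$ssim, q2$ssim)
})

test_that("dice protocols count voxels correctly and are symmetric", {
  A <- array(0L, c(8, 8, 2)); B <- array(0L, c(8, 8, 2))
  A[2:3, 2:3, 1] <- 1L          # 2x2 body block, 4 voxels
  B[3:4, 2:3, 1] <- 1L          # shifted by one: overlap 2
  expect_equal(dice(A, B)$per_volume, 0.5)
  expect_identical(dice(A, B)$per_volume, dice(B, A)$per_volume)
  expect_equal(dice(A, A)$per_volume, 1)
  B2 <- B; B2[] <- 0L; B2[6:7, 6:7, 2] <- 1L
  expect_equal(dice(A, B2)$per_volume, 0)
  # undefined DSC is NA, not zero: vertebra 2 has a body in both masks but a
  # spinous process in neither, so its posterior-only score is undefined
  A3 <- A; A3[] <- 0L; A3[1, 1, 1] <- 3L
  post <- dice(A3, A3, protocol = "posterior_only")$posterior_only
  expect_true(is.na(post$per_vertebra[["2"]]))
})

test_that("posterior-only protocol removes vertebral bodies and exclusions", {
  cs <- tiny_phantom(seed = 20)
  d <- dice(cs$mask, cs$mask, protocol = c("global", "per_vertebra",
                                           "posterior_only"))
  expect_equal(d$per_volume, 1)
  expect_true(all(d$per_vertebra == 1))
  expect_equal(d$posterior_only$per_volume, 1)
  # exclusions drop the vertebra from both masks
  dx <- dice(cs$mask, cs$mask, protocol = "per_vertebra", exclude = 2L)
  expect_false("2" %in% names(dx$per_vertebra))
  # degrading only the process labels hurts posterior-only DSC more
  noisy <- cs$mask
  proc <- noisy$data %% 2L == 0L & noisy$data > 0L
  flip <- which(proc)[seq(1, sum(proc), by = 2)]
  noisy$data[flip] <- 0L
  dd <- dice(cs$mask, noisy, protocol = c("global", "posterior_only"))
  expect_lt(dd$posterior_only$per_volume, dd$per_volume)
})
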