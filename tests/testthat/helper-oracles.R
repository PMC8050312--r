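# Independent oracles. Each is coded from the defining formula, not by
# calling the implementation under test.

# textbook Pearson correlation, sum formulation
pearson_direct <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Fisher z chain: forward log form, mean, t CI, inverse exp form
fisher_chain <- function(rs, conf = 0.95) {
  z <- 0.5 * log((1 + rs) / (1 - rs))
  k <- length(z)
  mz <- mean(z)
  inv <- function(z) (exp(2 * z) - 1) / (exp(2 * z) + 1)
  if (k == 1L) return(list(mean_r = inv(mz), ci_low = NA, ci_high = NA))
  half <- stats::qt(1 - (1 - conf) / 2, k - 1) * stats::sd(z) / sqrt(k)
  list(mean_r = inv(mz), ci_low = inv(mz - half), ci_high = inv(mz + half))
}

# brute-force zero-horizontal-moment point of a single wrench sample on the
# plane delta above the plate surface: coarse grid then simplex refinement
# of the residual horizontal moment magnitude
cop_brute_force <- function(f, m, delta = 0) {
  resid <- function(p) {
    px <- p[1]; py <- p[2]; pz <- delta
    mpx <- m[1] - (py * f[3] - pz * f[2])
    mpy <- m[2] - (pz * f[1] - px * f[3])
    sqrt(mpx^2 + mpy^2)
  }
  grid <- seq(-0.6, 0.6, by = 0.05)
  vals <- outer(grid, grid, Vectorize(function(a, b) resid(c(a, b))))
  idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  start <- c(grid[idx[1]], grid[idx[2]])
  opt <- stats::optim(start, resid, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
  # polish with a second restart to push below 1e-9 m reliably
  opt <- stats::optim(opt$par, resid, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
  opt$par
}

# random physically plausible wrench samples (vertical load 200..900 N,
# moderate shear and CoP inside a 0.6 m plate), wrench = p x F + free Mz
random_wrench_samples <- function(n, seed) {
  set.seed(seed)
  fz <- stats::runif(n, 200, 900)
  fx <- stats::rnorm(n, 0, 30)
  fy <- stats::rnorm(n, 0, 30)
  px <- stats::runif(n, -0.25, 0.25)
  py <- stats::runif(n, -0.25, 0.25)
  mz_free <- stats::rnorm(n, 0, 2)
  mx <- py * fz
  my <- -px * fz
  mz <- px * fy - py * fx + mz_free
  list(force = cbind(fx, fy, fz), moment = cbind(mx, my, mz),
       true_cop = cbind(px, py))
}
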