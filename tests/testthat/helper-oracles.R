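# Independent oracles used to cross-check the package's statistics.
# They deliberately share no code with the implementation.

# two-sided signed-rank p by full enumeration of all 2^n sign assignments
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# two-sided rank-sum p by enumeration of all group-label assignments
enum_rank_sum_p <- function(a, b) {
  m <- length(a)
  N <- m + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)])
  cs <- utils::combn(N, m)
  us <- colSums(matrix(r[cs], nrow = m))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# brute-force normal-equations least squares
normal_equations_fit <- function(x, y) {
  X <- cbind(1, x)
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

# two-way ANOVA mean squares via stats::aov (independent of the
# closed-form sums of squares inside the package)
aov_mean_squares <- function(M) {
  d <- data.frame(y = as.vector(M),
                  subj = factor(as.vector(row(M))),
                  rater = factor(as.vector(col(M))))
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  ms <- tab[["Mean Sq"]]
  list(MSR = ms[1], MSC = ms[2], MSE = ms[3])
}

# absolute-agreement ICC from ANOVA mean squares (McGraw & Wong forms)
aov_icc <- function(M) {
  n <- nrow(M); k <- ncol(M)
  ms <- aov_mean_squares(M)
  single <- (ms$MSR - ms$MSE) /
    (ms$MSR + (k - 1) * ms$MSE + (k / n) * (ms$MSC - ms$MSE))
  avg <- (ms$MSR - ms$MSE) / (ms$MSR + (ms$MSC - ms$MSE) / n)
  list(single = single, avg = avg, ms = ms)
}

# deterministic noiseless patient used across tests
ref_patient <- function(...) {
  virtual_patient(age_y = 63, height_cm = 176, weight_kg = 86,
                  rap0 = 5, ci0 = 2.65, svr = 12, starling_slope = 1.5,
                  transmission = 0.45, ...)
}

noiseless_config <- function(...) {
  sim_config(noise_sd_rap = 0, noise_sd_map = 0, noise_co_cv = 0, ...)
}
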