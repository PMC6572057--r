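# independent Q-function evaluator: expected complete-data log-likelihood
# under responsibilities r, written from the model factorization directly
q_oracle <- function(obs, r, theta) {
  K <- length(theta$false_weights)
  total <- 0
  for (j in seq_len(nrow(obs))) {
    if (obs$z[j] == 1L) {
      s <- obs$score[j]
      lm <- log(theta$rho) + log(theta$gamma1) + log(theta$tau) +
        stats::dnorm(s, theta$mu_T, sqrt(theta$sigma2_T), log = TRUE)
      total <- total + r[j, "y1w1"] * lm
      for (k in seq_len(K)) {
        lfk <- log(theta$false_weights[k]) +
          stats::dnorm(s, theta$false_means[k], sqrt(theta$false_vars[k]),
                       log = TRUE)
        total <- total + r[j, paste0("y1w0.", k)] *
          (log(theta$rho) + log(theta$gamma1) + log(1 - theta$tau) + lfk)
        total <- total + r[j, paste0("y0w0.", k)] *
          (log(1 - theta$rho) + log(theta$gamma0) + lfk)
      }
    } else {
      total <- total + r[j, "y1z0"] * (log(theta$rho) + log(1 - theta$gamma1))
      total <- total + r[j, "y0z0"] * (log(1 - theta$rho) + log(1 - theta$gamma0))
    }
  }
  total
}

random_theta <- function() {
  ident_params(rho = runif(1, 0.3, 0.8), tau = runif(1, 0.3, 0.8),
               gamma1 = runif(1, 0.6, 0.95), gamma0 = runif(1, 0.05, 0.3),
               mu_T = runif(1, 2, 8), sigma2_T = runif(1, 1, 6),
               false_means = runif(1, 30, 50), false_vars = runif(1, 50, 150))
}

test_that("complete_loglik matches direct substitution and term-by-term oracle", {
  theta <- ident_params(0.5, 0.5, 0.5, 0.1, mu_T = 5, sigma2_T = 4,
                        false_means = 40, false_vars = 100)
  # single metabolite, y = z = w = 1, s = mu_T
  st <- data.frame(y = 1, z = 1, w = 1, s = 5)
  expect_equal(complete_loglik(st, theta),
               log(0.5) + log(0.5) + log(0.5) + dnorm(5, 5, 2, log = TRUE))
  # impossible state: matched-but-absent cannot be correct
  expect_identical(complete_loglik(data.frame(y = 0, z = 1, w = 1, s = 10), theta),
                   -Inf)
  # random small instance vs independent summation
  set.seed(8)
  for (rep in 1:10) {
    th <- random_theta()
    y <- rbinom(6, 1, 0.5)
    z <- rbinom(6, 1, 0.7)
    w <- ifelse(z == 1, ifelse(y == 1, rbinom(6, 1, 0.5), 0L), NA)
    s <- ifelse(z == 1, runif(6, 0, 60), NA)
    st <- data.frame(y = y, z = z, w = w, s = s)
    manual <- 0
    for (i in 1:6) {
      term <- log(ifelse(y[i] == 1, th$rho, 1 - th$rho)) +
        log(ifelse(z[i] == 1,
                   ifelse(y[i] == 1, th$gamma1, th$gamma0),
                   ifelse(y[i] == 1, 1 - th$gamma1, 1 - th$gamma0)))
      if (z[i] == 1) {
        if (y[i] == 1) term <- term + log(ifelse(w[i] == 1, th$tau, 1 - th$tau))
        dens <- if (w[i] == 1) dnorm(s[i], th$mu_T, sqrt(th$sigma2_T))
                else th$false_weights * dnorm(s[i], th$false_means, sqrt(th$false_vars))
        term <- term + log(sum(dens))
      }
      manual <- manual + term
    }
    expect_equal(complete_loglik(st, th), manual, tolerance = 1e-12)
  }
})

test_that("e_step responsibilities normalize and obey the two-cell Bayes rule", {
  set.seed(21)
  for (rep in 1:10) {
    th <- random_theta()
    obs <- data.frame(z = c(1, 1, 0, 1, 0), score = c(4, 38, NA, 12, NA))
    r <- e_step(obs, th)
    expect_equal(unname(rowSums(r)), rep(1, 5), tolerance = 1e-12)
    # unmatched entries: Bayes over y only, from (rho, gamma1, gamma0)
    p1 <- th$rho * (1 - th$gamma1)
    p0 <- (1 - th$rho) * (1 - th$gamma0)
    expect_equal(unname(r[3, "y1z0"]), p1 / (p1 + p0), tolerance = 1e-12)
    expect_equal(unname(r[5, "y0z0"]), p0 / (p1 + p0), tolerance = 1e-12)
  }
})

test_that("e_step is certain of a correct match in the separated tau->1 limit", {
  th <- ident_params(0.5, 1 - 1e-9, 0.9, 0.1, mu_T = 5, sigma2_T = 1,
                     false_means = 60, false_vars = 4)
  r <- e_step(data.frame(z = 1, score = 5), th)
  expect_equal(unname(r[1, "y1w1"]), 1, tolerance = 1e-6)
})

test_that("m_step boundary and degenerate-weight updates are as expected", {
  obs <- data.frame(z = c(1, 1, 1, 0), score = c(3, 6, 40, NA))
  r <- e_step(obs, random_theta())
  # all posterior mass on y = 1 configurations -> rho clamps at 1 - eps
  r1 <- r
  r1[, c("y0w0.1", "y0z0")] <- 0
  r1 <- r1 / rowSums(r1)
  up <- m_step(obs, r1)
  expect_equal(up$rho, 1 - 1e-6)
  # equal responsibilities over (w=1, w=0): mu_T = plain mean of matched scores
  r2 <- r
  r2[obs$z == 1, ] <- 0
  r2[obs$z == 1, "y1w1"] <- 0.5
  r2[obs$z == 1, "y1w0.1"] <- 0.5
  up2 <- m_step(obs, r2)
  expect_equal(up2$mu_T, mean(obs$score[obs$z == 1]))
})

test_that("m_step attains the maximum of the EM target function", {
  set.seed(33)
  sim <- simulate_identification(n_library = 200, seed = 14)
  th0 <- random_theta()
  r <- e_step(sim$observed, th0)
  up <- m_step(sim$observed, r)
  q_at <- function(par) {
    th <- ident_params(plogis(par[1]), plogis(par[2]), plogis(par[3]),
                       plogis(par[4]), par[5], exp(par[6]),
                       false_means = max(par[7], par[5] + 1e-6),
                       false_vars = exp(par[8]))
    q_oracle(sim$observed, r, th)
  }
  start <- c(qlogis(up$rho), qlogis(up$tau), qlogis(up$gamma1),
             qlogis(up$gamma0), up$mu_T, log(up$sigma2_T),
             up$false_means, log(up$false_vars))
  opt <- optim(start, function(p) -q_at(p), method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  # a numeric optimizer started at the closed-form update cannot improve Q
  expect_lte(-opt$value - q_at(start), 1e-4)
  expect_equal(plogis(opt$par[1]), up$rho, tolerance = 1e-4)
  expect_equal(opt$par[5], up$mu_T, tolerance = 1e-4)
})

test_that("fit_em is deterministic, ascends, and converges near the truth", {
  sim <- simulate_identification(n_library = 600, seed = 77)
  f1 <- fit_frozen(sim$observed)
  f2 <- fit_frozen(sim$observed)
  expect_identical(f1$trace, f2$trace)
  expect_true(f1$converged)
  expect_true(all(diff(f1$trace$loglik) >= -1e-8 * (abs(f1$trace$loglik[-1]) + 1)))
  # init at the generating values stays in the neighborhood, few iterations
  init <- ident_params(0.7, 0.8, 0.9, 0.1, 5, 4, false_means = 40,
                       false_vars = 100)
  f3 <- fit_em(sim$observed, init = init,
               fixed = list(gamma1 = 0.9, gamma0 = 0.1))
  expect_true(f3$converged)
  expect_lt(f3$n_iter, 100)
  expect_lt(abs(f3$theta$mu_T - 5), 0.5)
  expect_true(all(diff(f3$trace$loglik) >= -1e-8 * (abs(f3$trace$loglik[-1]) + 1)))
})

test_that("fit_em refuses unidentifiably small matched sets", {
  obs <- data.frame(z = c(rep(1, 5), rep(0, 20)),
                    score = c(rnorm(5, 5), rep(NA, 20)))
  expect_error(fit_em(obs), "unidentifiable")
})

test_that("confidence_measure follows the closed-form unmatched posterior", {
  th <- ident_params(0.6, 0.7, 0.85, 0.2, 5, 4, false_means = 40,
                     false_vars = 100)
  obs <- data.frame(name = c("a", "b", "c"), z = c(0, 1, 0),
                    score = c(NA, 6, NA))
  cm <- confidence_measure(obs, th)
  expected_z0 <- 0.6 * (1 - 0.85) / (0.6 * (1 - 0.85) + 0.4 * (1 - 0.2))
  expect_equal(cm$posterior[cm$name == "a"], expected_z0, tolerance = 1e-12)
  expect_equal(cm$posterior[cm$name == "c"], expected_z0, tolerance = 1e-12)
  expect_true(all(cm$posterior >= 0 & cm$posterior <= 1))
  # sorted by posterior descending, ties broken by name
  expect_true(all(diff(cm$posterior) <= 1e-15))
  ties <- cm$name[abs(cm$posterior - expected_z0) < 1e-12]
  expect_identical(ties, sort(ties))
})

test_that("matched posterior is non-increasing in the score", {
  th <- ident_params(0.6, 0.7, 0.85, 0.2, 5, 4, false_means = 40,
                     false_vars = 100)
  # from the correct-match mean upward the correct/false likelihood ratio is
  # decreasing (below it the unequal component variances bend it back)
  grid <- seq(5, 60, by = 1)
  obs <- data.frame(z = rep(1, length(grid)), score = grid)
  post <- confidence_measure(obs, th)
  post <- post[order(post$score), ]
  expect_true(all(diff(post$posterior) <= 1e-10))
})
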