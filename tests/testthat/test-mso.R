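# Mixed-grained supervision: losses, prototypes, aggregation, joint objective.

test_that("strong loss has the closed forms of cross-entropy", {
  onehot <- diag(4)[c(1, 3, 2, 4), ]
  expect_equal(strong_loss(onehot, onehot, c(0, 2, 1, 3), c(0, 2, 1, 3)), 0,
               tolerance = 1e-9)
  unif <- matrix(0.25, 5, 4)
  y <- c(0, 1, 2, 3, 0)
  expect_equal(strong_loss(unif, unif, y, y, lambda_pl = 1), log(4) * 2,
               tolerance = 1e-12)
  expect_equal(strong_loss(unif, unif, y, y, lambda_pl = 0.5), log(4) * 1.5,
               tolerance = 1e-12)
  # hand-summed two-segment case
  p1 <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25))
  hand <- mean(c(-log(0.7), -log(0.25))) + mean(c(-log(0.1), -log(0.25)))
  expect_equal(strong_loss(p1, p1, c(0, 1), c(1, 2), 1), hand, tolerance = 1e-12)
  expect_error(strong_loss(p1, p1, NULL, c(1, 2)), "labels")
})

test_that("K-means initialisation recovers well-separated grade centroids", {
  set.seed(40)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(60 * 2, sd = 0.3), 60, 2), 2, centers[k, ], "+")))
  y <- rep(0:3, each = 60)
  bank <- init_prototypes(X, y, seed = 7)
  expect_true(bank$initialized)
  for (k in 1:4)
    expect_lt(sqrt(sum((bank$m[k, ] - centers[k, ])^2)), 0.1)
  # stability across seeds on separated blobs
  bank2 <- init_prototypes(X, y, seed = 99)
  expect_equal(bank$m, bank2$m, tolerance = 1e-6)
  # one point per grade: prototypes equal the points
  X4 <- centers
  b4 <- init_prototypes(X4, 0:3, seed = 1)
  expect_equal(b4$m, centers, tolerance = 1e-9)
})

test_that("prototype EMA follows its closed form and contracts to the batch mean", {
  bank <- structure(list(m = matrix(0, 4, 3), mu = 1, initialized = TRUE),
                    class = "prototype_bank")
  v <- matrix(rnorm(6), 2, 3)
  expect_equal(update_prototypes(bank, v, c(1, 1))$m, bank$m)  # mu = 1 frozen
  bank$mu <- 0.99
  up <- update_prototypes(bank, matrix(1, 2, 3), c(2, 2))
  expect_equal(up$m[3, ], rep(0.01, 3), tolerance = 1e-12)     # one-step form
  expect_equal(up$m[-3, ], bank$m[-3, ])                       # absent grades fixed
  # two sequential updates match the hand-unrolled recursion
  v1 <- matrix(2, 1, 3); v2 <- matrix(-1, 1, 3)
  b2 <- update_prototypes(update_prototypes(bank, v1, 0), v2, 0)
  expect_equal(b2$m[1, ], rep(0.99 * (0.99 * 0 + 0.01 * 2) + 0.01 * -1, 3))
  # contraction: |m_new - vbar| = mu * |m_old - vbar|
  m0 <- rnorm(3); vb <- rnorm(3)
  bank$m[2, ] <- m0
  bn <- update_prototypes(bank, matrix(vb, 1, 3, byrow = TRUE), 1)
  expect_equal(sqrt(sum((bn$m[2, ] - vb)^2)), 0.99 * sqrt(sum((m0 - vb)^2)))
  bank$initialized <- FALSE
  expect_error(update_prototypes(bank, v, c(0, 1)), "not initialized")
})

test_that("cosine similarities have hand values and an epsilon guard", {
  bank <- structure(list(m = rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 0)),
                         mu = 0.99, initialized = TRUE),
                    class = "prototype_bank")
  v <- rbind(c(1, 0), c(0, 2), c(0, 0))
  S <- similarity_matrix(v, bank)
  expect_equal(S[1, 1], 1)
  expect_equal(S[1, 3], 0)
  expect_equal(S[1, 2], 1 / sqrt(2))
  expect_equal(S[2, 3], 1)
  expect_equal(S[3, ], rep(0, 4))                 # zero-norm vector -> 0
  expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))
})

test_that("severity-aware aggregation matches hand computation", {
  S1 <- matrix(c(0.9, 0.1, -0.2, 0.05), 1, 4)
  expect_equal(aggregate_branch(S1), as.vector(exp(S1) / sum(exp(S1))),
               tolerance = 1e-12)                 # L = 1: softmax of the row
  S2 <- rbind(S1[1, ], S1[1, ], S1[1, ])
  expect_equal(aggregate_branch(S2), aggregate_branch(S1), tolerance = 1e-12)
  # L = 2 hand case
  Sa <- rbind(c(0.8, 0.2, 0.0, -0.1), c(0.1, 0.9, 0.3, 0.2))
  w <- exp(c(0.8, 0.9)); w <- w / sum(w)
  soft <- t(apply(Sa, 1, function(r) exp(r) / sum(exp(r))))
  expect_lt(max(abs(aggregate_branch(Sa) - as.vector(t(soft) %*% w))), 1e-6)
  set.seed(41)
  Sr <- matrix(rnorm(40), 10, 4)
  ab <- aggregate_branch(Sr)
  expect_equal(sum(ab), 1, tolerance = 1e-9)
  expect_true(all(ab > 0))
})

test_that("weak loss has cross-entropy closed forms", {
  expect_equal(weak_loss(c(1 - 3e-12, 1e-12, 1e-12, 1e-12), 0), 0, tolerance = 1e-9)
  expect_equal(weak_loss(rep(0.25, 4), 2), log(4), tolerance = 1e-12)
  expect_equal(weak_loss(c(0.7, 0.1, 0.1, 0.1), 0), -log(0.7), tolerance = 1e-12)
  expect_error(weak_loss(rep(0.25, 4), NA), "branch label")
})

test_that("mutual-exclusion loss scores logical contradictions as written", {
  onehot <- function(k) { v <- rep(0, 4); v[k + 1] <- 1; matrix(v, 1, 4) }
  # consistent normal segment
  expect_equal(mutex_loss(onehot(0), onehot(0)), 0)
  # stenosis without plaque: maximal penalty
  expect_equal(mutex_loss(onehot(1), onehot(0)), 1)
  # plaque without stenosis: penalised by the as-written second term...
  expect_equal(mutex_loss(onehot(0), onehot(1)), 1)
  # ...which the unidirectional switch drops
  expect_equal(mutex_loss(onehot(0), onehot(1), unidirectional = TRUE), 0)
  expect_equal(mutex_loss(onehot(2), onehot(0), unidirectional = TRUE), 1)
  # bounded in [0, 1] on random row-stochastic inputs
  set.seed(42)
  for (i in 1:10) {
    P1 <- t(apply(matrix(rexp(20), 5, 4), 1, function(r) r / sum(r)))
    P2 <- t(apply(matrix(rexp(20), 5, 4), 1, function(r) r / sum(r)))
    m <- mutex_loss(P1, P2)
    expect_gte(m, 0); expect_lte(m, 1)
  }
  expect_error(mutex_loss(matrix(0.3, 2, 4), matrix(0.25, 2, 4)), "stochastic")
})

test_that("mutex loss vanishes iff no contradictory mass co-occurs", {
  # all mass on (stenosis > 0, plaque > 0): zero under the full formula
  p_st <- rbind(c(0, 0.5, 0.5, 0), c(0, 0, 0, 1))
  p_pl <- rbind(c(0, 1, 0, 0), c(0, 0, 0.5, 0.5))
  expect_equal(mutex_loss(p_st, p_pl), 0)
  # any mass on plaque-absent with stenotic prediction raises it
  p_pl2 <- rbind(c(0.2, 0.8, 0, 0), c(0, 0, 0.5, 0.5))
  expect_gt(mutex_loss(p_st, p_pl2), 0)
})

test_that("smooth maximum obeys its LogSumExp identities and bounds", {
  p1 <- matrix(c(0.6, 0.2, 0.1, 0.1), 1, 4)
  expect_equal(smoothmax(p1, 10), as.vector(p1))   # L = 1 exact
  pr <- matrix(rep(c(0.4, 0.3, 0.2, 0.1), each = 6), 6, 4)
  expect_equal(smoothmax(pr, 10), c(0.4, 0.3, 0.2, 0.1) + log(6) / 10,
               tolerance = 1e-12)                  # equal rows closed form
  set.seed(43)
  for (i in 1:100) {
    L <- sample(2:12, 1); a <- stats::runif(1, 2, 40)
    P <- t(apply(matrix(rexp(L * 4), L, 4), 1, function(r) r / sum(r)))
    sm <- smoothmax(P, a)
    mx <- apply(P, 2, max)
    expect_true(all(sm >= mx - 1e-12))
    expect_true(all(sm <= mx + log(L) / a + 1e-12))
  }
  Pd <- t(apply(matrix(rexp(20), 5, 4), 1, function(r) r / sum(r)))
  expect_lt(max(abs(smoothmax(Pd, 500) - apply(Pd, 2, max))), 1e-3)
})

test_that("consistency loss is a permutation-invariant squared distance", {
  set.seed(44)
  P <- t(apply(matrix(rexp(20), 5, 4), 1, function(r) r / sum(r)))
  target <- smoothmax(P, 10)
  expect_equal(consistency_loss(P, target, 10), 0, tolerance = 1e-14)
  # hand L = 2 case
  P2 <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.6, 0.2, 0.1))
  pg <- c(0.4, 0.3, 0.2, 0.1)
  hand <- mean((log(colSums(exp(10 * P2))) / 10 - pg)^2)
  expect_equal(consistency_loss(P2, pg, 10), hand, tolerance = 1e-12)
  expect_equal(consistency_loss(P[5:1, ], pg, 10), consistency_loss(P, pg, 10))
  expect_error(consistency_loss(P2, c(0.5, 0.5), 10), "mismatch")
})

test_that("the joint objective weights losses by uncertainty as specified", {
  bundle <- list(l_strong = 0.8, l_weak = 1.7, l_mutex = 0.2, l_cons = 0.1,
                 sigma1 = 1, sigma2 = 1)
  tl <- total_loss(bundle, has_fine = TRUE)
  expect_equal(tl$l_task, 0.8)
  expect_equal(tl$l_total, 0.5 * 0.8 + 0.5 * 0.3)  # log term vanishes
  tw <- total_loss(bundle, has_fine = FALSE)
  expect_equal(tw$l_task, 1.7)
  expect_equal(tw$l_total, 0.5 * 1.7 + 0.5 * 0.3)
  # stationary point of the sigma profile: sigma^2 = Ltask
  f <- function(s) 0.8 / (2 * s^2) + 0.3 / (2 * 1^2) + log(s * 1)
  s_star <- stats::optimize(f, c(0.05, 5))$minimum
  expect_equal(s_star^2, 0.8, tolerance = 1e-4)
  g <- function(s) 0.8 / 2 + 0.3 / (2 * s^2) + log(s)
  expect_equal(stats::optimize(g, c(0.05, 5))$minimum^2, 0.3, tolerance = 1e-4)
  bundle$sigma1 <- -1
  expect_error(total_loss(bundle, TRUE), "positive")
})
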