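## Mixed-grained supervision optimisation: strong segment-level losses,
## anatomy-aware dynamic prototypes with EMA updates, prototype-based weak
## branch-level supervision, logical regularisers, and the uncertainty-
## weighted joint objective.
##
## Class conventions (0-based everywhere in the user API):
## stenosis 0=normal 1=mild 2=moderate 3=severe;
## plaque 0=absent 1=calcified 2=non-calcified 3=mixed.

#' Mean cross-entropy of row-stochastic predictions against integer labels
#' @param p n x K row-stochastic matrix (node or numeric).
#' @param y length-n labels in 0..K-1.
#' @param eps probability floor inside the log.
#' @keywords internal
ad_ce_probs <- function(p, y, eps = 1e-12) {
  pv <- ad_val(p)
  n <- nrow(pv)
  idx <- cbind(seq_len(n), as.integer(y) + 1L)
  v <- -mean(log(pmax(pv[idx], eps)))
  ad_apply(list(p), v, function(g) {
    gp <- matrix(0, n, ncol(pv))
    gp[idx] <- -g / (n * pmax(pv[idx], eps))
    list(gp)
  })
}

#' Strong (fine-grained) supervision loss
#'
#' Mean over segments of CE(stenosis) + lambda_pl * CE(plaque).
#'
#' @param pst,ppl L x 4 row-stochastic predictions.
#' @param yst,ypl length-L labels in 0..3.
#' @param lambda_pl plaque-loss weight.
#' @return nonnegative scalar (node if inputs are nodes).
#' @export
strong_loss <- function(pst, ppl, yst, ypl, lambda_pl = 1.0) {
  if (is.null(yst) || is.null(ypl)) stop("fine-grained labels are required")
  ad_add(ad_ce_probs(pst, yst), ad_mul(ad_ce_probs(ppl, ypl), lambda_pl))
}

#' Initialise the stenosis-grade prototype bank by K-means
#'
#' K-means (K = 4) clusters the pooled geometric embeddings of fine-labelled
#' segments; clusters are matched to grades greedily by their label-count
#' table. A grade that wins no cluster falls back to the mean embedding of
#' its labelled segments (with a message).
#'
#' @param vgeo_pool N x C matrix of geometric feature vectors.
#' @param labels length-N stenosis grades in 0..3.
#' @param mu EMA momentum kept in the bank (default 0.99).
#' @param seed RNG seed for the K-means initialisation.
#' @return object of class `prototype_bank`: list(m 4 x C, mu, initialized).
#' @export
init_prototypes <- function(vgeo_pool, labels, mu = 0.99, seed = 1L) {
  stopifnot(nrow(vgeo_pool) == length(labels))
  labels <- as.integer(labels)
  m <- matrix(0, 4L, ncol(vgeo_pool))
  km <- tryCatch(
    with_seed(seed, stats::kmeans(vgeo_pool, centers = 4L, nstart = 10L)),
    error = function(e) NULL)
  tab <- matrix(0L, 4L, 4L)   # cluster x grade counts
  if (!is.null(km)) {
    for (i in seq_along(labels))
      tab[km$cluster[i], labels[i] + 1L] <- tab[km$cluster[i], labels[i] + 1L] + 1L
    assigned_grade <- rep(NA_integer_, 4L)
    remaining_cl <- seq_len(4L); remaining_gr <- seq_len(4L)
    for (step in seq_len(4L)) {
      sub <- tab[remaining_cl, remaining_gr, drop = FALSE]
      best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      cl <- remaining_cl[best[1]]; gr <- remaining_gr[best[2]]
      assigned_grade[cl] <- gr
      remaining_cl <- setdiff(remaining_cl, cl)
      remaining_gr <- setdiff(remaining_gr, gr)
    }
    for (cl in seq_len(4L)) m[assigned_grade[cl], ] <- km$centers[cl, ]
  } else {
    message("K-means unavailable for this pool; prototypes fall back to grade means")
  }
  for (g in 0:3) {
    has <- labels == g
    if (!any(tab[, g + 1L] > 0)) {
      if (any(has)) {
        if (!is.null(km))
          message("prototype grade ", g, " had no cluster support; using grade mean")
        m[g + 1L, ] <- colMeans(vgeo_pool[has, , drop = FALSE])
      } else {
        message("prototype grade ", g, " absent from warm-up pool; left at zero")
      }
    }
  }
  structure(list(m = m, mu = mu, initialized = TRUE), class = "prototype_bank")
}

#' EMA update of the prototype bank from one strong-label batch
#'
#' For every grade k present in the batch: m_k <- mu * m_k + (1 - mu) *
#' mean(vgeo of that grade); absent grades are unchanged.
#'
#' @param bank a `prototype_bank`; @param vgeo L x C numeric features;
#' @param yst length-L stenosis labels in 0..3.
#' @export
update_prototypes <- function(bank, vgeo, yst) {
  if (!isTRUE(bank$initialized)) stop("prototype bank is not initialized")
  vgeo <- ad_val(vgeo)
  for (g in unique(as.integer(yst))) {
    vbar <- colMeans(vgeo[yst == g, , drop = FALSE])
    bank$m[g + 1L, ] <- bank$mu * bank$m[g + 1L, ] + (1 - bank$mu) * vbar
  }
  bank
}

#' Cosine similarity between segment features and the prototypes
#'
#' @param vgeo L x C features (node or numeric); @param bank `prototype_bank`.
#' @param eps norm guard; zero-norm vectors yield similarity 0.
#' @return L x 4 matrix with entries in [-1, 1].
#' @export
similarity_matrix <- function(vgeo, bank, eps = 1e-8) {
  mn <- bank$m / pmax(sqrt(rowSums(bank$m^2)), eps)
  ad_matmul(ad_row_normalize(vgeo, eps), t(mn))
}

#' Severity-aware aggregation of segment similarities to a branch prediction
#'
#' Each segment's softmaxed similarity row is mixed with weights
#' proportional to exp(max_k S_lk), so the most prototype-like (typically
#' most severe) segments dominate the branch-level distribution.
#'
#' @param S L x 4 similarity matrix.
#' @return length-4 probability vector.
#' @export
aggregate_branch <- function(S) {
  sv <- ad_val(S)
  if (nrow(sv) < 1L) stop("need at least one segment")
  wts <- ad_softmax_vec(ad_rowmax(S))
  probs <- ad_softmax_rows(S)
  out <- ad_reshape(ad_matmul(ad_aperm(probs, c(2, 1)),
                              ad_reshape(wts, c(nrow(sv), 1L))), 4L)
  if (is_node(out)) out else as.numeric(out)
}

#' Weak (branch-level) supervision loss
#' @param yhat_br length-4 probability vector from [aggregate_branch()].
#' @param ybr branch stenosis label in 0..3.
#' @export
weak_loss <- function(yhat_br, ybr) {
  if (is.null(ybr) || is.na(ybr)) stop("branch label is required")
  ad_neg(ad_log(ad_pick(yhat_br, as.integer(ybr) + 1L)))
}

#' Mutual-exclusion loss between stenosis and plaque predictions
#'
#' Penalises probability mass on the contradiction "stenosis without
#' plaque": mean over segments of
#' sum_{k=1..3} Pst[l,k] * Ppl[l,0]  +  Pst[l,0] * (1 - Ppl[l,0]),
#' the second term evaluated once per segment. With
#' `unidirectional = TRUE` the second term (which penalises "plaque without
#' stenosis") is dropped.
#'
#' @param pst,ppl L x 4 row-stochastic matrices.
#' @param unidirectional drop the plaque-without-stenosis term.
#' @return scalar in [0, 1].
#' @export
mutex_loss <- function(pst, ppl, unidirectional = FALSE) {
  pv <- ad_val(pst); qv <- ad_val(ppl)
  if (any(abs(rowSums(pv) - 1) > 1e-5) || any(abs(rowSums(qv) - 1) > 1e-5))
    stop("inputs must be row-stochastic")
  sten <- ad_matmul(pst, matrix(c(0, 1, 1, 1), 4L, 1L))   # P(stenosis > 0)
  st0 <- ad_matmul(pst, matrix(c(1, 0, 0, 0), 4L, 1L))
  pl0 <- ad_matmul(ppl, matrix(c(1, 0, 0, 0), 4L, 1L))
  term <- ad_mul(sten, pl0)
  if (!unidirectional) term <- ad_add(term, ad_mul(st0, ad_sub(1, pl0)))
  ad_mean(term)
}

#' Smooth maximum of segment probabilities per class (LogSumExp)
#'
#' out_k = (1/alpha) log sum_l exp(alpha * Pst[l,k]); satisfies
#' max_l Pst[l,k] <= out_k <= max_l Pst[l,k] + log(L)/alpha.
#'
#' @param pst L x 4 matrix; @param alpha temperature (> 0).
#' @return length-4 vector.
#' @export
smoothmax <- function(pst, alpha = 10) {
  stopifnot(alpha > 0, nrow(ad_val(pst)) >= 1L)
  ad_smoothmax_cols(pst, alpha)
}

#' Hierarchical consistency loss
#'
#' Mean squared difference between the smooth-max aggregate of the segment
#' stenosis distributions and the auxiliary branch-level distribution.
#'
#' @param pst L x 4 matrix; @param pglobal length-4 vector;
#' @param alpha smooth-max temperature.
#' @export
consistency_loss <- function(pst, pglobal, alpha = 10) {
  if (length(ad_val(pglobal)) != ncol(ad_val(pst))) stop("class count mismatch")
  d <- ad_sub(smoothmax(pst, alpha), pglobal)
  ad_mean(ad_mul(d, d))
}

#' Uncertainty-weighted joint objective
#'
#' Ltotal = Ltask/(2 sigma1^2) + (Lmutex + Lcons)/(2 sigma2^2)
#'          + log(sigma1 * sigma2),
#' where Ltask is the strong loss when fine labels are available and the
#' weak loss otherwise. `sigma1`, `sigma2` may be nodes (they are trained
#' jointly via their log-variance in the training loop).
#'
#' @param bundle list with l_strong and/or l_weak, l_mutex, l_cons,
#'   sigma1, sigma2 (scalars or nodes).
#' @param has_fine logical: select the strong or the weak task loss.
#' @return list(l_task, l_total).
#' @export
total_loss <- function(bundle, has_fine) {
  s1 <- bundle$sigma1; s2 <- bundle$sigma2
  if (any(ad_val(s1) <= 0) || any(ad_val(s2) <= 0)) stop("sigma must be positive")
  l_task <- if (has_fine) bundle$l_strong else bundle$l_weak
  reg <- ad_add(bundle$l_mutex, bundle$l_cons)
  tot <- ad_add(
    ad_add(ad_div(l_task, ad_mul(ad_mul(s1, s1), 2)),
           ad_div(reg, ad_mul(ad_mul(s2, s2), 2))),
    ad_log(ad_mul(s1, s2)))
  list(l_task = l_task, l_total = tot)
}
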