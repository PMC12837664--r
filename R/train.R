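## Orchestration: run configuration, patient-level stratified splitting, the
## mixed-grained training loop (homogeneous strong/weak batches, prototype
## warm-up and EMA schedule, uncertainty-weighted joint objective), and
## evaluation.

#' Full run configuration
#'
#' Optimiser defaults follow the reference training protocol (Adam,
#' learning rate 1e-4, batch size 3, 800 epochs); tests and the worked
#' examples override them with desk-scale values.
#'
#' @param phantom a [phantom_config()]; @param model a [model_config()].
#' @param lambda_pl plaque-loss weight; @param alpha smooth-max temperature;
#' @param mu prototype EMA momentum; @param mutex_unidirectional drop the
#'   plaque-without-stenosis term of the mutual-exclusion loss.
#' @param lr,batch_size,epochs optimiser settings.
#' @param warmup_frac fraction of epochs trained on strong labels only
#'   before the prototype bank is initialised.
#' @param use_weak enable the weak branch-level supervision path.
#' @param use_reg enable the mutual-exclusion and consistency regularisers.
#' @param val_every validation cadence (epochs); @param seed training seed.
#' @param test_frac,n_folds,split_seed patient-level splitting settings.
#' @export
run_config <- function(phantom = phantom_config(), model = model_config(),
                       lambda_pl = 1.0, alpha = 10, mu = 0.99,
                       mutex_unidirectional = FALSE,
                       lr = 1e-4, batch_size = 3L, epochs = 800L,
                       warmup_frac = 0.1, use_weak = TRUE, use_reg = TRUE,
                       val_every = 5L, seed = 1L,
                       test_frac = 0.2, n_folds = 5L, split_seed = 42L) {
  structure(list(
    phantom = phantom, model = model,
    loss = list(lambda_pl = lambda_pl, alpha = alpha, mu = mu,
                mutex_unidirectional = mutex_unidirectional),
    optim = list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs)),
    train = list(warmup_frac = warmup_frac, use_weak = use_weak,
                 use_reg = use_reg, val_every = as.integer(val_every),
                 seed = as.integer(seed)),
    split = list(test_frac = test_frac, n_folds = as.integer(n_folds),
                 seed = as.integer(split_seed))
  ), class = "run_config")
}

#' Save a run configuration to YAML
#' @param cfg a [run_config()]; @param path file path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(rapply(cfg, identity, how = "replace")), path)
  invisible(path)
}

#' Load a run configuration from YAML
#' @param path file path.
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  ph <- x$phantom
  cfg <- run_config(
    phantom = do.call(phantom_config, ph[setdiff(names(ph), character(0))]),
    model = do.call(model_config, x$model),
    lambda_pl = x$loss$lambda_pl, alpha = x$loss$alpha, mu = x$loss$mu,
    mutex_unidirectional = x$loss$mutex_unidirectional,
    lr = x$optim$lr, batch_size = x$optim$batch_size, epochs = x$optim$epochs,
    warmup_frac = x$train$warmup_frac, use_weak = x$train$use_weak,
    use_reg = x$train$use_reg, val_every = x$train$val_every,
    seed = x$train$seed,
    test_frac = x$split$test_frac, n_folds = x$split$n_folds,
    split_seed = x$split$seed)
  cfg
}

#' Patient-level stratified splitting
#'
#' The held-out test set is drawn exclusively from fine-grained branches
#' (stratified by branch stenosis grade); the remaining development pool is
#' partitioned into `n_folds` mutually exclusive folds stratified by
#' granularity and grade. No branch appears in more than one partition.
#'
#' @param manifest data.frame with branch_id, granularity, branch_stenosis.
#' @param test_frac fraction of the full cohort held out for testing.
#' @param n_folds number of cross-validation folds in the development pool.
#' @param seed RNG seed.
#' @return list(test = branch ids, folds = list of branch-id vectors).
#' @export
split_patients <- function(manifest, test_frac = 0.2, n_folds = 5L, seed = 1L) {
  stopifnot(all(c("branch_id", "granularity", "branch_stenosis") %in% names(manifest)))
  n_test <- round(test_frac * nrow(manifest))
  fine <- manifest[manifest$granularity == "fine", ]
  if (n_test > nrow(fine))
    stop("not enough fine-grained branches for the requested test fraction")
  with_seed(seed, {
    ## stratify the test draw over branch grade within the fine subset
    test_ids <- character(0)
    strata <- split(fine$branch_id, fine$branch_stenosis)
    alloc <- vapply(strata, length, integer(1))
    take <- round(alloc / sum(alloc) * n_test)
    excess <- n_test - sum(take)
    if (excess != 0) {
      ord <- order(alloc, decreasing = TRUE)
      for (i in seq_len(abs(excess)))
        take[ord[i]] <- take[ord[i]] + sign(excess)
    }
    for (s in seq_along(strata))
      test_ids <- c(test_ids, sample(strata[[s]], min(take[s], length(strata[[s]]))))
    dev <- manifest[!manifest$branch_id %in% test_ids, ]
    ## round-robin over grade x granularity strata spreads both evenly
    dev_strata <- split(dev$branch_id,
                        interaction(dev$granularity, dev$branch_stenosis, drop = TRUE))
    pool <- unlist(lapply(dev_strata, sample), use.names = FALSE)
    folds <- split(pool, rep_len(seq_len(n_folds), length(pool)))
    names(folds) <- NULL
    list(test = sort(test_ids), folds = lapply(folds, sort))
  })
}

.sample_by_id <- function(dataset, ids) {
  idx <- match(ids, dataset$manifest$branch_id)
  dataset$samples[idx]
}

## Per-branch smooth maximum of stacked segment distributions -> B x 4.
.block_smoothmax <- function(pst, alpha, B, L) {
  blk <- kronecker(diag(B), matrix(1, 1L, L))
  ad_mul(ad_log(ad_matmul(blk, ad_exp(ad_mul(pst, alpha)))), 1 / alpha)
}

## Severity-aware aggregation per branch block of a stacked similarity
## matrix -> B x 4 (identical to aggregate_branch() within each block).
.block_aggregate <- function(S, B, L) {
  blk <- kronecker(diag(B), matrix(1, 1L, L))
  e <- ad_reshape(ad_exp(ad_rowmax(S)), c(B * L, 1L))
  denom <- ad_matmul(t(blk), ad_matmul(blk, e))
  w <- ad_div(e, denom)
  probs <- ad_softmax_rows(S)
  ad_matmul(blk, ad_mul(probs, ad_matmul(w, matrix(1, 1L, 4L))))
}

## Joint loss of one homogeneous batch of branches (node-valued in training).
.batch_objective <- function(params, samples, cfg, bank) {
  has_fine <- samples[[1]]$granularity == "fine"
  outs <- net_forward_multi(params, samples, cfg$model)
  B <- outs$n_branch; L <- outs$L
  if (has_fine) {
    yst <- unlist(lapply(samples, `[[`, "seg_stenosis"))
    ypl <- unlist(lapply(samples, `[[`, "seg_plaque"))
    l_task <- strong_loss(outs$pst, outs$ppl, yst, ypl, cfg$loss$lambda_pl)
  } else {
    S <- similarity_matrix(outs$vgeo, bank)
    yhat <- .block_aggregate(S, B, L)
    ybr <- vapply(samples, `[[`, integer(1), "branch_stenosis")
    l_task <- ad_ce_probs(yhat, ybr)
  }
  if (cfg$train$use_reg) {
    l_mutex <- mutex_loss(outs$pst, outs$ppl, cfg$loss$mutex_unidirectional)
    pg <- if (B == 1L) ad_reshape(outs$pglobal, c(1L, 4L)) else outs$pglobal
    d <- ad_sub(.block_smoothmax(outs$pst, cfg$loss$alpha, B, L), pg)
    l_cons <- ad_mean(ad_mul(d, d))
  } else {
    l_mutex <- 0; l_cons <- 0
  }
  sigma1 <- ad_exp(ad_mul(params$log_var1, 0.5))
  sigma2 <- ad_exp(ad_mul(params$log_var2, 0.5))
  tl <- total_loss(list(l_strong = if (has_fine) l_task else NULL,
                        l_weak = if (has_fine) NULL else l_task,
                        l_mutex = l_mutex, l_cons = l_cons,
                        sigma1 = sigma1, sigma2 = sigma2), has_fine)
  list(total = tl$l_total, task = ad_val(l_task), outs = outs)
}

#' Train the network on a phantom dataset
#'
#' Warm-up epochs use strong (fine-grained) batches only; the prototype bank
#' is then initialised by K-means on the pooled geometric embeddings and
#' updated by EMA on every subsequent strong batch. Batches are homogeneous
#' in granularity. Model selection (when validation ids are given) uses the
#' mean of the stenosis and plaque macro-F1 on the fine validation branches.
#'
#' @param dataset a `vessel_dataset`.
#' @param cfg a [run_config()].
#' @param train_ids,val_ids branch ids (default: all branches train, no
#'   validation).
#' @param verbose print per-epoch progress.
#' @return object of class `vessel_model`: list(params, prototypes, cfg,
#'   history, mcfg).
#' @export
train_model <- function(dataset, cfg, train_ids = NULL, val_ids = NULL,
                        verbose = FALSE) {
  man <- dataset$manifest
  if (is.null(train_ids)) train_ids <- man$branch_id
  set.seed(cfg$train$seed)
  s0 <- dataset$samples[[1]]
  H <- dim(s0$xmpr)[2]; W <- dim(s0$xmpr)[3]; D <- dim(s0$x3d)[2]
  net <- vessel_net_init(cfg$model, H, W, D, seed = cfg$train$seed)
  arch <- net[c("h", "w", "H", "W", "D")]
  params <- params_to_nodes(net[setdiff(names(net), names(arch))])
  params <- c(params, arch)
  opt <- adam_new(params, lr = cfg$optim$lr)

  tr_man <- man[man$branch_id %in% train_ids, ]
  fine_ids <- tr_man$branch_id[tr_man$granularity == "fine"]
  coarse_ids <- tr_man$branch_id[tr_man$granularity == "coarse"]
  if (length(fine_ids) == 0) stop("training requires at least one fine-grained branch")

  epochs <- cfg$optim$epochs
  warmup <- max(0L, round(cfg$train$warmup_frac * epochs))
  bank <- NULL
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        task = numeric(0), val_score = numeric(0))
  best <- list(score = -Inf, params = NULL, bank = NULL)

  chunk <- function(ids, k) if (length(ids)) split(ids, ceiling(seq_along(ids) / k)) else list()

  for (epoch in seq_len(epochs)) {
    if (epoch == warmup + 1L) {
      pv <- params_to_values(params)
      fsm <- .sample_by_id(dataset, fine_ids)
      pool <- lapply(split(fsm, ceiling(seq_along(fsm) / 8)), function(ss) {
        net_forward_multi(pv, ss, cfg$model)$vgeo
      })
      bank <- init_prototypes(do.call(rbind, pool),
                              unlist(lapply(fsm, `[[`, "seg_stenosis")),
                              mu = cfg$loss$mu, seed = cfg$train$seed)
    }
    use_coarse <- cfg$train$use_weak && !is.null(bank) && length(coarse_ids) > 0
    batches <- c(lapply(chunk(sample(fine_ids), cfg$optim$batch_size),
                        function(b) list(ids = b, fine = TRUE)),
                 if (use_coarse)
                   lapply(chunk(sample(coarse_ids), cfg$optim$batch_size),
                          function(b) list(ids = b, fine = FALSE)))
    batches <- sample(batches)
    ep_loss <- 0; ep_task <- 0; nb <- 0L
    for (bt in batches) {
      ad_zero_grad(params)
      ss <- .sample_by_id(dataset, bt$ids)
      ob <- .batch_objective(params, ss, cfg, bank)
      total <- ob$total
      if (!is.finite(ad_val(total)))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      ad_backward(total)
      adam_step(opt)
      if (bt$fine && !is.null(bank))
        bank <- update_prototypes(bank, ad_val(ob$outs$vgeo),
                                  unlist(lapply(ss, `[[`, "seg_stenosis")))
      ep_loss <- ep_loss + ad_val(total)
      ep_task <- ep_task + ob$task
      nb <- nb + 1L
    }
    val_score <- NA_real_
    if (length(val_ids) && (epoch %% cfg$train$val_every == 0L || epoch == epochs)) {
      snap <- structure(c(params_to_values(params[setdiff(names(params), names(arch))]),
                          arch), class = "vessel_net")
      m <- structure(list(params = snap, prototypes = bank, cfg = cfg,
                          mcfg = cfg$model), class = "vessel_model")
      ev <- evaluate_model(m, dataset, val_ids)
      val_score <- if (!is.null(ev$stenosis))
        (ev$stenosis$macro["f1"] + ev$plaque$macro["f1"]) / 2
      else ev$branch$acc_global
      if (val_score > best$score)
        best <- list(score = val_score, params = snap, bank = bank)
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / max(nb, 1L),
                                         task = ep_task / max(nb, 1L),
                                         val_score = val_score))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  task %.4f  val %s", epoch,
                      ep_loss / max(nb, 1L), ep_task / max(nb, 1L),
                      ifelse(is.na(val_score), "-", sprintf("%.3f", val_score))))
  }
  final <- if (!is.null(best$params)) best$params else
    structure(c(params_to_values(params[setdiff(names(params), names(arch))]),
                arch), class = "vessel_net")
  final_bank <- if (!is.null(best$params)) best$bank else bank
  structure(list(params = final, prototypes = final_bank, cfg = cfg,
                 mcfg = cfg$model, history = history),
            class = "vessel_model")
}

#' @export
print.vessel_model <- function(x, ...) {
  cat("<vessel_model C=", x$mcfg$C, ", trained ",
      if (!is.null(x$history)) max(x$history$epoch) else 0, " epochs>\n", sep = "")
  invisible(x)
}

#' Predict stenosis/plaque labels for one branch
#' @param model a `vessel_model`; @param sample a `vessel_sample`.
#' @return list(st L, pl L, branch_global, branch_maxseg, outs).
#' @export
predict_sample <- function(model, sample) {
  outs <- net_forward(model$params, sample, model$mcfg)
  st <- max.col(outs$pst, ties.method = "first") - 1L
  pl <- max.col(outs$ppl, ties.method = "first") - 1L
  list(st = st, pl = pl,
       branch_global = which.max(outs$pglobal) - 1L,
       branch_maxseg = max(st),
       outs = outs)
}

#' Evaluate a trained model on a set of branches
#'
#' Segment-level stenosis and plaque metrics are computed on the fine
#' branches; branch-level accuracy is reported both from the auxiliary
#' global head (argmax of its distribution) and from the maximum of the
#' per-segment predictions.
#'
#' @param model a `vessel_model`; @param dataset a `vessel_dataset`;
#' @param ids branch ids to evaluate (default all).
#' @return list(stenosis, plaque, branch, tables).
#' @export
evaluate_model <- function(model, dataset, ids = NULL) {
  man <- dataset$manifest
  if (is.null(ids)) ids <- man$branch_id
  st_t <- integer(0); st_p <- integer(0)
  pl_t <- integer(0); pl_p <- integer(0)
  br_t <- integer(0); br_g <- integer(0); br_m <- integer(0)
  samples <- .sample_by_id(dataset, ids)
  for (chunk in split(samples, ceiling(seq_along(samples) / 8))) {
    outs <- net_forward_multi(model$params, chunk, model$mcfg)
    L <- outs$L
    st_all <- max.col(outs$pst, ties.method = "first") - 1L
    pl_all <- max.col(outs$ppl, ties.method = "first") - 1L
    pg <- if (outs$n_branch == 1L) matrix(outs$pglobal, 1L, 4L) else outs$pglobal
    for (b in seq_along(chunk)) {
      s <- chunk[[b]]
      rows <- (b - 1L) * L + seq_len(L)
      if (s$granularity == "fine") {
        st_t <- c(st_t, s$seg_stenosis); st_p <- c(st_p, st_all[rows])
        pl_t <- c(pl_t, s$seg_plaque); pl_p <- c(pl_p, pl_all[rows])
      }
      br_t <- c(br_t, s$branch_stenosis)
      br_g <- c(br_g, which.max(pg[b, ]) - 1L)
      br_m <- c(br_m, max(st_all[rows]))
    }
  }
  out <- list(branch = list(acc_global = mean(br_g == br_t),
                            acc_maxseg = mean(br_m == br_t)))
  if (length(st_t)) {
    stab <- confusion_table(st_t, st_p, c("normal", "mild", "moderate", "severe"))
    ptab <- confusion_table(pl_t, pl_p, c("absent", "calcified", "noncalc", "mixed"))
    out$stenosis <- suppressWarnings(macro_metrics(stab))
    out$plaque <- suppressWarnings(macro_metrics(ptab))
    out$tables <- list(stenosis = stab, plaque = ptab)
  }
  out
}

#' Save / load a trained model (RDS)
#' @param model a `vessel_model`; @param path file path.
#' @export
save_model <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
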