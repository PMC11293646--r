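# Dense SELU network discriminating genuine pre-miRNA structures from
# decoys, written in plain matrix numerics: seven hidden layers with SELU
# activation, optional batch normalisation and alpha-dropout, a 2-way
# softmax head, cross-entropy loss, Adam, early stopping on a validation
# split. Deterministic given the seed.

.selu_lambda <- 1.0507009873554805
.selu_alpha <- 1.6732632423543772

selu <- function(x) .selu_lambda * ifelse(x > 0, x, .selu_alpha * (exp(x) - 1))
selu_grad <- function(x) .selu_lambda * ifelse(x > 0, 1, .selu_alpha * exp(x))

#' Network and training specification
#'
#' Defaults: seven hidden layers with widths geometric from 256 down to 8,
#' SELU activations, batch normalisation on, alpha-dropout 0.1, Adam
#' (learning rate 1e-3), batch size 64, up to `epochs` passes with early
#' stopping (patience `patience`) on a 10% stratified validation split.
#'
#' @param hidden Integer vector of hidden-layer widths (7 layers by default).
#' @param dropout Alpha-dropout rate per hidden layer.
#' @param batch_norm Use batch normalisation.
#' @param epochs,batch_size,lr,patience,val_fraction Training controls.
#' @return A `model_spec` list.
#' @export
model_spec <- function(hidden = c(256L, 144L, 81L, 45L, 25L, 14L, 8L),
                       dropout = 0.1, batch_norm = TRUE, epochs = 60L,
                       batch_size = 64L, lr = 1e-3, patience = 8L,
                       val_fraction = 0.1) {
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 batch_norm = batch_norm, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience),
                 val_fraction = val_fraction),
            class = "model_spec")
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features)) features <- matrix(features, nrow = length(features))
  storage.mode(features) <- "double"
  features
}

init_params <- function(d_in, spec) {
  widths <- c(d_in, spec$hidden)
  layers <- list()
  for (l in seq_along(spec$hidden)) {
    fan_in <- widths[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * widths[l + 1], sd = 1 / sqrt(fan_in)),
                 fan_in, widths[l + 1]),
      b = rep(0, widths[l + 1]),
      gamma = rep(1, widths[l + 1]), beta = rep(0, widths[l + 1]),
      run_mean = rep(0, widths[l + 1]), run_var = rep(1, widths[l + 1]))
  }
  out <- list(W = matrix(rnorm(tail(widths, 1) * 2,
                               sd = 1 / sqrt(tail(widths, 1))),
                         tail(widths, 1), 2),
              b = rep(0, 2))
  list(layers = layers, out = out)
}

bn_eps <- 1e-5

forward_mlp <- function(params, X, spec, training = FALSE) {
  caches <- list()
  A <- X
  q <- 1 - spec$dropout
  ap <- -.selu_lambda * .selu_alpha
  a_scale <- (q + ap^2 * q * (1 - q))^(-0.5)
  b_shift <- -a_scale * (1 - q) * ap
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    Z <- A %*% ly$W
    if (!spec$batch_norm) Z <- sweep(Z, 2, ly$b, "+")
    if (spec$batch_norm) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(sweep(Z, 2, mu)^2)
      } else {
        mu <- ly$run_mean; v <- ly$run_var
      }
      Zh <- sweep(sweep(Z, 2, mu), 2, sqrt(v + bn_eps), "/")
      Y <- sweep(sweep(Zh, 2, ly$gamma, "*"), 2, ly$beta, "+")
    } else {
      Zh <- NULL; Y <- Z; mu <- NULL; v <- NULL
    }
    S <- selu(Y)
    if (training && spec$dropout > 0) {
      mask <- matrix(runif(length(S)) < q, nrow(S), ncol(S))
      D <- a_scale * (S * mask + ap * (1 - mask)) + b_shift
    } else {
      mask <- NULL
      D <- S
    }
    caches[[l]] <- list(A_in = A, Z = Z, Zh = Zh, Y = Y, mu = mu, v = v,
                        mask = mask)
    A <- D
  }
  Zo <- sweep(A %*% params$out$W, 2, params$out$b, "+")
  Zo <- Zo - apply(Zo, 1, max)
  P <- exp(Zo) / rowSums(exp(Zo))
  list(P = P, A_last = A, caches = caches,
       a_scale = a_scale, ap = ap)
}

backward_mlp <- function(params, fw, Y1, spec) {
  n <- nrow(fw$P)
  Yoh <- cbind(1 - Y1, Y1)
  dZo <- (fw$P - Yoh) / n
  grads <- list(out = list(W = t(fw$A_last) %*% dZo, b = colSums(dZo)),
                layers = vector("list", length(params$layers)))
  dA <- dZo %*% t(params$out$W)
  for (l in rev(seq_along(params$layers))) {
    ly <- params$layers[[l]]
    ch <- fw$caches[[l]]
    dS <- if (!is.null(ch$mask)) dA * (fw$a_scale * ch$mask) else dA
    dY <- dS * selu_grad(ch$Y)
    if (spec$batch_norm) {
      dgamma <- colSums(dY * ch$Zh)
      dbeta <- colSums(dY)
      dZh <- sweep(dY, 2, ly$gamma, "*")
      inv <- 1 / sqrt(ch$v + bn_eps)
      m1 <- colMeans(dZh)
      m2 <- colMeans(dZh * ch$Zh)
      dZ <- sweep(sweep(dZh, 2, m1) - sweep(ch$Zh, 2, m2, "*"), 2, inv, "*")
      grads$layers[[l]] <- list(W = t(ch$A_in) %*% dZ, b = rep(0, length(ly$b)),
                                gamma = dgamma, beta = dbeta)
    } else {
      dZ <- dY
      grads$layers[[l]] <- list(W = t(ch$A_in) %*% dZ, b = colSums(dZ),
                                gamma = NULL, beta = NULL)
    }
    dA <- dZ %*% t(ly$W)
  }
  grads
}

adam_state <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else
    rep(0, length(x))
  rapply(params, zero_like, how = "replace")
}

adam_update <- function(params, grads, m, v, t, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  upd <- function(p, g, mm, vv) {
    mm <- b1 * mm + (1 - b1) * g
    vv <- b2 * vv + (1 - b2) * g^2
    mh <- mm / (1 - b1^t); vh <- vv / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = mm, v = vv)
  }
  for (l in seq_along(params$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      g <- grads$layers[[l]][[nm]]
      if (is.null(g)) next
      u <- upd(params$layers[[l]][[nm]], g, m$layers[[l]][[nm]],
               v$layers[[l]][[nm]])
      params$layers[[l]][[nm]] <- u$p
      m$layers[[l]][[nm]] <- u$m
      v$layers[[l]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(params$out[[nm]], grads$out[[nm]], m$out[[nm]], v$out[[nm]])
    params$out[[nm]] <- u$p
    m$out[[nm]] <- u$m
    v$out[[nm]] <- u$v
  }
  list(params = params, m = m, v = v)
}

xent <- function(P, y1) {
  p <- ifelse(y1 == 1, P[, 2], P[, 1])
  -mean(log(pmax(p, 1e-12)))
}

#' Train the pre-miRNA/decoy classifier
#'
#' Features are z-scored with training statistics (stored in the model);
#' labels are binary. Training is deterministic given `seed`.
#'
#' @param features Numeric matrix or data frame (rows = candidates).
#' @param labels Binary vector (0 = decoy, 1 = miRNA), or a factor.
#' @param spec A [model_spec()].
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return A `pm_mlp` model exposing [predict_proba()].
#' @export
train <- function(features, labels, spec = model_spec(), seed = 1L) {
  X <- as_feature_matrix(features)
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2L)
    abort_argument("training labels contain a single class")
  if (length(y) != nrow(X))
    abort_argument("features and labels differ in length")
  set.seed(seed)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd); sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  # stratified validation split
  n <- nrow(Xs)
  val_idx <- integer(0)
  if (spec$val_fraction > 0 && n >= 20) {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      nv <- max(1L, floor(length(idx) * spec$val_fraction))
      val_idx <- c(val_idx, sample(idx, nv))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  params <- init_params(ncol(Xs), spec)
  m <- adam_state(params); v <- adam_state(params)
  t <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample(tr_idx)
    for (start in seq(1, length(ord), by = spec$batch_size)) {
      bidx <- ord[start:min(start + spec$batch_size - 1, length(ord))]
      if (length(bidx) < 2L) next
      fw <- forward_mlp(params, Xs[bidx, , drop = FALSE], spec,
                        training = TRUE)
      # update running batch-norm statistics
      if (spec$batch_norm) {
        for (l in seq_along(params$layers)) {
          ch <- fw$caches[[l]]
          params$layers[[l]]$run_mean <-
            0.9 * params$layers[[l]]$run_mean + 0.1 * ch$mu
          params$layers[[l]]$run_var <-
            0.9 * params$layers[[l]]$run_var + 0.1 * ch$v
        }
      }
      grads <- backward_mlp(params, fw, y[bidx], spec)
      t <- t + 1L
      st <- adam_update(params, grads, m, v, t, spec$lr)
      params <- st$params; m <- st$m; v <- st$v
    }
    vl <- if (length(val_idx)) {
      fwv <- forward_mlp(params, Xs[val_idx, , drop = FALSE], spec,
                         training = FALSE)
      xent(fwv$P, y[val_idx])
    } else {
      fwt <- forward_mlp(params, Xs[tr_idx, , drop = FALSE], spec,
                         training = FALSE)
      xent(fwt$P, y[tr_idx])
    }
    history <- c(history, vl)
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  structure(list(params = best$params, spec = spec, center = mu, scale = sdv,
                 n_features = ncol(X), feature_names = colnames(X),
                 classes = levels(as.factor(labels)),
                 val_loss = best$loss, epochs_run = length(history),
                 best_epoch = best$epoch, history = history, seed = seed),
            class = "pm_mlp")
}

#' Probability of the positive class
#'
#' @param model A `pm_mlp` from [train()].
#' @param features Numeric matrix/data frame with the training width.
#' @return Numeric vector of probabilities in `[0, 1]` (positive class,
#'   i.e. the second factor level of the training labels).
#' @export
predict_proba <- function(model, features) {
  X <- as_feature_matrix(features)
  if (nrow(X) == 0L) return(numeric(0))
  if (ncol(X) != model$n_features)
    abort_argument(sprintf("feature width %d does not match training width %d",
                           ncol(X), model$n_features))
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  fw <- forward_mlp(model$params, Xs, model$spec, training = FALSE)
  as.numeric(fw$P[, 2])
}

#' @export
print.pm_mlp <- function(x, ...) {
  cat(sprintf("<pm_mlp> %d features -> [%s] -> softmax(2); %d epochs (best %d), val loss %.4f\n",
              x$n_features, paste(x$spec$hidden, collapse = ", "),
              x$epochs_run, x$best_epoch, x$val_loss))
  invisible(x)
}

#' @export
predict.pm_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Classification metrics
#'
#' Accuracy, sensitivity, specificity, precision, F1, Matthews correlation
#' coefficient and AUC (rank/Mann-Whitney statistic with midrank tie
#' correction) at the given decision threshold.
#'
#' @param labels Binary labels.
#' @param scores Scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble of the seven metrics. With a single class
#'   present, AUC and MCC are `NA` with a warning.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) == 1L && length(y) > 0) {
    warn("one class absent: AUC and MCC are undefined")
    one_class <- TRUE
  } else one_class <- FALSE
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  acc <- (tp + tn) / length(y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  mcc <- if (one_class) NA_real_ else {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }
  auc <- if (one_class) NA_real_ else {
    r <- rank(scores) # midranks handle ties
    np <- sum(y == 1); nn <- sum(y == 0)
    (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
  }
  tibble(accuracy = acc, sensitivity = sens, specificity = spec,
         precision = prec, f1 = f1, mcc = mcc, auc = auc)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (k > length(idx))
      abort_argument(sprintf("k = %d exceeds class size %d", k, length(idx)))
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Positives and negatives are partitioned separately into `k` folds
#' (paired positive/negative partitioning); each fold is held out once.
#'
#' @param features Numeric matrix/data frame.
#' @param labels Binary labels.
#' @param k Number of folds (default 10).
#' @param spec A [model_spec()].
#' @param seed Seed for fold assignment and per-fold training.
#' @param threshold Decision threshold.
#' @return A `pm_metrics_report`: per-fold metric tibble plus mean/sd
#'   summary. [tidy()] gives the folds, [glance()] the means.
#' @export
kfold_cv <- function(features, labels, k = 10L, spec = model_spec(),
                     seed = 1L, threshold = 0.5) {
  X <- as_feature_matrix(features)
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2L) abort_argument("both classes required")
  if (k < 2L) abort_argument("k must be at least 2")
  set.seed(seed)
  fold <- stratified_folds(y, k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    model <- train(X[tr, , drop = FALSE], y[tr], spec, seed = seed + f)
    p <- predict_proba(model, X[te, , drop = FALSE])
    rows[[f]] <- dplyr::mutate(compute_metrics(y[te], p, threshold),
                               fold = f, n_test = length(te), .before = 1)
  }
  folds <- dplyr::bind_rows(rows)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "precision",
                   "f1", "mcc", "auc")
  summary <- tibble(metric = metric_cols,
                    mean = vapply(metric_cols, function(m)
                      mean(folds[[m]], na.rm = TRUE), 1.0),
                    sd = vapply(metric_cols, function(m)
                      sd(folds[[m]], na.rm = TRUE), 1.0))
  structure(list(folds = folds, summary = summary, k = k,
                 fold_assignment = fold, seed = seed),
            class = "pm_metrics_report")
}

#' @export
print.pm_metrics_report <- function(x, ...) {
  cat(sprintf("<pm_metrics_report> %d folds; mean +/- sd:\n", x$k))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Leave-one-group-out (versatility) evaluation
#'
#' For each group (e.g. species), the model is trained on all other groups
#' and evaluated on the held-out group; train and test are disjoint by
#' construction.
#'
#' @param features Numeric matrix/data frame.
#' @param labels Binary labels.
#' @param groups Group identifier per row (at least two distinct groups).
#' @param spec A [model_spec()].
#' @param seed Seed.
#' @param threshold Decision threshold.
#' @return A tibble with one metric row per held-out group; the train/test
#'   index split is recorded in `attr(, "splits")`.
#' @export
leave_one_group_out <- function(features, labels, groups,
                                spec = model_spec(), seed = 1L,
                                threshold = 0.5) {
  X <- as_feature_matrix(features)
  y <- as.integer(as.factor(labels)) - 1L
  g <- as.character(groups)
  ug <- unique(g)
  if (length(ug) < 2L) abort_argument("at least two groups required")
  splits <- list()
  rows <- list()
  for (grp in ug) {
    te <- which(g == grp); tr <- which(g != grp)
    splits[[grp]] <- list(train = tr, test = te)
    model <- train(X[tr, , drop = FALSE], y[tr], spec,
                   seed = seed + match(grp, ug))
    p <- predict_proba(model, X[te, , drop = FALSE])
    rows[[grp]] <- dplyr::mutate(compute_metrics(y[te], p, threshold),
                                 group = grp, n_test = length(te),
                                 .before = 1)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "splits") <- splits
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pm_metrics_report <- function(x, ...) x$folds

#' @export
glance.pm_metrics_report <- function(x, ...) {
  out <- as.list(setNames(x$summary$mean, x$summary$metric))
  out$k <- x$k
  as_tibble(out)
}

#' @export
tidy.pm_mlp <- function(x, ...) {
  widths <- c(x$n_features, x$spec$hidden)
  tibble(layer = seq_along(x$spec$hidden),
         units = x$spec$hidden,
         n_weights = widths[-length(widths)] * x$spec$hidden,
         activation = "selu",
         batch_norm = x$spec$batch_norm,
         dropout = x$spec$dropout)
}

#' @export
glance.pm_mlp <- function(x, ...) {
  tibble(n_features = x$n_features, hidden_layers = length(x$spec$hidden),
         epochs_run = x$epochs_run, best_epoch = x$best_epoch,
         val_loss = x$val_loss)
}
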