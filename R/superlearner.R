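## ---- learner registry -----------------------------------------------------
## each learner: list(fit = function(x, y, control) model,
##                    predict = function(model, x) probabilities)
## x is always a data.frame of covariates, y a 0/1 vector.

## design matrix shared by the glmnet learner (drop intercept column)
sl_design <- function(x) {
  m <- stats::model.matrix(~., data = x)[, -1, drop = FALSE]
  if (ncol(m) < 2L) m <- cbind(m, ..pad = 0)  # glmnet needs >= 2 columns
  m
}

sl_learner_registry <- function(control) {
  list(
    mean = list(  # intercept-only: deliberately uninformative baseline
      fit = function(x, y, ctl) mean(y),
      predict = function(model, x) rep(model, nrow(x))),
    glm = list(
      fit = function(x, y, ctl) {
        d <- cbind(..y = y, x)
        suppressWarnings(stats::glm(..y ~ ., stats::binomial(), data = d))
      },
      predict = function(model, x)
        suppressWarnings(stats::predict(model, newdata = x, type = "response"))),
    glm_interaction = list(
      fit = function(x, y, ctl) {
        d <- cbind(..y = y, x)
        suppressWarnings(stats::glm(..y ~ .^2, stats::binomial(), data = d))
      },
      predict = function(model, x)
        suppressWarnings(stats::predict(model, newdata = x, type = "response"))),
    glmnet = list(
      fit = function(x, y, ctl) {
        glmnet::cv.glmnet(sl_design(x), y, family = "binomial",
                          alpha = ctl$enet_alpha,
                          nfolds = ctl$glmnet_nfolds)
      },
      predict = function(model, x)
        as.numeric(stats::predict(model, newx = sl_design(x),
                                  s = "lambda.min", type = "response"))),
    xgboost = list(
      fit = function(x, y, ctl) {
        dm <- xgboost::xgb.DMatrix(sl_design(x), label = y)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = ctl$xgb_max_depth, eta = ctl$xgb_eta,
                        nthread = 1),
          data = dm, nrounds = ctl$xgb_nrounds, verbose = 0)
      },
      predict = function(model, x)
        as.numeric(stats::predict(model, xgboost::xgb.DMatrix(sl_design(x))))),
    random_forest = list(
      fit = function(x, y, ctl)
        randomForest::randomForest(x, factor(y, levels = 0:1),
                                   ntree = ctl$rf_ntree),
      predict = function(model, x)
        as.numeric(stats::predict(model, newdata = x, type = "prob")[, "1"]))
  )
}

#' Default Super Learner control settings
#'
#' Hyperparameters of the candidate learners: elastic-net mixing
#' `enet_alpha` (0.5) with internal `glmnet_nfolds` (5) lambda selection,
#' gradient boosting with `xgb_nrounds` (100) depth-`xgb_max_depth` (3)
#' trees at learning rate `xgb_eta` (0.1), and `rf_ntree` (500) random-forest
#' trees. Override any entry via the `control` argument of
#' [superlearner_fit()].
#'
#' @return named list of defaults.
#' @export
sl_control <- function() {
  list(enet_alpha = 0.5, glmnet_nfolds = 5L,
       xgb_nrounds = 100L, xgb_max_depth = 3L, xgb_eta = 0.1,
       rf_ntree = 500L)
}

## mean negative log-likelihood of probabilities p for outcome y
neg_log_lik <- function(y, p) {
  p <- clip_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Cross-validated Super Learner ensemble for a binary target
#'
#' Fits the requested candidate learners, obtains V-fold cross-validated
#' predictions for each, chooses convex ensemble weights minimizing the
#' cross-validated negative log-likelihood, and refits every learner on the
#' full data. The default library mirrors the five-model ensemble used for
#' nuisance estimation in the targeted-learning stage: main-terms logistic
#' regression, all-pairwise-interaction logistic regression, elastic-net
#' logistic regression, gradient-boosted trees, and random forest. A learner
#' that errors is excluded with weight zero and logged — never a crash.
#'
#' With a single requested learner the cross-validation layer is skipped and
#' the ensemble is exactly that learner.
#'
#' @param x data.frame of features.
#' @param y 0/1 target vector.
#' @param learners character vector of learner names among `"mean"`,
#'   `"glm"`, `"glm_interaction"`, `"glmnet"`, `"xgboost"`,
#'   `"random_forest"`.
#' @param v_folds number of cross-validation folds (default 10), stratified
#'   on the target.
#' @param seed optional integer seed for fold assignment and the stochastic
#'   learners.
#' @param control hyperparameter list, see [sl_control()].
#' @return object of class `"sl_fit"` with elements `weights`,
#'   `cv_logloss` (per learner and `ensemble`), `failed`, and a
#'   [predict.sl_fit()] method returning probabilities clipped to
#'   (1e-6, 1 - 1e-6).
#' @export
superlearner_fit <- function(x, y,
                             learners = c("glm", "glm_interaction", "glmnet",
                                          "xgboost", "random_forest"),
                             v_folds = 10L, seed = NULL,
                             control = list()) {
  stopifnot(is.data.frame(x), nrow(x) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2L) stop("both target classes must be present")
  ctl <- utils::modifyList(sl_control(), control)
  registry <- sl_learner_registry(ctl)
  unknown <- setdiff(learners, names(registry))
  if (length(unknown)) stop("unknown learner(s): ", paste(unknown, collapse = ", "))

  with_local_seed(seed, {
    n <- length(y)
    failed <- character()
    fit_one <- function(nm, xd, yd) {
      tryCatch(registry[[nm]]$fit(xd, yd, ctl), error = function(e) {
        message("learner '", nm, "' failed: ", conditionMessage(e))
        NULL
      })
    }
    pred_one <- function(nm, model, xd) {
      tryCatch(clip_prob(registry[[nm]]$predict(model, xd)),
               error = function(e) NULL)
    }

    cv_logloss <- stats::setNames(rep(NA_real_, length(learners)), learners)
    if (length(learners) > 1L) {
      ## stratified fold assignment
      fold <- integer(n)
      for (cls in 0:1) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep(seq_len(v_folds), length.out = length(idx)))
      }
      z <- matrix(NA_real_, n, length(learners),
                  dimnames = list(NULL, learners))
      for (nm in learners) {
        ok <- TRUE
        for (v in seq_len(v_folds)) {
          tr <- fold != v
          m <- fit_one(nm, x[tr, , drop = FALSE], y[tr])
          p <- if (is.null(m)) NULL else
            pred_one(nm, m, x[!tr, , drop = FALSE])
          if (is.null(p)) { ok <- FALSE; break }
          z[!tr, nm] <- p
        }
        if (!ok) failed <- c(failed, nm)
      }
      kept <- setdiff(learners, failed)
      if (length(kept) == 0L) stop("all Super Learner candidates failed")
      zk <- z[, kept, drop = FALSE]
      cv_logloss[kept] <- apply(zk, 2, function(p) neg_log_lik(y, p))
      if (length(kept) == 1L) {
        w <- stats::setNames(1, kept)
      } else {
        obj <- function(beta) {
          wv <- exp(c(0, beta)); wv <- wv / sum(wv)
          neg_log_lik(y, as.numeric(zk %*% wv))
        }
        ## start from the discrete best single learner
        opt <- stats::optim(rep(0, length(kept) - 1L), obj, method = "BFGS",
                            control = list(maxit = 200))
        wv <- exp(c(0, opt$par)); wv <- wv / sum(wv)
        w <- stats::setNames(wv, kept)
      }
      ens_logloss <- neg_log_lik(y, as.numeric(zk %*% w))
    } else {
      kept <- learners
      w <- stats::setNames(1, learners)
      ens_logloss <- NA_real_
    }

    ## refit retained learners on the full data
    models <- list()
    for (nm in kept) {
      m <- fit_one(nm, x, y)
      if (is.null(m)) {
        failed <- c(failed, nm)
        w <- w[names(w) != nm]
      } else models[[nm]] <- m
    }
    if (length(models) == 0L) stop("all Super Learner candidates failed")
    w <- w / sum(w)

    structure(list(models = models, weights = w, registry_names = names(w),
                   control = ctl, feature_names = names(x),
                   cv_logloss = c(cv_logloss, ensemble = ens_logloss),
                   failed = unique(failed)),
              class = "sl_fit")
  })
}

#' Predict from a fitted Super Learner ensemble
#'
#' @param object an `"sl_fit"` from [superlearner_fit()].
#' @param newdata data.frame with the training feature columns.
#' @param ... unused.
#' @return numeric vector of probabilities in (1e-6, 1 - 1e-6).
#' @export
predict.sl_fit <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  registry <- sl_learner_registry(object$control)
  newdata <- newdata[, object$feature_names, drop = FALSE]
  p <- rep(0, nrow(newdata))
  for (nm in names(object$weights)) {
    p <- p + object$weights[[nm]] *
      clip_prob(registry[[nm]]$predict(object$models[[nm]], newdata))
  }
  clip_prob(p)
}
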