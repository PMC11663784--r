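# Learner registry: six standard classifiers behind one fit/predict
# surface. `fit` takes a samples x genes matrix and a 0/1 outcome and
# returns a self-contained payload; `predict` returns P(class 1).
# Hyperparameter grids are small and fixed; they are searched inside the
# cross-validation loop of train_and_select().

# glmnet requires at least two predictor columns; a constant dummy column
# (which can never be selected, its coefficient stays 0) makes single-gene
# panels fittable without changing the fit on the real gene.
glmnet_pad <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, .pad = 0)
}

learner_registry <- function() {
  list(
    elastic_net = list(
      grid = list(list(lambda = 0.1), list(lambda = 0.01)),
      fit = function(x, y, hyper, seed) {
        local_seed(seed, {
          fit <- glmnet::glmnet(glmnet_pad(x), y, family = "binomial",
                                alpha = 0.5)
          list(fit = fit, lambda = hyper$lambda)
        })
      },
      predict = function(payload, x) {
        as.numeric(stats::predict(payload$fit, glmnet_pad(x),
                                  s = payload$lambda, type = "response"))
      },
      importance = function(payload, genes) {
        b <- as.matrix(stats::coef(payload$fit, s = payload$lambda))[-1, 1]
        abs(b)[genes]
      }
    ),
    boosted_trees = list(
      grid = list(list(nrounds = 50, max_depth = 2),
                  list(nrounds = 50, max_depth = 3)),
      fit = function(x, y, hyper, seed) {
        local_seed(seed, {
          dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
          fit <- xgboost::xgb.train(
            params = list(objective = "binary:logistic", eta = 0.3,
                          max_depth = hyper$max_depth, nthread = 1,
                          seed = seed),
            data = dm, nrounds = hyper$nrounds, verbose = 0)
          list(raw = xgboost::xgb.save.raw(fit), genes = colnames(x))
        })
      },
      predict = function(payload, x) {
        fit <- xgboost::xgb.load.raw(payload$raw)
        as.numeric(stats::predict(
          fit, xgboost::xgb.DMatrix(x[, payload$genes, drop = FALSE],
                                    nthread = 1)))
      },
      importance = function(payload, genes) {
        fit <- xgboost::xgb.load.raw(payload$raw)
        imp <- xgboost::xgb.importance(model = fit)
        out <- setNames(rep(0, length(genes)), genes)
        out[imp$Feature] <- imp$Gain
        out
      }
    ),
    l1_logistic = list(
      grid = list(list(lambda = 0.1), list(lambda = 0.01)),
      fit = function(x, y, hyper, seed) {
        local_seed(seed, {
          fit <- glmnet::glmnet(glmnet_pad(x), y, family = "binomial",
                                alpha = 1)
          list(fit = fit, lambda = hyper$lambda)
        })
      },
      predict = function(payload, x) {
        as.numeric(stats::predict(payload$fit, glmnet_pad(x),
                                  s = payload$lambda, type = "response"))
      },
      importance = function(payload, genes) {
        b <- as.matrix(stats::coef(payload$fit, s = payload$lambda))[-1, 1]
        abs(b)[genes]
      }
    ),
    neural_net = list(
      grid = list(list(size = 3, decay = 0.1)),
      fit = function(x, y, hyper, seed) {
        ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
        xs <- scale(x, center = ctr, scale = scl)
        fit <- local_seed(seed, {
          nnet::nnet(xs, y, size = hyper$size, decay = hyper$decay,
                     maxit = 300, trace = FALSE, entropy = TRUE)
        })
        list(fit = fit, center = ctr, scale = scl)
      },
      predict = function(payload, x) {
        xs <- scale(x[, names(payload$center), drop = FALSE],
                    center = payload$center, scale = payload$scale)
        as.numeric(stats::predict(payload$fit, xs))
      },
      importance = NULL
    ),
    random_forest = list(
      grid = list(list(ntree = 300)),
      fit = function(x, y, hyper, seed) {
        fit <- local_seed(seed, {
          randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                     ntree = hyper$ntree, importance = FALSE)
        })
        list(fit = fit)
      },
      predict = function(payload, x) {
        as.numeric(stats::predict(payload$fit, x, type = "prob")[, "1"])
      },
      importance = function(payload, genes) {
        imp <- payload$fit$importance[, "MeanDecreaseGini"]
        out <- setNames(rep(0, length(genes)), genes)
        out[names(imp)] <- imp
        out
      }
    ),
    svm = list(
      grid = list(list(cost = 1)),
      fit = function(x, y, hyper, seed) {
        fit <- local_seed(seed, {
          e1071::svm(x, factor(y, levels = c(0, 1)), cost = hyper$cost,
                     kernel = "radial", probability = TRUE)
        })
        list(fit = fit)
      },
      predict = function(payload, x) {
        pr <- stats::predict(payload$fit, x, probability = TRUE)
        as.numeric(attr(pr, "probabilities")[, "1"])
      },
      importance = NULL
    )
  )
}

learner_fit <- function(algorithm, x, y, hyper, seed) {
  reg <- learner_registry()
  if (!algorithm %in% names(reg)) {
    abort(paste0("unknown algorithm: ", algorithm), "radresp_validation_error")
  }
  reg[[algorithm]]$fit(x, y, hyper, seed)
}

learner_predict <- function(algorithm, payload, x) {
  # restored payloads dispatch S3 predict methods of the backing package,
  # which must be loaded even when no :: call touches it first
  backing <- c(elastic_net = "glmnet", l1_logistic = "glmnet",
               boosted_trees = "xgboost", neural_net = "nnet",
               random_forest = "randomForest", svm = "e1071")
  requireNamespace(backing[[algorithm]], quietly = TRUE)
  learner_registry()[[algorithm]]$predict(payload, x)
}

learner_importance <- function(algorithm, payload, genes) {
  f <- learner_registry()[[algorithm]]$importance
  if (is.null(f)) return(NULL)
  f(payload, genes)
}
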